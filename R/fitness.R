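#' Sphericity of a mechanical state
#'
#' `1 - cv`, where `cv` is the coefficient of variation of the particle
#' distances to the embryo centroid, clipped to `[0, 1]`. Equals 1 for
#' particles exactly on a sphere and is invariant under rigid motions.
#'
#' @param state A [mech_state()].
#' @return Sphericity in `[0, 1]`.
#' @export
sphericity <- function(state) {
  stopifnot(nrow(state$pos) >= 4)
  d <- sqrt(rowSums(sweep(state$pos, 2, colMeans(state$pos))^2))
  if (mean(d) <= 0) return(0)
  max(0, min(1, 1 - sd(d) / mean(d)))
}

#' Planarity of the epithelial layer
#'
#' Mean local coplanarity over cells: for each cell with at least 3
#' neighbours in the contact graph, the neighbourhood (cell + neighbours) is
#' decomposed by principal components and the local score is
#' `1 - 3 lambda_3 / (lambda_1 + lambda_2 + lambda_3)` (1 for a perfectly
#' flat neighbourhood, 0 for an isotropic cloud). Cells with fewer than 3
#' neighbours are skipped and counted in the `n_skipped` attribute.
#'
#' @param state A [mech_state()].
#' @param params A [mech_params()] (for the contact rule).
#' @return Planarity in `[0, 1]`; attribute `n_skipped`.
#' @export
planarity <- function(state, params = mech_params()) {
  cg <- contact_graph(state, params)
  n <- nrow(state$pos)
  nb <- vector("list", n)
  for (e in seq_len(nrow(cg))) {
    nb[[cg$i[e]]] <- c(nb[[cg$i[e]]], cg$j[e])
    nb[[cg$j[e]]] <- c(nb[[cg$j[e]]], cg$i[e])
  }
  scores <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (length(nb[[i]]) < 3L) next
    pts <- state$pos[c(i, nb[[i]]), , drop = FALSE]
    ctr <- colMeans(pts)
    cov_ <- crossprod(sweep(pts, 2, ctr)) / nrow(pts)
    ev <- sort(eigen(cov_, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    tot <- sum(ev)
    scores[i] <- if (tot <= 0) NA_real_ else 1 - 3 * ev[3] / tot
  }
  ok <- !is.na(scores)
  out <- if (any(ok)) mean(scores[ok]) else 0
  attr(out, "n_skipped") <- sum(!ok)
  out
}

# Micromeres pool into one population for population borders
border_population <- function(type) {
  ifelse(type %in% c("LMic", "SMic"), "Mic", type)
}

#' Descriptor of the borders between cell populations
#'
#' For each population border (Mic/Mac and Mac/Mes by default), summarises
#' the heterotypic interface in the contact graph by (i) the number of
#' heterotypic contact edges and (ii) the interface tortuosity: the rms
#' out-of-plane deviation of the heterotypic edge midpoints from their
#' best-fit plane, normalised by their mean in-plane spread. A clean
#' latitudinal border has low tortuosity.
#'
#' @param state A [mech_state()].
#' @param params A [mech_params()].
#' @param borders List of population pairs.
#' @return Data frame: `pop_a`, `pop_b`, `n_edges`, `tortuosity`, `present`.
#' @export
border_descriptor <- function(state, params = mech_params(),
                              borders = list(c("Mic", "Mac"), c("Mac", "Mes"))) {
  cg <- contact_graph(state, params)
  pop <- border_population(state$type)
  rows <- lapply(borders, function(bp) {
    present <- all(bp %in% pop)
    pa <- pop[cg$i]; pb <- pop[cg$j]
    het <- (pa == bp[1] & pb == bp[2]) | (pa == bp[2] & pb == bp[1])
    n_edges <- sum(het)
    tort <- NA_real_
    if (n_edges >= 3) {
      mid <- (state$pos[cg$i[het], , drop = FALSE] +
              state$pos[cg$j[het], , drop = FALSE]) / 2
      ctr <- colMeans(mid)
      cen <- sweep(mid, 2, ctr)
      ev <- eigen(crossprod(cen) / nrow(cen), symmetric = TRUE)
      nrml <- ev$vectors[, 3]
      out_of_plane <- sqrt(mean((cen %*% nrml)^2))
      spread <- sqrt(mean(rowSums(cen^2)))
      tort <- if (spread > 0) out_of_plane / spread else NA_real_
    }
    data.frame(pop_a = bp[1], pop_b = bp[2], n_edges = n_edges,
               tortuosity = tort, present = present,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Border dissimilarity to a reference
#'
#' Sums, over the borders present in both states, the relative difference in
#' heterotypic edge counts and the absolute difference in interface
#' tortuosity. Zero when the descriptors coincide; symmetric in the two
#' populations of each border.
#'
#' @param state A [mech_state()] (or a precomputed [border_descriptor()]).
#' @param reference A reference [border_descriptor()] (or a state).
#' @param params A [mech_params()].
#' @param w_tort Weight of the tortuosity term.
#' @return `D_s >= 0`; attribute `skipped` lists borders absent on either
#'   side.
#' @export
border_similarity <- function(state, reference, params = mech_params(),
                              w_tort = 1) {
  bd <- if (inherits(state, "mech_state")) {
    border_descriptor(state, params)
  } else {
    state
  }
  ref <- if (inherits(reference, "mech_state")) {
    border_descriptor(reference, params)
  } else {
    reference
  }
  stopifnot(nrow(bd) == nrow(ref))
  d <- 0
  skipped <- character()
  for (r in seq_len(nrow(bd))) {
    if (!bd$present[r] || !ref$present[r] ||
        is.na(bd$tortuosity[r]) || is.na(ref$tortuosity[r])) {
      skipped <- c(skipped, paste(bd$pop_a[r], bd$pop_b[r], sep = "/"))
      next
    }
    d <- d + abs(bd$n_edges[r] - ref$n_edges[r]) / max(ref$n_edges[r], 1) +
      w_tort * abs(bd$tortuosity[r] - ref$tortuosity[r])
  }
  attr(d, "skipped") <- skipped
  d
}

#' Idealised banded reference layout
#'
#' Constructs the latitudinal-band spherical layout for a given cell
#' complement (used as the reference border descriptor when no measured
#' specimen is available): same construction as [init_blastula()].
#'
#' @param cells A `sim_cells` table (the cells alive at the reference time)
#'   or a data frame with `cell_id`, `k`, `vbar`.
#' @param params A [mech_params()].
#' @param relax_steps Relaxation budget applied to settle the layout.
#' @return A [border_descriptor()] data frame.
#' @export
reference_border_descriptor <- function(cells, params = mech_params(),
                                        relax_steps = 200L) {
  st <- init_blastula(cells)
  st <- mech_step(st, params, steps = relax_steps)
  border_descriptor(st, params)
}

#' Combined fitness of a simulated embryo
#'
#' Weighted combination `w1 S_s + w2 P_s - w3 D_s`, monotone increasing in
#' sphericity and planarity and decreasing in border dissimilarity.
#'
#' @param S_s,P_s,D_s Objective scores.
#' @param w Length-3 weights.
#' @return Scalar fitness.
#' @export
combined_fitness <- function(S_s, P_s, D_s, w = c(1, 1, 1)) {
  w[1] * S_s + w[2] * P_s - w[3] * D_s
}

phase_label <- function(S_s, P_s) {
  if (is.na(S_s) || is.na(P_s)) return("other")
  if (P_s < 0.6) return("collapsed")
  if (S_s > 0.9 && P_s > 0.9) return("spherical-planar")
  if (P_s > 0.9 && S_s < 0.7) return("polylobular")
  "other"
}

#' Sweep the adhesion-parameter plane
#'
#' Embeds the lineage for every pair of homotypic / heterotypic adhesion
#' coefficients on a grid, with several seeded replicates per point, scores
#' the final state (sphericity, planarity, border dissimilarity to the
#' reference), averages the replicates, labels the phase of each point
#' (`spherical-planar`, `polylobular`, `collapsed`, `other`) and marks the
#' best-fit region: spherical-planar points whose mean combined fitness
#' reaches the upper quartile of the completed grid.
#'
#' @param cells A `sim_cells` lineage table.
#' @param base_params A [mech_params()]; its two adhesion entries are
#'   overridden at each grid point.
#' @param grid_o,grid_e Grid values for `omega_adh_o` and `omega_adh_e`
#'   (default 5 x 5 log-spaced over `[10, 1000]`, a desk-scale version of
#'   the full 40 x 40 exploration).
#' @param replicates Seeded replicates per point.
#' @param base_seed Base seed; run `r` of point `p` uses
#'   `base_seed + 1000 p + r`.
#' @param reference Reference [border_descriptor()]; default derived from
#'   the idealised banded layout of the lineage's final cell complement.
#' @param mask_quantile Fitness quantile defining the best-fit region.
#' @param slice_dt Passed to [embed_lineage()].
#' @return A list of class `sweep_result`: `runs` (one row per run),
#'   `summary` (one row per grid point with mean scores, phase and
#'   `best_fit`), `grid_o`, `grid_e`.
#' @export
sweep_adhesion <- function(cells, base_params = mech_params(),
                           grid_o = 10^seq(1, 3, length.out = 5),
                           grid_e = 10^seq(1, 3, length.out = 5),
                           replicates = 3L, base_seed = 1L,
                           reference = NULL, mask_quantile = 0.75,
                           slice_dt = 2) {
  stopifnot(replicates >= 1)
  if (is.null(reference)) {
    has_daughters <- cells$cell_id %in% cells$mother_id
    final <- cells[!has_daughters, , drop = FALSE]
    reference <- reference_border_descriptor(final, base_params)
  }
  pts <- expand.grid(omega_adh_o = grid_o, omega_adh_e = grid_e)
  runs <- list()
  for (p in seq_len(nrow(pts))) {
    par_p <- base_params
    par_p$omega_adh_o <- pts$omega_adh_o[p]
    par_p$omega_adh_e <- pts$omega_adh_e[p]
    for (r in seq_len(replicates)) {
      seed <- base_seed + 1000L * p + r
      res <- tryCatch({
        traj <- embed_lineage(cells, par_p, seed = seed, slice_dt = slice_dt,
                              checkpoint_every = 1e6L)
        fin <- traj$states[[length(traj$states)]]
        S <- sphericity(fin)
        P <- as.numeric(planarity(fin, par_p))
        D <- as.numeric(border_similarity(fin, reference, par_p))
        data.frame(point = p, omega_adh_o = pts$omega_adh_o[p],
                   omega_adh_e = pts$omega_adh_e[p], replicate = r,
                   seed = seed, S_s = S, P_s = P, D_s = D,
                   fitness = combined_fitness(S, P, D), failed = FALSE)
      }, error = function(e) {
        data.frame(point = p, omega_adh_o = pts$omega_adh_o[p],
                   omega_adh_e = pts$omega_adh_e[p], replicate = r,
                   seed = seed, S_s = NA_real_, P_s = NA_real_,
                   D_s = NA_real_, fitness = NA_real_, failed = TRUE)
      })
      runs[[length(runs) + 1L]] <- res
    }
  }
  runs <- do.call(rbind, runs)

  agg <- lapply(split(runs[!runs$failed, ], runs$point[!runs$failed]), function(d) {
    data.frame(point = d$point[1], omega_adh_o = d$omega_adh_o[1],
               omega_adh_e = d$omega_adh_e[1], n_ok = nrow(d),
               S_s = mean(d$S_s), P_s = mean(d$P_s), D_s = mean(d$D_s),
               fitness = mean(d$fitness))
  })
  summary <- do.call(rbind, agg)
  summary$phase <- vapply(seq_len(nrow(summary)), function(r) {
    phase_label(summary$S_s[r], summary$P_s[r])
  }, character(1))
  thr <- quantile(summary$fitness, mask_quantile, na.rm = TRUE)
  summary$best_fit <- summary$phase == "spherical-planar" &
    summary$fitness >= thr
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary,
                 grid_o = grid_o, grid_e = grid_e),
            class = "sweep_result")
}
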