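#' Default group laws for a synthetic cohort
#'
#' A complete law table for generations 6-10 of a cleavage-stage embryo with
#' the 32-cell type composition (16 Mes, 8 Mac, 4 LMic, 4 SMic). The values
#' are plausible placeholders for a sea-urchin blastula, not measurements:
#' the mean cycle length rises from ~40 to ~90 min with widening spread
#' across generations, micromeres cycle more slowly than mesomeres, the
#' daughter/mother volume ratio is log-normal around 0.5 with ~20% spread,
#' and the surface ratio is centred at `2^(-2/3)` (the isometric value for a
#' halved volume).
#'
#' @param generations Generation range covered (first entry = root
#'   generation, which carries the initial `m`, `vbar`, `sbar` laws).
#' @return A law table, see [law_table()].
#' @export
default_group_laws <- function(generations = 6:10) {
  g0 <- generations[1]
  gens <- generations[-1]
  mu_x_base <- approx(7:10, c(40, 55, 70, 90), xout = gens, rule = 2)$y
  sd_x_base <- approx(7:10, c(4, 6, 8, 10), xout = gens, rule = 2)$y
  type_speed <- c(Mes = 1.00, Mac = 0.95, LMic = 1.10, SMic = 1.30)

  rows <- list()
  for (k in CELL_TYPES) {
    rows[[length(rows) + 1L]] <- law_table(
      n = gens, k = k, feature = "x",
      mu = mu_x_base * type_speed[[k]], sigma = sd_x_base
    )
    # log-means shifted by -sigma^2/2 so the *mean* ratio is 0.5 (resp.
    # 2^(-2/3)): total volume is then conserved across divisions on
    # average, as observed at cleavage stages
    rows[[length(rows) + 1L]] <- law_table(
      n = gens, k = k, feature = "a",
      mu = log(0.5) - 0.18^2 / 2, sigma = 0.18
    )
    rows[[length(rows) + 1L]] <- law_table(
      n = gens, k = k, feature = "b",
      mu = -2 / 3 * log(2) - 0.12^2 / 2, sigma = 0.12
    )
  }
  v0 <- c(Mes = 12000, Mac = 22000, LMic = 8000, SMic = 3000) # um^3
  s_of_v <- function(v) (36 * pi)^(1 / 3) * v^(2 / 3)         # sphere surface
  for (k in CELL_TYPES) {
    rows[[length(rows) + 1L]] <- law_table(
      n = g0, k = k, feature = "m", mu = 360, sigma = 6
    )
    rows[[length(rows) + 1L]] <- law_table(
      n = g0, k = k, feature = "vbar", mu = log(v0[[k]]), sigma = 0.15
    )
    rows[[length(rows) + 1L]] <- law_table(
      n = g0, k = k, feature = "sbar", mu = log(s_of_v(v0[[k]])), sigma = 0.10
    )
  }
  do.call(rbind, rows)
}

#' Configuration of a synthetic digital-embryo cohort
#'
#' Describes a cohort of embryos sharing one set of group laws but observed
#' under embryo-specific distortions: an affine time distortion
#' `t -> beta * t + alpha` (individual developmental speed / start offset)
#' and a spatial scale `gamma` (egg size: volumes scale by `gamma^3`,
#' surfaces by `gamma^2`), plus per-embryo observation windows. The first
#' embryo defaults to the identity distortion so the cohort has a concrete
#' reference frame.
#'
#' @param n_embryos Number of embryos.
#' @param alpha,beta,gamma Per-embryo distortion parameters (recycled if
#'   scalar). `beta`, `gamma` must be positive.
#' @param dt Acquisition time step in minutes.
#' @param windows Optional list of per-embryo windows (in the embryo's own
#'   distorted time frame); `NULL` = full span.
#' @param laws Law table, defaults to [default_group_laws()].
#' @param generations Generation range, first = root generation.
#' @param divide_last Whether cells of the last generation divide (their
#'   daughters are then recorded for a short tail so that last-generation
#'   cycles are completely observed).
#' @param counts Named per-type root counts.
#' @param normalize_roots Make the injected distortions the *only*
#'   embryo-level factors, as the cohort model assumes (after rescaling,
#'   all embryos share one set of group laws): root volume/surface totals
#'   are normalised to the laws' nominal totals (size is exactly `gamma`),
#'   realised root division times are centred on the law mean (start offset
#'   is exactly `alpha`), and cycle/ratio draws are centred per
#'   (generation, type) group (growth speed is exactly `beta`). Within-group
#'   spread is untouched.
#' @param seed Base RNG seed; embryo `i` uses `seed + i`.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_embryos = 5,
                          alpha = c(0, -15, 10, 25, -30),
                          beta = c(1, 1.10, 0.93, 1.05, 0.88),
                          gamma = c(1, 1.08, 0.95, 1.12, 0.90),
                          dt = 2,
                          windows = NULL,
                          laws = default_group_laws(generations),
                          generations = 6:10,
                          divide_last = TRUE,
                          counts = c(Mes = 16, Mac = 8, LMic = 4, SMic = 4),
                          normalize_roots = TRUE,
                          seed = 1L) {
  alpha <- rep_len(alpha, n_embryos)
  beta <- rep_len(beta, n_embryos)
  gamma <- rep_len(gamma, n_embryos)
  stopifnot(all(beta > 0), all(gamma > 0), dt > 0)
  structure(list(
    n_embryos = n_embryos, alpha = alpha, beta = beta, gamma = gamma,
    dt = dt, windows = windows, laws = laws, generations = generations,
    divide_last = divide_last, counts = counts,
    normalize_roots = normalize_roots, seed = as.integer(seed)
  ), class = "cohort_config")
}

# Core branching-process draw shared by the synthetic-cohort generator and
# the lineage simulator: continuous division times, per-cycle mean volumes
# and surfaces. Returns one row per cell.
sim_cells <- function(laws, generations = 6:10,
                      counts = c(Mes = 16, Mac = 8, LMic = 4, SMic = 4),
                      divide_last = FALSE, center_groups = FALSE) {
  center <- function(v, target, log_space = FALSE) {
    if (!center_groups || length(v) < 2L) return(v)
    if (log_space) v * exp(target - mean(log(v))) else v - mean(v) + target
  }
  g0 <- generations[1]
  gmax <- generations[length(generations)]
  types <- rep(names(counts), counts)
  n0 <- length(types)

  m0 <- numeric(n0); v0 <- numeric(n0); s0 <- numeric(n0)
  for (k in unique(types)) {
    sel <- types == k
    m0[sel] <- law_rand(get_law(laws, g0, k, "m"), sum(sel))
    v0[sel] <- law_rand(get_law(laws, g0, k, "vbar"), sum(sel))
    s0[sel] <- law_rand(get_law(laws, g0, k, "sbar"), sum(sel))
  }
  cells <- data.frame(
    cell_id = seq_len(n0), mother_id = NA_integer_, k = types,
    n = as.integer(g0), birth = NA_real_, m = m0,
    vbar = v0, sbar = s0, stringsAsFactors = FALSE
  )
  parents <- cells
  next_id <- n0 + 1L
  dividing_gens <- if (divide_last) g0:(gmax) else g0:(gmax - 1L)

  for (g in dividing_gens) {
    par <- parents[parents$n == g & !is.na(parents$m), , drop = FALSE]
    if (nrow(par) == 0L) break
    nd <- 2L * nrow(par)
    gd <- g + 1L
    kd <- rep(par$k, each = 2L)
    birth <- rep(par$m, each = 2L)
    ids <- seq.int(next_id, length.out = nd)
    next_id <- next_id + nd

    # daughters one generation past the configured range (tail cells kept
    # only so that last-generation divisions are observable) reuse the final
    # generation's ratio laws and never divide
    g_laws <- min(gd, gmax)
    x <- a <- b <- numeric(nd)
    for (k in unique(kd)) {
      sel <- kd == k
      lx <- get_law(laws, g_laws, k, "x")
      la <- get_law(laws, g_laws, k, "a")
      lb <- get_law(laws, g_laws, k, "b")
      x[sel] <- center(law_rand(lx, sum(sel)), lx$mu)
      a[sel] <- center(law_rand(la, sum(sel)), la$mu, log_space = TRUE)
      b[sel] <- center(law_rand(lb, sum(sel)), lb$mu, log_space = TRUE)
    }
    m <- if (gd <= gmax) birth + x else rep(NA_real_, nd)
    dau <- data.frame(
      cell_id = ids, mother_id = rep(par$cell_id, each = 2L), k = kd,
      n = gd, birth = birth, m = m,
      vbar = rep(par$vbar, each = 2L) * a,
      sbar = rep(par$sbar, each = 2L) * b,
      stringsAsFactors = FALSE
    )
    cells <- rbind(cells, dau)
    parents <- dau
  }
  class(cells) <- c("sim_cells", "data.frame")
  cells
}

#' Render a simulated cell table as a lineage tree on a time grid
#'
#' Snaps the continuous division times of a [sim_cells] table onto an
#' acquisition grid (step `dt`, anchored at the window start): a cell is
#' recorded from the first grid point at or after its birth to the last grid
#' point strictly before its division (piecewise-constant volume/surface at
#' its cycle means), daughters therefore starting at the step after the
#' mother's last one. Records outside the window are discarded; cells whose
#' track is clipped at the window start lose their mother reference, as in a
#' real truncated observation.
#'
#' @param cells A `sim_cells` data frame.
#' @param dt Acquisition step (min).
#' @param window Observation window; default spans from 30 min before the
#'   first division to 3 steps after the last.
#' @return A validated [lineage_tree()].
#' @export
cells_to_tree <- function(cells, dt = 2, window = NULL) {
  if (is.null(window)) {
    window <- c(min(cells$m, na.rm = TRUE) - 30,
                max(cells$m, na.rm = TRUE) + 3 * dt)
  }
  w0 <- window[1]; w1 <- window[2]
  snap_up <- function(tt) w0 + dt * ceiling((tt - w0) / dt - 1e-9)
  snap_before <- function(tt) {
    # last grid point strictly below tt
    w0 + dt * (ceiling((tt - w0) / dt - 1e-9) - 1)
  }
  # a cell leaves the record at its division only if its daughters exist in
  # the table; terminal cells persist to the window end
  has_daughters <- cells$cell_id %in% cells$mother_id
  start <- ifelse(is.na(cells$birth), w0, snap_up(cells$birth))
  stop_ <- ifelse(has_daughters & !is.na(cells$m), snap_before(cells$m), w1)
  start <- pmax(start, w0)
  stop_ <- pmin(stop_, w0 + dt * floor((w1 - w0) / dt))
  keep <- start <= stop_ + 1e-9
  if (!any(keep)) stop("observation window excludes every cell")
  cells <- cells[keep, , drop = FALSE]
  start <- start[keep]; stop_ <- stop_[keep]

  nsteps <- as.integer(round((stop_ - start) / dt)) + 1L
  rid <- rep.int(seq_len(nrow(cells)), nsteps)
  toff <- sequence(nsteps) - 1L
  rec <- data.frame(
    cell_id = cells$cell_id[rid],
    mother_id = cells$mother_id[rid],
    t = start[rid] + dt * toff,
    x = 0, y = 0, z = 0,
    type = cells$k[rid],
    volume = cells$vbar[rid],
    surface = cells$sbar[rid],
    gen = cells$n[rid],
    stringsAsFactors = FALSE
  )
  # sever mother links to cells dropped by the truncation
  kept_ids <- unique(rec$cell_id)
  rec$mother_id[!(rec$mother_id %in% kept_ids)] <- NA_integer_
  lineage_tree(rec, window = window, validate = TRUE)
}

#' Generate one synthetic digital embryo
#'
#' Draws one embryo from the cohort's group laws, applies its individual
#' time distortion and spatial scale, and renders it on the acquisition grid.
#' The ground truth (every continuous draw and all parameters) is returned
#' alongside for recovery tests.
#'
#' @param config A [cohort_config()].
#' @param index Embryo index in `1:n_embryos`.
#' @return A list with elements `tree` ([lineage_tree()]) and `truth`
#'   (list: `cells`, `alpha`, `beta`, `gamma`, `laws`, `seed`).
#' @export
generate_embryo <- function(config, index) {
  stopifnot(index >= 1, index <= config$n_embryos)
  set.seed(config$seed + index)
  cells <- sim_cells(config$laws, config$generations,
                     counts = config$counts, divide_last = config$divide_last,
                     center_groups = isTRUE(config$normalize_roots))
  if (isTRUE(config$normalize_roots)) {
    # every descendant volume is its root value times a ratio cascade, so
    # scaling the whole column rescales exactly the embryo-level size
    g0 <- config$generations[1]
    roots <- is.na(cells$mother_id)
    # centre the realised root laws per type: geometric means of volumes and
    # surfaces on their law means (size offset is gamma's role), root
    # division times on the m law mean (start offset is alpha's role).
    # Descendants follow multiplicatively / by rigid shift since their
    # features cascade from the roots through group-centred draws.
    for (k in unique(cells$k)) {
      rk <- roots & cells$k == k
      sel <- cells$k == k
      fv <- exp(get_law(config$laws, g0, k, "vbar")$mu - mean(log(cells$vbar[rk])))
      fs <- exp(get_law(config$laws, g0, k, "sbar")$mu - mean(log(cells$sbar[rk])))
      cells$vbar[sel] <- cells$vbar[sel] * fv
      cells$sbar[sel] <- cells$sbar[sel] * fs
      shift <- get_law(config$laws, g0, k, "m")$mu - mean(cells$m[rk])
      cells$m[sel] <- cells$m[sel] + shift
      cells$birth[sel] <- cells$birth[sel] + shift
    }
  }
  truth_cells <- cells

  al <- config$alpha[index]; be <- config$beta[index]; ga <- config$gamma[index]
  cells$birth <- be * cells$birth + al
  cells$m <- be * cells$m + al
  cells$vbar <- cells$vbar * ga^3
  cells$sbar <- cells$sbar * ga^2

  window <- if (!is.null(config$windows)) config$windows[[index]] else NULL
  tree <- cells_to_tree(cells, dt = config$dt, window = window)
  if (!any(tree$records$gen == config$generations[1])) {
    stop("observation window excludes the root generation entirely")
  }
  list(tree = tree,
       truth = list(cells = truth_cells, alpha = al, beta = be, gamma = ga,
                    laws = config$laws, seed = config$seed + index))
}

#' Generate a full synthetic cohort
#'
#' @param config A [cohort_config()].
#' @return A list of class `synthetic_cohort` with elements `trees` (list of
#'   [lineage_tree()]) and `truth` (list of per-embryo ground-truth records).
#' @export
generate_cohort <- function(config) {
  out <- lapply(seq_len(config$n_embryos), function(i) generate_embryo(config, i))
  structure(list(
    trees = lapply(out, `[[`, "tree"),
    truth = lapply(out, `[[`, "truth"),
    config = config
  ), class = "synthetic_cohort")
}
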