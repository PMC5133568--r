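#' Extract per-cell features from a lineage tree
#'
#' Computes, for every cell: its birth time (first observed step), division
#' time `m` (first step of its daughters), cycle length `x = m - birth`,
#' time-averaged volume `vbar` and surface `sbar` over its observed steps
#' (uniform weights), and the daughter/mother ratios `a = vbar/vbar_mother`,
#' `b = sbar/sbar_mother`.
#'
#' A cycle is *complete* when both its start and end are observed, i.e. the
#' cell has a mother in the tree and divides inside the observation window.
#' Cells clipped by the window (roots, terminal cells) keep their partial
#' measurements but are flagged `complete = FALSE` and excluded from all
#' distribution fits downstream. Ratios are computed only when both mother
#' and daughter cycles are complete. `m` alone requires only the division to
#' be observed (`divides = TRUE`).
#'
#' @param tree A [lineage_tree()] with generations and types assigned.
#' @return A data frame, one row per cell, with columns `cell_id`,
#'   `mother_id`, `k` (type), `n` (generation), `birth`, `m`, `x`, `vbar`,
#'   `sbar`, `a`, `b`, `divides`, `complete`, `geom_present`.
#' @export
extract_features <- function(tree) {
  idx <- cell_index(tree)
  if (any(is.na(idx$gen)) || any(is.na(idx$type))) {
    stop("generations/types not assigned; run assign_generations_and_types()")
  }
  ids <- idx$cell_id
  mo <- idx$mother_id

  # division time of each mother = first observed step of her daughters
  first_by_mother <- tapply(idx$first_t, mo, min)
  m <- unname(first_by_mother[as.character(ids)])
  divides <- !is.na(m)

  # birth of a daughter is the mother's division time, i.e. the daughter's
  # own first observed step; unknown for roots
  birth <- ifelse(is.na(mo), NA_real_, idx$first_t)
  x <- m - birth
  complete <- !is.na(mo) & divides

  geom_present <- !all(is.na(idx$vbar))
  feat <- data.frame(
    cell_id = ids, mother_id = mo,
    k = idx$type, n = idx$gen,
    birth = birth, m = m, x = x,
    vbar = idx$vbar, sbar = idx$sbar,
    a = NA_real_, b = NA_real_,
    divides = divides, complete = complete,
    geom_present = geom_present,
    stringsAsFactors = FALSE
  )
  mi <- match(mo, ids)
  both <- complete & !is.na(mi) & feat$complete[mi]
  both[is.na(both)] <- FALSE
  feat$a[both] <- feat$vbar[both] / feat$vbar[mi[both]]
  feat$b[both] <- feat$sbar[both] / feat$sbar[mi[both]]
  feat
}

#' Attach contact degrees to a lineage
#'
#' Joins an externally supplied cell-contact graph (e.g. from membrane
#' segmentation adjacency or from the mechanics module) to the lineage
#' records, adding a `degree` column `d_i(t)` = number of neighbours of cell
#' `i` at time `t`.
#'
#' @param tree A [lineage_tree()].
#' @param contacts A data frame with columns `t`, `cell_a`, `cell_b`, one row
#'   per undirected contact at one time step.
#' @return The tree with a `degree` column on `records`.
#' @export
contact_degrees <- function(tree, contacts) {
  rec <- tree$records
  key <- paste(rec$cell_id, rec$t)
  ka <- paste(contacts$cell_a, contacts$t)
  kb <- paste(contacts$cell_b, contacts$t)
  unknown <- c(contacts$cell_a[!(ka %in% key)], contacts$cell_b[!(kb %in% key)])
  if (length(unknown)) {
    stop("contact edge names unknown cell(s): ",
         paste(unique(unknown), collapse = ", "))
  }
  cnt <- table(c(ka, kb))
  rec$degree <- as.integer(cnt[key])
  rec$degree[is.na(rec$degree)] <- 0L
  tree$records <- rec
  tree
}

#' Embryo-level curves N(t), W(t), Z(t)
#'
#' Total cell count, total cellular volume and total cellular surface area on
#' the tree's native time grid, for the whole embryo (`type = "all"`) and
#' restricted to each cell type.
#'
#' @param tree A [lineage_tree()].
#' @return A data frame of class `embryo_curves` with columns `t`, `type`,
#'   `N`, `W`, `Z`; the observation window is kept as attribute `window`.
#' @export
embryo_curves <- function(tree) {
  rec <- data.table::as.data.table(tree$records)
  N <- W <- Z <- type <- NULL
  whole <- rec[, list(type = "all", N = .N,
                      W = sum(volume), Z = sum(surface)), by = "t"]
  per <- rec[!is.na(type), list(N = .N, W = sum(volume), Z = sum(surface)),
             by = c("t", "type")]
  out <- rbind(as.data.frame(whole)[, c("t", "type", "N", "W", "Z")],
               as.data.frame(per)[, c("t", "type", "N", "W", "Z")])
  out <- out[order(match(out$type, c("all", CELL_TYPES)), out$t), ]
  rownames(out) <- NULL
  structure(out, class = c("embryo_curves", "data.frame"), window = tree$window)
}

# right-continuous step interpolation of a curve at arbitrary times
step_interp <- function(t, y, tout) {
  approx(t, y, xout = tout, method = "constant", f = 0, rule = 2)$y
}

# pull one (type, metric) step function out of an embryo_curves table
curve_values <- function(curves, tout, type = "all", metric = "N") {
  sel <- curves$type == type
  step_interp(curves$t[sel], curves[[metric]][sel], tout)
}
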