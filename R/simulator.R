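#' Simulate one stochastic artificial cell lineage
#'
#' Draws a cell lineage from a group model (or prototype law table):
#' starting from the 32-cell stage (16 Mes, 8 Mac, 4 LMic, 4 SMic by
#' default), root division times, volumes and surfaces come from the initial
#' generation laws; every later cell draws its cycle length from its group's
#' normal law (its division time being the root time plus the summed cycle
#' lengths of its ancestors) and its volume/surface from its mother's via
#' independent per-daughter log-normal ratio draws.
#'
#' @param model A law table covering the requested generations (see
#'   [group_model()]).
#' @param seed RNG seed (one integer; the whole lineage is a deterministic
#'   function of it).
#' @param generations Generation range.
#' @param counts Named per-type root counts.
#' @param divide_last Whether the last generation divides (default `FALSE`:
#'   terminal cells persist, so the cell count plateaus at
#'   `sum(counts) * 2^(length(generations) - 1)`).
#' @return A `sim_cells` data frame (one row per cell: `cell_id`,
#'   `mother_id`, `k`, `n`, `birth`, `m`, `vbar`, `sbar`).
#' @export
simulate_lineage <- function(model, seed = 1L, generations = 6:10,
                             counts = c(Mes = 16, Mac = 8, LMic = 4, SMic = 4),
                             divide_last = FALSE) {
  set.seed(seed)
  cells <- sim_cells(model, generations, counts = counts,
                     divide_last = divide_last)
  attr(cells, "seed") <- seed
  cells
}

#' Embryo-level curves of a simulated lineage
#'
#' Step curves `N(t)`, `W(t)`, `Z(t)` of a `sim_cells` table evaluated on a
#' time grid, whole-embryo and per type, using the piecewise-constant
#' per-cycle means. A cell is alive from its birth (roots: from the grid
#' start) until its division (terminal cells: until the grid end).
#'
#' @param cells A `sim_cells` data frame.
#' @param grid Time grid; default spans the lineage at step `dt`.
#' @param dt Grid step used when `grid` is `NULL`.
#' @return An [embryo_curves()]-style data frame.
#' @export
lineage_curves <- function(cells, grid = NULL, dt = 2) {
  if (is.null(grid)) {
    grid <- seq(min(cells$m, na.rm = TRUE) - 30,
                max(cells$m, na.rm = TRUE) + 3 * dt, by = dt)
  }
  has_daughters <- cells$cell_id %in% cells$mother_id
  birth <- ifelse(is.na(cells$birth), -Inf, cells$birth)
  death <- ifelse(has_daughters & !is.na(cells$m), cells$m, Inf)

  one_set <- function(sel, label) {
    ev_t <- c(birth[sel], death[sel])
    dn <- c(rep(1, sum(sel)), rep(-1, sum(sel)))
    dw <- c(cells$vbar[sel], -cells$vbar[sel])
    dz <- c(cells$sbar[sel], -cells$sbar[sel])
    fin <- is.finite(ev_t)
    base_n <- sum(ev_t == -Inf & dn > 0)
    base_w <- sum(dw[ev_t == -Inf & dn > 0])
    base_z <- sum(dz[ev_t == -Inf & dn > 0])
    o <- order(ev_t[fin])
    tt <- ev_t[fin][o]
    cn <- base_n + cumsum(dn[fin][o])
    cw <- base_w + cumsum(dw[fin][o])
    cz <- base_z + cumsum(dz[fin][o])
    ix <- findInterval(grid, tt)
    data.frame(
      t = grid, type = label,
      N = ifelse(ix == 0, base_n, cn[pmax(ix, 1)]),
      W = ifelse(ix == 0, base_w, cw[pmax(ix, 1)]),
      Z = ifelse(ix == 0, base_z, cz[pmax(ix, 1)]),
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    one_set(rep(TRUE, nrow(cells)), "all"),
    do.call(rbind, lapply(CELL_TYPES, function(k) one_set(cells$k == k, k)))
  )
  rownames(out) <- NULL
  structure(out, class = c("embryo_curves", "data.frame"), window = range(grid))
}

#' Ensemble of simulated lineages
#'
#' Runs `n_real` independent realisations (seeds `base_seed + 1 ..
#' base_seed + n_real`) and summarises the embryo-level curves by their
#' pointwise mean and standard deviation, whole-embryo and per type.
#'
#' @param model Law table.
#' @param n_real Number of realisations (`>= 2`).
#' @param base_seed Base seed.
#' @param grid Common time grid; default derived from the model's expected
#'   span.
#' @param generations,counts,divide_last Passed to [simulate_lineage()].
#' @param dt Grid step when `grid` is `NULL`.
#' @return A list of class `ensemble_summary`: `grid`, `mean` and `sd`
#'   (3-d arrays time x type x metric), `n_real`, `base_seed`.
#' @export
lineage_ensemble <- function(model, n_real = 300L, base_seed = 1L, grid = NULL,
                             generations = 6:10,
                             counts = c(Mes = 16, Mac = 8, LMic = 4, SMic = 4),
                             divide_last = FALSE, dt = 2) {
  stopifnot(n_real >= 2)
  if (is.null(grid)) {
    g0 <- generations[1]
    m0 <- mean(vapply(CELL_TYPES, function(k) get_law(model, g0, k, "m")$mu,
                      numeric(1)))
    span <- max(vapply(CELL_TYPES, function(k) {
      sum(vapply(generations[-1], function(g) get_law(model, g, k, "x")$mu,
                 numeric(1)))
    }, numeric(1)))
    grid <- seq(m0 - 30, m0 + span + 30, by = dt)
  }
  types <- c("all", CELL_TYPES)
  metrics <- c("N", "W", "Z")
  s1 <- array(0, c(length(grid), length(types), length(metrics)),
              dimnames = list(NULL, types, metrics))
  s2 <- s1
  for (r in seq_len(n_real)) {
    cells <- simulate_lineage(model, seed = base_seed + r,
                              generations = generations, counts = counts,
                              divide_last = divide_last)
    cu <- lineage_curves(cells, grid = grid)
    for (ty in types) for (me in metrics) {
      v <- cu[[me]][cu$type == ty]
      s1[, ty, me] <- s1[, ty, me] + v
      s2[, ty, me] <- s2[, ty, me] + v^2
    }
  }
  mean_ <- s1 / n_real
  var_ <- pmax(s2 / n_real - mean_^2, 0) * n_real / (n_real - 1)
  structure(list(grid = grid, mean = mean_, sd = sqrt(var_),
                 n_real = n_real, base_seed = base_seed),
            class = "ensemble_summary")
}

#' Fast ensemble of division times for one type
#'
#' Vectorised across realisations: returns the division times of every cell
#' of `type` at the final generation, over `n_real` independent lineages.
#' Used to check the variance-addition law (the variance of division times
#' within a group equals the initial variance plus the summed variances of
#' ancestor cycle lengths) without building full lineage tables.
#'
#' @param model Law table.
#' @param type Cell type.
#' @param n_real Number of realisations.
#' @param base_seed RNG seed.
#' @param generations Generation range.
#' @param n_roots Number of roots of this type per embryo.
#' @return Numeric vector of `n_roots * 2^(ngen-1) * n_real` division times.
#' @export
division_time_ensemble <- function(model, type = "Mes", n_real = 1e4,
                                   base_seed = 1L, generations = 6:10,
                                   n_roots = 16L) {
  set.seed(base_seed)
  g0 <- generations[1]
  m <- law_rand(get_law(model, g0, type, "m"), n_roots * n_real)
  for (g in generations[-1]) {
    law <- get_law(model, g, type, "x")
    m <- rep(m, each = 2L) + law_rand(law, 2L * length(m))
  }
  m
}

#' Compare an ensemble summary to a measured embryo
#'
#' Pointwise z-scores of the measured curves against the ensemble mean and
#' standard deviation, and the coverage fraction (share of time points
#' falling within +/- 2 sd), per (type, metric).
#'
#' @param summary An `ensemble_summary` from [lineage_ensemble()].
#' @param measured An [embryo_curves()] table.
#' @param z_band Band half-width in standard deviations.
#' @return A data frame with one row per (type, metric): `n_points`,
#'   `mean_abs_z`, `coverage`.
#' @export
compare_to_measured <- function(summary, measured, z_band = 2) {
  mt <- range(measured$t[measured$type == "all"])
  sel <- summary$grid >= mt[1] & summary$grid <= mt[2]
  if (!any(sel)) stop("disjoint time support between ensemble and measurement")
  grid <- summary$grid[sel]
  rows <- list()
  for (ty in dimnames(summary$mean)[[2]]) {
    if (!any(measured$type == ty)) next
    for (me in dimnames(summary$mean)[[3]]) {
      obs <- curve_values(measured, grid, type = ty, metric = me)
      mu <- summary$mean[sel, ty, me]
      sg <- summary$sd[sel, ty, me]
      ok <- sg > 0 & !is.na(obs)
      if (!any(ok)) next
      z <- (obs[ok] - mu[ok]) / sg[ok]
      rows[[length(rows) + 1L]] <- data.frame(
        type = ty, metric = me, n_points = sum(ok),
        mean_abs_z = mean(abs(z)), coverage = mean(abs(z) <= z_band),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
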