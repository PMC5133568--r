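#' Per-embryo rescaling parameters
#'
#' @param alpha Time shifts (min).
#' @param beta Time scales (dimensionless, `> 0`).
#' @param gamma Spatial factors (dimensionless, `> 0`).
#' @return A data frame of class `rescale_params` with one row per embryo.
#' @export
rescale_params <- function(alpha, beta, gamma = rep(1, length(alpha))) {
  stopifnot(length(alpha) == length(beta), length(alpha) == length(gamma),
            all(beta > 0), all(gamma > 0))
  structure(data.frame(embryo = seq_along(alpha), alpha = alpha, beta = beta,
                       gamma = gamma),
            class = c("rescale_params", "data.frame"))
}

# embryo curve evaluated in cohort time: value at tau of the transformed
# curve t -> beta * t + alpha
transformed_curve <- function(curves, tau, alpha, beta, metric = "N",
                              transform = identity) {
  sel <- curves$type == "all"
  transform(step_interp(beta * curves$t[sel] + alpha, curves[[metric]][sel], tau))
}

cohort_time_support <- function(curves_list, alpha, beta) {
  lo <- -Inf; hi <- Inf
  for (i in seq_along(curves_list)) {
    tr <- range(curves_list[[i]]$t[curves_list[[i]]$type == "all"])
    lo <- max(lo, beta[i] * tr[1] + alpha[i])
    hi <- min(hi, beta[i] * tr[2] + alpha[i])
  }
  c(lo, hi)
}

# deterministic multi-resolution grid search for one embryo's (alpha, beta)
fit_one_temporal <- function(curves, tau, avg, alpha0, beta0,
                             transform = identity, w = NULL) {
  if (is.null(w)) w <- rep(1, length(tau))
  obj <- function(al, be) {
    sum(w * (transformed_curve(curves, tau, al, be, transform = transform) - avg)^2) / sum(w)
  }
  al <- alpha0; be <- beta0
  spans <- list(c(40, 4, 0.15, 0.03), c(6, 0.5, 0.04, 0.004),
                c(0.8, 0.1, 0.006, 0.0005))
  for (sp in spans) {
    als <- al + seq(-sp[1], sp[1], by = sp[2])
    bes <- be * seq(1 - sp[3], 1 + sp[3], by = sp[4])
    vals <- outer(als, bes, Vectorize(obj))
    lo <- min(vals)
    # step curves make the objective piecewise constant, so the minimum is
    # attained on a plateau of parameters: stay put if the current point
    # already attains it, otherwise move to the centre of the tied region
    if (obj(al, be) > lo) {
      ties <- which(vals == lo, arr.ind = TRUE)
      al <- mean(range(als[ties[, 1]]))
      be <- mean(range(bes[ties[, 2]]))
      if (obj(al, be) > lo) {  # non-rectangular tie set: fall back
        al <- als[ties[1, 1]]; be <- bes[ties[1, 2]]
      }
    }
  }
  c(alpha = al, beta = be)
}

#' Fit the temporal rescaling of a cohort
#'
#' Finds per-embryo affine time maps `t -> beta * t + alpha` minimising the
#' L2 distance between each embryo's transformed cell-number curve `N(t)`
#' and the cohort-average curve, alternating curve averaging and per-embryo
#' fits to a fixed point. The cohort average is identifiable only up to a
#' common affine map; the first embryo is pinned to the identity (gauge
#' fixing).
#'
#' The discrepancy is evaluated on `log2(N)`: the cell count doubles once
#' per generation, so the log makes every division wave carry equal weight
#' instead of letting the last (largest) generations dominate, which
#' removes most of the shift/dilation trade-off of the raw-count objective.
#' `scale = "identity"` gives the plain L2-on-N fit.
#'
#' @param curves_list A list of [embryo_curves()], one per embryo (>= 2).
#' @param max_iter Maximum number of alternations.
#' @param tol Convergence threshold on the largest parameter change.
#' @param scale Objective scale, `"log2"` (default) or `"identity"`.
#' @return A [rescale_params()] (with `gamma = 1`); attribute `objective`
#'   holds the final per-embryo mean squared residuals.
#' @export
fit_temporal <- function(curves_list, max_iter = 50L, tol = 1e-4,
                         scale = c("log2", "identity")) {
  scale <- match.arg(scale)
  transform <- if (scale == "log2") function(v) log2(pmax(v, 1)) else identity
  nE <- length(curves_list)
  stopifnot(nE >= 2)
  gstep <- min(vapply(curves_list, function(cu) {
    min(diff(sort(unique(cu$t[cu$type == "all"]))))
  }, numeric(1)))
  alpha <- numeric(nE); beta <- rep(1, nE)

  for (it in seq_len(max_iter)) {
    sup <- cohort_time_support(curves_list, alpha, beta)
    if (sup[1] >= sup[2]) stop("non-overlapping observation windows after rescaling")
    tau <- seq(sup[1], sup[2], by = gstep)
    mat <- vapply(seq_len(nE), function(i) {
      transformed_curve(curves_list[[i]], tau, alpha[i], beta[i],
                        transform = transform)
    }, numeric(length(tau)))
    avg <- rowMeans(mat)
    old <- c(alpha, beta)
    for (i in 2:nE) {
      # leave-one-out average: fitting an embryo against a mean containing
      # its own curve creates sticky self-matching fixed points
      avg_i <- rowMeans(mat[, -i, drop = FALSE])
      p <- fit_one_temporal(curves_list[[i]], tau, avg_i, alpha[i], beta[i],
                            transform = transform)
      alpha[i] <- p[["alpha"]]; beta[i] <- p[["beta"]]
    }
    if (max(abs(c(alpha, beta) - old)) < tol) break
  }
  res <- vapply(seq_len(nE), function(i) {
    mean((transformed_curve(curves_list[[i]], tau, alpha[i], beta[i],
                            transform = transform) - avg)^2)
  }, numeric(1))
  out <- rescale_params(alpha, beta)
  attr(out, "objective") <- res
  attr(out, "iterations") <- it
  out
}

#' Fit the spatial rescaling of a cohort
#'
#' Given the temporal fit, finds the per-embryo scalar `gamma` whose cube
#' scales the temporally rescaled total-volume curve `W(t)` onto the cohort
#' mean (weighted least squares per embryo, alternated with the cohort
#' average; the first embryo is pinned to `gamma = 1`). The residual
#' variance of `W` across the cohort is strongly time dependent (tight at
#' the start of the record, wandering at later generations as per-division
#' volume-ratio noise accumulates), so each time point is weighted by the
#' inverse of the cohort's empirical residual variance (with a small floor),
#' re-estimated along the alternation.
#'
#' @param curves_list A list of [embryo_curves()].
#' @param temporal A [rescale_params()] from [fit_temporal()].
#' @param max_iter,tol Alternation control.
#' @return `temporal` with its `gamma` column filled.
#' @export
fit_spatial <- function(curves_list, temporal, max_iter = 100L, tol = 1e-8) {
  nE <- length(curves_list)
  sup <- cohort_time_support(curves_list, temporal$alpha, temporal$beta)
  gstep <- min(vapply(curves_list, function(cu) {
    min(diff(sort(unique(cu$t[cu$type == "all"]))))
  }, numeric(1)))
  tau <- seq(sup[1], sup[2], by = gstep)
  Wmat <- vapply(seq_len(nE), function(i) {
    transformed_curve(curves_list[[i]], tau, temporal$alpha[i],
                      temporal$beta[i], metric = "W")
  }, numeric(length(tau)))
  if (any(colSums(Wmat^2) == 0)) stop("zero-volume curve in cohort")
  # scale-free heteroscedasticity estimate: the dispersion across embryos of
  # log(W_i(t) / W_i(t_first)) does not depend on the spatial factors, so it
  # can be estimated once; time points where the cohort's volume evolution
  # is tight (the early record) then dominate the fit
  lr <- log(sweep(Wmat, 2, Wmat[1, ], `/`))
  v_t <- apply(lr, 1, var)
  w <- 1 / (v_t + 1e-6)
  g3 <- rep(1, nE)
  for (it in seq_len(max_iter)) {
    Wbar <- rowMeans(sweep(Wmat, 2, g3, `*`))
    old <- g3
    for (i in 2:nE) {
      g3[i] <- sum(w * Wmat[, i] * Wbar) / sum(w * Wmat[, i]^2)
    }
    if (max(abs(g3 - old)) < tol) break
  }
  temporal$gamma <- g3^(1 / 3)
  temporal
}

#' Fit temporal then spatial rescaling
#'
#' @param curves_list A list of [embryo_curves()].
#' @param ... Passed to [fit_temporal()].
#' @return A complete [rescale_params()].
#' @export
fit_rescale <- function(curves_list, ...) {
  fit_spatial(curves_list, fit_temporal(curves_list, ...))
}

#' Apply rescaling parameters to a lineage tree
#'
#' Transforms `t -> beta * t + alpha`, positions by `gamma`, volumes by
#' `gamma^3` and surfaces by `gamma^2`. Topology and cell counts are
#' untouched.
#'
#' @param tree A [lineage_tree()].
#' @param params A [rescale_params()] row or a list with `alpha`, `beta`,
#'   `gamma`.
#' @return The rescaled [lineage_tree()].
#' @export
apply_rescale <- function(tree, params) {
  al <- params$alpha[1]; be <- params$beta[1]; ga <- params$gamma[1]
  stopifnot(is.finite(al), is.finite(be), is.finite(ga), be > 0, ga > 0)
  rec <- tree$records
  rec$t <- be * rec$t + al
  rec$x <- ga * rec$x; rec$y <- ga * rec$y; rec$z <- ga * rec$z
  rec$volume <- ga^3 * rec$volume
  rec$surface <- ga^2 * rec$surface
  tree$records <- rec
  tree$window <- be * tree$window + al
  tree
}

#' Invert rescaling parameters
#'
#' @param params A [rescale_params()] row.
#' @return Parameters such that applying them after `params` restores the
#'   original tree.
#' @export
invert_rescale <- function(params) {
  list(alpha = -params$alpha[1] / params$beta[1], beta = 1 / params$beta[1],
       gamma = 1 / params$gamma[1])
}
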