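#' Kullback-Leibler divergence between two laws of the same family
#'
#' Closed form for two normals; two log-normals are handled as normals on
#' their log-space parameters (the divergence is invariant under the
#' monotone change of variable).
#'
#' @param p,q [cell_law()] objects of the same family with `sigma > 0`.
#' @return `D_KL(p || q)` in nats.
#' @export
kl_divergence <- function(p, q) {
  if (p$family != q$family) stop("family mismatch: ", p$family, " vs ", q$family)
  if (p$sigma <= 0 || q$sigma <= 0) stop("KL divergence needs sigma > 0")
  log(q$sigma / p$sigma) + (p$sigma^2 + (p$mu - q$mu)^2) / (2 * q$sigma^2) - 0.5
}

#' Symmetrised (Jeffreys) divergence
#'
#' `(D_KL(p||q) + D_KL(q||p)) / 2`.
#'
#' @inheritParams kl_divergence
#' @return The symmetrised divergence in nats.
#' @export
jeffreys_divergence <- function(p, q) {
  (kl_divergence(p, q) + kl_divergence(q, p)) / 2
}

#' Group model built from a law table
#'
#' Checks that a law table carries everything the recursive multi-level
#' model needs: initial laws `m`, `vbar`, `sbar` at the root generation and
#' per-generation laws `x`, `a`, `b` for each later generation of each type.
#'
#' @param laws A law table, e.g. from [default_group_laws()] or
#'   [fit_group_laws()].
#' @param generations Generation range the model must cover.
#' @param types Cell types the model must cover.
#' @return The law table, classed `group_model`.
#' @export
group_model <- function(laws, generations = 6:10, types = CELL_TYPES) {
  g0 <- generations[1]
  for (k in types) {
    for (f in c("m", "vbar", "sbar")) get_law(laws, g0, k, f)
    for (g in generations[-1]) for (f in c("x", "a", "b")) get_law(laws, g, k, f)
  }
  structure(laws, class = c("group_model", class(laws)))
}

#' Propagate the recursive group model across generations
#'
#' Applies the recursions `M_g = M_(g-1) + X_g` (normal: means and variances
#' add), `Vbar_g = Vbar_(g-1) * A_g` and `Sbar_g = Sbar_(g-1) * B_g`
#' (log-normal: log-space parameters add), per cell type, from the initial
#' laws at `from` up to generation `to`. The variance of division times in a
#' group is therefore the initial variance plus the summed variances of the
#' cycle lengths of all ancestor groups.
#'
#' @param model A law table holding initial laws at `from` and `x`, `a`, `b`
#'   laws for `from+1 .. to`.
#' @param from Initial generation (laws `m`, `vbar`, `sbar` must exist).
#' @param to Final generation.
#' @param types Cell types to propagate.
#' @return A law table of derived `m`, `vbar`, `sbar` laws for all
#'   generations `from..to`.
#' @export
propagate <- function(model, from = 6L, to = 10L, types = CELL_TYPES) {
  rows <- list()
  step_feature <- c(m = "x", vbar = "a", sbar = "b")
  for (k in types) {
    for (f in c("m", "vbar", "sbar")) {
      law <- get_law(model, from, k, f)
      mu <- law$mu; v <- law$sigma^2
      rows[[length(rows) + 1L]] <- law_table(from, k, f, mu, sqrt(v))
      if (to > from) for (g in (from + 1L):to) {
        inc <- get_law(model, g, k, step_feature[[f]], required = FALSE)
        if (is.null(inc)) {
          stop(sprintf("missing intermediate law '%s' for group (n = %d, k = %s)",
                       step_feature[[f]], g, k))
        }
        mu <- mu + inc$mu
        v <- v + inc$sigma^2
        rows[[length(rows) + 1L]] <- law_table(g, k, f, mu, sqrt(v))
      }
    }
  }
  do.call(rbind, rows)
}

#' Evaluate the multi-level model against measured final-group laws
#'
#' Predicts the final-generation laws of `m`, `vbar` and `sbar` from the
#' initial-generation laws via [propagate()], and compares them to the
#' measured ones with the symmetrised KL divergence. The divergence is
#' normalised by the cohort's internal variability: the mean pairwise
#' symmetrised divergence between the embryos of the cohort for the same
#' (group, feature). The normalised value `D_hat` is categorised as
#' `close` (`<= thresholds[1]`), `good` (`<= thresholds[2]`) or `far`.
#'
#' @param model A law table with initial and step laws for one embryo (or
#'   the prototype).
#' @param measured Law table of measured laws (must contain final-generation
#'   `m`, `vbar`, `sbar` rows; e.g. from [fit_group_laws()]).
#' @param cohort List of measured law tables, one per cohort member, used
#'   for the normaliser.
#' @param from,to Generation range of the propagation.
#' @param thresholds Category cut-offs on `D_hat`.
#' @return A data frame with one row per (type, feature): predicted and
#'   measured parameters, `d_sym`, `normaliser`, `d_hat`, `category`.
#' @export
evaluate_model <- function(model, measured, cohort, from = 6L, to = 10L,
                           thresholds = c(1, 2)) {
  rows <- list()
  for (k in CELL_TYPES) {
    for (f in c("m", "vbar", "sbar")) {
      meas <- get_law(measured, to, k, f, required = FALSE)
      if (is.null(meas)) next
      pred_tab <- propagate(model, from, to, types = k)
      pred <- get_law(pred_tab, to, k, f)
      d_sym <- jeffreys_divergence(pred, meas)
      # cohort normaliser: mean pairwise divergence among members holding
      # this (group, feature)
      mem <- Filter(Negate(is.null), lapply(cohort, function(tab) {
        get_law(tab, to, k, f, required = FALSE)
      }))
      norm <- NA_real_
      if (length(mem) >= 2) {
        pw <- c()
        for (i in seq_along(mem)) for (j in seq_along(mem)) if (i < j) {
          pw <- c(pw, jeffreys_divergence(mem[[i]], mem[[j]]))
        }
        norm <- mean(pw)
      }
      d_hat <- if (!is.na(norm) && norm > 1e-12) d_sym / norm else NA_real_
      cat_ <- if (is.na(d_hat)) {
        "undefined"
      } else if (d_hat <= thresholds[1]) {
        "close"
      } else if (d_hat <= thresholds[2]) "good" else "far"
      rows[[length(rows) + 1L]] <- data.frame(
        n = to, k = k, feature = f,
        mu_pred = pred$mu, sigma_pred = pred$sigma,
        mu_meas = meas$mu, sigma_meas = meas$sigma,
        d_sym = d_sym, normaliser = norm, d_hat = d_hat, category = cat_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# sum of Jeffreys divergences from candidate (mu, sg) to members; normal
# parameter space (log-normals live here through their log parameters)
jeffreys_sum <- function(mu, sg, mus, sgs) {
  d2 <- (mu - mus)^2
  sum((sg^2 + d2) / (4 * sgs^2) + (sgs^2 + d2) / (4 * sg^2) - 0.5)
}

# centroid of several (mu, sigma) under summed Jeffreys divergence: for
# fixed sigma the optimal mu is a precision-weighted mean (closed form),
# leaving a 1-D minimisation over sigma
jeffreys_centroid <- function(mus, sgs) {
  if (length(mus) == 1L) return(c(mu = mus, sigma = sgs))
  if (any(sgs <= 0)) return(c(mu = mean(mus), sigma = mean(sgs)))
  mu_of <- function(sg) {
    w <- 1 / sgs^2 + 1 / sg^2
    sum(w * mus) / sum(w)
  }
  obj <- function(sg) jeffreys_sum(mu_of(sg), sg, mus, sgs)
  o <- optimize(obj, interval = c(min(sgs) / 3, max(sgs) * 3), tol = 1e-10)
  c(mu = mu_of(o$minimum), sigma = o$minimum)
}

#' Cohort prototype as a Kullback-Leibler centroid
#'
#' For every (generation, type, feature) group present in at least two
#' cohort members, computes the law minimising the summed symmetrised KL
#' divergence to the members' laws (the "centroid" virtual embryo). Groups
#' present in a single member are copied as-is and flagged.
#'
#' @param cohort_laws List of law tables (one per embryo), e.g. from
#'   [fit_group_laws()] per embryo.
#' @param features Features included in the prototype.
#' @return A law table with extra columns `n_members`, `single_member`,
#'   `mu_spread`, `sigma_spread` (standard deviations of the member
#'   parameters).
#' @export
build_prototype <- function(cohort_laws,
                            features = c("x", "m", "vbar", "sbar", "a", "b")) {
  keys <- unique(do.call(rbind, lapply(cohort_laws, function(tab) {
    tab[tab$feature %in% features, c("n", "k", "feature")]
  })))
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    n <- keys$n[i]; k <- keys$k[i]; f <- keys$feature[i]
    mem <- Filter(Negate(is.null), lapply(cohort_laws, function(tab) {
      get_law(tab, n, k, f, required = FALSE)
    }))
    if (length(mem) == 0L) next
    mus <- vapply(mem, `[[`, numeric(1), "mu")
    sgs <- vapply(mem, `[[`, numeric(1), "sigma")
    cen <- jeffreys_centroid(mus, sgs)
    rows[[length(rows) + 1L]] <- cbind(
      law_table(n, k, f, cen[["mu"]], cen[["sigma"]]),
      data.frame(n_members = length(mem), single_member = length(mem) == 1L,
                 mu_spread = if (length(mem) > 1) sd(mus) else NA_real_,
                 sigma_spread = if (length(mem) > 1) sd(sgs) else NA_real_)
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$feature, match(out$k, CELL_TYPES), out$n), ]
  rownames(out) <- NULL
  out
}
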