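#' Bin cell features into (generation, type) groups
#'
#' Reshapes a feature table (one row per cell, see [extract_features()])
#' into long form with one row per (cell, feature) value, keeping only
#' values that are estimable: complete cycles for `x`, `vbar`, `sbar`,
#' observed divisions for `m`, and non-missing ratios for `a`, `b`. Groups
#' with no data are simply absent.
#'
#' @param features A feature table, optionally with an `embryo` column.
#' @return A long data frame with columns `embryo` (if present), `n`, `k`,
#'   `feature`, `cell_id`, `value`.
#' @export
bin_by_group <- function(features) {
  keep <- list(
    x = features$complete, m = features$divides,
    vbar = features$complete, sbar = features$complete,
    a = !is.na(features$a), b = !is.na(features$b)
  )
  out <- lapply(names(keep), function(f) {
    sel <- keep[[f]] & !is.na(features[[f]])
    if (!any(sel)) return(NULL)
    d <- data.frame(
      n = features$n[sel], k = features$k[sel], feature = f,
      cell_id = features$cell_id[sel], value = features[[f]][sel],
      stringsAsFactors = FALSE
    )
    if (!is.null(features$embryo)) d$embryo <- features$embryo[sel]
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit one parametric law to a sample
#'
#' Normal family: sample mean and unbiased standard deviation. Log-normal
#' family: mean and unbiased standard deviation of the log-values.
#'
#' @param sample Numeric values (`n >= 2`).
#' @param family `"normal"` or `"lognormal"`.
#' @return A [cell_law()].
#' @export
fit_group <- function(sample, family = c("normal", "lognormal")) {
  family <- match.arg(family)
  sample <- sample[!is.na(sample)]
  if (length(sample) < 2L) stop("need at least 2 values to fit a law")
  if (family == "lognormal") {
    if (any(sample <= 0)) stop("non-positive value under a log-normal law")
    sample <- log(sample)
  }
  cell_law(family, mean(sample), sd(sample))
}

#' Chi-square goodness-of-fit test against a fitted law
#'
#' Partitions the fitted law into equal-probability bins
#' (`max(5, floor(n/8))` of them) and tests the observed counts with
#' `bins - 1 - 2` degrees of freedom, the 2 accounting for the estimated
#' `(mu, sigma)`.
#'
#' @param sample Numeric values.
#' @param law A [cell_law()] fitted to the sample.
#' @param bins Number of bins; default as above.
#' @return The p-value; attributes `statistic`, `df`, `bins`.
#' @export
gof_chisq <- function(sample, law, bins = NULL) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (law$sigma <= 0 || sd(sample) == 0) stop("degenerate (zero-variance) sample")
  if (is.null(bins)) bins <- max(5L, floor(n / 8))
  qf <- if (law$family == "normal") qnorm else qlnorm
  brk <- qf(seq(0, 1, length.out = bins + 1L), law$mu, law$sigma)
  brk[1] <- -Inf; brk[bins + 1L] <- Inf
  obs <- tabulate(findInterval(sample, brk, left.open = TRUE), nbins = bins)
  expd <- n / bins
  stat <- sum((obs - expd)^2 / expd)
  df <- bins - 3L
  if (df < 1L) stop("too few bins for a chi-square test")
  p <- pchisq(stat, df, lower.tail = FALSE)
  attr(p, "statistic") <- stat
  attr(p, "df") <- df
  attr(p, "bins") <- bins
  p
}

#' Fit laws for every (generation, type, feature) group
#'
#' Fits the family implied by each feature (normal for `x`, `m`; log-normal
#' for `vbar`, `sbar`, `a`, `b`) to every group present in the data, flags
#' eligibility by sample size, and attaches a chi-square goodness-of-fit
#' p-value for eligible non-degenerate groups.
#'
#' @param features A feature table from [extract_features()] (or a pooled
#'   table with an `embryo` column) or an already binned long table from
#'   [bin_by_group()].
#' @param min_n Eligibility threshold on the sample size.
#' @return A law table with extra columns `n_obs`, `eligible`, `gof_p`.
#' @export
fit_group_laws <- function(features, min_n = 8L) {
  long <- if (!is.null(features$value)) features else bin_by_group(features)
  sp <- split(long, list(long$n, long$k, long$feature), drop = TRUE)
  rows <- lapply(sp, function(d) {
    fam <- FEATURE_FAMILY[[d$feature[1]]]
    n_obs <- nrow(d)
    if (n_obs < 2L) return(NULL)
    law <- fit_group(d$value, fam)
    elig <- n_obs >= min_n
    p <- NA_real_
    if (elig && law$sigma > 0) p <- as.numeric(gof_chisq(d$value, law))
    cbind(
      law_table(d$n[1], d$k[1], d$feature[1], law$mu, law$sigma),
      data.frame(n_obs = n_obs, eligible = elig, gof_p = p)
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$feature, match(out$k, CELL_TYPES), out$n), ]
  rownames(out) <- NULL
  out
}

#' Mother-daughter and sister-sister dependence report
#'
#' Pearson's R-squared between related cells' feature values, per daughter
#' group and feature, for the relations mother-daughter and sister-sister.
#' Sisters are an unordered pair, so each pair is assigned a random order
#' under a fixed seed to make the coefficient well defined and reproducible.
#' Degenerate samples (zero variance, or fewer than `min_pairs` pairs)
#' are reported as missing.
#'
#' The default features are the model's *increments* — cycle lengths `x`
#' and the daughter/mother ratios `a`, `b` — whose independence is what the
#' recursive model actually asserts. The cascade-derived features (`m`,
#' `vbar`, `sbar`) are dependent between relatives by construction (they
#' share the whole ancestral sum/product) and can be requested explicitly
#' via `feats`.
#'
#' @param features A feature table from [extract_features()].
#' @param feats Features tested.
#' @param min_pairs Minimum usable pairs per coefficient.
#' @param flag_threshold Pairs with `R^2` above this are flagged.
#' @param seed Seed for the sister ordering.
#' @return A data frame with columns `relation`, `n`, `k`, `feature`,
#'   `n_pairs`, `r2`, `flagged`.
#' @export
independence_tests <- function(features, feats = c("x", "a", "b"),
                               min_pairs = 3L, flag_threshold = 0.6,
                               seed = 1L) {
  mi <- match(features$mother_id, features$cell_id)
  has_mo <- !is.na(mi)

  # order sisters randomly within each pair, fixed seed
  set.seed(seed)
  sis <- features[has_mo, c("cell_id", "mother_id", "n", "k")]
  sp <- split(sis$cell_id, sis$mother_id)
  sp <- sp[lengths(sp) == 2L]
  flip <- runif(length(sp)) < 0.5
  s1 <- vapply(seq_along(sp), function(i) sp[[i]][1 + flip[i]], numeric(1))
  s2 <- vapply(seq_along(sp), function(i) sp[[i]][2 - flip[i]], numeric(1))

  one <- function(relation, ia, ib) {
    # ia, ib: row indices of the paired cells; grouped by the group of `ia`
    key <- paste(features$n[ia], features$k[ia])
    rows <- list()
    for (f in feats) {
      va <- features[[f]][ia]; vb <- features[[f]][ib]
      ok <- !is.na(va) & !is.na(vb)
      for (g in unique(key[ok])) {
        sel <- ok & key == g
        np <- sum(sel)
        r2 <- NA_real_
        if (np >= min_pairs && sd(va[sel]) > 0 && sd(vb[sel]) > 0) {
          r2 <- cor(va[sel], vb[sel])^2
        }
        gg <- strsplit(g, " ")[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          relation = relation, n = as.integer(gg[1]), k = gg[2], feature = f,
          n_pairs = np, r2 = r2,
          flagged = !is.na(r2) && r2 > flag_threshold,
          stringsAsFactors = FALSE
        )
      }
    }
    rows
  }
  rows <- c(
    one("mother_daughter", which(has_mo), mi[has_mo]),
    one("sister_sister", match(s1, features$cell_id), match(s2, features$cell_id))
  )
  out <- do.call(rbind, rows)
  out <- out[order(out$relation, out$feature, match(out$k, CELL_TYPES), out$n), ]
  rownames(out) <- NULL
  out
}
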