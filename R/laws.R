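#' @useDynLib blastomere, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom data.table as.data.table .N
#' @importFrom stats approx aggregate cor optimize pchisq qlnorm qnorm rlnorm
#'   rnorm runif sd quantile var prcomp
#' @importFrom utils read.table write.table head tail
NULL

#' Cell types of the 32-cell stage
#'
#' The four founder populations of the sea-urchin 32-cell embryo, ordered
#' from the animal pole to the vegetal pole: mesomeres (Mes), macromeres
#' (Mac), large micromeres (LMic) and small micromeres (SMic).
#'
#' @export
CELL_TYPES <- c("Mes", "Mac", "LMic", "SMic")

# distribution family used for each per-cell feature: cycle lengths and
# division times are modelled as normal, geometric features as log-normal
FEATURE_FAMILY <- c(
  x = "normal", m = "normal",
  vbar = "lognormal", sbar = "lognormal",
  a = "lognormal", b = "lognormal"
)

#' Parametric law of a cell feature
#'
#' A light container for a one-dimensional parametric distribution. For the
#' log-normal family `mu` and `sigma` are the mean and standard deviation of
#' the log-values (i.e. the `meanlog`/`sdlog` parameterisation).
#'
#' @param family `"normal"` or `"lognormal"`.
#' @param mu Mean (normal) or log-space mean (log-normal).
#' @param sigma Standard deviation (log-space for log-normal), `>= 0`.
#' @return An object of class `cell_law`.
#' @export
cell_law <- function(family = c("normal", "lognormal"), mu, sigma) {
  family <- match.arg(family)
  stopifnot(is.finite(mu), is.finite(sigma), sigma >= 0)
  structure(list(family = family, mu = mu, sigma = sigma), class = "cell_law")
}

#' @export
print.cell_law <- function(x, ...) {
  cat(sprintf("<cell_law %s(mu = %.4g, sigma = %.4g)>\n", x$family, x$mu, x$sigma))
  invisible(x)
}

law_mean <- function(law) {
  if (law$family == "normal") law$mu else exp(law$mu + law$sigma^2 / 2)
}

law_var <- function(law) {
  if (law$family == "normal") {
    law$sigma^2
  } else {
    (exp(law$sigma^2) - 1) * exp(2 * law$mu + law$sigma^2)
  }
}

law_rand <- function(law, n) {
  if (law$family == "normal") {
    rnorm(n, law$mu, law$sigma)
  } else {
    rlnorm(n, law$mu, law$sigma)
  }
}

#' Build a table of group laws
#'
#' Group laws are stored in a long data frame with one row per
#' (generation `n`, type `k`, feature) triple. The distribution family is
#' implied by the feature: normal for `x` (cycle length, min) and `m`
#' (division time, min), log-normal for `vbar` (mean cell volume, um^3),
#' `sbar` (mean cell surface, um^2) and the daughter/mother ratios `a`, `b`.
#'
#' @param n Generation rank(s).
#' @param k Cell type label(s), see [CELL_TYPES].
#' @param feature Feature name(s) among `x`, `m`, `vbar`, `sbar`, `a`, `b`.
#' @param mu,sigma Law parameters (log-space for log-normal features).
#' @return A `data.frame` with columns `n`, `k`, `feature`, `family`, `mu`,
#'   `sigma`.
#' @export
law_table <- function(n, k, feature, mu, sigma) {
  d <- data.frame(
    n = as.integer(n), k = as.character(k), feature = as.character(feature),
    mu = as.numeric(mu), sigma = as.numeric(sigma),
    stringsAsFactors = FALSE
  )
  bad <- !d$feature %in% names(FEATURE_FAMILY)
  if (any(bad)) stop("unknown feature(s): ", paste(unique(d$feature[bad]), collapse = ", "))
  bad <- !d$k %in% CELL_TYPES
  if (any(bad)) stop("unknown cell type(s): ", paste(unique(d$k[bad]), collapse = ", "))
  if (any(d$sigma < 0)) stop("sigma must be >= 0")
  d$family <- unname(FEATURE_FAMILY[d$feature])
  d[, c("n", "k", "feature", "family", "mu", "sigma")]
}

#' Look up one law in a law table
#'
#' @param laws A law table as returned by [law_table()] or [fit_group_laws()].
#' @param n Generation rank.
#' @param k Cell type label.
#' @param feature Feature name.
#' @param required Error (rather than return `NULL`) when the law is absent.
#' @return A [cell_law()] or `NULL`.
#' @export
get_law <- function(laws, n, k, feature, required = TRUE) {
  i <- which(laws$n == n & laws$k == k & laws$feature == feature)
  if (length(i) == 0L) {
    if (required) {
      stop(sprintf("no law for group (n = %d, k = %s), feature '%s'", n, k, feature))
    }
    return(NULL)
  }
  if (length(i) > 1L) stop("duplicate law rows for one (n, k, feature)")
  cell_law(laws$family[i], laws$mu[i], laws$sigma[i])
}
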