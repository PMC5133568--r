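test_that("fit_group matches closed forms and rejects bad input", {
  law <- fit_group(c(1, 2, 3), "normal")
  expect_equal(law$mu, 2); expect_equal(law$sigma, 1)

  law2 <- fit_group(rep(exp(1), 3), "lognormal")
  expect_equal(law2$mu, 1); expect_equal(law2$sigma, 0)
  # fitted log-normal median is exp(mu)
  expect_equal(qlnorm(0.5, law2$mu, 1), exp(law2$mu))

  expect_error(fit_group(c(1, -2, 3), "lognormal"), "non-positive")
  expect_error(fit_group(1, "normal"), "at least 2")
})

make_features <- function(seed = 5, generations = 6:9) {
  cfg <- cohort_config(n_embryos = 1, alpha = 0, beta = 1, gamma = 1,
                       generations = generations,
                       laws = default_group_laws(generations), seed = seed)
  tree <- generate_embryo(cfg, 1)$tree
  extract_features(tree)
}

test_that("bin_by_group partitions complete values and omits empty groups", {
  fe <- make_features()
  long <- bin_by_group(fe)
  # every complete x lands in exactly one group
  expect_equal(sum(long$feature == "x"), sum(fe$complete))
  # no zero-filled groups
  counts <- table(long$n, long$k, long$feature)
  expect_true(all(counts[counts > 0] >= 1))
  # root-generation ratios cannot exist (mother cycles are clipped)
  expect_false(any(long$feature == "a" & long$n <= 7))
  # m needs only the division: roots contribute
  expect_true(any(long$feature == "m" & long$n == 6))
})

test_that("chi-square GOF has nominal type-I error and real power", {
  set.seed(31)
  reps <- 1000
  pvals <- replicate(reps, {
    x <- rnorm(100, 50, 4)
    as.numeric(gof_chisq(x, fit_group(x, "normal")))
  })
  rate <- mean(pvals < 0.05)
  mc_sd <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(rate - 0.05), 4 * mc_sd)

  set.seed(32)
  punif <- replicate(20, {
    x <- runif(200, 0, 100)
    as.numeric(gof_chisq(x, fit_group(x, "normal")))
  })
  expect_gt(mean(punif < 0.01), 0.9)

  x <- rnorm(80)
  p1 <- gof_chisq(x, fit_group(x, "normal"))
  p2 <- gof_chisq(x, fit_group(x, "normal"))
  expect_identical(p1, p2)                       # deterministic
  expect_error(gof_chisq(rep(1, 50), cell_law("normal", 1, 0)), "degenerate")
})

test_that("fit_group_laws recovers the generating laws on one embryo", {
  fe <- make_features(seed = 17)
  laws_hat <- fit_group_laws(fe)
  cfg_laws <- default_group_laws(6:9)
  m <- merge(cfg_laws, laws_hat, by = c("n", "k", "feature"),
             suffixes = c("_cfg", "_hat"))
  m <- m[m$eligible, ]
  expect_gt(nrow(m), 20)
  z_mu <- (m$mu_hat - m$mu_cfg) / (m$sigma_hat / sqrt(m$n_obs))
  expect_true(all(abs(z_mu) < 4))
  expect_true(all(laws_hat$family[laws_hat$feature %in% c("x", "m")] == "normal"))
  expect_true(all(laws_hat$family[laws_hat$feature %in% c("vbar", "a")] == "lognormal"))
})

test_that("independence report: exact dependence, degeneracy, null behaviour", {
  fe <- make_features(seed = 23)
  rep_ <- independence_tests(fe)
  expect_true(all(rep_$r2 >= 0 & rep_$r2 <= 1, na.rm = TRUE))

  # construct exact mother-daughter dependence: daughter x = mother x
  fe2 <- make_features(seed = 24)
  mi <- match(fe2$mother_id, fe2$cell_id)
  ok <- !is.na(mi) & fe2$complete & fe2$complete[mi] & fe2$n == 8
  fe2$x[ok] <- fe2$x[mi[ok]]
  r2 <- independence_tests(fe2)
  md_x <- r2[r2$relation == "mother_daughter" & r2$feature == "x" &
               r2$n == 8 & !is.na(r2$r2), ]
  expect_gt(nrow(md_x), 0)
  expect_true(all(md_x$r2 > 0.999))

  # constant feature -> missing R2
  fe3 <- fe
  fe3$x[] <- 50
  r3 <- independence_tests(fe3)
  expect_true(all(is.na(r3$r2[r3$feature == "x"])))

  # independent draws: few flagged coefficients among decently sized groups
  # (tiny groups have a high null rate for R^2 > 0.6 by chance)
  big <- !is.na(rep_$r2) & rep_$n_pairs >= 10
  expect_gt(sum(big), 5)
  expect_lt(mean(rep_$flagged[big]), 0.25)
})
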