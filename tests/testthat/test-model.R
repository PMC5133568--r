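test_that("closed-form KL matches quadrature and basic identities", {
  p <- cell_law("normal", 0, 1)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, cell_law("normal", 1, 1)), 0.5)
  expect_error(kl_divergence(p, cell_law("lognormal", 0, 1)), "family mismatch")
  expect_error(kl_divergence(p, cell_law("normal", 0, 0)), "sigma > 0")

  set.seed(7)
  for (r in 1:50) {
    fam <- if (r %% 2 == 0) "normal" else "lognormal"
    a <- cell_law(fam, runif(1, -2, 5), runif(1, 0.1, 2))
    b <- cell_law(fam, runif(1, -2, 5), runif(1, 0.1, 2))
    expect_lt(abs(kl_divergence(a, b) - kl_quadrature(a, b)), 1e-6)
  }
})

test_that("KL is non-negative, zero iff identical (property sweep)", {
  set.seed(8)
  for (r in 1:1000) {
    a <- cell_law("normal", runif(1, -5, 5), runif(1, 0.05, 3))
    b <- cell_law("normal", runif(1, -5, 5), runif(1, 0.05, 3))
    d <- kl_divergence(a, b)
    expect_gte(d, 0)
    if (d < 1e-12) {
      expect_lt(abs(a$mu - b$mu) + abs(a$sigma - b$sigma), 1e-5)
    }
  }
})

test_that("propagation follows the closed-form recursions", {
  laws <- rbind(
    law_table(6, "Mes", "m", 360, 10),
    law_table(6, "Mes", "vbar", 4.6, 0.1),
    law_table(6, "Mes", "sbar", 8, 0.1),
    law_table(7, "Mes", "x", 50, 5),
    law_table(7, "Mes", "a", -0.69, 0.05),
    law_table(7, "Mes", "b", -0.46, 0.05)
  )
  pr <- propagate(laws, 6, 7, types = "Mes")
  m7 <- get_law(pr, 7, "Mes", "m")
  expect_equal(m7$mu, 410)
  expect_equal(m7$sigma, sqrt(125))
  v7 <- get_law(pr, 7, "Mes", "vbar")
  expect_equal(v7$mu, 4.6 - 0.69)
  expect_equal(v7$sigma, sqrt(0.0125))

  full <- default_group_laws(6:10)
  pr10 <- propagate(full, 6, 10, types = "Mac")
  v_expect <- get_law(full, 6, "Mac", "m")$sigma^2 +
    sum(vapply(7:10, function(g) get_law(full, g, "Mac", "x")$sigma^2,
               numeric(1)))
  expect_equal(get_law(pr10, 10, "Mac", "m")$sigma^2, v_expect)

  broken <- laws[!(laws$n == 7 & laws$feature == "x"), ]
  expect_error(propagate(broken, 6, 7, types = "Mes"), "missing intermediate")
})

test_that("prototype centroid: identities, symmetry, grid-search oracle", {
  one <- law_table(7, "Mes", "x", 50, 5)
  proto <- build_prototype(list(one, one, one))
  expect_equal(proto$mu, 50, tolerance = 1e-6)
  expect_equal(proto$sigma, 5, tolerance = 1e-5)
  expect_equal(proto$n_members, 3L)

  two <- list(law_table(7, "Mes", "x", 0, 1), law_table(7, "Mes", "x", 2, 1))
  cen <- build_prototype(two)
  expect_equal(cen$mu, 1, tolerance = 1e-6)   # symmetry

  # grid-search oracle on 5 random members
  set.seed(9)
  mus <- runif(5, 40, 60); sgs <- runif(5, 2, 8)
  members <- lapply(1:5, function(i) law_table(7, "Mes", "x", mus[i], sgs[i]))
  got <- build_prototype(members)
  objective <- function(mu, sg) {
    sum(vapply(1:5, function(i) {
      jeffreys_divergence(cell_law("normal", mu, sg),
                          cell_law("normal", mus[i], sgs[i]))
    }, numeric(1)))
  }
  grid <- expand.grid(mu = seq(40, 60, by = 0.05), sg = seq(2, 8, by = 0.02))
  vals <- mapply(objective, grid$mu, grid$sg)
  best <- grid[which.min(vals), ]
  expect_lt(abs(got$mu - best$mu), 0.1)
  expect_lt(abs(got$sigma - best$sg), 0.04)
  # centroid objective no worse than the best grid point or any member
  expect_lte(objective(got$mu, got$sigma), min(vals) + 1e-9)
  for (i in 1:5) expect_lte(objective(got$mu, got$sigma), objective(mus[i], sgs[i]))

  # groups present in one member only are copied and flagged
  part <- list(law_table(7, "Mes", "x", 50, 5),
               rbind(law_table(7, "Mes", "x", 52, 6),
                     law_table(8, "Mes", "x", 70, 7)))
  pp <- build_prototype(part)
  row8 <- pp[pp$n == 8, ]
  expect_true(row8$single_member)
  expect_equal(row8$mu, 70)
})

test_that("model evaluation categorises and guards the normaliser", {
  model <- default_group_laws(6:8)
  pred <- propagate(model, 6, 8)
  # measured == predicted -> D_hat = 0, category close
  cohortA <- pred; cohortB <- pred
  cohortB$mu <- cohortB$mu * 1.02 + 0.5
  ev <- evaluate_model(model, pred, list(cohortA, cohortB), from = 6, to = 8)
  expect_true(all(ev$d_sym < 1e-12))
  expect_true(all(ev$category == "close"))

  # identical cohort members -> normaliser undefined
  ev2 <- evaluate_model(model, pred, list(cohortA, cohortA), from = 6, to = 8)
  expect_true(all(is.na(ev2$d_hat)))
  expect_true(all(ev2$category == "undefined"))
})

test_that("model fitted on its own simulated data evaluates as close", {
  laws <- default_group_laws(6:9)
  # five pseudo-embryos, each a pooled pair of simulated lineages
  cohort_stats <- lapply(1:5, function(e) {
    fe <- do.call(rbind, lapply(1:2, function(r) {
      cfg <- cohort_config(n_embryos = 1, alpha = 0, beta = 1, gamma = 1,
                           generations = 6:9, laws = laws,
                           normalize_roots = FALSE, seed = 100 * e + r)
      extract_features(generate_embryo(cfg, 1)$tree)
    }))
    fit_group_laws(fe)
  })
  model <- cohort_stats[[1]]
  # start from the first fully observed generation (root geometric laws are
  # structurally unobservable when the record begins at the 32-cell stage)
  ev <- evaluate_model(model, cohort_stats[[1]], cohort_stats, from = 7, to = 9)
  ok <- !is.na(ev$d_hat)
  expect_gt(sum(ok), 4)
  expect_true(all(ev$category[ok] %in% c("close", "good")))
})
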