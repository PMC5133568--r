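test_that("pair force profile: zeros, signs, continuity", {
  pm <- mech_params()
  Ri <- Rj <- 10
  r_eq <- pm$c_eq * 10; r_max <- pm$c_max * 10
  expect_equal(pair_force(r_eq, Ri, Rj, TRUE, pm), 0)
  expect_equal(pair_force(r_max, Ri, Rj, TRUE, pm), 0)
  expect_equal(pair_force(r_max + 5, Ri, Rj, TRUE, pm), 0)
  expect_gt(pair_force(0.5 * r_eq, Ri, Rj, TRUE, pm), 0)       # repulsive
  mid <- (r_eq + r_max) / 2
  expect_lt(pair_force(mid, Ri, Rj, TRUE, pm), 0)              # adhesive
  # heterotypic adhesion uses its own coefficient
  expect_equal(pair_force(mid, Ri, Rj, FALSE, pm) * pm$omega_adh_o,
               pair_force(mid, Ri, Rj, TRUE, pm) * pm$omega_adh_e)
  # continuity across r_eq
  eps <- 1e-9
  expect_lt(abs(pair_force(r_eq - eps, Ri, Rj, TRUE, pm) -
                pair_force(r_eq + eps, Ri, Rj, TRUE, pm)), 1e-6)
})

test_that("attraction-repulsion obeys Newton's third law", {
  st <- shell_state(n = 20, R0 = 15, r_cell = 10)
  pm <- mech_params()
  f12 <- attraction_repulsion(st, 1, 2, pm)
  f21 <- attraction_repulsion(st, 2, 1, pm)
  expect_equal(f12, -f21)
  ff <- mech_forces(st, pm)
  expect_lt(max(abs(colSums(ff$F_ar))), 1e-9)
})

test_that("contact graph matches a brute-force all-pairs oracle", {
  set.seed(12)
  n <- 100
  pos <- matrix(runif(3 * n, 0, 60), ncol = 3)
  rad <- runif(n, 5, 12)
  st <- mech_state(pos, rad, sample(CELL_TYPES, n, replace = TRUE))
  pm <- mech_params()
  got <- contact_graph(st, pm)
  want <- do.call(rbind, lapply(1:(n - 1), function(i) {
    do.call(rbind, lapply((i + 1):n, function(j) {
      r <- sqrt(sum((pos[i, ] - pos[j, ])^2))
      if (r < pm$c_max * (rad[i] + rad[j]) / 2) data.frame(i = i, j = j, r = r)
    }))
  }))
  key <- function(d) paste(pmin(d$i, d$j), pmax(d$i, d$j))
  expect_setequal(key(got), key(want))
  # symmetric by construction, i < j once
  expect_true(all(got$i < got$j))
})

test_that("planarity force: coplanar limit, restoring sign, linearity", {
  # antipodal pairs put the centroid exactly at the sphere centre, so the
  # outward normals are exactly radial
  half <- shell_state(n = 64, R0 = 40, r_cell = 10)
  st <- mech_state(rbind(half$pos, -half$pos), rep(10, 128),
                   rep(half$type, 2))
  pm <- mech_params()
  # cells on a common sphere with radial axes: planarity force vanishes
  ff <- mech_forces(st, pm)
  expect_lt(max(abs(ff$F_plan)) / pm$k_rig, 1e-8)

  # displace one cell radially inward: restoring force points outward
  probe <- function(offset) {
    st2 <- st
    ax <- st2$pos[1, ] / sqrt(sum(st2$pos[1, ]^2))
    st2$pos[1, ] <- st2$pos[1, ] - offset * ax
    f <- mech_forces(st2, pm)$F_plan[1, ]
    sum(f * ax)   # radial component
  }
  expect_gt(probe(1), 0)
  # magnitude linear in the displacement for small offsets
  slope1 <- probe(0.01) / 0.01
  slope2 <- probe(0.02) / 0.02
  expect_lt(abs(slope1 - slope2) / slope1, 0.05)
})

test_that("centroid is conserved by pairwise forces (k_rig = 0 contract)", {
  set.seed(13)
  pos <- matrix(rnorm(3 * 30, sd = 8), ncol = 3)
  st <- mech_state(pos, rep(6, 30), sample(CELL_TYPES, 30, replace = TRUE))
  pm <- mech_params(k_rig = 0)
  before <- colMeans(st$pos)
  st2 <- mech_step(st, pm, steps = 50)
  expect_equal(colMeans(st2$pos), before, tolerance = 1e-9)
})

test_that("an isolated homotypic pair relaxes to the equilibrium distance", {
  pm <- mech_params()
  r0 <- 12; req <- pm$c_eq * r0
  st <- mech_state(rbind(c(0, 0, 0), c(0.4 * req, 0, 0)), c(r0, r0),
                   c("Mac", "Mac"))
  out <- mech_relax(st, pm, max_steps = 3000)
  expect_lt(abs(dist(out$pos) - req) / req, 1e-3)
  # from the adhesive side too
  st2 <- mech_state(rbind(c(0, 0, 0), c(1.2 * req, 0, 0)), c(r0, r0),
                    c("Mac", "Mac"))
  out2 <- mech_relax(st2, pm, max_steps = 3000)
  expect_lt(abs(dist(out2$pos) - req) / req, 1e-3)
})

test_that("daughter placement is tangential and symmetric", {
  set.seed(14)
  for (r in 1:20) {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    x <- rnorm(3, sd = 20)
    rd <- runif(2, 5, 10)
    dp <- place_daughters(x, ax, rd, theta = runif(1, 0, 2 * pi))
    sep <- dp[1, ] - dp[2, ]
    expect_lt(abs(sum(sep * ax)), 1e-8)                  # orthogonal to axis
    expect_equal(colMeans(dp), x, tolerance = 1e-12)     # symmetric
    expect_equal(sqrt(sum(sep^2)), 0.5 * 0.9 * mean(rd)) # half r_eq apart
  }
})

test_that("embedding a lineage is deterministic and stays monolayered", {
  laws0 <- default_group_laws(6:8); laws0$sigma <- 0
  cells <- simulate_lineage(laws0, seed = 1, generations = 6:8)
  pm <- mech_params()
  tr1 <- embed_lineage(cells, pm, seed = 3, checkpoint_every = 5L)
  tr2 <- embed_lineage(cells, pm, seed = 3, checkpoint_every = 5L)
  expect_identical(tr1$states[[length(tr1$states)]]$pos,
                   tr2$states[[length(tr2$states)]]$pos)
  fin <- tr1$states[[length(tr1$states)]]
  expect_equal(length(fin$cell_id), 128L)
  expect_gt(as.numeric(planarity(fin, pm)), 0.9)
  expect_gt(sphericity(fin), 0.9)
})
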