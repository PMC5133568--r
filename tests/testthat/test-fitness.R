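test_that("sphericity: sphere, concentric shells, isometry invariance", {
  # antipodal pairs put the centroid exactly at the sphere centre
  half <- shell_state(n = 40, R0 = 30, r_cell = 8)
  st <- mech_state(rbind(half$pos, -half$pos), rep(8, 80),
                   rep(half$type, 2))
  expect_equal(sphericity(st), 1, tolerance = 1e-9)

  two <- st
  two$pos[1:40, ] <- two$pos[1:40, ] / 2      # half on an inner sphere
  expect_lt(sphericity(two), sphericity(st))

  # rigid rotation + translation
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- st
  rot$pos <- st$pos %*% t(R) + matrix(rep(c(5, -3, 11), each = 80), ncol = 3)
  expect_equal(sphericity(rot), sphericity(st), tolerance = 1e-9)
})

test_that("planarity separates a shell from a solid ball", {
  pm <- mech_params()
  shell <- shell_state(n = 200, R0 = 42, r_cell = 10)
  p_shell <- as.numeric(planarity(shell, pm))
  expect_gt(p_shell, 0.95)

  set.seed(15)
  ball <- mech_state(matrix(runif(600, -21, 21), ncol = 3), rep(10, 200),
                     sample(CELL_TYPES, 200, replace = TRUE))
  p_ball <- as.numeric(planarity(ball, pm))
  expect_gt(p_shell - p_ball, 0.2)

  th <- 1.1
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  # rotation can flip borderline contact edges at machine precision, so the
  # score is invariant only up to that discreteness
  rot <- shell; rot$pos <- shell$pos %*% t(R)
  expect_equal(as.numeric(planarity(rot, pm)), p_shell, tolerance = 1e-4)
})

test_that("border similarity: zero at reference, permutation null, symmetry", {
  pm <- mech_params()
  st <- shell_state(n = 128, R0 = 34, r_cell = 10)
  ref <- border_descriptor(st, pm)
  expect_equal(as.numeric(border_similarity(st, ref, pm)), 0)

  set.seed(16)
  worse <- 0
  for (r in 1:20) {
    perm <- st
    perm$type <- sample(perm$type)
    if (as.numeric(border_similarity(perm, ref, pm)) > 0) worse <- worse + 1
  }
  expect_gte(worse, 19)   # banded layout beats shuffled labels

  # symmetry in the two populations of a border
  ref_swapped <- border_descriptor(st, pm,
                                   borders = list(c("Mac", "Mic"), c("Mes", "Mac")))
  expect_equal(ref$n_edges, ref_swapped$n_edges)
  expect_equal(ref$tortuosity, ref_swapped$tortuosity)
})

test_that("combined fitness is monotone in each component", {
  expect_gt(combined_fitness(0.9, 0.8, 0.1), combined_fitness(0.8, 0.8, 0.1))
  expect_gt(combined_fitness(0.9, 0.9, 0.1), combined_fitness(0.9, 0.8, 0.1))
  expect_gt(combined_fitness(0.9, 0.8, 0.1), combined_fitness(0.9, 0.8, 0.3))
})

test_that("phase labels are exclusive and cover all score combinations", {
  lab <- blastomere:::phase_label
  expect_equal(lab(0.95, 0.95), "spherical-planar")
  expect_equal(lab(0.95, 0.5), "collapsed")
  expect_equal(lab(0.6, 0.95), "polylobular")
  expect_equal(lab(0.8, 0.8), "other")
  set.seed(17)
  for (r in 1:200) {
    l <- lab(runif(1), runif(1))
    expect_true(l %in% c("spherical-planar", "polylobular", "collapsed", "other"))
  }
})

test_that("a small sweep runs to completion with full bookkeeping", {
  laws0 <- default_group_laws(6:7); laws0$sigma <- 0
  cells <- simulate_lineage(laws0, seed = 2, generations = 6:7)
  sw <- sweep_adhesion(cells, mech_params(),
                       grid_o = c(30, 300, 900), grid_e = c(30, 300, 900),
                       replicates = 2, base_seed = 5)
  expect_equal(nrow(sw$runs), 18L)
  expect_equal(nrow(sw$summary), 9L)
  expect_true(all(sw$summary$phase %in%
                  c("spherical-planar", "polylobular", "collapsed", "other")))
  # determinism of seeded runs
  sw2 <- sweep_adhesion(cells, mech_params(),
                        grid_o = c(30, 300, 900), grid_e = c(30, 300, 900),
                        replicates = 2, base_seed = 5)
  expect_identical(sw$runs$S_s, sw2$runs$S_s)
  expect_identical(sw$runs$fitness, sw2$runs$fitness)
})
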