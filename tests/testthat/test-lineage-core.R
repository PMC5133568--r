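test_that("read_lineage round-trips the canonical dialect byte for byte", {
  tree <- toy_tree()
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_lineage(tree, f1)
  back <- read_lineage(f1)
  expect_s3_class(back, "lineage_tree")
  expect_equal(length(unique(back$records$cell_id)), 3L)
  expect_equal(nrow(back$records), nrow(tree$records))
  write_lineage(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("hpf time unit is converted to minutes on read", {
  tree <- toy_tree()
  f <- tempfile(fileext = ".tsv")
  lines <- readLines(write_lineage(tree, f))
  lines[1] <- "# time_unit: hpf"
  writeLines(lines, f)
  back <- read_lineage(f)
  expect_equal(sort(unique(back$records$t)), sort(unique(tree$records$t)) * 60)
})

test_that("structural invariants are enforced with cell names in errors", {
  tree <- toy_tree()

  three <- tree$records
  extra <- three[three$cell_id == 2L, ]
  extra$cell_id <- 4L
  expect_error(validate_lineage(lineage_tree(rbind(three, extra))),
               "daughters other than 2")

  gap <- tree$records
  gap <- gap[!(gap$cell_id == 2L & gap$t == 14), ]
  expect_error(validate_lineage(lineage_tree(gap, window = tree$window)),
               "[Nn]on-contiguous.*2")

  orphan <- tree$records
  orphan$mother_id[orphan$cell_id == 2L] <- 99L
  expect_error(validate_lineage(lineage_tree(orphan)), "mother reference.*2")

  late <- tree$records
  late$mother_id[late$cell_id %in% 2:3] <- NA_integer_
  expect_error(validate_lineage(lineage_tree(late)), "without mother")

  bad_vol <- tree$records
  bad_vol$volume[1] <- -1
  expect_error(validate_lineage(lineage_tree(bad_vol)), "volume")
})

test_that("generations and types propagate from the roots", {
  # chain: 1 -> (2,3); 2 -> (4,5): leaves at root_generation + 2
  rec <- toy_tree()$records
  rec2 <- rbind(
    rec,
    data.frame(cell_id = 4:5, mother_id = 2L, t = 20, x = 0, y = 0, z = 0,
               type = NA_character_, volume = 25, surface = 41,
               gen = NA_integer_)
  )
  rec2$type[rec2$cell_id %in% 2:3] <- NA
  tree <- assign_generations_and_types(lineage_tree(rec2), root_generation = 6L)
  idx <- tree$records
  expect_equal(unique(idx$gen[idx$cell_id == 1L]), 6L)
  expect_equal(unique(idx$gen[idx$cell_id %in% 4:5]), 8L)
  expect_true(all(idx$type == "Mes"))

  # two roots with distinct labels keep their descent separate
  two <- rbind(
    data.frame(cell_id = 1L, mother_id = NA_integer_, t = c(0, 2), x = 0, y = 0,
               z = 0, type = "Mes", volume = 1, surface = 1),
    data.frame(cell_id = 2L, mother_id = NA_integer_, t = c(0, 2), x = 1, y = 0,
               z = 0, type = "SMic", volume = 1, surface = 1),
    data.frame(cell_id = 3:4, mother_id = 1L, t = 4, x = 0, y = 0, z = 0,
               type = NA, volume = 1, surface = 1),
    data.frame(cell_id = 5:6, mother_id = 2L, t = 4, x = 1, y = 0, z = 0,
               type = NA, volume = 1, surface = 1)
  )
  tree2 <- assign_generations_and_types(lineage_tree(two))
  idx2 <- cell_index <- tree2$records
  expect_equal(unique(idx2$type[idx2$cell_id %in% 3:4]), "Mes")
  expect_equal(unique(idx2$type[idx2$cell_id %in% 5:6]), "SMic")

  unl <- two
  unl$type[unl$cell_id == 2L] <- NA
  expect_error(assign_generations_and_types(lineage_tree(unl)),
               "unlabelled root.*2")
})

test_that("feature extraction: averages, ratios, completeness", {
  tree <- assign_generations_and_types(toy_tree(vol_mother = 100,
                                                vol_daughters = c(50, 80)))
  fe <- extract_features(tree)
  m <- fe[fe$cell_id == 1L, ]
  expect_equal(m$vbar, 100)          # constant volume -> average 100
  expect_equal(m$m, 10)              # daughters appear at t = 10
  expect_false(m$complete)           # root: birth unobserved
  expect_true(m$divides)

  d <- fe[fe$cell_id == 2L, ]
  expect_false(d$complete)           # terminal cell: division unobserved
  expect_true(is.na(d$a))            # ratio needs both cycles complete

  # ratios need a three-generation chain: both the cell and its mother must
  # have fully observed cycles
  row_of <- function(id, mo, t, vol) {
    data.frame(cell_id = id, mother_id = mo, t = t, x = 0, y = 0, z = 0,
               type = "Mac", volume = vol, surface = 4 * vol^(2 / 3))
  }
  chain <- rbind(
    row_of(1L, NA_integer_, c(0, 2), 400),          # root, divides at t = 4
    row_of(2L, 1L, c(4, 6), 200),                   # divides at t = 8
    row_of(3L, 1L, seq(4, 20, 2), 180),
    row_of(4L, 2L, seq(8, 12, 2), 100),             # divides at t = 14
    row_of(5L, 2L, seq(8, 20, 2), 90),
    row_of(6L, 4L, seq(14, 20, 2), 50),
    row_of(7L, 4L, seq(14, 20, 2), 45)
  )
  tree2 <- assign_generations_and_types(lineage_tree(chain, validate = TRUE))
  fe2 <- extract_features(tree2)
  mid <- fe2[fe2$cell_id == 4L, ]
  expect_true(mid$complete)
  expect_equal(mid$x, 14 - 8)
  expect_equal(mid$a, 100 / 200)     # vbar ratio to its (complete) mother
  # filiation: m_daughter = m_mother + x_daughter
  expect_equal(mid$m, fe2$m[fe2$cell_id == 2L] + mid$x)
  # the root's daughters have no estimable ratio (root cycle clipped)
  expect_true(is.na(fe2$a[fe2$cell_id == 2L]))
})

test_that("embryo curves: steps, totals and the partition property", {
  tree <- assign_generations_and_types(toy_tree())
  cu <- embryo_curves(tree)
  nall <- cu[cu$type == "all", ]
  expect_equal(nall$N[nall$t == 8], 1)
  expect_equal(nall$N[nall$t == 10], 2)   # division at t = 10
  expect_equal(nall$W[nall$t == 10], 100) # two cells of 50

  cfg <- cohort_config(n_embryos = 1, alpha = 0, beta = 1, gamma = 1,
                       generations = 6:8, laws = default_group_laws(6:8),
                       seed = 7)
  tree2 <- generate_embryo(cfg, 1)$tree
  cu2 <- embryo_curves(tree2)
  per <- cu2[cu2$type != "all", ]
  agg <- aggregate(cbind(N, W, Z) ~ t, per, sum)
  whole <- cu2[cu2$type == "all", ][, c("t", "N", "W", "Z")]
  expect_equal(agg[order(agg$t), ], whole[order(whole$t), ],
               ignore_attr = TRUE)
})

test_that("contact degrees join and validate", {
  tree <- toy_tree()
  contacts <- data.frame(t = 10, cell_a = 2L, cell_b = 3L)
  tr2 <- contact_degrees(tree, contacts)
  rec <- tr2$records
  expect_equal(rec$degree[rec$cell_id == 2L & rec$t == 10], 1L)
  expect_equal(rec$degree[rec$cell_id == 3L & rec$t == 10], 1L)  # symmetric
  expect_equal(rec$degree[rec$cell_id == 1L & rec$t == 0], 0L)   # isolated
  expect_error(contact_degrees(tree, data.frame(t = 10, cell_a = 2L,
                                                cell_b = 42L)),
               "unknown cell")
})

test_that("sigma = 0 synthetic embryo returns exactly the configured values", {
  laws <- tiny_laws()
  cfg <- cohort_config(n_embryos = 1, alpha = 0, beta = 1, gamma = 1,
                       generations = 6:8, laws = laws, divide_last = TRUE,
                       normalize_roots = FALSE, seed = 1)
  tree <- generate_embryo(cfg, 1)$tree
  fe <- extract_features(tree)
  for (k in CELL_TYPES) {
    comp <- fe[fe$complete & fe$k == k & fe$n == 7, ]
    expect_equal(unique(comp$x), get_law(laws, 7, k, "x")$mu)
    # ratios need the mother's cycle complete too, so the first estimable
    # ratio generation is 8
    comp8 <- fe[fe$complete & fe$k == k & fe$n == 8, ]
    expect_equal(unique(round(comp8$a, 10)),
                 round(exp(get_law(laws, 8, k, "a")$mu), 10))
  }
})
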