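test_that("degenerate keeps N-k originals and adds k pool proteins", {
  fam <- protein_set(sprintf("F%02d", 1:10), "fam")
  pool <- protein_set(sprintf("Q%02d", 1:30), "pool")

  expect_identical(degenerate(fam, pool, 0), fam)

  withr::with_seed(1, {
    full <- degenerate(fam, pool, 1)
    expect_length(intersect(full$members, fam$members), 0)
    expect_length(full$members, 10)

    mid <- degenerate(fam, pool, 0.3)
    expect_length(intersect(mid$members, fam$members), 7)
    expect_length(intersect(mid$members, pool$members), 3)
    expect_false(anyDuplicated(mid$members) > 0)

    # round-half-up: 0.25 of 10 -> 3 replacements
    up <- degenerate(fam, pool, 0.25)
    expect_length(intersect(up$members, pool$members), 3)
  })
})

test_that("degenerate validates disjointness and pool capacity", {
  fam <- protein_set(sprintf("F%02d", 1:10), "fam")
  expect_error(degenerate(fam, protein_set(c("F01", "Q1")), 0.5),
               "disjoint")
  expect_error(withr::with_seed(1, degenerate(fam, protein_set("Q1"), 0.5)),
               "pool too small")
  expect_error(degenerate(fam, protein_set("Q1"), 1.5), "fraction")
})

test_that("run_assay is deterministic and exact at level 0", {
  fx <- make_benchmark_fixture(n_family = 8L, n_pool = 60L, seed = 2)
  cfg <- assay_config(levels = c(0, 0.5), iterations = 3, seed = 11,
                      min_family_size = 5, metrics = c("agreement", "ui"))
  prof <- run_assay(fx$family, fx$pool, fx$corpus, fx$ontology, config = cfg)
  level0 <- prof[prof$level == 0, ]
  expect_equal(level0$sd, c(0, 0))
  expect_equal(level0$mean[level0$metric == "ui"],
               set_similarity(fx$family, fx$corpus, "ui")$value)
  expect_equal(level0$mean[level0$metric == "agreement"],
               agreement(fx$family, fx$corpus))

  again <- run_assay(fx$family, fx$pool, fx$corpus, fx$ontology,
                     config = cfg)
  expect_identical(prof, again)
})

test_that("similarity of a cohesive family degrades under full noise", {
  fx <- make_benchmark_fixture(n_family = 10L, n_pool = 120L, seed = 5)
  cfg <- assay_config(levels = c(0, 1), iterations = 10, seed = 3,
                      min_family_size = 5, metrics = "ui")
  prof <- run_assay(fx$family, fx$pool, fx$corpus, fx$ontology, config = cfg)
  expect_lt(prof$mean[prof$level == 1], prof$mean[prof$level == 0])
})

test_that("families below the minimal size are skipped with a message", {
  fx <- make_benchmark_fixture(n_family = 8L, n_pool = 40L, seed = 2)
  cfg <- assay_config(min_family_size = 20)
  expect_message(
    out <- run_assay(fx$family, fx$pool, fx$corpus, fx$ontology,
                     config = cfg),
    "skipped"
  )
  expect_null(out)
})

test_that("assay_config validates levels and iterations", {
  expect_error(assay_config(levels = c(0.5, 0.1)), "ascending")
  expect_error(assay_config(levels = c(0, 1.2)), "levels")
  expect_error(assay_config(iterations = 0), "iterations")
})

test_that("resolution averages per-family ranges across families", {
  prof <- data.frame(
    family = rep(c("A", "B"), each = 3),
    metric = "ui",
    level = rep(c(0, 0.5, 1), 2),
    mean = c(0.9, 0.6, 0.3, 0.8, 0.8, 0.8)
  )
  expect_equal(resolution(prof, "ui"), mean(c(0.6, 0)))

  constant <- prof[prof$family == "B", ]
  expect_equal(resolution(constant, "ui"), 0)

  expect_error(resolution(prof[0, ]), "empty")
  expect_error(resolution(prof[prof$level == 0, ], "ui"), "2 levels")
  expect_error(resolution(prof, "nope"), "no rows")
})

test_that("custom metric functions plug into the assay", {
  fx <- make_benchmark_fixture(n_family = 8L, n_pool = 60L, seed = 2)
  cfg <- assay_config(levels = c(0, 1), iterations = 2, seed = 1,
                      min_family_size = 5,
                      metrics = list(constant = function(set, corpus,
                                                         ontology, ic,
                                                         alpha) 0.42))
  prof <- run_assay(fx$family, fx$pool, fx$corpus, fx$ontology, config = cfg)
  expect_equal(unique(prof$metric), "constant")
  expect_equal(prof$mean, c(0.42, 0.42))
})
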