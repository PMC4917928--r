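test_that("agreement is 1 at full agreement and scales with sharing", {
  ont <- demo_ontology()
  same <- annotation_corpus(list(P1 = c("a1", "b"), P2 = c("a1", "b"),
                                 P3 = c("a1", "b")), ont)
  expect_equal(agreement(protein_set(c("P1", "P2", "P3")), same), 1)

  disjoint <- annotation_corpus(list(P1 = "a1", P2 = "b"), ont)
  expect_equal(agreement(protein_set(c("P1", "P2")), disjoint), 0.5)

  unique4 <- annotation_corpus(list(P1 = "a1", P2 = "a2", P3 = "b",
                                    P4 = "a"), ont)
  expect_equal(agreement(protein_set(c("P1", "P2", "P3", "P4")), unique4),
               4 / 16)

  empty <- annotation_corpus(list(), ont, extra_proteins = c("X1", "X2"))
  expect_equal(agreement(protein_set(c("X1", "X2")), empty), 0)
})

test_that("sim_ui follows the intersection-over-union definition", {
  expect_equal(sim_ui(c("a", "b"), c("a", "b")), 1)
  expect_equal(sim_ui(c("a1", "a", "r"), c("a2", "a", "r")), 0.5)
  expect_equal(sim_ui(character(), c("b", "r")), 0)
  expect_equal(sim_ui(character(), character()), 0)
})

test_that("sim_gic weights the overlap by information content", {
  corp <- demo_corpus()
  ic <- ic_table(corp)
  expect_equal(sim_gic(corp$extended$P1, corp$extended$P1, ic), 1)
  # intersection {a, r}: IC 0.2877; union {a, a1, a2, r}: IC sum 2.3671
  expect_equal(sim_gic(corp$extended$P1, corp$extended$P3, ic),
               0.1215323, tolerance = 1e-6)
  # IC sum of union equal to zero (both sets reduce to the root)
  expect_equal(sim_gic("r", "r", ic), 0)
  expect_error(sim_gic(c("a", "zzz"), "a", ic), "undefined")
})

test_that("sim_gic reduces to sim_ui under constant IC", {
  sim <- random_corpus(21)
  corp <- sim$corpus
  flat_ic <- stats::setNames(rep(1, length(corp$term_index)),
                             names(corp$term_index))
  prots <- names(corp$extended)
  for (i in 1:10) {
    pair <- sample(prots, 2)
    a <- corp$extended[[pair[[1]]]]
    b <- corp$extended[[pair[[2]]]]
    expect_equal(sim_gic(a, b, flat_ic), sim_ui(a, b))
  }
})

test_that("pairwise metrics are symmetric, bounded, and UI-monotone", {
  sim <- random_corpus(33)
  corp <- sim$corpus
  ic <- ic_table(corp)
  prots <- names(corp$extended)
  withr::with_seed(33, {
    for (i in 1:20) {
      pair <- sample(prots, 2)
      a <- corp$extended[[pair[[1]]]]
      b <- corp$extended[[pair[[2]]]]
      expect_equal(sim_ui(a, b), sim_ui(b, a))
      expect_equal(sim_gic(a, b, ic), sim_gic(b, a, ic))
      expect_gte(sim_ui(a, b), 0); expect_lte(sim_ui(a, b), 1)
      expect_gte(sim_gic(a, b, ic), 0); expect_lte(sim_gic(a, b, ic), 1)
      # adding a shared term never decreases sim_ui
      shared <- "NEW"
      expect_gte(sim_ui(c(a, shared), c(b, shared)), sim_ui(a, b))
    }
  })
})

test_that("set_similarity averages all unordered pairs", {
  corp <- demo_corpus()
  same <- annotation_corpus(list(P1 = "a1", P2 = "a1", P3 = "a1"),
                            demo_ontology())
  expect_equal(set_similarity(protein_set(c("P1", "P2", "P3")), same,
                              "ui")$value, 1)

  score <- set_similarity(protein_set(c("P1", "P2", "P4")), corp, "ui")
  expect_equal(score$value, 0.5)   # pairs 1.0, 0.25, 0.25
  expect_equal(score$n_pairs, 3L)
  expect_equal(score$n_considered, 3L)

  # one unannotated protein: its pairs score 0 but stay in the denominator
  ont <- demo_ontology()
  partial <- annotation_corpus(list(P1 = "a1", P2 = "a1"), ont,
                               extra_proteins = "X")
  expect_equal(set_similarity(protein_set(c("P1", "P2", "X")), partial,
                              "ui")$value, 1 / 3)

  expect_error(set_similarity(protein_set("P1"), corp, "ui"), "size < 2")
  expect_error(set_similarity(protein_set(c("P1", "ZZ")), corp, "ui"),
               "absent")
})

test_that("set_similarity matches the naive all-pairs oracle", {
  for (seed in c(5, 15)) {
    sim <- random_corpus(seed, n_proteins = 12L)
    corp <- sim$corpus
    ic <- ic_table(corp)
    members <- names(corp$extended)
    set <- protein_set(members, "all")
    expect_equal(set_similarity(set, corp, "ui")$value,
                 brute_all_pairs(members, corp$extended, brute_sim_ui))
    expect_equal(set_similarity(set, corp, "gic", ic = ic)$value,
                 brute_all_pairs(members, corp$extended,
                                 function(a, b) brute_sim_gic(a, b, ic)))
  }
})

test_that("the root can be excluded from extended sets on request", {
  ont <- demo_ontology()
  corp <- annotation_corpus(list(P1 = "a1", P2 = "b"), ont)
  with_root <- set_similarity(protein_set(c("P1", "P2")), corp, "ui")
  without <- set_similarity(protein_set(c("P1", "P2")), corp, "ui",
                            include_root = FALSE)
  expect_gt(with_root$value, 0)   # the shared root gives a floor
  expect_equal(without$value, 0)  # nothing shared once the root is gone
})
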