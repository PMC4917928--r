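# Chain fixture for the Elim trace: r <- a <- a1; 5 study proteins are
# annotated to the leaf a1, the 95 background proteins to a separate
# branch b, so only the study reaches a.
elim_chain_fixture <- function() {
  ont <- ontology_from_parents(list(r = character(), a = "r", a1 = "a",
                                    b = "r"))
  direct <- c(
    stats::setNames(rep(list("a1"), 5), sprintf("S%02d", 1:5)),
    stats::setNames(rep(list("b"), 95), sprintf("B%02d", 1:95))
  )
  list(ontology = ont, corpus = annotation_corpus(direct, ont),
       study = protein_set(sprintf("S%02d", 1:5), "study"))
}

test_that("fisher_over matches hand-computable tables and edge cases", {
  expect_equal(fisher_over(0, 3, 5, 20), 1)       # P(X >= 0) = 1
  expect_equal(fisher_over(2, 2, 2, 4), 1 / 6)
  expect_equal(fisher_over(3, 3, 10, 10), 1)      # term annotates everything
  expect_error(fisher_over(3, 2, 2, 4), "contingency")
  expect_error(fisher_over(1, 2, 5, 4), "contingency")
})

test_that("fisher_over equals the brute-force tail sum on small tables", {
  withr::with_seed(99, {
    for (i in 1:200) {
      M <- sample(2:30, 1)
      N <- sample.int(M, 1)
      mt <- sample.int(M, 1)
      nt <- sample.int(min(N, mt), 1)
      if ((mt - nt) > (M - N)) next
      expect_equal(fisher_over(nt, N, mt, M), brute_hyper_tail(nt, N, mt, M),
                   tolerance = 1e-12)
    }
  })
})

test_that("term_for_term tests exactly the study's extended terms", {
  corp <- demo_corpus()
  study <- protein_set(c("P1", "P2"), "study")
  res <- term_for_term(study, corp)
  expect_setequal(res$term, c("a1", "a", "r"))   # no row for a2 or b
  expect_equal(res$p_classic[res$term == "a1"], 1 / 6)
  expect_equal(res$N, rep(2L, 3))
  expect_equal(res$M, rep(4L, 3))
  expect_error(term_for_term(protein_set("ZZ"), corp), "absent")
})

test_that("a study equal to the background can enrich nothing", {
  corp <- demo_corpus()
  res <- term_for_term(protein_set(names(corp$direct), "all"), corp)
  expect_true(all(res$p_classic == 1))
})

test_that("p_elim equals p_classic on flat ontologies and at tiny alpha", {
  flat <- ontology_from_parents(list(r = character(), a = "r", b = "r",
                                     c = "r"))
  direct <- list(P1 = "a", P2 = "a", P3 = "b", P4 = "c", P5 = "c",
                 P6 = "b", P7 = "a", P8 = "c")
  corp <- annotation_corpus(direct, flat)
  study <- protein_set(c("P1", "P2", "P7"), "study")
  res <- elim_adjust(term_for_term(study, corp), study, corp, flat,
                     alpha = 0.05)
  non_root <- res$term != "r"
  expect_equal(res$p_elim[non_root], res$p_classic[non_root])

  fx <- elim_chain_fixture()
  tiny <- elim_adjust(term_for_term(fx$study, fx$corpus), fx$study,
                      fx$corpus, fx$ontology, alpha = 1e-12)
  expect_equal(tiny$p_elim, tiny$p_classic)
})

test_that("Elim eliminates a significant leaf's proteins from ancestors", {
  fx <- elim_chain_fixture()
  res <- elim_adjust(term_for_term(fx$study, fx$corpus), fx$study,
                     fx$corpus, fx$ontology, alpha = 0.05)
  leaf <- res[res$term == "a1", ]
  parent <- res[res$term == "a", ]
  expect_true(leaf$significant)
  expect_equal(leaf$p_elim, leaf$p_classic)
  # the 5 eliminated proteins empty the parent's counts
  expect_equal(parent$nt_elim, 0L)
  expect_equal(parent$mt_elim, 0L)
  expect_equal(parent$p_elim, 1)
  expect_false(parent$significant)
})

test_that("Elim never produces negative counts; unaffected terms unchanged", {
  for (seed in c(2, 9)) {
    fx <- make_benchmark_fixture(seed = seed)
    study <- fx$family
    res <- elim_adjust(term_for_term(study, fx$corpus), study, fx$corpus,
                       fx$ontology, alpha = 0.05)
    expect_true(all(res$nt_elim >= 0L))
    expect_true(all(res$mt_elim >= 0L))
    # terms with no significant descendant keep their classic p-value
    sig_terms <- res$term[res$significant]
    sig_anc <- unique(unlist(lapply(sig_terms, ancestors,
                                    ontology = fx$ontology)))
    untouched <- setdiff(res$term, sig_anc)
    idx <- res$term %in% untouched
    expect_equal(res$p_elim[idx], res$p_classic[idx])
  }
})

test_that("elim_adjust validates alpha", {
  fx <- elim_chain_fixture()
  res <- term_for_term(fx$study, fx$corpus)
  expect_error(elim_adjust(res, fx$study, fx$corpus, fx$ontology, alpha = 0),
               "alpha")
  expect_error(elim_adjust(res, fx$study, fx$corpus, fx$ontology, alpha = 2),
               "alpha")
})
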