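# Synthetic ontologies, annotation corpora and protein families with
# controlled structure: a rooted is_a DAG, families sharing a planted
# "core" of terms (possibly truncated to ancestors to emulate annotation
# incompleteness), and background proteins carrying decoy annotations.
# Everything is deterministic per seed; writers emit standard OBO/GAF so
# synthetic data exercises the real parsers end-to-end.

sample1 <- function(x) x[sample.int(length(x), 1L)]
sample_k <- function(x, k) x[sample.int(length(x), k)]

#' Generate a random single-rooted is_a DAG
#'
#' Term `i` (in creation order) receives one parent uniformly among
#' earlier terms with spare child capacity, plus, with probability
#' `p_extra_parent`, a second parent, making the graph a DAG rather than a
#' tree. Every term reaches the single root by construction.
#'
#' @param n_terms Number of terms including the root.
#' @param max_children Soft cap on the number of children per term.
#' @param p_extra_parent Probability that a term gets a second parent.
#' @param seed Integer seed; the same seed yields identical edge lists.
#' @param aspect Namespace label for the generated ontology.
#' @return A `go_ontology`.
#' @export
make_ontology <- function(n_terms, max_children = 3L, p_extra_parent = 0.15,
                          seed = 1L, aspect = "molecular_function") {
  stopifnot(n_terms >= 1L)
  withr::with_seed(seed, {
    ids <- sprintf("T:%04d", seq_len(n_terms))
    parents <- stats::setNames(vector("list", n_terms), ids)
    parents[[1L]] <- character()
    child_count <- stats::setNames(integer(n_terms), ids)
    for (i in seq_len(n_terms)[-1L]) {
      earlier <- ids[seq_len(i - 1L)]
      eligible <- earlier[child_count[earlier] < max_children]
      if (!length(eligible)) eligible <- earlier
      p1 <- sample1(eligible)
      ps <- p1
      others <- setdiff(eligible, p1)
      if (length(others) && stats::runif(1) < p_extra_parent) {
        ps <- c(ps, sample1(others))
      }
      parents[[ids[[i]]]] <- sort(ps)
      child_count[ps] <- child_count[ps] + 1L
    }
    nm <- stats::setNames(paste("synthetic term", seq_len(n_terms)), ids)
    nm[[ids[[1L]]]] <- aspect
    ontology_from_parents(parents, term_names = nm, aspect = aspect)
  })
}

#' Specification of a synthetic protein family
#'
#' @param label Family label; member identifiers are `<label>_P###`.
#' @param n_proteins Number of members.
#' @param core_terms Term identifiers forming the family's planted
#'   functional core.
#' @param core_coverage Fraction of members annotated to the core; the
#'   rest receive decoy annotations only.
#' @param depth_attrition Per-level probability that a core annotation
#'   stops at an ancestor instead of the core term itself, emulating
#'   annotation incompleteness (annotations dwindling towards the
#'   leaves). 0 plants the core terms exactly.
#' @param background_terms Decoy term pool for uncovered members; when
#'   empty, the generator falls back to the ontology's non-core leaves.
#' @return Object of class `family_spec`.
#' @export
family_spec <- function(label, n_proteins, core_terms, core_coverage = 1,
                        depth_attrition = 0, background_terms = character()) {
  stopifnot(n_proteins >= 1L,
            core_coverage >= 0, core_coverage <= 1,
            depth_attrition >= 0, depth_attrition < 1)
  structure(
    list(label = label, n_proteins = as.integer(n_proteins),
         core_terms = core_terms, core_coverage = core_coverage,
         depth_attrition = depth_attrition,
         background_terms = background_terms),
    class = "family_spec"
  )
}

# Walk a term towards the root: at each step, with probability
# `attrition`, move to a random parent and try again.
attrite_term <- function(ontology, term, attrition) {
  while (term != ontology$root && stats::runif(1) < attrition) {
    term <- sample1(ontology$parents[[term]])
  }
  term
}

#' Generate an annotation corpus with planted family cores
#'
#' Each family member receives the family's core terms with probability
#' `core_coverage` (each core annotation possibly truncated to an ancestor
#' according to `depth_attrition`); uncovered members and background
#' proteins draw 1-3 decoy terms from the decoy pool. The corpus mimics a
#' family collection mapped onto a GO annotation file: cohesive cores,
#' incomplete annotation, and an unrelated background.
#'
#' @param ontology A `go_ontology`.
#' @param specs List of [family_spec()] objects.
#' @param n_background Number of background (pool) proteins `BG_P####`.
#' @param background_terms Decoy term pool for background proteins;
#'   defaults to the ontology's leaves excluding all families' core terms.
#' @param seed Integer seed.
#' @return A list with components `corpus` (an `annotation_corpus`),
#'   `families` (named list of `protein_set`), and `background` (a
#'   `protein_set`, or `NULL` when `n_background` is 0).
#' @export
make_corpus <- function(ontology, specs, n_background = 0L,
                        background_terms = NULL, seed = 1L) {
  stopifnot(inherits(ontology, "go_ontology"))
  if (inherits(specs, "family_spec")) specs <- list(specs)
  all_core <- unique(unlist(lapply(specs, `[[`, "core_terms")))
  unknown <- setdiff(all_core, ontology$terms)
  if (length(unknown)) {
    stop("core term(s) absent from the ontology: ",
         paste(unknown, collapse = ", "))
  }
  default_decoys <- setdiff(leaves(ontology), all_core)
  if (is.null(background_terms)) background_terms <- default_decoys
  if (!length(background_terms)) {
    stop("no decoy terms available: supply `background_terms`")
  }

  withr::with_seed(seed, {
    direct <- list()
    families <- list()
    for (spec in specs) {
      ids <- sprintf("%s_P%03d", spec$label, seq_len(spec$n_proteins))
      decoys <- if (length(spec$background_terms)) spec$background_terms
                else background_terms
      for (p in ids) {
        if (stats::runif(1) <= spec$core_coverage) {
          terms <- vapply(spec$core_terms, attrite_term,
                          character(1), ontology = ontology,
                          attrition = spec$depth_attrition)
        } else {
          terms <- sample_k(decoys, min(length(decoys), sample1(1:3)))
        }
        direct[[p]] <- sort(unique(terms))
      }
      families[[spec$label]] <- protein_set(ids, label = spec$label)
    }
    background <- NULL
    if (n_background > 0L) {
      bg_ids <- sprintf("BG_P%04d", seq_len(n_background))
      for (p in bg_ids) {
        direct[[p]] <- sort(unique(
          sample_k(background_terms,
                   min(length(background_terms), sample1(1:3)))))
      }
      background <- protein_set(bg_ids, label = "background")
    }
    list(
      corpus = annotation_corpus(direct, ontology),
      families = families,
      background = background
    )
  })
}

#' Planted-core benchmark fixture
#'
#' A ready-made study condition for degeneration assays and shadow-graph
#' recovery: one cohesive family whose members all share a small core of
#' exclusive leaf terms, plus a large pool of background proteins carrying
#' scattered decoy annotations. The core terms annotate only the family,
#' so their over-representation is analytically extreme, and the family's
#' pairwise similarity is 1 at zero noise.
#'
#' @param n_family Family size.
#' @param n_pool Background pool size.
#' @param n_core Number of planted core terms.
#' @param n_terms Ontology size.
#' @param seed Integer seed.
#' @return A list: `ontology`, `corpus`, `family`, `pool`, `core_terms`.
#' @export
make_benchmark_fixture <- function(n_family = 20L, n_pool = 200L,
                                   n_core = 3L, n_terms = 60L, seed = 1L) {
  ontology <- make_ontology(n_terms, seed = seed)
  lv <- leaves(ontology)
  if (length(lv) < n_core + 5L) {
    stop("ontology too small to hold ", n_core, " core terms plus decoys")
  }
  # Deepest leaves make the core; remaining leaves are the decoy pool.
  core <- lv[order(-ontology$depth[lv], lv)][seq_len(n_core)]
  sim <- make_corpus(
    ontology,
    list(family_spec("FAM", n_family, core_terms = core)),
    n_background = n_pool,
    background_terms = setdiff(lv, core),
    seed = seed + 1L
  )
  list(ontology = ontology, corpus = sim$corpus,
       family = sim$families$FAM, pool = sim$background,
       core_terms = core)
}

#' Fixture presets for the three annotation scenarios
#'
#' Small named study conditions over a 100-protein set on a handcrafted
#' ontology, mirroring the three qualitative annotation situations the
#' metrics are meant to tease apart:
#' * `"agreement"` — every protein carries the identical specific term
#'   set; agreement is exactly 1.
#' * `"incompleteness"` — all proteins share one function but many are
#'   annotated only to ancestors of the specific terms, so counts dwindle
#'   towards the leaves.
#' * `"coherence"` — a strict subset of the proteins shares an exclusive
#'   enriched core while the rest carry scattered decoys; hybrid metrics
#'   isolate the core.
#'
#' @param scenario One of `"agreement"`, `"incompleteness"`,
#'   `"coherence"`.
#' @param n_proteins Set size (default 100).
#' @param seed Integer seed.
#' @return A list: `ontology`, `corpus`, `family`, `core_terms`.
#' @export
make_scenario_fixture <- function(scenario = c("agreement", "incompleteness",
                                               "coherence"),
                                  n_proteins = 100L, seed = 1L) {
  scenario <- match.arg(scenario)
  parents <- list(
    "T:ROOT" = character(),
    "T:A" = "T:ROOT", "T:A1" = "T:A", "T:A2" = "T:A",
    "T:A1a" = "T:A1", "T:A1b" = "T:A1",
    "T:B" = "T:ROOT", "T:B1" = "T:B", "T:B2" = "T:B",
    "T:C" = "T:ROOT", "T:C1" = "T:C", "T:C2" = "T:C"
  )
  ontology <- ontology_from_parents(parents)
  core <- c("T:A1a", "T:A1b")
  decoys <- c("T:B1", "T:B2", "T:C1", "T:C2")
  spec <- switch(scenario,
    agreement = family_spec("SCN", n_proteins, core_terms = core),
    incompleteness = family_spec("SCN", n_proteins, core_terms = core,
                                 depth_attrition = 0.45),
    coherence = family_spec("SCN", n_proteins, core_terms = core,
                            core_coverage = 0.6,
                            background_terms = decoys)
  )
  sim <- make_corpus(ontology, list(spec), n_background = 0L,
                     background_terms = decoys, seed = seed)
  list(ontology = ontology, corpus = sim$corpus, family = sim$families$SCN,
       core_terms = core)
}
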