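# Hybrid metrics mUI and mGIC: simUI/simGIC restricted to the "shadow
# graph" of statistically enriched terms and to the core proteins that
# carry them. The enrichment step pre-selects the subset of proteins
# annotated with significant terms, which is what confers the metrics'
# resilience to random-replacement noise.

#' Build the shadow graph of a study set
#'
#' Runs term-for-term enrichment with the Elim adjustment and collects the
#' terms whose adjusted p-value is strictly below `alpha`
#' (`enriched_terms`) together with the study members whose extended
#' annotation set intersects them (`core_proteins`).
#'
#' @inheritParams elim_adjust
#' @return Object of class `shadow_graph`: `enriched_terms`,
#'   `core_proteins`, and the full `results` table.
#' @export
build_shadow <- function(study, corpus, ontology, alpha = 0.05) {
  study <- as_protein_set(study)
  res <- elim_adjust(term_for_term(study, corpus), study, corpus, ontology,
                     alpha = alpha)
  enriched <- res$term[res$significant]
  core <- study$members[vapply(study$members, function(p) {
    length(intersect(corpus$extended[[p]], enriched)) > 0L
  }, logical(1))]
  structure(
    list(enriched_terms = enriched, core_proteins = core, results = res,
         alpha = alpha, label = study$label),
    class = "shadow_graph"
  )
}

#' @export
print.shadow_graph <- function(x, ...) {
  cat(sprintf(
    "shadow_graph '%s': %d enriched terms, %d core proteins (alpha %g)\n",
    x$label, length(x$enriched_terms), length(x$core_proteins), x$alpha
  ))
  invisible(x)
}

# Shared engine for m_ui / m_gic.
hybrid_score <- function(study, corpus, ontology, alpha, fun, metric,
                         scope = c("core", "all")) {
  study <- as_protein_set(study)
  scope <- match.arg(scope)
  if (length(study$members) < 2L) {
    stop("hybrid metrics undefined for study sets of size < 2")
  }
  shadow <- build_shadow(study, corpus, ontology, alpha = alpha)
  prots <- if (scope == "core") shadow$core_proteins else study$members
  if (length(shadow$core_proteins) < 2L) {
    message("fewer than 2 core proteins carry enriched terms in set '",
            study$label, "'; hybrid score is 0")
    return(new_set_score(0, 0L, length(shadow$core_proteins), metric,
                         study$label))
  }
  effective <- lapply(corpus$extended[prots], intersect,
                      y = shadow$enriched_terms)
  res <- all_pairs_mean(effective, fun)
  new_set_score(res$value, res$n_pairs, length(prots), metric, study$label)
}

#' mUI: enrichment-filtered simUI
#'
#' Each core protein's effective annotation set is its extended set
#' intersected with the enriched terms of the shadow graph; the score is
#' the all-pairs mean of [sim_ui()] over the core proteins only (the
#' default) or over the whole study set (`scope = "all"`, where non-core
#' members contribute empty sets). When fewer than two core proteins
#' exist, the score is 0 with `n_pairs = 0` (logged via [message()]), so
#' degeneration assays never abort.
#'
#' @inheritParams elim_adjust
#' @param scope `"core"` (default) averages over core proteins only;
#'   `"all"` over every study member.
#' @return A `set_score`; `n_considered` is the number of proteins that
#'   entered the pairwise average.
#' @export
m_ui <- function(study, corpus, ontology, alpha = 0.05,
                 scope = c("core", "all")) {
  hybrid_score(study, corpus, ontology, alpha, sim_ui, "mui", scope)
}

#' mGIC: enrichment-filtered simGIC
#'
#' As [m_ui()], with [sim_gic()] as the pairwise metric. Information
#' content is taken from the full reference corpus, restricted to the
#' enriched terms.
#'
#' @inheritParams m_ui
#' @param ic Information-content table (see [ic_table()]); computed from
#'   `corpus` when `NULL`.
#' @return A `set_score`.
#' @export
m_gic <- function(study, corpus, ontology, ic = NULL, alpha = 0.05,
                  scope = c("core", "all")) {
  if (is.null(ic)) ic <- ic_table(corpus)
  hybrid_score(study, corpus, ontology, alpha,
               function(a, b) sim_gic(a, b, ic), "mgic", scope)
}
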