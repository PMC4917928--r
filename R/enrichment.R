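# Term-for-term over-representation testing with the one-sided Fisher
# exact test, and the topology-based elimination (Elim) adjustment that
# walks the annotation DAG leaves-first and removes proteins annotated to
# significant descendants from their ancestors' counts.

# Validate the 2x2 contingency quadruple; all four cells must be >= 0.
check_table <- function(nt, N, mt, M) {
  ok <- is.finite(nt) & is.finite(N) & is.finite(mt) & is.finite(M) &
    nt >= 0 & N >= 0 & mt >= 0 & M >= 0 &
    nt <= N & nt <= mt & mt <= M & N <= M &
    (mt - nt) <= (M - N)
  if (!all(ok)) {
    stop("invalid contingency table: need 0 <= nt <= min(N, mt), ",
         "mt <= M, N <= M, and all 2x2 cells non-negative")
  }
}

#' One-sided Fisher exact test for term over-representation
#'
#' Upper hypergeometric tail \eqn{P(X \ge n_t)} for
#' \eqn{X \sim \mathrm{Hypergeom}(M, m_t, N)}: the probability of drawing
#' at least `nt` term-annotated proteins when sampling the study set
#' (size `N`) from a background of `M` proteins of which `mt` carry the
#' term. Equivalent to the one-sided Fisher exact test on the 2x2 table
#' `[[nt, mt-nt], [N-nt, (M-N)-(mt-nt)]]`.
#'
#' @param nt Study proteins annotated with the term.
#' @param N Study-set size.
#' @param mt Background proteins annotated with the term.
#' @param M Background size.
#' @return p-value in `[0, 1]`; vectorized over the four arguments.
#' @examples
#' fisher_over(2, 2, 2, 4)  # 1/6
#' @export
fisher_over <- function(nt, N, mt, M) {
  check_table(nt, N, mt, M)
  stats::phyper(nt - 1, mt, M - mt, N, lower.tail = FALSE)
}

#' Term-for-term enrichment of a study set
#'
#' For every term appearing in the ancestor-extended annotation sets of
#' the study members, builds the 2x2 contingency table of study versus
#' background annotation counts (both on extended annotation) and computes
#' the one-sided Fisher p-value. The background is the corpus universe.
#'
#' @param study A `protein_set`; members must belong to the corpus
#'   universe.
#' @param corpus An `annotation_corpus`.
#' @return A data frame of class `enrichment_result` with columns `term`,
#'   `nt`, `N`, `mt`, `M`, `p_classic`, ordered by term identifier.
#' @export
term_for_term <- function(study, corpus) {
  study <- as_protein_set(study)
  stopifnot(inherits(corpus, "annotation_corpus"))
  absent <- setdiff(study$members, corpus$universe)
  if (length(absent)) {
    stop("study protein(s) absent from the corpus universe: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  N <- length(study$members)
  M <- length(corpus$universe)
  terms <- sort(unique(unlist(corpus$extended[study$members],
                              use.names = FALSE)))
  nt <- vapply(terms, function(t) {
    sum(study$members %in% corpus$term_index[[t]])
  }, integer(1))
  mt <- vapply(terms, function(t) length(corpus$term_index[[t]]), integer(1))
  out <- data.frame(
    term = terms, nt = unname(nt), N = N, mt = unname(mt), M = M,
    p_classic = if (length(terms)) fisher_over(unname(nt), N, unname(mt), M)
                else numeric(),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Elim adjustment of term-for-term p-values
#'
#' Processes terms leaves-first (decreasing longest-path depth, ties
#' broken by ascending term identifier). When a term's recomputed p-value
#' falls below `alpha`, the proteins currently annotated to it — study and
#' background alike — are marked for elimination from the counts of all
#' its proper ancestors. Each term's `p_elim` is the Fisher p-value on its
#' counts after the removals contributed by its significant descendants.
#' The resulting p-values are conditioned on the terms' children and are
#' reported without further multiple-testing correction.
#'
#' @param results An `enrichment_result` from [term_for_term()] over the
#'   same study and corpus.
#' @inheritParams term_for_term
#' @param ontology The `go_ontology` the corpus was built against.
#' @param alpha Significance level in `(0, 1]`; strict inequality
#'   (`p < alpha`) is used throughout.
#' @return The input data frame with columns `p_elim`, `nt_elim`,
#'   `mt_elim` and `significant` added; attribute `alpha` records the
#'   level used and attribute `eliminated` the per-term count of proteins
#'   removed.
#' @export
elim_adjust <- function(results, study, corpus, ontology, alpha = 0.05) {
  stopifnot(inherits(results, "enrichment_result"),
            inherits(corpus, "annotation_corpus"),
            inherits(ontology, "go_ontology"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be a single number in (0, 1]")
  }
  study <- as_protein_set(study)
  members <- study$members
  N <- length(members)
  M <- length(corpus$universe)

  depths <- vapply(results$term, function(t) term_depth(ontology, t),
                   integer(1))
  ord <- order(-depths, results$term)

  eliminated <- new.env(parent = emptyenv())
  p_elim <- numeric(nrow(results))
  nt_elim <- integer(nrow(results))
  mt_elim <- integer(nrow(results))
  n_removed <- integer(nrow(results))

  for (i in ord) {
    t <- results$term[[i]]
    removed <- if (!is.null(eliminated[[t]])) eliminated[[t]] else character()
    annotated <- setdiff(corpus$term_index[[t]], removed)
    nt2 <- sum(members %in% annotated)
    mt2 <- length(annotated)
    p <- fisher_over(nt2, N, mt2, M)
    p_elim[[i]] <- p
    nt_elim[[i]] <- nt2
    mt_elim[[i]] <- mt2
    n_removed[[i]] <- length(removed)
    if (p < alpha) {
      for (a in ontology$anc[[t]]) {
        prev <- if (!is.null(eliminated[[a]])) eliminated[[a]] else character()
        eliminated[[a]] <- union(prev, annotated)
      }
    }
  }

  results$p_elim <- p_elim
  results$nt_elim <- nt_elim
  results$mt_elim <- mt_elim
  results$significant <- p_elim < alpha
  attr(results, "alpha") <- alpha
  attr(results, "eliminated") <- stats::setNames(n_removed, results$term)
  results
}

#' Term-for-term enrichment with Elim adjustment
#'
#' Convenience wrapper running [term_for_term()] then [elim_adjust()] and
#' attaching human-readable term names.
#'
#' @inheritParams elim_adjust
#' @return An `enrichment_result` with a `name` column, ordered by
#'   ascending `p_elim`.
#' @export
enrich <- function(study, corpus, ontology, alpha = 0.05) {
  res <- elim_adjust(term_for_term(study, corpus), study, corpus, ontology,
                     alpha = alpha)
  res$name <- unname(ontology$term_names[res$term])
  res[order(res$p_elim, res$term), ]
}
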