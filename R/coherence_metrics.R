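# Set-level coherence metrics: naive annotation agreement over direct
# annotations, and all-pairs averages of the groupwise semantic
# similarities simUI (term-set Jaccard) and simGIC (IC-weighted Jaccard)
# over ancestor-extended annotation sets.

#' Construct a protein set
#'
#' @param members Character vector of protein identifiers; duplicates are
#'   removed with a warning.
#' @param label Free-text label (e.g. the family name).
#' @return Object of class `protein_set` with components `members`, `label`.
#' @export
protein_set <- function(members, label = "") {
  members <- as.character(members)
  if (anyDuplicated(members)) {
    warning("duplicate protein identifier(s) removed from set '", label, "'")
    members <- unique(members)
  }
  if (length(members) < 1L) {
    stop("a protein set must contain at least one member")
  }
  structure(list(members = members, label = label), class = "protein_set")
}

#' @export
print.protein_set <- function(x, ...) {
  cat(sprintf("protein_set '%s': %d members\n", x$label, length(x$members)))
  invisible(x)
}

as_protein_set <- function(x, label = "") {
  if (inherits(x, "protein_set")) x else protein_set(x, label)
}

#' Read protein-set membership lists
#'
#' Each file holds one protein identifier per line (`#` comments and blank
#' lines ignored); the set label is the file name without extension.
#'
#' @param files Character vector of file paths.
#' @return Named list of `protein_set` objects.
#' @export
read_protein_sets <- function(files) {
  sets <- lapply(files, function(f) {
    ids <- readLines(f, warn = FALSE)
    ids <- trimws(ids)
    ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
    protein_set(ids, label = sub("\\.[^.]*$", "", basename(f)))
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "label"))
}

#' Annotation agreement of a protein set
#'
#' The fraction of direct annotations shared across a set: with \eqn{x_i}
#' the number of set members directly annotated with distinct term
#' \eqn{i}, \eqn{t} the number of distinct direct terms in the set and
#' \eqn{N} the set size, agreement is \eqn{(\sum_i x_i) / (t N)}. It is 1
#' exactly when every member carries the identical term set, and 0 when no
#' member has any annotation. Direct (not extended) annotations are used:
#' the score is deliberately naive, so shared ancestors earn no credit and
#' annotation incompleteness drags it down.
#'
#' @param set A `protein_set` (or character vector of members).
#' @param corpus An `annotation_corpus`.
#' @return Numeric in `[0, 1]`.
#' @export
agreement <- function(set, corpus) {
  set <- as_protein_set(set)
  stopifnot(inherits(corpus, "annotation_corpus"))
  direct <- corpus$direct[intersect(set$members, names(corpus$direct))]
  all_terms <- unlist(direct, use.names = FALSE)
  t_distinct <- length(unique(all_terms))
  if (t_distinct == 0L) return(0)
  length(all_terms) / (t_distinct * length(set$members))
}

#' simUI: union-intersection similarity of two extended term sets
#'
#' The Jaccard index of the two ancestor-extended annotation sets:
#' \eqn{|A \cap B| / |A \cup B|}; 0 when both sets are empty.
#'
#' @param ext_a,ext_b Character vectors of term identifiers (extended
#'   annotation sets).
#' @return Numeric in `[0, 1]`.
#' @export
sim_ui <- function(ext_a, ext_b) {
  u <- length(union(ext_a, ext_b))
  if (u == 0L) return(0)
  length(intersect(ext_a, ext_b)) / u
}

#' simGIC: information-content-weighted similarity of two term sets
#'
#' Sum of term information content over the intersection of the two
#' extended sets, divided by the sum over their union; 0 when the union's
#' IC sum is 0 (e.g. both sets reduce to the root).
#'
#' @inheritParams sim_ui
#' @param ic Named numeric information-content table (see [ic_table()]);
#'   every term in either set must have a defined entry.
#' @return Numeric in `[0, 1]`.
#' @export
sim_gic <- function(ext_a, ext_b, ic) {
  u <- union(ext_a, ext_b)
  if (!length(u)) return(0)
  missing <- u[!(u %in% names(ic))]
  if (length(missing)) {
    stop("information content undefined for term(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  denom <- sum(ic[u])
  if (denom == 0) return(0)
  sum(ic[intersect(ext_a, ext_b)]) / denom
}

# Resolve a pairwise-metric handle ("ui" | "gic" | function(a, b)).
pairwise_handle <- function(metric, ic) {
  if (is.function(metric)) return(metric)
  switch(metric,
    ui = sim_ui,
    gic = {
      if (is.null(ic)) stop("metric 'gic' needs an `ic` table")
      function(a, b) sim_gic(a, b, ic)
    },
    stop("unknown pairwise metric: ", metric)
  )
}

new_set_score <- function(value, n_pairs, n_considered, metric, label) {
  structure(
    list(value = value, n_pairs = n_pairs, n_considered = n_considered,
         metric = metric, label = label),
    class = "set_score"
  )
}

#' @export
print.set_score <- function(x, ...) {
  cat(sprintf("set_score [%s] '%s': %.4f (%d pairs over %d proteins)\n",
              x$metric, x$label, x$value, x$n_pairs, x$n_considered))
  invisible(x)
}

# All-pairs mean of a pairwise metric over a list of term sets.
all_pairs_mean <- function(ext_sets, fun) {
  n <- length(ext_sets)
  if (n < 2L) return(list(value = 0, n_pairs = 0L))
  total <- 0
  n_pairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      total <- total + fun(ext_sets[[i]], ext_sets[[j]])
      n_pairs <- n_pairs + 1L
    }
  }
  list(value = total / n_pairs, n_pairs = n_pairs)
}

#' Set-level similarity by all-pairs averaging
#'
#' Averages a pairwise similarity over all unordered pairs of distinct set
#' members. Proteins without annotations stay in the denominator: each of
#' their pairs scores 0, so random replacements lacking annotations drag
#' the set score down, as a degeneration assay requires.
#'
#' @param set A `protein_set` of size at least 2; members must belong to
#'   the corpus universe.
#' @param corpus An `annotation_corpus`.
#' @param metric `"ui"`, `"gic"`, or a `function(ext_a, ext_b)`.
#' @param ic Information-content table, required for `"gic"` (computed
#'   from `corpus` when `NULL`).
#' @param include_root Keep the ontology root in extended sets? The root
#'   gives annotated-vs-annotated pairs a small similarity floor (it is in
#'   every extended set); set `FALSE` to exclude it.
#' @return A `set_score`: `value`, `n_pairs`, `n_considered`.
#' @examples
#' ont <- ontology_from_parents(list(r = character(), a = "r", a1 = "a"))
#' corp <- annotation_corpus(list(P1 = "a1", P2 = "a1", P3 = "a"), ont)
#' set_similarity(protein_set(c("P1", "P2", "P3")), corp, "ui")
#' @export
set_similarity <- function(set, corpus, metric = "ui", ic = NULL,
                           include_root = TRUE) {
  set <- as_protein_set(set)
  stopifnot(inherits(corpus, "annotation_corpus"))
  if (length(set$members) < 2L) {
    stop("set similarity undefined for sets of size < 2")
  }
  absent <- setdiff(set$members, corpus$universe)
  if (length(absent)) {
    stop("protein(s) absent from the corpus universe: ",
         paste(utils::head(absent, 5), collapse = ", "))
  }
  if (identical(metric, "gic") && is.null(ic)) ic <- ic_table(corpus)
  fun <- pairwise_handle(metric, ic)

  ext <- corpus$extended[set$members]
  if (!include_root) ext <- lapply(ext, setdiff, y = corpus$root)
  res <- all_pairs_mean(ext, fun)
  new_set_score(res$value, res$n_pairs, length(set$members),
                if (is.function(metric)) "custom" else metric, set$label)
}
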