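# Annotation corpus: direct protein -> term sets, their ancestor-extended
# closure (true-path rule), the inverse term -> protein index, and the
# information content table derived from extended annotation frequencies.

#' Build an annotation corpus from direct protein-to-term assignments
#'
#' Canonicalizes alternate term identifiers, drops annotations to obsolete
#' or unknown terms (with a warning), extends every protein's direct term
#' set with all ancestors up to the root, and materializes the inverse
#' term -> protein index.
#'
#' Two protein counts are carried on the corpus and used downstream:
#' `n_annotated` (proteins with at least one direct annotation) is the
#' denominator for information content, so that `ic(root) = 0` holds
#' exactly; `length(universe)` (all proteins known to the corpus, including
#' proteins registered via `extra_proteins` with no annotations) is the
#' background size M of the enrichment contingency table, matching the
#' convention that family sizes count proteins, not annotated proteins.
#'
#' @param direct Named list: protein identifier -> character vector of
#'   directly annotated term identifiers.
#' @param ontology A `go_ontology`.
#' @param extra_proteins Protein identifiers to include in the universe
#'   with empty annotation sets (e.g. family members absent from the GAF).
#' @return An object of class `annotation_corpus` with components `direct`,
#'   `extended`, `term_index`, `universe`, `n_annotated`, `root`, `aspect`.
#' @examples
#' ont <- ontology_from_parents(list(r = character(), a = "r", a1 = "a"))
#' corp <- annotation_corpus(list(P1 = "a1"), ont)
#' corp$extended$P1  # "a" "a1" "r"
#' @export
annotation_corpus <- function(direct, ontology, extra_proteins = character()) {
  stopifnot(inherits(ontology, "go_ontology"))
  if (length(direct) && is.null(names(direct))) {
    stop("`direct` must be a named list (protein -> term set)")
  }

  n_obsolete <- 0L
  n_unknown <- 0L
  canon <- lapply(direct, function(terms) {
    terms <- unique(as.character(terms))
    ok <- character()
    for (t in terms) {
      if (t %in% ontology$terms) {
        ok <- c(ok, t)
      } else if (!is.na(ontology$alt_ids[t])) {
        ok <- c(ok, unname(ontology$alt_ids[t]))
      } else if (t %in% ontology$obsolete) {
        n_obsolete <<- n_obsolete + 1L
      } else {
        n_unknown <<- n_unknown + 1L
      }
    }
    sort(unique(ok))
  })
  if (n_obsolete > 0L) {
    warning(n_obsolete, " annotation(s) to obsolete terms dropped")
  }
  if (n_unknown > 0L) {
    warning(n_unknown, " annotation(s) to terms absent from the ontology ",
            "dropped")
  }

  for (p in setdiff(extra_proteins, names(canon))) {
    canon[[p]] <- character()
  }
  canon <- canon[order(names(canon))]

  extended <- lapply(canon, function(terms) {
    if (!length(terms)) return(character())
    sort(unique(c(
      terms,
      unlist(ontology$anc[terms], use.names = FALSE)
    )))
  })

  prot <- rep(names(extended), lengths(extended))
  term <- unlist(extended, use.names = FALSE)
  term_index <- if (length(term)) {
    lapply(split(prot, term), function(x) sort(unique(x)))
  } else {
    list()
  }

  structure(
    list(
      direct = canon,
      extended = extended,
      term_index = term_index,
      universe = names(canon),
      n_annotated = sum(lengths(canon) > 0L),
      root = ontology$root,
      aspect = ontology$aspect
    ),
    class = "annotation_corpus"
  )
}

#' @export
print.annotation_corpus <- function(x, ...) {
  cat(sprintf(
    "annotation_corpus: %d proteins (%d annotated), %d distinct terms (aspect %s)\n",
    length(x$universe), x$n_annotated, length(x$term_index), x$aspect
  ))
  invisible(x)
}

# Aspect column letter for a namespace label.
aspect_letter <- function(aspect) {
  switch(aspect,
    molecular_function = "F",
    biological_process = "P",
    cellular_component = "C",
    stop("unknown aspect: ", aspect)
  )
}

#' Parse a GAF 2.x annotation file
#'
#' Reads a 17-column tab-separated Gene Association File (GOA dialect),
#' keeping only rows whose aspect column matches the ontology's aspect
#' (`"F"` for molecular_function), dropping NOT-qualified rows, and
#' optionally filtering on evidence codes. Comment lines starting with `!`
#' are ignored.
#'
#' @param file Path or connection.
#' @param ontology A `go_ontology`.
#' @param evidence_filter Optional character vector of evidence codes to
#'   keep (e.g. `c("EXP", "IDA")`); `NULL` keeps everything, including IEA.
#' @param extra_proteins Passed to [annotation_corpus()].
#' @return An `annotation_corpus`.
#' @export
parse_gaf <- function(file, ontology, evidence_filter = NULL,
                      extra_proteins = character()) {
  stopifnot(inherits(ontology, "go_ontology"))
  lines <- if (inherits(file, "connection")) readLines(file) else {
    readLines(file, warn = FALSE)
  }
  keep_aspect <- aspect_letter(ontology$aspect)

  proteins <- character()
  terms <- character()
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "!")) next
    # sentinel keeps trailing empty columns, which strsplit would drop
    fields <- strsplit(paste0(ln, "\tEND"), "\t", fixed = TRUE)[[1]]
    fields <- fields[-length(fields)]
    if (length(fields) != 17L) {
      stop("GAF parse error at line ", i, ": expected 17 tab-separated ",
           "columns, found ", length(fields))
    }
    if (fields[[9]] != keep_aspect) next
    qualifier <- fields[[4]]
    if (nzchar(qualifier) &&
        any(strsplit(qualifier, "|", fixed = TRUE)[[1]] == "NOT")) next
    if (!is.null(evidence_filter) && !(fields[[7]] %in% evidence_filter)) next
    proteins <- c(proteins, fields[[2]])
    terms <- c(terms, fields[[5]])
  }

  direct <- if (length(proteins)) {
    lapply(split(terms, proteins), unique)
  } else {
    stats::setNames(list(), character())
  }
  annotation_corpus(direct, ontology, extra_proteins = extra_proteins)
}

#' Parse a two-column protein/term TSV into a corpus
#'
#' Fallback lightweight format: one `protein<TAB>term` pair per line,
#' `#` comments allowed.
#'
#' @inheritParams parse_gaf
#' @return An `annotation_corpus`.
#' @export
parse_annotation_tsv <- function(file, ontology, extra_proteins = character()) {
  lines <- if (inherits(file, "connection")) readLines(file) else {
    readLines(file, warn = FALSE)
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  proteins <- character()
  terms <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2L) {
      stop("TSV parse error at line ", i, ": expected 2 columns, found ",
           length(fields))
    }
    proteins <- c(proteins, fields[[1]])
    terms <- c(terms, fields[[2]])
  }
  direct <- if (length(proteins)) {
    lapply(split(terms, proteins), unique)
  } else {
    stats::setNames(list(), character())
  }
  annotation_corpus(direct, ontology, extra_proteins = extra_proteins)
}

#' Write a corpus to a GAF 2.2 file
#'
#' Emits the direct annotations as 17-column GAF rows so synthetic corpora
#' exercise the real parser end-to-end.
#'
#' @param corpus An `annotation_corpus`.
#' @param file Path or connection.
#' @param db Database label for column 1.
#' @return Invisibly, `file`.
#' @export
write_gaf <- function(corpus, file, db = "SYN") {
  stopifnot(inherits(corpus, "annotation_corpus"))
  letter <- aspect_letter(corpus$aspect)
  rows <- character()
  for (p in names(corpus$direct)) {
    for (t in corpus$direct[[p]]) {
      rows <- c(rows, paste(
        db, p, p, "", t, "GO_REF:0000000", "IEA", "", letter,
        "", "", "protein", "taxon:32644", "20260101", db, "", "",
        sep = "\t"
      ))
    }
  }
  writeLines(c("!gaf-version: 2.2", rows), file)
  invisible(file)
}

#' Information content of a term
#'
#' `-log(p)` (natural logarithm) of the term's extended annotation
#' frequency: the fraction of annotated proteins in the reference corpus
#' whose ancestor-extended annotation set contains the term. The root
#' annotates every annotated protein, so its information content is 0.
#'
#' @param corpus The reference `annotation_corpus`.
#' @param term A term identifier.
#' @return Non-negative numeric.
#' @examples
#' ont <- ontology_from_parents(list(r = character(), a = "r", b = "r"))
#' corp <- annotation_corpus(list(P1 = "a", P2 = "a", P3 = "b", P4 = "b"), ont)
#' information_content(corp, "a")  # -log(0.5)
#' @export
information_content <- function(corpus, term) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  n <- length(corpus$term_index[[term]])
  if (n == 0L) {
    stop("information content undefined: term ", term,
         " annotates no protein in the reference corpus")
  }
  -log(n / corpus$n_annotated)
}

#' Information-content table for all terms of a corpus
#'
#' @param corpus The reference `annotation_corpus`.
#' @return Named numeric vector (term -> information content) with
#'   attribute `corpus_size` (number of annotated proteins used).
#' @export
ic_table <- function(corpus) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  counts <- lengths(corpus$term_index)
  ic <- -log(counts / corpus$n_annotated)
  attr(ic, "corpus_size") <- corpus$n_annotated
  ic
}

#' Add proteins to a corpus universe with empty annotation sets
#'
#' Family membership lists often include proteins absent from the GAF;
#' they still count in set sizes and enrichment backgrounds.
#'
#' @param corpus An `annotation_corpus`.
#' @param proteins Character vector of protein identifiers.
#' @param ontology The `go_ontology` the corpus was built against.
#' @return A new `annotation_corpus`.
#' @export
add_proteins <- function(corpus, proteins, ontology) {
  stopifnot(inherits(corpus, "annotation_corpus"))
  annotation_corpus(corpus$direct, ontology,
                    extra_proteins = union(setdiff(proteins,
                                                   names(corpus$direct)),
                                           character()))
}
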