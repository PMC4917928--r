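# Rooted is_a DAG over one GO aspect, with precomputed ancestor closure and
# longest-path depths. All downstream metrics operate on this structure.

#' Construct an ontology from a parent list
#'
#' Low-level constructor used by [parse_obo()] and [make_ontology()], and
#' handy for building small fixtures directly in code. Terms must form a
#' single-rooted directed acyclic graph when edges are read child -> parent.
#'
#' @param parents Named list mapping each term identifier to a character
#'   vector of its parent identifiers (`character(0)` for the root).
#' @param term_names Optional named character vector of human-readable term
#'   names; unnamed terms get their identifier as name.
#' @param aspect Namespace label carried along (default
#'   `"molecular_function"`).
#' @param relations Relation labels the edges represent (metadata only at
#'   this level; filtering happens in [parse_obo()]).
#' @param alt_ids Named character vector mapping alternate identifiers to
#'   canonical ones.
#' @param obsolete Character vector of obsolete term identifiers. Obsolete
#'   terms never participate in edges or closure.
#' @return An object of class `go_ontology` with components `terms`,
#'   `term_names`, `parents`, `children`, `root`, `aspect`, `relations`,
#'   `alt_ids`, `obsolete`, plus precomputed ancestor sets and depths.
#' @examples
#' ont <- ontology_from_parents(list(r = character(), a = "r", a1 = "a"))
#' ancestors(ont, "a1")
#' @export
ontology_from_parents <- function(parents, term_names = NULL,
                                  aspect = "molecular_function",
                                  relations = "is_a",
                                  alt_ids = character(),
                                  obsolete = character()) {
  ids <- names(parents)
  if (is.null(ids) || any(!nzchar(ids)) || anyDuplicated(ids)) {
    stop("`parents` must be a named list with unique, non-empty names")
  }
  unknown <- setdiff(unique(unlist(parents, use.names = FALSE)), ids)
  if (length(unknown)) {
    stop("parent term(s) not present in ontology: ",
         paste(unknown, collapse = ", "))
  }

  edge_child <- rep(ids, lengths(parents))
  edge_parent <- unlist(parents, use.names = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edge_child, to = edge_parent,
               stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    stop("cycle detected among ontology terms; is_a closure requires a DAG")
  }
  roots <- ids[vapply(parents, length, integer(1)) == 0L]
  if (length(roots) != 1L) {
    stop("ontology must have exactly one root (parentless term); found ",
         length(roots), ": ", paste(utils::head(roots, 5), collapse = ", "))
  }
  root <- roots

  # Children before parents in this order; reverse it for the closure DP.
  topo <- names(igraph::topo_sort(g, mode = "out"))
  anc <- stats::setNames(vector("list", length(ids)), ids)
  depth <- stats::setNames(integer(length(ids)), ids)
  for (t in rev(topo)) {
    ps <- parents[[t]]
    if (!length(ps)) {
      anc[[t]] <- character()
      depth[[t]] <- 0L
    } else {
      anc[[t]] <- sort(unique(c(ps, unlist(anc[ps], use.names = FALSE))))
      depth[[t]] <- max(depth[ps]) + 1L
    }
  }

  children <- stats::setNames(vector("list", length(ids)), ids)
  for (t in ids) children[[t]] <- character()
  for (i in seq_along(edge_child)) {
    children[[edge_parent[[i]]]] <-
      c(children[[edge_parent[[i]]]], edge_child[[i]])
  }
  children <- lapply(children, function(x) sort(unique(x)))

  nm <- stats::setNames(ids, ids)
  if (!is.null(term_names)) nm[names(term_names)] <- term_names

  structure(
    list(
      terms = ids,
      term_names = nm,
      parents = parents,
      children = children,
      root = root,
      aspect = aspect,
      relations = relations,
      alt_ids = alt_ids,
      obsolete = obsolete,
      anc = anc,
      depth = depth
    ),
    class = "go_ontology"
  )
}

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf(
    "go_ontology: %d terms (aspect %s), root %s, %d edges, %d obsolete\n",
    length(x$terms), x$aspect, x$root,
    sum(lengths(x$parents)), length(x$obsolete)
  ))
  invisible(x)
}

# Resolve an identifier through the alt_id map; error on unknown/obsolete
# lookups so callers fail fast rather than silently scoring nothing.
resolve_term <- function(ontology, term) {
  if (term %in% ontology$terms) return(term)
  hit <- ontology$alt_ids[term]
  if (!is.na(hit)) return(unname(hit))
  if (term %in% ontology$obsolete) {
    stop("term ", term, " is obsolete in this ontology")
  }
  stop("unknown term: ", term)
}

#' Ancestors of a term
#'
#' Transitive closure over the traversed relations (by default `is_a`),
#' following edges child -> parent up to the root.
#'
#' @param ontology A `go_ontology`.
#' @param term A term identifier (alternate identifiers are resolved).
#' @param reflexive Include `term` itself in the result?
#' @return Character vector of term identifiers, sorted.
#' @examples
#' ont <- ontology_from_parents(list(r = character(), a = "r", a1 = "a"))
#' ancestors(ont, "a1")                  # "a" "r"
#' ancestors(ont, "a1", reflexive = TRUE)
#' @export
ancestors <- function(ontology, term, reflexive = FALSE) {
  stopifnot(inherits(ontology, "go_ontology"))
  term <- resolve_term(ontology, term)
  out <- ontology$anc[[term]]
  if (reflexive) out <- sort(unique(c(out, term)))
  out
}

#' Descendants of a term
#'
#' @inheritParams ancestors
#' @return Character vector of term identifiers, sorted.
#' @export
descendants <- function(ontology, term, reflexive = FALSE) {
  stopifnot(inherits(ontology, "go_ontology"))
  term <- resolve_term(ontology, term)
  seen <- character()
  frontier <- ontology$children[[term]]
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- setdiff(
      unique(unlist(ontology$children[frontier], use.names = FALSE)), seen)
  }
  if (reflexive) seen <- c(seen, term)
  sort(unique(seen))
}

#' Depth of a term (longest path from the root)
#'
#' Depth is the length of the longest root-to-term path, so every child is
#' strictly deeper than all of its parents. This guarantees the Elim
#' adjustment (see [elim_adjust()]) never processes a parent before any of
#' its children.
#'
#' @inheritParams ancestors
#' @return Non-negative integer; 0 for the root.
#' @export
term_depth <- function(ontology, term) {
  stopifnot(inherits(ontology, "go_ontology"))
  term <- resolve_term(ontology, term)
  unname(ontology$depth[[term]])
}

#' Leaf terms of an ontology
#'
#' @param ontology A `go_ontology`.
#' @return Character vector of terms with no children.
#' @export
leaves <- function(ontology) {
  stopifnot(inherits(ontology, "go_ontology"))
  sort(ontology$terms[lengths(ontology$children[ontology$terms]) == 0L])
}

#' Parse an OBO flat file into a single-aspect ontology
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas, keeps the terms of one namespace,
#' builds the child -> parent edge set over the requested relations, records
#' obsolete terms (excluded from all edges and closure), and maps alternate
#' identifiers to their canonical term.
#'
#' @param file Path to an OBO file, or a connection.
#' @param aspect Namespace to keep (default `"molecular_function"`).
#' @param relations Relation labels to traverse; `"is_a"` by default,
#'   `c("is_a", "part_of")` to also follow part-of relationships.
#' @return A `go_ontology`; see [ontology_from_parents()].
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c(
#'   "format-version: 1.2", "",
#'   "[Term]", "id: GO:0003674", "name: molecular_function",
#'   "namespace: molecular_function", "",
#'   "[Term]", "id: GO:0016829", "name: lyase activity",
#'   "namespace: molecular_function", "is_a: GO:0003674"
#' ), obo)
#' ont <- parse_obo(obo)
#' @export
parse_obo <- function(file, aspect = "molecular_function",
                      relations = "is_a") {
  lines <- if (inherits(file, "connection")) readLines(file) else {
    readLines(file, warn = FALSE)
  }

  stanza_starts <- which(trimws(lines) == "[Term]")
  if (!length(stanza_starts)) {
    stop("no [Term] stanzas found in OBO input")
  }
  boundaries <- c(stanza_starts, length(lines) + 1L)
  typedef_or_other <- grep("^\\[(?!Term\\])", trimws(lines), perl = TRUE)

  records <- vector("list", length(stanza_starts))
  for (s in seq_along(stanza_starts)) {
    from <- stanza_starts[[s]] + 1L
    to <- boundaries[[s + 1L]] - 1L
    # A later non-Term stanza truncates this record.
    cut <- typedef_or_other[typedef_or_other >= from & typedef_or_other <= to]
    if (length(cut)) to <- min(cut) - 1L
    if (to < from) {
      stop("malformed OBO stanza starting at line ", stanza_starts[[s]],
           ": empty [Term]")
    }
    rec <- list(id = NULL, name = NULL, namespace = NULL,
                is_a = character(), rel = list(), alt_id = character(),
                obsolete = FALSE)
    for (j in from:to) {
      ln <- trimws(lines[[j]])
      if (!nzchar(ln) || startsWith(ln, "!")) next
      colon <- regexpr(":", ln, fixed = TRUE)
      if (colon < 0) {
        stop("malformed OBO line ", j, ": ", ln)
      }
      key <- substr(ln, 1L, colon - 1L)
      val <- trimws(substr(ln, colon + 1L, nchar(ln)))
      val <- trimws(sub("!.*$", "", val))  # strip trailing comments
      switch(key,
        id = { rec$id <- val },
        name = { rec$name <- val },
        namespace = { rec$namespace <- val },
        is_a = { rec$is_a <- c(rec$is_a, val) },
        alt_id = { rec$alt_id <- c(rec$alt_id, val) },
        is_obsolete = { rec$obsolete <- identical(tolower(val), "true") },
        relationship = {
          parts <- strsplit(val, "\\s+")[[1]]
          if (length(parts) >= 2) {
            rec$rel[[length(rec$rel) + 1L]] <-
              c(type = parts[[1]], target = parts[[2]])
          }
        },
        NULL
      )
    }
    if (is.null(rec$id)) {
      stop("malformed OBO stanza starting at line ", stanza_starts[[s]],
           ": missing id")
    }
    records[[s]] <- rec
  }

  in_aspect <- vapply(records, function(r) {
    identical(r$namespace, aspect)
  }, logical(1))
  records <- records[in_aspect]
  if (!length(records)) {
    stop("aspect '", aspect, "' not present in OBO input")
  }

  obsolete <- vapply(records, `[[`, logical(1), "obsolete")
  live <- records[!obsolete]
  obsolete_ids <- vapply(records[obsolete], `[[`, character(1), "id")
  if (!length(live)) {
    stop("aspect '", aspect, "' contains only obsolete terms")
  }

  ids <- vapply(live, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate term id(s) in OBO input: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  term_names <- stats::setNames(
    vapply(live, function(r) r$name %||% r$id, character(1)), ids)

  keep <- function(targets) intersect(targets, ids)
  parents <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(live)) {
    r <- live[[i]]
    ps <- character()
    if ("is_a" %in% relations) ps <- c(ps, keep(r$is_a))
    for (rel in r$rel) {
      if (rel[["type"]] %in% relations) {
        ps <- c(ps, keep(rel[["target"]]))
      }
    }
    parents[[r$id]] <- sort(unique(ps))
  }

  alt_ids <- character()
  for (r in live) {
    if (length(r$alt_id)) {
      alt_ids[r$alt_id] <- r$id
    }
  }

  ontology_from_parents(parents, term_names = term_names, aspect = aspect,
                        relations = relations, alt_ids = alt_ids,
                        obsolete = obsolete_ids)
}

#' Write an ontology to an OBO file
#'
#' Emits a minimal OBO 1.2 document (id, name, namespace, is_a and obsolete
#' stanzas) that [parse_obo()] round-trips. Used so synthetic ontologies
#' exercise the real parser.
#'
#' @param ontology A `go_ontology`.
#' @param file Path or connection to write to.
#' @return Invisibly, the path/connection written to.
#' @export
write_obo <- function(ontology, file) {
  stopifnot(inherits(ontology, "go_ontology"))
  out <- c("format-version: 1.2", "")
  for (t in sort(ontology$terms)) {
    out <- c(out, "[Term]",
             paste0("id: ", t),
             paste0("name: ", ontology$term_names[[t]]),
             paste0("namespace: ", ontology$aspect),
             paste0("is_a: ", ontology$parents[[t]]),
             "")
  }
  for (t in sort(ontology$obsolete)) {
    out <- c(out, "[Term]",
             paste0("id: ", t),
             paste0("name: obsolete ", t),
             paste0("namespace: ", ontology$aspect),
             "is_obsolete: true",
             "")
  }
  writeLines(out, file)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
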