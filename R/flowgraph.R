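# Annotation-flow graphs: the ontology subgraph induced by a protein
# set's extended annotations, with per-term protein counts. Edges point
# parent -> child ("annotation flow"), and DOT edge widths are
# proportional to the child's protein count, so annotation bottlenecks —
# generic terms whose children annotate far fewer proteins — stand out.

#' Build the annotation-flow graph of a protein set
#'
#' Nodes are exactly the terms occurring in the members' ancestor-extended
#' annotation sets, each with the count of members whose extended set
#' contains it; edges are the ontology edges between those terms, oriented
#' parent -> child. Extended annotation is monotone up the DAG, so every
#' edge's child count is at most its parent's count.
#'
#' @param set A `protein_set` (non-empty).
#' @param corpus An `annotation_corpus`.
#' @param ontology The `go_ontology`.
#' @return Object of class `flow_graph`: `nodes` (data frame `term`,
#'   `name`, `count`) and `edges` (data frame `parent`, `child`,
#'   `child_count`), both sorted by term identifier.
#' @export
build_flow_graph <- function(set, corpus, ontology) {
  set <- as_protein_set(set)
  stopifnot(inherits(corpus, "annotation_corpus"),
            inherits(ontology, "go_ontology"))
  ext <- corpus$extended[intersect(set$members, names(corpus$extended))]
  terms <- sort(unique(unlist(ext, use.names = FALSE)))
  counts <- vapply(terms, function(t) {
    sum(vapply(ext, function(e) t %in% e, logical(1)))
  }, integer(1))
  nodes <- data.frame(
    term = terms,
    name = unname(ontology$term_names[terms]),
    count = unname(counts),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(parent = character(), child = character(),
                      child_count = integer(), stringsAsFactors = FALSE)
  for (child in terms) {
    for (parent in intersect(ontology$parents[[child]], terms)) {
      edges <- rbind(edges, data.frame(
        parent = parent, child = child,
        child_count = unname(counts[child]), stringsAsFactors = FALSE
      ))
    }
  }
  edges <- edges[order(edges$parent, edges$child), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, label = set$label),
            class = "flow_graph")
}

#' @export
print.flow_graph <- function(x, ...) {
  cat(sprintf("flow_graph '%s': %d terms, %d edges\n",
              x$label, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

# Escape a string for a double-quoted DOT identifier.
dot_quote <- function(x) {
  paste0('"', gsub('"', '\\\\"', x), '"')
}

#' Export a flow graph as a Graphviz DOT digraph
#'
#' Node labels are `term\\nname\\n(count)`; edge `penwidth` is linear in
#' the child's protein count, normalized to `[1, 8]`. Output ordering is
#' deterministic (sorted term identifiers), so identical graphs produce
#' identical bytes.
#'
#' @param graph A `flow_graph`.
#' @param file Path or connection to write to.
#' @return Invisibly, the DOT lines written.
#' @export
export_dot <- function(graph, file) {
  stopifnot(inherits(graph, "flow_graph"))
  nodes <- graph$nodes[order(graph$nodes$term), , drop = FALSE]
  edges <- graph$edges[order(graph$edges$parent, graph$edges$child), ,
                       drop = FALSE]
  max_count <- if (nrow(nodes)) max(nodes$count) else 1L
  lines <- c("digraph annotation_flow {", "  rankdir=TB;")
  for (i in seq_len(nrow(nodes))) {
    label <- sprintf("%s\\n%s\\n(%d)", nodes$term[[i]], nodes$name[[i]],
                     nodes$count[[i]])
    lines <- c(lines, sprintf("  %s [label=%s];",
                              dot_quote(nodes$term[[i]]), dot_quote(label)))
  }
  for (i in seq_len(nrow(edges))) {
    pen <- 1 + 7 * edges$child_count[[i]] / max_count
    lines <- c(lines, sprintf("  %s -> %s [penwidth=%.3f];",
                              dot_quote(edges$parent[[i]]),
                              dot_quote(edges$child[[i]]), pen))
  }
  lines <- c(lines, "}")
  writeLines(lines, file)
  invisible(lines)
}
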