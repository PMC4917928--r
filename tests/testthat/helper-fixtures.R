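# Shared fixtures and independent oracles. Oracles are deliberately
# naive (recursion, explicit sums, double loops) and never reuse the
# package's code paths they check.

# --- tiny ontologies -------------------------------------------------------

# r <- a <- a1 (chain)
chain_ontology <- function() {
  ontology_from_parents(list(r = character(), a = "r", a1 = "a"))
}

# diamond: r <- a, r <- b, a <- c, b <- c
diamond_ontology <- function() {
  ontology_from_parents(list(r = character(), a = "r", b = "r",
                             c = c("a", "b")))
}

# r <- a <- {a1, a2}, r <- b; 4-protein demo corpus
demo_ontology <- function() {
  ontology_from_parents(list(r = character(), a = "r", a1 = "a", a2 = "a",
                             b = "r"))
}

demo_corpus <- function(ont = demo_ontology()) {
  annotation_corpus(list(P1 = "a1", P2 = "a1", P3 = "a2", P4 = "b"), ont)
}

# Minimal OBO documents written to temp files.
write_obo_text <- function(lines) {
  path <- tempfile(fileext = ".obo")
  writeLines(lines, path)
  path
}

minimal_obo <- function() {
  write_obo_text(c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: GO:0000001",
    "name: root function",
    "namespace: molecular_function",
    "",
    "[Term]",
    "id: GO:0000002",
    "name: child function",
    "namespace: molecular_function",
    "alt_id: GO:0000099",
    "is_a: GO:0000001 ! root function",
    "",
    "[Term]",
    "id: GO:0000003",
    "name: gone function",
    "namespace: molecular_function",
    "is_obsolete: true",
    "",
    "[Term]",
    "id: GO:0000010",
    "name: process root",
    "namespace: biological_process"
  ))
}

# A syntactically valid GAF 2.2 line (17 columns).
gaf_line <- function(protein, term, aspect = "F", qualifier = "",
                     evidence = "IEA") {
  paste("DB", protein, protein, qualifier, term, "GO_REF:0000000",
        evidence, "", aspect, "", "", "protein", "taxon:32644",
        "20260101", "DB", "", "", sep = "\t")
}

write_gaf_text <- function(lines) {
  path <- tempfile(fileext = ".gaf")
  writeLines(c("!gaf-version: 2.2", lines), path)
  path
}

# --- independent oracles ---------------------------------------------------

# Reachability by naive recursion over the parent list.
brute_ancestors <- function(parents, term) {
  seen <- character()
  recurse <- function(t) {
    for (p in parents[[t]]) {
      if (!(p %in% seen)) {
        seen <<- c(seen, p)
        recurse(p)
      }
    }
  }
  recurse(term)
  sort(seen)
}

# Longest root-to-term path by exhaustive path enumeration.
brute_depth <- function(parents, term) {
  if (!length(parents[[term]])) return(0L)
  max(vapply(parents[[term]], function(p) brute_depth(parents, p) + 1L,
             integer(1)))
}

# Upper hypergeometric tail as an explicit sum of point masses.
brute_hyper_tail <- function(nt, N, mt, M) {
  ks <- nt:min(N, mt)
  sum(exp(lchoose(mt, ks) + lchoose(M - mt, N - ks) - lchoose(M, N)))
}

# Naive all-pairs mean via an explicit double loop over a member vector.
brute_all_pairs <- function(members, ext, fun) {
  total <- 0
  n_pairs <- 0L
  for (i in seq_along(members)) {
    for (j in seq_along(members)) {
      if (i < j) {
        total <- total + fun(ext[[members[[i]]]], ext[[members[[j]]]])
        n_pairs <- n_pairs + 1L
      }
    }
  }
  if (n_pairs == 0L) 0 else total / n_pairs
}

brute_sim_ui <- function(a, b) {
  u <- unique(c(a, b))
  if (!length(u)) return(0)
  sum(u %in% a & u %in% b) / length(u)
}

brute_sim_gic <- function(a, b, ic) {
  u <- unique(c(a, b))
  if (!length(u)) return(0)
  denom <- sum(ic[u])
  if (denom == 0) return(0)
  sum(ic[u[u %in% a & u %in% b]]) / denom
}

# Random study conditions for oracle-equivalence sweeps.
random_corpus <- function(seed, n_terms = 30L, n_proteins = 15L) {
  ont <- make_ontology(n_terms, seed = seed)
  withr::with_seed(seed + 1000L, {
    direct <- lapply(seq_len(n_proteins), function(i) {
      sample(ont$terms, sample.int(4L, 1L))
    })
    names(direct) <- sprintf("P%02d", seq_len(n_proteins))
    list(ontology = ont, corpus = annotation_corpus(direct, ont))
  })
}
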