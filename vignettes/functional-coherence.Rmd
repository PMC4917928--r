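---
title: "Measuring functional coherence in protein sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring functional coherence in protein sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funcoh)
```

## The problem

A set of proteins assembled on biological grounds — a CAZy enzyme
family, an orthologous group, the hits of a screen — should share
function, and its Gene Ontology annotations should say so. In practice
the annotation state of such a set mixes three distinct phenomena:

* **incompleteness** — members annotated only to generic ancestors of
  the terms that actually describe them, because automatic pipelines
  stop high in the DAG;
* **agreement** — the degree to which members carry literally the same
  direct terms;
* **coherence** — the existence of a *core* of terms, carried by a
  (possibly strict) subset of members, that characterizes the set's
  role even when other members are unannotated or noisy.

A single similarity score conflates these. `funcoh` therefore computes a
family of metrics with known, deliberately different sensitivities, and
provides a degeneration benchmark that measures those sensitivities
empirically.

## Metrics and their assumptions

All computation happens on one GO aspect (default `molecular_function`)
restricted to a single-rooted DAG, and on *extended* annotation sets:
each protein's direct terms plus all ancestors reachable over the
traversed relations. Only `is_a` edges are traversed by default.
`part_of` can be added via the `relations` argument of `parse_obo()`,
but cross-hierarchy relations are deliberately excluded: the closure
then stays a subsumption closure and the true-path rule applies
unambiguously.

**Agreement** uses *direct* annotations only. With $x_i$ the number of
members carrying distinct direct term $i$, $t$ the number of distinct
direct terms and $N$ the set size,

$$\mathrm{agreement}(S) = \frac{\sum_{i=1}^{t} x_i}{t\,N} \in [0, 1],$$

which is exactly 1 when every member has the identical term set and 0
when nothing is annotated. The unnormalized product form
$(\sum_i x_i)\cdot t/N$ would grow like $t^2$ at full agreement; we
normalize by $t\,N$ so the score is a fraction on the same $[0,1]$
scale as the other metrics and attains its maximum precisely in the
full-agreement situation. Working on direct annotations is the point:
the score must *not* credit shared ancestors, so it serves as the naive,
incompleteness-sensitive baseline.

**simUI** is the Jaccard index of two extended sets and **simGIC** its
information-content-weighted version,

$$\mathrm{simGIC}(A,B) =
  \frac{\sum_{t \in GO(A) \cap GO(B)} IC(t)}
       {\sum_{t \in GO(A) \cup GO(B)} IC(t)},
\qquad IC(t) = -\ln \frac{|\{P : t \in GO(P)\}|}{M_{ann}},$$

where $M_{ann}$ is the number of annotated proteins in the reference
corpus. IC uses the natural logarithm and is not normalized: simGIC is a
ratio, so any base cancels. The reference corpus is the full loaded
background (all families plus pool), not the single study set, so a
term's rarity is judged against the whole annotation space. The root has
$IC = 0$ and is kept inside extended sets by default; it gives
annotated-vs-annotated pairs a small similarity floor, which is part of
simUI's published behaviour (`include_root = FALSE` removes it).

**Set scores** are means over all $N(N-1)/2$ unordered member pairs.
Members without annotations score 0 in each of their pairs and *stay in
the denominator*: a random replacement without molecular-function
annotations must drag the set score down, otherwise the degeneration
benchmark would be blind to exactly the noise it injects.

## Enrichment and the hybrid metrics

For a study set of size $N$ inside a background of $M$ proteins, each
term $t$ occurring in the study's extended sets gets the 2×2 table
$[[n_t, m_t - n_t], [N - n_t, (M-N) - (m_t - n_t)]]$, where $n_t$ and
$m_t$ count study and background proteins whose *extended* set contains
$t$. `fisher_over()` computes the one-sided (over-representation)
hypergeometric tail $P(X \ge n_t)$. Two conventions matter:

* $M$ is the *full* universe, including proteins known only from family
  lists with no annotations — set sizes count proteins, not annotated
  proteins, and this keeps every cell non-negative when degenerated
  sets contain unannotated members. The IC denominator, in contrast, is
  the annotated count, so $IC(\mathrm{root}) = 0$ holds exactly.
* Significance is strict: a term with $p = \alpha$ is not enriched.
  $\alpha$ defaults to 0.05 and is configurable everywhere.

The **Elim** adjustment mitigates the parent–child dependency of
term-for-term testing. Terms are processed by decreasing longest-path
depth (ties broken by term identifier, so the order is total and
reproducible); depth is *longest* path from the root precisely so that
no parent is ever processed before any of its children. When a term's
recomputed p-value falls below $\alpha$, the proteins currently
annotated to it — study and background alike — are marked for removal
from the counts of all its proper ancestors. Removing them from both
margins treats the 2×2 table consistently; removing only study counts
would bias ancestor tables towards depletion. The adjusted p-values are
conditioned on the children and are reported without further
multiple-testing correction, since independence assumptions do not hold
for them. Whether the original Elim formulation handles background
counts identically cannot be settled from its published description;
the reading implemented here is documented, logged per term (attribute
`eliminated`), and hand-traceable on a chain fixture.

**mUI/mGIC** then score only the "shadow graph": enriched terms and the
core proteins whose extended sets intersect them. Each core protein's
effective term set is its extended set intersected with the enriched
terms, and simUI/simGIC is averaged over core-protein pairs only. The
published description of the hybrid metrics leaves the protein scope of
the final similarity computation implicit; scoring core proteins only is
the reading consistent with their stated purpose (pre-selecting the
protein subset carrying significant terms), and the complementary
whole-set variant remains available as `scope = "all"` for comparison.
With fewer than two core proteins the score is 0 with a logged message
rather than an error, so degeneration assays never abort at high noise.
In the $\alpha \to 1$ limit on a fully annotated set the shadow holds
every non-degenerate term and mUI/mGIC coincide with simUI/simGIC.

## The degeneration assay

`degenerate()` replaces $k = \mathrm{round}(f \cdot N)$ members (ties
rounded half up; exact at the default 10 % grid) with proteins sampled
without replacement from a disjoint pool, keeping $N - k$ randomly
sampled originals. `run_assay()` repeats this `iterations` times per
replacement level, scores every configured metric, and reports per-level
mean and standard deviation. Randomness is one documented stream:
iteration $i$ at level index $l$ runs under seed
`seed + 100003*l + i`, so profiles are bit-reproducible and individual
iterations can be replayed in isolation. Replacement proteins keep
whatever annotations the corpus has for them, possibly none. Families
below `min_family_size` (default 20; small sets make all-pairs means and
enrichment tables unstable) are skipped with a message.

`resolution()` summarizes profiles as the range (max − min) of per-level
means per family, averaged across families — the empirical spread a
metric can actually report under this benchmark. The shipped reference
table `pl_family_ranges.tsv` carries published per-family ranges for 15
polysaccharide-lyase benchmark families and six metrics (including the
external GS2 metric, present only as printed values; its algorithm is
out of scope here, but `run_assay()` accepts arbitrary metric functions
as a plug-in hook).

## What the synthetic generator emulates

`make_ontology()` grows a random single-rooted `is_a` DAG: each new term
attaches to one earlier term with spare child capacity and, with
probability `p_extra_parent` (default 0.15), to a second, so the graph
is a DAG rather than a tree. `make_corpus()` plants families: each
member receives the family's `core_terms` with probability
`core_coverage`, each core annotation truncated to a random ancestor
with per-level probability `depth_attrition` (the incompleteness knob);
uncovered members and background proteins draw 1–3 decoy terms.
`make_scenario_fixture()` packages the three canonical situations
(full agreement, incompleteness, a coherent core inside a noisy set) and
`make_benchmark_fixture()` the planted-core study condition used
throughout: a 20-protein family sharing 3 exclusive leaf terms against a
200-protein decoy pool, sizes chosen so the core's hypergeometric
p-value ($n_t = m_t = N = 20$, $M = 220$) is analytically far below any
reasonable $\alpha$ while the pool still dominates the background.

The generator emulates the *structure* that the metrics respond to —
rooted subsumption, planted cores, attrition towards the root, decoy
background — not the statistics of the real GO: no realistic term-depth
or fan-out distributions, no evidence-code mixture, no multi-aspect
annotations, no correlated annotation errors. Tests passing on synthetic
corpora therefore validate the algebra and the selection logic, not
performance on any particular real annotation release.

## Numerical choices and problem sizes

Fisher tails come from `phyper`; the test suite checks them against an
explicit sum of hypergeometric point masses on every admissible table
with $M \le 60$ (about $1.3\times10^5$ tables) to $10^{-10}$. All-pairs
means are checked against naive double loops on random corpora of up to
~20 proteins and ~50 terms. The shipped degeneration benchmark runs 11
levels × 25 iterations on the planted fixture — enough for standard
errors of a few percent while keeping the default suite fast; the
published study condition (100 iterations) is a parameter away.
Level-0 runs short-circuit the sampler ($k = 0$ returns the family
unchanged), so clean-set scores are exact with zero variance.

## Known limitations

* Only one aspect at a time; cross-aspect coherence is out of scope.
* Agreement's normalized form is this package's choice of scale; its
  unnormalized product form would rank identically within a fixed set
  size but is unbounded.
* Elim background-count handling is one documented reading (see above).
* mUI/mGIC are *local* metrics by design: at high noise they can rise
  again when a few random proteins happen to share enriched terms (a
  new similarity core). They should be read alongside simUI/simGIC and
  the core size `n_considered`, never alone.
* IC is corpus-relative; moving a family into a different background
  changes simGIC and mGIC.
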