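---
title: "Reconstructing metabolic pathways with knowledge-constrained Bayesian networks"
author: "kbnpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing metabolic pathways with knowledge-constrained Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kbnpath)
```

## The model

`kbnpath` treats a metabolic pathway as a Bayesian network over genes:
a directed acyclic graph in which each gene's log2 expression across
conditions is a linear-Gaussian function of its parents,

$$x_v = \beta_0 + \sum_{u \in \mathrm{Pa}(v)} \beta_u x_u +
\varepsilon, \qquad \varepsilon \sim N(0, \sigma_v^2).$$

Candidate structures are scored with the Bayesian Information
Criterion in its decomposable, higher-is-better form: per node, the
maximized Gaussian log-likelihood of the regression minus
$\tfrac{p}{2}\log N$, where $N$ is the number of conditions and
$p = |\mathrm{Pa}(v)| + 2$ counts the regression coefficients, the
intercept and the residual variance. The sign and penalty conventions
matter because BIC is often written with the opposite sign and a factor
of two; `node_bic()` documents ours, and the test suite pins the score
to an independent least-squares implementation.

Expression data are counts, not Gaussians, so all scoring and
clustering operate on $\log_2(\mathrm{CPM} + 1)$. This transform
(`log_cpm()`, configurable via the `transform` argument of
`bn_data()`) is standard for variance-stabilizing count data, and its
adequacy is an assumption of the model: strongly skewed or
zero-inflated genes violate it, which is one reason the non-expressed
gene filter runs first.

Two assumptions deserve emphasis. First, linearity: edges whose true
relation is strongly non-linear earn little likelihood and may be
missed. Second, faithfulness of co-expression to shared pathway
membership: the cluster-guided sampler assumes genes in the same
pathway have more similar profiles than random pairs. Both are
assumptions about the biology, not guarantees.

## Knowledge constraints

The search is never free. From the KGML inputs we pool every KO–KO
relation across pathways — multi-molecule nodes expand to all KO pairs
between two connected nodes — into a knowledgebase, and derive per
pathway:

* the **allowed** set: every ordered gene pair whose KO pair carries a
  relation; its complement is the blacklist, represented implicitly
  because materializing all forbidden pairs is quadratic in genes;
* the **whitelist**: gene-level edges of the initially mapped pathway,
  inserted in lexicographic $(\mathrm{from}, \mathrm{to})$ order, each
  insertion rejected if it would close a directed cycle. The
  lexicographic order is a reproducibility device — any fixed order
  yields an acyclic whitelist, but an unspecified one would make runs
  incomparable. Rejected edges are retained with reason tags.

Relations observed only in a user-named organism can be excluded from
whitelist support (`exclude_species`). This mirrors a hold-one-species-
out validation design: the withheld species' own evidence must be
rediscovered from data. Undirected relations license both orientations
in the allowed set but contribute only their stated orientation as
whitelist candidates.

After learning, `amend_cycles()` unions the withheld edges back into
the result. The amended graph may contain cycles; that is intentional,
since real metabolic feedback exists even though the probabilistic
model cannot represent it.

## Search

`hill_climb()` greedily applies the best strictly-improving single-edge
move (add within the allowed set, delete or reverse non-whitelist
edges), with cycle checks on every candidate. Restarts deserve a note:
permuting the move-evaluation order only changes the outcome when two
moves tie exactly, and exact ties have measure zero for continuous
scores. Restarts therefore perturb the starting graph with up to four
random allowed edge additions before climbing — the perturbation edges
are not whitelisted, so the climber deletes them when they do not pay.
The best-scoring final structure across restarts wins. With three
restarts this recovers the exhaustively enumerated global optimum on
the large majority of 4-node instances in the acceptance suite; one
restart is the default because constrained searches are typically
small and unimodal.

`expand_network()` implements iterative growth: sample a batch of
candidate genes from the cluster model, add them as isolated nodes,
re-climb, then freeze every edge of the local optimum incident to
previously-present nodes by promoting it to the working whitelist. We
read the growth step's "treat the accepted local network as a unit" as
this freezing, rather than literal node merging, because merging would
destroy the gene identities needed for evaluation and GO analysis; the
amended whitelist makes later rounds build strictly on earlier
decisions, which is the operative content of either reading.

## Clustering and sampling

`fit_gmm()` is a diagonal-covariance Gaussian mixture fitted by EM with
k-means++-style seeding, a variance floor of $10^{-6}$, and a
convergence tolerance of $10^{-6}$ on the log-likelihood; with
thousands of genes and 14 conditions, full covariances are
ill-conditioned and add little. The number of clusters is chosen by
5-fold cross-validation on held-out per-gene log-likelihood
(`select_k()`), ties to the smallest k.

`make_plan()` picks the pivot cluster — the one containing the most
initially mapped genes, ties to the smaller index — and weights cluster
$c$ by $1/(1 + d_c)$, with $d_c$ the Euclidean distance between mean
profiles. The kernel is a design choice: any decreasing function of
distance satisfies the intent, and this one is bounded, parameter-free
and automatically maximal at the pivot ($d = 0$). A softmax kernel
$\exp(-d)$ is available behind the `kernel` argument. Sampling is a
two-stage draw (cluster by weight, then a uniform unused gene within
it), batch size 10 per round by default.

## Evaluation and enrichment

`edge_recall_precision()` compares KO-level edge sets: recall is the
matched fraction of target edges, precision the matched fraction of
predicted edges. Direction is respected by default; an undirected mode
exists because score-equivalent orientations are indistinguishable from
data alone. Conventions for degenerate inputs: both sets empty gives
recall = precision = 1; an empty prediction against a non-empty target
gives recall 0 and an `NA` precision rather than an arbitrary number.
`repeat_evaluate()` averages over seeded repeats (50 is the
conventional count; the pipeline default is 1 for speed) and reports
per-repeat values and failures.

`fisher_enrichment()` tests GO-term over-representation with the
one-sided hypergeometric upper tail, i.e. the Fisher exact test with
alternative "greater". Raw p-values are reported and thresholded at
0.05 by default — no multiple-testing correction, matching common
practice of reporting raw enrichment p-values per pathway — with
Benjamini–Hochberg available via `adjust = "BH"`. `edge_go_stats()`
reports the fraction of network edges whose endpoint genes share an
identical GO term, overall and per category, counting unannotated
endpoints as non-sharing (a conservative convention).

## The synthetic benchmark

`gen_suite()` produces everything the pipeline consumes with no
external data: per-pathway random DAGs over KO groups (some groups hold
two genes, exercising multi-molecule handling), KGML serializations,
gene-to-KO tables, GO annotations, and a count matrix generated from
the truth network. Defaults define the benchmark conditions: 300 genes,
3 pathways of 20 genes and 25 KO-level edges, 14 conditions, edge
coefficients in $[0.8, 1.2]$, structural noise $\sigma = 0.5$ (log2
scale), and 10 withheld genes that appear in the data and the broad
KO table but not in the initial mapping — the synthetic analogue of
genes missed by homology-based assignment.

Counts are Poisson draws around $\mathrm{depth} \cdot 2^{z}$, where the
latent $z$ follows the structural model plus a per-gene baseline
(log2 mean 6, sd 1.2) and a per-pathway condition signature (sd 1)
that makes pathway members co-cluster. Depth 5 puts typical genes in
the hundreds of counts. Roughly 5% of background genes are essentially
silent so the CPM > 1 filter removes something real. Two deliberate
couplings constrain these constants: the signature must be strong
enough that clusters track pathways, yet weak enough that pathway
swings do not dominate library totals — when they do, CPM
normalization subtracts the shared signal back out (a compositional
artefact worth knowing about in real data too). Setting
`signature_sd = 0` and a degenerate `beta_range` of 0 yields the pure
null model used to check that the learner stays close to the empty
graph.

What the generator does **not** emulate: sequencing-depth variation
between libraries, overdispersion beyond Poisson, transcript-level
ambiguity, batch effects, or non-linear regulation. Passing tests on
this benchmark therefore demonstrate correctness of the machinery and
recoverability under the stated model, not performance on real
RNA-seq.

## Numerical choices and degenerate inputs

* Residual variances are floored at $10^{-12}$ before the
  log-likelihood so deterministic relationships cannot produce infinite
  scores; rank-deficient parent designs fall back to a ridge solve
  ($\lambda = 10^{-8}$) with a warning.
* The expression filter is strict (CPM **>** threshold), and
  re-normalizing an already-normalized matrix is an error, never a
  silent rescale.
* Ambiguous identifier mappings (one source to many targets, or many
  sources onto one target) are dropped and counted rather than
  resolved; resolution by sequence identity is out of scope.
* Self-relations in KGML are dropped with a warning; unknown relation
  types are kept as `other`.
* Genes without a KO assignment survive `group_by_ko()` as singleton
  pseudo-KO nodes (prefix `gene:`) so no learned edge is silently
  lost; they are excluded from KO-level evaluation.
* The empty knowledgebase, the edgeless pathway and the exhausted
  sampling pool all degrade to warnings plus empty results, not
  errors, because they occur legitimately (reference sets include
  relation-free pathways).

## Reproducibility and problem sizes

Every stochastic function takes a seed and restores the caller's RNG
state; the pipeline fans one global seed out by fixed offsets so stages
are independently reproducible, and two runs with the same seed produce
byte-identical outputs. The test and acceptance suites run the
method at desk scale — 4-node exhaustive comparisons (543 labeled
DAGs), 10-node/12-edge recovery at $N = 500$, 60–300-gene suites with
2–3 pathways — sizes chosen so the full suite completes in about two
minutes while still exercising every code path; the mechanisms under
test do not change with scale, though absolute recall and runtime of
course do.

## Limitations

Beyond the generative assumptions above: the blacklist confines
discovery to knowledge-licensed pairs, so genuinely novel relations
between KO pairs never related in any reference pathway are
unreachable by construction; hill climbing offers no global-optimality
guarantee beyond the restart heuristic; with 14 conditions the BIC
penalty is weak and some null edges survive (quantified in the tests);
and GO enrichment inherits whatever biases the annotation input
carries — the package consumes annotations, it does not predict them.
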