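---
title: "Co-expression modules and guide-gene targets: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-expression modules and guide-gene targets: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mybcoexp)
```

mybcoexp implements two complementary ways of reconstructing a
transcription-factor co-regulatory network from an expression compendium —
a **top-down** workflow (global correlation network, Markov Clustering
modules, degree hubs) and a **guide-gene** workflow (local expansion from
characterised seed genes, promoter cis-element scanning, target
nomination) — together with a synthetic-data generator whose planted truth
makes every stage testable. This vignette explains the models, the
parameters that matter, and the choices made where the design was open.

## The top-down workflow

### Signed correlation network

For genes $a, b$ with log2 expression profiles $x_a, x_b$ across samples,
the edge weight is the sample Pearson correlation $r(a,b)$. An edge is
retained iff $|r| > c$; the sign is kept, so the network distinguishes
positively and negatively co-expressed pairs without needing a second
mechanism. The cutoff is strict (`>`), matching the convention "PCC
magnitude above the threshold"; `build_network(strict = FALSE)` gives the
`>=` variant for sensitivity analysis. The default $c = 0.85$ is stringent:
the `sweep_thresholds()` diagnostics (node/edge counts, density
$2E/[N(N-1)]$, scale-free $R^2$ of the degree distribution) exist to make
that choice inspectable rather than baked in. The scale-free statistic is
an ordinary least-squares fit of $\log_{10}$ degree frequency on
$\log_{10} k$ over observed degrees — the raw-frequency reading, not
cumulative or log-binned, which is the simplest diagnostic and the one the
sweep table reports; it is undefined (NA) below three distinct degrees.

Zero-variance genes are excluded before correlation (their $r$ is
undefined); their ids are messaged, not silently dropped.

### Markov Clustering and the inflation sweep

MCL operates on the $|r|$-weighted adjacency — signs are dropped because
MCL requires non-negative flow, and negative edges still represent strong
co-regulation worth keeping in a module. Self-loops of weight 1 are added
(canonical MCL practice; they damp oscillation on bipartite-like
structure). The column-stochastic flow matrix is iterated through

1. expansion: $M \leftarrow M^e$ (default $e = 2$),
2. inflation: entrywise power $I$, column renormalisation,
3. pruning: entries below $10^{-6}$ zeroed, columns renormalised,

until the largest entry change falls below $10^{-8}$ or 200 iterations
(non-convergence is flagged, and the current matrix interpreted).
Attractors are rows with positive diagonal mass; a node joins the
lowest-indexed attractor whose row supports it, which resolves overlapping
attractor systems deterministically. Clusters under `min_cluster_size = 3`
genes move to the unassigned set — smaller clusters are rarely
biologically interpretable and cannot carry a two-gene enrichment anyway.

The inflation parameter trades granularity for cohesion, and there is no
universal best value, so `inflation_sweep()` scores every $I$ in
$1.1, 1.2, \ldots, 3.0$ (the conventional range; step 0.1 chosen as the
coarsest grid that still resolves the optimum) by annotation enrichment:

* **specificity** — fraction of retained modules with at least one
  significantly enriched term;
* **sensitivity** — fraction of all terms enriched in at least one module;
* **F-measure** — their harmonic mean, 0 when both are 0.

The argmax-F partition wins, ties going to the smallest inflation
(coarsest usable clustering). A partition with fewer than two retained
modules is unusable for this comparison and scores F = 0 — this reproduces
the practical observation that very low inflation values yield "no
modules".

Enrichment itself is the upper-tail hypergeometric test
$p = P(X \ge k)$ for $k$ of a term's $K$ genes landing in an $n$-gene
module from an $N$-gene universe, computed with `phyper`. The
Benjamini–Hochberg adjustment runs **jointly over all (module, term)
pairs of one partition**, because the specificity/sensitivity definitions
are partition-level statements at FDR 0.05; a proprietary set-counts
correction used by some web services is deliberately replaced by BH, the
transparent standard. A term needs $k \ge 2$ annotated genes in the module
to be called significant — one gene is never evidence of
over-representation. Terms with $k = 0$ are not tested (their $p$ is ~1;
skipping them reduces the test count honestly). Terms are opaque labels:
no GO-DAG propagation is performed, so real GO input must be
pre-propagated.

Partition quality is complemented by Newman–Girvan modularity
$Q = \sum_c (e_c/m - (d_c/2m)^2)$ on the unweighted simple graph
(igraph's implementation), with unassigned genes as singleton
communities; the weighted variant and the treatment of filtered genes are
open choices, and this is the most conservative reading.

### Hubs and the DEG overlay

Hubs are nodes of degree $\ge 5$ — a plain, widely used connectivity
definition; no betweenness or eigenvector centrality is computed because
degree is the quantity the workflow interprets. The hub report splits
edges by sign and gives mean $|r|$ per sign; `ego_subnetwork()` extracts a
hub's induced first-neighbour subgraph.

Differential expression uses a per-gene two-sample t-test on log2 values
with BH adjustment and the joint rule $|\mathrm{log_2FC}| \ge 1.5$ and
adjusted $p < 0.05$. The threshold is read in **log2** units: the matrix
is log2 after normalisation, and "more than two-fold" language is
consistent with log2. The pooled (equal-variance) t is the default rather
than Welch: the generator's replicate noise is homoscedastic on the log2
scale, and at 2–3 replicates the Welch degrees-of-freedom penalty (df can
drop to 2) costs substantial power for no robustness gain in this
setting. `var_equal = FALSE` restores Welch. Genes with zero
variance in both groups are untestable and flagged, never called.

## The guide-gene workflow

### Mutual ranks and expansion

The mutual rank of a pair is the geometric mean of the two reciprocal
correlation ranks, $\mathrm{MR}(a,b) = \sqrt{\mathrm{rank}_a(b)\,
\mathrm{rank}_b(a)}$ (best = 1); it is robust to one gene being globally
promiscuous. Ranks break ties by gene id, making the whole workflow
deterministic. Expansion from the guide genes is breadth-first to
`hierarchy_depth = 2`: a gene enters at level $k$ when an edge with
$\mathrm{MR} \le 5$ **and** $r \ge 0.6$ links it to a level-$(k{-}1)$
gene; a gene reachable at several depths keeps its minimal level, which
matters because only level-1 genes (first neighbours) are eligible as
putative targets. Both comparisons are inclusive; the stricter published
variant of these thresholds ($r > 0.64$, $\mathrm{MR} < 10$) is available
through `guide_config()`. Multiple guides expand as the union of
single-guide expansions over one shared network.

### Promoter scanning and target nomination

Promoters are 1 kb of sequence upstream of the translational start codon,
written 5'→3' on the coding strand; positions are 1-based indices of a
hit's leftmost base in that string. Scanning is exact-string search of
each consensus (strand `+`) and its reverse complement (strand `-`) —
all six default MYB elements are concrete sequences, so no PWM scoring or
IUPAC wildcards are needed; `N` never matches; overlapping hits are all
reported; a palindromic user motif is reported once per position as `+`.
The default dictionary carries CAACGG (CCAAT-box/MYBHv1), AACCTAA (MRE,
light), AAAAGTTAGTTA (MBSII, flavonoid), TAACTG and CAACTG (MBS,
drought-inducibility) and CGGTCA (generic MBS).

A first neighbour with at least one hit is nominated as a putative target
of each guide it touches; the drought-MBS subset is reported separately.
Motif over-representation is tested against an iid-composition null: with
base frequencies estimated from the scanned promoters, the expected hit
count is $\sum_g (L_g - w + 1)(p_+ + p_-)$ and the p-value the upper
binomial tail over all positions — a transparent background model that
replaces de-novo motif discovery, which is outside this package's scope.
The proximal/distal split calls a hit proximal when it lies within 200 bp
of the promoter's 3' end, the translational-start anchor standing proxy
for the TSS (the two are conflated by the 1 kb-upstream convention).

## The synthetic generator

`generate_expression()` plants co-expression with one latent factor per
module: $x_g = \mu_g + s_g \lambda z_m + \varepsilon$, with $z_m$ a
shared standard-normal sample profile, $\varepsilon \sim N(0,\sigma^2)$,
and $s_g = -1$ for the anti-correlated fraction. The latent-factor form
was chosen over copulas because it calibrates in closed form: the expected
within-module correlation is $\lambda^2/(\lambda^2+\sigma^2)$, so
$\lambda = \sigma\sqrt{r/(1-r)}$ hits any target $r$ exactly, and
$\sigma = 0$ degenerates to $|r| = 1$. Defaults describe the study
conditions: 200 genes with four modules of 10/15/20/25 among 130
background genes, 10% anti-correlated members, 10 conditions × 3
replicates (30 samples), target within-module $|r| = 0.9$, $\sigma = 0.2$
log2 units, baselines uniform on [4, 12]. Annotations give each module
one dedicated term covering 80% of its members — the minimal structure
under which a perfect partition can reach F = 1 — plus 10 noise terms of
5–30 random genes that keep the sweep non-trivial. Promoters are iid from
a uniform base composition with planted motifs **overwritten** (not
inserted) at recorded positions, keeping length fixed at 1000.

Differential expression is planted as a $+2$ log2 step in the last
condition for `n_deg_genes` genes — **opt-in, default 0**. A planted
condition step is itself a latent factor shared by every planted gene:
with the default design it induces pairwise correlations of
$d^2p(1-p)/(d^2p(1-p)+\sigma^2) \approx 0.9$ among the planted set,
i.e. a real co-expression module the planted-module truth would not
record. Module-recovery experiments therefore run without planted DEGs,
and the DEG calibration experiment runs without modules (20 planted
effects among 180 null genes, 2 conditions × 3 replicates) so its truth
is clean in the other direction.

What the generator does **not** emulate: probe-level array structure,
batch effects, heteroscedastic intensity-dependent noise, correlated
background genes, hormone- or tissue-specific response shapes, realistic
promoter composition or dinucleotide structure. Passing tests therefore
demonstrate correctness of the algorithms under a known clean model, not
performance on real compendia — on real data the correlation cutoff,
inflation optimum and enrichment yield will all differ.

## Numerical and degenerate-input choices

* Correlation: computed on log2 values; zero-variance genes excluded
  up front; the matrix is symmetrised and its diagonal forced to 1.
* MCL: convergence tolerance $10^{-8}$ on the max entry change; pruning
  threshold $10^{-6}$; a fully pruned column gets its self-loop back
  before renormalisation; column sums stay 1 within $10^{-9}$ after every
  step.
* Empty networks short-circuit the top-down workflow with an explicit
  "no modules" manifest rather than an error.
* Ties: MR ranks by gene id; sweep F ties to the smallest inflation;
  module labels are assigned by decreasing size then first gene id, so
  reruns are byte-identical.
* An empty hit table yields NA fractions in the proximal/distal split
  (not 0/0), and zero observed hits give a binomial p of 1.

## Problem sizes used by the test-suite experiments

The simulation experiments run at deliberately modest sizes chosen to
exercise every code path with comfortable statistical margins: the module
recovery check uses the default 200-gene study over 50 seeds with the full
20-point inflation grid; the MCL cross-check uses 30 random weighted
graphs of up to 60 nodes; DEG calibration uses 100 seeds of the 200-gene
two-condition design; the hypergeometric oracle enumerates all feasible
$(N \le 25, K, n, k)$ configurations. These sizes are the package's own
benchmark definition and are documented here so they can be scaled up by
anyone wanting tighter Monte-Carlo bounds.

## Known limitations

* Terms are flat labels; GO structure is the user's responsibility.
* No soft-thresholding or partial correlations; the network model is a
  hard-thresholded PCC graph by design.
* The binomial motif background ignores dinucleotide composition and
  shared promoter structure; on real promoters it will be anti-
  conservative for AT-rich elements.
* MCL is dense-matrix; fine for the hundreds-of-genes networks this
  workflow targets, not for genome-scale graphs.
* The "weighted PCC" used by the external co-expression database this
  workflow mirrors is not publicly defined; plain PCC is used with the
  same thresholds.
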