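---
title: "Methods: hub miR discovery from two-group expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hub miR discovery from two-group expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubmir)
```

`hubmir` chains eight analysis stages — differential expression,
knowledge overlap, target filtering, enrichment, regulatory-network
hub scoring, co-expression topology, clustering, and cross-network
synthesis — into one reproducible pipeline for case/control miR
microarray studies. This vignette documents the statistical model of
each stage, the conventions adopted where the methodology literature
leaves choices open, what the synthetic-data generator does and does
not emulate, and the package's known limitations.

## Differential expression: two-class SAM

For each miR $i$, with disease samples $x_{i1}$ and control samples
$x_{i2}$ (log2 expression ratios), the statistic is

$$d_i = \frac{r_i}{s_i + s_0}, \qquad
r_i = \bar x_{i1} - \bar x_{i2}, \qquad
s_i = \sqrt{\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)
      \frac{\sum (x_{i1}-\bar x_{i1})^2 + \sum (x_{i2}-\bar x_{i2})^2}
           {n_1 + n_2 - 2}}.$$

The method description we follow calls $r$ a regression coefficient;
in the two-class unpaired design the regression of expression on the
group indicator has exactly the group mean difference as its
coefficient, so `sam_statistic()` computes $r_i$ as that difference.

**The fudge factor $s_0$.** Small $s_i$ inflate $d_i$; $s_0$ damps
this. `choose_s0()` evaluates candidates at every 5th percentile of
the $s_i$ distribution. For each candidate it windows miRs into up to
100 $s$-quantile bins, takes the median absolute deviation of $d$ in
each window, and returns the candidate minimizing the coefficient of
variation of those window MADs — the classic "minimize the CV of $d$
across the range of $s$" recipe. Ties go to the smallest candidate;
fewer than 20 usable miRs fall back to `median(s)` with a warning.
$s_0$ is scale-equivariant: doubling the data doubles it.

**Permutation FDR.** Group labels are permuted (all
$\binom{n}{n_1}$ assignments when `n_permutations` covers them,
otherwise a seeded random sample), $d$ is recomputed per permutation,
and the expected order statistics $\bar d_{(i)}$ are the means of the
sorted permuted values. For a threshold $\Delta$ on
$d_{(i)} - \bar d_{(i)}$, the upper cut is the smallest observed $d$
whose displacement exceeds $+\Delta$ and the lower cut the largest
with displacement below $-\Delta$; the estimated FDR at the cut is
the median across permutations of the number of permuted $d$ beyond
the cuts, divided by the observed number called. Conventions adopted:
median rather than mean exceedance counts (more robust, standard in
SAM implementations); no $\pi_0$ correction (conservative: the
estimated FDR is biased upward, never downward); full rather than
balanced permutations. $\Delta$ is tuned to the largest call set with
estimated FDR at or below the target (default 0.3%); if no $\Delta$
qualifies the call set is empty, by design. Lowering the target can
only shrink the feasible $\Delta$ set, so the call set is monotone in
the target. Probes with more than 20% missing values are dropped
before fitting — the least destructive convention for two-channel
arrays with scattered missing spots; remaining missing values are
handled per-row with available samples (at least two per group, else
the miR is flagged unusable).

## Knowledge overlap and partition

With a background universe of $N$ assayed miRs containing $K$ known
disease miRs, and $n$ DE calls of which $k$ are known, the overlap
p-value is the hypergeometric upper tail $P(X \ge k)$. The background
defaults to the number of probes assayed after filtering; the
methodological literature does not fix this universe, so it is a
parameter (using all catalogued human miRs instead would make the
test more liberal). Known-list entries absent from the array count in
$K$ but cannot contribute to $k$. The partition is exact: Group 1 =
DE ∩ known, Group 2 = DE \\ known.

## Target filtering

Records `(miR, gene, predictor, score)` pass three ordered filters:
consensus (pair predicted by ≥ 3 distinct predictors), score (miTG-like
score ≥ 20, inclusive — a score exactly at the reliability boundary is
high-confidence), and per-miR top-10 by score, ties broken by gene
name ascending so results are deterministic. The consensus score of a
pair is its DIANA-predictor score where available (the screening score
of the original protocol); other predictors only vote membership.
Because the score is a per-pair attribute, the consensus and score
filters commute, which the test suite asserts. The published unique
target counts of the motivating study (1127 and 1227) depend on
2014-era database content and are deliberately not reproduction
targets; the filtering logic is.

## Enrichment

`enrich()` is an offline over-representation test: for each term,
$p = P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$ over a
user-supplied gene background (default: all genes in the GMT union
the target table). The default report is the unadjusted $p < 0.05$,
matching common practice of the web tools this replaces;
Benjamini–Hochberg values are always computed and can be filtered on
instead. Terms with zero query hits are suppressed.
`mirs_for_top_terms()` selects the miRs whose filtered targets
intersect the union of the top-20 terms' genes — the gate before
network construction.

## Regulatory network and IR hubs

The tripartite network has strict layers TF → miR → mRNA; an
identifier appearing in two layers is an error rather than silently
tolerated, because the hub score depends on clean layer membership.
Duplicate TF→miR evidence rows collapse to one edge ($m$ counts
distinct regulators). Each miR's intermediate regulation is
$IR = m \times n$: $m$ upstream TFs each push a signal through the
miR, which can act along $n$ target edges, so $m \times n$ counts the
TF-to-target routes through it. With the top-10 target cap, $n \le
10$. Hubs are miRs with $IR \ge 70$ (inclusive threshold), ranked by
IR then name. miRs with no known TF stay in the network with $m = 0$
(and so $IR = 0$): absence of TF evidence is data, not a reason to
drop a node.

## Co-expression topology

Pearson correlation is computed across all samples pooled — one
network over both conditions, not per-condition networks. Edges
require $r > 0.9$ strictly and signed; strong anticorrelation does
not connect nodes by default (an absolute-value mode exists).
Isolated miRs are dropped unless kept explicitly. Node metrics follow
the conventions whose magnitudes match published node-statistics
tables for networks of this size: betweenness is unnormalized, summed
over unordered pairs, endpoints excluded, unreachable pairs skipped;
eccentricity is the maximum finite shortest-path length (0 for an
isolated node); the clustering coefficient is
$C = 2e/(k(k-1))$, defined 0 for degree < 2. Summary statistics use
the population SD (divide by $N$). Degree hubs are nodes with degree
strictly above `fraction × max(degree)` (default 0.8) — with a
maximum degree of 79 the cutoff is 63.2. The alternative reading of
"hubs own 80% of total connectivity" (a cumulative-degree rule) is
arithmetically different; the degree-cutoff rule is implemented
because it reproduces the published cutoff value exactly.

## Hierarchical clustering

Distance is $1 - r$ (centered Pearson, consistent with the
co-expression stage; range $[0, 2]$). `average_linkage()` is UPGMA:
inter-cluster distance is the unweighted mean over all cross leaf
pairs, ties broken toward the lexicographically smallest pair of
cluster identifiers (a cluster is identified by its smallest leaf
name), making merge order fully deterministic even on degenerate
inputs. The implementation is checked against both an independent
all-cross-pairs oracle and `stats::hclust(method = "average")`.
`cut_clusters()` undoes the last $k - 1$ merges; $k$ is a user
parameter (default 6) since no principled cut criterion is implied by
the method — published cluster counts arise from particular data.
Cluster ids are assigned by decreasing size, then smallest member
name.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the pipeline is
designed around: 19 disease vs 13 control samples; 300 probes named
`hsa-miR-SIM####` (mixed case on purpose, to exercise name
canonicalization at file boundaries); 30 planted miRs upregulated by
+2.0 log2 units in disease only (the motivating dataset's DE set was
entirely upregulated); unit Gaussian noise; one correlation block of
20 miRs at target correlation 0.95; a 73-entry known list containing
half the planted DE names; three predictors with miTG-like scores
uniform on [10, 40]; 12 consensus targets per miR plus ~30% decoy
records seen by fewer than all predictors; and 25 annotation terms of
which 2 are planted from DE-miR targets. The probe count and
background universe are free parameters because the motivating
study's array size is not part of the method.

Correlated blocks use one latent factor per block,
$x = \sqrt{\rho} f + \sqrt{1-\rho}\,\varepsilon$, giving expected
pairwise correlation exactly $\rho$. Block members are drawn
preferentially from the planted DE rows: disease-responsive miRs in
real data are strongly co-expressed (in the motivating study 195 of
204 DE miRs joined the $r > 0.9$ network), and this choice makes the
default pipeline's co-expression stage non-trivial. One global seed
derives independent per-stream sub-seeds, so adding a generator never
perturbs the others, and every generator is bit-identical under a
fixed seed.

What the generator does **not** emulate: dye or array batch effects,
probe-level raw files, miR family sequence similarity, heavy-tailed
expression noise, correlated TF activity, or realistic annotation
overlap structure. Passing tests therefore demonstrate correctness of
the pipeline's logic and calibration under a clean Gaussian model,
not robustness to real microarray artifacts — normalization is
assumed done upstream.

## Numerical choices and degenerate inputs

- Equal group values give $d = 0$ even when $s + s_0 = 0$.
- Zero-variance miRs have undefined correlations: excluded from
  co-expression edges with a warning, and a hard error in
  `correlation_distance()`.
- Hypergeometric tails use `phyper` on the $k-1$ boundary
  (`P(X >= k)` exactly); brute-force enumeration backs this in tests
  for universes up to 15.
- The acceptance checks in `tests/testthat/test-acceptance.R` run the
  SAM calibration suites at 300 probes with 100 permutations over
  10–20 seeds; these sizes give stable averages for the planted
  effect (d ≈ 5.5 at effect 2.0) while keeping the default test run
  fast.
- GraphML export goes through igraph; SIF is written directly (3
  tab-separated fields, interaction labels `regulates`, `targets`,
  `coexpressed`).

## Limitations

- The SAM FDR estimate omits $\pi_0$; with many true positives it
  overestimates FDR slightly (conservative call sets).
- Enrichment ignores annotation-graph structure (no true-path
  propagation) and treats terms independently.
- The signed $r > 0.9$ rule discards strongly anticorrelated pairs;
  use `absolute = TRUE` when repression-driven modules matter.
- `n` (regulatory out-degree) saturates at the top-k cap, so IR
  differences among high-degree miRs are driven mostly by $m$.
- UPGMA heights are not guaranteed monotone on non-metric inputs;
  the dendrogram records merges, not an embedding.
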