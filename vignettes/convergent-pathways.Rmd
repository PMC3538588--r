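---
title: "Convergent pathway analysis: methods and design choices"
author: "convergeR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convergent pathway analysis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(convergeR)
```

# The problem

For complex diseases, the genes flagged by genome-wide association
studies (GWAS) seldom map cleanly onto the pathophysiology seen in the
clinic. The analysis implemented here takes the view that GWAS genes act
*through their network neighborhood*: a seed set of reported genes is
expanded one hop into a physical/genetic interaction network, and the
expanded set is then confronted with two phenotype-level data types —
drug–gene (toxicogenomic) associations and case/control expression
profiles from several disease-relevant tissues. Pathways on which all of
these screens agree, across every tissue-by-gender condition, are the
convergent candidates; a leave-pathway-out ablation then quantifies how
much each candidate carries the convergent signal.

# Pipeline stages and their statistics

## Seed selection

`thresholdGenes()` collapses per-SNP association records to the best
(minimum) p-value per gene and keeps genes at or below the cutoff
(default `1e-5`, the conventional catalog inclusion threshold). The
comparison is inclusive; catalog p-values essentially never sit exactly
on a boundary, and a gene reported by several records passes if any one
does. Multi-gene intergenic annotations (`"A - B"`) are split into
atomic symbols at read time — the split rule is ours, the messages make
it auditable, and space-free hyphens (legitimate symbols such as
`NKX2-1`) are never split.

## One-hop expansion

`firstNeighborExpand()` is strictly one hop: the union of all genes
adjacent to at least one seed, plus (by default) the seeds themselves.
Whether the published 561-gene expanded set of the study we model
included the seeds is not decidable from its text; both behaviors are
exposed via `includeSeeds`. Physical and genetic edges are both
traversed by default; a kind filter is available. Seeds absent from the
network are reported in the result, never dropped silently.

## Overlap and enrichment tests

Every set comparison reduces to the exact hypergeometric upper tail
$P(X \ge k)$ computed via `stats::phyper` (log-gamma, no normal
approximation). Two conventions deserve note:

* **Inclusive tail.** We standardize on $P(X \ge k)$. The worked
  example printed in the source study (p = 8e-9 for margins
  20/111/561/14306) was computed in a spreadsheet whose convention is
  unrecoverable; our inclusive tail gives 1.01e-8, and the package's
  check is an order-of-magnitude one for exactly this reason.
* **EASE score.** Pathway enrichment defaults to the DAVID-style EASE
  score — the tail at $\max(k-1, 0)$ — with Benjamini–Hochberg
  correction. It is conservative by construction; a single-gene overlap
  carries no evidence.

Enrichment margins are always computed within the declared universe. The
default backgrounds differ by stage, mirroring the tools the study used:
pathway enrichment uses the union of all pathway genes (a DAVID-like
background), overlap tests use the interaction-network node set.
Bonferroni correction is applied to overlap screens with $m$ = the
number of simultaneous comparisons actually performed — retained drugs
for the drug screen, conditions analyzed together (four here) for the
intersection tests. Result tables are sorted by adjusted then raw
p-value with lexicographic tie-breaks, so output order is reproducible.

## Differential expression

The expression arm of the original study used a proprietary array error
model; what is preserved exactly here is its *calling convention*, the
signed Diff score $\mathrm{sgn}(\Delta)\,(-10\log_{10} p)$ with the
published |13| threshold (p = 0.05). The p-value itself comes from a
documented substitute: technical replicates are averaged within each
biological replicate (avoiding pseudoreplication of the 3 × 4 replicate
structure), then a two-sided Welch t-test compares the biological
replicate means. Calling at unadjusted scores defines the condition's
"disease transcriptome"; a BH-adjusted mode is available and can only
call fewer genes. Published absolute DE counts are *not* reproduction
targets: they depend on the proprietary model and on probe-level data we
deliberately do not emulate.

Two numerical notes. A gene constant and equal across all samples gets
p = 1 (direction `none`); zero pooled variance with unequal means gets
the smallest positive double, which the Diff-score transform caps with a
warning. And at 3 biological replicates per group the Welch–Satterthwaite
approximation is *conservative* — empirical size ≈ 0.03–0.04 at nominal
0.05 — so the type-I calibration test runs at 8 replicates per group,
where the approximation is accurate, and separately asserts that the
3-replicate design never becomes anti-conservative. Linear-scale input
is transformed as $\log_2(x + 1)$ (offset configurable).

## Common pathways and ablation

`commonPathways()` keeps pathways whose selected p-value is ≤ α in
*every* condition, ordered by the worst p across conditions. Membership
defaults to the **unadjusted** p at α = 0.05: applied to the published
per-condition tables shipped with the package
(`t2dIntersectionPathways()`), this is the only rule that reproduces the
study's printed twelve common pathways (adjusted-p membership admits
three or fewer); the rule is an inference from those tables, and both
modes are exposed.

`ablatePathway()` removes one pathway's genes from a commonality set and
re-runs enrichment. The published account of this step is qualitative
("less pronounced enrichment"), so the impact metric is ours and is
defined as: the sum of $\log_{10}(p_\mathrm{after}/p_\mathrm{before})$
over pathways significant before ablation, plus the count of
significance flips at α. The pipeline ranks candidate convergent
pathways by total impact across conditions — a quantitative replacement
for the study's literature-curation step, which is out of scope. The
ablated pathway's own post-ablation overlap is zero and its raw p
exactly 1, which the tests assert.

## qPCR arm

`deltaDeltaCt()` implements comparative-Ct relative quantification:
replicate Ct values are averaged per group, $\Delta Ct$ is target minus
endogenous control, $\Delta\Delta Ct$ is case minus calibrator, and fold
change is $2^{-\Delta\Delta Ct}$. Rows above the 36-cycle detection
threshold are flagged undetected and excluded.

# The synthetic-data generator

`plantConvergentSignal()` emits a complete input bundle — association
table, interaction network, GMT pathway collection, drug–gene table,
per-condition expression matrices — whose statistical structure is the
one the analysis assumes, with the ground truth recorded verbatim.

The default dimensions (`syntheticDefaults()`) mirror the modeled study
at roughly one-third scale, chosen once: a 5000-gene universe (vs a
14,306-node interactome), 22,000 edges (vs 67,659), 66 pathways of
10–60 genes (vs 199 pathways over 5197 genes), 90 seed genes (vs 93), 6
drugs, four tissue-by-gender conditions, 3 biological × 4 technical
replicates per group. Signal parameters: 30% of seeds drawn from the
causal pathway; causal-pathway genes wired to seeds at 5× the baseline
adjacency rate; drug lists over-sampling the interactome 4:1; log2
effect size δ = 1.5 with noise σ = 0.5; DE probability π = 0.3 for
interactome genes against a 0.02 background.

Design choices worth stating explicitly:

* **Association p-values are cosmetic** (log-uniform in
  [1e-12, cutoff]); only thresholding consumes them.
* **The DE program is one shared disease signature.** Which genes shift,
  and in which direction, is drawn once per bundle and applied to every
  condition; replicate noise is independent per condition. This reflects
  the cross-tissue consistency the study's qPCR validation reported, and
  it is what makes a cross-condition convergence analysis a sensible
  target for the generator. Per-condition redraws are the obvious
  alternative and weaken cross-condition commonality substantially.
* **Directions are symmetric** (up/down equally likely), matching the
  mixed up/down calls of real comparisons.
* **Network degrees are heavy-tailed** (power-law fitness sampling) in
  the default mode, as in curated interactomes; a uniform mode exists
  for null checks.
* `syntheticGwasCatalog()` is a *synthetic stand-in* for the study's
  supplementary gene list, which ships with no machine-readable copy: it
  reconstructs the stated composition (46 genes at 1e-8, cumulative 62,
  71, 93 by decade) with per-SNP duplicates and multi-gene entries so
  the reader's collapse/split rules are exercised. Tests against it
  check the thresholding machinery, not the study's actual gene list.

## What passing the synthetic tests does and does not show

The generator emulates set-level structure: seeds enriched in the causal
pathway, neighborhoods over-representing it, DE genes over-representing
the expanded set. It does not emulate probe-level array noise,
normalization artifacts, batch effects, correlated expression between
genes, population structure in the GWAS, or literature bias in curated
networks. Recovery of the planted pathway therefore validates the
pipeline's statistical machinery and plumbing — not the biological
claims of any particular study.

Calibration has the same caveat in reverse: the null-bundle checks show
the *overlap* stage's p-values are nearly uniform (its discrete support
is large), while the enrichment stage on small discrete support is
conservative, as exact tests are — its null positive rate is asserted to
never exceed the level rather than to match it.

# Problem sizes and determinism

Tests run at three scales chosen as the smallest that exhibit each
property: toy fixtures (enumeration oracles, N ≤ 30), mid-scale bundles
(2000 genes, 6000 edges — the smallest scale at which the interactome
stays a small fraction of the universe, as in the study, so that planted
signals are recoverable), and the full defaults above for the 20-replicate
recovery check. A single integer seed governs every stochastic stage;
bundles, reports and their JSON serializations are byte-identical across
re-runs with the same seed, which the suite asserts.

# Known limitations

* Gene identity is the canonicalized author-reported symbol; no
  identifier mapping (aliases collide or split as in the source data).
* One-hop expansion only; no k-hop, diffusion or edge weighting.
* The per-gene test assumes approximate normality of log2
  biological-replicate means; at n = 3 it is conservative (above).
* Exact reproduction of the modeled study's full-scale tables requires
  its version-pinned external databases and is out of scope by design;
  the package substitutes property-based checks at desk scale.
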