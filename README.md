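# convergeR

Genome-to-phenome convergence analysis for complex disease.

Genome-wide association studies (GWAS) of complex diseases such as type 2
diabetes report genes that individually explain little of the disease
phenotype and rarely line up with the pathways clinicians recognize.
`convergeR` implements a systems-level analysis that closes this gap by
asking where four independent lines of evidence converge:

1. **Genome** — genes reported by GWAS at an association cutoff
   (default p &le; 10<sup>-5</sup>) form a seed set;
2. **Interactome** — the seeds are expanded one hop into a physical and
   genetic interaction network;
3. **Toxicogenome** — the expanded set is screened against drug–gene
   association tables (drugs sharing fewer than 5 genes are excluded);
4. **Transcriptome** — per-tissue case/control expression matrices are
   reduced to up/down calls with the signed Diff-score convention.

Per condition (tissue × gender), the interactome ∩ transcriptome
commonality genes are tested for pathway enrichment; pathways significant
in **every** condition are the candidate convergent pathways, and each is
ranked by a leave-pathway-out **ablation impact**: remove its genes from
the commonality sets, re-run enrichment, and sum the log-fold degradation
of the remaining pathways' significance.

## The statistics

All set overlaps use the exact hypergeometric upper tail

P(X ≥ k), X ~ Hypergeometric(N, K, n)

with Bonferroni correction over the simultaneous comparisons. Pathway
enrichment uses the EASE score (the conservative modified Fisher exact
p-value computed after removing one overlapping gene, i.e. the tail at
k − 1) with Benjamini–Hochberg correction, mirroring DAVID. Differential
expression is a Welch t-test on biological-replicate means (technical
replicates pre-averaged), mapped to the signed Diff score
`sign · (−10·log10 p)`; |13| corresponds to p = 0.05. qPCR validation
arithmetic (2<sup>−ΔΔCt</sup> fold changes) is included.

A synthetic-data generator (`plantConvergentSignal`) emits complete,
internally consistent input bundles — association table, interaction
network, GMT pathways, drug–gene table, per-condition expression
matrices — with one *causal pathway* planted so that seeds, network
neighborhoods, drug genes and differentially expressed genes all converge
on it, and records the ground truth for parameter-recovery and
calibration tests.

## Worked example

```r
library(convergeR)

bundle <- plantConvergentSignal(syntheticDefaults(), seed = 42)
bundle
#> SyntheticBundle: 90 association rows; 4772 network nodes / 22029 edges;
#>   66 pathways; 6 drugs; 4 condition(s)
#>   planted causal pathway: PW036

report <- runPipeline(bundle, pipelineConfig(seed = 42))
report
#> ConvergenceReport
#>   seeds: 90
#>   interactome: 1411
#>   conditions: female_visceral_adipose, male_visceral_adipose,
#>               female_subcutaneous_adipose, male_skeletal_muscle
#>   common pathways: 1
#>   top ablation impact: PW036

report@ablation
#>   pathway impactScore flips
#> 1   PW036    38.09009     4
```

The 90 seed genes expand into a 1411-gene interactome; exactly one
pathway is enriched in the commonality genes of all four conditions, and
it is the planted causal pathway `PW036`: ablating its genes degrades the
convergent enrichment signal by 38 orders of magnitude summed over the
four conditions, flipping 4 enrichment calls past α = 0.05.

Individual stages are exposed directly, e.g. the enrichment of a
561-gene expanded set for the 111 known interactors of a phosphatase
within a 14,306-gene interactome, of which 20 are shared:

```r
hypergeometricTail(20, 111, 561, 14306)
#> [1] 1.011895e-08

diffScore(0.05, +1)
#> [1] 13.0103
```

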