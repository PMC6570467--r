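---
title: "Prioritizing under-studied metabolic genes from multi-omics data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing under-studied metabolic genes from multi-omics data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprior)
```

## The problem and the model

Screens comparing estrogen-receptor-negative (ERneg) against ERpos breast
tumors produce long lists of significant transcripts, proteins and
metabolites, but follow-up work concentrates on a small set of famous
genes. This package ranks *metabolic* genes by the cross-study consistency
of their differential expression and crosses the ranking with literature
counts, so that significant-but-ignored enzymes surface as candidates.

The workflow has five statistical stages.

**Per-study screening.** For every feature, a raw two-group p-value and
the fold change FC = mean(ERneg)/mean(ERpos) on the linear abundance
scale. Metabolites and proteins use the Mann–Whitney *U* test (exact null
distribution for total n ≤ 12 without ties; mid-rank normal approximation
with tie and continuity correction otherwise). Transcripts use Welch's
*t*-test on log2 abundances, an intentionally simple stand-in for the
moderated statistics microarray services apply; its per-study counts are
therefore approximations, which is acceptable because downstream stages
consume only raw p-values and the meta-analysis dominates single-study
noise. Raw p-values are deliberately left uncorrected: the screening stage
feeds a meta-analysis, not a biomarker panel, and correcting per study
would discard exactly the weak-but-consistent signals the KS statistic is
designed to accumulate. Proteomics matrices are prevalence-filtered first:
a protein must be observed in at least six samples of *either* group
(either-group rule), reflecting missingness in FFPE-derived data.

**Metabolic-gene selection.** A gene is metabolic if at least one of its
EC numbers survives an exclusion list of macromolecule-substrate classes
(protein kinases EC 2.7.10–2.7.13, peptidases EC 3.4, RNA/DNA polymerases
and reverse transcriptase, topoisomerases EC 5.6.2, tRNA ligases EC 6.1.1,
ribonucleases EC 3.1.26/27, nucleic-acid motor ATPases EC 3.6.4, the
ubiquitin ligase EC 2.3.2.27). The list ships as an editable TSV because
no canonical exclusion list exists; the inclusive "≥ 1 retained EC" rule
means mixed-annotation genes (e.g. a kinase that also carries a
dehydrogenase activity) stay in. Selection is monotone in the rule list
and idempotent, both property-tested.

**KS meta-analysis.** For a gene with sorted raw p-values
p₍₁₎ ≤ … ≤ p₍ₙ₎ from n studies, D⁺ = maxᵢ (i/n − p₍ᵢ₎) measures the excess
of small p-values over the Uniform(0,1) null, and the meta p-value is the
exact one-sided Birnbaum–Tingey tail

$$P(D^+ \ge d) = d \sum_{j=0}^{\lfloor n(1-d)\rfloor} \binom{n}{j}
\left(d + \tfrac{j}{n}\right)^{j-1}\left(1 - d - \tfrac{j}{n}\right)^{n-j}.$$

The exact sum (evaluated term-wise in log space) rather than the
asymptotic distribution is essential: n is the number of *studies* —
around ten — and the interesting tails reach 1e-15 and below, where
asymptotics are meaningless. When ⌊n(1−d)⌋ = 0 the sum collapses to
(1−d)ⁿ, the corner the tests pin against Monte-Carlo simulation. The
statistic is one-sided by default because the question is enrichment of
*small* p-values; a two-sided mode (D = max(D⁺, D⁻), tail bounded by twice
the one-sided tail) is available for detecting miscalibration. With a
single study D⁺ = 1 − p and the exact tail returns p itself, so the n = 1
degenerate case is well-defined; the default floor is `min_studies = 3`,
below which genes are reported as "insufficient evidence" rather than
silently dropped. Under a uniform null the meta p-value is exactly
uniform, which the calibration tests verify end to end through the
generator. No study-size weighting is applied — each study contributes one
p-value.

**Pathway over-representation.** Significant features (pooled across
omics after optional id-mapping into the pathway namespace) are tested per
pathway with the hypergeometric upper tail P(X ≥ k) within the universe of
measured, pathway-mapped features — a conservative universe choice;
unmapped ids are counted and discarded, as is conventional. BH correction
runs across tested pathways. Per-omics support flags record which layers
contribute at least one overlapping member, reproducing the usual
three-color reading (genes only / genes+proteins / all three omics). A
per-omics "separate" mode exists because pooled and per-layer analyses
answer slightly different questions and the right choice is data-dependent.

**Network and prioritization.** Significant entities are assembled into an
undirected typed graph: gene, protein, metabolite and enzyme (EC) nodes;
gene–enzyme, protein–enzyme and compound–enzyme edges through shared EC
numbers; symmetric reactant-pair edges; and chemical-similarity edges for
metabolite pairs with Tanimoto similarity strictly greater than 0.7 (the
strictness is tested at exactly 0.7). Two all-zero fingerprints get
similarity 0, not 1, so unannotated compounds cannot form spurious
cliques. Communities come from Louvain modularity clustering on the
simplified unweighted graph with a fixed seed; Louvain communities are
connected, so disconnected components are never merged. (A greedy-merge
clusterer was rejected because its tie-breaking can split a clique.)
Finally, the top genes by meta p-value (lexicographic tie-break on the
symbol, so ranking is a pure function of the inputs) are annotated with
literature counts; `n_papers < 5` flags a gene under-studied. A count that
could not be retrieved is "unavailable", which is distinct from zero and
never enters the under-studied set.

## The synthetic cohort generator

`sim_config()` defines the study conditions; all defaults were fixed when
the generator was written. It emulates a ten-study transcriptomics
collection plus one proteomics and one metabolomics study on an anchor
cohort, the design of the motivating meta-analysis:

| parameter | default | meaning |
|---|---|---|
| `n_studies` | 10 | transcriptomics studies sharing one truth table |
| `n_genes`, `n_proteins`, `n_metabolites` | 1000 / 300 / 150 | feature universes; proteins are gene products and inherit the gene's truth |
| `n_neg`, `n_pos` | 30 / 30 | samples per group per study (within the 10–88 / 32–138 ranges of typical public cohorts, at desk scale) |
| `frac_diff` | 0.1 | planted differential fraction |
| `effect_size` | 1 | mean log2 shift in ERneg, in units of `sigma` |
| `sigma` | 1 | residual sd of log2 abundances |
| `panel_overlap` | 0.8 | fraction of the universe measured per study |
| `missing_rate` | 0.1 | proteomics per-cell missingness (MCAR default; an MNAR switch makes low-intensity cells up to twice as likely to be missing) |
| `effect_jitter` | 0 | per-study effect heterogeneity; 0 because cross-study consistency is the meta-analysis' working assumption, exposed as config since real heterogeneity is unknown |

Abundances are log2-normal: feature baselines are Uniform(6, 12) on the
log2 scale and a differential feature is shifted by ±`effect_size`·σ in
the ERneg group, so the expected group-mean ratio is 2^±effect and an
`effect_size` of log2(1.37) ≈ 0.45 reproduces an average 1.37-fold effect,
with significant-feature fold changes spanning roughly 0.6–3 at realistic
sample sizes. Literature counts are negative-binomial (size 0.5, mean 20 —
heavily overdispersed, like real publication counts) and drawn
independently of differential status, so significant-but-understudied
genes exist by construction and any association the pipeline reports would
be an artifact. Sub-seeds for truth, panels, noise and annotations are
derived arithmetically from the config seed, so identical config + seed
gives byte-identical output everywhere, including the files written by
`full_run()`.

What the generator does **not** emulate: batch effects, probe-level
microarray structure, correlated features (co-expression), platform-wise
normalization artifacts, or heavy-tailed abundance noise. Passing tests
therefore demonstrate the statistical machinery is correct and calibrated
under the stated generative model — not that any particular real cohort
satisfies that model.

## Numerical choices and degenerate inputs

- Mann–Whitney switches to the exact distribution only without ties at
  total n ≤ 12; ties always use the mid-rank approximation (the exact path
  refuses ties).
- Welch with both groups constant returns p = 1 when means are equal and
  p = 0 otherwise; a feature with fewer than two observations per group or
  a non-positive group mean is skipped with a collected warning, never an
  error.
- The Birnbaum–Tingey sum is evaluated in log space term by term and
  clamped to [0, 1]; `d = 0` returns 1 and `d ≥ 1` returns 0.
- Fold change uses arithmetic group means by default (geometric optional);
  "unchanged" is assigned only at a ratio of exactly 1, and significance
  never gates direction — consumers decide.
- All orderings use radix (C-locale) sorting so outputs are
  locale-independent; rank ties break lexicographically on the feature id.
- Hypergeometric inputs are validated (k ≤ min(K, n), K, n ≤ N) and
  inconsistent counts are fatal.

## Problem sizes used in the test suite

The acceptance-style checks run at 10 studies × 1000 genes with 30 vs 30
samples (calibration and recovery), 10⁶ uniform draws per KS Monte-Carlo
comparison at n ∈ {2, 5, 10}, exhaustive enumeration for Mann–Whitney
(total n ≤ 10) and the hypergeometric tail (N ≤ 20), and a 470-metabolite,
59 vs 192 anchor cohort in the acceptance script. These sizes give 3σ
binomial bands tight enough to detect calibration errors of a percentage
point while keeping the whole suite under a minute of statistics time.

## Known limitations

- The transcript test is an unmoderated Welch t; with very small studies
  (n < 10 per group) a variance-moderated test would be more powerful.
- The KS meta-analysis treats per-study p-values as independent and
  ignores study size and direction: a gene flipping direction across
  studies with consistently small p-values still ranks high. Direction
  consistency must be checked downstream (the priority table carries the
  anchor-cohort fold direction for that purpose).
- Pooled multi-omics enrichment counts a gene and its protein product once
  after id-mapping; evidence from two layers does not weigh more in the
  test itself, only in the support flags.
- Live literature counts drift over time and depend on query phrasing;
  fixture counts are the reproducible path.
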