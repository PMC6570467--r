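# metaprior

Multi-omics meta-analysis and prioritization of under-studied metabolic
genes.

Aggressive estrogen-receptor-negative (ERneg) breast tumors differ from
ERpos tumors across transcripts, proteins and metabolites, but candidate
genes emerging from such screens are dominated by a handful of heavily
published genes. `metaprior` implements a workflow that ranks **metabolic**
genes by the consistency of their differential expression across many
independent studies and then cross-references the ranking against
literature counts, surfacing significant genes that are barely studied —
candidate therapeutic targets hiding in plain sight.

The package is aimed at computational biologists integrating per-study
differential statistics across transcriptomics, proteomics and
metabolomics. All of its statistics run equally on real per-study tables
and on the built-in synthetic cohort generator with known ground truth,
which is how the package validates itself.

## The method

For each study *s* and feature *f*, a raw two-group p-value is computed
(Mann–Whitney *U* for metabolites and proteins, Welch *t* on log2
abundances for transcripts) together with the fold change
FC = mean(ERneg)/mean(ERpos). No multiple-testing correction is applied at
this stage: the raw p-values are the input of the meta-analysis.

Genes are restricted to *metabolic* genes: those with at least one Enzyme
Commission (EC) number that chemically transforms small molecules, after
excluding EC classes acting on proteins or nucleic acids (protein kinases
EC 2.7.10–13, peptidases EC 3.4, polymerases, tRNA ligases, ...).

For a gene measured in *n* studies with raw p-values p₍₁₎ ≤ … ≤ p₍ₙ₎, the
meta-analysis statistic is the one-sided Kolmogorov–Smirnov excursion
against the Uniform(0,1) null

    D⁺ = max_i ( i/n − p₍ᵢ₎ ),

and the meta p-value is the exact Birnbaum–Tingey tail

    P(D⁺ ≥ d) = d · Σ_{j=0}^{⌊n(1−d)⌋} C(n,j) (d + j/n)^{j−1} (1 − d − j/n)^{n−j},

which collapses to (1−d)ⁿ when ⌊n(1−d)⌋ = 0. Small meta p-values indicate
an excess of small per-study p-values, i.e. consistent cross-study
differential expression; with n = 10 studies the exact tail resolves values
down to the 1e-15 scale where asymptotics fail.

Significant features from all omics layers are pooled into a hypergeometric
over-representation test against user-supplied pathway sets (GMT), with
per-omics support flags; entities are assembled into an integrated
biochemical network (gene/protein/metabolite/enzyme nodes; gene–enzyme,
protein–enzyme, compound–enzyme, reactant-pair, and Tanimoto
chemical-similarity > 0.7 edges) with Louvain community labels and
GraphML/SIF export. Finally, the top meta-analysis genes are annotated with
PubMed literature counts (`"<SYMBOL>" AND "breast cancer"`), and genes with
fewer than five matching papers are flagged **under-studied**.

## Worked example

```r
library(metaprior)

cfg <- sim_config(n_studies = 10, n_genes = 1000, frac_diff = 0.1,
                  effect_size = 1, n_neg = 30, n_pos = 30, seed = 2)
res <- full_run(cfg, out_dir = "demo_out", top_n = 10)
head(res$priority[, c("rank", "gene", "meta_p", "n_papers", "understudied")])
```

```
  rank      gene       meta_p n_papers understudied
1    1 gene_0485 5.576311e-29       17        FALSE
2    2 gene_0286 6.025485e-26        0         TRUE
3    3 gene_0602 8.576054e-26       17        FALSE
4    4 gene_0096 7.719670e-22        5        FALSE
5    5 gene_0868 3.420751e-21        0         TRUE
6    6 gene_0305 1.025988e-20       41        FALSE
```

Each row is one metabolic gene, ranked by its exact KS meta p-value across
the ten simulated studies (ties broken alphabetically); meta p-values at
the 1e-20 scale arise for genes significant in essentially every study.
`n_papers` is its (simulated) literature count; `understudied = TRUE` marks
significant genes with fewer than five publications — the workflow's
candidate output. `res$summaries` holds per-study total/altered/up/down
counts, `res$enrichment` the pooled multi-omics pathway table with
per-omics support flags, and `demo_out/` the full set of TSV/GraphML/JSON
outputs (byte-identical across repeated runs with the same config).

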