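# orenhancer

Conservation and regulatory analysis of odorant-receptor (OR) enhancer
elements.

## The problem this package addresses

Mammalian OR genes sit in large genomic clusters and are expressed one per
neuron, under the control of short, deeply conserved cis-regulatory
elements. Identifying such an element and establishing that it acts as a
long-range enhancer involves a recurring set of computations:

* **Cross-species conservation scoring.** For a candidate element of length
  *L* and a pairwise whole-genome alignment to another species, count the
  element bases aligned to a query nucleotide (*A*) and score

  - coverage = *A* / *L*,
  - identity = identical pairs / *A*,
  - conservation index = (coverage\[%\] × identity\[%\]) / 100.

  Elements are screened by requiring a syntenic region in *every* tested
  species and an OR gene within 1 Mb on the same chromosome or scaffold in
  each species, then ranked by index.
* **VISTA-style profiling.** Sliding-window percent identity along a
  region (70% threshold, 100-bp window and minimum width by default;
  50 bp for the sensitive variant), conserved-segment calling, and
  classification of segments against exon annotations.
* **Motif analysis.** Both-strand scanning for the degenerate motifs of OR
  enhancers — homeodomain `TAATKR`, O/E-like `YYYCARRRR`, the class
  I-specific `AAACTTTTC`, and the extended homeodomain
  `AACTTTTTAATGA` — detection of the motif-dense 430-bp core window, and an
  ungapped log-odds profile built from a multiple alignment for retrieving
  the orthologous core in further genomes.
* **Deletion-phenotype statistics.** Differential expression of the
  clustered genes after element deletion (75% percentile-shift
  normalization, pooled or moderated t, BH FDR, the signed ±1.3
  fold-change classification, and the correlation of log2 fold change with
  genomic distance from the element), plus the cell-count tests used for
  in situ data: pooled t-tests straight from `mean ± s.e.m., n` summaries,
  Fisher's exact test on co-expression tables, and one-way ANOVA with
  Tukey HSD.

A synthetic-data module generates every input with known ground truth —
divergent pairwise alignments, multi-species element panels, sequences with
embedded motifs, a distance-decaying knockdown expression experiment, and
per-genotype cell counts — so the whole pipeline is testable offline.

## Worked example

Score a simulated 36-element, 7-species screen, apply both filters and rank
the survivors:

```r
library(orenhancer)

panel   <- simulate_enhancer_panel(seed = 1)           # fixtures + truth
records <- score_conservation(panel$elements, panel$alignments)
kept    <- filter_all_species(records, panel$species)  # synteny in all 7
linkage <- link_nearest_or(records[records$element_id %in% kept &
                                     records$syntenic_found, ],
                           panel$or_genes, max_distance = 1e6)
linked  <- tapply(linkage$linked, linkage$element_id, all)
ranking <- rank_elements(records, element_ids = names(linked)[linked])

length(kept); sum(linked)
#> [1] 21
#> [1] 15
head(ranking, 3)
#> # A tibble: 3 × 6
#>   element_id mean_index min_index n_species rank_mean rank_min
#>   <chr>           <dbl>     <dbl>     <int>     <int>    <int>
#> 1 elem_01          94.2      93.3         7         1        1
#> 2 elem_02          84.4      83.6         7         2        2
#> 3 elem_11          84.3      82.8         7         3        8
```

Of 36 candidates, 21 have a syntenic region in all seven species and 15 of
those are linked to an OR gene within 1 Mb in every species — the designed
truth of the fixture, recovered by the pipeline. `elem_01`, generated at
the lowest divergence, ranks first with a mean conservation index of 94.2
(its worst single-species index is 93.3).

The statistics functions reproduce published anchor values directly from
printed summaries:

```r
pooled_t_from_summary(148, 13.8, 6, 306, 43.5, 5)
#> # A tibble: 1 × 5
#>       t    df       p mean_diff degenerate
#>   <dbl> <dbl>   <dbl>     <dbl> <lgl>
#> 1  3.75     9 0.00455       158 FALSE

fisher_exact_2x2(258, 2854, 4, 3248)
#> # A tibble: 1 × 3
#>   odds_ratio        p degenerate
#>        <dbl>    <dbl> <lgl>
#> 1       73.4 4.23e-76 FALSE
```

The t-test on GFP-positive cell counts gives p = 0.0046 (printed as
0.0046); the Fisher test on the 258/3112 vs 4/3252 co-expression table is
far below the 2.2 × 10⁻¹⁶ reporting floor.

`run_pipeline()` chains every stage (simulate → conserve → vista → motifs →
de → stats) from a single config, writing TSV/JSON outputs plus the
effective configuration; reruns with the same seed are byte-identical.

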