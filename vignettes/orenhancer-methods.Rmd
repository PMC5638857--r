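---
title: "Methods: conservation, motif and expression analysis of OR enhancer elements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation, motif and expression analysis of OR enhancer elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orenhancer)
```

## Scope and scientific setting

Mammalian odorant-receptor (OR) genes are expressed under a strict
one-neuron-one-receptor rule, and their choice is controlled by short,
deeply conserved cis-regulatory elements that can act across an entire gene
cluster. `orenhancer` implements the computational workflow used to
characterise such an element for the class I OR cluster — a single ~3-Mb
region on mouse chromosome 7: cross-species conservation scoring of
candidate enhancers from pairwise whole-genome alignments, browser-style
(VISTA-like) percent-identity profiling, degenerate-motif and profile-based
motif analysis of the element's core, differential expression of the linked
gene cluster after element deletion, and the summary-statistic hypothesis
tests used for per-genotype cell counts.

Every stage consumes standard text formats (BED, AXT, FASTA, TSV) and every
stage has a matching simulator with known ground truth, so the complete
pipeline can be exercised and validated without any genome downloads.

## Coordinate conventions

All internal coordinates are 0-based half-open (`[start, end)`), the BED
convention, and every function operates in that space. Coordinates printed
in papers and genome browsers are 1-based fully inclusive; they are
converted at the I/O boundary by `printed_to_interval()` and
`interval_to_printed()`, which are mutual inverses. The conversion is pinned
by two published interval lengths: a 1982-bp element deletion
(chr7:102,509,690–102,511,671 in mm10) and its 430-bp core
(chr7:102,509,921–102,510,350).

AXT alignment blocks are normalized on read: 1-based coordinates shift to
the internal convention and minus-strand query anchors (which AXT stores in
reverse-complement space) are converted to forward-strand genome
coordinates, so downstream code never sees strand-relative coordinates.
Soft-masked lower-case bases are preserved on read; each consumer decides
how to treat them.

## Conservation scoring

For an element of length $L$ and one species' pairwise alignment, the three
statistics are

* **coverage** $= A/L$, where $A$ counts element reference bases aligned to
  a query *nucleotide* — bases opposite query gaps are covered by a block
  but not aligned to sequence, and are excluded from $A$;
* **identity**: the fraction of those $A$ pairs that are identical,
  compared case-insensitively; any pair involving an ambiguity code counts
  as aligned but never identical (a conservative choice — the divergence
  estimate can only go down);
* **conservation index** $= (\text{coverage}\,[\%] \times
  \text{identity}\,[\%])/100 \in [0, 100]$, a single number rewarding both
  alignable length and sequence similarity.

Identity is undefined when $A = 0$; the index is then 0 and the record is
flagged as having no syntenic region. When alignment blocks overlap on the
reference (rare in single-coverage "net" alignments), the first block in
file order wins, and a message reports it.

Two filters reproduce the screening logic of enhancer-conservation surveys:
`filter_all_species()` drops any element whose syntenic region is missing
from even one species, and `link_nearest_or()` requires an OR gene within
1 Mb (inclusive, edge-to-edge, overlap = 0) on the same chromosome or
scaffold of each species' assembly. The element's location in another
species is taken as the span of its aligned query positions. Ranking
reports both the mean and the minimum index across species; ties break by
element id so that the ranking is a pure function of its input set.

## VISTA-style identity profiling

`windowed_identity()` computes, for every reference base of a region, the
percent identity over a window of `window` consecutive *reference* bases
(not alignment columns) centered on it. The window for width $w$ at
position $p$ spans $[p - \lfloor (w-1)/2 \rfloor,\; p + \lceil (w-1)/2
\rceil]$; at the region edges it is truncated and the denominator shrinks
accordingly. Unaligned bases, bases opposite query gaps and ambiguity pairs
count as mismatches, so alignment gaps depress the curve exactly as they do
in browser conservation plots. The published parameter sets are the
defaults: threshold 70% with a 100-bp window and minimum width, and a
50-bp sensitive variant for distant comparisons. An optional
`mask_lowercase` flag scores soft-masked (repeat) bases as unalignable;
it is off by default.

`call_conserved_segments()` reports maximal runs of positions at or above
the threshold that are at least `min_width` long. Whether the minimum width
applies before or after merging adjacent qualifying windows is not fixed by
the published parameter description; this implementation applies it to
maximal runs, which is the simplest interpretation and is pinned by tests
(raising the threshold can then only shrink the called territory — a tested
invariant). Segment classification assigns the annotation category
(coding exon > noncoding exon > intergenic on ties) with the largest base
overlap, computed on per-category interval unions.

## Motif analysis

The default motif set contains the four degenerate motifs recurrent in OR
enhancers: the homeodomain site `TAATKR`, the O/E-like site `YYYCARRRR`,
the class I-specific site `AAACTTTTC` and the extended homeodomain site
`AACTTTTTAATGA`. `iupac_scan()` matches IUPAC classes case-insensitively on
both strands, reporting minus-strand occurrences in forward-strand
coordinates; overlapping and palindromic occurrences are all reported. Two
asymmetric rules keep the scan conservative: `N` in a *pattern* matches any
base, but `N` in the *target* matches nothing (an ambiguous base is never
evidence for a site). The scanner is implemented as compiled character-class
matching with a look-ahead so overlapping hits are found, and it is tested
for exact equality against a brute-force per-window oracle and for strand
symmetry on random sequences.

`find_core_window()` locates the motif-dense core of an element: the
fixed-width window (430 bp by default, the width of the core element that
motivated it) containing the most hits, required to include at least two
distinct motif classes — reflecting the biological signature of homeodomain
sites clustered with an O/E-like site. Ties break to the leftmost window.

For cross-species retrieval of an element core, `build_profile()` condenses
a multiple alignment into an ungapped log-odds profile: columns with more
than 50% gaps are dropped (the match-column rule), each retained column's
nucleotide frequencies receive a pseudocount (default 1) and are scored in
log2 odds against the observed background composition.
`profile_top_hit()` scans every ungapped placement on both strands and
returns the single best, with deterministic tie-breaking (leftmost, `+`
before `-`). The published analysis used a profile HMM for the same
retrieval task — the single top hit of a short, indel-poor element; an
ungapped log-odds profile is fully specified, dependency-free and
sufficient for that task, which is why it is the implementation here.
Gapped-placement scoring (insert/delete states) is a known limitation.

## Differential expression of the gene cluster

`de_analyze()` applies the array-style workflow:

1. **75% percentile-shift normalization**: each sample's log2 intensities
   are shifted so its 75th percentile is exactly zero, making the analysis
   invariant to per-sample additive shifts (tested exactly).
2. **Per-gene two-sample tests**: the classical pooled-variance t-test,
   with log2 fold change defined as mutant minus wild-type mean. An
   optional moderated variant shrinks each gene's variance toward the
   across-gene mean residual variance with a fixed prior weight of
   `prior_df = 4` pseudo-degrees of freedom (added to the residual df).
   This fixed-weight moderation is deliberately simple; the plain pooled t
   is the default and is what all calibration tests assert.
3. **BH adjustment** across all tested genes.
4. **Fold-change classification** in the signed convention of expression
   software (signed FC = ratio if ratio ≥ 1, else −1/ratio): a linear ratio
   cannot be negative, so "fold change < −1.3" is read as
   `log2fc ≤ −log2(1.3)`. Categories: *decreased* / *increased* (beyond the
   1.3-fold threshold with raw p < 0.05), *tending decreased* (beyond the
   negative threshold, p ≥ 0.05), else *unchanged*. Classification uses raw
   p-values; the BH-adjusted values are reported alongside.
5. **Distance correlation**: Pearson correlation of log2 fold change with
   the unsigned distance of the gene midpoint from the element midpoint.

`ish_fold_change()` supports the orthogonal cell-count route: fold change
as the ratio of mean positive-cell counts per section, log2-transformed for
agreement analysis with the array fold changes.

## Cell-count statistics

`pooled_t_from_summary()` computes Student's pooled-variance unpaired
t-test directly from `mean ± s.e.m., n` summaries ($sd_i = sem_i\sqrt{n_i}$),
and `t_from_raw()` delegates to it so both routes agree exactly. The pooled
(not Welch) test is used because it is the convention of the graphing
software these summaries come from, and it uniquely reproduces both
published p-values (0.91 and 0.0046) from the published summaries.
`fisher_exact_2x2()` uses the summed small-probability two-sided rule and
reports the sample odds ratio $ad/bc$. `anova_tukey()` is classical one-way
ANOVA with Tukey HSD via the studentized range distribution; the degenerate
all-values-equal case returns F = 0, p = 1 explicitly rather than the 0/0
ratio. All of these are cross-checked in the tests against independent
oracles: full hypergeometric enumeration, `t.test(var.equal = TRUE)`, and a
sums-of-squares/`ptukey` recomputation.

## The synthetic-data generators

The generators define the study conditions under which everything is
tested; their defaults are fixed and their ground truth is always computed
by construction, never by the code under test.

* `simulate_pairwise_alignment()`: substitutions are drawn per site,
  uniformly over the three alternative bases (a Jukes–Cantor-like choice
  with analytically known expected identity $1 - r$); indels occur per site
  at the stated rate, split evenly between deletions and insertions, with
  geometric lengths. The realized coverage and identity are recorded as
  truth. `dropout = TRUE` models an element absent from a species.
* `simulate_enhancer_panel()`: 36 candidate elements against 7 species by
  default, constructed so 21 have syntenic regions in all species and 15 of
  those are OR-linked in all species — the funnel shape of the enhancer
  screen this package was built around. Element 1 is simulated at a lower
  substitution rate (0.05 vs 0.15) so one element is uniformly the most
  conserved; unlinked elements get their nearest OR at 1.5 Mb, safely
  outside the 1-Mb rule.
* `embed_motifs()`: places concrete realizations of degenerate motifs at
  known positions/strands in an i.i.d. background of stated GC content,
  then removes spurious background occurrences by targeted resampling so
  the scanner truth is exact. Hits that overlap a placed interval (e.g. the
  homeodomain core inside an extended homeodomain placement) are genuine
  and retained.
* `simulate_cluster_expression()`: a two-genotype experiment on 200 genes
  spread over 3 Mb, 6 replicates per group, in which the mutant log2
  intensity of a gene at distance $d$ from the element is reduced by
  $k \cdot e^{-d/\lambda}$ with $k = 2$ log2 units and $\lambda = 1.5$ Mb —
  a strong proximal knockdown that decays but never vanishes across the
  cluster, matching the qualitative geometry of a long-range cluster
  enhancer. Measurement noise is Gaussian on the log2 scale with sd 0.3,
  a typical replicate-level dispersion for array intensities. The realized
  per-gene effects and their closed-form correlation with distance are
  stored as truth; at zero noise the analysis recovers that correlation to
  machine precision.
* `simulate_cell_counts()`: normal draws per group with stated moments.

One global seed plus fixed per-operation substreams make every fixture
reproducible byte-for-byte, and adding a fixture does not shift existing
ones.

What the generators deliberately do **not** emulate: phylogenetic structure
(no tree-aware evolution — each species diverges independently), probe-level
array artifacts, spatial section-to-section ISH variability, and genomic
context beyond the simulated elements. Passing tests therefore demonstrate
correctness of the computations and calibration under these idealized
conditions, not reproduction of the real-data screen: the published counts
(e.g. 75 decreased / 1 increased / 10 tending / 43 unaltered among 129
genes, and the r = 0.42 distance correlation) depend on the deposited
expression matrix and on alignment-file versions, and are outside
desk-scale reproduction.

## Numerical choices and problem sizes

* Identity comparisons are case-insensitive; ambiguity codes never count
  as matches.
* Fisher tie handling uses a relative tolerance of 1e-7 when comparing
  table probabilities, matching common practice.
* Tie-breaks are deterministic everywhere: first block in file order per
  reference base; leftmost window, `+` before `-` for profile hits;
  element id for ranking ties.
* The test suite runs at deliberately modest sizes chosen to finish in a
  few minutes while still constraining the implementations: 300-bp
  alignments for oracle equivalence (50 replicates), a 1-Mb profile for the
  scaling check, 1000 random sequences for scanner equality, a 5000-gene
  null simulation for test-size calibration, exhaustive Fisher enumeration
  for table totals up to 20 plus random totals up to 200.

## Limitations

* The profile search is ungapped; orthologs with indels inside the core
  would score suboptimally compared to a full profile HMM.
* The moderated t uses a fixed prior weight rather than estimating it from
  the data; for real studies a dedicated empirical-Bayes package is the
  better tool, and the plain pooled t is this package's default.
* `filter_all_species()` treats a missing (element, species) record as "no
  syntenic region", which is the conservative reading but conflates missing
  data with true absence.
* Repeat handling is limited to the optional lower-case masking flag;
  no repeat annotation is computed.
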