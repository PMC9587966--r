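---
title: "Methods: multi-region TIME heterogeneity and co-evolution"
author: "mrtime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-region TIME heterogeneity and co-evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrtime)
```

## Scope and data model

`mrtime` starts where upstream processing ends. Its inputs are the
products of standard pipelines — clonotype tables from repertoire
assembly, immune-cell fractions from deconvolution, TPM from RNA-seq
quantification, somatic variants from exome calling with optional
neoantigen flags, and purity-adjusted copy-number segments — organised
by a sample sheet that maps every sample to a patient, one of four
tissue classes (`normal`, `primary`, `metastasis`, `blood`) and a site
label. Every between-sample statistic in the package is computed within
patients only, and labelled with the comparison category implied by the
two tissue classes; blood samples pair only with non-blood samples.

Clonotype identity is the exact triple (CDR3 amino-acid junction,
V call, J call). The amino-acid junction was chosen over the nucleotide
junction because D-segment and nucleotide-level calls are unreliable in
short-amplicon repertoire data; `read_airr_tsv(junction_col =
"junction")` switches to nucleotide keys when the input supports them.
Rows with identical keys merge by summing counts, and total reads are
conserved by the merge.

Segment coordinates are 0-based half-open internally; SEG input is
treated as 1-based inclusive and converted on read. Infiltration rows
must sum to 1 within `1e-6`; deviations up to `1e-3` can be renormalized
on request, larger ones are treated as corrupt input, because
deconvolution output sums to 1 by construction.

## Repertoire diversity

For counts with fractions $p_i$ over $S$ clonotypes the package reports
richness $S$, Shannon entropy $H=-\sum p_i\ln p_i$ (natural log; a
`base` argument exists for reporting in bits), Pielou evenness
$J=H/\ln S$ and clonality $C=1-J$. At $S=1$, $J$ is the 0/0 limit; the
package defines $C=1$ (and $J=0$), the limit of a two-clone repertoire
as the minor clone vanishes — a monoclonal repertoire is maximally
skewed.

Highly expanded clones are those with read share strictly greater than
0.1% (`hec_threshold` is tunable). Because "proportion of HEC" admits
two readings, both are computed: the proportion of clonotypes that are
HEC (the headline number) and the proportion of reads they carry.

Richness depends on sequencing depth and on how much of the tissue is
T cells. The normalization rarefies each repertoire to a cohort-common
depth — by default the minimum total reads across samples — by seeded
uniform subsampling of reads without replacement, averaged over 10
replicates to damp sampling noise, and divides by the sample's relative
T-cell fraction. Rarefaction (rather than a parametric estimator) was
chosen because it makes no distributional assumption about clone sizes
and is the field's default for depth correction; the replicate average
is deterministic given the seed.

## Sharing, heterogeneity and divergence

Clonotype sharing between two samples is the Jaccard index of their
clonotype key sets; abundances are deliberately ignored so that sharing
measures repertoire composition, not expansion. TCR heterogeneity is
one minus the Jaccard index. The blood-surveillance view takes each
tissue sample's top-`n` (default 100) most abundant clonotypes — ties
at the boundary broken by descending count then lexicographic key, for
determinism — and reports the percentage found anywhere in the
patient's blood repertoire.

Immune infiltration divergence between two samples is the Euclidean
distance between their 22-dimensional fraction vectors, aligned by cell
type (mismatched cell-type sets are an error, not silently reindexed).
On the simplex this distance is bounded by $\sqrt 2$.

VJ usage per sample is the read-weighted frequency of each (V, J) pair;
differential usage between two groups of samples is tested per VJ pair
with the two-sided Wilcoxon rank-sum test (a VJ absent from a sample
contributes frequency 0) and corrected by Benjamini–Hochberg across all
VJ pairs tested.

## Expression summaries

The immunomodulator summary takes each panel gene, computes its median
TPM in the normal, primary and metastasis groups, and z-scores the
three medians (sample standard deviation, $n-1$; a zero-variance gene
maps to all-zero z-scores; genes absent from the matrix are flagged
missing, never imputed to zero). The bundled 70-gene panel with its
seven super-categories is editable package data and is a representative
reconstruction of the widely used immunomodulator panel — the exact
list is a configuration input, and any gene vector can be supplied.
Category labels are annotation only.

Cytolytic activity is the literal geometric mean of GZMA and PRF1 TPM,
with no pseudocount by default, so a zero in either gene yields zero
CYT; `cyt_pseudocount` restores the offset convention where preferred.
The immunotherapy biomarker panel (CYT, PD-L1, PD-L2, PD-1, CD39, CD8A,
CD8B, CD4) is z-scored across each patient's samples independently,
excluding blood (no tumour expression is expected there); a
single-sample patient is reported as undefined rather than as numbers.

## Genomic summaries

Over a patient's tumour samples (primary and metastatic; normal and
blood are excluded from the universe), a variant is *trunk* when
present in all tumour samples, *private* when present in exactly one,
and *shared* otherwise. Although "shared by two or more" literally
includes trunk variants, the three classes are kept disjoint so that
their counts partition the variant set — the conservation property the
tests enforce.

TMB counts, per sample, variants whose classification falls in the
standard non-synonymous set (missense, nonsense, nonstop, splice site,
frameshift and in-frame indels, translation start site). Unknown
classification strings are an error under `strict = TRUE` and counted
as non-synonymous otherwise. CIS is the aberrant fraction of the
genome, a segment being aberrant when its purity-adjusted copy number
is $\ge 3$ or $\le 1$ (inclusive bounds, applied to the values as
given, fractional or integer). The denominator is the total length
covered by the sample's segments, since exome segment coverage varies
between samples; `genome_size` overrides it with a fixed value.

## Co-evolution

For each patient with at least three tumour samples, dendrograms are
built by complete-linkage hierarchical clustering from three distance
matrices: Jaccard distances between per-sample neoantigen sets and
between TCR clonotype sets (presence/absence, mirroring the
heterogeneity metric), and Euclidean distances between infiltration
vectors. Labels are put in canonical sorted order before clustering so
the merge sequence, including tie resolution, is a deterministic
function of the distances.

Two dendrograms on the same leaves are compared by the cophenetic
correlation: the Pearson correlation of their leaf-pair cophenetic
distances (the merge height of the lowest common cluster), matched by
label. Fewer than three leaves leave a single height and an undefined
correlation, so such patients are skipped with a recorded reason; a
tree with constant cophenetic distances makes the correlation
undefined and is reported as `NA`.

Significance uses a leaf-label permutation null: the correlation is
recomputed under permutations of one tree's labels. The test is
one-sided by default (co-evolution means large positive $r$);
`two_sided = TRUE` tests $|r|$. For up to 7 leaves all $n!$
permutations are enumerated and the p-value is exact with support
$k/n!$; beyond that, permutations are sampled with the add-one
estimator $p=(1+\#\{r_{perm}\ge r_{obs}\})/(1+n_{perm})$, which cannot
fall below $1/(n_{perm}+1)$ and is reproducible given the seed. A
tolerance of $10^{-12}$ treats numerically tied correlations as ties.
No significance verdict is attached to the output: raw $r$ and $p$ are
reported.

## Group comparisons

The shared engine is the two-sided Wilcoxon rank-sum test. With pooled
size at most 12 and no ties, the p-value comes from the exact rank-sum
null distribution; otherwise the normal approximation with
tie-corrected variance and continuity correction is used (the exact
path refuses ties). The reported statistic is the rank sum of the
smaller group. Benjamini–Hochberg correction is applied within each
family of contrasts (category-vs-category per metric; VJ pairs per
usage comparison) independently.

Pairwise heterogeneity values within a patient share samples and are
not independent, so pooled rank-sum tests over pairs are
anti-conservative; this mirrors common practice and is therefore the
default, but `compare_categories(aggregate = "patient_median")`
collapses to one median per patient per category first as a sensitivity
analysis.

## The synthetic cohort generator

The generator's defaults describe a five-patient multi-region
gastro-oesophageal cohort at desk scale: per patient 2 normal, 3
primary, 3 metastatic, 1 blood sample; repertoire richness 450 (normal,
primary), 600 (metastasis), 300 (blood) at 4,000 reads; Zipf exponents
1.0/1.1/0.8/1.2 so metastases are the richest and most even;
same-class clonotype-sharing targets 0.08 (normal), 0.10 (primary),
0.04 (metastasis); blood capture rates for tissue top-100 clones
0.19/0.38/0.565 (normal/primary/metastasis); Dirichlet concentrations
100/50/2 so metastatic infiltration is the most dispersed; 60 mutations
per patient split 40/25/35% trunk/shared/private with neoantigen rate
0.4 on non-synonymous variants. These scaled-down sizes keep the whole
pipeline and its tests inside seconds per cohort while preserving the
orderings the analysis is meant to detect.

Clone sharing is generated through a patient-level clone pool of 600
CDR3-like clonotypes (valid TRBV/TRBJ names, so AIRR tooling parses the
output). The pool is split into 8 bands; each clone has a position on
the unit circle, and a sample includes the clones of band $b$ within an
arc of width $w$ centred at the sample's band-$b$ centre, topping up
with fresh clones to its class richness. With independent uniform
centres the expected same-class intersection is
$\text{pool} \times w^2$ — identical to independent pool mixing —
while averaging over bands keeps pair-to-pair variance low. Because
depth truncation (clones drawing zero reads under the Zipf multinomial)
shrinks observed sharing below the drawn sharing, the width $w$ for a
target Jaccard is calibrated empirically: mean observed Jaccard is
simulated over a grid of widths, smoothed by isotonic regression, and
inverted by interpolation.

The coupling parameter $\gamma\in[0,1]$ ties modalities together. Each
tumour sample has a latent position $u_i$; its TCR band centres are
$(u_i + (1-\gamma)\,\eta_{ib}) \bmod 1$ and its neoantigen position is
$(u_i + (1-\gamma)\,\eta'_i) \bmod 1$, with independent uniform noise
$\eta$. Shared and private variants pick their carriers as the samples
nearest the variant's random position, and the mutation tree realizes
the configured trunk/shared/private counts exactly by construction. At
$\gamma=1$ both modalities see the same latent geometry and their
dendrograms correlate; at $\gamma=0$ they are independent; marginal
sharing levels are unchanged by $\gamma$ because wrapped uniform noise
keeps every centre marginally uniform.

Expression is log-normal TPM with a class-specific location shift
(+1 on the log scale, metastasis) for a modulated gene subset
defaulting to the immunomodulator panel; segments live on a synthetic
genome of 22 chromosomes of 100 Mb with class-specific aberration
probabilities (0.02/0.25/0.4). T-cell fractions are Beta draws around
class means 0.30/0.25/0.15/0.60.

What the generator does *not* emulate: biophysically realistic VDJ
recombination or CDR3 sequence statistics, read-level sequencing error,
clone-size dynamics over time, covariance between infiltration and
expression, or inter-patient batch structure. Passing tests therefore
demonstrate that the statistics recover the structure they are defined
on — orderings, sharing levels, coupling — not that they are robust to
artefacts these simplifications exclude.

## Numerical choices and determinism

All stochastic steps (rarefaction, sampled permutations, every
generator stage) flow from one master seed through named sub-streams
(`derive_seed`), so toggling a stage never perturbs another's draws and
identical configuration plus seed reproduces outputs byte for byte —
including written cohort bundles and the pipeline's `summary.json`.
Zero-variance z-scores map to 0; empty-repertoire metrics and
empty-group tests are errors, not `NaN`s; exact permutation ties use a
$10^{-12}$ tolerance; infiltration rows are validated rather than
silently rescaled.

The test suite's problem sizes — 20-patient cohorts for target
recovery and direction-of-effect checks, 30-patient cohorts for the
coupling contrast, 200-replicate null simulations with 20 values per
group (a size at which the tie-corrected normal approximation is well
calibrated), repertoires of a few hundred clones at 3,000–4,000 reads —
were chosen so each property is detectable with comfortable margins
while a full run stays within a couple of minutes.

## Known limitations

The pooled pair-level rank-sum tests inherit the dependence caveat
above. Cophenetic correlation compares whole ultrametric structures;
with the minimum three leaves its permutation null has only six
states, so exact p-values are coarse for small patients. The CIS
denominator convention (covered length) makes scores comparable within
a cohort processed uniformly but not across platforms with different
coverage. The bundled immunomodulator panel is a reconstruction, and
analyses depending on exact panel membership should supply their own
list.
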