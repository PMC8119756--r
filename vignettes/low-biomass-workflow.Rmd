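---
title: "Decontamination and community analysis of low-biomass 16S studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decontamination and community analysis of low-biomass 16S studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lowbiom)
library(dplyr)
```

## The problem

In low-biomass specimens — amniotic fluid, meconium, placental tissue,
dust, biopsies — the amount of genuine microbial DNA is comparable to the
DNA introduced by sampling instruments, extraction kits and reagents.
Amplicon sequencing amplifies whatever is present, so a naive analysis of
such samples describes the contaminants at least as much as the biology.
The defensible designs therefore carry *field controls*: empty sampling
instruments exposed to the sampling environment and processed identically
to the specimens. Whatever is shared between specimens and these controls
is, to first order, contamination.

`lowbiom` implements the computational side of such a design end to end:
a field-control-based contaminant filter for amplicon sequence variant
(ASV) count tables, absolute 16S qPCR quantification with a
specimen-versus-control comparison, the community statistics used to
contrast two paired specimen types, and a synthetic-study generator with
ground-truth contaminant labels so that every stage can be validated
without access to sequencing data.

## The contaminant filter

For one sample type at a time (types are never mixed: each type has its
own specimens and its own field controls), and for every feature, the
filter computes four quantities on the *input* table:

* prevalence in specimens and in controls: the fraction of that group's
  samples in which the feature is detected (count ≥ `presence_threshold`,
  default 1 read);
* mean relative abundance in specimens and in controls: the feature's
  count divided by the sample's read depth, averaged over **all** samples
  of the group, zeros included.

A feature is removed when **both** criteria hold:

$$\mathrm{prev}_\mathrm{spec} \le 2 \times \mathrm{prev}_\mathrm{ctrl}
\quad\text{and}\quad
\overline{\mathrm{ra}}_\mathrm{spec} \le 10 \times \overline{\mathrm{ra}}_\mathrm{ctrl}.$$

The two ratios are parameters (`decontam_params()`), with 2 and 10 as
defaults. Three consequences worth spelling out:

* **Zero-control guarantee.** A feature absent from every control has
  prevalence 0 there; any presence in specimens violates
  $\mathrm{prev}_\mathrm{spec} \le 0$, so the feature is always retained.
  Genuine signal that never leaks into controls cannot be lost.
* **Single-pass semantics.** Both statistics are computed once, on the
  input table. Removal of one feature never changes another feature's
  statistics (relative abundances are computed against the original
  depths).
* **Monotonicity.** Raising either ratio can only grow the removal set.

After feature removal, any specimen whose remaining read depth is
*strictly* below `min_sample_reads` (default 500) is dropped; a specimen
landing on exactly 500 reads survives. The report object retains the full
audit trail: per-feature statistics and criteria, per-sample read counts
before and after, the retained tables both before and after the dropout
(the literature is not always explicit about whether composition figures
are drawn before or after sample exclusion, so both conventions are
reproducible).

Some choices here are interpretations, made once and documented:
the mean relative abundance averages over all samples of a group
*including* those where the feature is absent — the plain reading of
"mean relative abundance in a group", and the only one defined for every
feature; both sides of the abundance criterion use *relative* abundance
(comparing a fraction against a raw count would be dimensionally
inconsistent); detection for prevalence is ≥ 1 read by default, with the
threshold exposed as a parameter because published descriptions of such
filters rarely state one. An `"or"` removal logic is available for
sensitivity analysis, but the default requires both criteria, which is
the conservative reading of a conjunctive filter description.

## Absolute qPCR quantification

`fit_standard_curve()` regresses Cq on $\log_{10}$(input copies) over a
dilution series (at least three points) and reports the amplification
efficiency $10^{-1/\mathrm{slope}} - 1$; a slope of $-3.3219$ cycles per
decade corresponds to perfect doubling (efficiency 1.0).
`cq_to_copies()` inverts the curve,
$\mathrm{copies} = s \cdot 10^{(\mathrm{Cq} - b)/m}$, where the unit
scale $s$ converts reaction copies to the reporting unit (per sampling
swab, per 100 µl of fluid). `quantify_qpcr()` fits one curve per run —
standards are expected in every run, and no cross-run pooling is done —
and averages technical replicates on the copy scale by default (mean of
Cq first is available as an option; the two differ by Jensen's
inequality). Non-detected reactions are excluded by default, or mapped to
zero copies under an explicit policy flag.

Specimen and control copy numbers are compared with a two-tailed
Mann–Whitney U test written for exactness at the group sizes these
studies have (tens of samples). For $n_1 + n_2 \le 20$ without
cross-group ties, the p-value is computed by full enumeration of all
$\binom{n_1+n_2}{n_1}$ group assignments, with the two-tailed tail
defined by distance of U from its null mean $n_1 n_2/2$ (for tie-free
data this equals the usual doubled one-sided tail, since the null
distribution of U is symmetric). Larger or tied inputs use the normal
approximation with tie and continuity corrections. Because the exact
statistic is discrete, the attainable test level sits just below the
nominal α: at $n_1=n_2=10$ the largest attainable two-sided level not
exceeding 0.05 is 0.0433, which is what a null simulation of the exact
test converges to.

## Community statistics

All community-level methods operate on the decontaminated tables.

* **Rank aggregation** (`aggregate_by_rank()`) sums features sharing a
  classified lineage prefix down to the requested rank. Features
  unclassified at that rank are pooled under their deepest classified
  parent as `"unclassified <parent>"` rather than dropped, so per-sample
  depth is conserved exactly and entropy can only decrease under
  aggregation. Pooling under the parent (rather than discarding or
  keeping every unclassified feature separate) is a documented choice;
  genus-level profiles in this field routinely show such pooled groups.
* **Shannon diversity** uses the natural logarithm, computed on
  proportions, without rarefaction.
* **Bray–Curtis** is computed on per-sample proportions by default, so
  unequal sequencing depths do not masquerade as composition differences;
  a raw-count mode exists behind a flag.
* **PCoA** is classical metric scaling: double-centre the squared
  distance matrix, eigendecompose, keep positive-eigenvalue axes, scale
  eigenvectors by the square root of their eigenvalue. No
  negative-eigenvalue correction is applied; the magnitude of discarded
  negative eigenvalues is reported so the user can judge the embedding.
* **PERMANOVA** is the one-way pseudo-F test on the distance matrix with
  unrestricted label permutations and
  $p = (\#\{F^* \ge F\} + 1)/(B + 1)$; a full-enumeration mode exists for
  two groups. The observed partition can be duplicated by a random
  permutation (the label swap always reproduces it in a two-group
  design), which is why the minimal attainable p is reached only when
  the number of distinct partitions is large relative to $B$.
* **Dispersion homogeneity** (`permdisp()`) embeds samples by PCoA,
  computes each sample's distance to its group centroid in the
  positive-eigenvalue space, and tests equality of mean dispersion with
  a one-way F statistic whose p-value comes from permuting the
  dispersions. The reference implementation's bookkeeping of
  negative-eigenvalue (imaginary) axes is deliberately not reproduced;
  on Euclidean-embeddable distance matrices the two agree exactly, and
  the test suite checks this. Groups of fewer than two samples are
  rejected (their dispersion is undefined).
* **Paired correlations** (`paired_spearman()`) compute, per pair of
  samples (e.g. one meconium and one amniotic-fluid sample from the same
  cow–calf couple), the Spearman rank correlation between absolute count
  vectors over a selected feature set, Bonferroni-corrected across pairs.
  The selection (`select_shared_features()`) keeps features whose total
  count across all samples of both tables is strictly greater than a
  threshold (default 100). That phrase — "present more than 100 times in
  all samples" — is genuinely ambiguous between a grand total and a
  per-sample minimum; the grand total is the default and a per-sample
  mode is provided, rather than guessing a single intent. Pairs with a
  constant count vector have no defined rank correlation; they are
  flagged and excluded from the average ρ.

All permutation tests take an explicit seed and record it in their
result, so every reported p-value is reproducible.

## The synthetic-study generator

`simulation_config()` + `simulate_study()` generate a complete paired
two-type study with ground truth. The generative model is deliberately
the simplest one that reproduces what makes low-biomass filtering
nontrivial:

* **Contaminant taxa** (reagent/environmental DNA) draw per-sample
  absolute loads from a shared lognormal in specimens *and* field
  controls — same expected load in both groups, which is precisely the
  regime the 2×/10× thresholds presuppose (ratios centred near 1).
* **Signal taxa** occur only in specimens, each present independently
  with probability 0.3 and a heavy-tailed lognormal load. Each sample
  type has its own signal pool; by default the pools share half their
  taxa, so the two types are distinct (PERMANOVA has something to
  detect) while shared abundant features exist for the paired-correlation
  analysis. A `signal_leak` parameter (default 0) lets signal
  contaminate controls, for probing filter specificity.
* **Counts** are Dirichlet-multinomial draws from the normalised load
  vector, with overdispersion 0.02, at lognormal depths.

Default sizes and rates are the study conditions the package emulates:
23 specimen pairs; 11 meconium and 8 amniotic-fluid field controls;
depth distributions moment-matched to per-group raw read-count means and
SDs of roughly 92,000 (36,000) for meconium specimens, 128,000 (22,000)
for amniotic fluid, and 127,000–136,000 for controls. The qPCR model is
`copies = scale × total signal load × noise + background`, with
backgrounds moment-matched to control means (SDs) of 980 (850) and
1,610 (790) copies and the scale derived analytically in the constructor
so that specimen means are 4,350 (meconium, per swab) and 3,170
(amniotic fluid, per 100 µl). These four printed means are calibration
anchors, not fitted parameters. Signal makes up about 7% of a specimen's
expected composition, matching the fraction of reads that survives
decontamination in the emulated design, and with ~100k-read depths it
leaves typical post-filter specimens above the 500-read dropout while
pushing a realistic minority below it.

What the generator does **not** emulate: taxon-taxon correlations,
batch structure in contamination, chimeras and denoising artefacts,
PCR-cycle bias, per-run depth drift. Passing tests on synthetic data
therefore demonstrate the correctness of the computations and the
filter's behaviour in its intended regime — not that any particular real
dataset satisfies the model.

```{r simulate}
sim <- simulate_study(simulation_config(seed = 1))
sim$table[1:3, 1:4]

report <- apply_decontamination(sim$table, sim$metadata)
report
```

Filter accuracy is measurable because the truth is known:

```{r recovery}
stats <- dplyr::left_join(tidy(report), sim$ground_truth, by = "feature_id")
stats |>
  dplyr::group_by(sample_type) |>
  dplyr::summarise(
    sensitivity = mean(removed[truth == "contaminant"]),
    specificity = mean(!removed[truth == "signal" & prev_specimen > 0]))
```

The specificity of 1 is exact, not an estimate: with `signal_leak = 0`
signal taxa never reach the controls, and the zero-control guarantee is
a theorem about the filter, not a tendency.

## Numerical choices and degenerate inputs

* Zero-depth samples: an error in `relative_abundance()` (naming the
  sample); a zero-depth *group member* contributes relative abundance 0
  to the filter's mean.
* All-zero distance matrices: PERMANOVA and permdisp return F = 0,
  p = 1 rather than erroring.
* Eigenvalues below $10^{-9} \times$ the largest magnitude are treated
  as zero in PCoA; Euclidean inputs are reconstructed to well below
  $10^{-8}$.
* Exact enumerations (Mann–Whitney ≤ 20 observations, Spearman ≤ 8
  features, PERMANOVA two-group exact mode) include the observed
  arrangement in the tail, so exact p-values are never 0.
* The Mann–Whitney enumeration caches the permutation distribution of
  the rank sum keyed by the pooled midrank multiset, making repeated
  tie-free tests at the same group sizes cheap.
* Monte Carlo p-values use the add-one estimator
  $(\#\{T^* \ge T\}+1)/(B+1)$, bounded below by $1/(B+1)$.

## Problem sizes used in validation

The test suite validates the filter against a brute-force evaluation of
the two inequalities on 1,000 random tables of up to 30 features × 10
samples; the exact Mann–Whitney level on 1,000 null draws at
$n_1=n_2=10$; PERMANOVA's level on 500 null simulations at 999
permutations and its exact enumeration on 3+3 designs; and the qPCR
calibration on 200 replicate studies at the default design size. These
sizes give binomial/Monte-Carlo error small enough to detect meaningful
miscalibration while each suite section runs in well under a minute.

## Limitations

The filter is a hard threshold rule, not a probabilistic model: it has
no notion of uncertainty in prevalence estimated from 8–11 controls, and
a contaminant that happens to be absent from the few controls sequenced
is invisible to it (the generator shows this as sensitivity slightly
below 1 at default settings). Frequency- or concentration-based
contaminant models, batch-aware filtering, differential-abundance
testing and phylogenetic (UniFrac-type) distances are out of scope.
PERMANOVA here is one-way with unrestricted permutations — the design it
serves has a single grouping factor; nested or stratified designs need
the full machinery of a dedicated package.
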