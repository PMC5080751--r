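---
title: "Mapping polygenic sex determination in small families: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping polygenic sex determination in small families: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polysd)
```

## The genetic model

`polysd` analyses crosses from species where sex is set by the epistatic
interaction of dominant alleles at one or more loci. Each locus may carry a
male-determining **Y** or a female-determining **W**; phenotypic sex follows
a fixed dominance hierarchy implemented in `assign_sex()`:

* any W present → female (W is epistatic over Y, as in platyfish-style
  XYW systems);
* otherwise any Y present → male;
* otherwise female (the XX-female default).

Under this rule a heterozygous XY sire alone produces 1:1 sons:daughters; a
cross segregating a sire's Y at one locus *and* a dam's W at another
produces the classic 1:3 male:female ratio, because only the Y-no-W quarter
of offspring develops male. `expected_male_fraction()` computes this
expectation analytically for any configuration by enumerating Mendelian
transmissions.

Phenotypic sex matches genotypic sex with probability equal to the
**penetrance** (default 0.88, the mean observed across mapped families in
this system). Sex reversal is modelled as an i.i.d. phenotype flip with
probability 1 − penetrance, independent of genotype — the simplest
mechanism consistent with the candidate explanations (phenotyping error,
marker–locus recombination, true reversal); it makes no attempt to model
environment- or genotype-dependent reversal.

A modelling consequence worth stating explicitly: under the default-female
rule, a family segregating *only* a dam's W would be all-female and
unmappable. Real ZW families sit on a male-determining background (ZZ males).
The simulator therefore expresses a ZW family as a dam heterozygous for W
over a sire *homozygous* for a background Y (`sd_config_zw()`); the
background does not segregate, so it is invisible to transmission tests,
and W-free offspring develop male, giving the 1:1 ratio a segregating ZW
locus implies. Families driven by an unidentified locus (`sd_config_none()`)
carry a segregating Y on a linkage group outside the tested panel.

## Test statistics

**Fisher's exact test** (`fisher_exact_2x2()`) is computed by direct
hypergeometric enumeration with the minimum-likelihood two-sided rule: with
margins fixed, the p-value sums the probabilities of all tables whose point
probability does not exceed the observed one, within a relative tolerance
of 10⁻⁷. This is the convention of the common genetics tools, and the test
suite verifies exhaustive agreement with `stats::fisher.test()` for every
2×2 table with total ≤ 30.

Two association modes are provided. The *allelic* mode counts the two
alleles of each called offspring by sex, the standard case/control model
for biallelic markers. The *transmission* mode is family-aware: for each
offspring whose transmitted allele from the tested parent can be deduced
(parent heterozygous; the deduction combines offspring and other-parent
genotypes), it tabulates transmitted allele × sex. Testing the sire probes
Y-type associations and testing the dam W-type associations. Markers where
both parents are heterozygous for the *same* two alleles are excluded: in
that configuration only double-homozygous offspring are deducible and both
parents necessarily transmitted the same allele there, so parental origins
are confounded and one parent's signal would leak into the other's table —
the standard pseudo-testcross exclusion.

The **dominant screen** (`dominant_screen()`) retains significant markers
(p < 0.01) whose pooled minor allele sits at intermediate frequency in one
sex and is absent (≤ `absent_eps`) in the other. The intermediate window
defaults to [0.15, 0.60] around the 0.25 allelic frequency expected for a
heterozygous dominant sex allele among the carrier sex's alleles; the
bounds are configurable because no canonical values exist.

**Sliding windows** (`sliding_window()`) summarise ordered scans in
windows of 10 markers advanced by 1. The default score is the mean of
−log10 p; the fraction of markers with p < 0.01 (`frac_sig`, the density of
associated markers) is available by flag since either summary is defensible
and the windowed mean is the default. Window scores are bounded by the
window's maximum single-marker −log10 p.

## Family classification and penetrance

`classify_family()` evaluates candidate locus regions with the transmission
test, taking the minimum p per parent over region markers (ties broken by
more informative offspring, then marker id) at α = 0.05, uncorrected —
mirroring the per-marker reporting convention of family-based mapping
tables, where replication across families rather than multiplicity
correction carries the inferential weight. A region is called `XY` when the
sire's best p < α *and* his linked allele is carried predominantly by sons;
`ZW` symmetrically for the dam and daughters. Both significant → both calls
are emitted (real crosses do produce coexisting signals; a per-family table
cannot distinguish an XYW locus from occasional sex reversal, so no merged
"XYW" call is made at family level — `shared_haplotype_check()` addresses
it across families). The `tests` argument restricts which parent is probed
per region, reproducing the typical mapping-table design (sire probed at
every candidate locus, dam only where a W is plausible).

**Penetrance** is the proportion of informative offspring matching the
majority allele→sex mapping at the call's best marker; the mapping's
direction is anchored to the majority because nothing else in a single
family defines it. Penetrance is 1 exactly when the mismatch list is empty,
and `flag_sex_reversal()` returns the same offspring annotated with both
sexes. Mismatches conflate true sex reversal with marker–locus
recombination; they coincide with the simulator's truth only at a marker
with zero recombination distance to the locus and full informativeness,
which is how the truth-recovery test conditions.

## Sex-ratio statistics

`chisq_1to1()` is the Pearson goodness-of-fit χ² with df = 1 and expected
counts (m+f)/2, *without* Yates continuity correction — with the correction
the published pooled statistic of the reference families (63/115 → 15.2)
would not be reproduced (it gives ≈ 14.6), so the uncorrected statistic is
the verified convention. `welch_t()` wraps the unequal-variances *t*-test
with Welch–Satterthwaite degrees of freedom. The reference family table is
bundled as `aburtoni_families()` and `ratio_summary()` reproduces the
published pooled tests (χ² = 15.2 and 5.2; Welch p = 0.0053). Whether the
published pooling was count-pooled or family-weighted is not documented;
count pooling reproduces the printed statistics and is what
`ratio_summary()` implements.

## Two-point linkage and fusion detection

`count_recombinants()` applies the pseudo-testcross restriction: only
offspring with deducible transmission from the tested parent at both
markers count, and since parental phase is unknown the recombinant count is
the minimum mismatch count over the two phases. `two_point_lod()` evaluates
rf = min(R, N−R)/N and LOD = log10 L(rf)/L(0.5) in closed form (the rf → 0
limit is N·log10 2); the suite verifies agreement with numeric likelihood
maximisation to 10⁻⁶ for all N ≤ 50.

`lg_pair_linkage()` sums per-family, per-parent (N, R) over families before
computing the LOD — LODs are additive under a shared rf, and small families
are individually underpowered — then takes the maximum over cross-LG marker
pairs. `detect_fusions()` declares fusions above LOD 4 (the conventional
grouping threshold; configurable) and merges transitively linked pairs into
multi-LG groups, joining the LG numbers in the group name. Full multipoint
map construction is deliberately out of scope: the pairwise screen is
sufficient for fusion detection.

## Scaffold anchoring

`filter_alignments()` keeps uniquely mapping windows with fewer than 5
suboptimal hits and identity ≥ 0.90 (the boundary is inclusive: only
windows *below* 90 % are removed). Because aligners encode suboptimal-hit
counts differently, the PAF adapter takes `s2:i` as the count proxy,
defaults to 0 when absent, derives uniqueness from mapping quality > 0, and
leaves all three columns overridable. `assign_scaffold_lg()` places a
scaffold on the LG receiving > 60 % of ≥ 3 mapped windows — the filters are
published conventions but the assignment rule is not, so the majority-vote
threshold is explicit and configurable; unplaced scaffolds whose windows
split between two LGs are flagged as fusion-junction candidates.
`order_orient()` orders scaffolds by median window target position (ties:
minimum position, then id), orients by the sign of the Spearman correlation
between window index and target position (zero correlation → "+" with an
ambiguity flag), and lays pseudo-coordinates with a fixed 1-kb gap —
downstream uses are rank-based, so the gap is cosmetic. `liftover()` and
its inverse map marker coordinates on and off the pseudo-chromosomes.

## The simulator and what it does (not) emulate

`simulate_family()` builds founder parents (SNP founder allele frequencies
from Beta(2, 2); SSR founders drawn equifrequently from 4–8 labels, which
naturally yields a realistic share of uninformative markers), places the
model's sex alleles on carrier haplotypes, and generates offspring by
independent meioses: crossover counts Poisson in the chromosome's genetic
length, positions uniform — the Haldane, no-interference model, chosen for
its closed-form recombination fraction. Fused chromosomes recombine as one
unit, so markers of both constituent LGs co-segregate, which is exactly the
signal the fusion detector consumes. Genetic lengths default to 0.5–1
Morgan per chromosome and 20–40 Mb physical sizes, typical of cichlid
genomes. `simulate_depth_noise()` overlays Poisson per-call read depth
(zero depth → missing call), feeding the depth-based QC rule
(`qc_filter()`: homozygotes below depth 10 masked, heterozygotes never
masked — the stated rule covers only homozygotes — then markers called in
fewer than the required number of offspring dropped).
`simulate_alignments()` tiles scaffolds into fixed 5-kb windows whose
targets follow the true placement except a configurable misassigned
fraction.

Features of real data *not* emulated: linked-read or restriction-site
sequence structure, allele-calling error within called genotypes, crossover
interference, segregation distortion, genotype-dependent viability, and
environment-dependent sex reversal. Passing recovery tests therefore shows
the statistical machinery is correct under clean Mendelian assumptions, not
that real datasets will be as well-behaved.

## Validation design and problem sizes

The package validates itself against its own simulator with fixed seeds:

* **Classification benchmark** (`classification_benchmark()`): 200 families,
  16–36 offspring, penetrance 0.9, equal thirds XY / ZW / untyped-locus,
  classified with two SSRs clustered at each candidate locus and the
  three-test mapping-table design. Scoring: family-label accuracy ≥ 0.90,
  and zero XY↔ZW confusions, a confusion meaning the classifier emitted the
  opposite system *instead of* the true one at a true sex-locus region.
  With per-family exact tests at α = 0.05 uncorrected, rare chance
  inversions (expected ≈ 0.1–0.3 per 200 families) are irreducible, so the
  zero-confusion property is a per-seed statement, not an almost-sure
  guarantee; measured across eight seeds it held in seven.
* **Penetrance recovery** (`penetrance_benchmark()`): 50 XY families of 20
  offspring at true penetrance 0.88; the mean estimate over recovered calls
  must fall within ±0.04. Conditioning on detection biases the estimate
  slightly upward (≈ +0.01), well inside the band.
* **Fusion detection** (`fusion_benchmark()`): 50 replicate cohorts of
  2 × 24 offspring on a genome with one 50-cM fused chromosome and an
  unlinked control LG, four SSRs per LG; sensitivity 1 and false-positive
  rate 0 at LOD > 4.
* **Anchoring recovery** (`anchor_benchmark()`): 50 random tilings of a
  15-Mb, 3-LG genome into oriented scaffolds; noise-free recovery of LG,
  order and orientation must be 100 %, and ≥ 95 % under 5 % window
  misassignment.

Simulation sizes in the routine test suite are scaled to these figures;
larger one-off sweeps (e.g. type-I error at many thousands of markers)
reproduce the same calibration. The exact test is conservative under the
null (observed ≈ 0.6 % below a 1 % threshold), as expected for a discrete
exact test.

## Numerical and degenerate-input conventions

* Coordinates are 0-based half-open internally; VCF input is converted.
* The missing genotype token is `./.` in both TSV and VCF; depth 0 means
  "unknown" and exempts a call from depth masking (SSR genotypes carry no
  depth).
* All-zero association tables give p = 1 with a warning; monomorphic
  markers are padded with a phantom zero row so the test degrades to p = 1.
* `two_point_lod(N, 0)` uses the analytic rf → 0 limit.
* Ties are broken deterministically everywhere (documented per function) so
  that fixed-seed runs are bit-reproducible.
* One global seed drives each simulation entry point; internal sub-draws
  consume a single RNG stream, and scenario runs derive per-family
  sub-seeds.

## Known limitations

Per-family classification cannot separate a true LG13 Y allele from
occasional ZW→male sex reversal; the package follows the data's resolution,
reporting per-family calls plus cross-family haplotype consistency, and
leaves the interpretation open. Numerical reproduction of per-family
published p-values would require the original genotype files, which are not
bundled; the package instead validates the machinery property-wise and
reproduces the published quantities that are derivable from the bundled
family table. Partial-chromosome rearrangements (translocations) are not
modelled; a fused-vs-unfused dichotomy is assumed.
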