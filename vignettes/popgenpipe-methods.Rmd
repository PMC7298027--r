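---
title: "Methods: diversity, differentiation, selection scans and local ancestry in popgenpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, differentiation, selection scans and local ancestry in popgenpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

popgenpipe analyses dense diploid SNP genotypes from structured, admixed
animal populations. This vignette is the package's own account of the
statistics it implements, the choices behind their defaults, what the
synthetic-data generator does and does not emulate, and the limitations a
user should keep in mind.

## Data model and conventions

Genotypes are alternate-allele counts (0/1/2, `NA` missing) in a
samples-by-variants matrix; phased haplotypes are complete 0/1 matrices
with exactly two rows per sample. Coordinates are 1-based inclusive in
memory, in MAP files and in VCF; BED output is 0-based half-open — the two
standard dialects, converted only at the file boundary. The missing
genotype is `NA`, never a numeric code, and every statistic documents its
missing-data handling. In PED input, the first allele observed at a
variant becomes the reference-coded allele and calls count copies of the
other; two datasets are merged on (chromosome, position) with swapped
allele pairs recoded `2 - x`, and strand-ambiguous (A/T, C/G) variants are
dropped outright, since without strand information a silent mis-merge
corrupts every downstream frequency-based statistic.

## Quality control

Variant filtering applies, in a fixed order, a missingness ceiling
(default 0.2, i.e. an 80% genotyping-rate floor), a minor-allele-frequency
floor (default 0.01), and a Hardy–Weinberg equilibrium test at alpha
0.005 with Bonferroni correction over the number of variants tested. The
order matters only for the bookkeeping — a variant failing several
criteria is counted once, at the first stage — and the filter report
asserts `removed + retained = input` at every stage. HWE uses the
one-degree-of-freedom chi-square approximation rather than the exact
test: at array scale the approximation is what the filter needs, and it
keeps the oracle (direct expected-count evaluation) cheaply enumerable —
the suite checks every count triple with total at most 30. HWE can be
assessed on a designated subgroup (e.g. samples of mixed origin, where
population structure inflates homozygosity least) via
`hwe_test_samples`; the choice of subgroup is the user's, since no
principled default exists.

LD pruning follows the PLINK `--indep-pairwise` scheme (windows of 50
SNPs, step 5, r² ceiling 0.5): within each window, while any retained pair
exceeds the ceiling, the **later-positioned** member of the currently
worst pair is removed. The tie-break is a deliberate determinism choice —
any rule works statistically, but a fixed rule makes pruned sets
reproducible across runs and platforms.

## Diversity and relatedness

Per-individual statistics follow the PLINK `--het`/`--ibc` formulations:
observed heterozygosity over non-missing calls, expected homozygosity
`E(hom) = sum_j [1 - 2 p_j (1 - p_j) n_j/(n_j - 1)]`, the moment
inbreeding coefficient `F = (O - E)/(L - E)`, and Fhat3 as the mean
standardised genotype term. Allele frequencies for Fhat3 and for
identity-by-descent are computed on the full input cohort by default and
are parameterisable (`freq_samples`) — with structured cohorts the
reference panel matters, and the package records rather than hides that
choice. Cohort-level inbreeding outliers use a recomputed threshold of
mean + 2 SD of Fhat3, not a hard-coded constant, so the rule transfers
across cohorts.

PI_HAT uses asymptotic method-of-moments expectations of
identity-by-state given identity-by-descent; estimated state
probabilities are clamped to [0, 1] and renormalised. On simulated data
the estimator places duplicates at 1, parent–offspring pairs at 0.5 and
unrelated pairs near 0 (the package's tests assert all three). The greedy
relatedness filter repeatedly drops the sample with the most conflicts at
the PI_HAT ceiling (default 0.25), breaking ties toward the later sample.
Greedy removal can exceed the minimum removal count; the suite compares
against an exhaustive search on small instances and asserts the retained
set is always conflict-free.

## Differentiation

Pairwise differentiation is the multi-locus Weir–Cockerham (1984)
estimator, with missing-aware per-variant sample sizes, summed as ratio
of sums over polymorphic variants. AMOVA uses the Excoffier (1992)
allele-level decomposition extended to four levels (groups, populations
within groups, individuals within populations, within individuals),
computed as nested sums of squares of per-variant allele indicators with
the standard unbalanced-design coefficient equations. The two are
different estimators of the same quantity; for biallelic SNPs the
pairwise values are near-identical, and the package exposes both because
the pairwise estimator is the field's default for two-population
contrasts while the AMOVA gives the hierarchical picture. AMOVA requires
complete variants (those with missing calls are excluded with a message):
the multi-locus coefficient equations need one design matrix, and the
intended upstream filter for this analysis is complete-genotyping anyway.

Permutation significance uses the +1-corrected estimator
`p = (1 + exceedances)/(1 + n_perm)`, which can never report exactly
zero. The three AMOVA levels are tested with the matching permutation
schemes: alleles among individuals within populations (Phi_IS),
individuals among populations within groups (Phi_SC), and whole
populations among groups (Phi_CT). The default of 20,000 permutations is
the convention for publication-grade significance; tests and the demo
pipeline use a few hundred, which is ample for the effect sizes they
check.

## PCA

Genotypes are standardised per variant (zero mean, unit variance;
monomorphic variants excluded) and decomposed by SVD — numerically the
same computation as `prcomp(scale. = TRUE)` with samples as rows, which
the suite verifies directly. Because the SVD sign is arbitrary, each
component is flipped so its largest-magnitude loading is positive;
without a fixed convention, any threshold rule expressed in PC
coordinates (e.g. selecting a cluster with `PC1 < -40 & PC2 > 20`) is
irreproducible. Such thresholds must in any case be re-derived from the
cluster geometry of each new analysis, not copied across datasets.
Missing calls are an error by default; mean imputation is available
behind an explicit flag because silently imputing changes the geometry.

## Selection scans

The H statistic at a focal SNP is the average over haplotype pairs of the
base-pair length of their shared homozygosity tract: boundaries at the
nearest mismatching SNP at-or-left and at-or-right of the focal position,
truncated at the terminal SNPs, and zero when the pair differs at the
focal SNP itself. This boundary convention is locked by an exhaustive
pairwise oracle in the test suite, since off-by-one choices here shift
every value.

H12 and Tajima's D are computed in non-overlapping windows of a fixed
number of SNPs (default 351), values reported at the window's centre SNP.
Fixed-SNP windows, rather than fixed-bp windows, keep the variance of
window statistics comparable across the genome on array data;
non-overlapping windows match a one-value-per-window output and avoid
autocorrelated peak calls. Before windowed scans, dense regions (>16 SNPs
per 0.1 Mb, bins anchored at position 1) are thinned to 13 evenly spaced
SNPs per bin, keeping each bin's first and last SNP — array density
varies severalfold, and without thinning, window spans (in bp) would vary
inversely. Tajima's D uses the 1989 variance normalisation; windows with
no segregating site emit no value.

For display and peak calling, each track is min–max scaled to [0, 1]
genome-wide per statistic per group, with Tajima's D negated first so
sweep-like signals appear as peaks in all three statistics. Genome-wide
(not per-chromosome) scaling gives one threshold per scan, which is what
a single 99th-percentile cut-off presumes. Peaks are maximal runs of
positions at or above the threshold; runs closer than 100 kb merge (an
artifact parameter — windowed tracks are evaluated at isolated points, so
some merge distance is needed; it is configurable); single-point runs are
widened by half the median inter-position spacing; and regions spanning
more than 5 Mb are discarded as unspecific. Known artifact regions (e.g.
pericentromeric LD anomalies) are handled by an optional exclusion BED,
not hard-coded coordinates. Peak sets from several statistics/groups are
intersected by interval coverage; the headline region is the interval
with the highest overlap count, ties broken toward the smallest interval.

## Local ancestry

The classifier is a window-independent naive-Bayes assignment, a
deliberately simple stand-in for conditional-random-field local-ancestry
tools, validated by truth-track recovery on simulated mosaics rather
than by reproducing any published biological claim. Reference panels are
summarised as per-group allele frequencies with one pseudo-allele of each
type added (so no log-likelihood is ever infinite). Per 50-SNP window,
each haplotype gets a log-likelihood per group, a softmax posterior under
a uniform prior, and a label only when the top posterior reaches 0.99;
otherwise the window is unassigned — the same hard assignment contract
used in posterior-thresholded ancestry painting. Consecutive same-label
windows merge into segments whose boundaries split between adjacent
windows at the midpoint of their edge SNPs, so segments tile the scanned
span exactly and base-pair fractions sum to 1.

The 50-SNP default window is set against the expected tract scale: at 9
generations since admixture and ~1 cM/Mb, tracts average roughly 5–6 Mb,
spanning many windows at array density, so per-window independence
costs little in localisation. The main caveat is that the likelihood
ignores linkage between SNPs within a window, overstating confidence
when reference panels are similar; the 0.99 threshold absorbs much of
this, and the negative-control check (a diverged reference group must
capture ≤2% of labelled bases) guards against systematic leakage.

## The synthetic-data generator

The generator produces exactly the statistical structure each analysis
assumes, by construction rather than by evolutionary simulation:

* **Structured populations**: Balding–Nichols per-population frequencies
  `Beta(p(1-F)/F, (1-p)(1-F)/F)` around global frequencies (default
  Uniform(0.05, 0.95)), with per-population F. Reference panels are drawn
  site-independently (no background LD).
* **Admixture mosaics**: breakpoints from a Poisson process at rate
  G × recombination rate (default 9 generations, 1 cM/Mb uniform), tract
  sources drawn from the admixture proportions, alleles copied verbatim
  from reference haplotypes, truth tracts recorded and guaranteed
  consistent with the emitted alleles.
* **Hard sweeps**: a donor haplotype overwrites each carrier within
  exponentially distributed one-sided tracts (default mean 500 kb) around
  the sweep locus — shared cores with decaying extent, which is the
  signature H, H12 and Tajima's D respond to.
* **Neutral calibration**: sites with derived-allele counts drawn
  ∝ 1/i, under which windowed Tajima's D has mean zero analytically
  (E[π] = E[θ_W] = 1/a₁ per site).
* **Ascertainment**: an MAF floor emulating array site selection.

What it does **not** emulate: background linkage disequilibrium outside
mosaics and sweeps, mutation/drift dynamics, genotyping error, phasing
error, or non-uniform recombination maps. Passing tests on this generator
therefore demonstrate that the estimators recover the parameters of the
structures they target — not that real-data confounders (LD-induced
false peaks, switch errors, platform batch effects) are handled. The
default end-to-end fixture uses four reference populations with
per-population F from 0.02 to 0.30 (pairwise differentiation spanning
roughly 0.02–0.23, the range typical of strongly structured breeds), one
admixed group at 30% donor and G = 9, and one mid-chromosome sweep at
carrier fraction 0.6.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen so each
statistical check has clear power while the whole suite stays in the
minutes range: F recovery uses 2 × 50 diploids × 5000 variants; neutral
calibration 1000 windows of 50 SNPs over 40 haplotypes; sweep recovery
five replicates of 60 haplotypes × 7020 SNPs over 6 Mb (20 windows of
351); ancestry recovery 10 admixed samples against three 40-haplotype
panels over 5000 SNPs / 50 Mb; AMOVA permutation tests use ~200
permutations. Tolerances follow the generating process: Monte-Carlo
checks use 3 standard errors; oracle comparisons are exact
(`tolerance 1e-12`); sweep localisation is asserted at 250 kb, the
resolution of a 351-SNP window at the fixture's density.

Degenerate inputs are defined, not left to chance: monomorphic sites give
HWE p = 1 and are excluded from Fhat3/PI_HAT; a monomorphic chromosome
gives H equal to the SNP span everywhere; windows with no segregating
sites emit no D value; constant tracks refuse to scale; an AMOVA design
with one population per group reports that component as zero with a flag;
permutation p-values are +1-corrected and never zero.

## Known limitations

* The pairwise differentiation estimator and the AMOVA decomposition are
  different estimators; their values agree closely on biallelic SNPs but
  are not identical by construction.
* PI_HAT omits finite-sample correction factors; with very small cohorts
  the IBS expectations are slightly biased (the relatedness *filter* is
  insensitive to this at its 0.25 ceiling).
* The ancestry classifier's independence assumption inflates posteriors
  when panels are close; it is a screening tool, not a substitute for
  CRF-based local ancestry inference.
* H-scan cost grows with haplotype pairs × SNPs; cohorts of hundreds of
  haplotypes at array density are fine, whole-genome-sequence densities
  are not its target.
* The pipeline's stage graph always recomputes (cheap at its scale);
  determinism, not caching, is what makes re-runs reproducible.
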