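---
title: "Models and methods for germplasm association mapping and allele mining"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for germplasm association mapping and allele mining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical models behind `alleleminer`, the
conventions it pins down where the field's software leaves choices implicit,
and what the synthetic-data generator does and does not emulate. Everything
here describes what the code computes; no empirical claim is made beyond
what the test suite and `scripts/acceptance.R` verify.

## The data model

The package targets panels of inbred (selfed) accessions genotyped at
multi-allelic marker loci. Because lines are homozygous, one allele code per
accession per locus suffices, and a line's genotypes can be treated as a
haplotype. Allele codes are *locus-local labels*: code 2 at one locus has no
relationship to code 2 at another. Cells listing two codes are rejected by
the readers — heterozygotes are outside the data dialect. Markers with more
than 10% missing calls are removed by `filter_markers()` (strict
inequality: exactly 10% survives).

Phenotypes are long-format records by accession, environment, replicate and
trait. `line_means()` averages replicates within environment and then, for
across-environment means, averages the per-environment means without
weighting; unbalanced accessions are tolerated with a warning and an
`n_env` column rather than being dropped. Whether a scan should consume
replicate means or plot means is a convention, not a estimable choice; the
package standardises on replicate-averaged per-environment line means.

## Diversity statistics

Gene diversity is the uncorrected expected heterozygosity
$H_e = 1 - \sum_i p_i^2$; the $n/(n-1)$ bias correction is deliberately
omitted because the headline use of $H_e$ here is descriptive, but the
alternative is a one-line change on the frequency vector. PIC uses the
Botstein 1980 form
$1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$, the convention of the
classical SSR summary-statistics tools; for biallelic loci it reduces to
$H_e - 2p^2q^2$, which the tests assert exactly. Frequencies are always
computed over typed lines only. "Rare" means frequency strictly below 0.05;
"unique" means carried by exactly one accession regardless of frequency.

## Population structure

The number of subpopulations is chosen with the Evanno statistic on
replicate log-probabilities LnP(D) of a model-based clustering run:
$\Delta k = |\bar L(k{+}1) - 2\bar L(k) + \bar L(k{-}1)| \,/\, \mathrm{sd}\,L(k)$,
defined for interior $k$ with at least two replicates. LnP(D) typically
increases monotonically in $k$; the curvature statistic still peaks at the
dominant level of structure. Ties (including the all-zero curvature of
perfectly linear likelihoods) resolve toward the smaller $k$ — parsimony —
with a warning. A zero replicate standard deviation is an error rather than
an infinite Δk.

`estimate_Q_em()` is a deliberately lightweight maximum-likelihood
admixture model for haploid-equivalent calls, maximising
$\sum_i \sum_l \log \sum_c q_{ic} f_{cl}(a_{il})$ by EM block updates with
a $10^{-6}$ frequency floor. It is a convenience surrogate for full
Bayesian MCMC clustering: it asserts a non-decreasing likelihood every
iteration, restarts from random points (best likelihood wins), and is
seeded. The canonical path for published Q matrices is `read_q_matrix()`.
Accessions are assigned to the subpopulation whose membership exceeds 0.5
(strictly); otherwise they are labelled admixed. For the mixed model the Q
matrix enters with $k-1$ columns (`structure_covariates()`) because rows
sum to one and would be collinear with the intercept. Structure runs
conventionally use a thinned marker set; `select_structure_markers()`
implements a first-past spacing rule, one marker per 20 cM by default.

## Kinship

`loiselle_kinship()` implements the Loiselle et al. (1995) estimator for
homozygous lines,
$$F_{ij} = \frac{\sum_l \sum_a (x_{ila}-p_{la})(x_{jla}-p_{la})}
                {\sum_l \sum_a p_{la}(1-p_{la})},$$
with loci dropped pairwise when either member is untyped, and negative
estimates truncated to zero — the usual preparation of a kinship matrix for
a mixed model. The small-sample correction term is off by default
(`bias_correction = TRUE` enables it). Truncation and pairwise-complete
loci mean the matrix is only approximately positive semidefinite: on
simulated panels of 50–150 loci the smallest eigenvalue is typically −1% to
−10% of the largest. The REML fitter therefore *bends* the spectrum —
eigenvalues down to `-psd_tol` (default 0.25) times the leading eigenvalue
are clamped to zero — and rejects anything more indefinite as a genuinely
invalid input. Kinship estimates from a hundred-odd loci carry sampling
noise of roughly $1/\sqrt{(k_e-1)L}$ for $L$ loci with $k_e$ effective
alleles; this, not true relatedness, bounds how concentrated near zero the
estimated kinship distribution can be.

## Linkage disequilibrium

For two multi-allelic loci the package reports the frequency-weighted
average of allelic $r^2$ values: each allele pair $(i, j)$ is collapsed to
a 2×2 table, $r^2_{ij} = (p_{ij}-p_i q_j)^2 / (p_i(1-p_i)q_j(1-q_j))$, and
the summary is $\sum_{ij} p_i q_j\, r^2_{ij}$. The weights are the product
of marginal frequencies (they sum to one); for biallelic pairs all four
collapses coincide and the statistic equals the plain squared correlation,
which the tests check algebraically. Alleles below frequency 0.05 at a
locus are masked to missing before the pair is formed, frequencies are then
recomputed on pairwise-complete lines, and pairs monomorphic after masking
are skipped. The masking is applied uniformly to every LD summary.
Significance is Fisher's exact test for biallelic pairs and a seeded
Monte-Carlo permutation of one locus otherwise (`n_perm`, default 200 — a
resolution floor of ~1/200 on permutation p-values, adequate for the 0.01
significance level used in the summaries).

Background LD is the nearest-rank (no interpolation) 99th percentile of
$r^2$ among unlinked pairs — loci on different chromosomes. Decay is
fitted by least squares as $r^2 = a + b\ln d$ on linked pairs significant
at $P \le 0.01$, and each threshold's crossing distance is
$d^* = \exp((t-a)/b)$, reported only when the slope is negative and the
crossing falls within $[\min d,\, 10\max d]$; outside that window the
crossing is flagged not reached rather than extrapolated.

## Phenotype analysis

`anova_components()` computes the balanced two-factor ANOVA (genotype,
environment, replicate-within-environment, G×E) from cell means — on
balanced data the sums of squares partition the total exactly, which is a
test invariant — and solves the expected-mean-squares equations:
$\hat\sigma^2_e = MS_{err}$,
$\hat\sigma^2_{GE} = (MS_{GE}-MS_{err})/r$,
$\hat\sigma^2_G = (MS_G-MS_{GE})/(er)$, with block and environment
components analogous. Negative moment estimates are truncated to zero and
flagged. G is tested against G×E and G×E against the residual. Broad-sense
heritability uses the entry-mean denominator
$h_B^2 = \sigma^2_G/(\sigma^2_G + \sigma^2_{GE}/E + \sigma^2_e/(Er))$ —
the package pins this convention explicitly since "estimated with the
variance components" admits several. Trait correlations are
pairwise-complete Pearson on across-environment line means with t-test
stars; on balanced data the order of averaging cannot matter, and the
unbalanced behavior is the package's convention.

## The Q+K mixed-model scan

Per trait and environment the null model
$y = \mu + Qv + u + e$, $\mathrm{Var}(u) = \sigma^2_g K$,
$\mathrm{Var}(e) = \sigma^2_e I$ is fitted by REML, profiling the single
ratio $\lambda = \sigma^2_g/\sigma^2_e$ over the eigendecomposition of $K$
(EMMA-style): a 41-point grid on $\log\lambda \in [-6, 6]\cdot\ln 10$
followed by golden-section refinement, with the $\sigma^2_g = 0$ boundary
as an explicit candidate. When the profile is flat — e.g. $K = I$, where
only the total variance is identified — the boundary is chosen by
convention; generalized least squares is unaffected because the covariance
is then proportional to the identity, and the scan collapses to ordinary
one-way ANOVA (asserted against an independent `lm()` oracle to 1e-8).

Markers are tested P3D-style: the null variance components are reused for
every marker (exact per-marker REML is a deliberate non-goal at this panel
size; P3D is the standard approximation and the one the acceptance
simulations calibrate). Each marker enters as a categorical fixed effect
with one class per retained allele; alleles under 5% frequency among the
marker's complete cases are pooled into an "other" class by default
(`rare_policy = "pool"`; `"drop"` and `"none"` available). Lines missing
the call are dropped for that marker only, with the covariance restricted
and re-factorised. The F statistic compares marker and null models after
whitening by the Cholesky factor of the fitted covariance, and the reported
marker $R^2$ is $(RSS_0 - RSS_1)/TSS$ on the whitened scale, with TSS
taken about the whitened intercept — a definition the package states
because tool conventions differ.

The Bonferroni threshold is $-\log_{10}(\alpha/m)$, kept unrounded
internally. Stability combines two levels deliberately: a marker–trait pair
must pass the Bonferroni gate in at least one environment *and* reach the
per-environment detection level (default $\alpha = 0.01$,
$-\log_{10}P \ge 2$) in at least `min_env = 2` environments. The laxer
per-environment level reflects how multi-environment tables are read in
practice: an association that clears the family-wise hurdle somewhere and
reproduces at the nominal scan level elsewhere is called stable.

## Allele mining

For each allele $i$ of a scored marker, the phenotypic effect is
$a_i = \frac{1}{n_i}\sum_j x_{ij} - N_k/n_k$: the mean across-environment
line mean of its carriers minus the mean over all phenotyped accessions.
Accessions with a missing call are excluded from the carrier mean but kept
in the panel mean. With complete data the carrier-weighted effects of a
locus balance to zero, an identity the tests assert. Effects are computed
for stable associations by default; `min_carriers` can impose a carrier
floor (none by default). An allele is favorable when the sign of $a_i$
matches the trait's breeding objective (+1 for the yield traits, −1 for
seed index by default; configurable). Representative accessions are the
top three carriers in the objective direction, ties broken by accession id
so the output is deterministic.

Transmission classes compare the allele's frequency in the founder (CK)
group with the era groups I–VI: class 3 when absent from the founders;
class 1 when founder-present and at or above `high_freq_threshold`
(default 0.8, chosen so the three canonical worked examples classify as
1/2/3) in *every* era group; class 2 otherwise. The boundary is
qualitative in the literature, hence exposed as a parameter.

## The synthetic panel generator

`simulate_panel()` emulates the statistical structure of a historical
cultivar panel, not its biology. Genotypes arise from a three-layer
ancestry: (1) a small panel-wide pool of deep ancestral haplotypes
(`n_ancestral_haplotypes`, default 8) drawn independently per locus from
Dirichlet ancestral frequencies; (2) per-subpopulation founder pools
(default 16) built as recombinant mosaics of those ancestors over
`founder_generations` (default 5) at Haldane map distances, with
subpopulations differing only in Dirichlet-drifted ancestor-usage weights
scaled by `divergence_Fst`; (3) each line as a founder mosaic recombined
over `generations_of_mating` (default 10), its segment ancestry drawn from
a Dirichlet(`admixture_alpha`) admixture vector, then doubled to
homozygosity implicitly (one haplotype per line). This design separates
the two sources of association: tightly linked loci ride shared ancestral
segments (the narrow ancestral base of a breeding program), while unlinked
loci pick up only structure-driven admixture LD. Two consequences are
worth knowing: realized locus-level Fst is smaller than the weight-level
`divergence_Fst` parameter (ancestors share alleles), and realized allele
counts per locus are capped by the ancestral pool size, so the panel-level
mean of ~2.3 alleles per locus sits near the 2–3 alleles typical of
intraspecific SSR panels even when loci are configured with up to nine.

Phenotypes are grand mean + deterministic environment offsets + QTL
effects + a polygenic line value + G×E deviation + replicate error. The
polygenic value mixes a shared "yield factor" (per-locus allele effects
drawn once) with trait-specific effects according to per-trait loadings,
producing the familiar sign pattern of yield-component correlations;
variances are scaled so the genetic variance hits its target. Default
trait targets (means, CVs, heritabilities 0.51–0.76, 3 environments × 2
replicates) are typical of multi-environment lint-yield trials, and the
default QTL effects of half a genetic standard deviation put per-marker
$R^2$ in the 2–5% range — the regime in which real germplasm scans
operate, meaning a scan at n = 300 detects some but not all planted QTLs.
All randomness flows from one seed through fixed per-stage sub-streams, so
partial reruns are reproducible; `verify_realism()` reports realized Fst,
allele counts, rare fraction, LD half-decay and heritabilities next to
their targets.

What the generator does **not** emulate: allotetraploid duplicated-locus
band complexity (one locus is one column), genotyping error, linked QTL in
repulsion, selection during the breeding history (era groups are assigned
independently of genotype, so real founder-to-modern frequency trends are
not present in simulated data), and environment-specific QTL. Passing
tests on simulated panels therefore validate the statistical machinery,
not claims about any particular crop's genetic architecture.

## Numerical and design choices

* Percentiles are nearest-rank, deterministic, no interpolation.
* The REML grid spans $\lambda \in [10^{-6}, 10^{6}]$; flat profiles
  (range < 1e-8) fall to the zero-variance boundary.
* Under null phenotypes the REML variance ratio shows the classic boundary
  mixture — roughly half the fits exactly at zero, the rest small and
  positive — which is what the property tests encode.
* EM convergence is a likelihood gain below 1e-6 (default) with a
  monotonicity assertion each iteration.
* `delta_k` requires at least three consecutive k values; interior points
  need two or more replicates.
* Degenerate inputs error loudly and early: empty panels after filtering,
  all-missing markers, zero LnP(D) dispersion, Q rows off simplex beyond
  1e-6, frequencies outside [0, 1].
* Pipeline stages skip when outputs exist and no upstream stage reran;
  hashes in the manifest make staleness visible. Stochastic stages refuse
  to run without an explicit seed.

## Problem sizes used by tests and acceptance

Simulation-based checks run at deliberately modest sizes chosen to make
their expectations sharp rather than large: structure-correction and
calibration studies use 50 panels of 120 lines × 100 markers and one
200-line panel with 1000 null markers; recovery studies use n = 300 with
50 replicate seeds; generator property checks use 60–150 lines and 30–60
loci over up to 10 seeds. These sizes give Monte-Carlo standard errors
comfortably inside the asserted tolerances (e.g. ±2% on a 5% type-I rate
over 1000 markers).

## Known limitations

* P3D underestimates per-marker uncertainty slightly when a marker
  explains a large variance share; at germplasm effect sizes the effect is
  negligible and the calibration test bounds it.
* The admixture EM finds local optima; restarts mitigate but do not
  guarantee the global one. It is a surrogate, not a replacement, for
  MCMC clustering with burn-in diagnostics.
* Permutation p-values have resolution 1/(n_perm+1); raise `n_perm` for
  stringent per-pair inference.
* The kinship estimator's sampling noise at ~150 loci (SD ≈ 0.05–0.08)
  is of the same order as the weak relatedness it tries to measure;
  interpret the tail of the kinship distribution accordingly.
* Era-group metadata in simulations is independent of genotype, so
  transmission classes on simulated panels exercise the bookkeeping, not a
  historical signal.
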