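---
title: "Models and methods in growthqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in growthqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

growthqtl analyses season-long growth trajectories — canopy height scanned
repeatedly on a biparental inbred-line (RIL) trial — through five stages:
spatially adjusted per-time-point BLUPs, a factor-analytic temporal model,
B-spline smoothing with functional PCA, individual-time-point and
functional QTL scans, and GBLUP genomic prediction.  A synthetic-trial
generator with fully known genetic architecture backs every stage with
truth-known tests.  This vignette explains the models, the parameters that
matter, and the design decisions taken where several defensible choices
existed.

## Stage one: per-time-point spatial mixed model

For each sampling day (in days after sowing, DAS) the plot values are
modelled as

y = mu + check + g + xi + eta,

with fixed check-genotype effects (the replicated entries of an augmented
design), a random RIL genotype effect g with variance sigma2_g, a
spatially correlated error xi with separable AR1 x AR1 covariance
sigma2_xi * AR1(phi_c) (x) AR1(phi_r) over field columns and rows, and an
independent nugget eta with variance sigma2_eta.  The model is fitted by
REML.  The autocorrelations are screened on a coarse grid (step 0.3, ties
broken toward zero) and the full five-parameter vector is then polished
with Nelder-Mead on the profiled REML criterion, with a fresh-simplex
restart guarding against premature convergence.  A step-0.1 screen was
considered and rejected: with the polish step the coarse screen reaches
the same optimum in our recovery tests at roughly a tenth of the cost, and
the Nelder-Mead polish — not the grid — determines the final estimate.
The autocorrelations are constrained to |phi| <= 0.99, and the spatial
component is retained only when it improves the REML criterion by more
than 3 over the nested iid-error model (an AIC comparison): at phi = 0
the spatial term merges with the nugget, leaving its three parameters
unidentified, so near-ties resolve to the simpler model with phi = 0.

Entry-mean broad-sense heritability is H2 = sigma2_g / (sigma2_g +
sigma2_xi + sigma2_eta), with a delta-method standard error from the
numerically evaluated REML information matrix.  In an augmented design the
RILs are unreplicated, so the separation of genetic from nugget variance
rests on the replicated checks and on the spatial structure; individual
per-day H2 estimates are accordingly noisy and the package's calibration
checks therefore test the *mean* H2 over the season.

## Stage two: rank-1 factor-analytic temporal covariance

The lines x time-points BLUP matrix is given a one-factor covariance
Sigma = lambda lambda' + Psi (per-day loadings lambda, specific variances
Psi), fitted by maximum likelihood with an EM algorithm.  Supplying per-day
measurement-error variances (the mean prediction error variance of the
stage-one BLUPs) turns the fit into the errors-in-variables model
y = g + e, and the returned matrix holds E[g | y] — genotypic values
shrunken under Sigma.  Two numerical safeguards: specific variances are
clamped at 1e-6 of the observed variance (Heywood cases are flagged with a
warning), and if EM ends below the nested diagonal-covariance model's
likelihood the diagonal solution is returned instead.  The sign of lambda
is fixed by requiring the last loading to be non-negative.

This *two-stage* route (per-day spatial REML, then a temporal factor
model on the adjusted values) replaces a joint multi-trait spatial fit.
The joint fit requires a specialised sparse multi-trait REML solver; the
two-stage approximation is standard practice, fully testable, and its
adequacy is demonstrated by parameter recovery on simulated trials (the
loadings are recovered within 10% RMSE at 500 lines when the factor model
is fitted to directly observed genotypic values; fitted to stage-one BLUPs
they are attenuated by shrinkage, which affects neither heritability nor
any downstream scan).

## Smoothing and functional PCA

Each line's trajectory is smoothed with one shared cubic B-spline basis
with equispaced interior knots over the observed DAS range.  The basis
size is selected from candidates {4, ..., min(15, #TPs)} by k-fold
cross-validation in which the folds partition *time points* (round-robin
after a seeded shuffle), because basis adequacy is a property of the time
grid, not of the lines; the candidate minimising the held-out SSE summed
over lines wins, with ties to the smaller basis.  Whether folds should
partition days or lines, and whether knots are equispaced, are genuinely
open choices; both are fixed here as stated and exercised by tests.

Functional PCA is an eigen-decomposition of the between-line covariance of
the basis coefficients in the basis inner-product metric: the Gram matrix
of the B-spline basis, computed exactly by 4-point Gauss-Legendre
quadrature per inter-knot interval (exact for the degree-6 products of
cubics).  This treats curves as functions rather than coefficient vectors;
on a fine evaluation grid it agrees with ordinary PCA of the smoothed
values, which the test suite checks numerically.  The default number of
components is 3, 4 or 5 for 5, 10 or 26 time points.  The "last two"
B-spline coefficients — the two highest-index basis functions, which load
on the season's end — serve as low-dimensional late-growth phenotypes for
prediction.

## QTL scans

Genotype probabilities on a 1 cM pseudomarker grid come from a two-state
Markov chain per chromosome with RIL-expanded Haldane transitions,
R = 2r/(1+2r) with r = 0.5(1 - exp(-2d/100)); missing marker calls are
handled by forward-backward.  A sub-centimorgan step buys nothing at
roughly 200 lines, where mapping resolution is far coarser.

Individual-time-point scans use Haley-Knott regression:
LOD = (n/2) log10(RSS0/RSS1).  Composite interval mapping adds five
forward-selected marker covariates (refreshed per time point — the
alternative of freezing one covariate set across days has no clear
justification when per-day genetic architecture is the object of study)
and drops covariates within 10 cM of the test position.

Functional scans operate either on the functional PC scores — the
multivariate HKLOD = (n/2) log10(|RSS0|/|RSS(lambda)|), with a ridge of
1e-8 x trace added to a singular residual cross-product matrix — or on the
per-day LOD curves summarised by their maximum (MLOD) or mean (SLOD).
MLOD dominates SLOD by construction; SLOD dilutes signals confined to few
days, which is exactly why it loses power for transient QTLs.

Genome-wide thresholds come from permutations of the line labels, with
whole phenotype rows permuted jointly so the temporal correlation is
preserved, and one shared permutation-index matrix per run so the
HKLOD/MLOD/SLOD thresholds are comparable.  The threshold is the k-th
order statistic of the permutation maxima with k = ceiling((1 - alpha)
(N + 1)): declaring a scan significant when its maximum exceeds this
value is the exact-size permutation test (size 10/201 ~ 0.0497 at
alpha = 0.05 with N = 200 permutations), whereas an interpolated
(1 - alpha) sample quantile sits marginally low and inflates the realised
size to about 0.055.  Defaults: 1000 permutations, alpha = 0.05.

Multiple-QTL search maximises the penalized LOD, pLOD = joint LOD -
penalty x (#QTLs), with the single-scan permutation threshold as the
main-effect penalty: forward selection to six QTLs, backward elimination
to the null model, the best pLOD over the whole trajectory, and a final
within-chromosome refinement pass.  Only additive models are searched;
epistatic penalties are out of scope.  Peaks get 1.5-LOD support
intervals, and peaks within 20 cM merge into the higher one.

## Power simulation by data perturbation

An effect of +/- alpha is added to the two homozygote classes of a
uniformly drawn marker — at every day (persistent) or one random day
(transient) — and the genome is rescanned against thresholds computed once
on unperturbed data.  The effect size comes from the single-locus relation
PVE = 1/(1 + 1/(c k^2 p(1-p))) with k the effect in phenotypic-SD units.
The constant c is ambiguous in the field's usage: c = 4 is exact when
alpha is the half-difference between classes, c = 1 corresponds to reading
k as the full class difference.  Both are available; the default
calibrates alpha empirically by Monte-Carlo bisection until the realised
sample PVE matches the target, which makes the targeted PVE
interpretation-free.  Detection requires the genome-wide maximum to exceed
its threshold *and* the peak to lie on the perturbed marker's chromosome —
stricter than exceedance alone, because at high PVE the unlocalised rule
conflates true and false peaks.  For transient QTLs the individual-TP
comparison is scored on the perturbed day's scan.

## Genomic prediction

The kinship is VanRaden's first formula, G = WW'/(2 sum p(1-p)) with
dosages {0, 2} and W the centred dosages.  On a fully inbred panel the
mean diagonal is near 2 (that is, 1 + F) — expected under this scaling and
harmless, since GBLUP is invariant to the coding (the {0,1} and {0,2}
codings give identical GEBVs, which is tested).  GBLUP is fitted by REML
after rotating into the eigenbasis of G, where the profiled criterion is a
one-dimensional optimisation in the variance ratio; a Gibbs-sampling
backend (60 000 iterations, 15 000 burn-in, thin 5 by default) exists for
cross-checks but REML is the default because it is deterministic and two
orders of magnitude faster.  Genomic heritability is h2g =
sigma2_a/(sigma2_a + sigma2_e) on the model scale.

Cross-validation draws 50 random 75/25 train/validation splits;
predictive ability is the Pearson correlation between the validation
lines' adjusted values and their GEBVs (obtained by kinship projection
from the training fit).  With QTL covariates enabled, a single HKLOD scan
with its own permutation threshold (200 permutations by default, for
cost; configurable to 1000) runs inside each training set and significant
peak positions enter the model as fixed covariates, whose fitted effects
are added to the validation predictions.  Scenario comparison applies
Fisher's Z to the replicate correlations and groups scenarios by the
Scott-Knott procedure: recursive binary splits of the ordered means,
tested via lambda = pi/(2(pi-2)) B0/sigma0^2 against chi-squared with
k/(pi-2) degrees of freedom.

## The synthetic trial

The generator draws RIL genotypes by a Markov chain along each chromosome
(Haldane distances, RIL-expanded), then builds plot phenotypes
value = mu_t + check_t + g_t + xi + eta where the polygenic deviations
follow the rank-1 factor covariance, QTL effects enter as explicit per-day
allele-substitution profiles (persistent / transient / stage-specific
presets), xi is an AR1 x AR1 field drawn independently per day and eta is
a per-day nugget.  The common polygenic factor is a standardised
genome-wide polygenic score — every marker receives a small effect — so
the factor share of the genetic variance is marker-heritable, as genotypic
values in a real inbred panel are; the per-day specific deviations are
drawn independently of the markers (a deliberate simplification that keeps
them exactly independent across days even on the sparse maps the unit
tests use, at the cost of making the specific share invisible to genomic
prediction).  The mean curve is logistic to a changepoint at the
tillering/stem-elongation boundary (DAS 141) and linear after — rising
from about 0.06 m at DAS 23 to about 1.0 m at DAS 228, a typical tall
wheat season.

The calibrated preset (`preset_trial()`) fixes the study conditions used
throughout the tests: 197 lines, 26 sampling days from DAS 23 to 228
(fourteen tillering, eight stem-elongation, four heading/flowering), a 21
x 111-marker map (~2330 markers), genetic standard deviation growing from
2 to 10 cm with the mean curve, per-day plot-level heritability 0.68
(error split 55/45 between spatial and nugget, phi = 0.4 both ways), and
four QTLs: persistent on C2, tillering-specific on C5 and C8, and
heading/flowering-specific on C7, each scaled to about 45% of the
polygenic SD.  Where the real study does not publish a number (parental
mean curves, exact DAS grid, field autocorrelations), values were chosen
once to be agronomically plausible and are not revisited.  The grid adds
DAS 30, 51, 91 and 201 to the days named by the published selection
scenarios so that the scenario lists are all subsets of the grid.

What the generator deliberately does not emulate: residual
heterozygosity, genotype x environment interaction beyond the modelled
temporal structure, lodging and other late-season data-quality artefacts,
non-Gaussian measurement error, and linkage-map estimation error.  Passing
tests therefore demonstrate internal statistical correctness and
calibration under a faithful but idealised data-generating process, not
robustness to those artefacts.

## Problem sizes used by the test suite

The calibration checks run at desk scale: genome scans use a 5 x 50-marker
map with 197 lines; permutation thresholds use 200 permutations; type-I
error uses 200 null trials; power uses 100 perturbation iterations per
setting; parameter-recovery checks use 500 lines; prediction comparisons
use the full preset with 50 cross-validation replicates.  The
H2-estimator bias check runs 12 replicate fields of 120 plots.  These
sizes were chosen so the whole suite completes in minutes while keeping
Monte-Carlo error well inside the asserted tolerances.

## Known limitations

The two-stage BLUP route attenuates factor loadings relative to a joint
fit; FA orders above 1, pedigree relationship matrices, epistasis scans,
dominance (meaningless in a fully inbred panel) and multi-trait GBLUP are
out of scope.  The Wald/likelihood-ratio significance summaries mirror
standard mixed-model output only approximately, since denominator
degree-of-freedom conventions differ between solvers.  Scenario stage
counts are taken at face value from the published selection table even
where the stage windows might suggest a different attribution for
boundary days.
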