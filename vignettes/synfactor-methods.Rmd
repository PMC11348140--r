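---
title: "Methods: information-resolved synergy factors of brain network dysfunction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: information-resolved synergy factors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`synfactor` implements an information-resolved analysis of case-control
resting-state fMRI cohorts. The chain is:

1. decompose every region pair's lagged dependence into the sixteen
   atoms of an integrated information decomposition (PhiID), keeping the
   persistent synergy (`Syn->Syn`) and double redundancy (`Red->Red`)
   atoms as pairwise interaction matrices;
2. map case-control differences pair by pair with covariate-adjusted t
   statistics and summarize them regionally and per resting-state
   network;
3. z-normalize each patient's synergy matrix against the control
   distribution, keep only synergy *reductions*, discretize them into
   counts, and fit a latent Dirichlet allocation (LDA) model in which
   patients are documents, region pairs are words, and latent
   dysfunction factors are topics;
4. relate per-patient factor expressions to clinical scores
   (representational similarity analysis, per-site and pooled
   correlations, general-linear-model contrasts);
5. relate regional factor maps to gene expression (gene-factor
   correlations, risk-gene sets, co-expression networks, virtual gene
   knockout) and to microcircuit parameters of a heterogeneous dynamic
   mean-field model fitted with CMA-ES;
6. assess every map-to-map correlation against variogram-matched
   spatial-autocorrelation (SA) preserving surrogate maps.

Every stage runs on a fully synthetic cohort generated by the package,
so the pipeline is testable end to end without any imaging data.

# Gaussian PhiID with minimum-mutual-information redundancy

For one region pair the package forms the 4-dimensional Gaussian vector
$(X^1_t, X^2_t, X^1_{t+\tau}, X^2_{t+\tau})$ (default lag $\tau$ = 1
sample; the lag is configurable — one repetition time is the standard
choice for BOLD). All mutual informations are computed from the sample
covariance with the Gaussian formula
$I(A;B) = \tfrac12 \log \frac{\det\Sigma_{AA}\,\det\Sigma_{BB}}{\det\Sigma_{A\cup B}}$,
in nats, clamped at zero.

Sixteen atoms $(\alpha \to \beta)$, $\alpha,\beta \in
\{\mathrm{Red}, \mathrm{Un}_1, \mathrm{Un}_2, \mathrm{Syn}\}$, are
solved from sixteen cumulative constraints over the product redundancy
lattice: the nine lagged mutual informations between the past
collections $\{1\},\{2\},\{1,2\}$ and the future collections, plus
seven redundancy constraints built from the minimum-mutual-information
(MMI) rule, the double redundancy being
$\min_{ij} I(X^i_t; X^j_{t+\tau})$.

**Redundancy convention.** The MMI minimum in *all* redundancy
constraints runs over single-channel lagged mutual informations — the
same rule the double redundancy uses. This choice has two analytic
consequences that the package treats as defining properties: two
independent AR(1) channels carry zero persistent synergy and zero
double redundancy, and two identical AR(1) channels with coefficient
$\varphi$ carry `Red->Red` $= \tfrac12\log\frac{1}{1-\varphi^2}$ with
zero synergy. The alternative convention, in which one-sided
redundancies are evaluated against the joint collection
($\min_i I(X^i; X^{12})$), is available via
`phid_decompose(..., redundancy = "collection")`; under it,
independent autocorrelated channels retain a positive synergy floor of
$2\min(I_{11}, I_{22})$, which we consider undesirable as a baseline
for coupling-sensitive analyses.

Numerical choices: series are z-scored per region before covariance
estimation (Gaussian MI is scale-invariant; this only stabilizes
determinants); linearly dependent coordinates *within* a group are
projected out by an eigenvalue cut (duplicated channels carry no extra
information), while rank deficiency *across* past and future raises a
`singular-covariance` error; marginal MIs are clamped at zero but atoms
are reported as solved, including negative values — negativity is a
known property of MMI-based decompositions, not an error. The linear
solve is verified in the test suite against an independent Moebius
inversion over the product lattice, exactly.

# Group statistics

Confounds (age, gender, site by default) are regressed out of each pair
entry by OLS before a pooled-variance two-sample t test with contrast
NC − SCZ. Degrees of freedom are not reduced for the residualization —
a deliberate simplification, shared with common practice, that is
slightly anticonservative when the covariate count approaches the
sample size. The dispersion comparison applies an unpaired t test to
squared deviations from the group mean rather than an F test, so its
statistic stays on the t scale used elsewhere; its null calibration is
verified by simulation in the test suite.

# Latent factor model

Patient synergy matrices are z-scored entry-wise against the control
mean and n−1 standard deviation. Positive z-scores are set to zero and
negative z-scores enter as magnitudes: the model describes *reductions*
in synergy. The continuous magnitudes are multiplied by a
discretization `scale` (default 10, i.e. z = −1.7 becomes 17 counts)
and rounded; the scale is exposed in the configuration, and doubling it
leaves fitted patterns essentially unchanged (the tests check matched
correlation under scale doubling).

Inference is batch variational EM for smoothed LDA with symmetric
priors: `alpha = 100/K` on loadings and `eta = 0.01` on patterns — the
common heuristic for this model family. The evidence lower bound is
tracked and must be nondecreasing (tolerance 1e−6); fits are
deterministic given a seed. A collapsed Gibbs sampler was considered
and not implemented: variational EM makes every reported quantity
reproducible bit for bit at equal statistical quality for this use, and
a second inference engine would double the maintenance surface without
changing any scientific claim.

The factor count is chosen by split-half stability: for each candidate
K the subjects are split in half repeatedly, models fitted on both
halves are matched by exhaustive permutation search on pattern
correlations, and the K with the highest mean matched correlation wins.
This criterion is a declared substitute for an unspecified "best
results" rule; it is simple, symmetric, and penalizes both under- and
over-factorization.

# Clinical associations

Subject dissimilarity uses absolute differences (numeric), Euclidean
distances (vector-valued), and 0/1 mismatch (categorical); model fit is
Kendall tau-b over strict lower triangles because categorical RDMs are
tie-heavy. The RSA contrast compares tau distributions across LDA
restarts with the single tau of the raw vectorized z-matrices; the
"final estimate" shown alongside the distribution is the restart with
the highest training ELBO. Pooled clinical correlations merge all
patients after within-site residualization (not a meta-analytic
average), with Fisher-z 95% intervals and FDR-BH over the
factor-by-scale family. The GLM contrast fits
$Y = \beta_0 + \beta_1 p_1 + \beta_2 p_2 + \epsilon$ (the last loading
is implicit through the simplex) and tests $H\beta = 0$ with a Wald F
test; agreement with `car::linearHypothesis` is asserted in the tests.

# Transcriptomic associations

Factor patterns are aggregated to regions by summing each region's
incident pair weights. Per-gene Pearson correlations with a factor map
are ranked; the top and bottom tails (1500 each at full transcriptome
scale, scaled down proportionally on synthetic data) form the risk
sets. Regional co-expression is Spearman-over-genes with Fisher z;
correlations of exactly 1 from duplicated regions are capped at
1 − 1e−6 with a warning. Because the analysis needs a regional scalar
to correlate a co-expression *matrix* against a regional *map*, the
package uses the row mean of the Fisher-z matrix as regional
co-expression strength; this is a declared design decision. The
virtual knockout recomputes the co-expression-map correlation without
each gene; GCI = r(all) − r(without gene), so positive GCI marks genes
supporting the association. Each GCI is definitionally recomputable,
and the tests do exactly that.

# Dynamic mean-field model

Regional gating follows the reduced Wong-Wang dynamics with transfer
function $H(x) = (ax-b)/(1-e^{-d(ax-b)})$ and the literature constants
a = 270 nC⁻¹, b = 108 Hz, d = 0.154 s, τ_s = 0.1 s, γ = 0.641,
J = 0.2609 nA (config-exposed; the source analysis defers them to the
cited mean-field literature). The removable singularity at $ax = b$
evaluates to $1/d$. Regional recurrent strength W, external input I and
noise σ are linear in the myelin and gradient maps (nine coefficients),
plus a global coupling G — ten free parameters fitted by CMA-ES
(population $4 + \lfloor 3\ln 10\rfloor = 10$, 64 generations by
default) against the cost
(1 − r(FC)) + KS(FCD entries), with k-fold cross-validation over
subjects.

Numerical choices worth knowing:

- Euler-Maruyama at dt = 10 ms with S clipped to [0, 1]; the
  hemodynamic (Balloon-Windkessel, standard constants) state advances
  every 5 neural steps from the window-mean gating — its time constants
  (~1 s) are two orders slower than dt, and halving dt changes the
  deterministic terminal state by < 1e−4 (tested).
- Candidate evaluations share one noise seed (common random numbers),
  making the objective deterministic and the fit reproducible.
- Saturated or divergent candidates receive the worst attainable cost
  (3.0) rather than infinity, keeping the CMA-ES ranking informative.
- Default box constraints bracket the low-activity working point of a
  max-normalized connectome (c_w in [0.3, 1], c_I in [0.25, 0.4],
  G in [0, 1]); for such connectomes the low branch destabilizes —
  and the model saturates — well below the box edge, so a wider box
  mostly adds saturated volume. The bounds are plain arguments
  (`fit_pmfm(..., bounds = )`) for connectomes normalized differently.
- The meaningful FC regime is near-critical: fluctuations propagated
  through the connectome dominate only close to the low-state
  instability. The synthetic self-recovery tests place the generating
  parameters in that regime, which is also where empirical fits land
  in the mean-field literature.

# Spatial-autocorrelation surrogates

Surrogates are built in the variogram-matching family: permute the map,
smooth with k-nearest-neighbour exponential-decay kernels over a grid
of k, regress the original binned semivariogram on the smoothed one,
rescale, add the fitted nugget as white noise, and rank-remap onto the
original value multiset (so the permutation-test exchangeability
argument is exact on values). Two defaults differ from the common
minimal recipe, both chosen for calibration: the variogram regression
and kernel selection are weighted by inverse bin rank (short-range
autocorrelation dominates the effective degrees of freedom of a
map-to-map correlation), and the kernel is selected on the variogram of
the *final*, rank-remapped surrogate rather than the intermediate
smoothed field. With the default grid k/N in {0.1, ..., 0.9} the
false-positive rate on independent smooth map pairs is 6-9% at nominal
5%, versus 30-60% for naive permutation on the same maps. The test
surrogates the *first* map argument against the fixed second; the
asymmetry is documented in `sa_corr_test`.

# The synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
assumes, and nothing more:

- Controls follow a stable VAR(1) process, x_{t+1} = A x_t + e.
- K planted factor patterns are sets of disjoint region *dyads*. Within
  a dyad the coupling is negative (−0.55) while the innovation
  correlation is positive (+0.85). This sign opposition is what makes
  persistent synergy genuinely positive on planted pairs — the
  simultaneous correlation the coupling would create is cancelled,
  leaving purely cross-temporal joint structure — so that attenuating
  the coupling *reduces* synergy. Same-sign designs produce redundancy
  instead, and attenuation then raises the synergy atom.
- For each patient, off-diagonal couplings are multiplied by
  1 − effect·Σ_k loading_k·pattern_k(i,j), with Dirichlet(0.5)
  loadings; `effect` defaults to 0.6, a value chosen once to give
  comfortable factor recovery at desk scale (the source analysis states
  no effect size).
- PANSS subscales are linear in the loadings plus Gaussian noise
  (positive weight from factor 1 to the positive scale, negative
  weights from factor 3 to the negative and general scales), mapped
  affinely into the standard ranges [7,49]/[7,49]/[16,112]; item scores
  are subscale/n_items plus noise clipped to [1,7]. Only the
  correlation structure matters downstream. The default noise
  (`clinical_noise_sd = 0.95`) puts the true loading-symptom
  correlation near 0.3.
- Gene expression plants, per factor, genes equal to the factor map
  plus noise — half with the negated map so both ranking tails are
  populated — among spatially smooth null genes.
- The structural connectome is symmetric, nonnegative,
  distance-decaying and max-normalized; myelin and gradient maps are
  smooth z-scored fields.

What the generator does **not** emulate: hemodynamic filtering and
physiological noise in the cohort time series (the dynamics module has
its own forward model), scanner/site differences beyond an independent
site label, missing data, head-motion artifacts, and any spatial
topology of real dysfunction patterns (dyads are an idealization chosen
for stability and analytic control). Passing recovery tests therefore
demonstrates correctness of the estimators under the stated model, not
robustness to the full complexity of empirical fMRI.

# Problem sizes used by the tests

The automated checks run at desk scale, chosen as the package's
standard validation sizes: unit fixtures use 16-30 regions and 12-24
subjects; the end-to-end factor-recovery check uses 50 regions (1225
pairs), 60+60 subjects, 240 time points and K = 3; null calibrations
use 200 replicate mini-cohorts (12 regions, 10+10 subjects); the SA
calibration uses 200 independent smooth map pairs on 60 regions with
199 surrogates per test; the mean-field self-recovery uses 30 cortical
regions, 5 subjects and 20 optimizer seeds at 64 generations. Headline
empirical quantities from patient cohorts (e.g. region counts of 115
and pair counts of 6555) enter as exact structural identities, not as
statistical reproductions.

# Known limitations

- The PhiID estimator is Gaussian; nonlinear coupling beyond second
  moments is invisible to it.
- MMI-based atoms can be negative; downstream stages use only
  `Syn->Syn` and `Red->Red` and pass raw values forward without
  per-subject normalization (whether the source analysis normalized is
  unstated).
- Residualize-then-test does not adjust degrees of freedom.
- Euclidean distances between parcel centroids stand in for geodesic
  cortical distance in the surrogate machinery.
- The subcortical (SUB) block is treated like any other network; no
  claim is made about ventricle-like regions.
- LDA count discretization is a modeling device; results are stable in
  the scale but the counts have no physical unit.
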