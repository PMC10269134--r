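---
title: "Models and methods behind phycophys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phycophys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

phycophys packages the quantitative analysis layer of a microalgal
photophysiology study — PAM fluorescence, electrochromic-shift (ECS)
deconvolution, pigment and growth phenotyping, photoinhibition kinetics,
and reproducibility-optimized differential-abundance testing — together
with a synthetic-data module that generates every input with known truth.
This vignette explains each model, the choices that were genuinely open,
and what the validation does and does not demonstrate.

## Fluorescence parameters and rapid light curves

The saturating-pulse quantities are the universal definitions:
Fv/Fm = (Fm − F0)/Fm for dark-adapted cells, ΦPSII = (Fm′ − F′)/Fm′ under
actinic light (Genty yield), and Stern–Volmer NPQ = Fm/Fm′ − 1 against the
dark-adapted Fm. Inputs that violate F ≤ Fm — which happens with instrument
noise near saturation — are *flagged*, never clamped, so downstream
averaging cannot silently absorb impossible values.

Relative electron transport is rETR = ΦPSII·E with no absorptance or
PSII-fraction factor. The rate is deliberately *relative*: any constant
multiplier cancels both in Ek = rETRmax/α and in all mutant/WT
comparisons, which is where these numbers are used.

Rapid light curves are fitted with the Webb saturating exponential
rETR(E) = rETRmax·(1 − e^(−αE/rETRmax)). This form has no
photoinhibition term; it suits protocols that extend the irradiance ladder
only until the saturation plateau is reached, and it makes
Ek = rETRmax/α exact rather than approximate. Fitting is unweighted
nonlinear least squares on rETR (not on ΦPSII, whose errors are strongly
heteroscedastic once multiplied by E), initialized with α from the
regression slope of the three lowest irradiances and rETRmax from the raw
maximum. The fitted object stores Ek as the exact quotient, reports the
raw maximum rETR alongside the fitted asymptote (protocols differ on which
they quote; we fit the asymptote and log both), and flags the fit
`unsaturated` whenever the largest measured irradiance is below the fitted
Ek — the asymptote is then an extrapolation and should be treated as such.

The default irradiance ladder is 13 steps from 4 to 1088
µmol photons m⁻² s⁻¹. Only those endpoints and the step count are fixed by
the protocol being emulated; the intermediate steps are geometrically
spaced, and an optional 14th step at 1216 is available for
high-light-acclimated samples.

## ECS deconvolution, stoichiometry and electron flow

Absorbance-difference signals at 520 nm mix the linear electrochromic
shift with cytochrome redox changes. The three-wavelength deconvolution

> Cyt c = [554] − 0.4·[520] − 0.4·[563],  ECS_lin = [520] − 0.25·Cyt c

is applied pointwise per condition and regime. The synthetic generator
constructs traces by the *exact inverse* mixing
(A563 = 0.1·E, A520 = E + 0.25·C, A554 = C + 0.4·A520 + 0.4·A563), so
noise-free deconvolution returns the stored components to machine
precision; any mixing weights satisfying that inverse relationship would
do, and these are fixed for reproducibility. One wavelength set —
{520, 554, 563} nm — is used throughout.

The fast-phase flash amplitude is estimated by fitting a single
exponential to the post-flash ECS_lin and back-extrapolating to the flash
instant; reading the raw peak instead would bias the amplitude low by a
factor depending on the decay rate and the sampling delay. If the decay
fit fails, the mean over the first quartile of the fit window is used and
the result flagged `windowed`. Functional stoichiometry follows from the
amplitude drop upon PSII poisoning (DCMU + hydroxylamine):
PSII/PSI = (amp_control − amp_inhibited)/amp_inhibited. An
`amp_control < amp_inhibited` input is an error, not a clamped zero — it
indicates a measurement problem that averaging should not hide.

Electron flow comes from a light-to-dark transition:
flow = (slope_light − slope_dark)/a1, with a1 the single-charge flash
amplitude measured under DCMU + HA and slopes estimated by ordinary least
squares on the *deconvolved* ECS_lin (so cytochrome kinetics cannot
contaminate them). Default windows — 50 ms baseline, 1–20 ms decay-fit
window, 200 ms slope windows either side of the transition — are
engineering choices; the underlying protocol does not pin them down, and
all are arguments.

## Pigments and growth

Per-cell pigment amounts (fmol cell⁻¹) feed the de-epoxidation index
DES = Dtx/(Dtx + Ddx), computed per replicate and then averaged, and
ratios per Chl a. DES is scale-invariant and bounded in [0, 1]; a zero
xanthophyll pool makes it undefined and it is returned as `NA` with a
warning.

Division rates are slopes of log2(counts) against time — divisions per
day, matching how growth tables in this literature are stated — not
natural-log growth rates. "During the exponential phase" needs an
operational rule: we use the sliding window (≥ 3 samples by default)
maximizing the fitted slope subject to R² ≥ 0.99, which excludes lag and
plateau regions without manual curation; if no window qualifies, the
best-R² window is reported with a flag. Successive-interval rates
log2(N_{i+1}/N_i)/Δt are returned alongside, since some studies compute
table rates that way; on clean exponential data the two coincide.

## Photoinhibition: damage, repair and sustained quenching

The high-light ± lincomycin experiment is modelled with a two-state
(intact/damaged) first-order system: dD/dt = k_damage·(1 − D) −
k_repair·D during the 60-min high-light phase, with k_repair = 0 when
lincomycin blocks chloroplast translation; during the 30-min dim-light
recovery, damage stops and repair continues only without lincomycin. On
top of damage, a sustained-quenching term q(t) builds during high light
(rate k_qind) and relaxes during recovery (rate k_qrelax) towards a
residual q_res; reported relative Fv/Fm is (1 − D)·(1 − q).

Two identifiability choices deserve emphasis. First, studies of this
design print endpoint *fractions*, not rate constants, so the packaged
scenario back-computes its constants from those fractions:
k_damage = −ln(0.30)/60 min⁻¹ from the 30 % translation-blocked endpoint,
and, given chosen repair rates (0.065 min⁻¹ wild type, 0.040 min⁻¹
mutant), the quenching amplitude and residual are solved so the noise-free
model reproduces the 60-min (52 %/40 %) and 90-min (96 %/70 %) endpoints
exactly (`solve_quenching_params()`). Second, the lincomycin arm carries
no explicit quenching term: its damage constant absorbs the entire
decline, making the +LINC trajectory exactly e^(−k_damage·t). The
decomposition of the *non*-recovered signal into damage versus long-lived
quenching is not unique from Fv/Fm alone, and the model does not claim to
separate them — only the repair-competent versus repair-blocked contrast
is interpreted.

The analysis side is deliberately simple and model-free: normalization to
the replicate's own t = 0 value (percent of initial), the photodamage rate
as the through-origin slope of ln(rel) versus time in the +LINC arm
(reducing to −ln(rel(t_end))/t_end with a single endpoint), and endpoint
means with dispersions for the repair/recovery metrics.

## Proteomics: normalization, ROTS and selection rules

Preprocessing mirrors common label-free practice: proteins missing in two
or more biological replicates of either comparison group are excluded
(interpreted per group within each pairwise comparison — the strictest
reading; a per-row-total mode is available via `scope`), then each sample
column is rescaled so its total over the commonly observed proteins equals
the grand mean of raw totals. Filtering precedes scaling so the operation
is idempotent. Zeros are treated as missing — a zero intensity carries no
quantitative information. Log2 ratios are ratios of arithmetic means of
normalized abundances (the convention of platform ratio tables); a
mean-of-log-ratios alternative is one flag away, and the two differ when
replicate variance is large.

The differential test is a reproducibility-optimized statistic computed on
log2 abundances: d(a1, a2) = |x̄₁ − x̄₂|/(a1 + a2·s), with s the pooled
standard error. Neither the regularization (a1, a2) nor the top-list size
k is fixed a priori. Instead, B bootstrap pairs (resampling replicates
within groups) give observed top-k overlaps, group-label-permuted data
give null overlaps, and (a1, a2, k) maximize the Z-score
(R_k − R0_k)/sd(R_k). The grid keeps a1 > 0 wherever a2 = 1, so a protein
with zero pooled variance cannot produce an infinite statistic; the grid
also contains (a1 = 1, a2 = 0), the plain mean difference. P-values come
from the permutation null of the selected statistic pooled across
proteins; the FDR at rank r is the mean permutation count of null
statistics ≥ the r-th observed statistic divided by r, monotonized from
the bottom of the ranking and capped at 1. Bootstraps and permutations are
drawn on samples and proteins sorted by identifier, so results are
invariant to input row and column order at a fixed seed. The study
protocol this emulates used 1000 bootstraps with significance at p < 0.05
and FDR < 0.05; both are defaults, and both are cheap to lower for
exploratory runs.

Selection of concordantly regulated proteins applies four clauses:
FDR < 0.05 in *both* mutant lines, the same ratio sign in both,
|log2| ≥ 0.5 in at least one line (the boundary is included), and at
least two peptides. The implementation is tested against a brute-force
clause-by-clause filter. Fold conversions are exact exponentiation with
presentation helpers (floored percent-of-reference for "declined to N %",
rounded fold for "N-fold higher").

## Group comparisons

Two-way fixed-effects ANOVA (line × time, with interaction) uses
sequential sums of squares via `lm()`; for the balanced designs these
studies aim for, sequential and partial decompositions coincide, and
unbalanced input triggers a warning rather than silent reinterpretation.
Dunnett many-to-one comparisons run within each time point (matching how
per-time-point significance marks are drawn in this literature) using the
pooled residual mean square from the two-way model. Adjusted p-values
P(max_j |T_j| ≥ |t_i|) are estimated by seeded Monte Carlo from the exact
factor representation of the equicorrelated multivariate t induced by the
shared control (correlation 0.5 when balanced), with 10⁵ draws by default
(standard error on p below 0.002); the reported value is never allowed
below the unadjusted p. Monte Carlo was chosen over multivariate-t
quadrature because it is simple, seedable and testable — the test suite
checks the single-treatment reduction to the t-test, agreement with an
independent reference implementation, and family-wise error control.
Whether such a study fits one two-way model per parameter or per-time
one-way models is rarely stated; the two-way + within-time construction is
adopted and documented here.

## The synthetic-data module: what it emulates, and what it does not

Every generator draws from a `sim_scenario` and attaches the exact
noise-free truth to its output, so parameter recovery is checkable for
every estimator. Noise models follow assay type: multiplicative Gaussian
(1 + cv·Z) for fluorescence-derived quantities, additive Gaussian per
wavelength for ECS (instrument noise dominates at these small ΔA),
mean-one lognormal for counts and pigments (strictly positive,
right-skewed), and Gaussian on the log2 scale plus
MCAR-and-intensity-dependent (logistic) missingness for proteomics.
Instrument noise magnitudes are not printed in the protocols being
emulated; defaults of 3–5 % CV (2 × 10⁻⁴ ΔA for ECS) are package choices,
stated in the scenario, and typical of these instruments.

The packaged `cpftsy_study` scenario fixes its truths at published values:
per-line division rates under low and medium light, the photoinhibition
endpoint fractions above (wild type n = 3, pooled mutant n = 9), a
mutant electron flow half the wild type's, and anchored proteomics effects
(PsaC at −1.35/−1.96 log2, an APE1-like protein at +1.16/+1.58, PetD at
−0.39/−0.53, with their published peptide counts). Where the underlying
study prints no value — pigment means per cell, ECS amplitudes and decay
rates, NPQ kinetics — the scenario uses realistic magnitudes chosen once
(e.g. per-cell Chl a of 0.25 fmol from pigment mass per cell, a
single-charge amplitude of 0.01 ΔA, flash decay at 5 s⁻¹) and documented
in `scenario_defaults()`.

Passing recovery tests on these simulations demonstrates that the
*estimators invert the stated generative models* at realistic noise — it
does not validate the models against real instruments. Real PAM traces
have correlated drift and actinic artefacts; real ECS has slow phases and
pmf partitioning that this package deliberately does not model; real
proteomics has peptide-level structure, shared peptides and
batch effects that a protein-level lognormal cannot show. Conclusions
about real data rest on the published study's measurements, not on these
simulations.

## Numerical choices and problem sizes

Degenerate inputs have defined behaviour throughout: undefined DES is
`NA` with a warning; a constant-response ANOVA reports F = 0, p = 1;
a failed flash-decay fit falls back to a flagged windowed mean; an
unsaturated light curve is flagged rather than rejected. Seeding uses a
fixed RNG (Mersenne–Twister with inversion sampling) restored on exit, so
identical (scenario, seed) pairs give identical output across platforms,
and derived sub-seeds keep generators independent.

The test suite exercises calibration at sizes chosen to finish in minutes
on one CPU while keeping Monte-Carlo error well inside the asserted
tolerances: 500 noisy light-curve replicates; 60–100 seeded ECS and
growth simulations; ROTS null calibration over 50 simulated proteomes of
2000 proteins (B = 100, 100 permutations — the optimization and the
p-value pool behave identically at larger B, only more slowly) and power
with calibrated false-discovery proportion over 25 spiked proteomes;
1500 null replications for Dunnett family-wise error. The acceptance
script (`scripts/acceptance.R`) uses the replication counts of the
emulated study itself (n = 3/9 photoinhibition, 20 ECS experiments,
3 growth replicates).

## Known limitations

* The photoinhibition decomposition attributes all non-recovered signal to
  damage plus sustained quenching jointly; separating qI-type quenching
  from unrepaired damage needs measurements this package does not consume.
* The ECS module analyses only the linear component's fast phase and
  slopes: no slow-phase analysis, no ΔpH/Δψ partitioning.
* ROTS p-values are pooled across proteins, which assumes exchangeability
  of the null statistic across proteins after regularization — standard
  for this statistic family, but a protein with a wildly different
  variance structure inherits the pooled null.
* The CSV/TSV schemas round-trip doubles to the shortest representation
  that re-reads to the same value; nonlinear fits can amplify the last
  ulp, so file-based and in-memory pipelines agree to ~10⁻⁶ relative, not
  bit-for-bit.
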