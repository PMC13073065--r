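---
title: "Methods and modeling choices in qhtcp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modeling choices in qhtcp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtcp)
```

`qhtcp` implements the statistical pipeline of arrayed-colony phenomic
screening: per-spot growth-curve fitting, plate-standardized z-scores,
adjusted z-scores as gene–drug interaction estimates, a BIC-cut
hierarchical clustering of interaction profiles, Gene Ontology
over-representation, and a liquid-assay toolkit (4PL IC50, growth-curve
kinetics, ZIP synergy). This vignette explains the models, the tunable
parameters, the numerical choices, and what the synthetic benchmarks do
and do not establish.

## Growth model and fitting

Each spot's imaging time course is modeled as a symmetric logistic with a
constant background:

$$G(t) = b + \frac{K}{1 + e^{-r (t - L)}}$$

with $K$ the carrying capacity (intensity units), $r$ the maximum specific
growth rate (h⁻¹), $L$ the time to half capacity (h), and $b$ the imaging
background. The slope is maximal at $t = L$ with value $rK/4$ — the
identity used by the analytic self-tests.

**Why a fitted background rather than subtracting the series minimum.**
The first image of a culture already part-way into growth is
$b + K/(1+e^{rL})$, which is not close to $b$ when $rL$ is small
(e.g. 27% of $K$ at $r = 0.05$, $L = 20$). Subtracting the observed
minimum therefore biases $K$ downward by whatever growth preceded the
first image. A free $b$, bounded to $[0, \min y + 0.05\,\mathrm{range}]$,
recovers noiseless curves exactly and degrades gracefully under noise.
The cost is a mildly ill-conditioned Jacobian for saturated curves ($b$
and $K$ trade off through the early points only), which is why the fit
calls the damped Levenberg–Marquardt solver `minpack.lm::nls.lm` directly
on the residuals; the `nlsLM` wrapper's rank check rejects these fits even
when the solution is exact.

Starting values are data-driven and safe for monotone curves
($K_0$ = observed range, $L_0$ = time nearest the half-range crossing,
$r_0 = 4 \cdot \max(\text{slope})/K_0$), with box bounds
$K \in (0, 2\max y]$, $r \in (0, 5\ \mathrm{h^{-1}}]$,
$L \in [0, 2 t_{\max}]$. Fewer than 5 observations flags
`insufficient_data`; a dynamic range under 10% of the plate's median
dynamic range flags `non_grower` (a relative rule, so it adapts to imaging
gain); solver failure flags `poor_fit`. Flags never abort a screen.

Array-level QC fails a (plate, condition) array when more than 10% of
spots carry flags, or when any contiguous 4×4 window of the 16×24 grid
holds ≥ 8 failures — the signature of smears and pinning artifacts rather
than biology. Both thresholds are arguments of `qc_arrays()`.

$r$ is fitted and reported but never used for scoring: with a ~3.5 h
imaging cadence, $L$ is estimated far more precisely than $r$, and $K$
and $L$ carry the screen's phenotypes.

## Z-scores and interactions

Within each deletion array and condition,
$z = (\mathrm{CPP} - \mathrm{median\ of\ the\ array's\ valid\ CPPs}) /
\mathrm{sd}(\text{384-spot reference array})$. The median (computed over
converged, unflagged fits only) removes plate-level shifts; the
reference-strain array's standard deviation calibrates assay variation at
that condition. The matched reference array is named explicitly per
(deletion plate, condition) in the screen manifest — pairing is never
inferred, so silent mispairing cannot happen. The default manifest uses
one reference array per condition; how many reference arrays a screen
runs is a design choice the manifest records.

The interaction estimate is the adjusted z-score
$\mathrm{adj} = z_{\text{drug}} - z_{\text{untreated}}$: under a
proportional drug response both z-scores coincide and the interaction is
zero. Calling uses a symmetric threshold (default 2): suppressors have
$\mathrm{adjK} \ge 2$ or $\mathrm{adjL} \le -2$; enhancers the mirror
image. When rules conflict the larger |value| wins; an exact tie is
neutral. Raw adjusted values are always reported so users can re-threshold.

Duplicate ORF strains are scored per physical spot; they collapse to one
entry only in the enrichment background, and a duplicate assigned to two
clusters counts in each cluster's test list (once per cluster).

## Clustering and the BIC cut

Profiles (adjK and adjL at each drug dose; unperturbed z-scores carried
for display only) are clustered with Ward linkage on Euclidean distance
(average/complete linkage and correlation distance available). Features
are left unscaled: they are already z-standardized upstream and rescaling
would distort the screen's effect-size semantics. Entries missing more
than half the features are dropped and logged; remaining gaps take the
feature median.

Each candidate cut $k \in 1..k_{\max}$ (default 60) is scored by the BIC
of the spherical Gaussian mixture the cut parameterizes: component weights
and means from the hard assignment, one pooled variance, and the *mixture*
log-likelihood, with $p = kd + 1$ parameters and penalty $p\ln(nd)$. The
mixture likelihood is essential: a hard-assignment (classification)
likelihood rewards any split of even a perfectly homogeneous Gaussian
cloud far more than the penalty can offset, so it never selects small
$k$. With the mixture score, one spherical cloud yields $k = 1$, and five
planted clusters at 6-SD separation are recovered in 20/20 seeded
benchmarks with median adjusted Rand index ≈ 0.97. Ties in the BIC curve
resolve to the smallest $k$. Per-cluster variances sit behind
`pooled = FALSE`.

## Enrichment

Per cluster, each term with ≥ 2 background members is tested by one-sided
Fisher's exact test (the hypergeometric upper tail, via `phyper`); the
suite checks agreement with a brute-force log-binomial summation oracle to
10⁻¹⁰. BH correction uses `stats::p.adjust`. The correction family is
per-cluster by default — matching per-cluster reporting — with a
`scope = "global"` flag to pool all (cluster, term) tests. Reporting uses
q < 0.005, flagging each cluster's lowest-q term as representative
(alphabetical on ties). Annotations are taken as given (flat term→gene
table); an optional child→parent edge list enables ancestor propagation
to a fixed point.

## Dose–response and ZIP synergy

IC50 assays fit
$y = \mathrm{bottom} + (\mathrm{top}-\mathrm{bottom})/(1+(x/\mathrm{ec50})^{\mathrm{hill}})$
on log₁₀ dose; zero-dose wells anchor the untreated scale but stay out of
the logistic fit (log dose is undefined at 0). The reported IC50 is the
dose at which the fitted response is half the fitted untreated response,
which exceeds ec50 whenever the response floor is positive.

Liquid growth curves are smoothed with a centered moving average (default
3 points at 30-min reads) and differenced; lag is the time of maximum
slope and the maximum rate is that slope in absorbance×1000/min. On
noiseless logistic input both converge to $L$ and $rK/4$ within 1%.

ZIP synergy works on fractional inhibition. Monotherapy margins are fit
with a constrained logistic (baseline 0, maximum free in [0, 1]); the
zero-interaction expectation at a combination is
$y_1 + y_2 - y_1 y_2$; the observed response comes from potency-shifted
refits of each row and column with the baseline pinned to the
conditioning drug's fitted monotherapy effect and the two directions
averaged; $\delta$ = observed − expected in percentage points. Negative
inhibitions are retained, not clipped — clipping biases $\delta$ toward
zero near no-effect doses. Whenever a margin or conditional series is flat
(or the logistic cannot beat a constant), the fit degrades to the constant
mean, which keeps surfaces defined for inert drugs and makes the
flat-margin limit exact ($\delta$ equals the combination effect). On
noiseless Bliss-consistent matrices across Hill slopes 0.5–4 the entire
surface satisfies $|\delta| < 10^{-11}$; a planted 3×3 block of +15 points
under 1-point noise is localized with window mean within ±2. Window
search ties resolve to the lowest dose indices.

## The synthetic screen generator

`simulate_screen()` emulates the screen's statistical structure with known
truth. Per spot,
$K = K_0 (1+\Delta K_g)\, \mathrm{drugK}(c)\, (1+\mathrm{batch})(1+\mathrm{spot})$
and
$L = L_0 + \Delta L_g + \mathrm{drugL}(c) + \mathrm{interaction}_{g,c} + \mathrm{batch}_L + \mathrm{spot}_L$,
observed as $G(t)$ on a 3.5-h cadence over 120 h with lognormal (2%)
multiplicative and small additive intensity noise, plus a constant
background of 2. Reference arrays zero the gene effects. Defaults:
$K_0 = 100$, $r_0 = 0.2$ h⁻¹, $L_0 = 48$ h; drug effect 1/0.9/0.8 on $K$
and +0/+5/+10 h on $L$ at 0/10/20 µg/mL — so interactions are deviations
beyond this shared response; 30% of genes carry baseline defects
($\Delta K \in [-8\%, -2\%]$, $\Delta L \in [0.5, 4]$ h, i.e. fitness
z-scores up to roughly ±6, the magnitude real strong deletions show); 5%
enhancers and 5% suppressors with |effect| drawn from 4–12 reference-SD
units, planted on $L$ (the kinetic phenotype) and ramped 0/½/1 across the
dose ladder.

Two calibration choices deserve emphasis:

* **Reference-SD units.** `sd_unit_L` (0.8 h) and `sd_unit_K` (1.2) equal
  the fitted-CPP standard deviation of a reference array under the default
  noise model, measured once and frozen, so a planted "−6 SD" interaction
  lands near adjusted z = −6.
* **Reference arrays are noisier than deletion spots.** Reference spots
  carry independent spot-level variability (1.2% of $K$, 0.8 h on $L$)
  while replica-pinned deletion spots carry much less (0.15%, 0.1 h),
  reflecting independent inoculations versus high-density replica
  pinning. The z denominator then exceeds the per-spot estimation noise,
  null adjusted z-scores have SD ≈ 0.3–0.7, and the default ±2 calling
  threshold yields sensitivity ≈ 1 at ≥ 4 SD planted effects with a
  false-positive rate well under 2%. Had deletion spots matched
  reference-spot variability exactly, adjusted z-scores would have SD
  $\sqrt 2$ (the difference of two unit-variance z-scores) and a ±2
  threshold would be far too liberal — the matched-noise case is covered
  by a property test asserting exactly that $\sqrt2$ inflation. True
  Q-HTCP imager noise magnitudes are not published; all noise defaults
  are documented placeholders, set once, with every knob exposed in
  `screen_sim_config()`.

What the generator does **not** emulate: scanner image artifacts beyond
random dropout, spatial neighbor effects between colonies, condition- or
time-dependent noise, cadence jitter by default, and any real genetic
covariance structure (planted classes are the only structure). Passing the
synthetic benchmarks therefore shows the *statistical machinery* is
correct and calibrated under its stated model — not that any particular
biological screen meets those assumptions.

## Known limitations

* With a single 384-spot reference array per condition, the sampling error
  of that array's SD (~3.6%) multiplies every gene's fitness z-score. For
  strains with |z| ≈ 5 this adds a shared, random-sign offset of up to a
  few tenths to adjusted z-scores per screen; it averages out across
  screens (and the independence property is tested as a 5-seed average)
  but cannot be removed within one screen. Screens wanting tighter
  calibration should run replicate reference arrays and list them in the
  manifest.
* The BIC-selected $k$ on real screens depends on the (unknowable)
  likeness of profile clusters to spherical Gaussians; on heavy-tailed
  effect-size continua the cut is best read as a resolution choice, with
  the full BIC curve reported for inspection.
* ZIP conditional refits cap fitted inhibition at 1; uniform synergy
  planted on near-saturated combinations is attenuated accordingly.
* The 4PL IC50 is reported as NA when the fitted floor exceeds half the
  untreated response — no dose halves growth in that regime.

## Problem sizes used by the test suite

The self-tests run 500-curve parameter-recovery sweeps; three 500-gene
null screens and three 500-gene planted screens for calibration,
sensitivity and FPR; twenty 400-row planted 5-cluster benchmarks plus a
300-row single-Gaussian control; sixty random Fisher tables against the
brute-force oracle and 1000 random BH vectors; twenty random-annotation
null screens (800 genes, 20 clusters, 100 terms); and the full 4×4 Hill
grid of Bliss-consistent ZIP matrices. These sizes give each stochastic
check comfortable margins while keeping a full run to a couple of
minutes on one CPU; the same quantities at the same sizes are what
`scripts/acceptance.R` recomputes and reports.
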