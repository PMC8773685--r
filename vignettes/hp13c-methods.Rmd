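---
title: "Models and methods behind hp13c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hp13c}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the kinetic
model and its assumptions, the estimators and their numerical design, the
conventions of every pipeline stage, what the synthetic-data generator does
and does not emulate, and the design choices made where the design was
genuinely open.

## The two-site exchange model

Hyperpolarized [1-¹³C]pyruvate is injected as a bolus; the ¹³C label
exchanges into lactate through lactate dehydrogenase. The package models
the signal pools from the injection time ($t = 0$, both pools empty) as

$$\frac{dP}{dt} = b(t) - \frac{P}{T_{1P}} - k_{PL} P, \qquad
  \frac{dL}{dt} = k_{PL} P - \frac{L}{T_{1,\mathrm{eff}}},$$

with a peak-normalized gamma-variate bolus $b(t)$. The lactate loss term
$1/T_{1,\mathrm{eff}}$ is an *effective* relaxation rate absorbing
spin–lattice relaxation, back-conversion of the label, and any loss shared
between pools; no separate back-rate is modelled, and the estimators never
see $T_{1P}$ — pyruvate enters estimation only as a measured input. This
input-driven unidirectional form is the standard low-SNR-practical reading
of two-site exchange.

Assumptions worth making explicit: (i) exchange is unidirectional at the
signal level (back-conversion is inside $T_{1,\mathrm{eff}}$); (ii) the
acquisition samples both metabolites simultaneously at a fixed frame
spacing; (iii) RF depletion acts as a per-frame multiplicative factor
$\cos(\alpha)^{E}$ ($E$ excitations per frame) shared by both metabolites.
At the frame times that factor is indistinguishable from an extra shared
exponential decay at rate $-\log(\cos^E\alpha)/\Delta t$, so it shifts the
*apparent* lactate decay rate while leaving $k_{PL}$ untouched; the
simulator applies it to the sampled courses and `effective_decay_rate()`
translates an assumed tissue $T_{1,\mathrm{eff}}$ into the decay rate of
the data.

## Frequency-domain linear least-squares estimation of kPL

`fit_kpl_frequency_domain()` detrends both courses by their final value,
zero-pads fourfold, applies the DFT, and imposes the exchange model per
frequency bin as a linear system solved by ordinary least squares over
stacked real and imaginary parts.

The derivative symbol is the part of such estimators that decides their
accuracy at a 4 s frame spacing. The textbook choice $i\omega_m$ is exact
only for the trigonometric interpolant of a periodic record; a record that
starts 12 s after injection with substantial signal has a large
periodic-extension jump, and we measured worst-case noiseless $k_{PL}$
errors of about 3–4% with that symbol across the parameter range of
interest — outside our 2% accuracy budget. The package therefore uses the
*exact first-order-hold discretization* of the lactate equation: over one
frame interval, with pyruvate linearly interpolated,

$$L_{k+1} = a L_k + k_{PL}\,(g_0 P_k + g_1 P_{k+1}), \qquad a = e^{-r\Delta t},$$

with closed-form gains $g_0, g_1$. In the frequency domain a one-sample
delay of the padded, detrended record is exactly multiplication by
$\bar z_m = e^{-i\omega_m \Delta t}$, so the relation becomes a per-bin
linear system in the reparameterized coefficients $(a, c_0, c_1)$, from
which $r = -\log(a)/\Delta t$ and
$k_{PL} = (c_0 + c_1)\,r/(1 - a)$ are recovered. Three exact nuisance
regressors (the DFTs of an all-ones column, of the dynamic-row indicator,
and of the record-edge indicator) absorb the two boundary rows and the
detrending constants; each appears twice (column and $i\cdot$column)
because those constants carry the data's phase. The DFT being unitary, this
per-bin least-squares problem is exactly equivalent to the corresponding
time-domain one — the frequency formulation is the natural home of the
method and costs nothing in accuracy. Measured on noiseless courses, worst-
case $k_{PL}$ error is below 2% over $k_{PL} \in [0.001, 0.02]$ s⁻¹,
$T_{1,\mathrm{eff}} \in [15, 45]$ s, and agreement with the independent
time-domain oracle is within 0.5%.

Negative estimates are returned as-is and flagged (`negative_kpl`,
`negative_decay`), never clipped; downstream medians use them unchanged.
Degenerate inputs have pinned behaviour: an identically zero pyruvate
course is an error (unidentifiable), an identically zero lactate course
returns $k_{PL} = 0$ with a flag.

### Joint versus fixed decay rate

Whether the clinical analysis fitted $T_{1,\mathrm{eff}}$ per voxel or
fixed it is not something the method description settles, so the package
supports both and chooses per use case:

* **Joint estimation** (`t1_eff = NULL`) solves for $(k_{PL}, r)$ together.
  On noiseless or high-SNR (e.g. ROI-averaged) courses this is accurate and
  assumption-light.
* **Fixed decay** (`t1_eff = <seconds>`) reduces the model to a single
  linear coefficient: the regressor is the first-order-hold convolution of
  the measured pyruvate course with the decay kernel, plus complex
  initial-condition and intercept nuisances. This is the configuration of
  `fit_kpl_map()` (default 30 s, RF-corrected), because joint per-voxel
  fitting is unstable at realistic lactate SNR: in our Monte-Carlo
  experiments at the study's pyruvate SNR level the joint fit's median
  $k_{PL}$ was biased by more than half its value, while the fixed-decay
  fit stayed within a few percent. The cost is a documented sensitivity:
  misspecifying $T_{1,\mathrm{eff}}$ by ±5 s moves $k_{PL}$ by roughly
  ∓7%.

### Complex-course fitting

Voxel-wise fitting consumes the *complex* post-combination courses rather
than magnitudes. At the study's SNR the per-frame lactate signal sits near
the magnitude noise floor, and the Rayleigh/Rician floor of magnitude data
destroys the linear structure of the model (we measured magnitude-domain
median biases of order −80% in that regime, versus a few percent for
complex fitting, whose noise is zero-mean). Real-valued (e.g. noiseless or
magnitude) courses remain fully supported — the estimator treats them as
complex numbers with zero imaginary part, and all real/imaginary stacking
reduces to the real calculation. A shared per-voxel phase (the natural
state after matched-filter combination) cancels exactly.

### The time-domain oracle

`fit_kpl_time_domain_oracle()` is a deliberately different route used to
cross-check the frequency-domain fit: it models
$L(t) = L(t_1)e^{-r(t-t_1)} + k_{PL}\int_{t_1}^{t} P(\tau) e^{-r(t-\tau)}
d\tau$ with pyruvate linearly interpolated on a fine grid (trapezoidal
quadrature), profiles $k_{PL}$ out in closed form at each candidate rate,
and minimizes over $r \in [1/120, 1]$ s⁻¹ by bounded optimization from
four starting points with a bracketed polish; $k_{PL}$ is clamped to
$[0, 0.1]$ s⁻¹. The initial-condition term uses the observed first sample —
the record begins 12 s post injection with lactate already present, and
omitting the term makes accurate recovery impossible.

## Coil combination and metabolite maps

`compute_coil_weights()` forms, per voxel, the matrix of complex data
summed over all time points (both metabolites as rows, optionally a square
spatial neighborhood stacked in, default 1×1) by coils, and takes the
conjugate of its dominant right-singular vector as the weight vector —
a matched filter that captures the full array energy of rank-one data.
Weights have unit norm and the reference coil's weight is made real and
non-negative. Summing over time before computing weights minimizes noise
propagation into them; because combination is linear and the same weights
are applied to every frame, combining-then-summing equals
summing-then-combining, so the time-summed maps inherit the low-noise
weights exactly. No noise-covariance whitening is applied (the simulator's
coil noise is white); with real array data a whitening step would precede
the SVD.

Metabolite maps take the complex sum over frames first and the magnitude
last; total carbon is defined as the voxel-wise sum of the pyruvate and
lactate magnitude maps, which keeps the additivity property testable.

## SNR, noise estimation and the fitting mask

SNR follows the Rayleigh-corrected background formula
$(\mathrm{mean}(SI_{ROI}) - \mathrm{mean}(SI_{noise}))/(\sqrt 2\,
\mathrm{S.D.}(SI_{noise}))$; it may be negative, and it is exactly offset-
and scale-equivariant. Background statistics are estimated from an
extracorporeal region (at least 100 voxels) *per map* — the background
level of the total-carbon map differs from that of its components. One
subtlety the package embraces rather than hides: on pure-background voxels
the SVD weights align with the noise itself, so the combined background
follows the top-singular-value statistics of a small complex Gaussian
matrix, not a plain Rayleigh law; `noise_sd_for_snr()` calibrates simulated
noise levels against exactly this empirical procedure, because that is also
how a study measures its reported SNR. The fitting mask retains voxels
whose single-voxel total-carbon SNR is at least 5, inclusive at the
boundary.

## Regions of interest

Polygons (per-slice vertex lists in physical mm, checked for
self-intersection) and cylinders (default 30 mm diameter and height,
centred on biopsy coordinates) rasterize by *voxel-centre inclusion*:
0-based indices, centres at $(\mathrm{index}+0.5)\cdot$ voxel size
in-plane, slice centres at index · slice pitch. Boundary ties — a centre
exactly on a polygon edge or at distance exactly the radius — are
included; the convention is pinned by tests. At the default geometry (5 mm
gap, 30 mm slices) the 35 mm slice pitch means a 30 mm-high cylinder
centred on a slice covers exactly that slice. Biopsy coordinates are taken
as given inputs (the physical mold-based co-registration that produces
them is outside the package's scope). Patient-level aggregation applies
the inclusion rule *viable tumor fraction ≥ 0.75* (exclusion is strict
`<`), then takes per-patient medians to compensate for spatially
heterogeneous expression.

## Immunohistochemistry quantification

The quantifier is an open, documented reconstruction of commercial
area-quantification tooling: Beer–Lambert optical densities
($OD = -\log_{10}(I/I_0)$, zero-intensity pixels clamped at OD 3), linear
least-squares color deconvolution onto the standard H-DAB unit stain
vectors, a tissue mask at total OD ≥ 0.05, and DAB intensity classes with
*inclusive lower bounds* at OD 0.2164 / 0.3274 / 0.4938. Percent positive
tissue is the weak+moderate+strong area over the tissue area. Cell
counting is deliberately simplified — 8-connected components of
hematoxylin OD ≥ 0.3 with a minimum area — an honest stand-in rather than
a nucleus-segmentation claim. The generator and quantifier share one stain
matrix, so synthetic round trips are exact up to 8-bit quantization; real
slides would require stain-vector calibration before these defaults are
trusted.

## The synthetic-data module

The generator exists so that every downstream stage has known ground
truth. It emulates: a gamma-variate bolus arriving before the first frame
(default peak at 10 s); unidirectional exchange with effective lactate
relaxation (default $T_{1,\mathrm{eff}}$ = 30 s, a conventional value —
the true in-vivo decay is not an observable of this package); per-frame RF
depletion at 15° with five excitations per frame; ring-array complex coil
sensitivities; independent complex Gaussian coil noise; crisp region
phantoms (body, kidney, tumor, embedded disjoint biopsy subregions); H-DAB
micrographs with pixel-exact class areas and non-overlapping nuclei placed
by dart throwing (the realized count is the ground truth); and cohorts
whose grade→kPL link is monotone lognormal (defaults spanning
0.003–0.013 s⁻¹ across grades 1–4, scatter 0.10 on the log scale) with a
linear kPL→MCT1 link.

Equally important is what it does **not** emulate, and hence what passing
tests do not show about real data: no k-space trajectory or chemical-shift
reconstruction artifacts; no spatial blurring (real reconstructions
interpolate a 17 mm true resolution onto a fine grid, producing strongly
correlated noise — the phantom's noise is white); no partial-volume mixing
at region edges; no perfusion heterogeneity or bolus dispersion within a
region; no pyruvate-hydrate or alanine resonances; and histology images
with idealized, non-overlapping nuclei. One visible consequence: at the
generator's defaults the summed-map lactate SNR at the ccRCC exchange
level sits near 1–3, lower than typical clinical reports — the white-noise
phantom gives no credit for spatial correlation. The estimator stack is
validated *under these stated conditions*, not beyond them.

Seeding: every stochastic operation is a pure function of its inputs and
an integer seed, executed under a local RNG state so callers' streams are
untouched.

## Cohort statistics

Correlations use mid-ranks for ties; Spearman p-values are exact (full
permutation enumeration) for $n \le 8$ and t-approximate beyond. Rank-sum
and signed-rank tests enumerate their exact null for combined $n \le 10$
nonzero observations (two-sided doubling convention) and use tie-corrected
normal approximations with continuity correction otherwise.

The biopsy-level grade effect is tested by a **patient-blocked permutation
F-test**: least squares of kPL on patient indicators plus numeric-ordinal
grade, partial F for grade, null distribution by permuting grade labels
within each patient block, $p = (1 + \#\{F^\ast \ge F\})/(1 + n_{perm})$
(default $n_{perm} = 9999$, seed mandatory). This replaces mixed-model or
ordinal-ANOVA formulations whose exact specification is not available to
reconstruct: the permutation test is self-contained, assumption-light, and
targets the same null (no grade effect after accounting for patient).
Blocks are processed in order of first appearance so the permutation
stream — and hence the p-value — is invariant to relabeling patients; the
block structure makes it exactly invariant to adding per-patient
constants. A caveat stated plainly: with a strongly discrete grade
distribution, permutations can reproduce the observed F (e.g. by mirroring
a symmetric within-block pattern), so the minimum attainable p-value is
only reached when the observed alignment is strictly unmatched.

## Numerical choices and problem sizes

* ODE integration: `deSolve::lsoda` at tight tolerances (rtol 1e-9); the
  simulator refuses output steps coarser than a tenth of the frame
  spacing.
* DFT zero-padding factor 4; detrending by the final value (also removes
  most of any residual constant floor in noisy courses).
* Oracle quadrature step 0.02 s; optimizer L-BFGS-B with four starts and a
  golden-section polish; failures of individual starts are tolerated,
  failure of all is an error.
* Rasterization boundary epsilon 1e-9 mm for edge inclusion.
* IHC generation keeps a 0.02 OD margin from class boundaries so 8-bit
  quantization (OD error ≲ 0.003 at the relevant intensities) cannot move
  a pixel across a class.
* Test and validation problem sizes are scaled for a desk machine: phantom
  grids of 32×32 (single slice, 4 coils) for cohort work, with the
  clinical timing, flip angle and five-excitation RF schedule retained;
  full 128×128, 8-coil, 5-slice geometries remain the constructor
  defaults. Cohort validation uses 100 seeded six-patient cohorts and a
  500-replicate null calibration of the blocked test at
  $n_{perm} = 199$, chosen so that $p \le 0.05$ is exactly attainable.

## Known limitations

* The frequency-domain and oracle estimators share the assumption of
  linear pyruvate interpolation between frames; both inherit a small
  common discretization bias (≈1% at the default geometry, larger if the
  sampled courses include strong per-frame depletion, where the effective
  decay is fast relative to the 4 s spacing).
* Fixed-decay mapping trades a variance catastrophe for a documented
  sensitivity to the assumed $T_{1,\mathrm{eff}}$.
* The IHC quantifier's defaults are only exact against its paired
  generator; real-slide use needs stain calibration and a real nucleus
  segmenter.
* The phantom's white, uncorrelated noise and crisp regions make
  voxel-level estimator variance *pessimistic* relative to smoothed
  clinical reconstructions at matched map SNR, and region-level medians
  optimistic (no partial volume).
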