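# hp13c — kinetic analysis and simulation of hyperpolarized ¹³C-pyruvate MRI

Hyperpolarized [1-¹³C]pyruvate MRI images the enzymatic conversion of
injected pyruvate to lactate in vivo, a direct readout of the Warburg-like
metabolic phenotype of tumors. In clear cell renal cell carcinoma (ccRCC),
the apparent exchange rate constant *k*<sub>PL</sub> tracks WHO/ISUP tumor
grade and the expression of the pyruvate transporter MCT1, making it a
candidate non-invasive grading biomarker. `hp13c` implements the full
quantitative chain of such a study for R users — imaging scientists and
analysts working with dynamic metabolic MRI — together with a synthetic-data
module that makes every stage testable end to end without patient data
(which studies of this kind cannot share).

## The model and estimators

Label exchange is described by an input-driven two-site model. With
pyruvate signal *P*(*t*) treated as a measured input, the lactate signal
obeys

  d*L*/d*t* = *k*<sub>PL</sub> · *P*(*t*) − *L*(*t*) / *T*<sub>1,eff</sub>,

where *T*<sub>1,eff</sub> absorbs spin–lattice relaxation, back-conversion
and shared signal losses into one effective decay term. The package
estimates *k*<sub>PL</sub> by **frequency-domain linear least squares**: both
courses are detrended by their final value, zero-padded and transformed by
the DFT; the exchange model is imposed per frequency bin through the exact
first-order-hold discretization symbol and solved as an overdetermined
linear system over stacked real and imaginary parts. A bounded nonlinear
**time-domain oracle** (convolution model, profiled decay rate, multi-start)
provides an independent cross-check. For voxel-wise mapping of noisy data
the decay rate is fixed (default *T*<sub>1,eff</sub> = 30 s, corrected for
the known per-frame RF depletion cos(α)^(excitations) of the acquisition)
and the then-linear problem is solved on the complex post-combination
courses, avoiding the Rician noise-floor bias of magnitude fitting.

Around the estimator the package provides: SVD multi-coil combination from
time-summed complex data (matched-filter weights, unit norm, reference-coil
phase convention); metabolite SNR per the Rayleigh-corrected formula
SNR = (mean(SI<sub>ROI</sub>) − mean(SI<sub>noise</sub>)) / (√2 ·
S.D.(SI<sub>noise</sub>)); the SNR ≥ 5 fitting mask; polygonal and 3 cm
cylindrical biopsy ROIs (voxel-centre rasterization); H-DAB
immunohistochemistry quantification by optical-density classes at
thresholds 0.2164 / 0.3274 / 0.4938 (% positive tissue, cell density); and
cohort statistics (Spearman/Pearson with exact small-sample permutation
p-values, Wilcoxon rank tests, and a patient-blocked permutation F-test for
biopsy-level grade effects).

## Worked example

```r
library(hp13c)

## 1. Noiseless two-site exchange at the clear-cell carcinoma level
geom  <- acq_geometry()                  # 20 frames x 4 s, first frame at 12 s
bolus <- gamma_variate_bolus()           # peak 10 s post injection
sim <- simulate_two_site_exchange(kinetic_params(k_pl = 0.0065, t1_eff = 30),
                                  bolus, geom, rf_depletion = FALSE)
fit_kpl_frequency_domain(sim$pyruvate, sim$lactate, geom$frame_spacing)
#> kPL fit [frequency_domain]: k_pl = 0.0065798 /s, 1/t1_eff = 0.033584 /s (t1_eff = 29.8 s)
#>   residual norm 0.003785 over 20 frames

## 2. A noisy phantom through the full chain
g   <- cohort_geometry()                 # 32x32 single-slice, 4 coils
sc  <- default_phantom_scene(g, tumor_kpl = 0.0065, seed = 7)
sc$noise_sd <- noise_sd_for_snr(sc, bolus, g, target_snr = 27)
res <- analyze_patient_phantom(sc, g, bolus, patient_id = "P01")
res$tumor_summary[, c("label", "n_fitted", "kpl_median", "lac_pyr",
                      "snr_pyruvate", "snr_lactate")]
#>   label n_fitted kpl_median   lac_pyr snr_pyruvate snr_lactate
#> 1 tumor       60 0.00628996 0.0871241     27.02743   0.7805498

## 3. A six-patient synthetic cohort with a monotone grade -> kPL link
cohort  <- generate_cohort(n_patients = 6, seed = 42)
results <- run_cohort_pipeline(cohort)
stats   <- cohort_statistics(results, n_perm = 999, seed = 1)
stats$grade_kpl
#> spearman_rho = 0.9562, p = 0.02222 (n = 6) [mid-ranks; exact permutation (720)]
stats$blocked_grade
#> blocked_permutation_F = 1.699, p = 0.147 (n = 24) [within-patient permutation; n_perm = 999; seed = 1]
```

Reading the output: the noiseless fit recovers the simulated
*k*<sub>PL</sub> = 0.0065 s⁻¹ within 1.2% and the decay time within 1%; the
noisy phantom's tumor ROI lands at a pyruvate SNR of 27 with a median
mapped *k*<sub>PL</sub> 3% below truth; and on the synthetic cohort the
grade–*k*<sub>PL</sub> rank correlation is detected (exact permutation
p = 0.022), while the biopsy-level blocked test on this particular small
cohort (24 biopsies) does not reach significance — an honest reflection of
its power at this size.

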