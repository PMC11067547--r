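# fcpoct

Point-wise structure–function analysis of fundus-controlled perimetry (FCP,
microperimetry) and OCT en-face imaging in non-exudative age-related macular
degeneration (AMD).

In non-exudative AMD, multiple structural biomarkers — sub-RPE drusen,
subretinal drusenoid deposits (SDD), pigment epithelium detachments (PED),
hyper-reflective foci (HRF), vitelliform and refractile deposits, and
incomplete/complete RPE and outer retinal atrophy (iRORA/cRORA) — coexist in
one eye. This package quantifies how much localized retinal sensitivity
(mesopic and scotopic, in dB) is lost where each biomarker is present, and
how local function changes between annual visits, using spatially resolved
co-registration of the perimetry stimulus grid with OCT-derived retinal
layer thickness maps. It is written for retinal imaging researchers running
structure–function studies, and includes a full synthetic cohort generator
so the entire pipeline is testable without patient data.

## The model

At stimulus position *k* of eye *i* at visit *j*, the observed sensitivity
is normalized to the point-wise deviation from the control-cohort mean at
the same position (negative = loss), and layer thicknesses to z-scores
against the control mean and SD. The cross-sectional association model is a
linear mixed-effect model

    dev_ijk = α + β_age·age_i + β_pseudo·pseudo_i + Σ_b β_b·presence_b(i,j,k)
              + u_i + v_ij + w_k + ε_ijk

with random intercepts for patient (*u*), visit within eye (*v*) and grid
position (*w*); each β_b reads as the mean dB difference between affected
and unaffected positions. The inter-visit model regresses the change in
deviation between consecutive visits on the same exogenous variables taken
at the earlier visit, plus the years elapsed and the nine layer z-scores
(RNFL, GCL, IPL, INL, OPL, ONL, IS, OS, RPEDC). Models are fitted with
`lmerTest` (REML, Satterthwaite inference), mesopic and scotopic separately.

Upstream of the models: landmark-based registration (fovea, optic disc,
vessel bifurcations; weighted orthogonal-Procrustes similarity fit, right
eyes mirrored to left-eye orientation), extraction of disc means and
presence flags over the Goldmann-V stimulus area on a 56-point 10°×10°
grid, and control-based normalization with SD flooring.

## Worked example

Simulate the packaged cross-sectional scenario (54 AMD eyes of 49 patients,
27 controls, up to 4 annual visits) whose generating effects are the
published coefficient estimates, run the pipeline, and fit the mesopic
model:

```r
library(fcpoct)

cfg    <- default_config("table2", seed = 1)
cohort <- simulate_cohort(cfg)                 # ~20 s, deterministic
ext    <- extract_cohort(cohort)               # register + extract
ref    <- build_normative(ext$table[ext$table$group == "control", ])
amd    <- normalize_observations(ext$table[ext$table$group == "amd", ], ref)
fit    <- fit_cross_sectional(amd, model_spec("mesopic"))
print(compare_recovery(fit, cfg), digits = 2)
```

```
            term truth estimate    se    bias within_2se
1      intercept  5.06    3.675 1.433 -1.3849       TRUE
2            age -0.09   -0.072 0.021  0.0183       TRUE
3   pseudophakic -0.30   -0.405 0.210 -0.1046       TRUE
4  subRPE_drusen -0.22   -0.271 0.035 -0.0508       TRUE
5            SDD -0.38   -0.368 0.043  0.0116       TRUE
6            PED -1.30   -1.200 0.054  0.1000       TRUE
7            HRF -0.89   -0.880 0.057  0.0097       TRUE
8    vitelliform -0.97   -0.855 0.103  0.1147       TRUE
9     refractile  0.63    0.691 0.220  0.0610       TRUE
10         iRORA -0.66   -0.880 0.105 -0.2200      FALSE
11         cRORA -1.35   -1.440 0.113 -0.0895       TRUE
```

`truth` is the generating coefficient and `bias` the recovery error: on
this single simulated cohort, PED presence is estimated at −1.20 dB against
a configured −1.30 dB (SE 0.05), and ten of eleven effects sit within two
standard errors of truth (iRORA draws an unlucky 2.1 SE here; it averages
out across seeds, which is why the acceptance workflow below seed-averages
five cohorts). The intercept/age pair is confounded at the patient level
(49 patients), hence its wide interval. The inter-visit scenario works the
same way with `default_config("table3")`, `intervisit_differences()` and
`fit_intervisit()`.

The one-call version writes all tabular artifacts plus a run manifest:

```r
run_pipeline(default_config("table2", seed = 1), "out/")
```

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic cohort | `cohort_config()`, `default_config()`, `simulate_cohort()`, `simulate_thickness_stack()`, `simulate_landmarks()`, `lesion_set()` |
| Registration | `estimate_transform()`, `mirror_to_left()`, `map_stimuli()`, `register_visit()`, `transform2d()` |
| Extraction | `default_grid()`, `sample_disc_mean()`, `grade_presence()`, `extract_visit()`, `extract_cohort()` |
| Normalization | `build_normative()`, `sensitivity_deviation()`, `thickness_zscore()`, `normalize_observations()` |
| Models | `model_spec()`, `fit_cross_sectional()`, `intervisit_differences()`, `fit_intervisit()`, `compare_recovery()` |
| IO / pipeline | `read_/write_thickness_map()`, `read_/write_landmarks_csv()`, `read_/write_config_yaml()`, `write_model_csv()`, `run_pipeline()` |

The methods vignette (`vignettes/structure-function-methods.Rmd`) documents
the models, the generator's assumptions, and every design decision in
detail.
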