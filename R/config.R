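# Cohort configuration: study design, effect structure, generator knobs.

#' Published cross-sectional fixed effects (default generating truth)
#'
#' Per-modality named vectors of the cross-sectional coefficient estimates
#' (dB; flags read as dB for presence vs absence) used as the default
#' generating truth of the packaged cross-sectional recovery scenario.
#'
#' Where a published point estimate contradicts its own symmetric 95%
#' confidence interval (an impossible output of the fitting software), the
#' default is the interval midpoint instead: mesopic pseudophakia (-0.30)
#' and mesopic refractile deposits (+0.63) here, and the scotopic
#' time-between-visits slope (+0.13) in
#' [fixed_effects_intervisit_defaults()].
#'
#' @return Named list with `mesopic` and `scotopic` coefficient vectors.
#' @export
fixed_effects_cross_sectional_defaults <- function() {
  list(
    mesopic = c(intercept = 5.06, age = -0.09, pseudophakic = -0.30,
                subRPE_drusen = -0.22, SDD = -0.38, PED = -1.30,
                vitelliform = -0.97, HRF = -0.89, refractile = 0.63,
                iRORA = -0.66, cRORA = -1.35),
    scotopic = c(intercept = 1.52, age = -0.04, pseudophakic = 0.03,
                 subRPE_drusen = -0.18, SDD = -0.37, PED = -1.23,
                 vitelliform = -0.66, HRF = -0.87, refractile = 0.37,
                 iRORA = -0.86, cRORA = 0.47)
  )
}

#' Published inter-visit fixed effects (default generating truth)
#'
#' Per-modality named vectors of the inter-visit change coefficients (dB per
#' unit, per year for `years_between_visits`, per SD for the layer z-score
#' slopes) used as the generating truth of the synthetic inter-visit
#' scenario. See [fixed_effects_cross_sectional_defaults()] for the
#' confidence-interval consistency rule applied to the scotopic
#' time-between-visits slope.
#'
#' @return Named list with `mesopic` and `scotopic` coefficient vectors.
#' @export
fixed_effects_intervisit_defaults <- function() {
  list(
    mesopic = c(intercept = 2.65, age = -0.04, years_between_visits = -0.49,
                pseudophakic = 0.72, subRPE_drusen = 0.12, SDD = 0.03,
                PED = 0.74, vitelliform = 0.52, HRF = -0.07,
                refractile = -0.13, iRORA = 0.94, cRORA = -0.24,
                z_RNFL = -0.07, z_GCL = -0.03, z_IPL = -0.01, z_INL = 0.06,
                z_OPL = 0.02, z_ONL = 0.07, z_IS = -0.001, z_OS = 0.002,
                z_RPEDC = -0.046),
    scotopic = c(intercept = 10.71, age = -0.15, years_between_visits = 0.13,
                 pseudophakic = 0.21, subRPE_drusen = -0.30, SDD = -0.06,
                 PED = 0.40, vitelliform = 1.17, HRF = 0.65,
                 refractile = -3.50, iRORA = 0.95, cRORA = -2.15,
                 z_RNFL = -0.01, z_GCL = 0.04, z_IPL = -0.02, z_INL = 0.02,
                 z_OPL = 0.02, z_ONL = 0.003, z_IS = -0.0001, z_OS = -0.01,
                 z_RPEDC = -0.0002)
  )
}

#' Default lesion parameters per biomarker
#'
#' Per-eye prevalence, lesion count range, basal diameter range (µm), lesion
#' height range (µm, where a height is meaningful), diameter growth per
#' year (µm), and onset: `"baseline"` lesions are present from the first
#' visit, `"followup"` lesions (the late-stage lesions refractile deposits
#' and cRORA, the latter excluded at baseline by the study design) develop
#' at a uniformly drawn later visit. Sizes respect the grading definitions:
#' PED basal diameter >= 1000 µm and height >= 200 µm; cRORA extent
#' >= 250 µm; iRORA extent < 250 µm.
#'
#' @return Data frame, one row per biomarker.
#' @export
lesion_params_defaults <- function() {
  data.frame(
    biomarker = fcp_biomarkers(),
    prevalence = c(0.95, 0.50, 0.45, 0.60, 0.25, 0.25, 0.40, 0.35),
    count_min = c(8, 10, 1, 3, 1, 1, 1, 1),
    count_max = c(30, 35, 2, 12, 2, 3, 4, 2),
    diameter_min_um = c(130, 80, 1000, 60, 200, 120, 100, 250),
    diameter_max_um = c(500, 220, 2200, 200, 500, 350, 240, 900),
    height_min_um = c(25, 15, 200, NA, NA, NA, NA, NA),
    height_max_um = c(110, 50, 480, NA, NA, NA, NA, NA),
    growth_um_per_year = c(25, 10, 60, 5, 20, 10, 15, 150),
    onset = c("baseline", "baseline", "baseline", "baseline", "baseline",
              "followup", "baseline", "followup"),
    row.names = NULL
  )
}

# smooth radial layer baselines: thickness(r) = a + b * exp(-((r - c)/d)^2)
layer_profile_defaults <- function() {
  data.frame(
    layer = fcp_layers(),
    a = c(5, 10, 20, 12, 18, 50, 25, 30, 25),
    b = c(25, 25, 15, 18, 8, 40, 8, 15, 8),
    c = c(12, 4, 3, 3, 2, 0, 0, 0, 0),
    d = c(8, 3, 3, 2, 2, 2.5, 3, 2, 3),
    between_eye_sd_um = c(1.5, 2.5, 2.0, 2.0, 2.0, 5.0, 1.5, 2.5, 1.98),
    row.names = NULL
  )
}

#' Cohort configuration for the synthetic generator
#'
#' Collects the full study design and generative effect structure: cohort
#' sizes, visit schedule, demographics, the per-modality fixed effects for
#' the cross-sectional and inter-visit generative models, random-effect SDs,
#' lesion parameters, the sensitivity dynamic range, and map geometry.
#'
#' The generator has two generative modes. In `"cross_sectional"` mode every
#' visit's sensitivities are drawn independently around the cross-sectional
#' linear predictor (the cross-sectional recovery scenario). In
#' `"intervisit"` mode the
#' baseline visit is drawn from the cross-sectional model and each
#' subsequent visit adds an increment drawn from the inter-visit change
#' model evaluated at the earlier visit's structure (the inter-visit
#' recovery scenario).
#'
#' @param n_patients_amd,n_eyes_amd,n_controls Cohort sizes. At most two
#'   eyes per patient.
#' @param n_visits_max Maximum visits per AMD eye (baseline included, <= 5).
#' @param visit_count_probs Probabilities of an AMD eye completing 1, ...,
#'   `n_visits_max` visits (defaults follow the study's attrition).
#' @param visit_interval_months Mean and SD of the gap between visits.
#' @param age_amd,age_controls Mean and SD of age (years), truncated to
#'   `age_range`.
#' @param age_range Admissible age range (years).
#' @param pseudophakic_fraction_amd,pseudophakic_fraction_controls
#'   Proportion of pseudophakic eyes.
#' @param right_eye_fraction Proportion of right eyes (mirrored to left-eye
#'   orientation during analysis).
#' @param fixed_effects_cross_sectional,fixed_effects_intervisit Named
#'   per-modality coefficient lists; see the `*_defaults()` functions.
#' @param random_effect_sds Named vector: `patient`, `visit`, `grid`,
#'   `residual` (dB) for the cross-sectional level process.
#' @param random_effect_sds_intervisit Same structure for the inter-visit
#'   increment process (dB per visit pair); `patient` here is a persistent
#'   per-patient progression-rate offset.
#' @param lesion_params Data frame as [lesion_params_defaults()].
#' @param sensitivity_range Floor and ceiling of the threshold scale (dB);
#'   generated values outside are clamped and flagged censored.
#' @param normative_mesopic,normative_scotopic Parameters `(level,
#'   foveal_dip, dip_radius_deg, quadratic)` of the latent normative mean
#'   sensitivity profile `level - foveal_dip * exp(-(r/dip_radius)^2) -
#'   quadratic * r^2`.
#' @param map_size_px,field_of_view_deg En-face map geometry.
#' @param um_per_deg Retinal scale for lesion sizes (emmetropic model eye).
#' @param layer_profiles Data frame of radial layer baselines, see source.
#' @param pixel_noise_sd_um Per-pixel thickness noise SD.
#' @param n_vessels,landmark_noise_sd_deg Landmark simulation parameters.
#' @param lesion_field_deg Half-width of the region lesion centers are drawn
#'   from.
#' @param generative_model `"cross_sectional"` or `"intervisit"`.
#' @param reader_flip_prob Optional reader-noise mode: probability that a
#'   graded presence flag used for generation is flipped.
#' @param grid A [stimulus_grid()].
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A validated object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients_amd = 49,
                          n_eyes_amd = 54,
                          n_controls = 27,
                          n_visits_max = 4,
                          visit_count_probs = c(15, 4, 7, 28) / 54,
                          visit_interval_months = c(mean = 12, sd = 2),
                          age_amd = c(mean = 70.7, sd = 9.1),
                          age_controls = c(mean = 63.4, sd = 8.9),
                          age_range = c(45, 85),
                          pseudophakic_fraction_amd = 14 / 54,
                          pseudophakic_fraction_controls = 3 / 27,
                          right_eye_fraction = 0.5,
                          fixed_effects_cross_sectional =
                            fixed_effects_cross_sectional_defaults(),
                          fixed_effects_intervisit =
                            fixed_effects_intervisit_defaults(),
                          random_effect_sds = c(patient = 1.5, visit = 0.5,
                                                grid = 0.8, residual = 1.5),
                          random_effect_sds_intervisit =
                            c(patient = 0.5, visit = 0.3, grid = 0.3,
                              residual = 1.0),
                          lesion_params = lesion_params_defaults(),
                          sensitivity_range = c(floor = 0, ceiling = 20),
                          normative_mesopic = c(level = 14, foveal_dip = 0,
                                                dip_radius_deg = 1,
                                                quadratic = 0.10),
                          normative_scotopic = c(level = 12, foveal_dip = 1.5,
                                                 dip_radius_deg = 1.2,
                                                 quadratic = 0.04),
                          map_size_px = 256,
                          field_of_view_deg = 30,
                          um_per_deg = 288,
                          layer_profiles = layer_profile_defaults(),
                          pixel_noise_sd_um = 1.5,
                          n_vessels = 8,
                          landmark_noise_sd_deg = 0.05,
                          lesion_field_deg = 6,
                          generative_model = c("cross_sectional",
                                               "intervisit"),
                          reader_flip_prob = 0,
                          grid = default_grid(),
                          seed = 1L) {
  generative_model <- match.arg(generative_model)
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_visits_max < 1 || n_visits_max > 5) {
      config_error("n_visits_max must be between 1 and 5")
    }
    if (n_patients_amd < 0 || n_eyes_amd < 0 || n_controls < 0) {
      config_error("cohort sizes must be non-negative")
    }
    if (n_eyes_amd > 2 * n_patients_amd) {
      config_error("n_eyes_amd exceeds two eyes per patient")
    }
    if (n_eyes_amd > 0 && n_eyes_amd < n_patients_amd) {
      config_error("n_eyes_amd must be at least n_patients_amd (one eye each)")
    }
    if (any(random_effect_sds < 0) || any(random_effect_sds_intervisit < 0)) {
      config_error("random-effect SDs must be >= 0")
    }
    if (length(visit_count_probs) != n_visits_max ||
        abs(sum(visit_count_probs) - 1) > 1e-8) {
      config_error("visit_count_probs must have n_visits_max entries summing to 1")
    }
    if (sensitivity_range[1] >= sensitivity_range[2]) {
      config_error("sensitivity floor must be below the ceiling")
    }
    lp <- lesion_params
    if (any(lp$diameter_min_um > lp$diameter_max_um, na.rm = TRUE) ||
        any(lp$diameter_min_um <= 0)) {
      config_error("lesion diameter ranges must be positive and ordered")
    }
    ped <- lp[lp$biomarker == "PED", ]
    if (nrow(ped) && (ped$diameter_min_um < 1000 || ped$height_min_um < 200)) {
      config_error("PED lesions require basal diameter >= 1000 um and height >= 200 um")
    }
    crora <- lp[lp$biomarker == "cRORA", ]
    if (nrow(crora) && crora$diameter_min_um < 250) {
      config_error("cRORA lesions require an extent >= 250 um")
    }
    irora <- lp[lp$biomarker == "iRORA", ]
    if (nrow(irora) && irora$diameter_max_um >= 250) {
      config_error("iRORA lesions require an extent < 250 um")
    }
    if (reader_flip_prob < 0 || reader_flip_prob > 1) {
      config_error("reader_flip_prob must be in [0, 1]")
    }
    invisible(NULL)
  })
}

#' Packaged default scenarios
#'
#' `default_config("table2")` is the cross-sectional parameter-recovery
#' scenario (54 AMD eyes of 49 patients, 27 controls, up to 4 visits,
#' cross-sectional generative model with the published coefficient
#' estimates as truth). `default_config("table3")` is the matching
#' inter-visit scenario (increments drawn from the published inter-visit
#' change coefficients).
#'
#' @param scenario `"table2"` or `"table3"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
default_config <- function(scenario = c("table2", "table3"), seed = 1L, ...) {
  scenario <- match.arg(scenario)
  cohort_config(
    generative_model = if (scenario == "table2") "cross_sectional" else "intervisit",
    seed = seed, ...)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d AMD eyes / %d patients, %d controls, <= %d visits, %s generative model, seed %d\n",
    x$n_eyes_amd, x$n_patients_amd, x$n_controls, x$n_visits_max,
    x$generative_model, x$seed))
  invisible(x)
}

#' Read / write a cohort configuration as YAML
#'
#' Scalar fields, named vectors and the lesion-parameter table are
#' serialized; the stimulus grid is stored as its center coordinates.
#'
#' @param config A [cohort_config()].
#' @param path File path.
#' @return `write_config_yaml` returns `path` invisibly; `read_config_yaml`
#'   a validated `cohort_config`.
#' @export
write_config_yaml <- function(config, path) {
  obj <- unclass(config)
  # named vectors must become maps, or YAML drops their names
  for (nm in c("visit_interval_months", "age_amd", "age_controls",
               "random_effect_sds", "random_effect_sds_intervisit",
               "sensitivity_range", "normative_mesopic",
               "normative_scotopic")) {
    obj[[nm]] <- as.list(obj[[nm]])
  }
  obj$fixed_effects_cross_sectional <-
    lapply(obj$fixed_effects_cross_sectional, as.list)
  obj$fixed_effects_intervisit <-
    lapply(obj$fixed_effects_intervisit, as.list)
  obj$lesion_params <- as.list(config$lesion_params)
  obj$layer_profiles <- as.list(config$layer_profiles)
  obj$grid <- list(centers_x = config$grid$centers[, 1],
                   centers_y = config$grid$centers[, 2],
                   mesopic_diameter_deg = config$grid$mesopic_diameter_deg,
                   scotopic_diameter_deg = config$grid$scotopic_diameter_deg,
                   extraction_diameter_deg = config$grid$extraction_diameter_deg)
  # 17 significant digits: bit-exact double round trip
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file not found: %s", path))
  obj <- yaml::read_yaml(path)
  obj$lesion_params <- as.data.frame(obj$lesion_params)
  obj$lesion_params$height_min_um <- as.numeric(obj$lesion_params$height_min_um)
  obj$lesion_params$height_max_um <- as.numeric(obj$lesion_params$height_max_um)
  obj$layer_profiles <- as.data.frame(obj$layer_profiles)
  g <- obj$grid
  obj$grid <- stimulus_grid(cbind(g$centers_x, g$centers_y),
                            mesopic_diameter_deg = g$mesopic_diameter_deg,
                            scotopic_diameter_deg = g$scotopic_diameter_deg,
                            extraction_diameter_deg = g$extraction_diameter_deg)
  for (nm in c("visit_count_probs", "visit_interval_months", "age_amd",
               "age_controls", "age_range", "random_effect_sds",
               "random_effect_sds_intervisit",
               "sensitivity_range", "normative_mesopic",
               "normative_scotopic")) {
    obj[[nm]] <- unlist(obj[[nm]])
  }
  obj$fixed_effects_cross_sectional <-
    lapply(obj$fixed_effects_cross_sectional, unlist)
  obj$fixed_effects_intervisit <- lapply(obj$fixed_effects_intervisit, unlist)
  cfg <- structure(obj, class = "cohort_config")
  validate_config(cfg)
  cfg
}
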