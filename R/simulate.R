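# Synthetic cohort generator: landmarks, lesions, en-face thickness maps and
# sensitivities drawn from the configured mixed-effects structure.

map_geometry <- function(config) {
  n <- config$map_size_px
  list(
    dim_px = c(n, n),
    px_per_deg = n / config$field_of_view_deg,
    origin_px = c((n - 1) / 2, (n - 1) / 2)
  )
}

# degree coordinates of every pixel center (matrices shaped like the map)
pixel_coords <- function(geom) {
  n_row <- geom$dim_px[1]; n_col <- geom$dim_px[2]
  x <- (seq_len(n_col) - 1 - geom$origin_px[1]) / geom$px_per_deg
  y <- (seq_len(n_row) - 1 - geom$origin_px[2]) / geom$px_per_deg
  list(x = matrix(x, n_row, n_col, byrow = TRUE),
       y = matrix(y, n_row, n_col))
}

.fcpoct_cache <- new.env(parent = emptyenv())

# radial baseline thickness maps, memoized on the geometry + profile table
baseline_layers <- function(config) {
  geom <- map_geometry(config)
  key <- paste(config$map_size_px, config$field_of_view_deg,
               paste(unlist(config$layer_profiles[, c("a", "b", "c", "d")]),
                     collapse = ","), sep = "|")
  hit <- .fcpoct_cache$baseline
  if (!is.null(hit) && identical(hit$key, key)) return(hit$value)
  pc <- pixel_coords(geom)
  r <- sqrt(pc$x^2 + pc$y^2)
  prof <- config$layer_profiles
  value <- lapply(seq_len(nrow(prof)), function(i) {
    with(prof[i, ], pmax(a + b * exp(-((r - c) / d)^2), 0))
  })
  names(value) <- prof$layer
  .fcpoct_cache$baseline <- list(key = key, value = value)
  value
}

normative_profile <- function(params, r) {
  params[["level"]] -
    params[["foveal_dip"]] * exp(-(r / params[["dip_radius_deg"]])^2) -
    params[["quadratic"]] * r^2
}

# --- lesions -----------------------------------------------------------------

#' Construct a lesion set
#'
#' Holds per-biomarker lesion lists (centers in degrees, basal diameter and,
#' where meaningful, height in micrometers) together with binary masks
#' rasterized on the en-face map geometry (a pixel is covered when its
#' center lies within the lesion circle).
#'
#' @param lesions Data frame with columns `biomarker`, `x_deg`, `y_deg`,
#'   `diameter_um`, `height_um` (NA where not applicable).
#' @param config A [cohort_config()] supplying the map geometry and the
#'   degree-micrometer scale.
#' @param laterality Orientation the masks are expressed in.
#' @return An object of class `lesion_set`.
#' @export
lesion_set <- function(lesions, config, laterality = "left") {
  geom <- map_geometry(config)
  stopifnot(is.data.frame(lesions))
  masks <- stats::setNames(vector("list", length(fcp_biomarkers())),
                           fcp_biomarkers())
  if (nrow(lesions)) {
    pc <- NULL
    for (b in unique(lesions$biomarker)) {
      sub <- lesions[lesions$biomarker == b, ]
      m <- matrix(FALSE, geom$dim_px[1], geom$dim_px[2])
      for (i in seq_len(nrow(sub))) {
        dp <- disc_pixels(geom$dim_px, geom$px_per_deg, geom$origin_px,
                          c(sub$x_deg[i], sub$y_deg[i]),
                          sub$diameter_um[i] / config$um_per_deg)
        m[dp$idx] <- TRUE
      }
      masks[[b]] <- m
    }
  }
  structure(
    list(lesions = lesions, masks = masks,
         px_per_deg = geom$px_per_deg, origin_px = geom$origin_px,
         dim_px = geom$dim_px, laterality = laterality),
    class = "lesion_set"
  )
}

empty_lesion_df <- function() {
  data.frame(biomarker = character(0), x_deg = numeric(0), y_deg = numeric(0),
             diameter_um = numeric(0), height_um = numeric(0))
}

# Sample an eye's baseline lesions. Follow-up-onset biomarkers (late-stage
# lesions; cRORA is excluded at baseline by the study design) are assigned a
# uniformly drawn later onset visit; iRORA lesions are placed disjoint from
# any cRORA lesion at its maximal (last-visit) extent.
sample_eye_lesions <- function(config, n_visits) {
  lp <- config$lesion_params
  if (is.null(lp$onset)) lp$onset <- "baseline"
  L <- config$lesion_field_deg
  years_max <- (n_visits - 1)  # nominal annual visits, for max extent
  rows <- list()
  crora <- NULL
  for (i in seq_len(nrow(lp))) {
    p <- lp[i, ]
    if (stats::runif(1) > p$prevalence) next
    if (p$onset == "followup" && n_visits < 2) next
    k <- p$count_min + sample.int(p$count_max - p$count_min + 1L, 1) - 1L
    d <- stats::runif(k, p$diameter_min_um, p$diameter_max_um)
    h <- if (!is.na(p$height_min_um)) {
      stats::runif(k, p$height_min_um, p$height_max_um)
    } else rep(NA_real_, k)
    x <- stats::runif(k, -L, L)
    y <- stats::runif(k, -L, L)
    onset <- if (p$onset == "followup") {
      sample(seq_len(n_visits - 1), k, replace = TRUE)
    } else rep(0L, k)
    df <- data.frame(biomarker = p$biomarker, x_deg = x, y_deg = y,
                     diameter_um = d, height_um = h,
                     growth_um_per_year = p$growth_um_per_year,
                     onset_visit = onset)
    if (p$biomarker == "cRORA") crora <- df
    rows[[length(rows) + 1L]] <- df
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    cbind(empty_lesion_df(), growth_um_per_year = numeric(0),
          onset_visit = integer(0))
  # enforce iRORA / cRORA disjointness at maximal extent
  if (!is.null(crora) && any(out$biomarker == "iRORA")) {
    ir <- which(out$biomarker == "iRORA")
    keep <- rep(TRUE, length(ir))
    for (j in seq_along(ir)) {
      li <- out[ir[j], ]
      r_i <- (li$diameter_um + li$growth_um_per_year * years_max) / 2
      for (m in seq_len(nrow(crora))) {
        r_c <- (crora$diameter_um[m] +
                  crora$growth_um_per_year[m] * years_max) / 2
        dist_um <- sqrt((li$x_deg - crora$x_deg[m])^2 +
                          (li$y_deg - crora$y_deg[m])^2) * config$um_per_deg
        # center-distance test suffices: masks are subsets of the circles
        if (dist_um < r_i + r_c) keep[j] <- FALSE
      }
    }
    if (any(!keep)) out <- out[-ir[!keep], ]
  }
  rownames(out) <- NULL
  out
}

# Lesion table as of a given visit: growth applied, pre-onset lesions hidden.
lesions_at_visit <- function(baseline_lesions, visit_index, years_elapsed) {
  df <- baseline_lesions[baseline_lesions$onset_visit <= visit_index, ,
                         drop = FALSE]
  if (nrow(df)) {
    yrs <- pmax(years_elapsed, 0)
    df$diameter_um <- df$diameter_um + df$growth_um_per_year * yrs
  }
  df[, c("biomarker", "x_deg", "y_deg", "diameter_um", "height_um")]
}

# --- thickness maps ----------------------------------------------------------

#' Simulate an en-face thickness stack
#'
#' Each of the nine layers is a smooth radial baseline profile plus an
#' eye-level offset and independent per-pixel noise. Drusen-spectrum lesions
#' (sub-RPE drusen, SDD, PED) add smooth radial bumps to the RPE-drusen
#' complex, peaking at the lesion height at its center; atrophy lesions
#' (iRORA mildly, cRORA strongly) thin the ONL, OS and RPEDC inside the
#' lesion mask. All thicknesses are clamped at zero.
#'
#' @param lesions A [lesion_set()] on the configured geometry (left-eye
#'   orientation), or `NULL` for a lesion-free eye.
#' @param config A [cohort_config()].
#' @param layer_offsets Named numeric vector of per-layer eye offsets (µm);
#'   drawn from the configured between-eye SDs when `NULL`.
#' @param pixel_noise_sd_um Per-pixel noise SD; defaults to the configured
#'   value.
#' @return A left-eye [thickness_stack()].
#' @export
simulate_thickness_stack <- function(lesions, config, layer_offsets = NULL,
                                     pixel_noise_sd_um = NULL) {
  geom <- map_geometry(config)
  if (!is.null(lesions) &&
      (!identical(lesions$dim_px, geom$dim_px) ||
       !isTRUE(all.equal(lesions$px_per_deg, geom$px_per_deg)))) {
    config_error("lesion masks do not share the configured map geometry")
  }
  base <- baseline_layers(config)
  prof <- config$layer_profiles
  if (is.null(layer_offsets)) {
    layer_offsets <- stats::setNames(
      stats::rnorm(nrow(prof), 0, prof$between_eye_sd_um), prof$layer)
  }
  noise_sd <- pixel_noise_sd_um %||% config$pixel_noise_sd_um
  npx <- prod(geom$dim_px)
  layers <- lapply(prof$layer, function(l) {
    m <- base[[l]] + layer_offsets[[l]]
    if (noise_sd > 0) m <- m + stats::rnorm(npx, 0, noise_sd)
    m
  })
  names(layers) <- prof$layer
  if (!is.null(lesions) && nrow(lesions$lesions)) {
    pc <- pixel_coords(geom)
    bump_set <- lesions$lesions[lesions$lesions$biomarker %in%
                                  c("subRPE_drusen", "SDD", "PED"), ]
    for (i in seq_len(nrow(bump_set))) {
      les <- bump_set[i, ]
      h <- les$height_um
      if (is.na(h)) next
      r_deg <- les$diameter_um / config$um_per_deg / 2
      dx <- pc$x - les$x_deg; dy <- pc$y - les$y_deg
      d2 <- dx^2 + dy^2
      in_l <- d2 < r_deg^2
      if (!any(in_l)) next
      # smooth radial bump, peak = lesion height at its center
      bump <- 0.5 * h * (1 + cos(pi * sqrt(d2[in_l]) / r_deg))
      layers$RPEDC[in_l] <- layers$RPEDC[in_l] + bump
    }
    thin <- list(iRORA = c(ONL = 0.75, OS = 0.70, RPEDC = 0.85),
                 cRORA = c(ONL = 0.35, OS = 0.25, RPEDC = 0.50))
    for (b in names(thin)) {
      mask <- lesions$masks[[b]]
      if (is.null(mask) || !any(mask)) next
      for (l in names(thin[[b]])) {
        layers[[l]][mask] <- layers[[l]][mask] * thin[[b]][[l]]
      }
    }
  }
  layers <- lapply(layers, function(m) {
    m[m < 0] <- 0
    m
  })
  thickness_stack(layers, geom$px_per_deg, geom$origin_px, "left",
                  validate = FALSE)
}

# --- landmarks ---------------------------------------------------------------

#' Simulate a corresponding landmark pair
#'
#' Places OCT-frame landmarks (fovea at the origin, optic disc near
#' (-15.5, -1.5) degrees in left-eye orientation, vessel bifurcations
#' scattered over the posterior pole) and produces the FCP-frame set by
#' applying the true transform plus isotropic Gaussian noise.
#'
#' @param true_transform [transform2d()] mapping OCT to FCP coordinates in
#'   the eye's own (device) orientation.
#' @param n_vessels Number of vessel bifurcations (>= 2).
#' @param noise_sd_deg Isotropic landmark placement noise SD (degrees).
#' @param laterality `"left"` or `"right"`; right-eye landmark sets are in
#'   mirrored (device) orientation.
#' @return List with `oct` and `fcp` [landmark_set()]s.
#' @export
simulate_landmarks <- function(true_transform, n_vessels = 8,
                               noise_sd_deg = 0.05, laterality = "left") {
  if (n_vessels < 2) config_error("n_vessels must be >= 2")
  fovea <- c(0, 0)
  disc <- c(-15.5, -1.5)
  ang <- stats::runif(n_vessels, 0, 2 * pi)
  rad <- stats::runif(n_vessels, 4, 12)
  vessels <- cbind(rad * cos(ang), rad * sin(ang))
  if (laterality == "right") {
    disc[1] <- -disc[1]
    vessels[, 1] <- -vessels[, 1]
  }
  oct <- landmark_set(fovea, disc, vessels, frame_id = "OCT",
                      laterality = laterality)
  pts <- apply_transform(invert_transform(true_transform),
                         landmark_matrix(oct))
  # note: true_transform maps FCP -> OCT, so FCP landmarks are the inverse
  # image of the OCT landmarks, plus placement noise
  noise <- matrix(stats::rnorm(2 * nrow(pts), 0, noise_sd_deg), ncol = 2)
  pts <- pts + noise
  fcp <- landmark_set(pts[1, ], pts[2, ], pts[-(1:2), , drop = FALSE],
                      frame_id = "FCP", laterality = laterality)
  list(oct = oct, fcp = fcp)
}

# Small random FCP->OCT similarity: near-unit scale, a few degrees of
# rotation, sub-degree translation (test-retest placement variability).
random_true_transform <- function() {
  s <- stats::runif(1, 0.95, 1.05)
  th <- stats::runif(1, -3, 3) * pi / 180
  b <- stats::runif(2, -0.5, 0.5)
  transform2d(s * rot2(th), b)
}

# --- cohort ------------------------------------------------------------------

draw_truncated <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  guard <- 0
  while (length(bad) && guard < 1000) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
    guard <- guard + 1
  }
  pmin(pmax(out, lo), hi)
}

# Dummy sensitivities so extract_visit() can be reused for structural
# grading during generation.
placeholder_sens <- function(n) {
  matrix(0, n, 4, dimnames = list(NULL, c("mesopic", "scotopic",
                                          "mes_censored", "scot_censored")))
}

#' Simulate a complete synthetic cohort
#'
#' Generates a control cohort and an AMD cohort with, per visit: landmark
#' sets in both frames, a nine-layer en-face thickness stack, a lesion set,
#' and 56 mesopic + 56 scotopic sensitivities. Controls carry no lesions and
#' their sensitivities scatter around the latent positional normative
#' profile, so the control cohort defines the normative reference.
#'
#' AMD sensitivities follow the configured mixed-effects structure: latent
#' normative mean + fixed effects (intercept, age, pseudophakia, biomarker
#' presence) + patient, visit and grid-point random intercepts + residual
#' noise, clamped to the dynamic range (clamped values are flagged
#' censored). Presence flags entering the generative model are the *graded*
#' flags: the extraction module's grading of the simulated lesion masks at
#' the true stimulus positions, so that downstream recovery through the same
#' grading is unbiased. In `"intervisit"` mode, follow-up visits instead
#' accumulate increments drawn from the inter-visit change model evaluated
#' at the earlier visit's graded structure (including layer z-scores against
#' the simulated controls' normative reference).
#'
#' The whole cohort is a deterministic function of the configuration,
#' including its seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `fcp_cohort`: list with `config`, `grid`,
#'   `eyes` (one row per eye) and `visits` (list of visit records).
#' @export
simulate_cohort <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  grid <- config$grid
  n_pts <- nrow(grid$centers)
  perm <- mirror_permutation(grid)
  r_k <- sqrt(rowSums(grid$centers^2))
  norm_mes <- normative_profile(config$normative_mesopic, r_k)
  norm_scot <- normative_profile(config$normative_scotopic, r_k)
  sds <- config$random_effect_sds
  rng_floor <- config$sensitivity_range[1]
  rng_ceil <- config$sensitivity_range[2]
  w_mes <- stats::rnorm(n_pts, 0, sds[["grid"]])
  w_scot <- stats::rnorm(n_pts, 0, sds[["grid"]])
  prof <- config$layer_profiles

  clamp_sens <- function(mes, scot) {
    cbind(mesopic = pmin(pmax(mes, rng_floor), rng_ceil),
          scotopic = pmin(pmax(scot, rng_floor), rng_ceil),
          mes_censored = as.numeric(mes < rng_floor | mes > rng_ceil),
          scot_censored = as.numeric(scot < rng_floor | scot > rng_ceil))
  }

  eyes <- list()
  visits <- list()

  make_visit <- function(patient_id, eye_id, visit_index, months, age,
                         pseudophakic, laterality, group, stack, lesions,
                         lms, true_tr, sens_left, gen_flags = NULL) {
    # Everything is generated in left-eye orientation; right-eye artifacts
    # are stored mirrored (as acquired) and the sensitivity table re-indexed
    # to the device grid.
    sens <- sens_left
    if (laterality == "right") {
      # reflection is its own inverse, so "mirroring" the left-frame data
      # once produces the as-acquired right-eye orientation
      stack <- mirror_to_left(stack, "right")
      stack$laterality <- "right"
      if (!is.null(lesions)) {
        lesions <- mirror_to_left(lesions, "right")
        lesions$laterality <- "right"
      }
      sens <- sens_left[perm, , drop = FALSE]
    }
    list(patient_id = patient_id, eye_id = eye_id, visit_index = visit_index,
         months_since_baseline = months, nd_filter = 2.0, age = age,
         pseudophakic = pseudophakic, laterality = laterality, group = group,
         stack = stack, lesions = lesions,
         landmarks_oct = lms$oct, landmarks_fcp = lms$fcp,
         true_transform = true_tr, sensitivities = sens,
         gen_flags = gen_flags)  # left-frame grid indexing
  }

  # ---- controls -------------------------------------------------------------
  ctrl_obs <- NULL
  if (config$n_controls > 0) {
    ages_c <- draw_truncated(config$n_controls, config$age_controls[["mean"]],
                             config$age_controls[["sd"]],
                             config$age_range[1], config$age_range[2])
    pseudo_c <- stats::runif(config$n_controls) <
      config$pseudophakic_fraction_controls
    lat_c <- ifelse(stats::runif(config$n_controls) <
                      config$right_eye_fraction, "right", "left")
    for (i in seq_len(config$n_controls)) {
      pid <- sprintf("C%02d", i)
      eid <- sprintf("C%02d_OD", i)
      u_mes <- stats::rnorm(1, 0, sds[["patient"]])
      u_scot <- stats::rnorm(1, 0, sds[["patient"]])
      offsets <- stats::setNames(
        stats::rnorm(nrow(prof), 0, prof$between_eye_sd_um), prof$layer)
      tr_dev <- random_true_transform()
      lms <- simulate_landmarks(tr_dev, config$n_vessels,
                                config$landmark_noise_sd_deg, lat_c[i])
      stack_left <- simulate_thickness_stack(NULL, config, offsets)
      v <- stats::rnorm(1, 0, sds[["visit"]])
      v2 <- stats::rnorm(1, 0, sds[["visit"]])
      mes <- norm_mes + w_mes + u_mes + v +
        stats::rnorm(n_pts, 0, sds[["residual"]])
      scot <- norm_scot + w_scot + u_scot + v2 +
        stats::rnorm(n_pts, 0, sds[["residual"]])
      visits[[length(visits) + 1L]] <-
        make_visit(pid, eid, 0L, 0, ages_c[i], pseudo_c[i], lat_c[i],
                   "control", stack_left, NULL, lms, tr_dev,
                   clamp_sens(mes, scot))
      eyes[[length(eyes) + 1L]] <- data.frame(
        patient_id = pid, eye_id = eid, laterality = lat_c[i],
        age = ages_c[i], pseudophakic = pseudo_c[i], group = "control",
        n_visits = 1L)
    }
  }

  # normative reference for z-score generation (inter-visit mode): controls
  # extracted through the package's own grading/sampling at the true
  # transforms, closing the generation/analysis loop.
  norm_ref <- NULL
  if (config$generative_model == "intervisit" && config$n_controls >= 2) {
    ctrl_rows <- lapply(visits, function(vr) {
      extract_visit(vr, register_visit(vr), grid)
    })
    norm_ref <- build_normative(do.call(rbind, ctrl_rows))
  }

  # ---- AMD eyes -------------------------------------------------------------
  if (config$n_eyes_amd > 0) {
    n_pat <- config$n_patients_amd
    ages_p <- draw_truncated(n_pat, config$age_amd[["mean"]],
                             config$age_amd[["sd"]],
                             config$age_range[1], config$age_range[2])
    u_pat <- cbind(mes = stats::rnorm(n_pat, 0, sds[["patient"]]),
                   scot = stats::rnorm(n_pat, 0, sds[["patient"]]))
    sds_iv <- config$random_effect_sds_intervisit %||%
      c(patient = 0.5, visit = 0.3, grid = 0.3, residual = 1.0)
    ud_pat <- cbind(mes = stats::rnorm(n_pat, 0, sds_iv[["patient"]]),
                    scot = stats::rnorm(n_pat, 0, sds_iv[["patient"]]))
    wd_mes <- stats::rnorm(n_pts, 0, sds_iv[["grid"]])
    wd_scot <- stats::rnorm(n_pts, 0, sds_iv[["grid"]])
    # first (n_eyes - n_patients) patients contribute both eyes
    eye_patient <- c(seq_len(config$n_eyes_amd - n_pat), seq_len(n_pat))
    eye_patient <- sort(eye_patient)
    fxc <- config$fixed_effects_cross_sectional
    fxi <- config$fixed_effects_intervisit
    bio <- fcp_biomarkers()

    for (e in seq_len(config$n_eyes_amd)) {
      p <- eye_patient[e]
      pid <- sprintf("P%02d", p)
      second <- duplicated(eye_patient)[e]
      eid <- sprintf("%s_%s", pid, if (second) "E2" else "E1")
      age <- ages_p[p]
      pseudo <- stats::runif(1) < config$pseudophakic_fraction_amd
      lat <- if (stats::runif(1) < config$right_eye_fraction) "right" else "left"
      n_visits <- sample.int(config$n_visits_max, 1,
                             prob = config$visit_count_probs)
      gaps <- draw_truncated(max(n_visits - 1, 0),
                             config$visit_interval_months[["mean"]],
                             config$visit_interval_months[["sd"]], 7, 17)
      months <- c(0, cumsum(gaps))
      offsets <- stats::setNames(
        stats::rnorm(nrow(prof), 0, prof$between_eye_sd_um), prof$layer)
      baseline_lesions <- sample_eye_lesions(config, n_visits)
      latent_mes <- NULL; latent_scot <- NULL
      prev_flags <- NULL; prev_z <- NULL

      for (j in seq_len(n_visits)) {
        vi <- j - 1L
        les_df <- lesions_at_visit(baseline_lesions, vi, months[j] / 12)
        les <- lesion_set(les_df, config, "left")
        stack_left <- simulate_thickness_stack(les, config, offsets)
        tr_dev <- random_true_transform()
        lms <- simulate_landmarks(tr_dev, config$n_vessels,
                                  config$landmark_noise_sd_deg, lat)
        # graded structure at the registered stimulus positions: generation
        # consumes the extraction module's own grading (estimated transform,
        # identical to what the analysis pipeline computes) so that recovery
        # through the same grading is unbiased
        tr_est <- register_visit(list(landmarks_fcp = lms$fcp,
                                      landmarks_oct = lms$oct,
                                      laterality = lat))
        zmat <- NULL
        if (!is.null(norm_ref)) {
          probe <- list(patient_id = pid, eye_id = eid, visit_index = vi,
                        months_since_baseline = months[j], age = age,
                        pseudophakic = pseudo, laterality = "left",
                        stack = stack_left, lesions = les,
                        sensitivities = placeholder_sens(n_pts))
          struct <- extract_visit(probe, tr_est, grid)
          flags <- as.matrix(struct[, paste0("flag_", bio)]) * 1
          zmat <- vapply(fcp_layers(), function(l) {
            thickness_zscore(struct[[paste0("thk_", l)]], norm_ref,
                             struct$grid_index, l)
          }, numeric(n_pts))
        } else {
          # cross-sectional generation needs only the graded flags
          mapped <- map_stimuli(grid, tr_est)
          flags <- matrix(0, n_pts, length(bio),
                          dimnames = list(NULL, paste0("flag_", bio)))
          for (b in seq_along(bio)) {
            mask <- les$masks[[bio[b]]]
            if (is.null(mask)) next
            for (k in seq_len(n_pts)) {
              gp <- grade_presence(mask, mapped$centers[k, ],
                                   mapped$extraction_diameter_deg,
                                   stack_left$px_per_deg,
                                   stack_left$origin_px)
              flags[k, b] <- as.numeric(isTRUE(gp$present))
            }
          }
        }
        if (config$reader_flip_prob > 0) {
          flip <- matrix(stats::runif(length(flags)) <
                           config$reader_flip_prob, nrow(flags))
          flags[flip] <- 1 - flags[flip]
        }

        bio_eff <- function(fx) as.numeric(flags %*% fx[bio])
        if (config$generative_model == "cross_sectional" || j == 1L) {
          lp_mes <- norm_mes + fxc$mesopic[["intercept"]] +
            fxc$mesopic[["age"]] * age +
            fxc$mesopic[["pseudophakic"]] * pseudo +
            bio_eff(fxc$mesopic)
          lp_scot <- norm_scot + fxc$scotopic[["intercept"]] +
            fxc$scotopic[["age"]] * age +
            fxc$scotopic[["pseudophakic"]] * pseudo +
            bio_eff(fxc$scotopic)
          latent_mes <- lp_mes + w_mes + u_pat[p, "mes"] +
            stats::rnorm(1, 0, sds[["visit"]]) +
            stats::rnorm(n_pts, 0, sds[["residual"]])
          latent_scot <- lp_scot + w_scot + u_pat[p, "scot"] +
            stats::rnorm(1, 0, sds[["visit"]]) +
            stats::rnorm(n_pts, 0, sds[["residual"]])
        } else {
          yrs <- (months[j] - months[j - 1]) / 12
          z_eff <- function(fx) {
            if (is.null(prev_z)) return(0)
            as.numeric(prev_z %*% fx[paste0("z_", fcp_layers())])
          }
          prev_bio_eff <- function(fx) as.numeric(prev_flags %*% fx[bio])
          d_mes <- fxi$mesopic[["intercept"]] +
            fxi$mesopic[["age"]] * age +
            fxi$mesopic[["pseudophakic"]] * pseudo +
            fxi$mesopic[["years_between_visits"]] * yrs +
            prev_bio_eff(fxi$mesopic) + z_eff(fxi$mesopic)
          d_scot <- fxi$scotopic[["intercept"]] +
            fxi$scotopic[["age"]] * age +
            fxi$scotopic[["pseudophakic"]] * pseudo +
            fxi$scotopic[["years_between_visits"]] * yrs +
            prev_bio_eff(fxi$scotopic) + z_eff(fxi$scotopic)
          latent_mes <- latent_mes + d_mes + wd_mes + ud_pat[p, "mes"] +
            stats::rnorm(1, 0, sds_iv[["visit"]]) +
            stats::rnorm(n_pts, 0, sds_iv[["residual"]])
          latent_scot <- latent_scot + d_scot + wd_scot + ud_pat[p, "scot"] +
            stats::rnorm(1, 0, sds_iv[["visit"]]) +
            stats::rnorm(n_pts, 0, sds_iv[["residual"]])
        }
        prev_flags <- flags
        prev_z <- zmat

        visits[[length(visits) + 1L]] <-
          make_visit(pid, eid, vi, months[j], age, pseudo, lat, "amd",
                     stack_left, les, lms, tr_dev,
                     clamp_sens(latent_mes, latent_scot), gen_flags = flags)
      }
      eyes[[length(eyes) + 1L]] <- data.frame(
        patient_id = pid, eye_id = eid, laterality = lat, age = age,
        pseudophakic = pseudo, group = "amd", n_visits = n_visits)
    }
  }

  structure(
    list(config = config, grid = grid,
         eyes = if (length(eyes)) do.call(rbind, eyes) else
           data.frame(patient_id = character(0), eye_id = character(0),
                      laterality = character(0), age = numeric(0),
                      pseudophakic = logical(0), group = character(0),
                      n_visits = integer(0)),
         visits = visits),
    class = "fcp_cohort"
  )
}

# A right-eye device-frame transform re-expressed in left-eye orientation:
# T_left = M T M with M = diag(-1, 1).
left_frame_transform <- function(transform, laterality) {
  if (laterality == "left") return(transform)
  M <- diag(c(-1, 1))
  transform2d(M %*% transform$A %*% M, as.numeric(M %*% transform$b),
              family = transform$family,
              allow_reflection = transform$allow_reflection)
}

#' @export
print.fcp_cohort <- function(x, ...) {
  cat(sprintf("<fcp_cohort> %d eyes (%d AMD, %d control), %d visit records\n",
              nrow(x$eyes), sum(x$eyes$group == "amd"),
              sum(x$eyes$group == "control"), length(x$visits)))
  invisible(x)
}
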