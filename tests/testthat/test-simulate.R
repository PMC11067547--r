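test_that("an empty configuration yields an empty cohort without error", {
  cfg <- cohort_config(n_patients_amd = 0, n_eyes_amd = 0, n_controls = 0,
                       map_size_px = 64)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$eyes), 0L)
  expect_length(coh$visits, 0L)
})

test_that("configuration invariants are enforced", {
  expect_error(cohort_config(n_visits_max = 0), class = "fcpoct_config_error")
  expect_error(cohort_config(n_patients_amd = 5, n_eyes_amd = 11),
               "two eyes", class = "fcpoct_config_error")
  lp <- lesion_params_defaults()
  lp$diameter_min_um[lp$biomarker == "PED"] <- 600
  expect_error(cohort_config(lesion_params = lp), "PED",
               class = "fcpoct_config_error")
  lp <- lesion_params_defaults()
  lp$diameter_max_um[lp$biomarker == "iRORA"] <- 300
  expect_error(cohort_config(lesion_params = lp), "iRORA",
               class = "fcpoct_config_error")
  lp <- lesion_params_defaults()
  lp$diameter_min_um[lp$biomarker == "cRORA"] <- 200
  expect_error(cohort_config(lesion_params = lp), "cRORA",
               class = "fcpoct_config_error")
  expect_error(cohort_config(sensitivity_range = c(floor = 20, ceiling = 0)),
               class = "fcpoct_config_error")
  expect_error(
    cohort_config(random_effect_sds = c(patient = -1, visit = 0, grid = 0,
                                        residual = 0)),
    class = "fcpoct_config_error")
})

test_that("simulated cohorts are bit-reproducible from their configuration", {
  cfg <- tiny_config(seed = 21)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$eyes, b$eyes)
  expect_identical(lapply(a$visits, `[[`, "sensitivities"),
                   lapply(b$visits, `[[`, "sensitivities"))
  expect_identical(a$visits[[3]]$stack$layers$RPEDC,
                   b$visits[[3]]$stack$layers$RPEDC)
  expect_identical(lapply(a$visits, `[[`, "gen_flags"),
                   lapply(b$visits, `[[`, "gen_flags"))
})

test_that("every visit carries complete artifacts within the dynamic range", {
  cfg <- tiny_config(seed = 22)
  coh <- simulate_cohort(cfg)
  expect_equal(sum(coh$eyes$group == "amd"), cfg$n_eyes_amd)
  expect_equal(sum(coh$eyes$group == "control"), cfg$n_controls)
  expect_equal(length(unique(coh$eyes$patient_id[coh$eyes$group == "amd"])),
               cfg$n_patients_amd)
  for (v in coh$visits) {
    expect_s3_class(v$stack, "thickness_stack")
    expect_equal(length(v$stack$layers), 9L)
    expect_false(any(vapply(v$stack$layers, function(m) any(m < 0),
                            logical(1))))
    expect_equal(nrow(v$sensitivities), 56L)
    expect_true(all(v$sensitivities[, "mesopic"] >= 0 &
                      v$sensitivities[, "mesopic"] <= 20))
    expect_true(all(v$sensitivities[, "scotopic"] >= 0 &
                      v$sensitivities[, "scotopic"] <= 20))
    expect_s3_class(v$landmarks_oct, "landmark_set")
    expect_s3_class(v$landmarks_fcp, "landmark_set")
    if (v$group == "control") {
      expect_null(v$lesions)
    } else {
      expect_s3_class(v$lesions, "lesion_set")
    }
  }
  # visit months strictly increasing per eye
  for (eye in unique(coh$eyes$eye_id)) {
    months <- vapply(Filter(function(v) v$eye_id == eye, coh$visits),
                     `[[`, numeric(1), "months_since_baseline")
    expect_true(all(diff(months) > 0) || length(months) == 1)
  }
  # iRORA and cRORA masks stay disjoint at every visit
  for (v in coh$visits) {
    if (is.null(v$lesions)) next
    mi <- v$lesions$masks$iRORA; mc <- v$lesions$masks$cRORA
    if (!is.null(mi) && !is.null(mc)) expect_false(any(mi & mc))
  }
})

test_that("the default scenario reproduces the study cohort dimensions", {
  cfg <- default_config("table2", seed = 3)
  coh <- simulate_cohort(cfg)
  expect_equal(sum(coh$eyes$group == "amd"), 54L)
  expect_equal(length(unique(coh$eyes$patient_id[coh$eyes$group == "amd"])),
               49L)
  expect_equal(sum(coh$eyes$group == "control"), 27L)
  expect_true(all(coh$eyes$n_visits[coh$eyes$group == "amd"] <= 4))
  ages <- coh$eyes$age
  expect_true(all(ages >= 45 & ages <= 85))
})

test_that("zero variance reduces sensitivities to the linear predictor", {
  cfg <- do.call(tiny_config, c(list(seed = 23, right_eye_fraction = 0),
                                zero_noise_overrides()))
  coh <- simulate_cohort(cfg)
  fx <- cfg$fixed_effects_cross_sectional
  r_k <- sqrt(rowSums(cfg$grid$centers^2))
  norm_mes <- fcpoct:::normative_profile(cfg$normative_mesopic, r_k)
  for (v in Filter(function(v) v$group == "amd", coh$visits)) {
    lp <- norm_mes + fx$mesopic[["intercept"]] +
      fx$mesopic[["age"]] * v$age +
      fx$mesopic[["pseudophakic"]] * v$pseudophakic +
      as.numeric(v$gen_flags %*% fx$mesopic[fcp_biomarkers()])
    expect_equal(v$sensitivities[, "mesopic"],
                 pmin(pmax(lp, 0), 20), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("lesion-free zero-noise maps equal the radial baseline profile", {
  cfg <- tiny_config(seed = 24, pixel_noise_sd_um = 0, map_size_px = 97)
  offs <- stats::setNames(rep(0, 9), fcp_layers())
  st <- simulate_thickness_stack(NULL, cfg, layer_offsets = offs)
  geom <- fcpoct:::map_geometry(cfg)
  pc <- fcpoct:::pixel_coords(geom)
  r <- sqrt(pc$x^2 + pc$y^2)
  prof <- cfg$layer_profiles
  for (i in seq_len(nrow(prof))) {
    expected <- pmax(prof$a[i] + prof$b[i] * exp(-((r - prof$c[i]) /
                                                     prof$d[i])^2), 0)
    expect_equal(st$layers[[prof$layer[i]]], expected, tolerance = 1e-9)
  }
})

test_that("a PED bump peaks at its configured height", {
  cfg <- tiny_config(seed = 25, pixel_noise_sd_um = 0, map_size_px = 97)
  les <- lesion_set(data.frame(biomarker = "PED", x_deg = 0, y_deg = 0,
                               diameter_um = 1500, height_um = 250), cfg)
  offs <- stats::setNames(rep(0, 9), fcp_layers())
  base <- simulate_thickness_stack(NULL, cfg, layer_offsets = offs)
  with_ped <- simulate_thickness_stack(les, cfg, layer_offsets = offs)
  diff_map <- with_ped$layers$RPEDC - base$layers$RPEDC
  expect_equal(max(diff_map), 250, tolerance = 1e-9)
  expect_true(all(diff_map >= 0))
  expect_equal(sum(abs(with_ped$layers$ONL - base$layers$ONL)), 0)
})

test_that("cRORA thins the outer retina inside the mask", {
  cfg <- tiny_config(seed = 26, pixel_noise_sd_um = 0, map_size_px = 97)
  les <- lesion_set(data.frame(biomarker = "cRORA", x_deg = 1, y_deg = -1,
                               diameter_um = 800, height_um = NA), cfg)
  offs <- stats::setNames(rep(0, 9), fcp_layers())
  st <- simulate_thickness_stack(les, cfg, layer_offsets = offs)
  base <- simulate_thickness_stack(NULL, cfg, layer_offsets = offs)
  mask <- les$masks$cRORA
  for (l in c("ONL", "OS", "RPEDC")) {
    expect_lt(mean(st$layers[[l]][mask]), mean(base$layers[[l]][mask]))
    expect_equal(st$layers[[l]][!mask], base$layers[[l]][!mask])
  }
})

test_that("geometry mismatches between lesions and maps are rejected", {
  cfg_a <- tiny_config(map_size_px = 96)
  cfg_b <- tiny_config(map_size_px = 64)
  les <- lesion_set(data.frame(biomarker = "HRF", x_deg = 0, y_deg = 0,
                               diameter_um = 150, height_um = NA), cfg_a)
  expect_error(simulate_thickness_stack(les, cfg_b), "geometry",
               class = "fcpoct_config_error")
})

test_that("landmark pairs honour the zero-noise and identity limits", {
  set.seed(27)
  tr <- transform2d(1.04 * rot2(0.05), c(0.3, -0.2))
  lms <- simulate_landmarks(tr, n_vessels = 6, noise_sd_deg = 0)
  expect_equal(fcpoct:::landmark_matrix(lms$fcp),
               apply_transform(invert_transform(tr),
                               fcpoct:::landmark_matrix(lms$oct)),
               tolerance = 1e-12, ignore_attr = TRUE)
  lms_id <- simulate_landmarks(transform2d(), n_vessels = 4, noise_sd_deg = 0)
  expect_equal(fcpoct:::landmark_matrix(lms_id$fcp),
               fcpoct:::landmark_matrix(lms_id$oct), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(simulate_landmarks(tr, n_vessels = 1),
               class = "fcpoct_config_error")
})

test_that("landmark noise matches its stated scale over replicates", {
  set.seed(28)
  tr <- transform2d(rot2(0.02), c(0.1, 0.1))
  rms <- replicate(100, {
    lms <- simulate_landmarks(tr, n_vessels = 10, noise_sd_deg = 0.1)
    res <- fcpoct:::landmark_matrix(lms$fcp) -
      apply_transform(invert_transform(tr),
                      fcpoct:::landmark_matrix(lms$oct))
    sqrt(mean(rowSums(res^2)))
  })
  expect_gt(mean(rms), 0.05)
  expect_lt(mean(rms), 0.2)
})

test_that("per-stimulus presence rates follow the lesion parameters", {
  # Empirical rate of the generator's graded flags over 20 seeds, against an
  # independent Monte-Carlo oracle that redraws lesion configurations and
  # re-implements the pixel-center grading geometrically. Baseline-onset
  # biomarkers only (follow-up lesions depend on the visit schedule).
  cfg <- tiny_config(seed = 1, n_patients_amd = 12, n_eyes_amd = 12,
                     n_controls = 2, n_visits_max = 1,
                     visit_count_probs = 1)
  geom <- fcpoct:::map_geometry(cfg)
  grid <- cfg$grid
  lp <- cfg$lesion_params

  emp <- matrix(NA_real_, 20, nrow(lp), dimnames = list(NULL, lp$biomarker))
  for (s in 1:20) {
    coh <- simulate_cohort(tiny_config(seed = 100 + s, n_patients_amd = 12,
                                       n_eyes_amd = 12, n_controls = 2,
                                       n_visits_max = 1,
                                       visit_count_probs = 1))
    fl <- do.call(rbind, lapply(Filter(function(v) v$group == "amd",
                                       coh$visits), `[[`, "gen_flags"))
    emp[s, ] <- colMeans(fl)
  }

  set.seed(999)
  n_mc <- 600
  oracle <- matrix(NA_real_, n_mc, nrow(lp))
  disc_r <- grid$extraction_diameter_deg / 2
  for (i in seq_len(nrow(lp))) {
    p <- lp[i, ]
    if (p$onset != "baseline") next
    for (m in seq_len(n_mc)) {
      if (runif(1) > p$prevalence) { oracle[m, i] <- 0; next }
      # stimulus placement variability: same FCP->OCT similarity family the
      # generator draws per visit
      s_tr <- runif(1, 0.95, 1.05)
      th_tr <- runif(1, -3, 3) * pi / 180
      b_tr <- runif(2, -0.5, 0.5)
      centers <- s_tr * grid$centers %*% t(rot2(th_tr))
      centers[, 1] <- centers[, 1] + b_tr[1]
      centers[, 2] <- centers[, 2] + b_tr[2]
      disc_r_m <- disc_r * s_tr
      k <- p$count_min + sample.int(p$count_max - p$count_min + 1L, 1) - 1L
      hit <- rep(FALSE, nrow(grid$centers))
      for (j in seq_len(k)) {
        cx <- runif(1, -cfg$lesion_field_deg, cfg$lesion_field_deg)
        cy <- runif(1, -cfg$lesion_field_deg, cfg$lesion_field_deg)
        r_l <- runif(1, p$diameter_min_um, p$diameter_max_um) /
          cfg$um_per_deg / 2
        # pixel centers covered by the lesion circle (independent
        # re-implementation of the raster rule)
        cols <- floor((cx - r_l) * geom$px_per_deg + geom$origin_px[1]):
          ceiling((cx + r_l) * geom$px_per_deg + geom$origin_px[1])
        rows <- floor((cy - r_l) * geom$px_per_deg + geom$origin_px[2]):
          ceiling((cy + r_l) * geom$px_per_deg + geom$origin_px[2])
        pts <- expand.grid(col = cols, row = rows)
        px <- (pts$col - geom$origin_px[1]) / geom$px_per_deg
        py <- (pts$row - geom$origin_px[2]) / geom$px_per_deg
        inside <- (px - cx)^2 + (py - cy)^2 <= r_l^2
        if (!any(inside)) next
        px <- px[inside]; py <- py[inside]
        for (q in which(!hit)) {
          if (any((px - centers[q, 1])^2 +
                    (py - centers[q, 2])^2 <= disc_r_m^2)) hit[q] <- TRUE
        }
      }
      oracle[m, i] <- mean(hit)
    }
  }

  for (i in seq_len(nrow(lp))) {
    if (lp$onset[i] != "baseline") next
    e_mean <- mean(emp[, i]); e_se <- sd(emp[, i]) / sqrt(nrow(emp))
    o_mean <- mean(oracle[, i], na.rm = TRUE)
    o_se <- sd(oracle[, i], na.rm = TRUE) / sqrt(n_mc)
    expect_lt(abs(e_mean - o_mean), 3 * sqrt(e_se^2 + o_se^2) + 1e-9)
  }
})
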