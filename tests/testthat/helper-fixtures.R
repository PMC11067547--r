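# Shared fixtures: small desk-scale configurations and an independent
# numerical-optimizer oracle for the similarity fit.

tiny_config <- function(scenario = "table2", seed = 1, ...) {
  args <- list(...)
  defaults <- list(
    n_patients_amd = 8, n_eyes_amd = 9, n_controls = 6,
    n_visits_max = 3, visit_count_probs = c(0.2, 0.3, 0.5),
    map_size_px = 96, seed = seed,
    generative_model = if (scenario == "table2") "cross_sectional" else "intervisit"
  )
  do.call(cohort_config, utils::modifyList(defaults, args))
}

zero_noise_overrides <- function() {
  list(
    random_effect_sds = c(patient = 0, visit = 0, grid = 0, residual = 0),
    random_effect_sds_intervisit = c(patient = 0, visit = 0, grid = 0,
                                     residual = 0),
    pixel_noise_sd_um = 0, landmark_noise_sd_deg = 0
  )
}

# run simulate -> register -> extract -> normalize, returning the normalized
# AMD table plus the reference
run_to_table <- function(config) {
  cohort <- simulate_cohort(config)
  ext <- extract_cohort(cohort)
  ref <- build_normative(ext$table[ext$table$group == "control", ])
  amd <- normalize_observations(ext$table[ext$table$group == "amd", ], ref)
  list(cohort = cohort, amd = amd, reference = ref,
       control = normalize_observations(
         ext$table[ext$table$group == "control", ], ref))
}

# independent similarity-fit oracle: numerical minimization of the weighted
# least-squares objective, with the linear parameters (scale, translation)
# profiled out exactly for each candidate rotation angle
optim_similarity <- function(src, dst, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, nrow(src))
  solve_linear <- function(theta) {
    rp <- src %*% t(rot2(theta))
    # columns: s, bx, by in stacked x/y regression
    X <- rbind(cbind(rp[, 1], 1, 0), cbind(rp[, 2], 0, 1))
    y <- c(dst[, 1], dst[, 2])
    w <- c(weights, weights)
    coef <- solve(crossprod(X * w, X), crossprod(X * w, y))
    res <- y - X %*% coef
    list(coef = coef, value = sum(w * res^2))
  }
  thetas <- seq(-pi, pi, length.out = 721)
  vals <- vapply(thetas, function(t) solve_linear(t)$value, numeric(1))
  t0 <- thetas[which.min(vals)]
  opt <- stats::optimize(function(t) solve_linear(t)$value,
                         interval = c(t0 - 0.02, t0 + 0.02), tol = 1e-14)
  sol <- solve_linear(opt$minimum)
  list(A = sol$coef[1] * rot2(opt$minimum), b = as.numeric(sol$coef[2:3]),
       value = sol$value)
}

canonical_cross_terms <- c("intercept", "age", "pseudophakic",
                           fcp_biomarkers())

# independent brute-force oracle: enumerate every pixel of the map, test its
# center against the disc, and average
brute_disc <- function(map, center, diameter, s, origin) {
  total <- 0; acc <- 0
  for (row in seq_len(nrow(map)) - 1L) {
    for (col in seq_len(ncol(map)) - 1L) {
      x <- (col - origin[1]) / s
      y <- (row - origin[2]) / s
      if ((x - center[1])^2 + (y - center[2])^2 <= (diameter / 2)^2) {
        total <- total + 1
        acc <- acc + map[row + 1, col + 1]
      }
    }
  }
  list(mean = if (total) acc / total else NA_real_, n = total)
}
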