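test_that("identity and pure-translation fits are exact", {
  set.seed(41)
  src <- matrix(rnorm(10), ncol = 2)
  fit <- estimate_transform(src, src)
  expect_equal(fit$A, diag(2), tolerance = 1e-12)
  expect_equal(fit$b, c(0, 0), tolerance = 1e-12)
  expect_equal(attr(fit, "diagnostics")$rms, 0, tolerance = 1e-12)

  shifted <- src
  shifted[, 1] <- shifted[, 1] + 5
  fit <- estimate_transform(src, shifted)
  expect_equal(fit$A, diag(2), tolerance = 1e-12)
  expect_equal(fit$b, c(5, 0), tolerance = 1e-12)
})

test_that("a known similarity is recovered to machine precision", {
  set.seed(42)
  src <- matrix(rnorm(12), ncol = 2)
  truth <- transform2d(1.2 * rot2(30 * pi / 180), c(3, -2))
  fit <- estimate_transform(src, apply_transform(truth, src))
  expect_lt(max(abs(fit$A - truth$A)), 1e-9)
  expect_lt(max(abs(fit$b - truth$b)), 1e-9)
  expect_lt(attr(fit, "diagnostics")$rms, 1e-9)
  expect_equal(transform_scale(fit), 1.2, tolerance = 1e-9)
})

test_that("closed-form similarity equals a numerical optimizer", {
  set.seed(43)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    src <- matrix(rnorm(2 * n, sd = 4), ncol = 2)
    dst <- matrix(rnorm(2 * n, sd = 4), ncol = 2)  # unrelated: noisy problem
    w <- runif(n, 0.5, 3)
    fit <- estimate_transform(src, dst, weights = w)
    ora <- optim_similarity(src, dst, w)
    expect_lt(max(abs(fit$A - ora$A)), 1e-6)
    expect_lt(max(abs(fit$b - ora$b)), 1e-6)
  }
})

test_that("affine fit interpolates three non-collinear points exactly", {
  set.seed(44)
  src <- rbind(c(0, 0), c(4, 1), c(1, 5))
  dst <- matrix(rnorm(6, sd = 3), ncol = 2)
  fit <- estimate_transform(src, dst, family = "affine")
  expect_lt(attr(fit, "diagnostics")$rms, 1e-9)
  expect_equal(apply_transform(fit, src), dst, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("degenerate correspondences raise informative errors", {
  expect_error(estimate_transform(matrix(c(1, 2), 1, 2),
                                  matrix(c(1, 2), 1, 2)),
               "at least 2", class = "fcpoct_config_error")
  col_src <- cbind(1:4, 2 * (1:4))
  expect_error(estimate_transform(col_src, col_src + 1, family = "affine"),
               "non-collinear", class = "fcpoct_config_error")
  expect_error(estimate_transform(matrix(rnorm(8), 4, 2),
                                  matrix(rnorm(6), 3, 2)),
               "mismatched", class = "fcpoct_config_error")
  same <- matrix(1, 4, 2)
  expect_error(estimate_transform(same, same + rnorm(8)),
               "degenerate", class = "fcpoct_config_error")
})

test_that("landmark weighting drives the weighted objective", {
  set.seed(45)
  oct <- landmark_set(c(0, 0), c(-15.5, -1.5), matrix(rnorm(12, sd = 6), ncol = 2))
  fcp_pts <- fcpoct:::landmark_matrix(oct) + matrix(rnorm(16, sd = 0.3), ncol = 2)
  fcp <- landmark_set(fcp_pts[1, ], fcp_pts[2, ], fcp_pts[-(1:2), ])
  fit <- estimate_transform(fcp, oct)
  w <- fcpoct:::landmark_weights(fcp)
  expect_equal(w[1:2], c(3, 3))
  ora <- optim_similarity(fcpoct:::landmark_matrix(fcp),
                          fcpoct:::landmark_matrix(oct), w)
  expect_lt(max(abs(fit$A - ora$A)), 1e-6)
  expect_lt(max(abs(fit$b - ora$b)), 1e-6)
})

test_that("mirroring reflects x and is an involution", {
  lm_r <- landmark_set(c(0, 0), c(15.5, -1.5), cbind(c(3, -4), c(1, 2)),
                       laterality = "right")
  lm_l <- mirror_to_left(lm_r)
  expect_equal(lm_l$x, -lm_r$x)
  expect_equal(lm_l$y, lm_r$y)
  expect_identical(mirror_to_left(lm_l), lm_l)  # left input unchanged

  g <- default_grid()
  expect_identical(mirror_to_left(g, "left"), g)
  gm <- mirror_to_left(g, "right")
  expect_equal(gm$centers[, 1], -g$centers[, 1])
  expect_error(mirror_to_left(g), class = "fcpoct_config_error")

  set.seed(46)
  st <- thickness_stack(list(RPEDC = matrix(runif(30), 5, 6)),
                        px_per_deg = 2, origin_px = c(2.5, 2),
                        laterality = "right")
  once <- mirror_to_left(st)
  expect_equal(once$laterality, "left")
  twice <- mirror_to_left(once, "right")
  expect_identical(twice$layers$RPEDC, st$layers$RPEDC)
  expect_equal(twice$origin_px, st$origin_px)
})

test_that("map_stimuli is equivariant and rescales the stimulus radius", {
  g <- default_grid()
  ident <- map_stimuli(g, transform2d())
  expect_equal(ident$centers, g$centers, tolerance = 1e-12)
  expect_equal(ident$extraction_diameter_deg, g$extraction_diameter_deg)

  shift <- map_stimuli(g, transform2d(diag(2), c(1, 1)))
  expect_equal(shift$centers, g$centers + 1, tolerance = 1e-12,
               ignore_attr = TRUE)

  scaled <- map_stimuli(g, transform2d(2 * diag(2), c(0, 0)))
  expect_equal(scaled$extraction_diameter_deg, 2 * g$extraction_diameter_deg)
  d0 <- as.matrix(dist(g$centers))
  d2 <- as.matrix(dist(scaled$centers))
  expect_equal(d2, 2 * d0, tolerance = 1e-9)  # all 56*55/2 pairs

  broken <- transform2d()
  broken$A <- matrix(0, 2, 2)
  expect_error(map_stimuli(g, broken), "singular",
               class = "fcpoct_config_error")
})

test_that("registration error scales with landmark noise", {
  set.seed(47)
  truth <- transform2d(1.03 * rot2(0.03), c(0.4, -0.2))
  n <- 12
  sigma <- 0.1
  rms_noise <- numeric(100)
  fov_err <- numeric(100)
  for (i in 1:100) {
    oct <- matrix(rnorm(2 * n, sd = 5), ncol = 2)
    fcp <- apply_transform(invert_transform(truth), oct) +
      matrix(rnorm(2 * n, 0, sigma), ncol = 2)
    # stated noise model: FCP landmarks scatter isotropically around the
    # transform image of the OCT landmarks
    res <- fcp - apply_transform(invert_transform(truth), oct)
    rms_noise[i] <- sqrt(mean(rowSums(res^2)))
    fit <- estimate_transform(fcp, oct)
    # error of the fitted map at the true fovea position
    true_fov <- apply_transform(invert_transform(truth), oct[1, , drop = FALSE])
    pred <- apply_transform(fit, true_fov)
    fov_err[i] <- sqrt(sum((pred - oct[1, ])^2))
  }
  expect_gt(mean(rms_noise), 0.05)
  expect_lt(mean(rms_noise), 0.2)
  # fovea registration error stays below 3*sigma/sqrt(n)
  expect_lt(sqrt(mean(fov_err^2)), 3 * sigma / sqrt(n))
})

test_that("transforms round-trip through JSON", {
  tr <- estimate_transform(matrix(rnorm(12), ncol = 2),
                           matrix(rnorm(12), ncol = 2))
  path <- tempfile(fileext = ".json")
  write_transform_json(tr, path)
  back <- read_transform_json(path)
  expect_equal(back$A, tr$A, tolerance = 1e-12)
  expect_equal(back$b, tr$b, tolerance = 1e-12)
  expect_equal(attr(back, "diagnostics")$rms, attr(tr, "diagnostics")$rms,
               tolerance = 1e-12)
})
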