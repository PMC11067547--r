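test_that("disc means reduce to the constant on constant maps", {
  m <- matrix(100, 48, 48)
  for (ctr in list(c(0, 0), c(2.3, -1.1), c(-3, 3))) {
    sm <- sample_disc_mean(m, ctr, 1.7, px_per_deg = 4,
                           origin_px = c(23.5, 23.5))
    expect_equal(sm$mean, 100)
    expect_equal(sm$reason, "ok")
  }
})

test_that("symmetric discs cancel a linear gradient", {
  # odd-sized map with the origin on a pixel center: the in-disc pixel set is
  # symmetric about the origin, so a map linear in x averages to its center
  # value
  n <- 49
  origin <- c((n - 1) / 2, (n - 1) / 2)
  xcoord <- matrix(rep((0:(n - 1) - origin[1]) / 4, each = n), n, n)
  m <- 50 + 3 * xcoord
  sm <- sample_disc_mean(m, c(0, 0), 1.7, px_per_deg = 4, origin_px = origin)
  expect_equal(sm$mean, 50, tolerance = 1e-12)
})

test_that("disc means and presence fractions match brute-force enumeration", {
  set.seed(51)
  s <- 64 / 14
  origin <- c(31.5, 31.5)
  for (i in 1:100) {
    m <- matrix(runif(64 * 64, 0, 400), 64, 64)
    ctr <- runif(2, -4, 4)
    dia <- runif(1, 0.4, 2.5)
    sm <- sample_disc_mean(m, ctr, dia, s, origin)
    ora <- brute_disc(m, ctr, dia, s, origin)
    expect_equal(sm$n_pixels, ora$n)
    if (!is.na(ora$mean) && sm$reason == "ok") {
      expect_equal(sm$mean, ora$mean, tolerance = 1e-12)
    }
    mask <- m > 200
    gp <- grade_presence(mask, ctr, dia, s, origin, min_fraction = 0.3)
    orb <- brute_disc(mask * 1, ctr, dia, s, origin)
    if (gp$reason == "ok") {
      expect_equal(gp$fraction, orb$mean, tolerance = 1e-12)
      expect_equal(gp$present, orb$mean >= 0.3)
    }
  }
})

test_that("disc means scale linearly with the map", {
  set.seed(52)
  m <- matrix(runif(32 * 32, 10, 50), 32, 32)
  a <- sample_disc_mean(m, c(0.5, -0.5), 1.7, 3, c(15.5, 15.5))
  b <- sample_disc_mean(3.5 * m, c(0.5, -0.5), 1.7, 3, c(15.5, 15.5))
  expect_equal(b$mean, 3.5 * a$mean, tolerance = 1e-12)
})

test_that("presence grading handles empty, saturated and partial masks", {
  geom <- list(s = 4, origin = c(23.5, 23.5))
  empty <- matrix(FALSE, 48, 48)
  full <- matrix(TRUE, 48, 48)
  expect_false(grade_presence(empty, c(0, 0), 1.7, geom$s, geom$origin)$present)
  for (f in c(0, 0.25, 1)) {
    expect_true(grade_presence(full, c(0, 0), 1.7, geom$s, geom$origin,
                               min_fraction = f)$present)
  }
  # half-plane mask covering x >= 0: fraction close to one half
  half <- matrix(rep((0:47 - 23.5) >= 0, each = 48), 48, 48)
  gp25 <- grade_presence(half, c(0, 0), 1.7, geom$s, geom$origin,
                         min_fraction = 0.25)
  gp75 <- grade_presence(half, c(0, 0), 1.7, geom$s, geom$origin,
                         min_fraction = 0.75)
  ora <- brute_disc(half * 1, c(0, 0), 1.7, geom$s, geom$origin)
  expect_true(gp25$present)
  expect_false(gp75$present)
  expect_equal(gp25$fraction, ora$mean, tolerance = 1e-12)
})

test_that("presence grading is monotone in min_fraction", {
  set.seed(53)
  for (i in 1:20) {
    mask <- matrix(runif(32 * 32) < 0.3, 32, 32)
    ctr <- runif(2, -3, 3)
    fr <- sort(runif(3))
    res <- vapply(fr, function(f) {
      grade_presence(mask, ctr, 1.7, 3, c(15.5, 15.5),
                     min_fraction = f)$present
    }, logical(1))
    # true at a threshold implies true at every smaller threshold
    expect_true(all(res == cummin(res)))
  }
})

test_that("off-map discs yield flagged missing values, not silent means", {
  m <- matrix(1, 32, 32)
  sm <- sample_disc_mean(m, c(10, 0), 1.7, 3, c(15.5, 15.5))
  expect_true(is.na(sm$mean))
  expect_equal(sm$reason, "edge")
  half_off <- sample_disc_mean(m, c(5.4, 0), 1.7, 3, c(15.5, 15.5))
  expect_equal(half_off$reason, "edge")
  tiny <- sample_disc_mean(m, c(0.3, 0.3), 0.05, 3, c(15.5, 15.5))
  expect_equal(tiny$reason, "no_pixels")
  expect_error(sample_disc_mean(m, c(0, 0), -1, 3, c(15.5, 15.5)),
               class = "fcpoct_config_error")
})

make_test_visit <- function(layer_value = 120, lesions = NULL,
                            laterality = "left", n_px = 97) {
  cfg <- tiny_config(map_size_px = n_px)
  geom <- fcpoct:::map_geometry(cfg)
  layers <- stats::setNames(
    lapply(fcp_layers(), function(l) matrix(layer_value, n_px, n_px)),
    fcp_layers())
  stack <- thickness_stack(layers, geom$px_per_deg, geom$origin_px, "left")
  les <- if (!is.null(lesions)) lesion_set(lesions, cfg, "left") else NULL
  sens <- cbind(mesopic = (1:56) / 10, scotopic = rep(8, 56),
                mes_censored = 0, scot_censored = 0)
  list(patient_id = "P01", eye_id = "P01_E1", visit_index = 0L,
       months_since_baseline = 0, age = 70, pseudophakic = FALSE,
       laterality = laterality, group = "amd", stack = stack, lesions = les,
       sensitivities = sens)
}

test_that("extract_visit composes sampling, grading and covariates", {
  v <- make_test_visit()
  tab <- extract_visit(v, transform2d(), default_grid())
  expect_equal(nrow(tab), 56L)
  expect_equal(tab$grid_index, 0:55)
  for (l in fcp_layers()) expect_equal(tab[[paste0("thk_", l)]], rep(120, 56))
  for (b in fcp_biomarkers()) expect_false(any(tab[[paste0("flag_", b)]]))
  expect_equal(tab$mes_db, (1:56) / 10)
  expect_equal(tab$age, rep(70, 56))
})

test_that("a central PED flags exactly the stimuli its disc overlaps", {
  # PED of basal diameter 1000 um (~3.47 deg) at the fovea: overlaps the
  # 12 inner-ring stimuli (|c| = 1 deg < 1.74 + 0.85) but no 3-deg-ring
  # stimulus (3 - 0.85 = 2.15 > 1.74)
  les <- data.frame(biomarker = "PED", x_deg = 0, y_deg = 0,
                    diameter_um = 1000, height_um = 250)
  v <- make_test_visit(lesions = les)
  tab <- extract_visit(v, transform2d(), default_grid())
  r <- sqrt(tab$x_deg^2 + tab$y_deg^2)
  expect_true(all(tab$flag_PED[r < 1.5]))
  expect_false(any(tab$flag_PED[r > 2.5]))
  expect_false(any(tab$flag_cRORA))
})

test_that("extraction is invariant under mirroring the whole visit", {
  set.seed(54)
  les <- data.frame(biomarker = c("PED", "HRF"),
                    x_deg = c(1.5, -2.5), y_deg = c(0.5, -1),
                    diameter_um = c(1200, 180), height_um = c(260, NA))
  v <- make_test_visit(lesions = les)
  # impose an asymmetric thickness pattern
  v$stack$layers$RPEDC <- v$stack$layers$RPEDC +
    matrix(runif(97 * 97, 0, 30), 97, 97)
  tab_left <- extract_visit(v, transform2d(), default_grid())

  # mirrored (as-acquired right eye) version of the same retina
  vr <- v
  vr$laterality <- "right"
  vr$stack <- mirror_to_left(v$stack, "right"); vr$stack$laterality <- "right"
  vr$lesions <- mirror_to_left(v$lesions, "right")
  vr$lesions$laterality <- "right"
  perm <- fcpoct:::mirror_permutation(default_grid())
  vr$sensitivities <- v$sensitivities[perm, ]
  tab_right <- extract_visit(vr, transform2d(), default_grid())
  expect_equal(tab_right$thk_RPEDC, tab_left$thk_RPEDC, tolerance = 1e-12)
  expect_equal(tab_right$flag_PED, tab_left$flag_PED)
  expect_equal(tab_right$flag_HRF, tab_left$flag_HRF)
  expect_equal(tab_right$mes_db, tab_left$mes_db)
})
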