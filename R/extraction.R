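# Per-stimulus sampling of en-face thickness maps and biomarker grading.

#' Construct an en-face thickness stack
#'
#' A thickness stack holds one 2-D en-face thickness map (micrometers) per
#' retinal layer, all sharing the same pixel geometry: `px_per_deg` pixels
#' per degree and the fovea at pixel `origin_px` (0-based `(x, y)` =
#' (column, row), pixel centers, `(0, 0)` at the top-left). Values are
#' non-negative; `NA` marks missing pixels.
#'
#' @param layers Named list of equally sized numeric matrices (rows = y,
#'   columns = x), names from [fcp_layers()] (a subset is allowed).
#' @param px_per_deg Pixels per degree of visual angle.
#' @param origin_px Length-2 (x, y) 0-based pixel position of the fovea.
#' @param laterality `"left"` or `"right"`.
#' @param validate Check value constraints (skipped internally for maps the
#'   generator has already clamped).
#' @return An object of class `thickness_stack`.
#' @export
thickness_stack <- function(layers, px_per_deg, origin_px,
                            laterality = "left", validate = TRUE) {
  if (!length(layers) || is.null(names(layers)) || any(names(layers) == "")) {
    config_error("layers must be a non-empty named list of matrices")
  }
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    config_error("all layer maps must share the same dimensions")
  }
  if (validate) {
    for (nm in names(layers)) {
      m <- layers[[nm]]
      if (!is.numeric(m)) config_error(sprintf("layer %s is not numeric", nm))
      if (any(m < 0, na.rm = TRUE)) {
        config_error(sprintf("layer %s has negative thicknesses", nm))
      }
    }
  }
  if (!laterality %in% c("left", "right")) {
    config_error("laterality must be 'left' or 'right'")
  }
  structure(
    list(layers = layers, px_per_deg = px_per_deg,
         origin_px = as.numeric(origin_px), laterality = laterality,
         dim_px = dim(layers[[1]])),
    class = "thickness_stack"
  )
}

#' @export
print.thickness_stack <- function(x, ...) {
  cat(sprintf("<thickness_stack> %d layers, %d x %d px, %.2f px/deg, %s eye\n",
              length(x$layers), x$dim_px[1], x$dim_px[2], x$px_per_deg,
              x$laterality))
  invisible(x)
}

# Pixels whose centers fall inside the disc of given center/diameter (deg).
# Returns linear indices of in-map pixels plus total and in-map disc pixel
# counts (pixels are counted on the virtual infinite grid so edge coverage
# can be assessed).
disc_pixels <- function(dim_px, px_per_deg, origin_px, center, diameter) {
  r <- diameter / 2
  # pixel (row, col) center in degrees: x = (col - ox)/s, y = (row - oy)/s
  s <- px_per_deg
  ox <- origin_px[1]; oy <- origin_px[2]
  col_lo <- ceiling((center[1] - r) * s + ox - 0.5 + 1e-12)
  col_hi <- floor((center[1] + r) * s + ox + 0.5 - 1e-12)
  row_lo <- ceiling((center[2] - r) * s + oy - 0.5 + 1e-12)
  row_hi <- floor((center[2] + r) * s + oy + 0.5 - 1e-12)
  if (col_hi < col_lo || row_hi < row_lo) {
    return(list(idx = integer(0), n_total = 0L, n_inside = 0L))
  }
  cols <- col_lo:col_hi
  rows <- row_lo:row_hi
  cx <- (cols - ox) / s
  cy <- (rows - oy) / s
  inside <- outer(cy - center[2], cx - center[1],
                  function(dy, dx) dx^2 + dy^2 <= r^2)
  n_total <- sum(inside)
  ok_row <- rows >= 0L & rows < dim_px[1]
  ok_col <- cols >= 0L & cols < dim_px[2]
  inside_map <- inside & outer(ok_row, ok_col, `&`)
  n_inside <- sum(inside_map)
  if (!n_inside) {
    return(list(idx = integer(0), n_total = n_total, n_inside = 0L))
  }
  rr <- rows[row(inside_map)[inside_map]]
  cc <- cols[col(inside_map)[inside_map]]
  list(idx = rr + 1L + cc * dim_px[1], n_total = n_total, n_inside = n_inside)
}

#' Mean thickness over a stimulus disc
#'
#' Arithmetic mean of a single-layer en-face map over all pixels whose
#' centers fall within the disc of the given center and diameter. If less
#' than half of the disc lies inside the map (or no pixel center falls in
#' the disc) the result is `NA` with a reason code rather than a silently
#' truncated mean.
#'
#' @param map Numeric matrix (rows = y, columns = x), micrometers.
#' @param center Length-2 (x, y) disc center in degrees.
#' @param diameter Disc diameter in degrees.
#' @param px_per_deg,origin_px Map geometry as in [thickness_stack()].
#' @param min_coverage Minimum fraction of disc pixels that must lie inside
#'   the map (default 0.5).
#' @return List with `mean` (µm or `NA`), `n_pixels` used, and `reason`
#'   (`"ok"`, `"edge"`, or `"no_pixels"`).
#' @export
sample_disc_mean <- function(map, center, diameter, px_per_deg, origin_px,
                             min_coverage = 0.5) {
  if (diameter <= 0 || anyNA(center) || any(!is.finite(center))) {
    config_error("disc center must be finite and diameter positive")
  }
  dp <- disc_pixels(dim(map), px_per_deg, origin_px, center, diameter)
  if (dp$n_total == 0L) {
    return(list(mean = NA_real_, n_pixels = 0L, reason = "no_pixels"))
  }
  if (dp$n_inside / dp$n_total < min_coverage) {
    return(list(mean = NA_real_, n_pixels = dp$n_inside, reason = "edge"))
  }
  list(mean = mean(map[dp$idx]), n_pixels = dp$n_inside, reason = "ok")
}

#' Grade biomarker presence within a stimulus disc
#'
#' A biomarker is graded present when the fraction of disc pixels covered by
#' the lesion mask reaches `min_fraction`. With the default
#' `min_fraction = 0` any overlap at all flags presence, mirroring a human
#' reader who flags a biomarker anywhere within the stimulus area.
#'
#' @param mask Logical (or 0/1) matrix with the stack's geometry.
#' @inheritParams sample_disc_mean
#' @param min_fraction Required covered fraction in `[0, 1]`.
#' @return List with `present` (logical or `NA`), `fraction` covered,
#'   `n_pixels`, and `reason`.
#' @export
grade_presence <- function(mask, center, diameter, px_per_deg, origin_px,
                           min_fraction = 0, min_coverage = 0.5) {
  if (min_fraction < 0 || min_fraction > 1) {
    config_error("min_fraction must be in [0, 1]")
  }
  dp <- disc_pixels(dim(mask), px_per_deg, origin_px, center, diameter)
  if (dp$n_total == 0L) {
    return(list(present = NA, fraction = NA_real_, n_pixels = 0L,
                reason = "no_pixels"))
  }
  if (dp$n_inside / dp$n_total < min_coverage) {
    return(list(present = NA, fraction = NA_real_, n_pixels = dp$n_inside,
                reason = "edge"))
  }
  frac <- sum(mask[dp$idx] != 0) / dp$n_inside
  present <- if (min_fraction == 0) frac > 0 else frac >= min_fraction
  list(present = present, fraction = frac, n_pixels = dp$n_inside,
       reason = "ok")
}

#' Extract per-stimulus observations for one visit
#'
#' Combines the registered stimulus positions with the visit's thickness
#' stack, lesion masks, sensitivities and covariates into one row per grid
#' point: the unit of analysis of the association models. Right-eye visits
#' are mirrored to left-eye orientation first (maps, masks and the
#' sensitivity indexing); the supplied transform must already be expressed
#' in left-eye orientation (as produced by [register_visit()]).
#'
#' @param visit A visit record as produced by [simulate_cohort()] (fields
#'   `stack`, `lesions`, `sensitivities`, `eye_id`, `visit_index`,
#'   `months_since_baseline`, `laterality`, plus eye covariates `age`,
#'   `pseudophakic`, `patient_id`).
#' @param transform FCP-to-OCT [transform2d()] in left-eye orientation.
#' @param grid A [stimulus_grid()].
#' @param min_fraction Presence-grading threshold, see [grade_presence()].
#' @return Data frame with 56 rows (columns: ids, covariates, mapped
#'   centers, per-layer mean thicknesses `thk_*`, per-biomarker flags
#'   `flag_*`, `mes_db`, `scot_db`, censoring flags, `n_pixels`, `reason`).
#' @export
extract_visit <- function(visit, transform, grid, min_fraction = 0) {
  stack <- mirror_to_left(visit$stack)
  lesions <- if (!is.null(visit$lesions)) mirror_to_left(visit$lesions) else NULL
  sens <- visit$sensitivities
  if (visit$laterality == "right") {
    perm <- mirror_permutation(grid)
    sens <- sens[perm, , drop = FALSE]
  }
  mapped <- map_stimuli(grid, transform)
  n <- nrow(grid$centers)
  layers <- names(stack$layers)
  bio <- fcp_biomarkers()

  thk <- matrix(NA_real_, n, length(layers),
                dimnames = list(NULL, paste0("thk_", layers)))
  npx <- integer(n)
  reason <- character(n)
  flags <- matrix(NA, n, length(bio),
                  dimnames = list(NULL, paste0("flag_", bio)))

  for (k in seq_len(n)) {
    ctr <- mapped$centers[k, ]
    dia <- mapped$extraction_diameter_deg
    first <- TRUE
    for (l in seq_along(layers)) {
      sm <- sample_disc_mean(stack$layers[[l]], ctr, dia,
                             stack$px_per_deg, stack$origin_px)
      thk[k, l] <- sm$mean
      if (first) {
        npx[k] <- sm$n_pixels
        reason[k] <- sm$reason
        first <- FALSE
      }
    }
    for (b in seq_along(bio)) {
      mask <- lesions$masks[[bio[b]]]
      if (is.null(mask)) {
        flags[k, b] <- FALSE
      } else {
        gp <- grade_presence(mask, ctr, dia, stack$px_per_deg,
                             stack$origin_px, min_fraction = min_fraction)
        flags[k, b] <- gp$present
      }
    }
  }

  out <- data.frame(
    patient_id = visit$patient_id,
    eye_id = visit$eye_id,
    visit_index = visit$visit_index,
    grid_index = seq_len(n) - 1L,
    x_deg = mapped$centers[, 1],
    y_deg = mapped$centers[, 2],
    age = visit$age,
    pseudophakic = visit$pseudophakic,
    months_since_baseline = visit$months_since_baseline,
    mes_db = sens[, "mesopic"],
    scot_db = sens[, "scotopic"],
    mes_censored = sens[, "mes_censored"] != 0,
    scot_censored = sens[, "scot_censored"] != 0,
    n_pixels = npx,
    reason = reason
  )
  cbind(out, as.data.frame(thk), as.data.frame(flags))
}

#' Register one visit's landmark pair in left-eye orientation
#'
#' Mirrors both landmark frames of a right-eye visit to left-eye orientation
#' and estimates the FCP-to-OCT transform from the correspondences.
#'
#' @param visit Visit record carrying `landmarks_fcp` and `landmarks_oct`.
#' @param ... Passed to [estimate_transform()].
#' @return A [transform2d()] in left-eye orientation.
#' @export
register_visit <- function(visit, ...) {
  src <- mirror_to_left(visit$landmarks_fcp, visit$laterality)
  dst <- mirror_to_left(visit$landmarks_oct, visit$laterality)
  estimate_transform(src, dst, ...)
}
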