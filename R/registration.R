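# Landmark-based registration of the FCP frame to the OCT en-face frame.

#' Construct a landmark set
#'
#' Landmarks are the anchors used to register the perimetry (FCP) frame to
#' the OCT en-face frame: the foveal pit, the optic disc position, and an
#' ordered list of vessel bifurcations. Correspondence across frames is by
#' type and index (fovea to fovea, disc to disc, vessel i to vessel i); the
#' package does not attempt automatic bifurcation matching.
#'
#' @param fovea,optic_disc Length-2 numeric (x, y) in degrees.
#' @param vessels n x 2 numeric matrix of vessel bifurcations (may be empty).
#' @param frame_id Character label, e.g. `"OCT"` or `"FCP"`.
#' @param laterality `"left"` or `"right"`.
#' @return An object of class `landmark_set`: a data frame with columns
#'   `landmark_type`, `index`, `x`, `y` and attributes `frame_id`,
#'   `laterality`.
#' @export
landmark_set <- function(fovea, optic_disc, vessels = NULL,
                         frame_id = "OCT", laterality = "left") {
  if (is.null(vessels)) vessels <- matrix(numeric(0), ncol = 2)
  vessels <- as.matrix(vessels)
  pts <- rbind(matrix(fovea, ncol = 2), matrix(optic_disc, ncol = 2), vessels)
  if (anyNA(pts) || any(!is.finite(pts))) {
    config_error("all landmark coordinates must be finite")
  }
  df <- data.frame(
    landmark_type = c("fovea", "disc",
                      rep("vessel", nrow(vessels))),
    index = c(0L, 0L, seq_len(nrow(vessels))),
    x = pts[, 1], y = pts[, 2]
  )
  structure(df, class = c("landmark_set", "data.frame"),
            frame_id = frame_id, laterality = laterality)
}

landmark_matrix <- function(lm) as.matrix(lm[, c("x", "y")])

# Default anchor weighting: fovea and optic disc are the primary anchors and
# get 3x the weight of each vessel bifurcation.
landmark_weights <- function(lm, fovea_disc_weight = 3) {
  ifelse(lm$landmark_type %in% c("fovea", "disc"), fovea_disc_weight, 1)
}

#' Estimate the transform between two landmark frames
#'
#' Weighted least-squares estimation of the planar transform mapping `src`
#' landmark positions onto `dst`. The similarity family (isotropic scale +
#' rotation + translation) is solved in closed form by weighted orthogonal
#' Procrustes analysis with scale; the affine family by weighted linear
#' regression. The fovea and optic disc are up-weighted relative to vessel
#' bifurcations (default 3x) as the primary anchors.
#'
#' @param src,dst Corresponding [landmark_set()]s (or plain n x 2 matrices of
#'   paired points) in the source and destination frames. Points are paired
#'   in order.
#' @param family `"similarity"` (default) or `"affine"`.
#' @param weights Optional per-point positive weights; defaults to the
#'   fovea/disc up-weighting for landmark sets and uniform weights for
#'   matrices.
#' @param fovea_disc_weight Relative weight of fovea and disc landmarks.
#' @param allow_reflection Permit a reflecting similarity. Off by default:
#'   right eyes are mirrored explicitly beforehand (see [mirror_to_left()]).
#' @return A [transform2d()] with attribute `"diagnostics"` carrying the RMS
#'   residual and per-point residuals (in destination units).
#' @export
#' @examples
#' src <- matrix(rnorm(12), ncol = 2)
#' tr <- transform2d(1.2 * rot2(pi / 6), c(3, -2))
#' fit <- estimate_transform(src, apply_transform(tr, src))
#' attr(fit, "diagnostics")$rms  # ~ 0
estimate_transform <- function(src, dst,
                               family = c("similarity", "affine"),
                               weights = NULL,
                               fovea_disc_weight = 3,
                               allow_reflection = FALSE) {
  family <- match.arg(family)
  if (inherits(src, "landmark_set")) {
    if (is.null(weights)) weights <- landmark_weights(src, fovea_disc_weight)
    src <- landmark_matrix(src)
  }
  if (inherits(dst, "landmark_set")) dst <- landmark_matrix(dst)
  src <- as.matrix(src); dst <- as.matrix(dst)
  n <- nrow(src)
  if (nrow(dst) != n) {
    config_error(sprintf("mismatched correspondence: %d source vs %d destination points",
                         n, nrow(dst)))
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n || any(weights <= 0)) {
    config_error("weights must be positive, one per landmark pair")
  }
  min_n <- if (family == "similarity") 2L else 3L
  if (n < min_n) {
    config_error(sprintf("%s estimation needs at least %d point pairs, got %d",
                         family, min_n, n))
  }

  w <- weights / sum(weights)
  mu_s <- colSums(src * w)
  mu_d <- colSums(dst * w)
  xs <- sweep(src, 2, mu_s)
  xd <- sweep(dst, 2, mu_d)
  var_s <- sum(w * rowSums(xs^2))

  if (family == "similarity") {
    if (var_s < .Machine$double.eps) {
      config_error("degenerate landmarks: all source points coincide")
    }
    # weighted Umeyama: C = sum_i w_i * xd_i xs_i'
    C <- t(xd * w) %*% xs
    sv <- svd(C)
    if (!allow_reflection) {
      # constrain to det(R) = +1 (Umeyama correction term)
      S <- diag(c(1, if (det(sv$u) * det(sv$v) < 0) -1 else 1))
      R <- sv$u %*% S %*% t(sv$v)
      s <- sum(diag(S) * sv$d) / var_s
    } else {
      R <- sv$u %*% t(sv$v)
      s <- sum(sv$d) / var_s
    }
    if (s <= 0) config_error("estimated non-positive scale; landmarks are degenerate")
    A <- s * R
    b <- mu_d - as.numeric(A %*% mu_s)
    tr <- transform2d(A, b, family = "similarity",
                      allow_reflection = allow_reflection)
  } else {
    # rank check on centered source
    if (min(svd(xs * sqrt(w))$d) < 1e-10 * max(1, max(abs(xs)))) {
      config_error("affine estimation needs >= 3 non-collinear source points")
    }
    fitx <- stats::lm.wfit(cbind(1, src), dst[, 1], w = weights)
    fity <- stats::lm.wfit(cbind(1, src), dst[, 2], w = weights)
    A <- rbind(fitx$coefficients[2:3], fity$coefficients[2:3])
    b <- c(fitx$coefficients[1], fity$coefficients[1])
    tr <- transform2d(A, b, family = "affine")
  }

  res <- apply_transform(tr, src) - dst
  per_point <- sqrt(rowSums(res^2))
  attr(tr, "diagnostics") <- list(
    rms = sqrt(mean(per_point^2)),
    per_point = per_point
  )
  tr
}

#' Rotation matrix helper
#'
#' @param theta Angle in radians (positive = from +x toward +y).
#' @return 2 x 2 rotation matrix.
#' @export
rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Map stimulus centers into the OCT frame
#'
#' Transforms every stimulus center of a grid through the fitted FCP-to-OCT
#' transform and rescales the effective extraction radius by the transform's
#' isotropic scale factor. Output row order preserves grid indexing.
#'
#' @param grid A [stimulus_grid()].
#' @param transform A [transform2d()].
#' @return List with `centers` (n x 2 matrix in the OCT frame) and
#'   `extraction_diameter_deg` (rescaled disc diameter).
#' @export
map_stimuli <- function(grid, transform) {
  stopifnot(inherits(grid, "stimulus_grid"))
  if (abs(det(transform$A)) < .Machine$double.eps) {
    config_error("cannot map stimuli through a singular transform")
  }
  sc <- if (transform$family == "similarity") transform_scale(transform) else 1
  list(
    centers = apply_transform(transform, grid$centers),
    extraction_diameter_deg = grid$extraction_diameter_deg * sc
  )
}

# mirroring -------------------------------------------------------------------

#' Mirror right-eye data to left-eye orientation
#'
#' Retinal data from right eyes are reflected about the vertical axis through
#' the fovea so that all eyes share a common (left-eye) anatomical
#' orientation: x rightward, y downward, optic disc on the nasal (negative x)
#' side. Left-eye input is returned unchanged; applying the mirror twice to
#' right-eye data is the identity.
#'
#' @param data A [landmark_set()], [stimulus_grid()], `thickness_stack` or
#'   `lesion_set`.
#' @param laterality `"left"` or `"right"`; defaults to the object's own
#'   laterality where it carries one.
#' @return The object in left-eye orientation.
#' @export
mirror_to_left <- function(data, laterality = NULL) {
  UseMethod("mirror_to_left")
}

resolve_laterality <- function(data, laterality) {
  lat <- laterality %||% attr(data, "laterality") %||% data$laterality
  if (is.null(lat) || !lat %in% c("left", "right")) {
    config_error("laterality must be 'left' or 'right'")
  }
  lat
}

#' @export
mirror_to_left.landmark_set <- function(data, laterality = NULL) {
  lat <- resolve_laterality(data, laterality)
  if (lat == "left") return(data)
  data$x <- -data$x
  attr(data, "laterality") <- "left"
  data
}

#' @export
mirror_to_left.stimulus_grid <- function(data, laterality = NULL) {
  if (is.null(laterality)) {
    config_error("laterality must be 'left' or 'right'")
  }
  if (laterality == "left") return(data)
  if (laterality != "right") config_error("laterality must be 'left' or 'right'")
  data$centers[, 1] <- -data$centers[, 1]
  data
}

#' @export
mirror_to_left.thickness_stack <- function(data, laterality = NULL) {
  lat <- resolve_laterality(data, laterality)
  if (lat == "left") return(data)
  nc <- ncol(data$layers[[1]])
  data$layers <- lapply(data$layers, function(m) m[, nc:1, drop = FALSE])
  data$origin_px[1] <- (nc - 1) - data$origin_px[1]
  data$laterality <- "left"
  data
}

#' @export
mirror_to_left.lesion_set <- function(data, laterality = NULL) {
  lat <- resolve_laterality(data, laterality)
  if (lat == "left") return(data)
  data$masks <- lapply(data$masks, function(m) {
    if (is.null(m)) return(NULL)
    m[, ncol(m):1, drop = FALSE]
  })
  if (nrow(data$lesions)) data$lesions$x_deg <- -data$lesions$x_deg
  data$origin_px[1] <- (data$dim_px[2] - 1) - data$origin_px[1]
  data$laterality <- "left"
  data
}
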