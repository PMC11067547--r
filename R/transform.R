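# 2-D similarity / affine transforms between the FCP and OCT frames.

#' Construct a 2-D planar transform
#'
#' A transform maps points `p` (row vectors, degrees) to `A %*% p + b`. For
#' the `"similarity"` family the linear part must be `s * R` with `s > 0` and
#' `R` a rotation (reflections are excluded unless `allow_reflection = TRUE`;
#' eye mirroring is handled explicitly by [mirror_to_left()], not by the
#' fitted transform). For the `"affine"` family any invertible linear part is
#' accepted.
#'
#' @param A 2 x 2 numeric matrix, the linear part.
#' @param b Length-2 numeric translation.
#' @param family `"similarity"` or `"affine"`.
#' @param allow_reflection Permit `det(A) < 0` for similarity transforms.
#' @return An object of class `transform2d`.
#' @export
transform2d <- function(A = diag(2), b = c(0, 0),
                        family = c("similarity", "affine"),
                        allow_reflection = FALSE) {
  family <- match.arg(family)
  A <- matrix(as.numeric(A), 2, 2)
  b <- as.numeric(b)
  if (length(b) != 2L || anyNA(A) || anyNA(b) || any(!is.finite(A))) {
    config_error("transform2d needs a finite 2x2 linear part and length-2 translation")
  }
  d <- det(A)
  if (family == "similarity") {
    if (d < 0 && !allow_reflection) {
      config_error("similarity transform has a reflection but allow_reflection is FALSE")
    }
    s <- sqrt(abs(d))
    if (s <= 0) config_error("similarity transform has zero scale")
    R <- A / s
    if (max(abs(crossprod(R) - diag(2))) > 1e-6) {
      config_error("linear part is not scale * rotation; use family = 'affine'")
    }
  } else if (abs(d) < .Machine$double.eps) {
    config_error("affine transform has a singular linear part")
  }
  structure(
    list(A = A, b = b, family = family, allow_reflection = allow_reflection),
    class = "transform2d"
  )
}

#' Apply a transform to points
#'
#' @param transform A [transform2d()].
#' @param points n x 2 numeric matrix (or length-2 vector) of points.
#' @return n x 2 matrix of transformed points.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "transform2d"))
  pts <- if (is.null(dim(points))) matrix(points, ncol = 2) else as.matrix(points)
  out <- pts %*% t(transform$A)
  out[, 1] <- out[, 1] + transform$b[1]
  out[, 2] <- out[, 2] + transform$b[2]
  colnames(out) <- c("x", "y")
  out
}

#' Scale factor of a transform
#'
#' For a similarity transform this is the isotropic scale `s`; for an affine
#' transform the square root of `|det(A)|` (area-preserving scale).
#'
#' @inheritParams apply_transform
#' @return Positive scalar.
#' @export
transform_scale <- function(transform) {
  sqrt(abs(det(transform$A)))
}

#' Invert a transform
#' @inheritParams apply_transform
#' @return The inverse `transform2d`.
#' @export
invert_transform <- function(transform) {
  Ai <- solve(transform$A)
  transform2d(Ai, -as.numeric(Ai %*% transform$b), family = transform$family,
              allow_reflection = transform$allow_reflection)
}

compose_transforms <- function(second, first) {
  # second(first(x))
  fam <- if (second$family == "affine" || first$family == "affine") "affine" else "similarity"
  transform2d(second$A %*% first$A,
              as.numeric(second$A %*% first$b) + second$b,
              family = fam,
              allow_reflection = second$allow_reflection || first$allow_reflection)
}

#' @export
print.transform2d <- function(x, ...) {
  cat(sprintf("<transform2d:%s> scale %.4f\n", x$family, transform_scale(x)))
  cat("A =\n"); print(x$A)
  cat("b =", format(x$b), "\n")
  invisible(x)
}

#' Serialize / restore a transform as JSON
#'
#' The JSON carries the family, the six coefficients and (optionally) fit
#' diagnostics attached by [estimate_transform()].
#'
#' @inheritParams apply_transform
#' @param path File path.
#' @return `write_transform_json` returns `path` invisibly;
#'   `read_transform_json` returns a `transform2d`.
#' @export
write_transform_json <- function(transform, path) {
  diag_ <- attr(transform, "diagnostics")
  obj <- list(
    family = transform$family,
    A = as.numeric(transform$A),  # column-major
    b = transform$b,
    allow_reflection = transform$allow_reflection
  )
  if (!is.null(diag_)) {
    obj$rms_residual <- diag_$rms
    obj$per_point_residuals <- diag_$per_point
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  if (!file.exists(path)) io_error(sprintf("transform file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- transform2d(matrix(obj$A, 2, 2), obj$b, family = obj$family,
                    allow_reflection = isTRUE(obj$allow_reflection))
  if (!is.null(obj$rms_residual)) {
    attr(tr, "diagnostics") <- list(rms = obj$rms_residual,
                                    per_point = obj$per_point_residuals)
  }
  tr
}
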