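# Stimulus grid: fovea-centered microperimetry test-point layout.

#' Construct a stimulus grid
#'
#' A stimulus grid holds the fovea-centered test-point layout of a
#' fundus-controlled perimetry exam together with the per-modality Goldmann
#' stimulus sizes. Coordinates are in degrees of visual angle, x rightward and
#' y downward in left-eye orientation, fovea at the origin.
#'
#' @param centers Two-column numeric matrix (x, y) of stimulus centers in
#'   degrees.
#' @param mesopic_diameter_deg,scotopic_diameter_deg Stimulus diameters in
#'   degrees of visual angle (Goldmann III and V).
#' @param extraction_diameter_deg Diameter of the disc over which structural
#'   quantities are sampled; defaults to the scotopic (Goldmann V) stimulus.
#'
#' @return An object of class `stimulus_grid`.
#' @seealso [default_grid()]
#' @export
stimulus_grid <- function(centers,
                          mesopic_diameter_deg = 0.43,
                          scotopic_diameter_deg = 1.7,
                          extraction_diameter_deg = scotopic_diameter_deg) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 2L || !is.numeric(centers) || anyNA(centers) ||
      any(!is.finite(centers))) {
    config_error("stimulus centers must be a finite numeric n x 2 matrix")
  }
  colnames(centers) <- c("x", "y")
  rownames(centers) <- NULL
  structure(
    list(
      centers = centers,
      mesopic_diameter_deg = mesopic_diameter_deg,
      scotopic_diameter_deg = scotopic_diameter_deg,
      extraction_diameter_deg = extraction_diameter_deg
    ),
    class = "stimulus_grid"
  )
}

#' Default 56-point 10 x 10 degree stimulus grid
#'
#' The default layout places 56 stimuli on three concentric rings of 12, 20
#' and 24 points at radii 1, 3 and 5 degrees, centered on the fovea, spanning
#' a 10 x 10 degree field. Each ring starts on the positive x axis with
#' uniform angular spacing, giving a 4-fold symmetric, mirror-symmetric
#' pattern. The measured pattern of a specific device can be substituted via
#' [read_grid_csv()].
#'
#' @inheritParams stimulus_grid
#' @return A `stimulus_grid` with 56 centers.
#' @export
#' @examples
#' g <- default_grid()
#' nrow(g$centers)  # 56
default_grid <- function(extraction_diameter_deg = 1.7) {
  ring <- function(n, r) {
    a <- 2 * pi * (seq_len(n) - 1) / n
    cbind(r * cos(a), r * sin(a))
  }
  centers <- rbind(ring(12, 1), ring(20, 3), ring(24, 5))
  stimulus_grid(centers, extraction_diameter_deg = extraction_diameter_deg)
}

#' @export
print.stimulus_grid <- function(x, ...) {
  cat(sprintf(
    "<stimulus_grid> %d points, mesopic %.2f deg / scotopic %.2f deg, extraction disc %.2f deg\n",
    nrow(x$centers), x$mesopic_diameter_deg, x$scotopic_diameter_deg,
    x$extraction_diameter_deg
  ))
  invisible(x)
}

# Index permutation induced by mirroring the grid about the vertical axis
# through the fovea (x -> -x). The default grid is closed under this
# reflection; a custom grid must be too for right-eye data to be usable.
mirror_permutation <- function(grid, tol = 1e-8) {
  ctr <- grid$centers
  mirrored <- cbind(-ctr[, 1], ctr[, 2])
  perm <- integer(nrow(ctr))
  for (k in seq_len(nrow(ctr))) {
    d2 <- (ctr[, 1] - mirrored[k, 1])^2 + (ctr[, 2] - mirrored[k, 2])^2
    j <- which.min(d2)
    if (d2[j] > tol^2) {
      config_error("stimulus grid is not mirror-symmetric; cannot re-index right-eye data")
    }
    perm[k] <- j
  }
  if (anyDuplicated(perm)) {
    config_error("stimulus grid mirror mapping is not one-to-one")
  }
  perm
}
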