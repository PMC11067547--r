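# Readers and writers for on-disk artifacts. Thickness maps and lesion masks
# are tab-delimited numeric grids with the geometry carried in '#' comment
# header lines (single-file portability); tabular artifacts are plain CSV
# (UTF-8, comma separator, '.' decimal).

map_header <- function(px_per_deg, origin_px, laterality, layer = NULL) {
  h <- c(sprintf("# px_per_deg: %.*g", 15, px_per_deg),
         sprintf("# origin_px: %.*g %.*g", 15, origin_px[1], 15, origin_px[2]),
         sprintf("# laterality: %s", laterality))
  if (!is.null(layer)) h <- c(h, sprintf("# layer: %s", layer))
  h
}

parse_map_header <- function(lines, path) {
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(ln)) {
      io_error(sprintf("%s: missing '%s' geometry header", path, key))
    }
    sub(paste0("^#\\s*", key, ":\\s*"), "", ln[1])
  }
  list(
    px_per_deg = as.numeric(get("px_per_deg")),
    origin_px = as.numeric(strsplit(trimws(get("origin_px")), "\\s+")[[1]]),
    laterality = trimws(get("laterality")),
    layer = {
      ln <- grep("^#\\s*layer:", hdr, value = TRUE)
      if (length(ln)) trimws(sub("^#\\s*layer:\\s*", "", ln[1])) else NULL
    }
  )
}

read_delimited_grid <- function(path) {
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  lines <- readLines(path)
  hdr <- parse_map_header(lines, path)
  body_ln <- which(!grepl("^#", lines) & nzchar(lines))
  if (!length(body_ln)) io_error(sprintf("%s: no data rows", path))
  rows <- strsplit(lines[body_ln], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- body_ln[which(widths != widths[1])[1]]
    io_error(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                     path, bad, widths[which(widths != widths[1])[1]],
                     widths[1]))
  }
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  raw <- unlist(rows)
  bad_cell <- which(is.na(vals) & !(raw %in% c("NA", "NaN", "")))
  if (length(bad_cell)) {
    line_of <- body_ln[ceiling(bad_cell[1] / widths[1])]
    io_error(sprintf("%s: non-numeric cell '%s' at line %d",
                     path, raw[bad_cell[1]], line_of))
  }
  m <- matrix(vals, nrow = length(rows), byrow = TRUE)
  list(matrix = m, header = hdr)
}

#' Write / read a single-layer en-face thickness map
#'
#' Tab-delimited numeric grid (one row of the map per line) preceded by `#`
#' comment lines carrying the geometry: pixels per degree, the fovea origin
#' pixel and the laterality, plus the layer name. `NA` cells are preserved
#' as missing. Malformed files (ragged rows, non-numeric cells, missing
#' geometry) raise an error naming the offending line.
#'
#' @param map Numeric matrix (µm).
#' @param path File path.
#' @param px_per_deg,origin_px,laterality Map geometry, see
#'   [thickness_stack()].
#' @param layer Optional layer name stored in the header.
#' @return `write_thickness_map` returns `path` invisibly;
#'   `read_thickness_map` a list with `matrix`, `px_per_deg`, `origin_px`,
#'   `laterality`, `layer`.
#' @export
write_thickness_map <- function(map, path, px_per_deg, origin_px,
                                laterality = "left", layer = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(map_header(px_per_deg, origin_px, laterality, layer), con)
  # %.17g guarantees a bit-exact double round trip
  body <- apply(map, 1, function(row) {
    txt <- sprintf("%.17g", row)
    txt[is.na(row)] <- "NA"
    paste(txt, collapse = "\t")
  })
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_thickness_map
#' @export
read_thickness_map <- function(path) {
  out <- read_delimited_grid(path)
  list(matrix = out$matrix, px_per_deg = out$header$px_per_deg,
       origin_px = out$header$origin_px, laterality = out$header$laterality,
       layer = out$header$layer)
}

#' Write / read a whole thickness stack as one file per layer
#'
#' @param stack A [thickness_stack()].
#' @param dir Directory; files are named `thickness_<layer>.tsv`.
#' @return `write_thickness_stack` returns the file paths invisibly;
#'   `read_thickness_stack` a `thickness_stack`.
#' @export
write_thickness_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(names(stack$layers), function(l) {
    p <- file.path(dir, sprintf("thickness_%s.tsv", l))
    write_thickness_map(stack$layers[[l]], p, stack$px_per_deg,
                        stack$origin_px, stack$laterality, l)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_thickness_stack
#' @export
read_thickness_stack <- function(dir) {
  files <- list.files(dir, pattern = "^thickness_.*\\.tsv$",
                      full.names = TRUE)
  if (!length(files)) io_error(sprintf("no thickness maps found in %s", dir))
  maps <- lapply(files, read_thickness_map)
  layers <- lapply(maps, `[[`, "matrix")
  names(layers) <- vapply(maps, function(m) {
    m$layer %||% sub("^thickness_(.*)\\.tsv$", "\\1", basename(files[1]))
  }, character(1))
  ord <- intersect(fcp_layers(), names(layers))
  thickness_stack(layers[ord], maps[[1]]$px_per_deg, maps[[1]]$origin_px,
                  maps[[1]]$laterality)
}

#' Write / read a binary lesion mask as a 0/1 tab-delimited grid
#'
#' Same format and geometry header as [write_thickness_map()].
#'
#' @param mask Logical (or 0/1) matrix.
#' @inheritParams write_thickness_map
#' @param biomarker Optional biomarker name stored in the header.
#' @return `read_lesion_mask` returns a list with a logical `mask` plus the
#'   geometry fields.
#' @export
write_lesion_mask <- function(mask, path, px_per_deg, origin_px,
                              laterality = "left", biomarker = NULL) {
  write_thickness_map(mask * 1, path, px_per_deg, origin_px, laterality,
                      layer = biomarker)
}

#' @rdname write_lesion_mask
#' @export
read_lesion_mask <- function(path) {
  out <- read_delimited_grid(path)
  if (any(!out$matrix %in% c(0, 1), na.rm = TRUE)) {
    io_error(sprintf("%s: mask cells must be 0 or 1", path))
  }
  list(mask = out$matrix != 0, px_per_deg = out$header$px_per_deg,
       origin_px = out$header$origin_px, laterality = out$header$laterality,
       biomarker = out$header$layer)
}

#' Write / read a landmark set as CSV
#'
#' Columns: `frame_id`, `landmark_type` (fovea, disc, vessel), `index`,
#' `x`, `y`, `units`.
#'
#' @param landmarks A [landmark_set()].
#' @param path File path.
#' @return `read_landmarks_csv` returns a `landmark_set`.
#' @export
write_landmarks_csv <- function(landmarks, path) {
  df <- data.frame(frame_id = attr(landmarks, "frame_id"),
                   landmark_type = landmarks$landmark_type,
                   index = landmarks$index,
                   x = landmarks$x, y = landmarks$y, units = "deg",
                   laterality = attr(landmarks, "laterality"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks_csv
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("landmark file not found: %s", path))
  df <- utils::read.csv(path)
  need <- c("frame_id", "landmark_type", "index", "x", "y")
  if (!all(need %in% names(df))) {
    io_error(sprintf("%s: landmark CSV needs columns %s", path,
                     paste(need, collapse = ", ")))
  }
  fov <- df[df$landmark_type == "fovea", c("x", "y")]
  disc <- df[df$landmark_type == "disc", c("x", "y")]
  if (nrow(fov) != 1 || nrow(disc) != 1) {
    io_error(sprintf("%s: exactly one fovea and one disc landmark required",
                     path))
  }
  vess <- df[df$landmark_type == "vessel", ]
  vess <- vess[order(vess$index), c("x", "y")]
  landmark_set(as.numeric(fov), as.numeric(disc), as.matrix(vess),
               frame_id = df$frame_id[1],
               laterality = if ("laterality" %in% names(df))
                 df$laterality[1] else "left")
}

#' Read a stimulus grid from CSV
#'
#' Expects columns `x` and `y` in degrees (one row per stimulus), so a
#' measured device pattern can replace the default layout.
#'
#' @param path CSV path.
#' @param ... Passed to [stimulus_grid()].
#' @return A `stimulus_grid`.
#' @export
read_grid_csv <- function(path, ...) {
  if (!file.exists(path)) io_error(sprintf("grid file not found: %s", path))
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df))) {
    io_error(sprintf("%s: grid CSV needs 'x' and 'y' columns", path))
  }
  stimulus_grid(cbind(df$x, df$y), ...)
}

#' Write / read the point-wise observation table as CSV
#'
#' One row per (eye, visit, grid position), fixed column schema as produced
#' by [extract_visit()] / [normalize_observations()].
#'
#' @param table Data frame.
#' @param path File path.
#' @return `read_pointwise_csv` returns the data frame.
#' @export
write_pointwise_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pointwise_csv
#' @export
read_pointwise_csv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("table not found: %s", path))
  utils::read.csv(path)
}

#' Write / read a normative reference as CSV
#'
#' Long format: `grid_index`, `quantity`, `mean`, `sd`, `n`, `floored`.
#'
#' @param reference A [build_normative()] reference.
#' @param path File path.
#' @return `read_normative_csv` returns a `normative_reference`.
#' @export
write_normative_csv <- function(reference, path) {
  df <- as.data.frame(reference)
  df$n_controls <- attr(reference, "n_controls")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_normative_csv
#' @export
read_normative_csv <- function(path) {
  if (!file.exists(path)) io_error(sprintf("reference not found: %s", path))
  df <- utils::read.csv(path)
  n_controls <- df$n_controls[1]
  df$n_controls <- NULL
  structure(df, class = c("normative_reference", "data.frame"),
            n_controls = n_controls)
}

#' Export a fitted model result
#'
#' `write_model_csv` writes the coefficient table in the result-table layout
#' (term, estimate, SE, 95% CI, p-value); `write_model_json` additionally
#' serializes random-effect SDs and fit metadata.
#'
#' @param result An `sf_model_result`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_model_csv <- function(result, path) {
  utils::write.csv(result$coefficients, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_csv
#' @export
write_model_json <- function(result, path) {
  obj <- list(
    endogenous = result$spec$endogenous,
    type = result$spec$type,
    method = result$method,
    p_value_method = result$p_value_method,
    n_rows = result$n_rows,
    n_dropped = result$n_dropped,
    converged = result$converged,
    singular = result$singular,
    logLik = result$logLik,
    coefficients = result$coefficients,
    random_effects = result$random_effects
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
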