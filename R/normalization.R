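# Normative reference from the control cohort; deviations and z-scores.

SD_FLOOR_SENS_DB <- 0.25
SD_FLOOR_THK_UM <- 0.5

#' Build a normative reference from control observations
#'
#' Computes, at every grid position, the control-cohort mean and sample SD of
#' mesopic and scotopic sensitivity (dB) and of each layer's sampled
#' thickness (µm). These define the point-wise sensitivity deviation and
#' thickness z-scores entering the association models.
#'
#' Positions with control SD below a floor (0.25 dB for sensitivities,
#' 0.5 µm for thicknesses) are floored to that value so that z-scores stay
#' bounded when the control cohort is small; the `floored` column records
#' where this happened.
#'
#' @param control_observations Point-wise table of control eyes as produced
#'   by [extract_visit()] (one eye may contribute several rows per position
#'   only via several visits; each position needs at least 2 distinct
#'   control eyes).
#' @return Object of class `normative_reference`: a long data frame with
#'   columns `grid_index`, `quantity` (`"mes_db"`, `"scot_db"`, or
#'   `"thk_<layer>"`), `mean`, `sd`, `n`, `floored`, plus attribute
#'   `n_controls`.
#' @export
build_normative <- function(control_observations) {
  tab <- control_observations
  quantities <- c("mes_db", "scot_db",
                  intersect(paste0("thk_", fcp_layers()), names(tab)))
  counts <- tapply(tab$eye_id, tab$grid_index,
                   function(e) length(unique(e)))
  bad <- names(counts)[is.na(counts) | counts < 2]
  if (length(bad)) {
    config_error(sprintf(
      "normative reference needs >= 2 control eyes at every grid position; deficient positions: %s",
      paste(bad, collapse = ", ")))
  }
  gi <- sort(unique(tab$grid_index))
  out <- do.call(rbind, lapply(quantities, function(q) {
    mu <- tapply(tab[[q]], tab$grid_index, mean, na.rm = TRUE)
    sdv <- tapply(tab[[q]], tab$grid_index, stats::sd, na.rm = TRUE)
    nn <- tapply(!is.na(tab[[q]]), tab$grid_index, sum)
    floor_v <- if (startsWith(q, "thk_")) SD_FLOOR_THK_UM else SD_FLOOR_SENS_DB
    floored <- !is.na(sdv) & sdv < floor_v
    sdv[floored] <- floor_v
    data.frame(grid_index = as.integer(names(mu)), quantity = q,
               mean = as.numeric(mu), sd = as.numeric(sdv),
               n = as.integer(nn), floored = floored, row.names = NULL)
  }))
  structure(out, class = c("normative_reference", "data.frame"),
            n_controls = length(unique(tab$eye_id)))
}

normative_lookup <- function(reference, quantity) {
  sub <- reference[reference$quantity == quantity, ]
  if (!nrow(sub)) {
    config_error(sprintf("normative reference has no quantity '%s'", quantity))
  }
  sub[match(seq(0, max(sub$grid_index)), sub$grid_index), c("mean", "sd")]
}

#' Point-wise sensitivity deviation from the normative mean
#'
#' `observed - control mean` at the same grid position: negative values
#' signify a sensitivity loss, positive values supra-normal sensitivity.
#'
#' @param observed Numeric vector of observed sensitivities (dB).
#' @param reference A [build_normative()] reference.
#' @param grid_index Integer vector (0-based), same length as `observed`.
#' @param modality `"mesopic"` or `"scotopic"`.
#' @return Numeric vector of deviations (dB); `NA` where the reference is
#'   undefined at a position.
#' @export
sensitivity_deviation <- function(observed, reference, grid_index,
                                  modality = c("mesopic", "scotopic")) {
  modality <- match.arg(modality)
  q <- if (modality == "mesopic") "mes_db" else "scot_db"
  look <- normative_lookup(reference, q)
  observed - look$mean[grid_index + 1L]
}

#' Thickness z-score against the normative reference
#'
#' `(observed - control mean) / control SD` at the same grid position, with
#' the control SD floored as described in [build_normative()].
#'
#' @param observed Numeric vector of sampled thicknesses (µm).
#' @inheritParams sensitivity_deviation
#' @param layer Layer name from [fcp_layers()].
#' @return Numeric vector of z-scores.
#' @export
thickness_zscore <- function(observed, reference, grid_index, layer) {
  if (!layer %in% fcp_layers()) {
    config_error(sprintf("unknown layer '%s'", layer))
  }
  look <- normative_lookup(reference, paste0("thk_", layer))
  (observed - look$mean[grid_index + 1L]) / look$sd[grid_index + 1L]
}

#' Normalize a point-wise table against a reference
#'
#' Adds `mes_dev` and `scot_dev` (dB deviations) and one `z_<layer>` column
#' per layer present in the table.
#'
#' @param table Point-wise table from [extract_visit()] rows.
#' @param reference A [build_normative()] reference.
#' @return The table with normalized columns appended.
#' @export
normalize_observations <- function(table, reference) {
  table$mes_dev <- sensitivity_deviation(table$mes_db, reference,
                                         table$grid_index, "mesopic")
  table$scot_dev <- sensitivity_deviation(table$scot_db, reference,
                                          table$grid_index, "scotopic")
  for (layer in fcp_layers()) {
    col <- paste0("thk_", layer)
    if (col %in% names(table)) {
      table[[paste0("z_", layer)]] <-
        thickness_zscore(table[[col]], reference, table$grid_index, layer)
    }
  }
  table
}
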