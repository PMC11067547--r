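# End-to-end pipeline: simulate -> register -> extract -> normalize -> fit.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    if (inherits(e, "fcpoct_error")) {
      fcp_error(sprintf("[stage %s] %s", name, conditionMessage(e)),
                class(e)[1])
    }
    fcp_error(sprintf("[stage %s] %s", name, conditionMessage(e)),
              "fcpoct_error")
  })
}

#' Extract the point-wise table for a whole cohort
#'
#' Registers every visit (estimating the FCP-to-OCT transform from its
#' landmark pair in left-eye orientation) and extracts one observation row
#' per stimulus position. Visits recorded with a neutral-density filter
#' other than 2.0 log units are excluded, since threshold values are not
#' comparable across filters.
#'
#' @param cohort An [simulate_cohort()] cohort (or a compatible list of
#'   visit records).
#' @param grid A [stimulus_grid()]; defaults to the cohort's grid.
#' @param use_true_transforms Use the generator's true transforms instead of
#'   estimating from landmarks (diagnostic mode).
#' @param min_fraction Presence-grading threshold.
#' @return List with `table` (all rows), `transforms` (per-visit fitted
#'   transforms, left-eye orientation), `registration_rms` (per-visit RMS
#'   residuals, degrees).
#' @export
extract_cohort <- function(cohort, grid = NULL, use_true_transforms = FALSE,
                           min_fraction = 0) {
  grid <- grid %||% cohort$grid
  keep <- vapply(cohort$visits, function(v) isTRUE(v$nd_filter == 2.0),
                 logical(1))
  visits <- cohort$visits[keep]
  transforms <- vector("list", length(visits))
  rms <- numeric(length(visits))
  rows <- vector("list", length(visits))
  for (i in seq_along(visits)) {
    v <- visits[[i]]
    tr <- if (use_true_transforms) {
      left_frame_transform(v$true_transform, v$laterality)
    } else {
      register_visit(v)
    }
    transforms[[i]] <- tr
    d <- attr(tr, "diagnostics")
    rms[i] <- if (is.null(d)) NA_real_ else d$rms
    rows[[i]] <- extract_visit(v, tr, grid, min_fraction = min_fraction)
  }
  tab <- do.call(rbind, rows)
  tab$group <- rep(vapply(visits, `[[`, character(1), "group"),
                   each = nrow(grid$centers))
  list(table = tab, transforms = transforms, registration_rms = rms)
}

#' Run the full analysis pipeline on a configuration
#'
#' Simulates the configured cohort, registers and extracts every visit,
#' builds the normative reference from the control rows, normalizes the AMD
#' rows, fits the cross-sectional mixed models (both modalities) and — when
#' at least one eye has two visits — the inter-visit change models, and
#' writes all tabular outputs plus a run manifest to `out_dir`.
#'
#' Outputs: `pointwise_table.csv`, `normative_reference.csv`,
#' `model_cross_<modality>.csv/json`, `model_intervisit_<modality>.csv/json`
#' (result-table layout), `recovery_report.csv` (configured truth vs
#' recovered estimate per coefficient), `transforms/visit_<k>.json`, and
#' `manifest.json`. Per-visit thickness maps and lesion masks are written
#' only with `write_images = TRUE` (they dominate disk usage).
#'
#' @param config A [cohort_config()], or the path to a YAML configuration.
#' @param out_dir Output directory (created if needed).
#' @param write_images Also write per-visit thickness maps and lesion masks.
#' @return A run manifest (list) with stage outputs, invisibly; the fitted
#'   models are attached as attribute `"results"`.
#' @export
run_pipeline <- function(config, out_dir, write_images = FALSE) {
  if (is.character(config)) config <- stage("config", read_config_yaml(config))
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- stage("simulate", simulate_cohort(config))
  ext <- stage("register+extract", extract_cohort(cohort))
  tab <- ext$table

  ctrl <- tab[tab$group == "control", ]
  amd <- tab[tab$group == "amd", ]
  reference <- stage("normalize", build_normative(ctrl))
  amd <- stage("normalize", normalize_observations(amd, reference))
  ctrl_norm <- stage("normalize", normalize_observations(ctrl, reference))

  results <- list()
  for (mod in c("mesopic", "scotopic")) {
    results[[paste0("cross_", mod)]] <-
      stage("fit", fit_cross_sectional(amd, model_spec(mod)))
  }
  diffs <- stage("fit", intervisit_differences(amd))
  if (nrow(diffs)) {
    for (mod in c("mesopic", "scotopic")) {
      results[[paste0("intervisit_", mod)]] <-
        stage("fit", fit_intervisit(diffs, model_spec(mod, "intervisit")))
    }
  }

  stage("report", {
    write_pointwise_csv(rbind(ctrl_norm, amd),
                        file.path(out_dir, "pointwise_table.csv"))
    write_normative_csv(reference,
                        file.path(out_dir, "normative_reference.csv"))
    tr_dir <- file.path(out_dir, "transforms")
    dir.create(tr_dir, showWarnings = FALSE)
    for (i in seq_along(ext$transforms)) {
      write_transform_json(ext$transforms[[i]],
                           file.path(tr_dir, sprintf("visit_%03d.json", i)))
    }
    report <- list()
    for (nm in names(results)) {
      write_model_csv(results[[nm]],
                      file.path(out_dir, sprintf("model_%s.csv", nm)))
      write_model_json(results[[nm]],
                       file.path(out_dir, sprintf("model_%s.json", nm)))
      rec <- compare_recovery(results[[nm]], config)
      rec$model <- nm
      report[[nm]] <- rec
    }
    utils::write.csv(do.call(rbind, report),
                     file.path(out_dir, "recovery_report.csv"),
                     row.names = FALSE)
    if (write_images) {
      for (i in seq_along(cohort$visits)) {
        v <- cohort$visits[[i]]
        vdir <- file.path(out_dir, "visits",
                          sprintf("%s_v%d", v$eye_id, v$visit_index))
        write_thickness_stack(v$stack, vdir)
        if (!is.null(v$lesions)) {
          for (b in names(v$lesions$masks)) {
            if (is.null(v$lesions$masks[[b]])) next
            write_lesion_mask(v$lesions$masks[[b]],
                              file.path(vdir, sprintf("mask_%s.tsv", b)),
                              v$lesions$px_per_deg, v$lesions$origin_px,
                              v$laterality, b)
          }
        }
        write_landmarks_csv(v$landmarks_oct,
                            file.path(vdir, "landmarks_oct.csv"))
        write_landmarks_csv(v$landmarks_fcp,
                            file.path(vdir, "landmarks_fcp.csv"))
      }
    }
  })

  cfg_path <- file.path(out_dir, "config.yaml")
  write_config_yaml(config, cfg_path)
  manifest <- list(
    tool = "fcpoct",
    version = as.character(utils::packageVersion("fcpoct")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_file = "config.yaml",
    config_hash = config_hash(config),
    n_eyes = nrow(cohort$eyes),
    n_visits = length(cohort$visits),
    n_rows = nrow(tab),
    registration_rms_mean = mean(ext$registration_rms, na.rm = TRUE),
    models = lapply(results, function(r) list(
      converged = r$converged, singular = r$singular, n_rows = r$n_rows)),
    outputs = list.files(out_dir, recursive = TRUE)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  attr(manifest, "results") <- results
  invisible(manifest)
}

config_hash <- function(config) {
  # order-stable content digest (no external digest dependency)
  s <- paste(utils::capture.output(utils::str(config, digits.d = 15)),
             collapse = "\n")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 977)) %%
            .Machine$integer.max)
}
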