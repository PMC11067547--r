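# Cross-sectional and inter-visit linear mixed-effect association models.

#' Specify an association model
#'
#' The cross-sectional model regresses the point-wise sensitivity deviation
#' on age, pseudophakia and the eight structural biomarker presence flags;
#' the inter-visit model regresses the change in deviation between
#' consecutive visits on the same exogenous variables taken at the earlier
#' visit, plus the years elapsed between visits and the nine retinal layer
#' thickness z-scores. Both carry random intercepts for patient, visit
#' (nested in eye) and grid point.
#'
#' @param endogenous `"mesopic"` or `"scotopic"`.
#' @param type `"cross_sectional"` or `"intervisit"`.
#' @param method `"REML"` (default) or `"ML"`.
#' @param include_layers Include layer z-score covariates; defaults to
#'   `FALSE` for the cross-sectional model and `TRUE` for the inter-visit
#'   model, matching how the two analyses are reported.
#' @param drop_censored Drop rows whose sensitivity hit the dynamic-range
#'   floor or ceiling instead of treating them as observed at the bound
#'   (sensitivity-analysis mode; default `FALSE`).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(endogenous = c("mesopic", "scotopic"),
                       type = c("cross_sectional", "intervisit"),
                       method = c("REML", "ML"),
                       include_layers = NULL,
                       drop_censored = FALSE) {
  endogenous <- match.arg(endogenous)
  type <- match.arg(type)
  method <- match.arg(method)
  if (is.null(include_layers)) include_layers <- type == "intervisit"
  structure(
    list(endogenous = endogenous, type = type, method = method,
         include_layers = include_layers, drop_censored = drop_censored),
    class = "model_spec"
  )
}

model_terms <- function(spec) {
  terms <- c("age", "pseudophakic")
  if (spec$type == "intervisit") terms <- c(terms, "years_elapsed")
  terms <- c(terms, paste0("flag_", fcp_biomarkers()))
  if (spec$include_layers) terms <- c(terms, paste0("z_", fcp_layers()))
  terms
}

# canonical display names matching the result tables
term_label <- function(term) {
  lab <- sub("^flag_", "", term)
  lab[lab == "(Intercept)"] <- "intercept"
  lab[lab == "years_elapsed"] <- "years_between_visits"
  lab
}

fit_mixed <- function(table, spec) {
  resp <- switch(paste(spec$type, spec$endogenous),
                 "cross_sectional mesopic" = "mes_dev",
                 "cross_sectional scotopic" = "scot_dev",
                 "intervisit mesopic" = "d_mes_dev",
                 "intervisit scotopic" = "d_scot_dev")
  terms <- model_terms(spec)
  missing_cols <- setdiff(c(resp, terms), names(table))
  if (length(missing_cols)) {
    config_error(sprintf("table lacks model columns: %s",
                         paste(missing_cols, collapse = ", ")))
  }
  if (spec$drop_censored) {
    cens <- switch(spec$endogenous,
                   mesopic = table$mes_censored,
                   scotopic = table$scot_censored)
    if (!is.null(cens)) table <- table[!cens %in% TRUE, ]
  }
  keep <- stats::complete.cases(table[, c(resp, terms)])
  n_dropped <- sum(!keep)
  dat <- table[keep, ]
  if (!nrow(dat)) config_error("no complete rows available for the model")
  dat$.visit_id <- interaction(dat$eye_id, dat$visit_index, drop = TRUE)
  dat$.grid <- factor(dat$grid_index)
  dat$.patient <- factor(dat$patient_id)
  # flags enter as 0/1 numerics so estimates read as dB for presence
  for (tm in grep("^flag_", terms, value = TRUE)) dat[[tm]] <- as.numeric(dat[[tm]])
  dat$pseudophakic <- as.numeric(dat$pseudophakic)

  fml <- stats::as.formula(paste(
    resp, "~", paste(terms, collapse = " + "),
    "+ (1 | .patient) + (1 | .visit_id) + (1 | .grid)"))
  fit <- withCallingHandlers(
    tryCatch(
      lmerTest::lmer(fml, data = dat, REML = spec$method == "REML",
                     control = lme4::lmerControl(
                       check.conv.singular = "ignore",
                       calc.derivs = TRUE)),
      error = function(e) {
        convergence_error(sprintf("mixed model failed to converge: %s",
                                  conditionMessage(e)))
      }),
    warning = function(w) invokeRestart("muffleWarning"),
    message = function(m) invokeRestart("muffleMessage")
  )

  smry <- suppressWarnings(summary(fit))
  co <- smry$coefficients
  # lmerTest Satterthwaite columns: Estimate, Std. Error, df, t value, Pr(>|t|)
  if (!"df" %in% colnames(co)) {
    # fall back to normal approximation if Satterthwaite is unavailable
    co <- cbind(co[, 1:2, drop = FALSE], df = Inf,
                `t value` = co[, 1] / co[, 2],
                `Pr(>|t|)` = 2 * stats::pnorm(-abs(co[, 1] / co[, 2])))
  }
  df_t <- ifelse(is.finite(co[, "df"]) & co[, "df"] > 0, co[, "df"], Inf)
  crit <- stats::qt(0.975, df_t)
  coefs <- data.frame(
    term = term_label(rownames(co)),
    estimate = co[, "Estimate"],
    se = co[, "Std. Error"],
    ci_lower = co[, "Estimate"] - crit * co[, "Std. Error"],
    ci_upper = co[, "Estimate"] + crit * co[, "Std. Error"],
    df = df_t,
    p_value = co[, "Pr(>|t|)"],
    row.names = NULL
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  opt <- fit@optinfo
  converged <- length(opt$conv$lme4$messages %||% character(0)) == 0 &&
    (opt$conv$opt %||% 0) == 0
  structure(
    list(
      coefficients = coefs,
      random_effects = data.frame(group = vc$grp, sd = vc$sdcor),
      n_rows = nrow(dat),
      n_dropped = n_dropped,
      converged = converged,
      singular = lme4::isSingular(fit),
      logLik = as.numeric(stats::logLik(fit)),
      method = spec$method,
      p_value_method = "Satterthwaite",
      spec = spec,
      fit = fit
    ),
    class = "sf_model_result"
  )
}

#' Fit the cross-sectional structure-function model
#'
#' Linear mixed-effect model of the point-wise sensitivity deviation (dB)
#' on age, pseudophakia and the eight biomarker presence flags, with random
#' intercepts for patient, visit and grid point. Presence estimates read as
#' the mean dB difference between affected and unaffected stimulus
#' positions. Rows with missing model variables are dropped (complete-case)
#' and counted in `n_dropped`.
#'
#' @param table Normalized point-wise table ([normalize_observations()]).
#' @param spec A [model_spec()]; a `"mesopic"`/`"scotopic"` string is also
#'   accepted as shorthand.
#' @return An object of class `sf_model_result`: coefficient table
#'   (estimate, SE, 95% CI, Satterthwaite p-value), random-effect SDs, fit
#'   metadata, and the underlying `lmerMod` in `$fit`.
#' @export
fit_cross_sectional <- function(table, spec = model_spec("mesopic")) {
  if (is.character(spec)) spec <- model_spec(spec, "cross_sectional")
  stopifnot(spec$type == "cross_sectional")
  fit_mixed(table, spec)
}

#' Point-wise sensitivity differences between consecutive visits
#'
#' For every eye with at least two visits, pairs consecutive visits and
#' computes the later-minus-earlier change in mesopic and scotopic deviation
#' per grid position. Exogenous covariates (biomarker flags, layer z-scores)
#' are taken from the earlier visit of each pair, reading the model as
#' prognostic: does the structure present now predict the functional change
#' to the next visit. `years_elapsed` is the elapsed time in years.
#'
#' @param table Normalized point-wise table covering >= 1 visit per eye.
#' @return Data frame with one row per (eye, consecutive visit pair, grid
#'   position); empty (0 rows) if no eye has two visits.
#' @export
intervisit_differences <- function(table) {
  pieces <- list()
  for (eye in unique(table$eye_id)) {
    sub <- table[table$eye_id == eye, ]
    visits <- sort(unique(sub$visit_index))
    if (length(visits) < 2) next
    for (i in seq_len(length(visits) - 1)) {
      v0 <- sub[sub$visit_index == visits[i], ]
      v1 <- sub[sub$visit_index == visits[i + 1], ]
      m <- match(v0$grid_index, v1$grid_index)
      ok <- !is.na(m)
      v0 <- v0[ok, ]; v1 <- v1[m[ok], ]
      d <- v0[, intersect(names(v0),
                          c("patient_id", "eye_id", "grid_index", "age",
                            "pseudophakic",
                            paste0("flag_", fcp_biomarkers()),
                            paste0("z_", fcp_layers())))]
      d$visit_index <- v0$visit_index   # pair labelled by its earlier visit
      d$pair_index <- i - 1L
      d$years_elapsed <-
        (v1$months_since_baseline - v0$months_since_baseline) / 12
      d$d_mes_dev <- v1$mes_dev - v0$mes_dev
      d$d_scot_dev <- v1$scot_dev - v0$scot_dev
      d$mes_censored <- v0$mes_censored | v1$mes_censored
      d$scot_censored <- v0$scot_censored | v1$scot_censored
      pieces[[length(pieces) + 1L]] <- d
    }
  }
  if (!length(pieces)) {
    return(data.frame())
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Fit the inter-visit change model
#'
#' Linear mixed-effect model of the change in point-wise sensitivity
#' deviation between consecutive visits on the earlier visit's exogenous
#' variables, years elapsed, and the nine layer thickness z-scores, with
#' random intercepts for patient, visit pair and grid point.
#'
#' @param diff Difference table from [intervisit_differences()].
#' @inheritParams fit_cross_sectional
#' @return An `sf_model_result`, as for [fit_cross_sectional()].
#' @export
fit_intervisit <- function(diff, spec = model_spec("mesopic", "intervisit")) {
  if (is.character(spec)) spec <- model_spec(spec, "intervisit")
  stopifnot(spec$type == "intervisit")
  if (!nrow(diff)) config_error("difference table is empty: no eye has two visits")
  fit_mixed(diff, spec)
}

#' @export
print.sf_model_result <- function(x, digits = 3, ...) {
  cat(sprintf("<sf_model_result> %s %s model (%s), %d rows (%d dropped)%s%s\n",
              x$spec$endogenous, sub("_", "-", x$spec$type), x$method,
              x$n_rows, x$n_dropped,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$singular) " [singular fit]" else ""))
  print(cbind(x$coefficients[1],
              round(x$coefficients[, c("estimate", "se", "ci_lower",
                                       "ci_upper", "p_value")], digits)))
  cat("Random-effect SDs:\n")
  print(cbind(x$random_effects[1], round(x$random_effects["sd"], digits)))
  invisible(x)
}

#' Side-by-side comparison of configured truth and recovered estimates
#'
#' For a synthetic scenario, lines up each fitted coefficient with the
#' generating value from the cohort configuration.
#'
#' @param result An `sf_model_result`.
#' @param config The [cohort_config()] used to generate the data.
#' @return Data frame with `term`, `truth`, `estimate`, `se`, `bias`,
#'   `within_2se`.
#' @export
compare_recovery <- function(result, config) {
  fx <- if (result$spec$type == "cross_sectional") {
    config$fixed_effects_cross_sectional[[result$spec$endogenous]]
  } else {
    config$fixed_effects_intervisit[[result$spec$endogenous]]
  }
  co <- result$coefficients
  truth <- fx[co$term]
  data.frame(
    term = co$term,
    truth = as.numeric(truth),
    estimate = co$estimate,
    se = co$se,
    bias = co$estimate - as.numeric(truth),
    within_2se = abs(co$estimate - as.numeric(truth)) <= 2 * co$se
  )
}
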