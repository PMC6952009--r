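# Per-pair Cox proportional-hazards analysis.
#
# The model is the usual log-relative-hazard regression
#   ln h(t) / h0(t) = b1 P1 + ... + bn Pn
# where one predictor is the binary exposure indicator (diagnosed with X or
# not) and the remaining predictors are confounders such as age at index,
# gender and ethnicity. The exposure coefficient's exp is the adjusted
# hazard ratio for X -> Y; its Wald p-value, BH-adjusted across all pairs
# of one run, decides significance.

#' Fit the Cox proportional-hazards model for one matched cohort
#'
#' Maximizes the Cox partial likelihood over follow-up time, event status,
#' the exposure indicator and the requested covariates. Categorical
#' covariates are one-hot encoded against the alphabetically first level as
#' reference. Subjects missing a value of a used covariate are dropped and
#' counted.
#'
#' @param cohort a `matched_cohort`.
#' @param covariates character vector of covariate column names to adjust
#'   for; defaults to age at index, gender and ethnicity. Use
#'   `character(0)` for the unadjusted exposure-only model.
#' @param tie_method partial-likelihood tie approximation, `"efron"`
#'   (default; diagnosis dates have day resolution so ties are common) or
#'   `"breslow"`.
#' @return An object of class `cox_pair_fit`: list with the `pair`,
#'   exposure `coefficient`, `hazard_ratio`, `se`, `p_raw` (Wald),
#'   `zph_p` + `zph_testable` (proportional-hazards test, see
#'   [test_proportional_hazards()]), `n` (subjects used), `n_events`,
#'   `n_dropped_missing`, `covariate_effects` (coefficient and p per
#'   encoded covariate term) and the underlying [survival::coxph()] `fit`.
#' @export
fit_cox_pair <- function(cohort,
                         covariates = c("age_at_index", "gender", "ethnicity"),
                         tie_method = c("efron", "breslow")) {
  stopifnot(inherits(cohort, "matched_cohort"))
  tie_method <- match.arg(tie_method)
  s <- cohort$subjects
  absent <- setdiff(covariates, names(s))
  if (length(absent) > 0L)
    dcn_stop("dcn_missing_column",
             sprintf("covariate(s) not on subjects: %s", paste(absent, collapse = ", ")))

  df <- data.frame(time = s$time_to_event, status = as.integer(s$event),
                   exposed = as.numeric(s$exposed))
  for (cn in covariates) {
    v <- s[[cn]]
    if (is.character(v) || is.logical(v)) v <- factor(v, levels = sort(unique(v[!is.na(v)])))
    df[[cn]] <- v
  }
  complete <- stats::complete.cases(df)
  n_dropped <- sum(!complete)
  df <- df[complete, , drop = FALSE]
  # constant-level factors carry no information and break the design matrix
  covariates <- covariates[vapply(covariates, function(cn) {
    v <- df[[cn]]; if (is.factor(v)) nlevels(droplevels(v)) > 1L else stats::sd(v) > 0
  }, TRUE)]

  if (sum(df$status) < 1L)
    dcn_stop("dcn_degenerate_cohort",
             sprintf("no events in cohort %s -> %s", cohort$pair[1], cohort$pair[2]))

  fml <- stats::as.formula(paste(
    "survival::Surv(time, status) ~ exposed",
    if (length(covariates) > 0L) paste("+", paste(covariates, collapse = " + ")) else ""))
  warns <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = tie_method, x = TRUE, model = TRUE),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (any(grepl("Ran out of iterations", warns)))
    dcn_stop("dcn_not_converged",
             paste("Cox model did not converge:", paste(warns, collapse = "; ")),
             warnings = warns)
  co <- summary(fit)$coefficients
  if (!is.finite(co["exposed", "coef"]) || abs(co["exposed", "coef"]) > 15)
    dcn_stop("dcn_separation",
             "exposure coefficient diverged (complete or quasi-complete separation)")

  cov_rows <- setdiff(rownames(co), "exposed")
  res <- structure(list(
    pair = cohort$pair,
    coefficient = unname(co["exposed", "coef"]),
    hazard_ratio = unname(exp(co["exposed", "coef"])),
    se = unname(co["exposed", "se(coef)"]),
    p_raw = unname(co["exposed", "Pr(>|z|)"]),
    n = nrow(df),
    n_events = sum(df$status),
    n_dropped_missing = n_dropped,
    covariate_effects = if (length(cov_rows) > 0L) {
      data.frame(term = cov_rows, coefficient = unname(co[cov_rows, "coef"]),
                 p = unname(co[cov_rows, "Pr(>|z|)"]), stringsAsFactors = FALSE)
    } else NULL,
    tie_method = tie_method,
    fit = fit,
    data = df
  ), class = "cox_pair_fit")
  zph <- test_proportional_hazards(res)
  res$zph_p <- zph$p
  res$zph_testable <- zph$testable
  res
}

#' Test the proportional-hazards assumption for the exposure term
#'
#' Score test of the scaled Schoenfeld residuals of the exposure term
#' against the Kaplan-Meier transform of event time
#' ([survival::cox.zph()]). A p-value below 0.05 indicates the hazard
#' ratio is not constant over follow-up and the pair's Cox result should be
#' interpreted with caution. Cohorts with fewer than 3 distinct event times
#' are flagged not testable.
#'
#' @param x a `cox_pair_fit`.
#' @param transform time transform passed to [survival::cox.zph()]
#'   (default `"km"`).
#' @return list with `p` (NA when not testable), `testable`, and the
#'   scaled-Schoenfeld residual series (`time`, `residual`) for the
#'   exposure term.
#' @export
test_proportional_hazards <- function(x, transform = "km") {
  stopifnot(inherits(x, "cox_pair_fit"))
  ev_times <- unique(x$data$time[x$data$status == 1L])
  if (length(ev_times) < 3L)
    return(list(p = NA_real_, testable = FALSE, series = NULL))
  z <- tryCatch(survival::cox.zph(x$fit, transform = transform, terms = FALSE),
                error = function(e) NULL)
  if (is.null(z) || !"exposed" %in% rownames(z$table))
    return(list(p = NA_real_, testable = FALSE, series = NULL))
  series <- data.frame(time = z$time, residual = z$y[, "exposed"])
  list(p = unname(z$table["exposed", "p"]), testable = TRUE, series = series)
}

#' Cox-Snell residual plot data
#'
#' The Cox-Snell residual of a subject is its estimated cumulative hazard
#' at the observed time (baseline cumulative hazard times exp of the linear
#' predictor). Under a well-fitting model the residuals behave like
#' censored unit-exponential variates, so their Nelson-Aalen cumulative
#' hazard plotted against the residuals should follow the 45-degree
#' diagonal.
#'
#' @param x a `cox_pair_fit`.
#' @return data frame with columns `residual` (sorted, non-negative) and
#'   `cumhaz` (Nelson-Aalen cumulative hazard of the residuals, treating
#'   them as survival times with the original event indicators).
#' @export
coxsnell_plot_data <- function(x) {
  stopifnot(inherits(x, "cox_pair_fit"))
  mart <- stats::residuals(x$fit, type = "martingale")
  cs <- x$data$status - mart
  sf <- survival::survfit(survival::Surv(cs, x$data$status) ~ 1)
  data.frame(residual = sf$time, cumhaz = sf$cumhaz)
}

#' Benjamini-Hochberg adjustment across disease pairs
#'
#' Step-up false-discovery-rate adjustment applied to the per-pair raw
#' p-values of one pipeline run (one p-value per pair and arm). Thin,
#' validating wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of raw p-values in \[0, 1\] (NAs pass through).
#' @param method adjustment method (default `"BH"`).
#' @return adjusted p-values, clipped at 1, order-preserving.
#' @export
adjust_pvalues <- function(p, method = "BH") {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    dcn_stop("dcn_bad_input", "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' @export
print.cox_pair_fit <- function(x, ...) {
  cat(sprintf("<cox_pair_fit> %s -> %s (n = %d, events = %d)\n",
              x$pair[1], x$pair[2], x$n, x$n_events))
  cat(sprintf("  exposure: coef %.4f, HR %.3f, Wald p %.3g; PH-test p %s\n",
              x$coefficient, x$hazard_ratio, x$p_raw,
              if (isTRUE(x$zph_testable)) sprintf("%.3g", x$zph_p) else "not testable"))
  invisible(x)
}
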