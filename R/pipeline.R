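# End-to-end pipeline: enumerate pairs, build cohorts, run both survival
# arms and the quality controls, BH-adjust across all pairs of the run,
# assemble the network, and persist everything as plain CSV/JSON.

#' Analyse all disease pairs of a dataset
#'
#' The computational core of [run_pipeline()], operating in memory. Pairs
#' whose cohort construction or model fit fails with an expected condition
#' (empty exposure, no matches, degenerate cohort, separation) are recorded
#' in the status table and skipped, not fatal. BH adjustment is applied
#' across all successfully fitted pairs of this call — the multiplicity
#' family is the whole run.
#'
#' @param ds an `emr_dataset`.
#' @param pairs data frame `from`/`to` (default: all pairs from
#'   [enumerate_disease_pairs()] with `min_exposed`).
#' @param mparams a [match_params()] object.
#' @param rparams an [rsf_params()] object; `NULL` skips the RSF arm.
#' @param covariates covariate columns to adjust for in both arms.
#' @param min_exposed minimum exposed-patient count for a pair to be
#'   analysed (default 50).
#' @param alpha significance threshold on adjusted p-values.
#' @param mode network mode, see [build_network()].
#' @return list with data frames `cox`, `rsf`, `qc`, `status` and the
#'   `network` (`disease_network`).
#' @export
analyse_pairs <- function(ds, pairs = NULL, mparams = match_params(),
                          rparams = rsf_params(),
                          covariates = c("age_at_index", "gender", "ethnicity"),
                          min_exposed = 50, alpha = 0.05, mode = "overlap") {
  stopifnot(inherits(ds, "emr_dataset"))
  if (is.null(rparams) && mode == "overlap") mode <- "cox"
  if (is.null(pairs)) pairs <- enumerate_disease_pairs(ds, min_exposed)
  attr(ds, "match_index") <- make_match_index(ds)

  n <- nrow(pairs)
  status <- character(n)
  cox_rows <- vector("list", n); rsf_rows <- vector("list", n)
  qc_rows <- vector("list", n)
  for (i in seq_len(n)) {
    X <- pairs$from[i]; Y <- pairs$to[i]
    status[i] <- tryCatch({
      cohort <- build_matched_cohort(ds, X, Y, mparams)
      cfit <- fit_cox_pair(cohort, covariates = covariates)
      kt <- ks_dropout_test(cohort)
      qc_rows[[i]] <- data.frame(
        from = X, to = Y, ks_statistic = kt$ks_statistic, ks_p = kt$ks_p,
        n_exposed_dropouts = kt$n_exposed_dropouts,
        n_comparison_dropouts = kt$n_comparison_dropouts,
        ks_testable = kt$testable, stringsAsFactors = FALSE)
      cox_rows[[i]] <- data.frame(
        from = X, to = Y, coefficient = cfit$coefficient,
        hazard_ratio = cfit$hazard_ratio, se = cfit$se, n = cfit$n,
        n_events = cfit$n_events, p_raw = cfit$p_raw,
        zph_p = cfit$zph_p, stringsAsFactors = FALSE)
      if (is.null(rparams)) "ok" else tryCatch({
        curves <- fit_rsf(cohort, rparams, covariates = covariates)
        cmp <- compare_mean_survival(cohort, curves)
        rsf_rows[[i]] <- data.frame(
          from = X, to = Y, mean_exposed = cmp$mean_exposed,
          mean_comparison = cmp$mean_comparison,
          wilcoxon_p_raw = cmp$wilcoxon_p, ttest_p_raw = cmp$ttest_p,
          n = cfit$n, stringsAsFactors = FALSE)
        "ok"
      }, dcn_error = function(e) paste0("cox_only:", class(e)[1]))
    }, dcn_error = function(e) class(e)[1])
  }

  cox <- data.table::setDF(data.table::rbindlist(cox_rows))
  rsf <- data.table::setDF(data.table::rbindlist(rsf_rows))
  qc <- data.table::setDF(data.table::rbindlist(qc_rows))
  if (nrow(cox) > 0L) cox$p_adjusted <- adjust_pvalues(cox$p_raw)
  if (nrow(rsf) > 0L) {
    rsf$wilcoxon_p_adjusted <- adjust_pvalues(rsf$wilcoxon_p_raw)
    rsf$ttest_p_adjusted <- adjust_pvalues(rsf$ttest_p_raw)
  }
  net <- build_network(cox, rsf = if (is.null(rparams)) NULL else rsf,
                       qc = if (nrow(qc) > 0L) qc else NULL,
                       alpha = alpha, mode = mode)
  list(cox = cox, rsf = rsf, qc = qc,
       status = data.frame(from = pairs$from, to = pairs$to, status = status,
                           stringsAsFactors = FALSE),
       network = net)
}

#' Run the full pipeline and persist its outputs
#'
#' Reads (or accepts) a first-diagnosis table, analyses every ordered
#' disease pair, and writes per-pair Cox, RSF and QC result tables, the
#' per-pair status table, the network in all three export formats, the
#' input-validation report and a machine-readable run manifest recording
#' every parameter and seed. Re-running with the same inputs and seed
#' reproduces every CSV byte for byte.
#'
#' @param input path to a CSV/TSV diagnosis table, or an `emr_dataset`.
#' @param output_dir directory for outputs (created if needed).
#' @param column_map,date_format passed to [read_emr_table()].
#' @param mparams,rparams,covariates,min_exposed,alpha,mode passed to
#'   [analyse_pairs()].
#' @param seed overrides the seeds in `mparams`/`rparams` when non-NULL.
#' @return the [analyse_pairs()] result list, invisibly, with an added
#'   `output_dir`.
#' @export
run_pipeline <- function(input, output_dir, column_map = NULL,
                         date_format = "%Y-%m-%d",
                         mparams = match_params(), rparams = rsf_params(),
                         covariates = c("age_at_index", "gender", "ethnicity"),
                         min_exposed = 50, alpha = 0.05, mode = "overlap",
                         seed = NULL) {
  if (!is.null(seed)) {
    mparams$seed <- as.integer(seed)
    if (!is.null(rparams)) rparams$seed <- as.integer(seed)
  }
  ds <- if (inherits(input, "emr_dataset")) input
        else read_emr_table(input, column_map = column_map, date_format = date_format)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  res <- analyse_pairs(ds, mparams = mparams, rparams = rparams,
                       covariates = covariates, min_exposed = min_exposed,
                       alpha = alpha, mode = mode)

  fwrite_ <- function(df, name) data.table::fwrite(df, file.path(output_dir, name))
  fwrite_(res$cox, "cox_results.csv")
  if (nrow(res$rsf) > 0L) fwrite_(res$rsf, "rsf_results.csv")
  fwrite_(res$qc, "qc_results.csv")
  fwrite_(res$status, "pair_status.csv")
  export_network(res$network, file.path(output_dir, "network_edges.csv"), "csv-edgelist")
  export_network(res$network, file.path(output_dir, "network.graphml"), "graphml")
  export_network(res$network, file.path(output_dir, "network.cyjs.json"), "cytoscape-json")
  data.table::fwrite(degrees(res$network), file.path(output_dir, "network_degrees.csv"))
  jsonlite::write_json(ds$report, file.path(output_dir, "validation_report.json"),
                       auto_unbox = TRUE)

  manifest <- list(
    package = "dcnet",
    version = as.character(utils::packageVersion("dcnet")),
    match_params = unclass(mparams),
    rsf_params = if (is.null(rparams)) NULL else unclass(rparams),
    covariates = covariates, min_exposed = min_exposed,
    alpha = alpha, mode = mode,
    n_patients = length(ds$patients), n_diseases = length(ds$diseases),
    n_pairs = nrow(res$status),
    n_pairs_analysed = sum(res$status$status == "ok"),
    n_edges = nrow(res$network$edges)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  res$output_dir <- output_dir
  invisible(res)
}
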