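# Independent machine-learning arm: random survival forest.
#
# Bootstrap survival trees are grown with the log-rank splitting rule
# (ranger); each terminal node's conditional cumulative hazard is the
# Nelson-Aalen estimate over the tree's in-bag subjects in that node,
# computed here on the cohort's event-time grid, and per-subject curves are
# the average over all trees of the estimate in the node the subject falls
# into. Each subject's predicted survival curve S(t) = exp(-H(t)) is
# reduced to a restricted mean survival time (the integral of S up to the
# follow-up window), and the exposed and comparison groups are compared
# with the Wilcoxon rank-sum test (primary, conservative) and the
# two-sample t-test.

#' Random-survival-forest parameters
#'
#' @param n_trees number of bootstrap trees (default 500).
#' @param mtry predictors tried per split; default `ceiling(sqrt(p))`.
#' @param min_node_size minimal node size to attempt a split (default 15).
#' @param bootstrap draw an n-out-of-n bootstrap sample with replacement per
#'   tree (default TRUE). `FALSE` grows every tree on the full cohort,
#'   which with `n_trees = 1` and a large `min_node_size` reduces the
#'   forest to the cohort-wide Nelson-Aalen estimator (a useful oracle).
#' @param seed integer seed for tree growing.
#' @return A list of class `rsf_params`.
#' @export
rsf_params <- function(n_trees = 500, mtry = NULL, min_node_size = 15,
                       bootstrap = TRUE, seed = 1L) {
  if (n_trees < 1) dcn_stop("dcn_bad_input", "n_trees must be >= 1")
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
            class = "rsf_params")
}

#' Fit the random survival forest and predict per-subject survival curves
#'
#' @param cohort a `matched_cohort`.
#' @param params an [rsf_params()] object.
#' @param covariates covariate columns used as predictors alongside the
#'   exposure indicator.
#' @return An object of class `rsf_curves`: list with `times` (the cohort's
#'   sorted unique event times), `chf` and `surv` (n-by-length(times)
#'   matrices of per-subject ensemble cumulative hazard and survival),
#'   `subjects` (patient id + exposure flag per row) and `params`.
#'   Deterministic given `params$seed`.
#' @export
fit_rsf <- function(cohort, params = rsf_params(),
                    covariates = c("age_at_index", "gender", "ethnicity")) {
  stopifnot(inherits(cohort, "matched_cohort"), inherits(params, "rsf_params"))
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
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  if (sum(df$status) < 1L)
    dcn_stop("dcn_degenerate_cohort",
             sprintf("all subjects censored in cohort %s -> %s",
                     cohort$pair[1], cohort$pair[2]))

  p <- ncol(df) - 2L
  mtry <- params$mtry %||% ceiling(sqrt(p))
  rf <- ranger::ranger(
    formula = survival::Surv(time, status) ~ .,
    data = df,
    num.trees = params$n_trees,
    mtry = min(mtry, p),
    min.node.size = params$min_node_size,
    splitrule = "logrank",
    replace = params$bootstrap,
    sample.fraction = 1,
    keep.inbag = TRUE,
    oob.error = FALSE,
    seed = params$seed,
    num.threads = 1L
  )
  nodes <- stats::predict(rf, data = df, type = "terminalNodes",
                          num.threads = 1L)$predictions
  inbag <- matrix(unlist(rf$inbag.counts, use.names = FALSE), nrow = nrow(df))

  grid <- sort(unique(df$time[df$status == 1L]))
  chf <- ensemble_nelson_aalen(df$time, df$status, nodes, inbag, grid)

  structure(list(times = grid, chf = chf, surv = exp(-chf),
                 subjects = data.frame(
                   patient_id = if ("patient_id" %in% names(s)) s$patient_id[keep] else as.character(which(keep)),
                   exposed = s$exposed[keep], stringsAsFactors = FALSE),
                 params = params, pair = cohort$pair),
            class = "rsf_curves")
}

# Terminal-node Nelson-Aalen estimation, averaged over trees.
# time/status: per training subject; nodes: n x ntrees terminal node ids;
# inbag: n x ntrees bootstrap multiplicities; grid: sorted unique event
# times. Hazard increments with an empty risk set contribute zero.
ensemble_nelson_aalen <- function(time, status, nodes, inbag, grid) {
  n <- length(time)
  G <- length(grid)
  ntree <- ncol(nodes)
  # column index of each subject's event time on the grid (events only),
  # and the last grid point the subject is still at risk for
  ev_col <- match(time, grid)
  risk_col <- findInterval(time, grid)
  chf_sum <- matrix(0, n, G)
  for (tr in seq_len(ntree)) {
    g <- nodes[, tr]
    w <- inbag[, tr]
    node_ids <- sort(unique(g))
    f <- match(g, node_ids)
    K <- length(node_ids)
    use <- w > 0
    # weighted event counts per (node, grid time)
    evs <- use & status == 1L
    d <- as.matrix(Matrix::sparseMatrix(i = f[evs], j = ev_col[evs],
                                        x = w[evs], dims = c(K, G)))
    # weighted at-risk counts: subject contributes to all grid points <= its time
    rc <- risk_col >= 1L & use
    cnt <- as.matrix(Matrix::sparseMatrix(i = f[rc], j = risk_col[rc],
                                          x = w[rc], dims = c(K, G)))
    if (G > 1L) for (j in (G - 1L):1L) cnt[, j] <- cnt[, j] + cnt[, j + 1L]
    hz <- d / pmax(cnt, 1e-300)
    hz[cnt == 0] <- 0
    node_chf <- hz
    if (G > 1L) for (j in 2L:G) node_chf[, j] <- node_chf[, j] + node_chf[, j - 1L]
    chf_sum <- chf_sum + node_chf[f, , drop = FALSE]
  }
  chf_sum / ntree
}

#' Restricted mean survival time of a step survival curve
#'
#' The mean survival time equals the integral of the survival function;
#' restricted to the study window \[0, tau\] it is the sum of step widths
#' times step heights. Curves are right-continuous step functions equal to
#' 1 before the first knot.
#'
#' @param curve either an `rsf_curves` object (one RMST per subject is
#'   returned) or a list/data frame with `times` and `surv` describing one
#'   curve.
#' @param tau restriction point in days.
#' @return numeric vector of restricted mean survival times (days), one per
#'   curve, each in \[0, tau\].
#' @export
mean_survival_time <- function(curve, tau) {
  if (tau <= 0) dcn_stop("dcn_bad_input", "tau must be positive")
  if (inherits(curve, "rsf_curves")) {
    times <- curve$times; surv <- curve$surv
  } else {
    times <- curve$times; surv <- matrix(curve$surv, nrow = 1L)
  }
  if (is.null(times) || length(times) == 0L) return(rep(tau, nrow(surv)))
  if (is.unsorted(times)) dcn_stop("dcn_bad_input", "curve times must be sorted")
  if (any(surv > 1 + 1e-9 | surv < -1e-9))
    dcn_stop("dcn_bad_input", "survival values must lie in [0, 1]")
  if (ncol(surv) > 1L && any(surv[, -1L, drop = FALSE] - surv[, -ncol(surv), drop = FALSE] > 1e-9))
    dcn_stop("dcn_bad_input", "survival curve must be non-increasing")
  knots <- c(0, pmin(times, tau))
  widths <- diff(c(knots, tau))          # width of [t_k, t_{k+1}) segments
  heights <- cbind(1, surv)              # S = 1 on [0, t_1)
  as.numeric(heights %*% widths)
}

#' Compare restricted mean survival time between exposed and comparison
#'
#' Per-subject restricted mean survival times are treated as approximately
#' independent normal draws (central-limit argument), so the two groups are
#' compared with a standard two-sample test; the non-parametric Wilcoxon
#' rank-sum test is the conservative primary choice, the t-test is reported
#' alongside. Both are BH-adjusted across pairs by the pipeline; a pair is
#' RSF-significant only when both adjusted p-values pass.
#'
#' @param cohort the `matched_cohort` the curves were fitted on.
#' @param curves an `rsf_curves` object from [fit_rsf()].
#' @param tau restriction point in days (default: the cohort's follow-up
#'   window).
#' @return An object of class `rsf_pair_result`: list with `pair`,
#'   `per_subject` (patient id, exposed flag, RMST in days), group means
#'   `mean_exposed` / `mean_comparison`, `wilcoxon_p`, `ttest_p`, and
#'   `ttest_testable` (FALSE when a degenerate zero-variance sample makes
#'   the t statistic undefined; the Wilcoxon p is still computed).
#' @export
compare_mean_survival <- function(cohort, curves, tau = NULL) {
  stopifnot(inherits(cohort, "matched_cohort"), inherits(curves, "rsf_curves"))
  tau <- tau %||% cohort$params$followup_window
  rmst <- mean_survival_time(curves, tau)
  exposed <- curves$subjects$exposed
  if (!any(exposed) || all(exposed))
    dcn_stop("dcn_degenerate_cohort", "both groups must be non-empty")
  x <- rmst[exposed]; y <- rmst[!exposed]

  if (stats::var(c(x, y)) == 0) {
    wp <- 1
  } else {
    wp <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = TRUE)$p.value)
    if (is.na(wp)) wp <- 1
  }
  tt <- tryCatch(stats::t.test(x, y), error = function(e) NULL)
  structure(list(pair = curves$pair,
                 per_subject = data.frame(patient_id = curves$subjects$patient_id,
                                          exposed = exposed, rmst = rmst,
                                          stringsAsFactors = FALSE),
                 mean_exposed = mean(x), mean_comparison = mean(y),
                 wilcoxon_p = wp,
                 ttest_p = if (is.null(tt)) NA_real_ else tt$p.value,
                 ttest_testable = !is.null(tt),
                 tau = tau),
            class = "rsf_pair_result")
}

#' Group-averaged survival curves (plot data)
#'
#' @param curves an `rsf_curves` object.
#' @return data frame with `time`, `surv_exposed`, `surv_comparison` — the
#'   pointwise mean predicted survival per group, for the per-pair RSF
#'   survival plot.
#' @export
rsf_group_curves <- function(curves) {
  stopifnot(inherits(curves, "rsf_curves"))
  e <- curves$subjects$exposed
  data.frame(time = curves$times,
             surv_exposed = colMeans(curves$surv[e, , drop = FALSE]),
             surv_comparison = colMeans(curves$surv[!e, , drop = FALSE]))
}

#' @export
print.rsf_pair_result <- function(x, ...) {
  cat(sprintf("<rsf_pair_result> %s -> %s\n", x$pair[1], x$pair[2]))
  cat(sprintf("  restricted mean survival (tau = %g d): %.0f exposed vs %.0f comparison\n",
              x$tau, x$mean_exposed, x$mean_comparison))
  cat(sprintf("  Wilcoxon p %.3g; t-test p %s\n", x$wilcoxon_p,
              if (x$ttest_testable) sprintf("%.3g", x$ttest_p) else "not testable"))
  invisible(x)
}
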