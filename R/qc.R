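# Dropout-balance quality control.
#
# Not every subject can be followed for the whole window: records end early
# (drop-out). If dropout number and timing differ between the exposed and
# comparison groups, censoring may be informative and differential, and the
# pair's survival results should be read with caution. The check compares
# the two groups' censoring-time distributions with a two-sample
# Kolmogorov-Smirnov test; subjects censored administratively at the full
# window completed follow-up and are not dropouts.

#' Kolmogorov-Smirnov comparison of dropout timing between groups
#'
#' @param cohort a `matched_cohort`.
#' @param alpha caution threshold on the KS p-value (default 0.05).
#' @return An object of class `dropout_test`: list with `pair`,
#'   `ks_statistic`, `ks_p`, `n_exposed_dropouts`, `n_comparison_dropouts`,
#'   `testable` (FALSE when either group has no dropouts, in which case no
#'   p-value is reported), `caution` (`ks_p < alpha`), and `freq` (the
#'   per-group drop-off/event/survival tally from [dropout_times()]).
#' @details The exact two-sided p-value is used when the combined number of
#'   dropouts is below 40, the asymptotic one otherwise. Ties (day-resolution
#'   censoring times) make the exact p approximate; warnings are suppressed.
#' @export
ks_dropout_test <- function(cohort, alpha = 0.05) {
  stopifnot(inherits(cohort, "matched_cohort"))
  d <- dropout_times(cohort)
  n_e <- length(d$exposed); n_c <- length(d$comparison)
  if (n_e == 0L || n_c == 0L) {
    return(structure(list(pair = cohort$pair, ks_statistic = NA_real_,
                          ks_p = NA_real_, n_exposed_dropouts = n_e,
                          n_comparison_dropouts = n_c, testable = FALSE,
                          caution = FALSE, freq = d$freq),
                     class = "dropout_test"))
  }
  kt <- suppressWarnings(stats::ks.test(d$exposed, d$comparison,
                                        exact = (n_e + n_c) < 40))
  structure(list(pair = cohort$pair,
                 ks_statistic = unname(kt$statistic),
                 ks_p = unname(kt$p.value),
                 n_exposed_dropouts = n_e, n_comparison_dropouts = n_c,
                 testable = TRUE, caution = unname(kt$p.value) < alpha,
                 freq = d$freq),
            class = "dropout_test")
}

#' @export
print.dropout_test <- function(x, ...) {
  cat(sprintf("<dropout_test> %s -> %s\n", x$pair[1], x$pair[2]))
  if (x$testable) {
    cat(sprintf("  KS D = %.3f, p = %.3g (%d vs %d dropouts)%s\n",
                x$ks_statistic, x$ks_p, x$n_exposed_dropouts,
                x$n_comparison_dropouts,
                if (x$caution) " -- interpret with caution" else ""))
  } else {
    cat("  not testable (a group has no dropouts)\n")
  }
  invisible(x)
}
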