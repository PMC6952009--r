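# Matched retrospective cohort construction for one ordered disease pair.
#
# For the pair X -> Y the exposed group is every patient diagnosed with X
# (index date = first X diagnosis). Each exposed subject is matched 1:1 to a
# randomly selected comparison subject never diagnosed with X, with identical
# gender and ethnicity, whose index date is the date of a randomly chosen
# non-X diagnosis within `max_date_diff` days of the case's index date and
# whose age at index differs by at most `max_age_diff` years. The event of
# interest is the first diagnosis of Y after the index date within the
# follow-up window; subjects whose record ends earlier are censored
# (dropouts).

#' Matching and follow-up parameters
#'
#' @param max_date_diff maximum difference (days) between the case's index
#'   date and the comparison subject's index diagnosis (default 7, i.e.
#'   within one week).
#' @param max_age_diff maximum age difference in years between matched
#'   subjects (default 5).
#' @param max_group_size cap on the number of exposed subjects (and hence
#'   matched pairs); exposed groups larger than this are subsampled
#'   uniformly at random (default 10000).
#' @param followup_window administrative follow-up horizon in days
#'   (default 3650, ten years).
#' @param seed integer seed governing exposure subsampling and control
#'   draws. Each disease pair uses a substream derived deterministically
#'   from this seed and the pair labels, so per-pair cohorts do not depend
#'   on the order in which pairs are processed.
#' @return A list of class `match_params`.
#' @export
match_params <- function(max_date_diff = 7, max_age_diff = 5,
                         max_group_size = 10000, followup_window = 3650,
                         seed = 1L) {
  if (max_date_diff <= 0 || max_age_diff <= 0 || max_group_size <= 0 ||
      followup_window <= 0) {
    dcn_stop("dcn_bad_input", "all matching bounds must be positive")
  }
  structure(list(max_date_diff = max_date_diff, max_age_diff = max_age_diff,
                 max_group_size = max_group_size,
                 followup_window = followup_window, seed = as.integer(seed)),
            class = "match_params")
}

# Precomputed lookup structures shared by all pairs of one dataset:
# patient attributes, and per-(gender, ethnicity) stratum the diagnosis rows
# sorted by calendar day for windowed control lookup.
make_match_index <- function(ds) {
  pat <- patient_table(ds)
  pat$pid <- seq_len(nrow(pat))
  rec <- ds$records
  pidx <- match(rec$patient_id, pat$patient_id)
  key <- paste(pat$gender[pidx], pat$ethnicity[pidx], sep = "\r")
  ord <- order(key, rec$day)
  strata_key <- key[ord]
  runs <- rle(strata_key)
  starts <- cumsum(c(1L, runs$lengths[-length(runs$lengths)]))
  strata <- vector("list", length(runs$values))
  names(strata) <- runs$values
  day_s <- rec$day[ord]; pid_s <- pidx[ord]; dis_s <- rec$disease[ord]
  for (i in seq_along(runs$values)) {
    idx <- starts[i]:(starts[i] + runs$lengths[i] - 1L)
    strata[[i]] <- list(day = day_s[idx], pid = pid_s[idx], disease = dis_s[idx])
  }
  pat_key <- paste(pat$gender, pat$ethnicity, sep = "\r")
  list(pat = pat, strata = strata, pat_key = pat_key)
}

#' Build the matched cohort for one ordered disease pair
#'
#' Implements the matching design described in [match_params()]. Subjects
#' (in either group) whose first Y diagnosis falls on or before their index
#' date are excluded before matching (the event must be a later diagnosis).
#' Control matching is without replacement within the pair; exposed subjects
#' with no eligible control are dropped, keeping the two groups equal in
#' size.
#'
#' @param ds an `emr_dataset`.
#' @param X exposure disease label.
#' @param Y outcome disease label.
#' @param params a [match_params()] object.
#' @return An object of class `matched_cohort`: list with `pair`,
#'   `subjects` (data frame: `patient_id`, `exposed`, `index_date`,
#'   `time_to_event`, `event`, `age_at_index`, `gender`, `ethnicity`, extra
#'   covariates), `n_exposed`, `n_comparison`, `n_unmatched`, `params`.
#' @export
build_matched_cohort <- function(ds, X, Y, params = match_params()) {
  stopifnot(inherits(ds, "emr_dataset"))
  if (identical(X, Y)) dcn_stop("dcn_bad_input", "X and Y must differ")
  if (!X %in% ds$diseases)
    dcn_stop("dcn_empty_exposure", sprintf("no patients diagnosed with %s", X))
  if (!Y %in% ds$diseases)
    dcn_stop("dcn_unknown_disease", sprintf("disease not in dataset: %s", Y))
  index <- attr(ds, "match_index") %||% make_match_index(ds)
  pat <- index$pat
  patients <- pat$patient_id

  first_x <- first_dx_days(ds, patients, X)
  first_y <- first_dx_days(ds, patients, Y)
  has_x <- is.finite(first_x)

  cases <- which(has_x)
  if (length(cases) == 0L)
    dcn_stop("dcn_empty_exposure", sprintf("no patients diagnosed with %s", X))
  # prevalent-Y exclusion for the exposed: Y on or before the X index date
  cases <- cases[first_y[cases] > first_x[cases]]
  if (length(cases) == 0L)
    dcn_stop("dcn_empty_exposure",
             sprintf("no exposed subjects free of prevalent %s", Y))

  with_seed(mix_seed(params$seed, X, Y), {
    cases <- cases[sample.int(length(cases))]
    if (length(cases) > params$max_group_size)
      cases <- cases[seq_len(params$max_group_size)]

    used <- logical(nrow(pat))
    used[cases] <- TRUE  # a case cannot also serve as its own pool member
    m_case <- integer(0); m_ctrl <- integer(0); m_ctrl_day <- integer(0)
    dd <- params$max_date_diff
    for (ci in cases) {
      s <- index$strata[[index$pat_key[ci]]]
      if (is.null(s)) next
      idx_day <- first_x[ci]
      lo <- findInterval(idx_day - dd - 0.5, s$day) + 1L
      hi <- findInterval(idx_day + dd + 0.5, s$day)
      if (hi < lo) next
      rows <- lo:hi
      cpid <- s$pid[rows]
      # candidate eligibility deliberately ignores Y: the control's index
      # diagnosis is drawn first, and prevalent-Y status is judged against
      # that drawn index — exactly as the exposed side is judged against its
      # X date. Conditioning the candidate days on Y would retain controls
      # destined to have the event and bias the hazard ratio downward.
      ok <- !has_x[cpid] & !used[cpid] & s$disease[rows] != X &
        abs((s$day[rows] - pat$birth_day[cpid]) -
              (idx_day - pat$birth_day[ci])) <= params$max_age_diff * DAYS_PER_YEAR
      if (!any(ok)) next
      rows <- rows[ok]
      cand <- unique(s$pid[rows])
      repeat {
        if (length(cand) == 0L) break
        pick <- cand[sample.int(length(cand), 1L)]
        prows <- rows[s$pid[rows] == pick]
        prow <- prows[sample.int(length(prows), 1L)]
        if (first_y[pick] <= s$day[prow]) {
          # prevalent case at its drawn index: excluded for this slot
          cand <- cand[cand != pick]
          next
        }
        used[pick] <- TRUE
        m_case <- c(m_case, ci)
        m_ctrl <- c(m_ctrl, pick)
        m_ctrl_day <- c(m_ctrl_day, s$day[prow])
        break
      }
    }
  })

  if (length(m_case) == 0L)
    dcn_stop("dcn_no_matches",
             sprintf("no eligible matched controls for %s -> %s", X, Y))

  last_day <- pat$last_day
  fu <- function(pids, idays) {
    ev_day <- first_y[pids]
    event <- ev_day > idays & ev_day <= idays + params$followup_window
    tte <- ifelse(event, ev_day - idays,
                  pmin(last_day[pids] - idays, params$followup_window))
    list(time = pmax(tte, 1), event = event)
  }
  fe <- fu(m_case, first_x[m_case])
  fc <- fu(m_ctrl, m_ctrl_day)

  mk <- function(pids, idays, f, exposed) {
    df <- data.frame(
      patient_id = pat$patient_id[pids],
      exposed = exposed,
      index_date = as.Date(idays, origin = "1970-01-01"),
      time_to_event = as.numeric(f$time),
      event = f$event,
      age_at_index = (idays - pat$birth_day[pids]) / DAYS_PER_YEAR,
      gender = pat$gender[pids],
      ethnicity = pat$ethnicity[pids],
      stringsAsFactors = FALSE
    )
    for (cn in ds$covariate_names) df[[cn]] <- pat[[cn]][pids]
    df
  }
  subjects <- rbind(mk(m_case, first_x[m_case], fe, TRUE),
                    mk(m_ctrl, m_ctrl_day, fc, FALSE))
  rownames(subjects) <- NULL

  matched_cohort(pair = c(X, Y), subjects = subjects, params = params,
                 n_unmatched = length(cases) - length(m_case))
}

#' Low-level matched-cohort constructor
#'
#' Assembles a `matched_cohort` from an explicit subject table, validating
#' the container invariants (positive follow-up times bounded by the window,
#' equal group sizes when `check_balance`). Useful for simulation studies
#' and audits that bypass [build_matched_cohort()].
#'
#' @param pair character vector `c(X, Y)`.
#' @param subjects data frame with at least `exposed` (logical),
#'   `time_to_event` (days > 0) and `event` (logical); demographics and
#'   covariates optional.
#' @param params a [match_params()] object.
#' @param n_unmatched number of exposed subjects dropped for lack of an
#'   eligible control.
#' @param check_balance assert 1:1 group sizes (default TRUE).
#' @return A `matched_cohort` object.
#' @export
matched_cohort <- function(pair, subjects, params = match_params(),
                           n_unmatched = 0L, check_balance = TRUE) {
  stopifnot(is.data.frame(subjects),
            all(c("exposed", "time_to_event", "event") %in% names(subjects)))
  if (any(subjects$time_to_event <= 0))
    dcn_stop("dcn_bad_input", "time_to_event must be positive")
  if (any(subjects$time_to_event > params$followup_window + 1e-9))
    dcn_stop("dcn_bad_input", "time_to_event exceeds the follow-up window")
  n_e <- sum(subjects$exposed); n_c <- sum(!subjects$exposed)
  if (check_balance && n_e != n_c)
    dcn_stop("dcn_bad_input", "exposed and comparison groups must be the same size")
  structure(list(pair = pair, subjects = subjects, n_exposed = n_e,
                 n_comparison = n_c, n_unmatched = n_unmatched,
                 params = params),
            class = "matched_cohort")
}

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("<matched_cohort> %s -> %s: %d exposed + %d comparison (%d cases unmatched)\n",
              x$pair[1], x$pair[2], x$n_exposed, x$n_comparison, x$n_unmatched))
  cat(sprintf("  events: %d exposed / %d comparison; window %d days\n",
              sum(x$subjects$event[x$subjects$exposed]),
              sum(x$subjects$event[!x$subjects$exposed]),
              as.integer(x$params$followup_window)))
  invisible(x)
}

#' Follow-up time and event indicator for one subject
#'
#' If the patient's first Y diagnosis lies in (index, index + window] the
#' subject has the event at that time; otherwise the subject is censored at
#' the end of its record (last recorded diagnosis) or administratively at
#' the window, whichever is earlier. A censoring time of zero (no record
#' after the index date) is floored to one day.
#'
#' @param ds an `emr_dataset`.
#' @param patient patient identifier.
#' @param index_date `Date` (or days since 1970-01-01) index date.
#' @param Y outcome disease label.
#' @param window follow-up window in days.
#' @return list with `time_to_event` (days) and `event` (logical).
#' @export
compute_followup <- function(ds, patient, index_date, Y, window = 3650) {
  stopifnot(inherits(ds, "emr_dataset"))
  rec <- ds$records[ds$records$patient_id == patient, ]
  if (nrow(rec) == 0L)
    dcn_stop("dcn_bad_input", sprintf("unknown patient: %s", patient))
  iday <- as.numeric(if (inherits(index_date, "Date")) unclass(index_date) else index_date)
  y_day <- rec$day[rec$disease == Y]
  y_day <- if (length(y_day) > 0L) min(y_day) else Inf
  if (y_day <= iday)
    dcn_stop("dcn_prevalent_case",
             sprintf("%s diagnosed on or before the index date for patient %s", Y, patient))
  if (y_day <= iday + window) {
    list(time_to_event = y_day - iday, event = TRUE)
  } else {
    list(time_to_event = max(min(max(rec$day) - iday, window), 1), event = FALSE)
  }
}

#' Censoring (dropout) times and the drop-off/event/survival tally
#'
#' Dropouts are subjects censored strictly before the follow-up window
#' (their record ended early); subjects censored at the full window
#' completed follow-up and are tallied as "survival".
#'
#' @param cohort a `matched_cohort`.
#' @return list with `exposed` and `comparison` (numeric vectors of dropout
#'   times in days) and `freq`, a data frame with one row per group giving
#'   drop-off, event and survival counts (the three rows of the per-pair
#'   drop-off distribution table).
#' @export
dropout_times <- function(cohort) {
  stopifnot(inherits(cohort, "matched_cohort"))
  s <- cohort$subjects
  w <- cohort$params$followup_window
  is_drop <- !s$event & s$time_to_event < w
  is_surv <- !s$event & s$time_to_event >= w
  tally <- function(g) {
    data.frame(group = if (g) "exposed" else "comparison",
               dropoff = sum(is_drop & s$exposed == g),
               event = sum(s$event & s$exposed == g),
               survival = sum(is_surv & s$exposed == g),
               stringsAsFactors = FALSE)
  }
  list(exposed = s$time_to_event[is_drop & s$exposed],
       comparison = s$time_to_event[is_drop & !s$exposed],
       freq = rbind(tally(TRUE), tally(FALSE)))
}

#' Export a cohort's subject table
#'
#' @param x a `matched_cohort`.
#' @param ... unused.
#' @return The subject data frame with `from`/`to` pair columns prepended.
#' @export
as.data.frame.matched_cohort <- function(x, ...) {
  cbind(data.frame(from = x$pair[1], to = x$pair[2], stringsAsFactors = FALSE),
        x$subjects)
}
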