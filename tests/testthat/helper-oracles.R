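# Independent brute-force oracles and in-code fixtures.

# --- Cox partial likelihood, hand-written ---------------------------------
# Negative log partial likelihood for a single covariate, no ties. The
# exposure coefficient reported by the package must match the 1-D
# maximizer of this function.
pl_coef_oracle <- function(time, status, x) {
  negll <- function(b) {
    s <- 0
    for (i in which(status == 1)) {
      risk <- which(time >= time[i])
      s <- s - (b * x[i] - log(sum(exp(b * x[risk]))))
    }
    s
  }
  stats::optimize(negll, c(-10, 10), tol = 1e-10)$minimum
}

# --- Nelson-Aalen, hand-written -------------------------------------------
na_cumhaz_oracle <- function(time, status) {
  tt <- sort(unique(time[status == 1]))
  ch <- numeric(length(tt))
  h <- 0
  for (k in seq_along(tt)) {
    d <- sum(time == tt[k] & status == 1)
    n <- sum(time >= tt[k])
    h <- h + d / n
    ch[k] <- h
  }
  list(time = tt, cumhaz = ch)
}

# --- exhaustive matching eligibility --------------------------------------
# All (case, control, control_index_day) triples satisfying the matching
# rules, found by direct looping over the raw records. Independent of the
# package's stratified lookup structures.
eligible_triples <- function(ds, X, Y, params) {
  rec <- ds$records
  pts <- unique(rec$patient_id)
  first_day <- function(p, d) {
    v <- rec$day[rec$patient_id == p & rec$disease == d]
    if (length(v)) min(v) else Inf
  }
  demo <- function(p) {
    r <- rec[rec$patient_id == p, ][order(rec$day[rec$patient_id == p]), ][1, ]
    list(g = r$gender, e = r$ethnicity, birth = r$day - r$age * 365.25)
  }
  cases <- pts[vapply(pts, function(p) is.finite(first_day(p, X)), TRUE)]
  cases <- cases[vapply(cases, function(p) first_day(p, Y) > first_day(p, X), TRUE)]
  pool <- pts[vapply(pts, function(p) !is.finite(first_day(p, X)), TRUE)]
  out <- list()
  for (cs in cases) {
    dc <- demo(cs); idx <- first_day(cs, X)
    for (ct in pool) {
      dd <- demo(ct)
      if (dd$g != dc$g || dd$e != dc$e) next
      rows <- rec[rec$patient_id == ct & rec$disease != X, ]
      for (j in seq_len(nrow(rows))) {
        day <- rows$day[j]
        if (abs(day - idx) > params$max_date_diff) next
        age_c <- (idx - dc$birth) / 365.25
        age_t <- (day - dd$birth) / 365.25
        if (abs(age_t - age_c) > params$max_age_diff) next
        if (first_day(ct, Y) <= day) next
        out[[length(out) + 1L]] <- data.frame(case = cs, control = ct,
                                              control_day = day)
      }
    }
  }
  if (length(out) == 0L) {
    data.frame(case = character(0), control = character(0),
               control_day = numeric(0))
  } else do.call(rbind, out)
}

# --- fixtures --------------------------------------------------------------

# Direct cohort generator for calibration/recovery studies: exponential
# event times with a multiplicative exposure effect, exponential dropout,
# administrative censoring at the window.
sim_exp_cohort <- function(n_per_arm, hr, lambda0 = 1e-3, window = 3650,
                           dropout_rate = 1e-4, seed = 1) {
  set.seed(seed)
  exposed <- rep(c(TRUE, FALSE), each = n_per_arm)
  ev <- stats::rexp(2 * n_per_arm, lambda0 * ifelse(exposed, hr, 1))
  cens <- if (dropout_rate > 0) stats::rexp(2 * n_per_arm, dropout_rate) else Inf
  time <- pmin(ev, cens, window)
  matched_cohort(c("X", "Y"),
                 data.frame(patient_id = sprintf("S%d", seq_along(time)),
                            exposed = exposed,
                            time_to_event = pmax(time, 1e-3),
                            event = ev <= pmin(cens, window),
                            age_at_index = round(stats::runif(2 * n_per_arm, 30, 70), 1),
                            gender = sample(c("F", "M"), 2 * n_per_arm, TRUE),
                            ethnicity = "any",
                            stringsAsFactors = FALSE),
                 match_params(followup_window = window, seed = seed))
}

# Small deterministic EMR table exercising matching edge cases.
toy_emr <- function() {
  rec <- list()
  add <- function(p, d, day, age0, g, e) {
    rec[[length(rec) + 1L]] <<- data.frame(
      patient_id = p, disease = d,
      first_dx_date = as.Date("2010-01-01") + day,
      age = age0 + day / 365.25, gender = g, ethnicity = e,
      stringsAsFactors = FALSE)
  }
  # cases with X (and some with later Y)
  add("c1", "X", 100, 50, "F", "w"); add("c1", "Y", 500, 50, "F", "w")
  add("c2", "X", 200, 60, "M", "w"); add("c2", "A", 300, 60, "M", "w")
  add("c3", "X", 300, 40, "F", "b"); add("c3", "Y", 250, 40, "F", "b") # prevalent Y
  # controls
  add("k1", "A", 103, 51, "F", "w"); add("k1", "B", 900, 51, "F", "w")
  add("k2", "A", 205, 58, "M", "w"); add("k2", "Y", 2000, 58, "M", "w")
  add("k3", "B", 199, 33, "M", "w")                  # age too far from c2
  add("k4", "A", 101, 50, "M", "w")                  # gender mismatch for c1
  add("k5", "Y", 102, 49, "F", "w")                  # only Y near c1's index
  as_emr_dataset(do.call(rbind, rec))
}

# Random directed network fixture with the full edge attribute set.
random_network <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  all_pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  pick <- all_pairs[sample.int(nrow(all_pairs), min(n_edges, nrow(all_pairs))), ]
  cox <- data.frame(from = pick$from, to = pick$to,
                    coefficient = round(stats::rnorm(nrow(pick)), 4),
                    hazard_ratio = NA, n = sample(50:5000, nrow(pick), TRUE),
                    p_raw = stats::runif(nrow(pick), 0, 0.04),
                    p_adjusted = stats::runif(nrow(pick), 0, 0.04),
                    zph_p = stats::runif(nrow(pick)),
                    stringsAsFactors = FALSE)
  cox$hazard_ratio <- exp(cox$coefficient)
  build_network(cox, alpha = 0.05, mode = "cox", require_positive = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
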