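# Synthetic longitudinal medical-record simulator with planted temporal
# effects.
#
# Each patient carries a demographic profile and an independent exponential
# first-diagnosis clock per disease (a Markov illness process with
# piecewise-constant hazards). A planted effect (X, Y, hazard_ratio)
# multiplies Y's hazard by the hazard ratio from the moment of the
# patient's X onset, so the true exposure hazard ratio of the matched
# design is known and recoverable. Records are truncated at an exponential
# per-patient dropout time and at the observation span, producing the
# irregular horizons (drop-outs) real records show.

#' Simulation configuration
#'
#' Defaults emulate, at configurable scale, a multi-year hospital-registry
#' extract: tens of chronic conditions, roughly 10% ten-year cumulative
#' incidence per condition, a ten-year observation window and substantial
#' record churn.
#'
#' @param n_patients number of patients.
#' @param diseases character vector of disease labels.
#' @param planted_effects data frame with columns `from`, `to`,
#'   `hazard_ratio` (or NULL for a null configuration). The effect graph
#'   must be acyclic.
#' @param baseline_rate per-day first-diagnosis hazard, recycled across
#'   diseases (default 3e-5/day, about 10% in ten years).
#' @param gender_probs,ethnicity_probs named category probabilities
#'   (must sum to 1).
#' @param age_mean,age_sd,age_range age-at-entry distribution (normal,
#'   truncated to `age_range`).
#' @param observation_span length of the observation window in days
#'   (default 3650, ten years).
#' @param dropout_rate per-day hazard of record truncation (default
#'   2e-4/day: roughly half of all records end before ten years). 0 means
#'   no early dropout.
#' @param age_effect log hazard-ratio per decade of age applied to every
#'   disease clock (default 0; set positive to exercise covariate
#'   adjustment).
#' @param seed master seed. Each patient uses an RNG substream derived from
#'   it, so increasing `n_patients` extends the population without
#'   reshuffling earlier patients.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 1000,
                              diseases = sprintf("D%02d", 1:15),
                              planted_effects = NULL,
                              baseline_rate = 3e-5,
                              gender_probs = c(F = 0.5, M = 0.5),
                              ethnicity_probs = c(white = 0.6, black = 0.2,
                                                  hispanic = 0.15, other = 0.05),
                              age_mean = 50, age_sd = 15, age_range = c(18, 90),
                              observation_span = 3650,
                              dropout_rate = 2e-4,
                              age_effect = 0,
                              seed = 1L) {
  if (n_patients < 1) dcn_stop("dcn_bad_input", "n_patients must be >= 1")
  if (length(diseases) < 1) dcn_stop("dcn_bad_input", "at least one disease required")
  if (anyDuplicated(diseases)) dcn_stop("dcn_bad_input", "duplicate disease labels")
  if (abs(sum(gender_probs) - 1) > 1e-8 || abs(sum(ethnicity_probs) - 1) > 1e-8)
    dcn_stop("dcn_bad_input", "category probabilities must sum to 1")
  if (any(baseline_rate <= 0)) dcn_stop("dcn_bad_input", "baseline_rate must be positive")
  if (observation_span <= 0) dcn_stop("dcn_bad_input", "observation_span must be positive")
  if (dropout_rate < 0) dcn_stop("dcn_bad_input", "dropout_rate must be non-negative")
  if (!is.null(planted_effects)) {
    pe <- as.data.frame(planted_effects, stringsAsFactors = FALSE)
    if (!all(c("from", "to", "hazard_ratio") %in% names(pe)))
      dcn_stop("dcn_bad_input", "planted_effects needs columns from, to, hazard_ratio")
    if (any(pe$from == pe$to)) dcn_stop("dcn_bad_input", "planted effect with X == Y")
    if (any(pe$hazard_ratio <= 0)) dcn_stop("dcn_bad_input", "hazard ratios must be positive")
    if (!all(c(pe$from, pe$to) %in% diseases))
      dcn_stop("dcn_bad_input", "planted effect on unknown disease")
    if (is_cyclic(pe$from, pe$to))
      dcn_stop("dcn_bad_input", "planted effect graph must be acyclic")
    planted_effects <- pe
  }
  structure(list(n_patients = as.integer(n_patients), diseases = diseases,
                 planted_effects = planted_effects,
                 baseline_rate = rep_len(baseline_rate, length(diseases)),
                 gender_probs = gender_probs, ethnicity_probs = ethnicity_probs,
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 observation_span = observation_span,
                 dropout_rate = dropout_rate, age_effect = age_effect,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

is_cyclic <- function(from, to) {
  nodes <- unique(c(from, to))
  indeg <- stats::setNames(tabulate(match(to, nodes), length(nodes)), nodes)
  repeat {
    free <- names(indeg)[indeg == 0]
    if (length(free) == 0L) return(length(indeg) > 0L)
    drop_edges <- from %in% free
    for (t in to[drop_edges]) indeg[t] <- indeg[t] - 1L
    indeg <- indeg[!names(indeg) %in% free]
    from2 <- from[!drop_edges]; to2 <- to[!drop_edges]
    if (length(from2) == 0L) return(FALSE)
    from <- from2; to <- to2
  }
}

# Diseases ordered so every planted effect's source precedes its target.
topo_order <- function(diseases, pe) {
  if (is.null(pe) || nrow(pe) == 0L) return(diseases)
  ord <- character(0)
  remaining <- diseases
  while (length(remaining) > 0L) {
    blocked <- unique(pe$to[pe$from %in% remaining])
    free <- setdiff(remaining, blocked)
    ord <- c(ord, free)
    remaining <- setdiff(remaining, free)
  }
  ord
}

#' Simulate a longitudinal first-diagnosis table
#'
#' @param config a [simulation_config()].
#' @return list with `dataset` (an `emr_dataset` in the same layout
#'   [read_emr_table()] produces; calendar dates start at 2000-01-01) and
#'   `truth` (the planted directed edge list, see [planted_truth()]).
#'   Deterministic given `config$seed`. Patients whose record holds no
#'   diagnosis within their horizon do not appear in the table.
#' @export
simulate_emr <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  d_names <- config$diseases
  nd <- length(d_names)
  ord <- topo_order(d_names, config$planted_effects)
  pe <- config$planted_effects
  rate <- stats::setNames(config$baseline_rate, d_names)
  span <- config$observation_span

  res_pid <- vector("list", config$n_patients)
  res_dis <- vector("list", config$n_patients)
  res_day <- vector("list", config$n_patients)
  res_demo <- matrix(NA_real_, config$n_patients, 1)
  demo_g <- character(config$n_patients); demo_e <- character(config$n_patients)

  with_seed(config$seed, NULL)  # validate seed early
  for (i in seq_len(config$n_patients)) {
    set.seed(mix_seed(config$seed, "patient", i))
    g <- sample(names(config$gender_probs), 1L, prob = config$gender_probs)
    e <- sample(names(config$ethnicity_probs), 1L, prob = config$ethnicity_probs)
    age0 <- min(max(stats::rnorm(1, config$age_mean, config$age_sd),
                    config$age_range[1]), config$age_range[2])
    # one standard-exponential draw regardless of the rate keeps per-patient
    # streams aligned across configurations that differ only in dropout
    u_drop <- stats::rexp(1)
    dropout <- if (config$dropout_rate > 0) u_drop / config$dropout_rate else Inf
    horizon <- min(span, dropout)
    m_age <- exp(config$age_effect * (age0 - 50) / 10)

    onset <- stats::setNames(rep(Inf, nd), d_names)
    for (d in ord) {
      lam <- rate[[d]] * m_age
      srcs <- if (!is.null(pe)) which(pe$to == d) else integer(0)
      E <- stats::rexp(1)
      if (length(srcs) == 0L) {
        onset[[d]] <- E / lam
      } else {
        jumps <- sort(onset[pe$from[srcs]][is.finite(onset[pe$from[srcs]])])
        hrs <- pe$hazard_ratio[srcs][order(onset[pe$from[srcs]])][seq_along(jumps)]
        onset[[d]] <- invert_piecewise_hazard(E, lam, jumps, hrs)
      }
    }
    keep <- which(onset <= horizon & onset <= span)
    if (length(keep) > 0L) {
      days <- pmax(ceiling(onset[keep]), 1)
      inside <- days <= floor(horizon)
      keep <- keep[inside]; days <- days[inside]
    }
    if (length(keep) > 0L) {
      res_pid[[i]] <- rep.int(i, length(keep))
      res_dis[[i]] <- d_names[keep]
      res_day[[i]] <- as.integer(days)
      res_demo[i, 1] <- age0
      demo_g[i] <- g; demo_e[i] <- e
    }
  }

  pid <- unlist(res_pid, use.names = FALSE)
  if (length(pid) == 0L)
    dcn_stop("dcn_empty_input", "simulation produced no diagnoses; raise rates or span")
  day <- unlist(res_day, use.names = FALSE)
  age0 <- res_demo[pid, 1]
  records <- data.frame(
    patient_id = sprintf("P%06d", pid),
    disease = unlist(res_dis, use.names = FALSE),
    first_dx_date = as.Date("2000-01-01") + day,
    age = round(age0 + day / DAYS_PER_YEAR, 6),
    gender = demo_g[pid],
    ethnicity = demo_e[pid],
    stringsAsFactors = FALSE
  )
  list(dataset = as_emr_dataset(records), truth = planted_truth(config))
}

# Inverse cumulative hazard for a clock with baseline rate `lam` and
# multiplicative jumps `hrs` at (sorted) times `jumps`: returns the time at
# which cumulative hazard reaches E.
invert_piecewise_hazard <- function(E, lam, jumps, hrs) {
  if (length(jumps) == 0L) return(E / lam)
  mult <- 1
  t0 <- 0
  H <- 0
  for (k in seq_along(jumps)) {
    seg <- lam * mult * (jumps[k] - t0)
    if (H + seg >= E) return(t0 + (E - H) / (lam * mult))
    H <- H + seg
    t0 <- jumps[k]
    mult <- mult * hrs[k]
  }
  t0 + (E - H) / (lam * mult)
}

#' Ground-truth planted edge set
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `from`, `to`, `hazard_ratio`: the
#'   directed edges the pipeline should recover. Empty for a null
#'   configuration. Depends only on the configuration, not on any seed.
#' @export
planted_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$planted_effects))
    return(data.frame(from = character(0), to = character(0),
                      hazard_ratio = numeric(0)))
  config$planted_effects[, c("from", "to", "hazard_ratio")]
}
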