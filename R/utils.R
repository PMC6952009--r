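# Internal helpers: typed conditions and reproducible local RNG.

# Typed error constructor. All package errors inherit from "dcn_error" so
# callers (and the pipeline's per-pair status table) can distinguish
# expected analysis failures from programming bugs.
dcn_stop <- function(class, message, ...) {
  stop(structure(
    class = c(class, "dcn_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' @keywords internal
is_dcn_error <- function(e) inherits(e, "dcn_error")

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so library code never perturbs the user's random stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit hash mixing a base seed with strings; used to derive
# per-pair and per-patient substreams from one master seed so results do not
# depend on processing order.
mix_seed <- function(seed, ...) {
  m <- 2147483587
  h <- as.double(seed %% m)
  for (s in c(...)) {
    for (k in utf8ToInt(as.character(s))) h <- (h * 31 + k) %% m
  }
  as.integer(h)
}

DAYS_PER_YEAR <- 365.25

`%||%` <- function(a, b) if (is.null(a)) b else a
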