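# Structured error conditions used across the package. Every condition
# carries class c(<specific>, "tcs_error", "error") so callers can catch
# either the family or the precise failure mode.

stop_tcs <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "tcs_error")))
}

stop_dimension <- function(msg, ...) stop_tcs("tcs_dimension_error", msg, ...)
stop_parameter <- function(msg, ...) stop_tcs("tcs_parameter_error", msg, ...)
stop_provenance <- function(msg, ...) stop_tcs("tcs_provenance_error", msg, ...)
stop_state <- function(msg, ...) stop_tcs("tcs_state_error", msg, ...)
stop_configuration <- function(msg, ...) stop_tcs("tcs_configuration_error", msg, ...)
stop_format <- function(msg, ...) stop_tcs("tcs_format_error", msg, ...)
stop_training <- function(msg, ...) stop_tcs("tcs_training_error", msg, ...)

#' Derive a stream seed from a base seed and a counter
#'
#' Counter-based seeding: every randomized sub-task (mask plane b, clip i,
#' noise draw t, training step s) derives its own seed from `(seed, k)` and
#' seeds the RNG locally, so results do not depend on global draw order.
#' Kept strictly below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param k non-negative integer counter.
#' @return an integer seed.
#' @keywords internal
mix_seed <- function(seed, k) {
  s <- as.numeric(seed %% 2147483647L)
  as.integer((s * 48271 + as.numeric(k) * 9973 + 1) %% 2147483647)
}

# Run expr under a local, derived seed without touching the caller's RNG.
with_stream_seed <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(mix_seed(seed, k))
  expr
}
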