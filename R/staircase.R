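#' Bisection threshold staircase
#'
#' Per-location thresholding by interval bisection. The state tracks a lower
#' and upper sensitivity bound in dB (initially the 14-40 dB test range); each
#' presentation is at the midpoint of the current interval (or at a seed
#' intensity for the very first presentation); a "seen" response raises the
#' lower bound to the presented value, a "not seen" response lowers the upper
#' bound. Testing stops when the interval is narrower than 1 dB and the final
#' threshold is the interval midpoint. From the full unseeded range the
#' interval width halves 26 -> 13 -> 6.5 -> 3.25 -> 1.625 -> 0.8125, so an
#' unseeded staircase always takes exactly five presentations.
#'
#' @param lower,upper Initial interval bounds in dB.
#' @param seed Optional seed intensity for the first presentation (typically
#'   the previously measured central threshold). A seed outside
#'   `[lower, upper]` is rejected with a warning and the staircase proceeds
#'   unseeded.
#' @return A `threshold_state` object.
#' @examples
#' st <- init_state()
#' next_intensity(st)  # 27, the midpoint of [14, 40]
#' st <- stair_update(st, 27, seen = TRUE)
#' next_intensity(st)  # 33.5
#' @export
init_state <- function(lower = 14, upper = 40, seed = NULL) {
  if (!(lower < upper)) abort("staircase requires lower < upper")
  if (!is.null(seed) && (seed < lower || seed > upper)) {
    warn(sprintf("seed %.4g outside [%.4g, %.4g]; falling back to unseeded",
                 seed, lower, upper))
    seed <- NULL
  }
  structure(
    list(
      lower = lower, upper = upper,
      init_lower = lower, init_upper = upper,
      seed = seed,
      pres_intensity = numeric(), pres_seen = logical(),
      terminated = FALSE
    ),
    class = "threshold_state"
  )
}

#' @rdname init_state
#' @param state A `threshold_state`.
#' @export
next_intensity <- function(state) {
  stopifnot(inherits(state, "threshold_state"))
  if (state$terminated) abort("staircase already terminated")
  if (length(state$pres_intensity) == 0 && !is.null(state$seed)) {
    return(state$seed)
  }
  (state$lower + state$upper) / 2
}

#' @rdname init_state
#' @param presented Intensity presented, dB.
#' @param seen Logical response.
#' @export
stair_update <- function(state, presented, seen) {
  stopifnot(inherits(state, "threshold_state"), is.logical(seen))
  if (state$terminated) abort("staircase already terminated")
  if (seen) state$lower <- presented else state$upper <- presented
  if (state$lower > state$upper) {
    abort("presentation outside the current interval inverted the bounds")
  }
  state$pres_intensity <- c(state$pres_intensity, presented)
  state$pres_seen <- c(state$pres_seen, seen)
  state$terminated <- (state$upper - state$lower) < 1
  state
}

#' @rdname init_state
#' @export
stair_log <- function(state) {
  stopifnot(inherits(state, "threshold_state"))
  tibble::tibble(intensity = state$pres_intensity, seen = state$pres_seen)
}

#' @rdname init_state
#' @export
final_threshold <- function(state) {
  stopifnot(inherits(state, "threshold_state"))
  if (!state$terminated) abort("staircase has not terminated")
  tibble::tibble(
    threshold = (state$lower + state$upper) / 2,
    floored = state$lower == state$init_lower,
    ceilinged = state$upper == state$init_upper,
    n_presentations = length(state$pres_intensity)
  )
}

#' Run one staircase to completion against a response function
#'
#' Drives a [init_state()] staircase by repeatedly presenting
#' [next_intensity()] and updating with the response until termination.
#'
#' @param respond_fn Function of one argument (presented dB) returning a
#'   logical seen flag.
#' @inheritParams init_state
#' @return The one-row tibble from [final_threshold()], plus the presentation
#'   log as attribute `"log"`.
#' @examples
#' # deterministic observer with true sensitivity 30 dB
#' run_staircase(function(db) db <= 30)$threshold  # 29.84375
#' @export
run_staircase <- function(respond_fn, lower = 14, upper = 40, seed = NULL) {
  st <- init_state(lower, upper, seed)
  while (!st$terminated) {
    intensity <- next_intensity(st)
    st <- stair_update(st, intensity, isTRUE(respond_fn(intensity)))
  }
  out <- final_threshold(st)
  attr(out, "log") <- stair_log(st)
  out
}
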