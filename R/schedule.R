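# Reduce-on-plateau learning-rate schedule: when the monitored metric fails
# to improve for `patience` consecutive epochs, the rate is multiplied by
# `factor` (lr' = lr * factor), never dropping below a positive floor.

#' Plateau schedule state
#'
#' @param lr initial learning rate. Default 0.01.
#' @param factor multiplicative cut in (0, 1). Default 0.5 (a factor of 0.1
#'   cuts too steeply, freezing learning in early epochs).
#' @param patience epochs without improvement before a cut. Default 2
#'   ("fails to change every two epochs").
#' @param min_delta smallest decrease of the monitored metric that counts as
#'   improvement. Default 1e-4.
#' @param floor smallest allowed learning rate; must be strictly positive.
#'   Default 1e-12, below the 1e-11 the schedule reaches under a sustained
#'   plateau of 60+ epochs.
#' @return object of class `schedule_state`.
#' @export
schedule_state <- function(lr = 0.01, factor = 0.5, patience = 2L,
                           min_delta = 1e-4, floor = 1e-12) {
  stopifnot(lr > 0, factor > 0, factor < 1, patience >= 1,
            min_delta >= 0, floor > 0)
  structure(list(lr = lr, factor = factor, patience = as.integer(patience),
                 min_delta = min_delta, floor = floor,
                 best = Inf, wait = 0L, cuts = 0L),
            class = "schedule_state")
}

#' Advance the plateau schedule by one epoch
#'
#' The monitored metric is minimized (validation loss). An improvement
#' greater than `min_delta` resets the stagnation counter; once the counter
#' reaches `patience`, `lr` is cut to `max(lr * factor, floor)` and the
#' counter resets.
#'
#' @param state a [schedule_state()].
#' @param metric the epoch's monitored value (finite).
#' @return the updated state.
#' @export
step_on_plateau <- function(state, metric) {
  stopifnot(inherits(state, "schedule_state"))
  if (!is.finite(metric))
    stop("monitored metric must be finite (got ", metric, ")", call. = FALSE)
  if (state$best - metric > state$min_delta) {
    state$best <- metric
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= state$patience) {
      state$lr <- max(state$lr * state$factor, state$floor)
      state$cuts <- state$cuts + 1L
      state$wait <- 0L
    }
  }
  state
}

#' Simulate the schedule under a sustained plateau
#'
#' Feeds a constant metric for `epochs` epochs and returns the learning-rate
#' trajectory (one cut per `patience` epochs).
#'
#' @param epochs number of stagnant epochs to simulate.
#' @param state starting [schedule_state()].
#' @return data.frame with columns `epoch` and `lr` (rate after that epoch).
#' @export
simulate_plateau <- function(epochs, state = schedule_state()) {
  lr <- numeric(epochs)
  for (e in seq_len(epochs)) {
    state <- step_on_plateau(state, 1)   # constant metric: never improves
    lr[e] <- state$lr
  }
  data.frame(epoch = seq_len(epochs), lr = lr)
}
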