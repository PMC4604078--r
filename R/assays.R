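#' Novel-object discrimination index
#'
#' 100 x novel-object exploration over total exploration (time or
#' frequency); 50 is chance level.
#'
#' @param novel_measure,familiar_measure non-negative exploration measures
#'   (time or contact counts), not both zero
#' @return discrimination index in percent
#' @export
discrimination_index <- function(novel_measure, familiar_measure) {
  stopifnot(novel_measure >= 0, familiar_measure >= 0)
  if (novel_measure + familiar_measure == 0)
    stop("discrimination index undefined: no exploration of either object")
  100 * novel_measure / (novel_measure + familiar_measure)
}

#' Grip strength from repeated trials
#'
#' Strength is estimated as the arithmetic mean of the trial maxima
#' (two trials in the standard protocol).
#'
#' @param trial_forces numeric vector of per-trial maximal forces (N)
#' @param n_trials expected number of trials
#' @return mean force in Newtons
#' @export
grip_strength <- function(trial_forces, n_trials = 2L) {
  if (length(trial_forces) != n_trials)
    stop("expected ", n_trials, " trials, got ", length(trial_forces))
  mean(trial_forces)
}

#' Peak twitch and tetanic force normalised to muscle wet weight
#'
#' Each trace is baseline-corrected by the median force over the
#' pre-stimulus window; the maximal response per stimulus kind is the
#' tallest baseline-corrected peak across that kind's traces, divided by
#' the muscle wet weight (Newtons per gram).
#'
#' @param traces list of traces, each a list/data.frame with numeric
#'   `time` (s) and `force` (N) and a `kind` field ("twitch" or "tetanus")
#' @param wet_weight_g muscle wet weight in grams (> 0)
#' @param baseline_window_s length of the pre-stimulus baseline window (s)
#' @return list with `twitch_n_per_g` and `tetanus_n_per_g`; a kind with
#'   no traces is reported as NA, not zero
#' @export
force_summary <- function(traces, wet_weight_g, baseline_window_s = 0.05) {
  stopifnot(wet_weight_g > 0, length(traces) >= 1)
  peaks <- vapply(traces, function(tr) {
    t0 <- min(tr$time)
    base <- median(tr$force[tr$time <= t0 + baseline_window_s])
    max(tr$force) - base
  }, 1)
  kinds <- vapply(traces, function(tr) as.character(tr$kind), "")
  if (!all(kinds %in% c("twitch", "tetanus")))
    stop("trace kind must be 'twitch' or 'tetanus'")
  peak_of <- function(k) {
    sel <- kinds == k
    if (!any(sel)) return(NA_real_)
    max(peaks[sel]) / wet_weight_g
  }
  list(twitch_n_per_g = peak_of("twitch"),
       tetanus_n_per_g = peak_of("tetanus"))
}
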