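#' Build the paired-recording stimulation protocol
#'
#' Constructs the per-trial current-injection protocol used to probe both
#' electrical and chemical connections from a driver cell: two brief (5 ms)
#' high suprathreshold depolarizations separated by 50 ms (20 Hz), one more
#' brief depolarization at 500 ms, one long (200 ms) low suprathreshold
#' depolarization, and one long (200 ms) hyperpolarizing step (-200 pA)
#' starting 300 ms after the end of the depolarizing step.
#'
#' @param brief_amp_pA amplitude of the brief suprathreshold pulses; must lie
#'   in \[600, 1000\] pA.
#' @param long_depol_pA amplitude of the long depolarizing step; must lie in
#'   \[200, 600\] pA.
#' @param hyper_amp_pA magnitude of the hyperpolarizing step; fixed at 200 pA.
#' @param n_trials_electrical,n_trials_chemical trials per probed driver for
#'   each detection mode (at least 10 each).
#' @return An object of class `stim_protocol` with a `pulses` data frame
#'   (onset_ms, duration_ms, amplitude_pA) and `trial_length_ms`.
#' @examples
#' p <- build_protocol(800, 400, 200)
#' nrow(p$pulses)  # 5
#' @export
build_protocol <- function(brief_amp_pA, long_depol_pA, hyper_amp_pA = 200,
                           n_trials_electrical = 10, n_trials_chemical = 10) {
  if (brief_amp_pA < 600 || brief_amp_pA > 1000)
    stopf("brief_amp_pA must be in [600, 1000] pA, got %g", brief_amp_pA)
  if (long_depol_pA < 200 || long_depol_pA > 600)
    stopf("long_depol_pA must be in [200, 600] pA, got %g", long_depol_pA)
  if (hyper_amp_pA != 200)
    stopf("hyper_amp_pA is fixed at 200 pA, got %g", hyper_amp_pA)
  if (n_trials_electrical < 10 || n_trials_chemical < 10)
    stopf("at least 10 trials per detection mode are required")
  pulses <- data.frame(
    onset_ms     = c(100, 150, 500, 700, 1200),
    duration_ms  = c(5, 5, 5, 200, 200),
    amplitude_pA = c(brief_amp_pA, brief_amp_pA, brief_amp_pA,
                     long_depol_pA, -abs(hyper_amp_pA))
  )
  proto <- structure(list(pulses = pulses, trial_length_ms = 1500,
                          n_trials_electrical = as.integer(n_trials_electrical),
                          n_trials_chemical = as.integer(n_trials_chemical)),
                     class = "stim_protocol")
  validate_protocol(proto)
  proto
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  pl <- p$pulses
  if (any(pl$duration_ms <= 0)) stopf("pulse durations must be positive")
  if (is.unsorted(pl$onset_ms, strictly = TRUE))
    stopf("pulses must be sorted by onset")
  off <- pl$onset_ms + pl$duration_ms
  if (any(off[-nrow(pl)] > pl$onset_ms[-1]))
    stopf("pulses must not overlap")
  if (p$trial_length_ms < max(off))
    stopf("trial length shorter than the last pulse offset")
  invisible(p)
}

# the hyperpolarizing epoch (used by electrical detection)
hyper_pulse <- function(protocol) {
  pl <- protocol$pulses
  h <- pl[pl$amplitude_pA < 0, , drop = FALSE]
  if (nrow(h) == 0) stopf("protocol has no hyperpolarizing pulse")
  h[nrow(h), ]
}

# brief suprathreshold pulses (anchor the presynaptic APs for chemical
# detection)
brief_pulses <- function(protocol) {
  pl <- protocol$pulses
  pl[pl$amplitude_pA > 0 & pl$duration_ms <= 10, , drop = FALSE]
}

#' Build a membrane-characterization step family
#'
#' A sweep family for feature extraction: one 500 ms subthreshold
#' hyperpolarizing step and a family of 1 s depolarizing steps, from which
#' the nine membrane/firing features (input resistance, maximal firing
#' frequency within 1 s, adaptation ratio, ...) are measured.
#'
#' @param sub_step_pA subthreshold step amplitude (negative, pA).
#' @param depol_steps_pA vector of 1 s depolarizing step amplitudes (pA).
#' @return A `stim_protocol`-like list with one sweep definition per step.
#' @export
characterization_protocol <- function(sub_step_pA = -50,
                                      depol_steps_pA = seq(100, 600, by = 100)) {
  stopifnot(sub_step_pA < 0, all(depol_steps_pA > 0))
  steps <- data.frame(
    amplitude_pA = c(sub_step_pA, depol_steps_pA),
    onset_ms = 200,
    duration_ms = c(500, rep(1000, length(depol_steps_pA)))
  )
  steps$trial_length_ms <- steps$onset_ms + steps$duration_ms + 300
  structure(list(steps = steps), class = "charac_protocol")
}
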