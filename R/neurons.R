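#' Single-cell biophysical parameters
#'
#' Parameters of the leaky single-compartment model with a stamped
#' action-potential waveform. The waveform is parametric so that the features
#' the FS/non-FS classifier measures (half-width, AHP amplitude, AHP time
#' from peak) are exactly controllable.
#'
#' @param rest_mV resting membrane potential.
#' @param R_in_MOhm input resistance (> 0).
#' @param C_pF membrane capacitance (> 0).
#' @param spike_threshold_mV voltage threshold for stamping an AP.
#' @param ap_peak_mV AP peak voltage.
#' @param ap_halfwidth_ms width at half peak-to-threshold amplitude (> 0).
#' @param ap_rise_ms threshold-to-peak upstroke duration.
#' @param ahp_amp_mV afterhyperpolarization depth below threshold.
#' @param ahp_time_ms time from AP peak to AHP minimum.
#' @param adaptation_strength per-spike increment (mV) of an exponentially
#'   decaying threshold offset; 0 gives non-adapting (FS-like) firing.
#' @param subtype_label generating label: "FS", "nonFS" or "PN".
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(rest_mV, R_in_MOhm, C_pF, spike_threshold_mV,
                          ap_peak_mV, ap_halfwidth_ms, ap_rise_ms,
                          ahp_amp_mV, ahp_time_ms, adaptation_strength,
                          subtype_label = c("FS", "nonFS", "PN")) {
  subtype_label <- match.arg(subtype_label)
  if (R_in_MOhm <= 0 || C_pF <= 0) stopf("R_in and C must be positive")
  if (ap_halfwidth_ms <= 0) stopf("half-width must be positive")
  if (rest_mV >= spike_threshold_mV) stopf("rest must lie below threshold")
  if (adaptation_strength < 0) stopf("adaptation_strength must be >= 0")
  fall <- 1.5 * ap_halfwidth_ms - ap_rise_ms
  if (fall <= 0)
    stopf("half-width too small for the rise time (need halfwidth > 2/3 rise)")
  if (ahp_time_ms <= fall)
    stopf("ahp_time_ms must exceed the AP downstroke duration (%.2f ms)", fall)
  structure(list(rest_mV = rest_mV, R_in_MOhm = R_in_MOhm, C_pF = C_pF,
                 spike_threshold_mV = spike_threshold_mV,
                 ap_peak_mV = ap_peak_mV, ap_halfwidth_ms = ap_halfwidth_ms,
                 ap_rise_ms = ap_rise_ms, ahp_amp_mV = ahp_amp_mV,
                 ahp_time_ms = ahp_time_ms,
                 adaptation_strength = adaptation_strength,
                 subtype_label = subtype_label),
            class = "neuron_params")
}

#' Preset cell types
#'
#' `fs_preset()` satisfies every FS classification threshold with margin;
#' `nonfs_preset()` violates several (input resistance, threshold, AHP
#' amplitude and timing, adaptation); `pn_preset()` is a regular-spiking,
#' adapting pyramidal-cell stand-in.
#'
#' @name presets
#' @export
fs_preset <- function() {
  neuron_params(rest_mV = -65, R_in_MOhm = 150, C_pF = 100,
                spike_threshold_mV = -33, ap_peak_mV = 30,
                ap_halfwidth_ms = 0.5, ap_rise_ms = 0.6,
                ahp_amp_mV = 12, ahp_time_ms = 3,
                adaptation_strength = 0, subtype_label = "FS")
}

#' @rdname presets
#' @export
nonfs_preset <- function() {
  neuron_params(rest_mV = -62, R_in_MOhm = 400, C_pF = 80,
                spike_threshold_mV = -40, ap_peak_mV = 35,
                ap_halfwidth_ms = 1.2, ap_rise_ms = 1.0,
                ahp_amp_mV = 4, ahp_time_ms = 12,
                adaptation_strength = 4, subtype_label = "nonFS")
}

#' @rdname presets
#' @export
pn_preset <- function() {
  neuron_params(rest_mV = -68, R_in_MOhm = 120, C_pF = 200,
                spike_threshold_mV = -42, ap_peak_mV = 35,
                ap_halfwidth_ms = 1.5, ap_rise_ms = 1.1,
                ahp_amp_mV = 6, ahp_time_ms = 15,
                adaptation_strength = 5, subtype_label = "PN")
}

#' Cell metadata
#'
#' @param cell_id integer id.
#' @param fluor_label one of "EGFP", "mCherry", "EGFP+mCherry", "none".
#' @param position_um numeric 3-vector, micrometres.
#' @param layer cortical layer.
#' @param area cortical area (somatosensory or visual).
#' @param age_P postnatal day (>= 0).
#' @param clone_id optional clone id (NA when unknown).
#' @export
cell_meta <- function(cell_id, fluor_label = "EGFP",
                      position_um = c(0, 0, 0),
                      layer = c("L2_3", "L4", "L5", "L6"),
                      area = c("SCX", "VCX"), age_P = 16L, clone_id = NA) {
  layer <- match.arg(layer); area <- match.arg(area)
  fluor_label <- match.arg(fluor_label,
                           c("EGFP", "mCherry", "EGFP+mCherry", "none"))
  stopifnot(length(position_um) == 3, all(is.finite(position_um)), age_P >= 0)
  structure(list(cell_id = as.integer(cell_id), fluor_label = fluor_label,
                 position_um = as.numeric(position_um), layer = layer,
                 area = area, age_P = as.integer(age_P), clone_id = clone_id),
            class = "cell_meta")
}

# feature-side checks used by make_population jitter validation: parameters
# that map one-to-one onto classifier criteria
param_criteria_side <- function(p) {
  c(input_resistance = p$R_in_MOhm <= 300,
    ap_threshold = p$spike_threshold_mV >= -35,
    halfwidth = p$ap_halfwidth_ms <= 1.7,
    rise = p$ap_rise_ms <= 1.9,
    ahp_amp = p$ahp_amp_mV >= 8,
    ahp_time = p$ahp_time_ms <= 6.5)
}

#' Generate a mixed cell population
#'
#' Draws `n_FS` fast-spiking, `n_nonFS` non-fast-spiking interneurons and
#' `n_PN` pyramidal cells from the presets, with optional multiplicative
#' Gaussian jitter on the continuous parameters. Jitter must not move any
#' preset across the side of a classification threshold it was designed to
#' sit on; a draw that would is a validation error.
#'
#' @param n_FS,n_nonFS,n_PN non-negative counts.
#' @param jitter relative s.d. of multiplicative parameter jitter (e.g. 0.05).
#' @param seed integer seed.
#' @param extent_um spatial extent (x, y, z) within which somata are placed
#'   uniformly at random.
#' @return list of elements `list(params = neuron_params, meta = cell_meta)`.
#' @export
make_population <- function(n_FS, n_nonFS, n_PN = 0, jitter = 0, seed = 1,
                            extent_um = c(200, 200, 300)) {
  stopifnot(n_FS >= 0, n_nonFS >= 0, n_PN >= 0, jitter >= 0)
  presets <- c(replicate(n_FS, fs_preset(), simplify = FALSE),
               replicate(n_nonFS, nonfs_preset(), simplify = FALSE),
               replicate(n_PN, pn_preset(), simplify = FALSE))
  with_seed(seed, {
    out <- vector("list", length(presets))
    for (k in seq_along(presets)) {
      p <- presets[[k]]
      base_side <- param_criteria_side(p)
      if (jitter > 0) {
        jit <- function(x) x * (1 + rnorm(1, 0, jitter))
        p2 <- p
        p2$R_in_MOhm <- jit(p$R_in_MOhm)
        p2$C_pF <- jit(p$C_pF)
        p2$ap_halfwidth_ms <- jit(p$ap_halfwidth_ms)
        p2$ap_rise_ms <- jit(p$ap_rise_ms)
        p2$ahp_amp_mV <- jit(p$ahp_amp_mV)
        p2$ahp_time_ms <- jit(p$ahp_time_ms)
        p2$rest_mV <- p$rest_mV + rnorm(1, 0, jitter * 10)
        if (!identical(param_criteria_side(p2), base_side))
          stopf("jitter %.3g moved a %s parameter across a classification threshold",
                jitter, p$subtype_label)
        p <- p2
      }
      pos <- runif(3) * extent_um
      out[[k]] <- list(
        params = p,
        meta = cell_meta(k, position_um = pos,
                         layer = sample(c("L2_3", "L5"), 1),
                         fluor_label = if (p$subtype_label == "PN") "none" else "EGFP")
      )
    }
    out
  })
}
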