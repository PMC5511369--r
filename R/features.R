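#' FS classification thresholds
#'
#' The nine bounds used to classify an interneuron as fast-spiking: maximal
#' firing frequency at least 80 Hz, AHP amplitude at least 8 mV, AP threshold
#' at least -35 mV, input resistance at most 300 MOhm, adaptation ratio at
#' most 2.5, AP half-width at most 1.7 ms, AP rise at most 1.9 ms, decay at
#' most 7.5 ms and AHP time from peak at most 6.5 ms. Cells failing any
#' bound are non-FS.
#'
#' @param ... named overrides of individual bounds.
#' @export
subtype_criteria <- function(...) {
  crit <- list(max_firing_ge = 80, ahp_amp_ge = 8, ap_threshold_ge = -35,
               input_resistance_le = 300, adaptation_ratio_le = 2.5,
               halfwidth_le = 1.7, rise_le = 1.9, decay_le = 7.5,
               ahp_time_le = 6.5)
  ov <- list(...)
  bad <- setdiff(names(ov), names(crit))
  if (length(bad)) stopf("unknown criteria: %s", paste(bad, collapse = ", "))
  structure(modifyList(crit, ov), class = "subtype_criteria")
}

# linear interpolation of the time at which v crosses `level`
# between samples k and k+1
cross_time <- function(tt, v, level, rising = TRUE) {
  idx <- if (rising) which(v[-length(v)] < level & v[-1] >= level)
         else which(v[-length(v)] > level & v[-1] <= level)
  if (length(idx) == 0) return(NA_real_)
  k <- idx[1]
  tt[k] + (level - v[k]) / (v[k + 1] - v[k]) * (tt[k + 1] - tt[k])
}

detect_ap_onsets <- function(v, fs_Hz, dvdt_min = 20) {
  dt <- 1000 / fs_Hz
  dvdt <- c(0, diff(v)) / dt
  up <- which(dvdt >= dvdt_min)
  if (length(up) == 0) return(integer())
  # group contiguous runs; onset = first sample of each run, separated by
  # a 1 ms refractory guard
  keep <- up[c(TRUE, diff(up) > round(1 / dt))]
  keep
}

#' Extract membrane and firing features from a current-clamp sweep family
#'
#' Measures the nine-feature vector used for FS/non-FS subtyping:
#' resting membrane potential (pre-stimulus mean), input resistance
#' (steady-state deflection over current of the subthreshold step), AP
#' threshold (voltage at dV/dt >= 20 mV/ms), AP half-width (width at half
#' peak-to-threshold amplitude), AP rise (10-90% upstroke time), AP decay
#' (peak-to-threshold e-fold time of the downstroke), maximal firing
#' frequency (largest spike count within the 1 s depolarizing steps), AHP
#' amplitude (threshold minus post-spike minimum), AHP time from peak, and
#' the spike-frequency adaptation ratio (last interspike interval divided by
#' the first within the 1 s step).
#'
#' Waveform features are measured on the first AP of the maximal-firing
#' sweep; sub-sample precision comes from linear interpolation of level
#' crossings. When no suprathreshold sweep exists, firing-dependent fields
#' are returned as NA and flagged.
#'
#' @param fam a `sweep_family` from [characterize_cell()] (or an equivalent
#'   list of current-clamp sweeps with known steps).
#' @return An object of class `membrane_features` (named list).
#' @export
extract_features <- function(fam) {
  stopifnot(inherits(fam, "sweep_family"))
  fs <- fam$sampling_rate_Hz
  dt <- 1000 / fs

  sw_sub <- Filter(function(s) s$I_pA < 0, fam$sweeps)
  sw_dep <- Filter(function(s) s$I_pA > 0 && s$duration_ms >= 1000, fam$sweeps)
  if (length(sw_sub) == 0)
    stopf("sweep family lacks a subthreshold hyperpolarizing step")

  rmp <- mean(vapply(fam$sweeps, function(s)
    mean(s$voltage_mV[seq_len(round((s$onset_ms - 10) / dt))]), 0))

  s0 <- sw_sub[[1]]
  i_on <- round(s0$onset_ms / dt); i_off <- round((s0$onset_ms + s0$duration_ms) / dt)
  base <- mean(s0$voltage_mV[seq_len(i_on - round(10 / dt))])
  ss <- mean(s0$voltage_mV[(i_off - round(100 / dt)):i_off])
  rin <- (ss - base) / s0$I_pA * 1000   # mV / pA -> MOhm

  feat <- list(rmp_mV = rmp, input_resistance_MOhm = rin,
               ap_threshold_mV = NA_real_, ap_halfwidth_ms = NA_real_,
               ap_rise_ms = NA_real_, ap_decay_ms = NA_real_,
               max_firing_Hz = NA_real_, ahp_amp_mV = NA_real_,
               ahp_time_ms = NA_real_, adaptation_ratio = NA_real_,
               firing_defined = FALSE)

  if (length(sw_dep)) {
    counts <- vapply(sw_dep, function(s) {
      on <- detect_ap_onsets(s$voltage_mV, fs)
      i_on <- round(s$onset_ms / dt)
      i_off <- round((s$onset_ms + 1000) / dt)
      sum(on >= i_on & on <= i_off)
    }, 0L)
    best <- sw_dep[[which.max(counts)]]
    feat$max_firing_Hz <- max(counts)   # spikes within the 1 s step
    v <- best$voltage_mV
    tt <- (seq_along(v) - 1) * dt
    onsets <- detect_ap_onsets(v, fs)
    if (length(onsets) >= 1) {
      o1 <- max(onsets[1] - 1, 1)   # last sample before the upstroke
      thr <- v[o1]
      seg_end <- if (length(onsets) > 1) onsets[2] - 2 else
        min(o1 + round(25 / dt), length(v))
      seg <- o1:seg_end
      vpk <- max(v[seg]); ipk <- seg[which.max(v[seg])]
      half <- thr + (vpk - thr) / 2
      t_up <- cross_time(tt[o1:ipk], v[o1:ipk], half, rising = TRUE)
      t_dn <- cross_time(tt[ipk:seg_end], v[ipk:seg_end], half, rising = FALSE)
      t10 <- cross_time(tt[o1:ipk], v[o1:ipk], thr + 0.1 * (vpk - thr))
      t90 <- cross_time(tt[o1:ipk], v[o1:ipk], thr + 0.9 * (vpk - thr))
      efold <- cross_time(tt[ipk:seg_end], v[ipk:seg_end],
                          thr + (vpk - thr) / exp(1), rising = FALSE)
      imin <- seg[which.min(v[seg])]
      feat$ap_threshold_mV <- thr
      feat$ap_halfwidth_ms <- t_dn - t_up
      feat$ap_rise_ms <- t90 - t10
      feat$ap_decay_ms <- efold - tt[ipk]
      feat$ahp_amp_mV <- thr - v[imin]
      feat$ahp_time_ms <- tt[imin] - tt[ipk]
      feat$firing_defined <- TRUE
    }
    # adaptation ratio over APs inside the 1 s window of the best sweep
    i_on <- round(best$onset_ms / dt); i_off <- round((best$onset_ms + 1000) / dt)
    on1s <- onsets[onsets >= i_on & onsets <= i_off]
    if (length(on1s) >= 3) {
      isi <- diff(tt[on1s])
      feat$adaptation_ratio <- isi[length(isi)] / isi[1]
    }
  }
  structure(feat, class = "membrane_features")
}

#' Classify an interneuron as FS or non-FS
#'
#' Strict conjunction of the nine threshold criteria: a cell is FS iff every
#' bound in [subtype_criteria()] is met (boundaries inclusive); otherwise it
#' is non-FS.
#'
#' @param features a `membrane_features` object.
#' @param criteria a [subtype_criteria()].
#' @return "FS" or "nonFS".
#' @export
classify_subtype <- function(features, criteria = subtype_criteria()) {
  need <- c("max_firing_Hz", "ahp_amp_mV", "ap_threshold_mV",
            "input_resistance_MOhm", "adaptation_ratio", "ap_halfwidth_ms",
            "ap_rise_ms", "ap_decay_ms", "ahp_time_ms")
  miss <- need[vapply(need, function(f) is.na(features[[f]]), TRUE)]
  if (length(miss))
    stopf("cannot classify: undefined features: %s",
          paste(miss, collapse = ", "))
  ok <- features$max_firing_Hz >= criteria$max_firing_ge &&
    features$ahp_amp_mV >= criteria$ahp_amp_ge &&
    features$ap_threshold_mV >= criteria$ap_threshold_ge &&
    features$input_resistance_MOhm <= criteria$input_resistance_le &&
    features$adaptation_ratio <= criteria$adaptation_ratio_le &&
    features$ap_halfwidth_ms <= criteria$halfwidth_le &&
    features$ap_rise_ms <= criteria$rise_le &&
    features$ap_decay_ms <= criteria$decay_le &&
    features$ahp_time_ms <= criteria$ahp_time_le
  if (ok) "FS" else "nonFS"
}

#' Feature table for a population
#'
#' Runs [characterize_cell()], [extract_features()] and [classify_subtype()]
#' on each cell of a [make_population()] list and returns one row per cell
#' (the nine features + cell_id + subtype_call).
#'
#' @param population list from [make_population()].
#' @param noise_sd_mV observation noise for the characterization sweeps.
#' @param seed integer seed.
#' @export
features_table <- function(population, noise_sd_mV = 0, seed = 1,
                           criteria = subtype_criteria()) {
  rows <- lapply(seq_along(population), function(k) {
    fam <- characterize_cell(population[[k]]$params,
                             noise_sd_mV = noise_sd_mV, seed = seed + k)
    ft <- extract_features(fam)
    call <- tryCatch(classify_subtype(ft, criteria),
                     error = function(e) NA_character_)
    data.frame(cell_id = population[[k]]$meta$cell_id,
               rmp_mV = ft$rmp_mV,
               input_resistance_MOhm = ft$input_resistance_MOhm,
               ap_threshold_mV = ft$ap_threshold_mV,
               ap_halfwidth_ms = ft$ap_halfwidth_ms,
               ap_rise_ms = ft$ap_rise_ms, ap_decay_ms = ft$ap_decay_ms,
               max_firing_Hz = ft$max_firing_Hz, ahp_amp_mV = ft$ahp_amp_mV,
               ahp_time_ms = ft$ahp_time_ms,
               adaptation_ratio = ft$adaptation_ratio,
               subtype_call = call)
  })
  do.call(rbind, rows)
}
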