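#' Connection-detection criteria
#'
#' Amplitude and window criteria for calling connections from paired
#' recordings: electrical coupling when the trial-averaged hyperpolarized
#' deflection in the receiver exceeds 0.1 mV (and matches the driver's
#' sign); a chemical connection when the AP-triggered average postsynaptic
#' current exceeds 0.5 pA within 1-5 ms after the presynaptic AP peak.
#'
#' @param electrical_min_mV receiver deflection threshold (default 0.1).
#' @param chemical_min_pA PSC amplitude threshold (default 0.5).
#' @param chemical_window_ms post-AP-peak search window (default (1, 5]).
#' @param min_trials_per_mode minimum trials per detection mode (default 10).
#' @param psc_measure "peak" (extremum of the baseline-subtracted average in
#'   the window) or "mean" (window mean).
#' @export
detection_criteria <- function(electrical_min_mV = 0.1, chemical_min_pA = 0.5,
                               chemical_window_ms = c(1, 5),
                               min_trials_per_mode = 10,
                               psc_measure = c("peak", "mean")) {
  psc_measure <- match.arg(psc_measure)
  stopifnot(electrical_min_mV > 0, chemical_min_pA > 0,
            chemical_window_ms[1] < chemical_window_ms[2])
  structure(list(electrical_min_mV = electrical_min_mV,
                 chemical_min_pA = chemical_min_pA,
                 chemical_window_ms = chemical_window_ms,
                 min_trials_per_mode = as.integer(min_trials_per_mode),
                 psc_measure = psc_measure),
            class = "detection_criteria")
}

session_trials <- function(session, driver, mode_of_receiver, receiver) {
  Filter(function(tr) tr$driver == driver &&
           tr$clamp_mode[receiver] == mode_of_receiver, session$trials)
}

# window means around the hyperpolarizing epoch: 50 ms pre-pulse baseline,
# steady state over the last 100 ms of the 200 ms pulse
hyper_windows <- function(session) {
  h <- hyper_pulse(session$protocol)
  fs <- session$sampling_rate_Hz / 1000   # samples per ms
  list(base = seq(round((h$onset_ms - 50) * fs) + 1, round(h$onset_ms * fs)),
       ss = seq(round((h$onset_ms + h$duration_ms - 100) * fs) + 1,
                round((h$onset_ms + h$duration_ms) * fs)))
}

#' Detect electrical coupling between a driver and a receiver
#'
#' Averages the receiver's current-clamp trace over trials in which the
#' driver received the hyperpolarizing step, measures the deflection
#' (steady-state mean over the last 100 ms of the pulse minus a 50 ms
#' pre-pulse baseline) and calls the pair coupled when the deflection
#' exceeds the 0.1 mV criterion with the driver's (hyperpolarizing) sign.
#' The coupling coefficient is the receiver deflection over the driver
#' deflection from the same epochs.
#'
#' @param session a [simulate_session()] (or [read_session()]) object.
#' @param driver,receiver cell indices.
#' @param criteria a [detection_criteria()].
#' @return list(coupled, receiver_deflection_mV, coupling_coefficient,
#'   n_trials_used).
#' @export
detect_electrical <- function(session, driver, receiver,
                              criteria = detection_criteria()) {
  trs <- Filter(function(tr) all(tr$clamp_mode == "cc"),
                session_trials(session, driver, "cc", receiver))
  if (length(trs) < criteria$min_trials_per_mode)
    stopf("insufficient data: %d current-clamp trials with driver %d (need %d)",
          length(trs), driver, criteria$min_trials_per_mode)
  w <- hyper_windows(session)
  avg_r <- rowMeans(vapply(trs, function(tr) tr$traces[, receiver],
                           numeric(nrow(trs[[1]]$traces))))
  avg_d <- rowMeans(vapply(trs, function(tr) tr$traces[, driver],
                           numeric(nrow(trs[[1]]$traces))))
  defl_r <- mean(avg_r[w$ss]) - mean(avg_r[w$base])
  defl_d <- mean(avg_d[w$ss]) - mean(avg_d[w$base])
  if (defl_d >= 0)
    stopf("protocol error: driver %d shows no hyperpolarized deflection", driver)
  coupled <- defl_r < 0 && abs(defl_r) > criteria$electrical_min_mV
  list(coupled = coupled, receiver_deflection_mV = defl_r,
       coupling_coefficient = defl_r / defl_d, n_trials_used = length(trs))
}

# AP peaks of the driver located from its own voltage trace: the maximum
# within each brief suprathreshold pulse epoch (+10 ms tail)
driver_ap_peaks <- function(session, trace_driver) {
  bp <- brief_pulses(session$protocol)
  fs <- session$sampling_rate_Hz / 1000
  vapply(seq_len(nrow(bp)), function(k) {
    i0 <- round(bp$onset_ms[k] * fs) + 1
    i1 <- round((bp$onset_ms[k] + bp$duration_ms[k] + 10) * fs)
    seg <- trace_driver[i0:i1]
    (i0 - 1 + which.max(seg) - 1) / fs   # peak time, ms
  }, 0)
}

psc_from_trials <- function(session, trs, pre, post, criteria) {
  fs <- session$sampling_rate_Hz / 1000
  win <- criteria$chemical_window_ms
  lag_idx <- seq(round(-5 * fs), round(5 * fs))
  segs <- list(); pre_segs <- list()
  for (tr in trs) {
    peaks <- driver_ap_peaks(session, tr$traces[, pre])
    if (length(peaks) == 0)
      stopf("protocol error: no presynaptic AP detected for driver %d", pre)
    for (pk in peaks) {
      ipk <- round(pk * fs) + 1
      idx <- ipk + lag_idx
      if (min(idx) >= 1 && max(idx) <= nrow(tr$traces)) {
        segs[[length(segs) + 1]] <- tr$traces[idx, post]
        pre_segs[[length(pre_segs) + 1]] <- tr$traces[idx, pre]
      }
    }
  }
  avg <- rowMeans(do.call(cbind, segs))
  lags <- lag_idx / fs

  # gap-junction spikelet correction: the hyperpolarizing epoch of these
  # same voltage-clamp trials measures the gap conductance directly
  # (receiver clamped, so its current deflection is -g * driver deflection);
  # the predicted spikelet current -g * dV_pre(t) around the AP is then
  # subtracted before applying the amplitude criterion
  w <- hyper_windows(session)
  dI <- mean(vapply(trs, function(tr)
    mean(tr$traces[w$ss, post]) - mean(tr$traces[w$base, post]), 0))
  dV <- mean(vapply(trs, function(tr)
    mean(tr$traces[w$ss, pre]) - mean(tr$traces[w$base, pre]), 0))
  if (abs(dI) > 0.3 && dV < 0) {
    g_hat <- -dI / dV
    avg_pre <- rowMeans(do.call(cbind, pre_segs))
    dv_pre <- avg_pre - mean(avg_pre[lags > -5 & lags <= 0])
    avg <- avg + g_hat * dv_pre
  }
  base <- mean(avg[lags > -5 & lags <= 0])
  inwin <- which(lags > win[1] & lags <= win[2])
  y <- avg[inwin] - base
  if (criteria$psc_measure == "mean") {
    amp <- mean(y); peak_lag <- mean(lags[inwin]); lat <- peak_lag
  } else {
    k <- which.max(abs(y)); amp <- y[k]; peak_lag <- lags[inwin][k]
    # latency = PSC onset: first sustained crossing of 10% of the extremum
    # after the AP peak (linear interpolation between samples)
    post <- which(lags > 0 & lags <= peak_lag)
    yy <- (avg[post] - base) * sign(amp)
    lvl <- 0.1 * abs(amp)
    ci <- which(yy[-length(yy)] < lvl & yy[-1] >= lvl)
    lat <- if (length(ci)) {
      k0 <- ci[length(ci)]   # last upward crossing before the peak
      lags[post][k0] + (lvl - yy[k0]) / (yy[k0 + 1] - yy[k0]) / fs
    } else peak_lag
  }
  list(amp = amp, latency = lat, peak_lag = peak_lag, n = length(trs),
       avg = avg - base, lags = lags)
}

#' Detect a chemical connection from pre onto post
#'
#' Uses trials in which `pre` is the current-injected driver and `post` is
#' voltage clamped. Builds the AP-peak-triggered average of the postsynaptic
#' current, subtracts the (-5, 0] ms pre-peak baseline and measures the
#' extremum within the 1-5 ms window; connected when its magnitude exceeds
#' the 0.5 pA criterion.
#'
#' For gap-coupled pairs the presynaptic AP leaks a spikelet current into
#' the clamped receiver that can exceed the criterion. Because the receiver
#' is clamped, the hyperpolarizing epoch of these same trials yields the
#' gap conductance directly (receiver current deflection = -g times driver
#' voltage deflection), and the predicted spikelet current is subtracted
#' from the triggered average before the criterion is applied.
#'
#' @param holding_mV which holding potential's trials to use (default -70,
#'   the convention when both holdings were recorded).
#' @inheritParams detect_electrical
#' @return list(connected, psc_amp_pA, latency_ms, n_trials_used).
#' @export
detect_chemical <- function(session, pre, post,
                            criteria = detection_criteria(),
                            holding_mV = -70) {
  trs <- Filter(function(tr) isTRUE(abs(tr$holding_mV[post] - holding_mV) < 1e-9),
                session_trials(session, pre, "vc", post))
  if (length(trs) < ceiling(criteria$min_trials_per_mode / 2))
    stopf("insufficient data: %d voltage-clamp trials at %g mV for pair %d->%d",
          length(trs), holding_mV, pre, post)
  r <- psc_from_trials(session, trs, pre, post, criteria)
  list(connected = abs(r$amp) > criteria$chemical_min_pA,
       psc_amp_pA = r$amp, latency_ms = r$latency,
       peak_lag_ms = r$peak_lag, n_trials_used = r$n,
       avg_pA = r$avg, lags_ms = r$lags)
}

#' Classify one cell pair (electrical + chemical, both directions)
#'
#' Runs [detect_electrical()] in both probing directions (electrical
#' coupling is undirected: the pair is coupled if either direction passes)
#' and [detect_chemical()] in both directions. Chemical detection subtracts
#' the predicted gap-junction spikelet current (see [detect_chemical()]),
#' so electrically coupled pairs are not mistaken for chemically connected
#' ones.
#'
#' @inheritParams detect_electrical
#' @param i,j cell indices of the unordered pair.
#' @return An object of class `connection_result`.
#' @export
classify_pair <- function(session, i, j, criteria = detection_criteria()) {
  e_ij <- detect_electrical(session, i, j, criteria)
  e_ji <- detect_electrical(session, j, i, criteria)
  coupled <- e_ij$coupled || e_ji$coupled
  c_ij <- detect_chemical(session, i, j, criteria)
  c_ji <- detect_chemical(session, j, i, criteria)
  directionality <- if (c_ij$connected && c_ji$connected) "bi"
                    else if (c_ij$connected || c_ji$connected) "uni"
                    else "none"
  structure(list(pair = c(i, j),
                 electrical = list(
                   coupled = coupled,
                   receiver_deflection_mV = e_ij$receiver_deflection_mV,
                   coupling_coefficient = e_ij$coupling_coefficient,
                   coupling_coefficient_rev = e_ji$coupling_coefficient),
                 chemical = list(ij = c_ij, ji = c_ji),
                 directionality = directionality,
                 n_trials_used = e_ij$n_trials_used + e_ji$n_trials_used +
                   c_ij$n_trials_used + c_ji$n_trials_used),
            class = "connection_result")
}

#' Connection calls for every unordered pair in a session
#'
#' @inheritParams detect_electrical
#' @return list of `connection_result`, ordered by (i, j).
#' @export
connection_matrix <- function(session, criteria = detection_criteria()) {
  n <- nrow(session$cells)
  out <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    out[[length(out) + 1]] <- classify_pair(session, i, j, criteria)
  out
}

#' Flat connections table
#'
#' One row per ordered direction per pair, CSV-ready.
#' @param results list from [connection_matrix()].
#' @export
connections_table <- function(results) {
  rows <- lapply(results, function(r) {
    data.frame(pre = c(r$pair[1], r$pair[2]), post = c(r$pair[2], r$pair[1]),
               electrical_coupled = r$electrical$coupled,
               deflection_mV = r$electrical$receiver_deflection_mV,
               coupling_coefficient = c(r$electrical$coupling_coefficient,
                                        r$electrical$coupling_coefficient_rev),
               chemical_connected = c(r$chemical$ij$connected,
                                      r$chemical$ji$connected),
               psc_amp_pA = c(r$chemical$ij$psc_amp_pA,
                              r$chemical$ji$psc_amp_pA),
               latency_ms = c(r$chemical$ij$latency_ms,
                              r$chemical$ji$latency_ms),
               n_trials = r$n_trials_used)
  })
  do.call(rbind, rows)
}
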