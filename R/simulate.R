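#' Simulate a paired/quadruple recording session
#'
#' Forward model of an acute-slice multi-cell patch-clamp session. Each cell
#' is a leaky single compartment; gap junctions pass ohmic current
#' g (V_other - V_self); a chemical synapse launches a difference-of-
#' exponentials conductance transient at its stated latency after the
#' presynaptic AP peak; action potentials are stamped parametric waveforms.
#' For every probed driver the session contains `n_trials_electrical` trials
#' with all cells in current clamp (electrical-coupling probing via the
#' hyperpolarizing step) and `n_trials_chemical` trials with all non-driver
#' cells in voltage clamp (chemical probing), holdings alternating between
#' -70 and -20 mV.
#'
#' Recording noise is white Gaussian observation noise added to the stored
#' traces (sd `noise_sd_mV` on voltages, `noise_sd_pA` on currents), with an
#' optional slow sinusoidal drift. `process_noise_sd_pA` adds white current
#' noise inside the integration (units pA sqrt(ms)), used to jitter spike
#' times in synchrony experiments.
#'
#' @param circuit a [circuit_spec()].
#' @param protocol a [build_protocol()] protocol.
#' @param noise_sd_mV,noise_sd_pA observation noise s.d. (defaults 0.05 mV,
#'   0.5 pA).
#' @param seed integer seed; identical seeds give bit-identical sessions.
#' @param drivers cells to probe (default all).
#' @param holdings_mV voltage-clamp holding potentials cycled across chemical
#'   trials.
#' @param process_noise_sd_pA integration current noise (default 0).
#' @param drift_amp_mV,drift_period_ms optional slow sinusoidal drift added
#'   to voltage traces (amplitude default 0).
#' @param sampling_rate_Hz sampling rate (default 10 kHz; integration runs at
#'   two substeps per sample).
#' @return An object of class `recording_session`.
#' @export
simulate_session <- function(circuit, protocol, noise_sd_mV = 0.05,
                             noise_sd_pA = 0.5, seed,
                             drivers = seq_along(circuit$cells),
                             holdings_mV = c(-70, -20),
                             process_noise_sd_pA = 0,
                             drift_amp_mV = 0, drift_period_ms = 2000,
                             sampling_rate_Hz = 10000) {
  stopifnot(inherits(circuit, "circuit_spec"))
  validate_protocol(protocol)
  if (noise_sd_mV < 0 || noise_sd_pA < 0) stopf("noise sd must be >= 0")
  if (missing(seed)) stopf("a seed is required")
  n <- length(circuit$cells)
  pm <- params_matrix(circuit)
  gaps <- as.matrix(circuit$gap_junctions)
  if (nrow(gaps) == 0) gaps <- matrix(0, 0, 3)
  syn_cols <- c("pre", "post", "g_nS", "latency_ms", "rise_ms", "decay_ms",
                "reversal_mV")
  syns <- if (nrow(circuit$chem_synapses))
    as.matrix(circuit$chem_synapses[, syn_cols]) else matrix(0, 0, 7)

  dt <- 1000 / sampling_rate_Hz / 2   # two substeps per recorded sample
  n_samples <- round(protocol$trial_length_ms * sampling_rate_Hz / 1000)
  tvec <- (seq_len(n_samples) - 1) / sampling_rate_Hz * 1000

  with_seed(seed, {
    trials <- list()
    for (d in drivers) {
      pulses <- cbind(d, protocol$pulses$onset_ms, protocol$pulses$duration_ms,
                      protocol$pulses$amplitude_pA)
      # electrical probing: everyone in current clamp
      for (k in seq_len(protocol$n_trials_electrical)) {
        trials[[length(trials) + 1]] <-
          run_trial(pm, gaps, syns, pulses, rep(0L, n), rep(NA_real_, n),
                    protocol$trial_length_ms, dt, d, noise_sd_mV, noise_sd_pA,
                    process_noise_sd_pA, drift_amp_mV, drift_period_ms, tvec)
      }
      # chemical probing: non-drivers voltage clamped
      for (k in seq_len(protocol$n_trials_chemical)) {
        hold <- holdings_mV[(k - 1) %% length(holdings_mV) + 1]
        mode <- ifelse(seq_len(n) == d, 0L, 1L)
        holding <- ifelse(mode == 1L, hold, NA_real_)
        trials[[length(trials) + 1]] <-
          run_trial(pm, gaps, syns, pulses, mode, holding,
                    protocol$trial_length_ms, dt, d, noise_sd_mV, noise_sd_pA,
                    process_noise_sd_pA, drift_amp_mV, drift_period_ms, tvec)
      }
    }
    structure(list(sampling_rate_Hz = sampling_rate_Hz, protocol = protocol,
                   cells = cells_meta_df(circuit), trials = trials,
                   seed = as.integer(seed)),
              class = "recording_session")
  })
}

run_trial <- function(pm, gaps, syns, pulses, mode, holding, trial_len, dt,
                      driver, noise_sd_mV, noise_sd_pA, process_noise,
                      drift_amp, drift_period, tvec) {
  res <- sim_trial_cpp(pm, gaps, syns, pulses, mode, holding, trial_len, dt,
                       2L, process_noise, 0, 20, 200)
  tr <- res$traces
  for (i in seq_along(mode)) {
    if (mode[i] == 0L) {
      if (noise_sd_mV > 0) tr[, i] <- tr[, i] + rnorm(nrow(tr), 0, noise_sd_mV)
      if (drift_amp > 0)
        tr[, i] <- tr[, i] +
          drift_amp * sin(2 * pi * tvec / drift_period + runif(1, 0, 2 * pi))
    } else if (noise_sd_pA > 0) {
      tr[, i] <- tr[, i] + rnorm(nrow(tr), 0, noise_sd_pA)
    }
  }
  colnames(tr) <- as.character(seq_along(mode))
  list(driver = driver,
       clamp_mode = ifelse(mode == 1L, "vc", "cc"),
       holding_mV = holding, traces = tr, spikes = res$spikes)
}

#' Simulate sustained co-driven firing of a cell pair
#'
#' Drives both cells of a (possibly gap-coupled) pair with independent 1 s
#' suprathreshold steps over repeated trials, with integration current noise
#' to jitter spike times, and returns the pooled spike trains (trials
#' concatenated end-to-end with a silent gap). This is the induced-firing
#' experiment behind spike-synchrony cross-correlograms.
#'
#' @param circuit two-cell [circuit_spec()].
#' @param I_pA length-2 drive amplitudes.
#' @param duration_ms step duration per trial.
#' @param n_trials number of trials pooled.
#' @param process_noise_sd_pA independent integration current noise per cell
#'   (pA sqrt(ms)); jitters spike timing.
#' @param common_noise_sd_pA stationary s.d. of an Ornstein-Uhlenbeck
#'   current shared by both cells, emulating slow common network drive;
#'   produces broad (tens of ms) rate co-modulation without
#'   sub-millisecond synchrony.
#' @param common_noise_tau_ms correlation time of the shared drive.
#' @param seed integer seed.
#' @return list with `train1`, `train2` ([spike_train()] objects).
#' @export
simulate_paired_drive <- function(circuit, I_pA, duration_ms = 1000,
                                  n_trials = 30, process_noise_sd_pA = 60,
                                  common_noise_sd_pA = 0,
                                  common_noise_tau_ms = 20, seed) {
  stopifnot(length(circuit$cells) == 2, length(I_pA) == 2)
  if (missing(seed)) stopf("a seed is required")
  pm <- params_matrix(circuit)
  gaps <- as.matrix(circuit$gap_junctions)
  if (nrow(gaps) == 0) gaps <- matrix(0, 0, 3)
  syns <- matrix(0, 0, 7)
  trial_len <- duration_ms + 200
  pulses <- rbind(c(1, 100, duration_ms, I_pA[1]),
                  c(2, 100, duration_ms, I_pA[2]))
  dt <- 0.05
  with_seed(seed, {
    t1 <- numeric(); t2 <- numeric()
    for (k in seq_len(n_trials)) {
      res <- sim_trial_cpp(pm, gaps, syns, pulses, c(0L, 0L),
                           c(NA_real_, NA_real_), trial_len, dt, 2L,
                           process_noise_sd_pA, common_noise_sd_pA,
                           common_noise_tau_ms, 200)
      off <- (k - 1) * trial_len
      t1 <- c(t1, res$spikes[[1]] + off)
      t2 <- c(t2, res$spikes[[2]] + off)
    }
    T_ms <- n_trials * trial_len
    list(train1 = spike_train(t1, T_ms), train2 = spike_train(t2, T_ms))
  })
}

#' Simulate a membrane-characterization sweep family for one cell
#'
#' Runs the [characterization_protocol()] steps on a single isolated cell and
#' returns the current-clamp sweeps needed by [extract_features()].
#'
#' @param params a [neuron_params()] object.
#' @param protocol a [characterization_protocol()].
#' @param noise_sd_mV observation noise s.d.
#' @param seed integer seed.
#' @return An object of class `sweep_family`.
#' @export
characterize_cell <- function(params, protocol = characterization_protocol(),
                              noise_sd_mV = 0, seed = 1,
                              sampling_rate_Hz = 10000) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "charac_protocol"))
  circuit <- circuit_spec(list(list(params = params, meta = cell_meta(1L))))
  pm <- params_matrix(circuit)
  dt <- 1000 / sampling_rate_Hz / 2
  with_seed(seed, {
    sweeps <- lapply(seq_len(nrow(protocol$steps)), function(k) {
      st <- protocol$steps[k, ]
      pulses <- cbind(1, st$onset_ms, st$duration_ms, st$amplitude_pA)
      res <- sim_trial_cpp(pm, matrix(0, 0, 3), matrix(0, 0, 7), pulses,
                           0L, NA_real_, st$trial_length_ms, dt, 2L, 0, 0, 20, 200)
      v <- res$traces[, 1]
      if (noise_sd_mV > 0) v <- v + rnorm(length(v), 0, noise_sd_mV)
      list(I_pA = st$amplitude_pA, onset_ms = st$onset_ms,
           duration_ms = st$duration_ms, voltage_mV = v)
    })
    structure(list(sampling_rate_Hz = sampling_rate_Hz, sweeps = sweeps),
              class = "sweep_family")
  })
}
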