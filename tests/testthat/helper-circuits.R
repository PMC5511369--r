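# shared fixtures, all generated in code

std_protocol <- function(...) build_protocol(800, 400, 200, ...)

# noiseless session for a given circuit, probing the given drivers
quiet_session <- function(circuit, seed = 1, drivers = seq_along(circuit$cells)) {
  simulate_session(circuit, std_protocol(), noise_sd_mV = 0, noise_sd_pA = 0,
                   seed = seed, drivers = drivers)
}

# ground-truth adjacency of a circuit_spec as logical matrices
truth_matrices <- function(cir) {
  n <- length(cir$cells)
  e <- matrix(FALSE, n, n); ch <- matrix(FALSE, n, n)
  gj <- cir$gap_junctions
  for (k in seq_len(nrow(gj))) e[gj$i[k], gj$j[k]] <- TRUE
  cs <- cir$chem_synapses
  for (k in seq_len(nrow(cs))) ch[cs$pre[k], cs$post[k]] <- TRUE
  list(electrical = e, chemical = ch)
}

# does the detected table match ground truth exactly?
graph_matches <- function(tab, cir) {
  gt <- truth_matrices(cir)
  for (r in seq_len(nrow(tab))) {
    i <- tab$pre[r]; j <- tab$post[r]
    if (tab$electrical_coupled[r] != gt$electrical[min(i, j), max(i, j)])
      return(FALSE)
    if (tab$chemical_connected[r] != gt$chemical[i, j]) return(FALSE)
  }
  TRUE
}

# hand-built sweep family with exactly regular APs and a clean subthreshold
# step: rest -65 mV, R = 200 MOhm, spikes every 10 ms
synthetic_sweep_family <- function(fs = 10000, n_spikes = 10, isi_ms = 10) {
  dt <- 1000 / fs
  rest <- -65
  ap_shape <- c(-35, -5, 25, -5, -35, -47, -45.5)  # onset->peak->AHP
  sub <- rep(rest, 1000 / dt)
  i0 <- 200 / dt; i1 <- 700 / dt
  sub[(i0 + 1):i1] <- rest - 10          # -50 pA -> -10 mV => 200 MOhm
  dep <- rep(rest, 1500 / dt)
  for (k in seq_len(n_spikes)) {
    at <- (250 + (k - 1) * isi_ms) / dt
    dep[at + seq_along(ap_shape)] <- ap_shape
  }
  structure(list(sampling_rate_Hz = fs, sweeps = list(
    list(I_pA = -50, onset_ms = 200, duration_ms = 500, voltage_mV = sub),
    list(I_pA = 300, onset_ms = 200, duration_ms = 1000, voltage_mV = dep))),
    class = "sweep_family")
}

# feature vector that satisfies every FS criterion
fs_features <- function(...) {
  f <- list(rmp_mV = -65, input_resistance_MOhm = 150,
            ap_threshold_mV = -32, ap_halfwidth_ms = 0.5, ap_rise_ms = 0.8,
            ap_decay_ms = 4, max_firing_Hz = 150, ahp_amp_mV = 12,
            ahp_time_ms = 3, adaptation_ratio = 1.5, firing_defined = TRUE)
  structure(modifyList(f, list(...)), class = "membrane_features")
}
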