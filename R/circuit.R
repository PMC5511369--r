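#' Ground-truth circuit specification
#'
#' Holds the cells plus the generating connectivity: undirected gap junctions
#' (stored with i < j) and directed chemical synapses with conductance
#' transients and an axonal/synaptic latency below 5 ms (chemical connections
#' are operationally defined by a < 5 ms post-spike delay).
#'
#' @param cells list as returned by [make_population()].
#' @param gap_junctions data frame (i, j, g_nS) or NULL.
#' @param chem_synapses data frame
#'   (pre, post, g_nS, latency_ms, rise_ms, decay_ms, reversal_mV) or NULL;
#'   missing kinetic columns get defaults (rise 0.5 ms, decay 8 ms,
#'   reversal -40 mV).
#' @return An object of class `circuit_spec`.
#' @export
circuit_spec <- function(cells, gap_junctions = NULL, chem_synapses = NULL) {
  n <- length(cells)
  stopifnot(n >= 1)
  if (is.null(gap_junctions))
    gap_junctions <- data.frame(i = integer(), j = integer(), g_nS = numeric())
  if (is.null(chem_synapses))
    chem_synapses <- data.frame(pre = integer(), post = integer(),
                                g_nS = numeric(), latency_ms = numeric())
  gj <- gap_junctions
  if (nrow(gj)) {
    if (any(gj$i == gj$j)) stopf("gap junction on a single cell")
    if (any(gj$g_nS < 0)) stopf("gap conductance must be >= 0")
    swap <- gj$i > gj$j
    tmp <- gj$i[swap]; gj$i[swap] <- gj$j[swap]; gj$j[swap] <- tmp
    if (any(gj$i < 1 | gj$j > n)) stopf("gap junction cell index out of range")
  }
  cs <- chem_synapses
  if (nrow(cs)) {
    if (is.null(cs$rise_ms)) cs$rise_ms <- 0.5
    if (is.null(cs$decay_ms)) cs$decay_ms <- 8
    if (is.null(cs$reversal_mV)) cs$reversal_mV <- -40
    if (any(cs$pre == cs$post)) stopf("chemical self-connection")
    if (any(cs$latency_ms < 0.8 | cs$latency_ms >= 5))
      stopf("chemical latency must lie in [0.8, 5) ms")
    if (any(cs$g_nS < 0)) stopf("synaptic conductance must be >= 0")
    if (any(cs$decay_ms <= cs$rise_ms)) stopf("synaptic decay must exceed rise")
    if (any(cs$pre < 1 | cs$post > n)) stopf("synapse cell index out of range")
  }
  structure(list(cells = cells, gap_junctions = gj, chem_synapses = cs),
            class = "circuit_spec")
}

#' Two-cell gap-junction test circuit
#'
#' A passive pair coupled by a single gap junction; handy because the
#' steady-state coupling coefficient has the closed form g / (g + G2) with
#' G2 the receiver leak conductance.
#'
#' @param g_nS gap conductance.
#' @param R1_MOhm,R2_MOhm input resistances of driver and receiver.
#' @export
two_cell_gap_circuit <- function(g_nS, R1_MOhm = 150, R2_MOhm = 150) {
  mk <- function(id, R) list(
    params = neuron_params(rest_mV = -65, R_in_MOhm = R, C_pF = 100,
                           spike_threshold_mV = 40, ap_peak_mV = 45,
                           ap_halfwidth_ms = 0.5, ap_rise_ms = 0.6,
                           ahp_amp_mV = 10, ahp_time_ms = 3,
                           adaptation_strength = 0, subtype_label = "FS"),
    meta = cell_meta(id))
  # threshold far above rest so the pair stays passive
  gj <- if (g_nS > 0) data.frame(i = 1L, j = 2L, g_nS = g_nS) else NULL
  circuit_spec(list(mk(1L, R1_MOhm), mk(2L, R2_MOhm)), gap_junctions = gj)
}

#' Random ground-truth quadruple circuit
#'
#' Draws a 4-cell interneuron circuit with random gap junctions and chemical
#' synapses for detection-fidelity experiments. Gap conductances are drawn
#' so that direct coupling coefficients sit in 0.012-0.025: direct
#' deflections then clear the 0.1 mV detection criterion with margin (worst
#' case ~0.36 mV) while second-order deflections stay below it even when two
#' two-hop paths coincide (worst case ~0.09 mV), keeping the detectable
#' graph equal to the generating graph. Chemical conductances give PSCs of
#' ~9-15 pA, far above the 0.5 pA criterion.
#'
#' @param seed integer seed.
#' @param p_gap probability of a gap junction per unordered pair.
#' @param p_chem probability of a chemical synapse per ordered pair.
#' @param n_FS,n_nonFS cell counts (total 4 by default).
#' @export
random_quad_circuit <- function(seed, p_gap = 0.3, p_chem = 0.25,
                                n_FS = 2, n_nonFS = 2) {
  with_seed(seed, {
    pop <- make_population(n_FS, n_nonFS, 0, jitter = 0,
                           seed = sample.int(2^30, 1))
    n <- length(pop)
    gj <- list(); cs <- list()
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < p_gap) {
        G_recv <- 1000 / pop[[j]]$params$R_in_MOhm
        cc_target <- runif(1, 0.012, 0.025)
        gj[[length(gj) + 1]] <- data.frame(
          i = i, j = j, g_nS = cc_target * G_recv / (1 - cc_target))
      }
    }
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && runif(1) < p_chem)
        cs[[length(cs) + 1]] <- data.frame(
          pre = i, post = j, g_nS = runif(1, 0.3, 0.5),
          latency_ms = runif(1, 1.2, 3))
    }
    circuit_spec(pop,
                 gap_junctions = if (length(gj)) do.call(rbind, gj) else NULL,
                 chem_synapses = if (length(cs)) do.call(rbind, cs) else NULL)
  })
}

# parameter matrix handed to the C++ integrator
params_matrix <- function(circuit) {
  do.call(rbind, lapply(circuit$cells, function(cl) {
    p <- cl$params
    c(p$rest_mV, 1000 / p$R_in_MOhm, p$C_pF, p$spike_threshold_mV,
      p$ap_peak_mV, p$ap_rise_ms, p$ap_halfwidth_ms, p$ahp_amp_mV,
      p$ahp_time_ms, p$adaptation_strength)
  }))
}

cells_meta_df <- function(circuit) {
  do.call(rbind, lapply(circuit$cells, function(cl) {
    m <- cl$meta
    data.frame(cell_id = m$cell_id, subtype_label = cl$params$subtype_label,
               fluor_label = m$fluor_label, x_um = m$position_um[1],
               y_um = m$position_um[2], z_um = m$position_um[3],
               layer = m$layer, area = m$area, age_P = m$age_P,
               clone_id = if (is.na(m$clone_id)) NA_character_ else as.character(m$clone_id))
  }))
}
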