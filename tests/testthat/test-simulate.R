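# window means used to measure step deflections directly from traces
epoch_mean <- function(trace, fs_kHz, from_ms, to_ms)
  mean(trace[(round(from_ms * fs_kHz) + 1):round(to_ms * fs_kHz)])

test_that("two-cell gap steady state matches the analytic coupling ratio", {
  # g = 1 nS onto a receiver with leak 9 nS: cc = g / (g + G2) = 0.10
  cir <- two_cell_gap_circuit(1, R1_MOhm = 150, R2_MOhm = 1000 / 9)
  ses <- quiet_session(cir, drivers = 1)
  e <- detect_electrical(ses, 1, 2)
  expect_lt(abs(e$coupling_coefficient - 0.10) / 0.10, 0.02)
})

test_that("uncoupled passive receiver stays exactly at rest without noise", {
  cir <- two_cell_gap_circuit(0)
  ses <- quiet_session(cir, drivers = 1)
  v2 <- ses$trials[[1]]$traces[, 2]
  expect_equal(max(abs(v2 - v2[1])), 0)
})

test_that("identical seeds give bit-identical sessions", {
  cir <- two_cell_gap_circuit(1.5)
  s1 <- simulate_session(cir, std_protocol(), seed = 42, drivers = 1)
  s2 <- simulate_session(cir, std_protocol(), seed = 42, drivers = 1)
  expect_identical(s1$trials[[1]]$traces, s2$trials[[1]]$traces)
  expect_false(identical(
    s1$trials[[1]]$traces,
    simulate_session(cir, std_protocol(), seed = 43,
                     drivers = 1)$trials[[1]]$traces))
})

test_that("passive responses scale linearly with injected current", {
  # single clean step from rest: doubling the current doubles the
  # steady-state deflection to integrator precision
  p <- fs_preset(); p$spike_threshold_mV <- 100   # keep the cell passive
  defl <- vapply(c(-50, -100), function(I) {
    fam <- characterize_cell(p, characterization_protocol(sub_step_pA = I))
    sw <- fam$sweeps[[1]]
    fs <- fam$sampling_rate_Hz / 1000
    epoch_mean(sw$voltage_mV, fs, 650, 700) -
      epoch_mean(sw$voltage_mV, fs, 150, 190)
  }, 0)
  expect_lt(abs(defl[2] - 2 * defl[1]) / abs(defl[2]), 1e-6)
})

test_that("coupling coefficient is symmetric for equal leak conductances", {
  cir <- two_cell_gap_circuit(1.2, R1_MOhm = 180, R2_MOhm = 180)
  ses <- quiet_session(cir)
  cc12 <- detect_electrical(ses, 1, 2)$coupling_coefficient
  cc21 <- detect_electrical(ses, 2, 1)$coupling_coefficient
  expect_lt(abs(cc12 - cc21) / cc12, 0.01)
})

test_that("simulated PSCs respect causality and the specified latency", {
  pop <- make_population(2, 0, 0, seed = 1)
  cir <- circuit_spec(pop, chem_synapses = data.frame(
    pre = 1, post = 2, g_nS = 0.4, latency_ms = 2))
  ses <- quiet_session(cir, drivers = 1)
  r <- detect_chemical(ses, 1, 2)
  expect_true(r$connected)
  # onset latency recovers the synaptic delay
  expect_lt(abs(r$latency_ms - 2), 0.2)
  # nothing precedes the AP peak: average current flat before lag 0
  pre_lag <- r$avg_pA[r$lags_ms < 0 & r$lags_ms > -4]
  expect_lt(max(abs(pre_lag)), 0.05)
})

test_that("population generator respects counts, seeds and jitter limits", {
  pop <- make_population(5, 5, 0, jitter = 0.03, seed = 9)
  expect_length(pop, 10)
  expect_equal(sum(vapply(pop, function(x) x$params$subtype_label, "") == "FS"), 5)
  pop2 <- make_population(5, 5, 0, jitter = 0.03, seed = 9)
  expect_identical(pop, pop2)
  # jitter so large it must push some parameter across a threshold
  expect_error(make_population(5, 5, 0, jitter = 0.8, seed = 1),
               "classification threshold")
})

test_that("clonal pattern generator produces the stated geometry", {
  # degenerate dispersion: all siblings coincide
  cs0 <- make_clonal_pattern(4, 3, clone_sd_um = 0, seed = 2)
  cd0 <- clonal_distances(cs0)
  expect_true(all(cd0$intra_um == 0))
  expect_true(all(cd0$inter_um > 0))
  # reproducibility
  expect_identical(make_clonal_pattern(6, 4, 50, seed = 5),
                   make_clonal_pattern(6, 4, 50, seed = 5))
  # all clones unsampled: explicit empty set, not an error
  cs_empty <- make_clonal_pattern(5, 3, 50, labelling_density = 1e-9, seed = 1)
  expect_s3_class(cs_empty, "clone_set")
  expect_equal(nrow(cs_empty), 0)
})

test_that("isolated clones keep intraclonal below interclonal distances", {
  # widely separated clone centres: every draw must order the means
  for (s in 1:25) {
    cs <- make_clonal_pattern(6, 4, clone_sd_um = 50, volume_um3 = 4000^3,
                              seed = s)
    cd <- clonal_distances(cs)
    if (length(cd$intra_um) == 0) next
    expect_lt(mean(cd$intra_um), mean(cd$inter_um))
  }
})
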