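test_that("input resistance and adaptation ratio from a clean sweep family", {
  fam <- synthetic_sweep_family()
  ft <- extract_features(fam)
  # -50 pA -> -10 mV steady state: Ohm's law gives 200 MOhm
  expect_equal(ft$input_resistance_MOhm, 200, tolerance = 1e-6)
  # ten identical 10 ms interspike intervals
  expect_equal(ft$adaptation_ratio, 1.0, tolerance = 1e-9)
  expect_equal(ft$rmp_mV, -65, tolerance = 1e-9)
  expect_equal(ft$max_firing_Hz, 10)
})

test_that("extraction round-trips the simulator's waveform parameters", {
  ft <- extract_features(characterize_cell(fs_preset()))
  expect_lt(abs(ft$ap_halfwidth_ms - 0.5), 0.1)
  expect_lt(abs(ft$ahp_amp_mV - 12), 0.5)
  expect_equal(ft$ahp_time_ms, 3, tolerance = 0.1)
  expect_lt(abs(ft$ap_threshold_mV - (-33)), 0.5)
  expect_gt(ft$max_firing_Hz, 100)
})

test_that("no suprathreshold sweep flags firing features undefined", {
  fam <- synthetic_sweep_family()
  fam$sweeps <- fam$sweeps[1]   # subthreshold only
  ft <- extract_features(fam)
  expect_false(ft$firing_defined)
  expect_true(is.na(ft$max_firing_Hz))
  expect_error(classify_subtype(ft), "undefined features")
})

test_that("FS call is a strict conjunction with inclusive boundaries", {
  expect_equal(classify_subtype(fs_features()), "FS")
  # single-criterion failure
  expect_equal(classify_subtype(fs_features(max_firing_Hz = 79.9)), "nonFS")
  # boundary inclusive
  expect_equal(classify_subtype(fs_features(max_firing_Hz = 80)), "FS")
  expect_equal(classify_subtype(fs_features(input_resistance_MOhm = 300)), "FS")
  expect_equal(classify_subtype(fs_features(adaptation_ratio = 2.5)), "FS")
  expect_equal(classify_subtype(fs_features(ap_threshold_mV = -35)), "FS")
})

test_that("moving a feature toward its FS side never flips FS to nonFS", {
  toward <- list(max_firing_Hz = 10, ahp_amp_mV = 2, ap_threshold_mV = 2,
                 input_resistance_MOhm = -50, adaptation_ratio = -0.5,
                 ap_halfwidth_ms = -0.2, ap_rise_ms = -0.3,
                 ap_decay_ms = -1, ahp_time_ms = -1)
  set.seed(11)
  for (k in 1:20) {
    base <- fs_features(
      max_firing_Hz = runif(1, 80, 200), ahp_amp_mV = runif(1, 8, 20),
      ap_threshold_mV = runif(1, -35, -25),
      input_resistance_MOhm = runif(1, 80, 300),
      adaptation_ratio = runif(1, 0.8, 2.5))
    expect_equal(classify_subtype(base), "FS")
    nm <- sample(names(toward), 1)
    shifted <- base
    shifted[[nm]] <- base[[nm]] + toward[[nm]]
    expect_equal(classify_subtype(shifted), "FS")
  }
})

test_that("classifier recovers generating subtypes on clean populations", {
  pop <- make_population(5, 5, 0, jitter = 0, seed = 21)
  tab <- features_table(pop, noise_sd_mV = 0, seed = 1)
  truth <- vapply(pop, function(x) x$params$subtype_label, "")
  expect_identical(tab$subtype_call, ifelse(truth == "FS", "FS", "nonFS"))
  # pyramidal presets are never called FS
  pn <- features_table(make_population(0, 0, 3, seed = 4), seed = 2)
  expect_true(all(pn$subtype_call == "nonFS"))
})

test_that("subtype recovery tolerates recording noise", {
  pop <- make_population(4, 4, 0, jitter = 0, seed = 31)
  tab <- features_table(pop, noise_sd_mV = 0.2, seed = 3)
  truth <- ifelse(vapply(pop, function(x) x$params$subtype_label, "") == "FS",
                  "FS", "nonFS")
  expect_gte(mean(tab$subtype_call == truth), 0.95)
})

test_that("unknown criteria overrides are rejected", {
  expect_error(subtype_criteria(bogus = 1), "unknown criteria")
  crit <- subtype_criteria(max_firing_ge = 100)
  expect_equal(crit$max_firing_ge, 100)
  expect_equal(subtype_criteria()$input_resistance_le, 300)
})
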