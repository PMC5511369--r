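test_that("percentages round half-up to one decimal like the published text", {
  expect_equal(rate(27, 80), 33.8)
  expect_equal(rate(49, 79), 62.0)
  expect_equal(rate(19, 80), 23.8)
  expect_equal(rate(11, 34), 32.4)
  expect_equal(rate(0, 10), 0.0)
  expect_equal(rate(14, 35), 40.0)
  expect_error(rate(1, 0), "undefined")
  expect_error(rate(5, 4), "must lie")
})

test_that("chi-square matches a brute-force computation and edge cases", {
  groups <- list(c(27, 80), c(59, 462))
  cr <- compare_rates(groups)
  # brute force sum((O-E)^2/E) on the 2x2 table
  O <- rbind(c(27, 53), c(59, 403))
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(cr$statistic, sum((O - E)^2 / E), tolerance = 1e-9)
  expect_lt(cr$p_value, 0.001)
  ident <- compare_rates(list(c(10, 50), c(10, 50)))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(compare_rates(list(c(0, 10), c(0, 20))), "degenerate")
  expect_error(compare_rates(list(c(5, 10))), "at least 2")
  f <- compare_rates(list(c(1, 5), c(4, 6)), method = "fisher")
  expect_true(is.na(f$statistic) && f$p_value > 0 && f$p_value <= 1)
})

test_that("stratified rates conserve totals and handle single records", {
  rec <- make_pair_cohort(seed = 31)
  sr <- stratified_rates(rec, "distance_bins")
  agg <- aggregate(cbind(k, n) ~ lineage_class, sr, sum)
  expect_equal(sum(agg$n), nrow(rec))
  expect_equal(sum(agg$k), sum(rec$electrical))
  one <- rec[1, ]
  sr1 <- stratified_rates(one, "distance_bins")
  expect_equal(nrow(sr1), 1)
  expect_true(is.na(sr1$chi2_p))
})

test_that("lineage-dependent coupling probabilities are recovered", {
  rec <- make_pair_cohort(n = c(sparse_cluster = 400, non_lineage = 800),
                          p_electrical = c(sparse_cluster = 0.6,
                                           non_lineage = 0.15),
                          seed = 77)
  sr <- stratified_rates(rec, "lineage")
  for (cl in c("sparse_cluster", "non_lineage")) {
    row <- sr[sr$stratum == cl, ]
    ci <- binom.test(row$k, row$n)$conf.int
    p_true <- c(sparse_cluster = 0.6, non_lineage = 0.15)[[cl]]
    expect_gte(p_true, ci[1]); expect_lte(p_true, ci[2])
  }
})

test_that("independence analysis reproduces the published NS contrasts", {
  # counts transcribed from the published pair table
  ind <- list(
    elec_by_chem = compare_rates(list(c(11, 34), c(33, 100))),
    chem_by_elec = compare_rates(list(c(11, 44), c(23, 90))))
  expect_gt(ind$elec_by_chem$p_value, 0.05)
  expect_gt(ind$chem_by_elec$p_value, 0.05)
  # perfectly nested simulation is detected as strongly dependent
  rec <- make_pair_cohort(n = c(sparse_cluster = 300),
                          p_electrical = c(sparse_cluster = 0.5),
                          p_chemical = 0.9, seed = 3)
  rec$chemical <- ifelse(rec$electrical, "uni", "none")   # chemical subset
  res <- electrical_chemical_independence(rec)
  expect_lt(res$electrical_by_chemical$p_value, 0.001)
  # independent generating processes are usually NS
  ns <- 0
  for (s in 1:40) {
    rec <- make_pair_cohort(n = c(sparse_cluster = 500),
                            p_electrical = c(sparse_cluster = 0.3),
                            p_chemical = 0.25, seed = 100 + s)
    res <- electrical_chemical_independence(rec)
    if (res$electrical_by_chemical$p_value > 0.05) ns <- ns + 1
  }
  expect_gte(ns / 40, 0.9)
})

test_that("coordinated-output rates follow the published convention", {
  # reconstruct pair records carrying the published (k, n) structure
  mk <- function(cl, coupled, k, n) data.frame(
    lineage_class = cl, electrical = coupled,
    both_output_to_common_PN = c(rep(TRUE, k), rep(FALSE, n - k)))
  rec <- rbind(mk("sparse_cluster", TRUE, 14, 35),
               mk("sparse_cluster", FALSE, 14, 95),
               mk("non_lineage", TRUE, 1, 15),
               mk("non_lineage", FALSE, 10, 107))
  out <- coordinated_output(rec)
  get <- function(cl, cp) out$rate_percent[out$lineage_class == cl &
                                             out$coupled == cp]
  expect_equal(get("sparse_cluster", TRUE), 40.0)
  expect_equal(get("sparse_cluster", FALSE), 14.7)
  expect_equal(get("non_lineage", TRUE), 6.7)
  expect_equal(get("non_lineage", FALSE), 9.3)
  expect_lt(attr(out, "tests")$sparse_cluster, 0.01)
})

test_that("common-target coordination is read off the connection matrix", {
  # both interneurons (1, 2) chemically target PN 4
  pop <- c(make_population(2, 0, 0, seed = 41),
           make_population(0, 0, 2, seed = 42))
  for (k in 3:4) pop[[k]]$meta$cell_id <- as.integer(k)
  cir <- circuit_spec(pop, chem_synapses = data.frame(
    pre = c(1, 2), post = c(4, 4), g_nS = 0.4, latency_ms = 2))
  res <- connection_matrix(quiet_session(cir, seed = 43))
  expect_true(pair_is_coordinated(res, c(1, 2), pn_cells = c(3, 4)))
  expect_error(pair_is_coordinated(res, c(1, 2), pn_cells = integer()),
               "pyramidal")
})
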