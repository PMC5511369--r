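#' Percentage with half-up rounding to one decimal
#'
#' The convention used when quoting connection rates: 100 * k / n rounded
#' half-up to one decimal place (so 27/80 -> 33.8, 19/80 -> 23.8).
#'
#' @param k successes (0 <= k <= n).
#' @param n total (> 0).
#' @export
rate <- function(k, n) {
  if (any(n <= 0)) stopf("rate undefined for n = 0")
  if (any(k < 0 | k > n)) stopf("k must lie in [0, n]")
  floor(1000 * k / n + 0.5) / 10
}

#' Compare connection rates across groups
#'
#' Pearson chi-square test (no continuity correction) on the 2 x k table of
#' (coupled, not coupled) by group; Fisher's exact test available for sparse
#' tables.
#'
#' @param groups list of c(k, n) pairs, or a 2-column matrix (k, n) with one
#'   row per group.
#' @param method "chi2" or "fisher".
#' @param correct apply Yates continuity correction (default FALSE).
#' @return list(rates_percent, k, n, statistic, p_value, method).
#' @export
compare_rates <- function(groups, method = c("chi2", "fisher"),
                          correct = FALSE) {
  method <- match.arg(method)
  m <- if (is.matrix(groups)) groups else do.call(rbind, groups)
  if (nrow(m) < 2) stopf("need at least 2 groups")
  k <- m[, 1]; n <- m[, 2]
  if (any(n <= 0) || any(k < 0 | k > n)) stopf("invalid counts")
  tab <- cbind(k, n - k)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("degenerate table: a margin is zero")
  if (method == "fisher") {
    ht <- fisher.test(tab)
    stat <- NA_real_
  } else {
    ht <- suppressWarnings(chisq.test(tab, correct = correct))
    stat <- unname(ht$statistic)
  }
  list(rates_percent = rate(k, n), k = k, n = n, statistic = stat,
       p_value = ht$p.value, method = method)
}

#' Simulate a pair-outcome cohort with known connection probabilities
#'
#' Draws pair records whose electrical-coupling and chemical-connection
#' outcomes are Bernoulli with probabilities depending on lineage class
#' (and optionally distance), providing ground truth for rate-recovery and
#' independence checks. Default class sizes mirror a large paired-recording
#' cohort (80 lineage-related cluster pairs versus 462 non-lineage pairs).
#'
#' @param n named vector of pair counts per lineage class.
#' @param p_electrical named vector of coupling probabilities per class.
#' @param p_chemical chemical connection probability (shared).
#' @param p_bi_given_chem probability a chemical connection is bidirectional.
#' @param seed integer seed.
#' @return data frame of pair records.
#' @export
make_pair_cohort <- function(n = c(sparse_cluster = 80, non_lineage = 462),
                             p_electrical = c(sparse_cluster = 0.6,
                                              non_lineage = 0.15),
                             p_chemical = 0.25, p_bi_given_chem = 0.3,
                             seed) {
  if (missing(seed)) stopf("a seed is required")
  stopifnot(all(names(n) %in% names(p_electrical)))
  with_seed(seed, {
    rows <- lapply(names(n), function(cl) {
      m <- n[[cl]]
      e <- rbinom(m, 1, p_electrical[[cl]]) == 1
      ch <- rbinom(m, 1, p_chemical) == 1
      bi <- ch & rbinom(m, 1, p_bi_given_chem) == 1
      data.frame(pair_id = paste0(cl, "_", seq_len(m)), lineage_class = cl,
                 subtype_pair = sample(c("FS_FS", "nonFS_nonFS", "FS_nonFS"),
                                       m, replace = TRUE),
                 intersoma_dist_um = runif(m, 5, 250),
                 age_P = sample(14:28, m, replace = TRUE),
                 layer = sample(c("L2_3", "L5"), m, replace = TRUE),
                 area = "SCX", electrical = e,
                 chemical = ifelse(!ch, "none", ifelse(bi, "bi", "uni")))
    })
    do.call(rbind, rows)
  })
}

default_distance_bins <- c(0, 20, 50, 100, 150, 200, Inf)
default_age_bins <- c(-Inf, 6, 10, 13, 21, Inf)

#' Stratified connection rates with per-stratum tests
#'
#' Splits pair records by a stratifier (distance bins, age bins, subtype
#' pair, layer, or lineage class itself), computes (k, n, rate) per lineage
#' class within each stratum and a chi-square contrast across classes where
#' at least two classes have data.
#'
#' @param records pair-record data frame (see [make_pair_cohort()]).
#' @param stratifier one of "lineage", "subtype", "distance_bins",
#'   "age_bins", "layer".
#' @param outcome "electrical" or "chemical" (chemical counts uni or bi).
#' @param distance_bins,age_bins bin edges (defaults \[0,20), \[20,50),
#'   \[50,100), \[100,150), \[150,200), \[200,Inf) um and <=P6, P7-P10,
#'   P11-P13, P14-P21, >=P22).
#' @return data frame with one row per stratum x lineage class, plus
#'   chi-square p per stratum.
#' @export
stratified_rates <- function(records,
                             stratifier = c("lineage", "subtype",
                                            "distance_bins", "age_bins",
                                            "layer"),
                             outcome = c("electrical", "chemical"),
                             distance_bins = default_distance_bins,
                             age_bins = default_age_bins) {
  stratifier <- match.arg(stratifier)
  outcome <- match.arg(outcome)
  y <- if (outcome == "electrical") records$electrical
       else records$chemical != "none"
  stratum <- switch(stratifier,
    lineage = records$lineage_class,
    subtype = records$subtype_pair,
    layer = records$layer,
    distance_bins = as.character(cut(records$intersoma_dist_um, distance_bins,
                                     right = FALSE)),
    age_bins = as.character(cut(records$age_P, age_bins, right = TRUE)))
  cls <- if (stratifier == "lineage") rep("all", nrow(records))
         else records$lineage_class
  out <- list()
  for (s in unique(stratum)) {
    sel <- stratum == s
    tab <- lapply(unique(cls[sel]), function(cc) {
      kk <- sum(y[sel & cls == cc]); nn <- sum(sel & cls == cc)
      data.frame(stratum = s, lineage_class = cc, k = kk, n = nn,
                 rate_percent = if (nn > 0) rate(kk, nn) else NA_real_)
    })
    tab <- do.call(rbind, tab)
    usable <- tab$n > 0
    tab$chi2_p <- if (sum(usable) >= 2 && sum(tab$k[usable]) > 0 &&
                      sum(tab$k[usable]) < sum(tab$n[usable])) {
      compare_rates(as.matrix(tab[usable, c("k", "n")]))$p_value
    } else NA_real_
    out[[length(out) + 1]] <- tab
  }
  do.call(rbind, out)
}

#' Independence of electrical and chemical synapse formation
#'
#' Cross-tabulates the two call types over a pair cohort: coupling rate given
#' chemical status, chemical rate given coupling status, and bidirectional-
#' versus-unidirectional chemical connections by coupling status, each with
#' a chi-square test.
#'
#' @param records pair-record data frame.
#' @return named list of [compare_rates()] results.
#' @export
electrical_chemical_independence <- function(records) {
  e <- records$electrical
  ch <- records$chemical != "none"
  bi <- records$chemical == "bi"
  res <- list(
    electrical_by_chemical = compare_rates(list(
      c(sum(e & ch), sum(ch)), c(sum(e & !ch), sum(!ch)))),
    chemical_by_electrical = compare_rates(list(
      c(sum(ch & e), sum(e)), c(sum(ch & !e), sum(!e)))))
  if (sum(ch & e) > 0 && sum(ch & !e) > 0) {
    res$bidirectional_by_electrical <- tryCatch(
      compare_rates(list(c(sum(bi & e), sum(ch & e)),
                         c(sum(bi & !e), sum(ch & !e)))),
      error = function(err) NULL)
  }
  res
}

#' Coordinated inhibitory output onto common pyramidal targets
#'
#' A recorded interneuron pair counts as coordinated when both interneurons
#' are chemically presynaptic to at least one common pyramidal neuron in the
#' session. Given pair records carrying a `both_output_to_common_PN` flag
#' (or connection matrices from quadruple sessions), returns coordinated-
#' output rates stratified by lineage class and electrical coupling status,
#' with a chi-square contrast by coupling within each class.
#'
#' @param records pair records with logical `both_output_to_common_PN`.
#' @return data frame (lineage_class, coupled, k, n, rate_percent) plus the
#'   within-class chi-square p as attribute "tests".
#' @export
coordinated_output <- function(records) {
  stopifnot("both_output_to_common_PN" %in% names(records))
  rec <- records[!is.na(records$both_output_to_common_PN), ]
  n_dropped <- nrow(records) - nrow(rec)
  if (n_dropped > 0)
    message(sprintf("coordinated_output: %d pairs without PN data excluded",
                    n_dropped))
  out <- list(); tests <- list()
  for (cl in unique(rec$lineage_class)) {
    for (cp in c(TRUE, FALSE)) {
      sel <- rec$lineage_class == cl & rec$electrical == cp
      out[[length(out) + 1]] <- data.frame(
        lineage_class = cl, coupled = cp,
        k = sum(rec$both_output_to_common_PN[sel]), n = sum(sel),
        rate_percent = if (sum(sel) > 0)
          rate(sum(rec$both_output_to_common_PN[sel]), sum(sel)) else NA_real_)
    }
    sub <- do.call(rbind, out[(length(out) - 1):length(out)])
    tests[[cl]] <- if (all(sub$n > 0))
      tryCatch(compare_rates(as.matrix(sub[, c("k", "n")]))$p_value,
               error = function(e) NA_real_) else NA_real_
  }
  res <- do.call(rbind, out)
  attr(res, "tests") <- tests
  res
}

#' Count interneuron pairs coordinated onto a common pyramidal target
#'
#' Helper for quadruple-session analysis: given the chemical adjacency of a
#' session (from [connection_matrix()]) and the indices of the two
#' interneurons and the pyramidal cells, decides the coordinated-output flag.
#'
#' @param results list from [connection_matrix()].
#' @param in_pair length-2 interneuron indices.
#' @param pn_cells pyramidal cell indices (>= 1).
#' @export
pair_is_coordinated <- function(results, in_pair, pn_cells) {
  if (length(pn_cells) == 0) stopf("session lacks a pyramidal cell")
  tab <- connections_table(results)
  conn <- function(pre, post)
    any(tab$pre == pre & tab$post == post & tab$chemical_connected)
  any(vapply(pn_cells, function(pn)
    conn(in_pair[1], pn) && conn(in_pair[2], pn), TRUE))
}
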