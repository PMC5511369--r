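#' Load the transcribed published pair-count table
#'
#' The bundled fixture `paper_counts.csv` transcribes, from the published
#' Results of the lineage-coupling study, every pair-outcome count (k out of
#' n) together with the percentage printed alongside it and, where a
#' significance call is attached to the comparison, the printed label.
#'
#' @param path optional path to an alternative counts CSV.
#' @export
paper_counts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "paper_counts.csv", package = "clonecircuit")
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("comparison_id", "group", "k", "n")
  if (!all(need %in% names(df)))
    stopf("counts table lacks columns: %s",
          paste(setdiff(need, names(df)), collapse = ", "))
  df
}

#' Recompute every published rate and significance call from the counts
#'
#' For each row of the counts table the percentage is recomputed with
#' [rate()] and compared (to one decimal) with the printed value; for each
#' comparison carrying an expected significance label, a Pearson chi-square
#' test (no continuity correction) across its groups is evaluated against
#' that label at the printed threshold (p < 0.001, p < 0.01, or NS at
#' alpha = 0.05).
#'
#' @param counts counts table from [paper_counts()].
#' @param alpha significance level for "NS" calls.
#' @return list(rates = data.frame, tests = data.frame, all_pass = logical).
#' @export
reproduce_paper <- function(counts = paper_counts(), alpha = 0.05) {
  counts$computed_percent <- rate(counts$k, counts$n)
  has_printed <- !is.na(counts$printed_percent) & counts$printed_percent != ""
  counts$rate_pass <- ifelse(has_printed,
                             abs(counts$computed_percent -
                                   as.numeric(counts$printed_percent)) < 0.05,
                             NA)
  tests <- list()
  for (id in unique(counts$comparison_id[counts$expected_sig != "" &
                                         !is.na(counts$expected_sig)])) {
    sub <- counts[counts$comparison_id == id, ]
    if (nrow(sub) < 2) next
    cr <- compare_rates(as.matrix(sub[, c("k", "n")]))
    expected <- sub$expected_sig[1]
    pass <- switch(expected,
                   "p<0.001" = cr$p_value < 0.001,
                   "p<0.01" = cr$p_value < 0.01,
                   "NS" = cr$p_value >= alpha,
                   NA)
    tests[[length(tests) + 1]] <- data.frame(
      comparison_id = id, chi2 = cr$statistic, p_value = cr$p_value,
      expected = expected, test_pass = pass)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(comparison_id = character(), chi2 = numeric(),
               p_value = numeric(), expected = character(),
               test_pass = logical())
  list(rates = counts, tests = tests,
       all_pass = all(counts$rate_pass, na.rm = TRUE) &&
         all(tests$test_pass, na.rm = TRUE))
}

#' Print a reproduction report
#'
#' @param rep result of [reproduce_paper()].
#' @param file connection for output (default stdout).
#' @export
print_reproduction_report <- function(rep, file = stdout()) {
  cat("published-rate reproduction\n", file = file)
  for (i in seq_len(nrow(rep$rates))) {
    r <- rep$rates[i, ]
    if (is.na(r$rate_pass)) next
    cat(sprintf("  %-28s %-24s %3d/%-3d -> %5.1f%% (printed %5.1f%%) %s\n",
                r$comparison_id, r$group, r$k, r$n, r$computed_percent,
                as.numeric(r$printed_percent),
                if (r$rate_pass) "PASS" else "FAIL"), file = file)
  }
  cat("significance calls\n", file = file)
  for (i in seq_len(nrow(rep$tests))) {
    t <- rep$tests[i, ]
    cat(sprintf("  %-28s chi2 = %6.2f, p = %.3g, expected %s: %s\n",
                t$comparison_id, t$chi2, t$p_value, t$expected,
                if (t$test_pass) "PASS" else "FAIL"), file = file)
  }
  cat(sprintf("overall: %s\n", if (rep$all_pass) "PASS" else "FAIL"),
      file = file)
  invisible(rep$all_pass)
}
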