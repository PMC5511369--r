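#' Spike train container
#'
#' @param times_ms sorted spike times within \[0, duration_ms\].
#' @param duration_ms recording time T.
#' @export
spike_train <- function(times_ms, duration_ms) {
  times_ms <- as.numeric(times_ms)
  if (is.unsorted(times_ms)) times_ms <- sort(times_ms)
  if (length(times_ms) && (times_ms[1] < 0 || times_ms[length(times_ms)] > duration_ms))
    stopf("spike times must lie in [0, T]")
  structure(list(times_ms = times_ms, duration_ms = duration_ms),
            class = "spike_train")
}

#' Homogeneous Poisson spike train
#'
#' @param rate_Hz firing rate.
#' @param duration_ms recording time.
#' @param seed integer seed.
#' @export
poisson_train <- function(rate_Hz, duration_ms, seed = NULL) {
  with_seed(seed, {
    n_exp <- rate_Hz * duration_ms / 1000
    t <- cumsum(rexp(ceiling(n_exp + 5 * sqrt(n_exp) + 10), rate_Hz / 1000))
    spike_train(t[t <= duration_ms], duration_ms)
  })
}

#' Binned spike-train cross-correlogram, Z-normalized
#'
#' Counts ordered spike-time differences (train1 minus train2) in 1 ms bins
#' over +/- `window_ms` and normalizes each bin count to a standard score
#' against the independence expectation E = lambda1 * lambda2 * dt * T with
#' Poisson s.d. sigma = sqrt(E): Z = (C - E) / sigma.
#'
#' @param train1,train2 [spike_train()] objects (non-empty).
#' @param window_ms half-width of the lag window (>= 200 ms).
#' @param bin_ms bin width (default 1 ms).
#' @return An object of class `correlogram`: data frame-like list with
#'   lag_ms (bin centres), count, expected, z, plus rates and T.
#' @export
crosscorrelogram <- function(train1, train2, window_ms = 250, bin_ms = 1) {
  stopifnot(inherits(train1, "spike_train"), inherits(train2, "spike_train"))
  if (length(train1$times_ms) == 0 || length(train2$times_ms) == 0)
    stopf("empty spike train: firing rates undefined")
  if (window_ms < 200) stopf("window must be at least 200 ms per side")
  T_ms <- max(train1$duration_ms, train2$duration_ms)
  t1 <- train1$times_ms; t2 <- sort(train2$times_ms)
  lags_centres <- seq(-window_ms, window_ms, by = bin_ms)
  counts <- integer(length(lags_centres))
  # per-spike neighbourhood enumeration (O(pairs), not O(n1*n2))
  lo <- findInterval(t1 - window_ms - bin_ms / 2, t2) + 1
  hi <- findInterval(t1 + window_ms + bin_ms / 2, t2)
  for (k in seq_along(t1)) {
    if (hi[k] < lo[k]) next
    d <- t1[k] - t2[lo[k]:hi[k]]
    # bin index by symmetric rounding so that C_ab(lag) = C_ba(-lag) exactly
    b <- round(d / bin_ms) + window_ms / bin_ms + 1
    b <- b[b >= 1 & b <= length(counts)]
    tb <- tabulate(b, nbins = length(counts))
    counts <- counts + tb
  }
  lam1 <- length(t1) / T_ms; lam2 <- length(t2) / T_ms   # per ms
  expected <- lam1 * lam2 * bin_ms * T_ms
  sigma <- sqrt(expected)
  structure(list(lag_ms = lags_centres, count = counts,
                 expected = rep(expected, length(counts)),
                 z = (counts - expected) / sigma,
                 sigma = sigma, rate1_Hz = lam1 * 1000,
                 rate2_Hz = lam2 * 1000, T_ms = T_ms, bin_ms = bin_ms),
            class = "correlogram")
}

#' Significant synchrony peaks of a correlogram
#'
#' A bin is a significant peak when its Z score exceeds that of every other
#' bin within +/- 200 ms by more than 3 (the strict all-neighbours reading);
#' with `rule = "any"` it suffices to exceed the larger of the two adjacent
#' bins by 3. Bins near the window edge use the truncated neighbourhood.
#'
#' @param cg a [crosscorrelogram()].
#' @param rule "all" (default) or "any".
#' @return data frame (lag_ms, z) of significant bins (possibly empty).
#' @export
significant_peaks <- function(cg, rule = c("all", "any"), delta_z = 3,
                              neighbourhood_ms = 200) {
  rule <- match.arg(rule)
  z <- cg$z; lags <- cg$lag_ms
  n <- length(z)
  sig <- logical(n)
  if (rule == "any") {
    for (b in seq_len(n)) {
      nb <- c(if (b > 1) z[b - 1], if (b < n) z[b + 1])
      sig[b] <- length(nb) > 0 && z[b] - min(nb) > delta_z
    }
  } else {
    # candidates must beat every bin in their neighbourhood by delta_z;
    # prefilter on the global max to keep this cheap
    cand <- which(z >= max(z) - delta_z)
    w <- round(neighbourhood_ms / cg$bin_ms)
    for (b in cand) {
      idx <- max(1, b - w):min(n, b + w)
      idx <- idx[idx != b]
      sig[b] <- all(z[b] - z[idx] > delta_z)
    }
  }
  data.frame(lag_ms = lags[sig], z = z[sig])
}

#' Export a correlogram as CSV
#' @export
write_correlogram <- function(cg, path) {
  df <- data.frame(lag_ms = cg$lag_ms, count = cg$count,
                   expected = cg$expected, z = cg$z)
  atomic_write(path, function(tmp)
    write.csv(df, tmp, row.names = FALSE, quote = FALSE))
  invisible(path)
}
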