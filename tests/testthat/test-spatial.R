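test_that("nearest-neighbour distances on a hand-computable pattern", {
  cs <- clone_set(cbind(c(0, 10, 30), 0, 0), c("a", "b", "c"))
  res <- nnd(cs, "all")
  expect_equal(sort(res$d_um), c(10, 10, 20))
  expect_equal(res$cdf(10), 2 / 3)
  expect_equal(res$cdf(20), 1)
  expect_equal(res$cdf(5), 0)
})

test_that("NND CDF is invariant under rigid motion", {
  set.seed(7)
  pts <- matrix(runif(60) * 300, ncol = 3)
  cs <- clone_set(pts, as.character(1:20))
  theta <- 0.7
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0), c(0, 0, 1))
  cs2 <- clone_set(pts %*% R + 50, as.character(1:20))
  expect_equal(sort(nnd(cs, "all")$d_um), sort(nnd(cs2, "all")$d_um),
               tolerance = 1e-9)
})

test_that("cross-label NND requires two labels and pools both directions", {
  cs <- clone_set(cbind(c(0, 1, 10, 11), 0, 0), c("a", "a", "b", "b"),
                  fluor_labels = c("EGFP", "EGFP", "mCherry", "mCherry"))
  res <- nnd(cs, "cross-label")
  expect_length(res$d_um, 4)     # both directions pooled
  expect_equal(sort(res$d_um), c(9, 9, 10, 10))
  one_label <- clone_set(cbind(c(0, 1), 0, 0), c("a", "b"))
  expect_error(nnd(one_label, "cross-label"), "two labels")
})

test_that("intra/inter pair counts partition the full pair set", {
  cs <- make_clonal_pattern(5, 4, 40, seed = 13)
  cd <- clonal_distances(cs)
  n <- nrow(cs)
  expect_equal(unname(cd$n_pairs["intra"] + cd$n_pairs["inter"]),
               n * (n - 1) / 2)
  sizes <- table(cs$clone_id)
  expect_equal(unname(cd$n_pairs["intra"]),
               sum(sizes * (sizes - 1) / 2))
  # 2 clones of 2 cells: 2 intra pairs, 4 inter pairs
  cs22 <- clone_set(matrix(runif(12), 4), c("a", "a", "b", "b"))
  cd22 <- clonal_distances(cs22)
  expect_equal(unname(cd22$n_pairs[c("intra", "inter")]), c(2L, 4L))
})

test_that("same-barcode fraction handles degenerate and constructed cases", {
  tri <- clone_set(matrix(runif(9) * 10, 3), rep("c1", 3))
  expect_equal(same_barcode_fraction(tri, 450)$fraction, 1.0)
  singles <- clone_set(matrix(runif(9) * 10, 3), c("a", "b", "c"))
  expect_equal(same_barcode_fraction(singles, 450)$fraction, 0.0)
  expect_false(same_barcode_fraction(singles, 0.0001)$defined)
  # below the minimum interclonal distance the fraction is exactly 1
  cs <- clone_set(rbind(c(0, 0, 0), c(5, 0, 0), c(1000, 0, 0), c(1005, 0, 0)),
                  c("a", "a", "b", "b"))
  expect_equal(same_barcode_fraction(cs, 50)$fraction, 1.0)
})

test_that("single-linkage dendrogram merges at hand-computable heights", {
  cs <- clone_set(cbind(c(0, 1, 10), 0, 0), c("a", "b", "c"))
  hc <- linkage_dendrogram(cs)
  expect_equal(hc$height, c(1, 9))
  expect_length(hc$order, 3)
  # Newick export round-trips through ape
  f <- tempfile(fileext = ".nwk")
  write_newick(hc, f)
  phy <- ape::read.tree(f)
  expect_equal(ape::Ntip(phy), 3)
})

test_that("tree heights agree with a brute-force single-linkage oracle", {
  set.seed(19)
  pts <- matrix(runif(36) * 100, ncol = 3)
  cs <- clone_set(pts, as.character(1:12))
  hc <- linkage_dendrogram(cs)
  # O(n^3) agglomeration oracle
  clusters <- as.list(seq_len(12))
  dm <- as.matrix(dist(pts))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      d <- min(dm[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, j, i)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  expect_equal(hc$height, heights, tolerance = 1e-12)
})

test_that("shuffled clone ids abolish the intra-inter distance difference", {
  cs <- make_clonal_pattern(8, 4, 40, volume_um3 = 2000^3, seed = 23)
  cd <- clonal_distances(cs)
  p_real <- wilcox.test(cd$intra_um, cd$inter_um)$p.value
  expect_lt(p_real, 1e-6)
  ps <- vapply(1:30, function(s) {
    cds <- clonal_distances(shuffle_clone_ids(cs, seed = s))
    suppressWarnings(wilcox.test(cds$intra_um, cds$inter_um)$p.value)
  }, 0)
  # permutation null: p roughly uniform, so clearly not concentrated low
  expect_gt(mean(ps > 0.05), 0.8)
})
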