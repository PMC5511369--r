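#' Nearest-neighbour distances and their cumulative distribution
#'
#' For each eligible cell i, the Euclidean distance to its closest eligible
#' neighbour, d_i, under one of two class rules: `"within-label"` (nearest
#' neighbour carrying the same fluorophore label, pooled over labels) or
#' `"cross-label"` (for every cell of either label, the nearest cell of the
#' other label, both directions pooled). The empirical CDF F(d) is the mean
#' of the indicator f(y, d) = 1\{d_y <= d\} over cells.
#'
#' Optionally a guard-region (minus-sampling) edge correction restricts the
#' focal cells to those at least `guard_um` from every face of the bounding
#' box, while neighbours remain unrestricted; this removes the boundary bias
#' when comparing against the homogeneous-Poisson law.
#'
#' @param cs a [clone_set()].
#' @param class_rule "all", "within-label" or "cross-label".
#' @param guard_um guard distance for edge correction (default 0 = none).
#' @return An object of class `nnd_result`: list(d_um, cdf = function,
#'   n_excluded).
#' @export
nnd <- function(cs, class_rule = c("all", "within-label", "cross-label"),
                guard_um = 0) {
  class_rule <- match.arg(class_rule)
  pts <- clone_points(cs)
  n <- nrow(pts)
  if (n < 2) stopf("need at least 2 points")
  labs <- cs$label
  d_all <- numeric(0)
  nn_of <- function(focal_idx, nbr_idx) {
    if (length(focal_idx) == 0) return(numeric())
    nb <- pts[nbr_idx, , drop = FALSE]
    out <- numeric(length(focal_idx))
    # blocked pairwise distances keep memory bounded at large n
    blocks <- split(seq_along(focal_idx),
                    ceiling(seq_along(focal_idx) / 512))
    for (bl in blocks) {
      fp <- pts[focal_idx[bl], , drop = FALSE]
      d2 <- outer(rowSums(fp^2), rowSums(nb^2), `+`) - 2 * fp %*% t(nb)
      d2[cbind(seq_along(bl),
               match(focal_idx[bl], nbr_idx))[!is.na(match(focal_idx[bl], nbr_idx)), ,
                                              drop = FALSE]] <- Inf
      m <- apply(d2, 1, min)
      out[bl] <- ifelse(is.finite(m), sqrt(pmax(m, 0)), NA_real_)
    }
    out
  }
  focal_ok <- rep(TRUE, n)
  if (guard_um > 0) {
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    focal_ok <- apply(pts, 1, function(p)
      all(p - lo >= guard_um) && all(hi - p >= guard_um))
  }
  if (class_rule == "all") {
    d_all <- nn_of(which(focal_ok), seq_len(n))
  } else if (class_rule == "within-label") {
    for (L in unique(labs))
      d_all <- c(d_all, nn_of(which(labs == L & focal_ok), which(labs == L)))
  } else {
    Ls <- unique(labs)
    if (length(Ls) < 2) stopf("cross-label NND needs two labels")
    for (L in Ls)
      d_all <- c(d_all, nn_of(which(labs == L & focal_ok), which(labs != L)))
  }
  excluded <- sum(is.na(d_all)) + sum(!focal_ok)
  d_all <- d_all[!is.na(d_all)]
  if (excluded > 0)
    message(sprintf("nnd: %d cells excluded (guard region or no eligible neighbour)",
                    excluded))
  structure(list(d_um = d_all, class_rule = class_rule,
                 cdf = stats::ecdf(d_all), n_excluded = excluded),
            class = "nnd_result")
}

#' Intra- versus interclonal pairwise distances
#'
#' Euclidean distances between every unordered pair of clone-assigned cells,
#' partitioned into intraclonal (same clone id; only multi-cell clones
#' contribute) and interclonal (different clone ids) pairs.
#'
#' @param cs a [clone_set()].
#' @return list(intra_um, inter_um, per_clone, n_pairs).
#' @export
clonal_distances <- function(cs) {
  pts <- clone_points(cs)
  n <- nrow(pts)
  if (n < 2) stopf("need at least 2 cells")
  dm <- as.matrix(dist(pts))
  same <- outer(cs$clone_id, cs$clone_id, "==")
  ut <- upper.tri(dm)
  intra <- dm[ut & same]
  inter <- dm[ut & !same]
  if (length(intra) == 0)
    warning("no multi-cell clone: intraclonal distance list is empty")
  sizes <- table(cs$clone_id)
  per_clone <- data.frame(clone_id = names(sizes), size = as.integer(sizes))
  per_clone$mean_intra_um <- vapply(per_clone$clone_id, function(id) {
    k <- which(cs$clone_id == id)
    if (length(k) < 2) return(NA_real_)
    mean(dm[k, k][upper.tri(dm[k, k])])
  }, 0)
  list(intra_um = intra, inter_um = inter, per_clone = per_clone,
       n_pairs = c(intra = length(intra), inter = length(inter),
                   total = n * (n - 1) / 2))
}

#' Fraction of nearby pairs sharing a clone barcode
#'
#' Among all unordered pairs with intersoma Euclidean distance at most
#' `max_dist_um`, the fraction whose two cells carry the same clone
#' (barcode) id.
#'
#' @param cs a [clone_set()].
#' @param max_dist_um distance cut-off (e.g. 450).
#' @return list(fraction, n_pairs, n_same, defined).
#' @export
same_barcode_fraction <- function(cs, max_dist_um = 450) {
  pts <- clone_points(cs)
  if (nrow(pts) < 2)
    return(list(fraction = NA_real_, n_pairs = 0L, n_same = 0L, defined = FALSE))
  dm <- as.matrix(dist(pts))
  ut <- upper.tri(dm)
  close <- ut & dm <= max_dist_um
  n_pairs <- sum(close)
  if (n_pairs == 0)
    return(list(fraction = NA_real_, n_pairs = 0L, n_same = 0L, defined = FALSE))
  same <- outer(cs$clone_id, cs$clone_id, "==")
  n_same <- sum(close & same)
  list(fraction = n_same / n_pairs, n_pairs = n_pairs, n_same = n_same,
       defined = TRUE)
}

#' Hierarchical binary cluster tree of a point set
#'
#' Agglomerative clustering on Euclidean distances (single linkage by
#' default, the conventional default of the linkage function; average
#' linkage available). Exportable as Newick with branch lengths derived
#' from merge heights.
#'
#' @param cs a [clone_set()].
#' @param method "single" or "average".
#' @return An `hclust` object with leaf labels `clone_id:index`.
#' @export
linkage_dendrogram <- function(cs, method = c("single", "average")) {
  method <- match.arg(method)
  pts <- clone_points(cs)
  if (nrow(pts) < 2) stopf("need at least 2 points")
  hc <- hclust(dist(pts), method = method)
  hc$labels <- sprintf("%s:%d", cs$clone_id, seq_len(nrow(pts)))
  hc
}

#' Write a dendrogram as Newick
#'
#' @param hc an `hclust` from [linkage_dendrogram()].
#' @param path output path.
#' @export
write_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  atomic_write(path, function(tmp) ape::write.tree(phy, file = tmp))
  invisible(path)
}

#' Shuffle clone identities (permutation control)
#'
#' @param cs a [clone_set()].
#' @param seed integer seed.
#' @export
shuffle_clone_ids <- function(cs, seed = NULL) {
  with_seed(seed, {
    cs$clone_id <- sample(cs$clone_id)
    cs
  })
}

#' Shuffle fluorophore labels (permutation control)
#' @export
shuffle_labels <- function(cs, seed = NULL) {
  with_seed(seed, {
    cs$label <- sample(cs$label)
    cs
  })
}

#' Write an NND empirical CDF as CSV (d, F)
#' @export
write_nnd_csv <- function(res, path) {
  d <- sort(res$d_um)
  df <- data.frame(d_um = d, F = res$cdf(d))
  atomic_write(path, function(tmp)
    write.csv(df, tmp, row.names = FALSE, quote = FALSE))
  invisible(path)
}
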