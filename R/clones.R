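#' Labelled 3-D point pattern with clone identities
#'
#' @param points_um numeric matrix (n x 3), soma positions in micrometres.
#' @param clone_ids character/integer vector of clone (barcode) identities.
#' @param fluor_labels optional fluorophore labels (default "EGFP").
#' @param region optional region label per point.
#' @return An object of class `clone_set` (data frame with columns
#'   x_um, y_um, z_um, clone_id, label, region).
#' @export
clone_set <- function(points_um, clone_ids,
                      fluor_labels = rep("EGFP", nrow(points_um)),
                      region = rep("cortex", nrow(points_um))) {
  points_um <- matrix(as.numeric(points_um), ncol = 3)
  n <- nrow(points_um)
  stopifnot(length(clone_ids) == n, length(fluor_labels) == n,
            length(region) == n, all(is.finite(points_um)) || n == 0)
  df <- data.frame(x_um = points_um[, 1], y_um = points_um[, 2],
                   z_um = points_um[, 3], clone_id = as.character(clone_ids),
                   label = as.character(fluor_labels),
                   region = as.character(region))
  structure(df, class = c("clone_set", "data.frame"))
}

clone_points <- function(cs) as.matrix(cs[, c("x_um", "y_um", "z_um")])

#' Generate a clonal spatial point pattern
#'
#' Clone centres are placed uniformly in a cubic volume; clone members are
#' isotropic Gaussian offsets (s.d. `clone_sd_um`) around their centre.
#' `labelling_density` retains each clone independently, emulating the
#' low-titre versus high-titre labelling contrast: at low density the
#' surviving clones form spatially isolated clusters.
#'
#' @param n_clones number of candidate clones.
#' @param mean_clone_size mean cells per clone (sizes are 1 + Poisson).
#' @param clone_sd_um within-clone dispersion (>= 0).
#' @param volume_um3 cubic volume (micrometres cubed).
#' @param labelling_density probability in (0, 1] that a clone is labelled.
#' @param seed integer seed.
#' @param labels fluorophore labels assigned per clone (recycled at random).
#' @return A [clone_set()]; empty (zero rows) if no clone survives sampling.
#' @export
make_clonal_pattern <- function(n_clones, mean_clone_size = 4,
                                clone_sd_um = 50, volume_um3 = 1000^3,
                                labelling_density = 1, seed,
                                labels = c("EGFP", "mCherry")) {
  stopifnot(clone_sd_um >= 0, labelling_density > 0, labelling_density <= 1)
  if (missing(seed)) stopf("a seed is required")
  side <- volume_um3^(1 / 3)
  with_seed(seed, {
    keep <- which(runif(n_clones) <= labelling_density)
    if (length(keep) == 0)
      return(clone_set(matrix(numeric(), 0, 3), character()))
    pts <- list(); ids <- character(); labs <- character()
    for (c_id in keep) {
      centre <- runif(3) * side
      size <- 1L + rpois(1, max(mean_clone_size - 1, 0))
      offs <- matrix(rnorm(3 * size, 0, clone_sd_um), ncol = 3)
      pts[[length(pts) + 1]] <- sweep(offs, 2, centre, `+`)
      ids <- c(ids, rep(sprintf("clone_%03d", c_id), size))
      labs <- c(labs, rep(sample(labels, 1), size))
    }
    clone_set(do.call(rbind, pts), ids, labs)
  })
}

#' Read / write clone sets as CSV
#'
#' Column layout: x_um, y_um, z_um, clone_id, label, region.
#' @param path file path.
#' @export
read_clone_set <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("x_um", "y_um", "z_um", "clone_id")
  if (!all(need %in% names(df)))
    stopf("clone-set CSV %s lacks columns: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  clone_set(as.matrix(df[, c("x_um", "y_um", "z_um")]), df$clone_id,
            df$label %||% rep("EGFP", nrow(df)),
            df$region %||% rep("cortex", nrow(df)))
}

#' @rdname read_clone_set
#' @param cs a [clone_set()].
#' @export
write_clone_set <- function(cs, path) {
  atomic_write(path, function(tmp)
    write.csv(as.data.frame(cs), tmp, row.names = FALSE, quote = FALSE))
  invisible(path)
}

#' Ingest a barcoded clonal dataset
#'
#' Reads an externally produced table of barcoded interneuron coordinates
#' (one row per cell) and maps its columns onto the [clone_set()] layout.
#' The default mapping expects columns x, y, z (micrometres), barcode and
#' optionally region; 2-D tables are accepted with z set to 0.
#'
#' @param path CSV path.
#' @param mapping named character vector mapping clone_set fields to the
#'   file's column names.
#' @param region_filter optional region to keep (e.g. "cortex").
#' @export
read_barcoded_csv <- function(path,
                              mapping = c(x_um = "x", y_um = "y", z_um = "z",
                                          clone_id = "barcode",
                                          region = "region"),
                              region_filter = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (f in c("x_um", "y_um", "clone_id")) {
    if (!mapping[[f]] %in% names(df))
      stopf("barcoded CSV %s lacks mapped column '%s' for %s", path,
            mapping[[f]], f)
  }
  z <- if (mapping[["z_um"]] %in% names(df)) df[[mapping[["z_um"]]]] else 0
  region <- if (!is.na(mapping["region"]) && mapping[["region"]] %in% names(df))
    df[[mapping[["region"]]]] else rep("cortex", nrow(df))
  cs <- clone_set(cbind(df[[mapping[["x_um"]]]], df[[mapping[["y_um"]]]], z),
                  df[[mapping[["clone_id"]]]], region = region)
  if (!is.null(region_filter)) cs <- cs[cs$region %in% region_filter, ]
  structure(cs, class = c("clone_set", "data.frame"))
}
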