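## Spectral diversity metrics: distance-based (MSD, SD, ^qD(SM)) and
## spectral-species-based (cluster pixels with PAM at a k chosen by an
## ensemble of cluster-validity indices, then treat cluster proportions as
## abundances).

#' Euclidean distance matrix among valid pixel spectra
#'
#' @param cube a cleaned [plot_cube] (or a pixel x band matrix).
#' @param method `"euclidean"` (default) or `"cosine"`.
#' @return symmetric pixel distance matrix.
#' @export
spectral_distance_matrix <- function(cube, method = c("euclidean", "cosine")) {
  method <- match.arg(method)
  px <- if (inherits(cube, "plot_cube")) valid_pixels(cube) else as.matrix(cube)
  if (nrow(px) < 2) stop("need >= 2 valid pixels", call. = FALSE)
  if (method == "euclidean") {
    as.matrix(stats::dist(px))
  } else {
    nrm <- sqrt(rowSums(px^2))
    cs <- tcrossprod(px / nrm)
    d <- 1 - cs
    d[d < 0] <- 0
    diag(d) <- 0
    d
  }
}

#' Mean spectral distance (MSD)
#'
#' @param d pixel distance matrix.
#' @return mean pairwise distance over pixels.
#' @export
msd <- function(d) mean_pairwise_distance(d)

#' Spectral diversity (SD): total pixel-dendrogram branch length
#'
#' The spectral analogue of root-inclusive phylogenetic diversity: total
#' branch length of the UPGMA dendrogram built from the pixel distance
#' matrix.  Identical pixels contribute no length.
#'
#' @param d pixel distance matrix (>= 2 pixels).
#' @return total dendrogram branch length.
#' @export
spectral_sd <- function(d) {
  check_distance_matrix(d)
  if (nrow(d) < 2) stop("need >= 2 pixels", call. = FALSE)
  if (max(d) == 0) return(0)
  if (nrow(d) == 2) return(d[1, 2])
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  sum(tr$edge.length)
}

#' Spectral dispersion at diversity order zero, ^0D(SM)
#'
#' `1 + (n - 1) * M'` with `M'` the mean scaled pairwise pixel distance —
#' the q = 0 reduction of the dispersion metric under equal pixel weights.
#'
#' @param d pixel distance matrix.
#' @param scaling_max maximum distance used to scale into [0, 1] (default:
#'   the matrix's own maximum; pass a run-wide maximum for comparability).
#' @return dispersion value in [1, n].
#' @export
spectral_dispersion_q0 <- function(d, scaling_max = max(d)) {
  check_distance_matrix(d)
  n <- nrow(d)
  if (n < 2) return(1)
  if (scaling_max <= 0) return(1)
  ds <- d / scaling_max
  if (any(ds > 1 + 1e-12))
    stop("distances exceed 1 after scaling", call. = FALSE)
  1 + (n - 1) * mean(ds[upper.tri(ds)])
}

#' Partitioning Around Medoids on a distance matrix
#'
#' BUILD + SWAP k-medoids (the `cluster` package's original PAM algorithm),
#' deterministic for a given distance matrix.
#'
#' @param d distance matrix (or pixel matrix, converted via
#'   [spectral_distance_matrix()]).
#' @param k number of clusters, `1 <= k <= n`.
#' @return list with `assignment` (integer vector) and `medoids` (indices).
#' @export
pam_cluster <- function(d, k) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) d <- spectral_distance_matrix(d)
  n <- nrow(d)
  if (k > n) stop("k cannot exceed the number of points", call. = FALSE)
  if (k == n)
    return(list(assignment = seq_len(n), medoids = seq_len(n)))
  if (k == 1)
    return(list(assignment = rep(1L, n),
                medoids = which.min(colSums(d))[1]))
  fit <- cluster::pam(stats::as.dist(d), k = k, diss = TRUE,
                      variant = "original")
  list(assignment = as.integer(fit$clustering), medoids = as.integer(fit$id.med))
}

#' Spectral-species diversity from a cluster assignment
#'
#' Cluster relative sizes are treated as abundances: richness (q = 0),
#' Shannon (q = 1) and Simpson (q = 2).
#'
#' @param assignment integer cluster labels.
#' @return named vector `c(SS_q0, SS_q1, SS_q2)`.
#' @export
spectral_species_metrics <- function(assignment) {
  if (!length(assignment)) stop("empty assignment", call. = FALSE)
  p <- as.numeric(table(assignment)) / length(assignment)
  c(SS_q0 = length(p), SS_q1 = -sum(p * log(p)), SS_q2 = 1 - sum(p^2))
}

#' Estimate spectral species for one plot
#'
#' Subsamples valid pixels to `max_pixels` (seeded), chooses the number of
#' clusters with [estimate_cluster_number()], partitions with
#' [pam_cluster()] and returns the spectral-species metrics.
#'
#' @param cube cleaned [plot_cube].
#' @param k_range candidate cluster numbers (default `2:min(20, n - 1)`).
#' @param indices validity indices passed to [estimate_cluster_number()].
#' @param max_pixels pixel subsampling cap before O(n^2) work (default 400).
#' @param seed seed for the pixel subsample.
#' @return list with `k`, `per_index`, `assignment`, `pixel_index` (indices
#'   of the used rows within the valid-pixel set), `sizes`, `metrics`.
#' @export
spectral_species <- function(cube, k_range = NULL, indices = NULL,
                             max_pixels = 400, seed = 1) {
  px <- valid_pixels(cube)
  idx <- seq_len(nrow(px))
  if (nrow(px) > max_pixels) {
    idx <- sort(with_seed(seed, sample(nrow(px), max_pixels)))
    px <- px[idx, , drop = FALSE]
  }
  est <- estimate_cluster_number(px, k_range = k_range, indices = indices)
  fit <- pam_cluster(spectral_distance_matrix(px), est$k)
  sizes <- as.integer(table(fit$assignment))
  list(k = est$k, per_index = est$per_index, assignment = fit$assignment,
       pixel_index = idx, sizes = sizes,
       metrics = spectral_species_metrics(fit$assignment))
}

#' Distance- and cluster-based spectral metrics for a set of plots
#'
#' @param cubes named list of cleaned [plot_cube]s (rejections are skipped).
#' @param site optional site id per plot (recycled into the output).
#' @param max_pixels pixel cap per plot.
#' @param k_range candidate cluster numbers for the spectral-species step.
#' @param seed root seed.
#' @return long data.frame (plot, site, dimension, metric, q, value) with
#'   MSD, SD, ^0D(SM) (scaled by the run-wide maximum pixel distance) and
#'   SS metrics at q = 0, 1, 2.
#' @export
compute_spectral_metrics <- function(cubes, site = NULL, max_pixels = 400,
                                     k_range = NULL, seed = 1) {
  keep <- !vapply(cubes, inherits, logical(1), what = "plot_rejection")
  cubes <- cubes[keep]
  site <- if (is.null(site)) rep(NA_character_, length(cubes)) else site[keep]
  dists <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    px <- valid_pixels(cubes[[i]])
    if (nrow(px) > max_pixels) {
      idx <- with_seed(child_seed(seed, "clustering", i),
                       sample(nrow(px), max_pixels))
      px <- px[sort(idx), , drop = FALSE]
    }
    dists[[i]] <- spectral_distance_matrix(px)
  }
  dmax <- max(vapply(dists, max, numeric(1)))
  rows <- vector("list", length(cubes))
  for (i in seq_along(cubes)) {
    d <- dists[[i]]
    ss <- spectral_species(cubes[[i]], k_range = k_range,
                           max_pixels = max_pixels,
                           seed = child_seed(seed, "clustering", i))
    rows[[i]] <- data.frame(
      plot = names(cubes)[i], site = site[i], dimension = "spectral",
      metric = c("MSD", "SD", "qDSM", "SS", "SS", "SS"),
      q = c(NA, NA, 0, 0, 1, 2),
      value = c(msd(d), spectral_sd(d),
                spectral_dispersion_q0(d, scaling_max = dmax),
                ss$metrics))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
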