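## Pairwise community dissimilarity (PCD): the variance of one community's
## tip states, conditional on the other community, relative to the variance
## expected for random draws from the species pool.  Decomposes
## multiplicatively into a compositional part (species overlap only) and a
## phylogenetic/trait part (relationships of nonshared species).

#' Tip-state correlation matrix of an ultrametric tree
#'
#' Shared-path-length covariance of tip states under Brownian motion,
#' scaled to unit diagonal.  A star tree yields the identity matrix.
#'
#' @param tree ultrametric [ape::phylo] (phylogeny or calibrated trait
#'   dendrogram).
#' @return species correlation matrix.
#' @export
phylo_correlation <- function(tree) {
  if (!is_ultrametric_tol(tree, 1e-6))
    stop("tree must be ultrametric", call. = FALSE)
  V <- ape::vcv(tree)
  stats::cov2cor(V)
}

## Phylogenetic species variability of a covariance submatrix:
## mean variance minus mean covariance, normalized; for a correlation
## matrix this is 1 minus the mean off-diagonal correlation.
.psv <- function(C) {
  n <- nrow(C)
  denom <- if (n > 1) n * (n - 1) else n * n
  (n * sum(diag(C)) - sum(C)) / denom
}

## Conditional covariance of set `a` given values observed on set `b`.
.cond_cov <- function(V, a, b) {
  Cab <- V[a, b, drop = FALSE]
  V[a, a, drop = FALSE] -
    Cab %*% solve(V[b, b, drop = FALSE], t(Cab))
}

#' Monte-Carlo expectations for the PCD denominator
#'
#' For each richness value `1..max_richness`, estimates the expected
#' conditional phylogenetic species variability of a random community given
#' another random community of that richness, plus the pool-level PSV.
#'
#' @param V pool correlation matrix.
#' @param max_richness largest conditioning-community richness needed.
#' @param reps Monte-Carlo replicates per richness.
#' @param seed integer seed.
#' @return list with `cond_psv` (length `max_richness`) and `pool_psv`.
#' @export
pcd_expectations <- function(V, max_richness, reps = 1000, seed = 1) {
  n <- nrow(V)
  cond <- numeric(max_richness)
  with_seed(seed, {
    for (r in seq_len(max_richness)) {
      vals <- numeric(reps)
      for (t in seq_len(reps)) {
        a <- sample.int(n, 2)
        b <- sample.int(n, r)
        vals[t] <- .psv(.cond_cov(V, a, b))
      }
      cond[r] <- mean(vals)
    }
  })
  list(cond_psv = cond, pool_psv = .psv(V))
}

#' PCD between two communities
#'
#' The observed statistic is the richness-weighted conditional phylogenetic
#' species variability (PSV) of each community given the other, relative to
#' the communities' unconditional PSV; it is normalized by the expectation
#' of the same statistic for random assemblages from the pool, so random
#' draws expect PCD = 1.  The compositional component compares the Sorensen
#' overlap against its random expectation; the phylogenetic (or trait)
#' component is `PCD_total / PCD_COMP`, giving the multiplicative
#' decomposition `PCD_total = PCD_COMP * PCD_PHY`.
#'
#' @param V pool correlation matrix (labelled).
#' @param a,b character vectors of member species.
#' @param expectations output of [pcd_expectations()] covering
#'   `max(|a|, |b|)`.
#' @return list with `pcd`, `pcd_comp`, `pcd_phy`, and the overlap count.
#' @export
pcd_pair <- function(V, a, b, expectations) {
  if (!length(a) || !length(b)) stop("empty community", call. = FALSE)
  sp <- rownames(V)
  ia <- match(a, sp); ib <- match(b, sp)
  if (anyNA(ia) || anyNA(ib)) stop("species missing from pool", call. = FALSE)
  n1 <- length(ia); n2 <- length(ib)
  if (setequal(ia, ib)) {
    shared <- n1
    return(list(pcd = 0, pcd_comp = 0, pcd_phy = NA_real_, shared = shared))
  }
  S11 <- .cond_cov(V, ia, ib)
  S22 <- .cond_cov(V, ib, ia)
  obs <- (n1 * .psv(S11) + n2 * .psv(S22)) /
    (n1 * .psv(V[ia, ia, drop = FALSE]) + n2 * .psv(V[ib, ib, drop = FALSE]))
  expct <- (n1 * expectations$cond_psv[n2] + n2 * expectations$cond_psv[n1]) /
    ((n1 + n2) * expectations$pool_psv)
  pcd <- obs / expct
  shared <- length(intersect(ia, ib))
  obs_dissim <- 1 - 2 * shared / (n1 + n2)
  n <- nrow(V)
  exp_dissim <- 1 - 2 * n1 * n2 / ((n1 + n2) * n)
  pcd_comp <- obs_dissim / exp_dissim
  list(pcd = pcd, pcd_comp = pcd_comp, pcd_phy = pcd / pcd_comp,
       shared = shared)
}

#' All-pairs PCD table for a community matrix
#'
#' @param V pool correlation matrix from [phylo_correlation()].
#' @param community a `community_table` or a plots x species presence /
#'   cover matrix.
#' @param reps Monte-Carlo replicates for the expectations.
#' @param seed integer seed.
#' @param dimension label recorded in the output (e.g. `"phylogenetic"`,
#'   `"trait"`).
#' @return data.frame with one row per unordered plot pair: `plot_a`,
#'   `plot_b`, `dimension`, `pcd_total`, `pcd_comp`, `pcd_phy`.
#' @export
pcd_matrix <- function(V, community, reps = 1000, seed = 1,
                       dimension = "phylogenetic") {
  cover <- if (inherits(community, "community_table")) community$cover
  else as.matrix(community)
  keep <- rowSums(cover > 0) >= 1
  if (any(!keep)) warning(sum(!keep), " empty plot(s) skipped")
  cover <- cover[keep, , drop = FALSE]
  m <- nrow(cover)
  if (m < 2) stop("need >= 2 plots", call. = FALSE)
  members <- apply(cover > 0, 1, function(r) colnames(cover)[r],
                   simplify = FALSE)
  maxr <- max(lengths(members))
  ex <- pcd_expectations(V, maxr, reps = reps, seed = seed)
  out <- vector("list", m * (m - 1) / 2)
  k <- 0
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      k <- k + 1
      r <- pcd_pair(V, members[[i]], members[[j]], ex)
      out[[k]] <- data.frame(plot_a = rownames(cover)[i],
                             plot_b = rownames(cover)[j],
                             dimension = dimension,
                             pcd_total = r$pcd, pcd_comp = r$pcd_comp,
                             pcd_phy = r$pcd_phy)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
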