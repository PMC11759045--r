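## Plot-level diversity metrics for the taxonomic, trait and phylogenetic
## dimensions: Hill-style taxonomic metrics (S, H, D), mean pairwise
## distance (MTD/MPD depending on the distance matrix supplied), Faith's PD
## with the stem path to the root, the dispersion metric ^qD(.M), and SES
## standardization against a taxa-label randomization null.

#' Relative abundances of one plot
#'
#' @param cover named percent-cover vector (one plot row).
#' @return named vector of relative abundances `p_i` (zero-cover species
#'   dropped), summing to 1.
#' @export
relative_abundance <- function(cover) {
  keep <- !is.na(cover) & cover > 0
  if (!any(keep)) stop("all covers are zero", call. = FALSE)
  p <- cover[keep] / sum(cover[keep])
  p
}

#' Taxonomic diversity: richness, Shannon, Simpson
#'
#' `S` counts species, `H = -sum p_i log p_i` (order q = 1) and
#' `D = 1 - sum p_i^2` (order q = 2).
#'
#' @param p relative-abundance vector from [relative_abundance()].
#' @return named numeric vector `c(S, H, D)`.
#' @export
taxonomic_metrics <- function(p) {
  c(S = sum(p > 0), H = -sum(p * log(p)), D = 1 - sum(p^2))
}

#' Mean pairwise distance among community members
#'
#' Unweighted mean of distances over unordered pairs; called MTD, MPD or MSD
#' depending on whether `d` holds trait, phylogenetic or spectral distances.
#'
#' @param d symmetric distance matrix.
#' @param members character vector of member labels (or indices); all rows
#'   by default.
#' @return the mean pairwise distance; `NA` when fewer than 2 members.
#' @export
mean_pairwise_distance <- function(d, members = NULL) {
  check_distance_matrix(d)
  if (is.null(members)) members <- seq_len(nrow(d))
  sub <- d[members, members, drop = FALSE]
  n <- nrow(sub)
  if (n < 2) return(NA_real_)
  sum(sub[upper.tri(sub)]) / (n * (n - 1) / 2)
}

#' Faith's phylogenetic diversity (root-inclusive)
#'
#' Sum of branch lengths of the minimal subtree connecting `members`,
#' including the stem path to the root; a single member yields its
#' root-to-tip path length.
#'
#' @param tree [ape::phylo] tree with branch lengths.
#' @param members tip labels.
#' @return total branch length.
#' @export
faith_pd <- function(tree, members) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  unknown <- setdiff(members, tree$tip.label)
  if (length(unknown))
    stop("unknown member(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  tips <- match(unique(members), tree$tip.label)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(n_tip + tree$Nnode)
  elen <- numeric(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  on_path <- logical(n_tip + tree$Nnode)
  for (t in tips) {
    v <- t
    while (v != root && !on_path[v]) {
      on_path[v] <- TRUE
      v <- parent[v]
    }
  }
  sum(elen[on_path])
}

#' Patristic (tip-to-tip path length) distance matrix
#'
#' @param tree [ape::phylo] tree with branch lengths.
#' @return symmetric labelled distance matrix.
#' @export
patristic_matrix <- function(tree) {
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  as.matrix(stats::cophenetic(tree))
}

#' Standardized effect size against a randomization null
#'
#' `z = (obs - mean(null)) / sd(null)` with the null distribution produced by
#' `null_generator`, typically a taxa-label shuffle holding plot richness
#' fixed.  Positive z indicates overdispersion, negative z clustering.
#'
#' @param observed observed metric value.
#' @param null_generator function of no arguments returning one null value.
#' @param n_null number of null replicates (>= 99).
#' @param seed integer seed.
#' @return list with `observed`, `null_mean`, `null_sd`, `z`, `n_null`, `seed`.
#' @export
ses_standardize <- function(observed, null_generator, n_null = 999, seed = 1) {
  if (n_null < 99) stop("n_null must be >= 99", call. = FALSE)
  null <- with_seed(seed, vapply(seq_len(n_null),
                                 function(i) null_generator(), numeric(1)))
  m <- mean(null)
  s <- stats::sd(null)
  if (s == 0) stop("degenerate null (sd = 0)", call. = FALSE)
  list(observed = observed, null_mean = m, null_sd = s,
       z = (observed - m) / s, n_null = n_null, seed = seed)
}

#' SES of the mean pairwise distance for one plot
#'
#' Taxa-label null: `n_null` random draws of the same richness from the
#' species pool (the labels of `d`), recomputing the mean pairwise distance.
#'
#' @param d pool-wide distance matrix.
#' @param members community member labels (>= 2).
#' @param n_null,seed see [ses_standardize()].
#' @return as [ses_standardize()].
#' @export
ses_mpd <- function(d, members, n_null = 999, seed = 1) {
  obs <- mean_pairwise_distance(d, members)
  s <- length(members)
  pool <- nrow(d)
  pairs_mean <- function() {
    idx <- sample.int(pool, s)
    sub <- d[idx, idx]
    sum(sub[upper.tri(sub)]) / (s * (s - 1) / 2)
  }
  ses_standardize(obs, pairs_mean, n_null = n_null, seed = seed)
}

#' Dispersion: the effective number of distinct species, ^qD(.M)
#'
#' Composite dispersion metric over a distance matrix scaled to [0, 1]:
#' per-species mean distances `m_i = sum_{j != i} d_ij / (S - 1)`, magnitude
#' of dispersion `M' = mean(m_i)`, a Hill aggregation of the dispersion
#' profile `w_i` (by default abundance-weighted, `w_i` proportional to
#' `p_i * m_i`) giving the effective number of equally distinct species
#' `qD(T)`, evenness `qE(T) = qD(T)/S`, and finally
#' `qD(TM) = 1 + (S - 1) * qE(T) * M'`, which ranges from 1 (no dispersion)
#' to S (all species maximally distinct, uniform abundance).  At q = 0 the
#' profile reduces to counting, so `0D(TM) = 1 + (S - 1) * M'`.
#'
#' @param d symmetric distance matrix for the community, pre-scaled to
#'   [0, 1] (divide by the analysis-wide maximum; see `scaling_max`).
#' @param p relative abundances aligned with `d` rows.
#' @param q diversity order (0, 1 or 2).
#' @param scaling_max optional maximum used to scale `d` before computing.
#' @param abundance_weighted logical; if `FALSE` the profile uses
#'   `w_i` proportional to `m_i` alone.
#' @return list with `S`, `m_i`, `M`, `qDT`, `qET`, `qDTM`.
#' @export
dispersion_qD <- function(d, p, q = 0, scaling_max = NULL,
                          abundance_weighted = TRUE) {
  if (!q %in% c(0, 1, 2)) stop("q must be 0, 1 or 2", call. = FALSE)
  check_distance_matrix(d)
  if (!is.null(scaling_max)) d <- d / scaling_max
  S <- length(p)
  if (nrow(d) != S) stop("p and d dimensions differ", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-9) stop("abundances must sum to 1", call. = FALSE)
  if (S == 1)
    return(list(S = 1L, m_i = NA_real_, M = NA_real_, qDT = 1, qET = 1, qDTM = 1))
  if (any(d > 1 + 1e-12))
    stop("distances exceed 1 after scaling", call. = FALSE)
  m_i <- rowSums(d) / (S - 1)
  M <- mean(m_i)
  if (all(m_i == 0))
    return(list(S = S, m_i = m_i, M = 0, qDT = S, qET = 1, qDTM = 1))
  w <- if (abundance_weighted) p * m_i else m_i
  w <- w / sum(w)
  qDT <- if (q == 0) {
    sum(w > 0)
  } else if (q == 1) {
    nz <- w[w > 0]
    exp(-sum(nz * log(nz)))
  } else {
    1 / sum(w^2)
  }
  qET <- qDT / S
  list(S = S, m_i = m_i, M = M, qDT = qDT, qET = qET,
       qDTM = 1 + (S - 1) * qET * M)
}

#' Plot-level metric table across dimensions
#'
#' Computes the full set of ground metrics for every plot of a community
#' table: taxonomic S/H/D; trait MTD, its SES z, and ^qD(TM) at q = 0,1,2;
#' phylogenetic PD, MPD, their SES z, and ^qD(PM) at q = 0,1,2.  Distances
#' are scaled per dimension by the maximum across the whole run.
#'
#' @param community a `community_table` (see [assemble_communities()]).
#' @param tree pool phylogeny ([ape::phylo]).
#' @param trait_dist pool-wide trait distance matrix (e.g. [gower_distance()]).
#' @param n_null,seed SES null replicates and seed (`n_null = 0` skips SES).
#' @return long data.frame: plot, site, dimension, metric, q, value, z.
#' @export
compute_ground_metrics <- function(community, tree, trait_dist,
                                   n_null = 999, seed = 1) {
  cover <- community$cover
  pd_mat <- patristic_matrix(tree)
  sp <- colnames(cover)
  pd_mat <- pd_mat[sp, sp]
  trait_dist <- trait_dist[sp, sp]
  max_t <- max(trait_dist)
  max_p <- max(pd_mat)
  rows <- vector("list", nrow(cover))
  for (i in seq_len(nrow(cover))) {
    p <- relative_abundance(cover[i, ])
    members <- names(p)
    tm <- taxonomic_metrics(p)
    rec <- data.frame(
      plot = rownames(cover)[i], site = as.character(community$site[i]),
      dimension = "taxonomic", metric = c("S", "H", "D"), q = c(0, 1, 2),
      value = as.numeric(tm), z = NA_real_)
    for (dim in c("trait", "phylogenetic")) {
      dmat <- if (dim == "trait") trait_dist else pd_mat
      dmax <- if (dim == "trait") max_t else max_p
      mpd <- mean_pairwise_distance(dmat, members)
      z <- NA_real_
      if (n_null > 0 && length(members) >= 2) {
        z <- ses_mpd(dmat, members, n_null = n_null,
                     seed = child_seed(seed, "nulls", i))$z
      }
      disp <- vapply(c(0, 1, 2), function(q) {
        if (length(members) < 2) return(1)
        dispersion_qD(dmat[members, members] / dmax, p, q = q)$qDTM
      }, numeric(1))
      lab <- if (dim == "trait") c("MTD", "qDTM") else c("MPD", "qDPM")
      rec <- rbind(rec, data.frame(
        plot = rownames(cover)[i], site = as.character(community$site[i]),
        dimension = dim,
        metric = c(lab[1], rep(lab[2], 3)), q = c(NA, 0, 1, 2),
        value = c(mpd, disp), z = c(z, rep(NA_real_, 3))))
      if (dim == "phylogenetic") {
        pdv <- faith_pd(tree, members)
        zpd <- NA_real_
        if (n_null > 0) {
          zpd <- ses_standardize(
            pdv, function() faith_pd(tree, sample(sp, length(members))),
            n_null = max(99, min(n_null, 199)),
            seed = child_seed(seed, "nulls", i + nrow(cover)))$z
        }
        rec <- rbind(rec, data.frame(
          plot = rownames(cover)[i], site = as.character(community$site[i]),
          dimension = "phylogenetic", metric = "PD", q = NA,
          value = pdv, z = zpd))
      }
    }
    rows[[i]] <- rec
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
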