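## Ensemble estimation of the number of spectral species per plot: ten
## cluster-validity indices are each evaluated over a range of k-medoids
## partitions of the pixel spectra, each proposes an optimal k, and the
## chosen k is the round-half-up mean of the per-index optima.  Indices are
## guarded against the zero-within-variance case (pure, noise-free pixel
## groups) where within-cluster sums of squares vanish at the true k.

## Within/between sums of squares of a partition of rows of x.
.partition_ss <- function(x, assignment) {
  k <- max(assignment)
  centroid <- rowsum(x, assignment) / as.numeric(table(assignment))
  wss_k <- numeric(k)
  for (g in seq_len(k)) {
    rows <- assignment == g
    wss_k[g] <- sum(sweep(x[rows, , drop = FALSE], 2, centroid[g, ])^2)
  }
  gmean <- colMeans(x)
  bss <- sum(as.numeric(table(assignment)) *
               rowSums(sweep(centroid, 2, gmean)^2))
  list(wss = sum(wss_k), wss_k = wss_k, bss = bss, centroid = centroid,
       sizes = as.numeric(table(assignment)))
}

## safe ratio with 0/0 -> `both_zero`
.sratio <- function(a, b, both_zero = 1) {
  ifelse(b == 0, ifelse(a == 0, both_zero, Inf), a / b)
}

## --- individual validity indices -------------------------------------------
## Each receives: ks (candidate k >= 2), W (named W_k including k = 1),
## st/parts aligned with ks, x, d, n, p; returns the proposed k.

.idx_ch <- function(st, ks, n) {            # Calinski-Harabasz: maximize
  ch <- vapply(seq_along(ks), function(i)
    .sratio(st[[i]]$bss / (ks[i] - 1), st[[i]]$wss / (n - ks[i]),
            both_zero = 0), numeric(1))
  ks[which.max(ch)]
}

.idx_hartigan <- function(W, ks, n) {       # smallest k with H(k) <= 10
  kk <- as.integer(names(W))
  H <- vapply(seq_len(length(W) - 1), function(i)
    (.sratio(W[i], W[i + 1]) - 1) * (n - kk[i] - 1), numeric(1))
  cand <- kk[seq_len(length(W) - 1)]
  ok <- cand %in% ks & is.finite(H) & H <= 10
  if (any(ok)) return(cand[ok][1])
  ## fallback: k after the largest improvement
  ks[min(which.max(H[cand %in% ks]) + 1, length(ks))]
}

.idx_kl <- function(W, ks, p) {             # Krzanowski-Lai: maximize
  kk <- as.integer(names(W))
  DIFF <- vapply(seq.int(2, length(W)), function(i)
    kk[i - 1]^(2 / p) * W[i - 1] - kk[i]^(2 / p) * W[i], numeric(1))
  ## DIFF[j] corresponds to k = kk[j + 1]; KL(k) = |DIFF_k| / |DIFF_{k+1}|
  if (length(DIFF) < 2) return(ks[1])
  kl <- vapply(seq_len(length(DIFF) - 1), function(j)
    .sratio(abs(DIFF[j]), abs(DIFF[j + 1]), both_zero = 0), numeric(1))
  cand <- kk[seq.int(2, length(W) - 1)]
  keep <- cand %in% ks
  if (!any(keep)) return(ks[1])
  cand[keep][which.max(kl[keep])]
}

.idx_silhouette <- function(d, parts, ks) { # maximize mean silhouette width
  sw <- vapply(seq_along(ks), function(i) {
    s <- cluster::silhouette(parts[[i]], dmatrix = d)
    v <- s[, "sil_width"]
    mean(ifelse(is.finite(v), v, 0))
  }, numeric(1))
  ks[which.max(sw)]
}

.idx_cindex <- function(d, parts, ks) {     # minimize C-index
  dv <- d[upper.tri(d)]
  dv_sorted <- sort(dv)
  ci <- vapply(seq_along(ks), function(i) {
    a <- parts[[i]]
    within <- outer(a, a, "==")[upper.tri(d)]
    sw <- sum(dv[within])
    nw <- sum(within)
    smin <- sum(dv_sorted[seq_len(nw)])
    smax <- sum(dv_sorted[seq.int(length(dv) - nw + 1, length(dv))])
    if (smax == smin) 0 else (sw - smin) / (smax - smin)
  }, numeric(1))
  ks[which.min(ci)]
}

.idx_db <- function(st, ks) {               # minimize Davies-Bouldin
  db <- vapply(seq_along(ks), function(i) {
    k <- ks[i]
    if (k == 1) return(Inf)
    disp <- sqrt(st[[i]]$wss_k / st[[i]]$sizes)
    dc <- as.matrix(stats::dist(st[[i]]$centroid))
    r <- vapply(seq_len(k), function(g) {
      others <- setdiff(seq_len(k), g)
      max(.sratio(disp[g] + disp[others], dc[g, others], both_zero = 0))
    }, numeric(1))
    mean(r)
  }, numeric(1))
  ks[which.min(db)]
}

## Duda-Hart: smallest k whose partition has no cluster worth splitting
## (a split is justified when Je(2)/Je(1) falls below the critical value).
.idx_duda <- function(x, parts, ks, z = 3.2, tss = NULL) {
  p <- ncol(x)
  if (is.null(tss)) tss <- sum(sweep(x, 2, colMeans(x))^2)
  splittable <- function(rows) {
    ## the two-group test is meaningless on a handful of points
    if (length(rows) < 8) return(FALSE)
    sub <- x[rows, , drop = FALSE]
    je1 <- sum(sweep(sub, 2, colMeans(sub))^2)
    if (je1 <= 1e-9 * tss) return(FALSE)
    two <- pam_cluster(spectral_distance_matrix(sub), 2)$assignment
    je2 <- .partition_ss(sub, two)$wss
    crit <- 1 - 2 / (pi * p) -
      z * sqrt(2 * (1 - 8 / (pi^2 * p)) / (length(rows) * p))
    (je2 / je1) < max(crit, 0.1)
  }
  for (i in seq_along(ks)) {
    a <- parts[[i]]
    if (!any(vapply(split(seq_along(a), a), splittable, logical(1))))
      return(ks[i])
  }
  ks[length(ks)]
}

## Pseudo-t2 on successive partitions: smallest k whose refinement to k + 1
## no longer yields a large improvement.
.idx_pseudot2 <- function(W, ks, n, crit = 10) {
  kk <- as.integer(names(W))
  t2 <- vapply(seq_len(length(W) - 1), function(i)
    .sratio(W[i] - W[i + 1], W[i + 1] / max(n - kk[i + 1], 1),
            both_zero = 0), numeric(1))
  cand <- kk[seq_len(length(W) - 1)]
  ok <- cand %in% ks & t2 <= crit
  if (any(ok)) return(cand[ok][1])
  ks[length(ks)]
}

.idx_ratkowsky <- function(x, parts, ks) {  # maximize mean sqrt(BSS_j/TSS_j)/sqrt(k)
  tss_j <- colSums(sweep(x, 2, colMeans(x))^2)
  rl <- vapply(seq_along(ks), function(i) {
    a <- parts[[i]]
    cen <- rowsum(x, a) / as.numeric(table(a))
    bss_j <- colSums(as.numeric(table(a)) * sweep(cen, 2, colMeans(x))^2)
    mean(sqrt(pmin(.sratio(bss_j, tss_j, both_zero = 0), 1))) / sqrt(ks[i])
  }, numeric(1))
  ks[which.max(rl)]
}

.idx_ballhall <- function(W, ks) {          # largest drop of W/k
  kk <- as.integer(names(W))
  bh <- W / kk
  drops <- -diff(bh)                        # drop achieved AT kk[i + 1]
  cand <- kk[-1]
  keep <- cand %in% ks
  if (!any(keep)) return(ks[1])
  cand[keep][which.max(drops[keep])]
}

#' Estimate the number of spectral clusters with a validity-index ensemble
#'
#' Evaluates k-medoids partitions over `k_range` under ten cluster-validity
#' indices (Calinski-Harabasz, Hartigan, Krzanowski-Lai, silhouette,
#' C-index, Davies-Bouldin, Duda-Hart, pseudo-t2, Ratkowsky-Lance,
#' Ball-Hall); each proposes an optimum and the chosen k is the
#' round-half-up mean of the proposals.  Near-zero total variance
#' short-circuits to k = 1.
#'
#' @param x pixel x band matrix (>= 10 rows).
#' @param k_range candidate ks (default `2:min(20, n - 1)`).
#' @param indices subset of the ten index names to use.
#' @return list with `k` (chosen), `per_index` (named optima).
#' @export
estimate_cluster_number <- function(x, k_range = NULL, indices = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10) stop("need >= 10 pixels", call. = FALSE)
  all_idx <- c("ch", "hartigan", "kl", "silhouette", "cindex", "db",
               "duda", "pseudot2", "ratkowsky", "ballhall")
  indices <- if (is.null(indices)) all_idx else match.arg(indices, all_idx,
                                                          several.ok = TRUE)
  tss <- sum(sweep(x, 2, colMeans(x))^2)
  if (tss < 1e-12 * n)
    return(list(k = 1L, per_index = stats::setNames(rep(1, length(indices)),
                                                    indices)))
  if (is.null(k_range)) k_range <- 2:min(20, n - 1)
  ks <- sort(unique(pmin(pmax(as.integer(k_range), 2L), n - 1L)))
  d <- spectral_distance_matrix(x)
  parts <- lapply(ks, function(k) pam_cluster(d, k)$assignment)
  st <- lapply(parts, function(a) .partition_ss(x, a))
  ## flush floating-point dust: within-SS below 1e-9 of total is exact zero,
  ## otherwise ratio-based indices chase noise in separable partitions
  st <- lapply(st, function(s) {
    s$wss_k[s$wss_k < 1e-9 * tss] <- 0
    s$wss <- sum(s$wss_k)
    s
  })
  W <- c(tss, vapply(st, `[[`, numeric(1), "wss"))
  names(W) <- c(1L, ks)
  p <- ncol(x)
  opt <- vapply(indices, function(nm) {
    switch(nm,
           ch = .idx_ch(st, ks, n),
           hartigan = .idx_hartigan(W, ks, n),
           kl = .idx_kl(W, ks, p),
           silhouette = .idx_silhouette(d, parts, ks),
           cindex = .idx_cindex(d, parts, ks),
           db = .idx_db(st, ks),
           duda = .idx_duda(x, parts, ks, tss = tss),
           pseudot2 = .idx_pseudot2(W, ks, n),
           ratkowsky = .idx_ratkowsky(x, parts, ks),
           ballhall = .idx_ballhall(W, ks))
  }, numeric(1))
  k <- as.integer(floor(mean(opt) + 0.5))   # round half up
  list(k = k, per_index = opt)
}
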