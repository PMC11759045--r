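## Trait-table preparation and phylogenetic-comparative utilities:
## phylogenetic eigenvectors, random-forest trait imputation assisted by
## them, maximum-likelihood Pagel's lambda, BM-vs-OU model adequacy, Gower
## distances and the root-calibrated UPGMA trait dendrogram.

#' Phylogenetic eigenvectors from the patristic distance matrix
#'
#' Eigendecomposition of `-1/2 J D^2 J` (D patristic distances, J the
#' centering matrix), i.e. the principal-coordinate representation of the
#' phylogeny.  Vectors are orthogonal and ordered by non-increasing
#' eigenvalue.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param n_vectors number of eigenvectors to return; the default keeps the
#'   smallest set explaining 95% of the positive-eigenvalue trace, capped
#'   at 30.
#' @return list with `vectors` (species x E), `values`, `trace`.
#' @export
compute_phylo_eigenvectors <- function(tree, n_vectors = NULL) {
  if (length(tree$tip.label) < 3) stop("need >= 3 tips", call. = FALSE)
  D <- patristic_matrix(tree)
  if (max(D) == 0) stop("degenerate distances", call. = FALSE)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-10 * max(abs(e$values))
  values <- e$values[pos]
  vectors <- e$vectors[, pos, drop = FALSE]
  if (is.null(n_vectors)) {
    cum <- cumsum(values) / sum(values)
    n_vectors <- min(which(cum >= 0.95)[1], 30L, length(values))
  }
  if (n_vectors >= n) stop("n_vectors must be < n_tips", call. = FALSE)
  n_vectors <- min(n_vectors, length(values))
  vectors <- vectors[, seq_len(n_vectors), drop = FALSE]
  dimnames(vectors) <- list(rownames(D), paste0("PEV", seq_len(n_vectors)))
  list(vectors = vectors, values = values[seq_len(n_vectors)],
       trace = sum(diag(G)))
}

#' Impute missing trait values with phylogenetically informed random forests
#'
#' Iterative random-forest imputation: missing cells are initialized at
#' column means, then each incomplete trait is regressed on all other traits
#' plus the phylogenetic eigenvectors and its missing cells replaced by the
#' forest predictions, repeating until the imputations stop improving
#' (missForest-style stopping on the change in imputed values).  Observed
#' cells are never altered.
#'
#' @param traits species x trait numeric matrix with `NA`s.
#' @param eigenvectors optional species x E matrix from
#'   [compute_phylo_eigenvectors()]; rows matched by name.
#' @param n_vectors_used number of eigenvector columns used (default all).
#' @param seed integer seed.
#' @param max_iter iteration cap.
#' @param ntree forest size.
#' @return list with `traits` (completed matrix) and `oob_error` (per-trait
#'   out-of-bag MSE of the final forests, an imputation-error estimate).
#' @export
impute_traits <- function(traits, eigenvectors = NULL, n_vectors_used = NULL,
                          seed = 1, max_iter = 10, ntree = 100) {
  traits <- as.matrix(traits)
  miss <- is.na(traits)
  all_missing <- colnames(traits)[colSums(!miss) == 0]
  if (length(all_missing))
    stop("column(s) entirely missing: ", paste(all_missing, collapse = ", "),
         call. = FALSE)
  if (any(colSums(!miss) < 10))
    stop("each trait needs >= 10 observed values", call. = FALSE)
  if (!any(miss))
    return(list(traits = traits, oob_error = rep(0, ncol(traits))))
  X <- traits
  for (j in seq_len(ncol(X))) X[miss[, j], j] <- mean(X[!miss[, j], j])
  ev <- NULL
  if (!is.null(eigenvectors)) {
    ev <- eigenvectors[rownames(traits), , drop = FALSE]
    if (!is.null(n_vectors_used))
      ev <- ev[, seq_len(min(n_vectors_used, ncol(ev))), drop = FALSE]
  }
  ord <- order(colSums(miss))                    # least missing first
  prev_change <- Inf
  oob <- rep(NA_real_, ncol(X))
  names(oob) <- colnames(traits)
  with_seed(seed, {
    for (it in seq_len(max_iter)) {
      X_old <- X
      for (j in ord) {
        if (!any(miss[, j])) { oob[j] <- 0; next }
        pred <- cbind(X[, -j, drop = FALSE], ev)
        fit <- randomForest::randomForest(
          x = pred[!miss[, j], , drop = FALSE], y = X[!miss[, j], j],
          ntree = ntree)
        X[miss[, j], j] <- stats::predict(fit, pred[miss[, j], , drop = FALSE])
        oob[j] <- fit$mse[length(fit$mse)]
      }
      change <- sum((X[miss] - X_old[miss])^2) / max(sum(X[miss]^2), 1e-12)
      if (change >= prev_change) { X <- X_old; break }
      prev_change <- change
    }
  })
  X[!miss] <- traits[!miss]
  list(traits = X, oob_error = oob)
}

## Negative profile log-likelihood of the lambda-scaled BM model.
## Mean and rate are profiled out analytically (GLS).
.lambda_negll <- function(lambda, trait, V) {
  W <- lambda * V
  diag(W) <- diag(V)
  n <- length(trait)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  logdet <- 2 * sum(log(diag(ch)))
  Winv_y <- backsolve(ch, forwardsolve(t(ch), trait))
  Winv_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  mu <- sum(Winv_y) / sum(Winv_1)
  r <- trait - mu
  Winv_r <- backsolve(ch, forwardsolve(t(ch), r))
  s2 <- sum(r * Winv_r) / n
  0.5 * (n * log(2 * pi * s2) + logdet + n)
}

#' Maximum-likelihood estimate of Pagel's lambda
#'
#' The Brownian covariance's off-diagonal entries are multiplied by lambda;
#' lambda is optimized on [0, 1] with the mean and rate profiled
#' analytically.  An approximate 95% interval is read off the profile
#' likelihood (1.92 log-likelihood-unit drop).
#'
#' @param tree [ape::phylo] tree (>= 10 tips).
#' @param trait named numeric vector of tip values.
#' @return list with `lambda`, `logL` at the optimum, `logL0`/`logL1` at
#'   lambda = 0/1, and `ci` (profile interval).
#' @export
estimate_lambda <- function(tree, trait) {
  if (length(tree$tip.label) < 10) stop("need >= 10 tips", call. = FALSE)
  if (!is.null(names(trait))) trait <- trait[tree$tip.label]
  if (length(trait) != length(tree$tip.label))
    stop("one trait value per tip required", call. = FALSE)
  if (any(!is.finite(trait))) stop("non-finite trait values", call. = FALSE)
  if (stats::var(trait) == 0) stop("zero trait variance", call. = FALSE)
  V <- ape::vcv(tree)
  f <- function(l) .lambda_negll(l, trait, V)
  opt <- stats::optimize(f, c(0, 1), tol = 1e-6)
  ## compare against the boundary values: optimize() can miss an endpoint
  cand <- c(opt$minimum, 0, 1)
  negll <- c(opt$objective, f(0), f(1))
  best <- which.min(negll)
  lambda <- cand[best]
  logL <- -negll[best]
  thr <- logL - 1.92
  grid <- seq(0, 1, length.out = 101)
  prof <- -vapply(grid, f, numeric(1))
  inside <- grid[prof >= thr]
  list(lambda = lambda, logL = logL, logL0 = -negll[2], logL1 = -negll[3],
       ci = if (length(inside)) range(inside) else c(lambda, lambda))
}

## ML fit of BM on a tree: profiled mean and rate. Returns logL and AIC (k=2).
.fit_bm <- function(trait, V) {
  n <- length(trait)
  negll <- .lambda_negll(1, trait, V)
  list(logL = -negll, AIC = 2 * negll + 2 * 2)
}

## ML fit of single-optimum OU (alpha, rate, mean free; root state free,
## non-stationary). Profile over log(alpha). Returns logL and AIC (k=3).
.fit_ou <- function(trait, S, Tdep) {
  negll_alpha <- function(la) {
    a <- exp(la)
    W <- exp(-2 * a * (Tdep - S)) * (1 - exp(-2 * a * S)) / (2 * a)
    .lambda_negll(1, trait, W)   # lambda=1 leaves W untouched; GLS profile
  }
  opt <- stats::optimize(negll_alpha, c(log(1e-4 / Tdep), log(50 / Tdep)))
  list(logL = -opt$objective, AIC = 2 * opt$objective + 2 * 3,
       alpha = exp(opt$minimum))
}

#' BM-versus-OU adequacy test of a phylogeny
#'
#' Simulates `n_sim` traits under Brownian motion on the tree, fits BM and a
#' single-optimum OU by maximum likelihood to each replicate, and compares
#' them with Akaike weights.  A replicate whose Akaike-weight ratio is below
#' `indecisive_ratio` is labelled indecisive.  If the tree is adequate for
#' comparative analysis, BM should be favored in most replicates.
#'
#' @param tree ultrametric [ape::phylo].
#' @param n_sim number of simulated trait datasets (>= 10).
#' @param seed integer seed.
#' @param generating `"BM"` (default) or `"OU"`: model used to simulate.
#' @param ou_alpha selection strength when `generating = "OU"`.
#' @param indecisive_ratio Akaike-weight ratio below which a replicate is
#'   indecisive (default 2).
#' @return list with per-replicate `table` (AICs, weights, evidence ratio,
#'   winner) and summary `fractions` (bm / ou / indecisive), plus
#'   `n_failed` replicates flagged for non-convergence.
#' @export
adequacy_bm_ou <- function(tree, n_sim = 100, seed = 1, generating = "BM",
                           ou_alpha = 1, indecisive_ratio = 2) {
  if (n_sim < 10) stop("n_sim must be >= 10", call. = FALSE)
  S <- ape::vcv(tree)
  Tdep <- max(S)
  traits <- simulate_traits(tree, n_sim, model = generating, lambda = 1,
                            seed = seed, ou_alpha = ou_alpha)
  res <- vector("list", n_sim)
  for (i in seq_len(n_sim)) {
    y <- traits[, i]
    bm <- tryCatch(.fit_bm(y, S), error = function(e) NULL)
    ou <- tryCatch(.fit_ou(y, S, Tdep), error = function(e) NULL)
    if (is.null(bm) || is.null(ou)) {
      res[[i]] <- data.frame(rep = i, aic_bm = NA, aic_ou = NA, w_bm = NA,
                             w_ou = NA, er = NA, winner = "failed")
      next
    }
    d <- c(bm$AIC, ou$AIC) - min(bm$AIC, ou$AIC)
    w <- exp(-d / 2) / sum(exp(-d / 2))
    er <- max(w) / min(w)
    winner <- if (er < indecisive_ratio) "indecisive" else
      c("BM", "OU")[which.max(w)]
    res[[i]] <- data.frame(rep = i, aic_bm = bm$AIC, aic_ou = ou$AIC,
                           w_bm = w[1], w_ou = w[2], er = er, winner = winner)
  }
  tab <- do.call(rbind, res)
  ok <- tab$winner != "failed"
  fr <- c(bm = mean(tab$winner[ok] == "BM"),
          ou = mean(tab$winner[ok] == "OU"),
          indecisive = mean(tab$winner[ok] == "indecisive"))
  list(table = tab, fractions = fr, n_failed = sum(!ok))
}

#' Gower distance between species trait rows
#'
#' Per-trait range-normalized absolute differences, averaged over the traits
#' observed in both species of a pair; values in [0, 1].  Zero-range traits
#' are skipped with a warning.
#'
#' @param traits species x trait numeric matrix (NAs allowed).
#' @return symmetric species x species distance matrix.
#' @export
gower_distance <- function(traits) {
  traits <- as.matrix(traits)
  if (nrow(traits) < 2) stop("need >= 2 species", call. = FALSE)
  rng <- apply(traits, 2, function(x) diff(range(x, na.rm = TRUE)))
  if (any(rng == 0)) {
    warning("zero-range trait(s) skipped: ",
            paste(colnames(traits)[rng == 0], collapse = ", "))
    traits <- traits[, rng > 0, drop = FALSE]
    rng <- rng[rng > 0]
  }
  n <- nrow(traits)
  d <- matrix(0, n, n, dimnames = list(rownames(traits), rownames(traits)))
  scaled <- sweep(traits, 2, rng, "/")
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      diffs <- abs(scaled[i, ] - scaled[j, ])
      ok <- !is.na(diffs)
      d[i, j] <- d[j, i] <- if (any(ok)) mean(diffs[ok]) else NA_real_
    }
  }
  d
}

#' Root-calibrated UPGMA trait dendrogram
#'
#' UPGMA (average-linkage) clustering of a trait distance matrix, with all
#' branch lengths rescaled by a single factor so the root age equals
#' `root_age` — making the dendrogram comparable to a time-calibrated
#' phylogeny.
#'
#' @param d symmetric distance matrix.
#' @param root_age positive target root age.
#' @return an ultrametric [ape::phylo] dendrogram.
#' @export
build_trait_dendrogram <- function(d, root_age) {
  check_distance_matrix(d)
  if (root_age <= 0) stop("root_age must be > 0", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  depth <- max(node_depths(tr)$depth[seq_along(tr$tip.label)])
  tr$edge.length <- tr$edge.length * root_age / depth
  tr
}
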