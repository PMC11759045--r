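test_that("phylogenetic eigenvectors are orthogonal and structured", {
  tr <- simulate_phylogeny(24, seed = 14)
  pe <- compute_phylo_eigenvectors(tr, n_vectors = 8)
  g <- crossprod(pe$vectors)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  expect_true(all(diff(pe$values) <= 1e-9))

  ## eigenvalue sum identity on the full decomposition
  pe_all <- compute_phylo_eigenvectors(tr, n_vectors = 23)
  D <- patristic_matrix(tr)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% D^2 %*% J
  expect_equal(sum(pe_all$values), sum(diag(G)), tolerance = 1e-6)

  ## perfectly balanced two-clade tree: first eigenvector separates clades
  bal <- ape::read.tree(text = "((A:1,B:1):2,(C:1,D:1):2);")
  pb <- compute_phylo_eigenvectors(bal, n_vectors = 2)
  v1 <- pb$vectors[, 1]
  expect_true(all(sign(v1[c("A", "B")]) == sign(v1["A"])))
  expect_true(all(sign(v1[c("C", "D")]) == -sign(v1["A"])))

  star0 <- ape::read.tree(text = "(A:0,B:0,C:0);")
  expect_error(compute_phylo_eigenvectors(star0), "degenerate")
})

test_that("imputation preserves observed cells and recovers held-out values", {
  tr <- simulate_phylogeny(60, seed = 17)
  traits <- simulate_traits(tr, 4, seed = 17)
  pe <- compute_phylo_eigenvectors(tr)

  ## complete table: identity
  r0 <- impute_traits(traits, pe$vectors, seed = 1)
  expect_identical(r0$traits, traits)

  ## single missing cell stays within the observed range
  t1 <- traits
  t1[5, 2] <- NA
  r1 <- impute_traits(t1, pe$vectors, seed = 1, ntree = 50)
  expect_false(anyNA(r1$traits))
  expect_gte(r1$traits[5, 2], min(traits[-5, 2]))
  expect_lte(r1$traits[5, 2], max(traits[-5, 2]))
  expect_identical(r1$traits[!is.na(t1)], traits[!is.na(t1)])

  ## 20% holdout: correlation with truth, and eigenvectors help
  nrmse <- function(imp, truth, mask)
    sqrt(mean((imp[mask] - truth[mask])^2)) / sd(truth[mask])
  cors <- numeric(10); gain <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    mask <- matrix(runif(length(traits)) < 0.2, nrow(traits))
    ## keep >= 10 observed per column
    for (j in seq_len(ncol(traits)))
      if (sum(!mask[, j]) < 10) mask[, j] <- FALSE
    tm <- traits; tm[mask] <- NA
    with_ev <- impute_traits(tm, pe$vectors, seed = s, ntree = 50,
                             max_iter = 5)$traits
    without_ev <- impute_traits(tm, NULL, seed = s, ntree = 50,
                                max_iter = 5)$traits
    cors[s] <- cor(with_ev[mask], traits[mask])
    gain[s] <- nrmse(without_ev, traits, mask) - nrmse(with_ev, traits, mask)
  }
  expect_gt(mean(cors), 0.6)
  expect_gt(mean(gain), 0)   # phylogenetic information improves imputation

  bad <- traits; bad[, 3] <- NA
  expect_error(impute_traits(bad, pe$vectors), "trait3")
})

test_that("Pagel's lambda ML recovers signal regimes", {
  tr <- simulate_phylogeny(100, seed = 19)
  ## iid traits: no signal
  l0 <- vapply(1:50, function(i) {
    x <- simulate_traits(tr, 1, lambda = 0, seed = 300 + i)[, 1]
    estimate_lambda(tr, x)$lambda
  }, numeric(1))
  expect_lt(mean(l0), 0.1)
  expect_true(all(l0 >= 0 & l0 <= 1))

  ## BM traits: lambda near 1
  l1 <- vapply(1:20, function(i) {
    x <- simulate_traits(tr, 1, lambda = 1, seed = 400 + i)[, 1]
    estimate_lambda(tr, x)$lambda
  }, numeric(1))
  expect_gte(mean(l1), 0.9)
  expect_true(all(l1 <= 1))

  ## scale invariance
  x <- simulate_traits(tr, 1, lambda = 0.6, seed = 5)[, 1]
  expect_lt(abs(estimate_lambda(tr, x)$lambda -
                  estimate_lambda(tr, x * 1000)$lambda), 1e-6)

  expect_error(estimate_lambda(tr, rep(1, 100)), "variance")

  skip_if_not_installed("phytools")
  ps <- phytools::phylosig(tr, x, method = "lambda")
  expect_equal(estimate_lambda(tr, x)$lambda, unname(ps$lambda),
               tolerance = 0.01)
})

test_that("BM/OU adequacy favors the generating model", {
  tr <- simulate_phylogeny(80, seed = 23)
  bm <- adequacy_bm_ou(tr, n_sim = 40, seed = 1)
  expect_gte(bm$fractions["bm"] + bm$fractions["indecisive"], 0.7)
  expect_gte(bm$fractions["bm"], 0.5)

  depth <- max(ape::node.depth.edgelength(tr))
  ou <- adequacy_bm_ou(tr, n_sim = 40, seed = 2, generating = "OU",
                       ou_alpha = 10 / depth)
  expect_gte(ou$fractions["ou"], 0.7)

  ## evidence ratio definition per replicate
  tab <- bm$table[bm$table$winner != "failed", ]
  expect_equal(tab$er, pmax(tab$w_bm, tab$w_ou) / pmin(tab$w_bm, tab$w_ou),
               tolerance = 1e-12)
  expect_equal(bm$n_failed, 0)
})

test_that("Gower distance matches hand computation and daisy", {
  m <- rbind(A = c(0, 10), B = c(1, 30), C = c(2, 50))
  d <- gower_distance(m)
  expect_equal(d["A", "B"], 0.5)      # ranges (2, 40): (0.5 + 0.5) / 2
  expect_equal(d["A", "C"], 1)        # opposite extremes of every trait
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))

  m2 <- rbind(A = c(1, 2, 3), B = c(1, 2, 3), C = c(4, 0, 5))
  expect_equal(gower_distance(m2)["A", "B"], 0)
  expect_warning(gower_distance(cbind(m, const = 1)), "zero-range")

  ## NA-tolerant agreement with cluster::daisy on a random matrix
  set.seed(31)
  mm <- matrix(rnorm(60), 12)
  mm[sample(60, 8)] <- NA
  rownames(mm) <- paste0("s", 1:12)
  colnames(mm) <- paste0("t", 1:5)
  d1 <- gower_distance(mm)
  d2 <- as.matrix(cluster::daisy(as.data.frame(mm), metric = "gower"))
  expect_equal(unname(d1), unname(d2), tolerance = 1e-10)
})

test_that("trait dendrogram is UPGMA, calibrated and ultrametric", {
  d <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- build_trait_dendrogram(d, root_age = 10)
  depths <- ape::node.depth.edgelength(tr)[1:4]
  expect_equal(depths, rep(10, 4), tolerance = 1e-9)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  ## manual UPGMA: (A,B) at h=2, (C,D) at h=4, then root at h=8
  expect_true(ape::is.monophyletic(tr, c("A", "B")))
  expect_true(ape::is.monophyletic(tr, c("C", "D")))
  ## relative node heights preserved by the single scaling factor
  Dtr <- patristic_matrix(tr)
  expect_equal(Dtr["A", "B"] / Dtr["A", "C"], 2 / 8, tolerance = 1e-9)

  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- build_trait_dendrogram(d2, root_age = 5)
  expect_equal(sort(t2$edge.length), c(5, 5))

  bad <- d; bad[1, 2] <- 99
  expect_error(build_trait_dendrogram(bad, 10), "symmetric")
})
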