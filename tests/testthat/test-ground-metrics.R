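test_that("relative abundance and taxonomic metrics match closed forms", {
  expect_equal(unname(relative_abundance(c(a = 50, b = 30, c = 20))),
               c(0.5, 0.3, 0.2))
  expect_equal(unname(relative_abundance(c(x = 7))), 1)
  expect_equal(unname(relative_abundance(c(a = 5, b = 5, c = 5, d = 5))),
               rep(0.25, 4))
  expect_error(relative_abundance(c(a = 0, b = 0)), "zero")

  expect_equal(taxonomic_metrics(1), c(S = 1, H = 0, D = 0))
  expect_equal(taxonomic_metrics(rep(0.25, 4)),
               c(S = 4, H = log(4), D = 0.75))
  p <- c(0.5, 0.3, 0.2)
  expect_equal(taxonomic_metrics(p), oracle_hill(p), tolerance = 1e-12)
})

test_that("mean pairwise distance agrees with the pair-loop oracle", {
  d <- matrix(c(0, 2, 4, 2, 0, 6, 4, 6, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(mean_pairwise_distance(d), 4)
  expect_equal(mean_pairwise_distance(d, c("a", "b")), 2)
  expect_true(is.na(mean_pairwise_distance(d, "a")))

  set.seed(1)
  m <- matrix(runif(64), 8)
  dd <- as.matrix(dist(m))
  expect_equal(mean_pairwise_distance(dd), oracle_mpd(dd, rownames(dd)))

  ## all pairs equal c
  dc <- matrix(3, 4, 4); diag(dc) <- 0
  dimnames(dc) <- list(LETTERS[1:4], LETTERS[1:4])
  expect_equal(mean_pairwise_distance(dc), 3)
})

test_that("faith_pd includes the root path and matches edge enumeration", {
  t2 <- toy_tree_2()
  expect_equal(faith_pd(t2, c("A", "B")), 2)
  t4 <- toy_tree_4()
  expect_equal(faith_pd(t4, c("A", "C")), 4)
  expect_equal(faith_pd(t4, t4$tip.label), sum(t4$edge.length))
  expect_equal(faith_pd(t4, "A"), 2)     # stem path for a single member
  expect_error(faith_pd(t4, c("A", "zz")), "zz")

  tr <- simulate_phylogeny(30, seed = 8)
  members <- sample(tr$tip.label, 7)
  expect_equal(faith_pd(tr, members), oracle_pd(tr, members),
               tolerance = 1e-12)
  skip_if_not_installed("picante")
  comm <- matrix(0, 1, 30, dimnames = list("p1", tr$tip.label))
  comm[1, members] <- 1
  expect_equal(faith_pd(tr, members),
               picante::pd(comm, tr, include.root = TRUE)$PD,
               tolerance = 1e-10)
})

test_that("patristic matrix equals path enumeration and ultrametric identity", {
  t4 <- toy_tree_4()
  D <- patristic_matrix(t4)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["A", "B"], 2)
  tr <- simulate_phylogeny(20, seed = 9)
  D2 <- patristic_matrix(tr)
  a <- tr$tip.label[3]; b <- tr$tip.label[17]
  expect_equal(D2[a, b], oracle_patristic(tr, a, b), tolerance = 1e-10)
  ## tips on opposite sides of the root sit at 2 x root age
  age <- max(ape::node.depth.edgelength(tr))
  expect_equal(max(D2), 2 * age, tolerance = 1e-8)
})

test_that("SES standardization is correct and calibrated", {
  vals <- rep(c(3, 5), 50)
  i <- 0
  gen <- function() { i <<- i + 1; vals[i] }
  r <- ses_standardize(6, gen, n_null = 100, seed = 1)
  expect_equal(r$z, (6 - mean(vals)) / sd(vals))
  i <- 0
  expect_equal(ses_standardize(mean(vals), gen, n_null = 100, seed = 1)$z, 0)
  expect_error(ses_standardize(1, function() 2, n_null = 100), "degenerate")
  expect_error(ses_standardize(1, function() rnorm(1), n_null = 10), "n_null")
})

test_that("dispersion metric follows the formula chain and its bounds", {
  ## hand-computed 3-species example (q = 0)
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1
  d[1, 3] <- d[3, 1] <- 0.5
  d[2, 3] <- d[3, 2] <- 0.25
  r <- dispersion_qD(d, rep(1 / 3, 3), q = 0)
  expect_equal(r$m_i, c(0.75, 0.625, 0.375))
  expect_equal(r$M, 0.58333, tolerance = 1e-4)
  expect_equal(r$qDTM, 2.16667, tolerance = 1e-4)

  ## upper bound: all scaled distances 1, uniform p -> S, for every q
  S <- 5
  d1 <- matrix(1, S, S); diag(d1) <- 0
  for (q in 0:2)
    expect_equal(dispersion_qD(d1, rep(1 / S, S), q = q)$qDTM, S)

  ## lower bound: all distances zero -> 1; single species -> 1
  d0 <- matrix(0, 4, 4)
  expect_equal(dispersion_qD(d0, rep(0.25, 4), q = 1)$qDTM, 1)
  expect_equal(dispersion_qD(matrix(0, 1, 1), 1, q = 2)$qDTM, 1)

  expect_error(dispersion_qD(d1 * 2, rep(1 / S, S), q = 0), "exceed 1")
})

test_that("dispersion, MPD and PD match brute force on random communities", {
  tr <- simulate_phylogeny(12, seed = 21)
  D <- patristic_matrix(tr)
  Ds <- D / max(D)
  set.seed(22)
  for (rep in 1:50) {
    s <- sample(2:6, 1)
    members <- sample(rownames(D), s)
    p <- as.numeric(relative_abundance(setNames(runif(s, 1, 10), members)))
    sub <- Ds[members, members]
    for (q in 0:2) {
      expect_equal(dispersion_qD(sub, p, q = q)$qDTM,
                   oracle_qdtm(sub, p, q), tolerance = 1e-10)
    }
    expect_equal(mean_pairwise_distance(D, members),
                 oracle_mpd(D, members), tolerance = 1e-10)
    expect_equal(faith_pd(tr, members), oracle_pd(tr, members),
                 tolerance = 1e-10)
  }
})

test_that("metrics are permutation invariant and distance-scaling monotone", {
  set.seed(30)
  n <- 6
  d <- as.matrix(dist(matrix(runif(n * 3), n)))
  dimnames(d) <- list(letters[1:n], letters[1:n])
  p <- as.numeric(relative_abundance(setNames(runif(n, 1, 5), letters[1:n])))
  perm <- sample(n)
  dp <- d[perm, perm]
  expect_equal(mean_pairwise_distance(dp), mean_pairwise_distance(d))
  expect_equal(dispersion_qD(dp / max(dp), p[perm], q = 1)$qDTM,
               dispersion_qD(d / max(d), p, q = 1)$qDTM, tolerance = 1e-12)

  ds <- d / max(d)
  for (c_scale in c(0.2, 0.5, 1)) {
    expect_equal(mean_pairwise_distance(d * c_scale),
                 c_scale * mean_pairwise_distance(d), tolerance = 1e-12)
    for (q in 0:2) {
      expect_lte(dispersion_qD(ds * c_scale, p, q = q)$qDTM,
                 dispersion_qD(ds, p, q = q)$qDTM + 1e-12)
    }
  }
})

test_that("ground metric table has the full metric complement per plot", {
  cfg <- scenario_config(n_sites = 2, plots_per_site = 3, pool_size = 25,
                         richness_range = c(3, 8),
                         wavelengths = seq(400, 2500, 20), seed = 6)
  pool <- simulate_species_pool(cfg)
  comm <- assemble_communities(pool, cfg)
  gm <- compute_ground_metrics(comm, pool$phylogeny,
                               gower_distance(pool$traits),
                               n_null = 99, seed = 1)
  expect_setequal(unique(gm$metric),
                  c("S", "H", "D", "MTD", "qDTM", "MPD", "qDPM", "PD"))
  expect_equal(nrow(gm), 6 * 12)
  s_row <- gm[gm$metric == "S" & gm$plot == "plot001", ]
  expect_equal(s_row$value, sum(comm$cover[1, ] > 0))
  expect_true(all(is.finite(gm$z[gm$metric %in% c("MTD", "MPD", "PD")])))
})
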