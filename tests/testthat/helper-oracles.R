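## Independent brute-force oracles used to pin down expected metric values.
## These deliberately re-derive every quantity with plain loops and base R,
## sharing no code path with the package implementations.

oracle_hill <- function(p) {
  S <- 0; H <- 0; D2 <- 0
  for (pi in p) {
    if (pi > 0) {
      S <- S + 1
      H <- H - pi * log(pi)
      D2 <- D2 + pi^2
    }
  }
  c(S = S, H = H, D = 1 - D2)
}

oracle_mpd <- function(d, members) {
  n <- length(members)
  if (n < 2) return(NA_real_)
  tot <- 0; cnt <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + d[members[i], members[j]]
    cnt <- cnt + 1
  }
  tot / cnt
}

## Faith PD including the path to the root: union of root-to-tip edges.
oracle_pd <- function(tree, members) {
  root <- length(tree$tip.label) + 1L
  edges_used <- character(0)
  for (m in members) {
    tip <- which(tree$tip.label == m)
    path <- ape::nodepath(tree, root, tip)
    for (i in seq_len(length(path) - 1)) {
      edges_used <- union(edges_used, paste(path[i], path[i + 1]))
    }
  }
  tot <- 0
  for (e in edges_used) {
    nodes <- as.integer(strsplit(e, " ")[[1]])
    row <- which(tree$edge[, 1] == nodes[1] & tree$edge[, 2] == nodes[2])
    tot <- tot + tree$edge.length[row]
  }
  tot
}

oracle_patristic <- function(tree, a, b) {
  ia <- which(tree$tip.label == a)
  ib <- which(tree$tip.label == b)
  path <- ape::nodepath(tree, ia, ib)
  tot <- 0
  for (i in seq_len(length(path) - 1)) {
    row <- which((tree$edge[, 1] == path[i] & tree$edge[, 2] == path[i + 1]) |
                   (tree$edge[, 1] == path[i + 1] & tree$edge[, 2] == path[i]))
    tot <- tot + tree$edge.length[row]
  }
  tot
}

## Dispersion metric via the explicit formula chain, scalar loops only.
## d must already be scaled to [0, 1].
oracle_qdtm <- function(d, p, q) {
  S <- length(p)
  if (S == 1) return(1)
  m <- numeric(S)
  for (i in 1:S) {
    acc <- 0
    for (j in 1:S) if (j != i) acc <- acc + d[i, j]
    m[i] <- acc / (S - 1)
  }
  Mp <- mean(m)
  if (Mp == 0) return(1)
  w <- numeric(S)
  for (i in 1:S) w[i] <- p[i] * m[i]
  w <- w / sum(w)
  if (q == 0) {
    qDT <- sum(w > 0)
  } else if (q == 1) {
    acc <- 0
    for (wi in w) if (wi > 0) acc <- acc - wi * log(wi)
    qDT <- exp(acc)
  } else {
    acc <- 0
    for (wi in w) acc <- acc + wi^q
    qDT <- acc^(1 / (1 - q))
  }
  1 + (S - 1) * (qDT / S) * Mp
}

## Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- ai * bj / n2
  (nij - expected) / ((ai + bj) / 2 - expected)
}

## Small toy trees used across tests.
toy_tree_4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
toy_tree_2 <- function(t = 1) {
  ape::read.tree(text = sprintf("(A:%g,B:%g);", t, t))
}

## Quick synthetic cube: pure per-pixel species, optional soil/noise.
make_test_cube <- function(n_species = 3, grid = 10, coupling = 0.1,
                           soil_fraction = 0, noise = 0, m_per_pixel = 1,
                           bands = seq(400, 2500, by = 35), seed = 1,
                           brightness_sd = 0.15, within_species_sd = 0) {
  rr <- max(n_species, 2)
  cfg <- scenario_config(n_sites = 1, plots_per_site = 1, pool_size = 20,
                         richness_range = c(rr, rr),
                         wavelengths = bands, grid_size = grid,
                         soil_fraction = soil_fraction,
                         sensor_noise_sd = noise, trait_coupling = coupling,
                         max_species_per_pixel = m_per_pixel, seed = seed,
                         brightness_sd = brightness_sd,
                         within_species_sd = within_species_sd)
  pool <- simulate_species_pool(cfg)
  comm <- assemble_communities(pool, cfg)
  cover <- comm$cover[1, ]
  if (n_species == 1) {
    keep <- names(cover)[cover > 0][1]
    cover[setdiff(names(cover), keep)] <- 0
  }
  r <- render_plot_cube(cover, pool$spectral_library, cfg,
                        seed = child_seed(seed, "cubes", 1))
  list(cube = r$cube, truth = r$truth, pool = pool, cfg = cfg, cover = cover)
}
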