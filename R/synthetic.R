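## Synthetic landscape generator: virtual species pools (phylogeny + traits +
## reflectance library), communities nested in sites, and plot-scale
## hyperspectral cubes with known ground truth.

#' Scenario configuration for the synthetic landscape
#'
#' Bundles every knob of the generator with validated defaults.  Defaults
#' emulate the study system: communities nested in sites, plot richness
#' between 2 and 15 species, 40 m x 40 m plots at 1 m pixels, and a 426-band
#' wavelength grid (384-2512 nm at 5 nm).
#'
#' @param n_sites number of sites (plots are nested in sites).
#' @param plots_per_site plots per site.
#' @param pool_size species-pool size.
#' @param richness_range integer range `c(lo, hi)` of per-plot richness.
#' @param filter_strength phi >= 0; strength of trait-based environmental
#'   filtering when assembling plots. 0 gives neutral (uniform) assembly;
#'   larger values cluster co-occurring species in trait space.
#' @param wavelengths strictly increasing band centres in nm.
#' @param grid_size pixels per plot side (grid is `grid_size` x `grid_size`).
#' @param soil_fraction fraction of pixels rendered as bare soil, in [0, 1).
#' @param sensor_noise_sd additive Gaussian sensor noise (reflectance units).
#' @param within_species_sd within-species spectral variability: per-band
#'   Gaussian jitter (reflectance units) applied to every vegetation pixel,
#'   emulating leaf-level chemical/structural variation that survives
#'   brightness normalization.
#' @param trait_coupling scalar (or K x G matrix) linking standardized traits
#'   to reflectance perturbation amplitudes; 0 makes all species spectra equal.
#' @param n_traits number of traits evolved on the phylogeny.
#' @param birth_rate,death_rate birth-death rates of the simulated phylogeny.
#' @param brightness_sd sdlog of the per-pixel lognormal brightness factor.
#' @param dirichlet_conc Dirichlet concentration for within-plot cover.
#' @param max_species_per_pixel maximum species mixed into one pixel.
#' @param cover_total_range range of summed percent cover per plot (<= 100).
#' @param seed root seed; all stages derive child seeds from it.
#' @return an object of class `scenario_config` (a validated list).
#' @export
scenario_config <- function(n_sites = 10, plots_per_site = 20, pool_size = 100,
                            richness_range = c(2, 15), filter_strength = 0,
                            wavelengths = seq(384, 2512, by = 5),
                            grid_size = 40, soil_fraction = 0.1,
                            sensor_noise_sd = 0.002, within_species_sd = 0.005,
                            trait_coupling = 0.04,
                            n_traits = 4, birth_rate = 1, death_rate = 0,
                            brightness_sd = 0.15, dirichlet_conc = 1,
                            max_species_per_pixel = 3,
                            cover_total_range = c(60, 95), seed = 1) {
  cfg <- list(
    n_sites = as.integer(n_sites), plots_per_site = as.integer(plots_per_site),
    pool_size = as.integer(pool_size),
    richness_range = as.integer(richness_range),
    filter_strength = filter_strength, wavelengths = as.numeric(wavelengths),
    grid_size = as.integer(grid_size), soil_fraction = soil_fraction,
    sensor_noise_sd = sensor_noise_sd, within_species_sd = within_species_sd,
    trait_coupling = trait_coupling,
    n_traits = as.integer(n_traits), birth_rate = birth_rate,
    death_rate = death_rate, brightness_sd = brightness_sd,
    dirichlet_conc = dirichlet_conc,
    max_species_per_pixel = as.integer(max_species_per_pixel),
    cover_total_range = cover_total_range, seed = as.integer(seed)
  )
  counts <- c("n_sites", "plots_per_site", "pool_size", "grid_size",
              "n_traits", "max_species_per_pixel")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop(sprintf("'%s' must be >= 1", nm), call. = FALSE)
  if (length(cfg$richness_range) != 2L ||
      cfg$richness_range[1] < 2L || cfg$richness_range[2] > cfg$pool_size ||
      cfg$richness_range[1] > cfg$richness_range[2])
    stop("richness_range must lie within [2, pool_size]", call. = FALSE)
  if (cfg$filter_strength < 0) stop("filter_strength must be >= 0", call. = FALSE)
  if (any(diff(cfg$wavelengths) <= 0))
    stop("wavelengths must be strictly increasing", call. = FALSE)
  if (cfg$soil_fraction < 0 || cfg$soil_fraction >= 1)
    stop("soil_fraction must be in [0, 1)", call. = FALSE)
  if (cfg$sensor_noise_sd < 0) stop("sensor_noise_sd must be >= 0", call. = FALSE)
  if (cfg$within_species_sd < 0)
    stop("within_species_sd must be >= 0", call. = FALSE)
  class(cfg) <- "scenario_config"
  cfg
}

#' Simulate a rooted ultrametric birth-death phylogeny
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth_rate,death_rate speciation/extinction rates,
#'   `birth_rate > death_rate >= 0`.
#' @param seed integer seed.
#' @param max_tries bounded number of retries should a simulation fail.
#' @return an [ape::phylo] ultrametric tree with `n_tips` tips labelled
#'   `sp001`, `sp002`, ...
#' @export
simulate_phylogeny <- function(n_tips, birth_rate = 1, death_rate = 0, seed = 1,
                               max_tries = 20L) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  if (!(birth_rate > death_rate && death_rate >= 0))
    stop("need birth_rate > death_rate >= 0", call. = FALSE)
  tree <- NULL
  for (i in seq_len(max_tries)) {
    tree <- with_seed(seed + (i - 1L) * 1000L, tryCatch(
      ape::rphylo(n_tips, birth = birth_rate, death = death_rate),
      error = function(e) NULL))
    if (!is.null(tree)) break
  }
  if (is.null(tree))
    stop("phylogeny simulation failed after ", max_tries, " tries", call. = FALSE)
  tree$tip.label <- sprintf("sp%03d", seq_len(n_tips))
  tree
}

#' Simulate continuous traits on a phylogeny
#'
#' Traits are drawn from a multivariate normal whose covariance is the
#' shared-path-length (Brownian-motion) matrix of the tree, optionally the
#' Ornstein-Uhlenbeck analogue, with Pagel's lambda rescaling applied to the
#' off-diagonal entries.  `lambda = 0` gives independent tip values.
#'
#' @param tree ultrametric [ape::phylo] tree.
#' @param n_traits number of independent traits.
#' @param model `"BM"` or `"OU"`.
#' @param lambda Pagel's lambda in [0, 1].
#' @param seed integer seed.
#' @param sigma2 Brownian rate (variance per unit branch length).
#' @param ou_alpha selection strength for `model = "OU"`.
#' @return numeric matrix, species x traits, rownames = tip labels.
#' @export
simulate_traits <- function(tree, n_traits = 1, model = c("BM", "OU"),
                            lambda = 1, seed = 1, sigma2 = 1, ou_alpha = 1) {
  model <- match.arg(model)
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]", call. = FALSE)
  if (!is_ultrametric_tol(tree, 1e-6))
    stop("tree must be ultrametric", call. = FALSE)
  V <- sigma2 * ape::vcv(tree)
  if (model == "OU") {
    ## non-stationary OU started at the root: Cov = s2/(2a) e^{-2a(T-s)}(1-e^{-2as})
    Tdep <- max(V) / sigma2
    S <- ape::vcv(tree)                      # shared path lengths s_ij
    V <- sigma2 / (2 * ou_alpha) *
      exp(-2 * ou_alpha * (Tdep - S)) * (1 - exp(-2 * ou_alpha * S))
  }
  dg <- diag(V)
  V <- lambda * V
  diag(V) <- dg
  L <- chol(V + diag(1e-10 * max(dg), nrow(V)))
  x <- with_seed(seed,
                 matrix(stats::rnorm(nrow(V) * n_traits), ncol = n_traits))
  out <- crossprod(L, x)
  dimnames(out) <- list(tree$tip.label, paste0("trait", seq_len(n_traits)))
  out
}

#' Build a trait-coupled species reflectance library
#'
#' Each species signature is a shared green-vegetation template (chlorophyll
#' troughs near 450 and 680 nm, red-edge rise to a NIR plateau, water
#' absorption troughs near 1450 and 1940 nm) plus Gaussian perturbations
#' whose amplitudes are linear in the standardized traits; signatures are
#' clipped to [0, 1] and damped, if necessary, so every pure signature keeps
#' NDVI > 0.5.
#'
#' @param pool a `species_pool` or a species x trait matrix.
#' @param wavelengths band centres (nm); must cover a red (660-680 nm) and a
#'   NIR (800-860 nm) window.
#' @param trait_coupling scalar amplitude per standardized trait unit, or a
#'   K x G matrix mapping K traits onto G Gaussian perturbations.
#' @param seed seed for perturbation centres/widths.
#' @param within_species_cv within-species coefficient of variation recorded
#'   in the library (used as the brightness spread when rendering).
#' @return list with `reflectance` (species x bands), `wavelength`, `cv`.
#' @export
build_spectral_library <- function(pool, wavelengths, trait_coupling = 0.04,
                                   seed = 1, within_species_cv = 0.1) {
  traits <- if (inherits(pool, "species_pool")) pool$traits else pool
  if (!any(wavelengths >= 660 & wavelengths <= 680) ||
      !any(wavelengths >= 800 & wavelengths <= 860))
    stop("wavelengths must cover the red (660-680) and NIR (800-860) windows",
         call. = FALSE)
  K <- ncol(traits)
  z <- scale(traits)
  z[is.na(z)] <- 0
  if (is.matrix(trait_coupling)) {
    if (nrow(trait_coupling) != K)
      stop("trait_coupling matrix must have one row per trait", call. = FALSE)
    A <- trait_coupling
    G <- ncol(A)
  } else {
    ## each trait modulates several absorption features (seeded random
    ## loadings), normalized so the per-trait perturbation energy matches
    ## the scalar amplitude
    G <- 3L * K
    A <- NULL
  }
  template <- vegetation_template(wavelengths)
  rng <- range(wavelengths)
  ## perturbation shapes: seeded Gaussian bumps across the spectrum
  shapes <- with_seed(seed, {
    centre <- stats::runif(G, rng[1] + 50, rng[2] - 50)
    width <- stats::runif(G, 40, 120)
    if (is.null(A))
      A <- trait_coupling * matrix(stats::rnorm(K * G), K, G) / sqrt(3)
    vapply(seq_len(G),
           function(g) exp(-(wavelengths - centre[g])^2 / (2 * width[g]^2)),
           numeric(length(wavelengths)))
  })
  amp <- z %*% A                                # species x G amplitudes
  refl <- matrix(rep(template, each = nrow(traits)), nrow = nrow(traits))
  pert <- amp %*% t(shapes)
  sig <- pmin(pmax(refl + pert, 0), 1)
  ## damp perturbations until every pure signature stays clearly vegetated
  for (i in seq_len(nrow(sig))) {
    f <- 1
    while (!isTRUE(ndvi_of(sig[i, ], wavelengths) > 0.5) && f > 1e-4) {
      f <- f * 0.7
      sig[i, ] <- pmin(pmax(template + f * pert[i, ], 0), 1)
    }
  }
  dimnames(sig) <- list(rownames(traits), NULL)
  list(reflectance = sig, wavelength = wavelengths,
       cv = stats::setNames(rep(within_species_cv, nrow(sig)), rownames(sig)))
}

## Green-vegetation reflectance template over wavelengths in nm.
vegetation_template <- function(wl) {
  vis <- 0.05 + 0.05 * exp(-(wl - 550)^2 / (2 * 40^2)) -
    0.015 * exp(-(wl - 450)^2 / (2 * 30^2)) -
    0.020 * exp(-(wl - 680)^2 / (2 * 25^2))
  nir <- 0.45 * exp(-pmax(0, wl - 1350) / 1500) -
    0.26 * exp(-(wl - 1450)^2 / (2 * 45^2)) -
    0.30 * exp(-(wl - 1940)^2 / (2 * 55^2))
  s <- 1 / (1 + exp(-(wl - 715) / 15))          # red edge
  pmin(pmax(vis * (1 - s) + nir * s, 0.005), 1)
}

## Bare-soil reflectance: featureless linear ramp (NDVI < 0.2).
soil_template <- function(wl) {
  0.08 + (wl - min(wl)) / max(1, diff(range(wl))) * 0.25
}

ndvi_of <- function(spectrum, wl) {
  red <- mean(spectrum[wl >= 660 & wl <= 680])
  nir <- mean(spectrum[wl >= 800 & wl <= 860])
  (nir - red) / (nir + red)
}

#' Assemble plot communities from a species pool
#'
#' Per plot, richness is drawn uniformly from `richness_range` and species are
#' sampled without replacement with weight `exp(-phi * z_i^2)`, where `z_i`
#' is the standardized distance of species i's first trait to a site-level
#' trait optimum. `phi = 0` is neutral assembly. Percent cover follows a
#' Dirichlet draw scaled to a total <= 100.
#'
#' @param pool a `species_pool` (see [simulate_species_pool()]).
#' @param config a [scenario_config()].
#' @return a `community_table`: list with `cover` (plots x species percent
#'   cover matrix) and `site` (factor of site ids per plot).
#' @export
assemble_communities <- function(pool, config) {
  traits <- pool$traits
  if (nrow(traits) == 0) stop("empty species pool", call. = FALSE)
  phi <- config$filter_strength
  z1 <- as.numeric(scale(traits[, 1]))
  n_plots <- config$n_sites * config$plots_per_site
  cover <- matrix(0, n_plots, nrow(traits),
                  dimnames = list(sprintf("plot%03d", seq_len(n_plots)),
                                  rownames(traits)))
  site <- factor(rep(sprintf("site%02d", seq_len(config$n_sites)),
                     each = config$plots_per_site))
  with_seed(child_seed(config$seed, "communities"), {
    site_opt <- stats::runif(config$n_sites, min(z1), max(z1))
    for (p in seq_len(n_plots)) {
      rich_vals <- seq(config$richness_range[1], config$richness_range[2])
      s <- rich_vals[sample.int(length(rich_vals), 1)]
      w <- exp(-phi * (z1 - site_opt[as.integer(site[p])])^2)
      members <- sample(nrow(traits), s, prob = w)
      alpha <- rep(config$dirichlet_conc, s)
      prop <- stats::rgamma(s, alpha)
      prop <- prop / sum(prop)
      total <- stats::runif(1, config$cover_total_range[1],
                            config$cover_total_range[2])
      cover[p, members] <- prop * total
    }
  })
  structure(list(cover = cover, site = site), class = "community_table")
}

#' Simulate a complete species pool
#'
#' Phylogeny, traits evolved on it, and a trait-coupled reflectance library
#' with consistent species sets.
#'
#' @param config a [scenario_config()].
#' @return a `species_pool`: list with `phylogeny`, `traits`,
#'   `spectral_library`, `species`.
#' @export
simulate_species_pool <- function(config) {
  tree <- simulate_phylogeny(config$pool_size, config$birth_rate,
                             config$death_rate,
                             seed = child_seed(config$seed, "phylogeny"))
  traits <- simulate_traits(tree, config$n_traits, model = "BM", lambda = 1,
                            seed = child_seed(config$seed, "traits"))
  lib <- build_spectral_library(traits, config$wavelengths,
                                trait_coupling = config$trait_coupling,
                                seed = child_seed(config$seed, "spectra"),
                                within_species_cv = config$brightness_sd)
  structure(list(phylogeny = tree, traits = traits, spectral_library = lib,
                 species = tree$tip.label), class = "species_pool")
}

#' Render the hyperspectral cube of one plot
#'
#' A `soil_fraction` of pixels receive a featureless soil ramp; every other
#' pixel is a convex mixture of at most `max_species_per_pixel` species
#' signatures with weights proportional to local cover draws, times a
#' lognormal within-species brightness factor, plus Gaussian sensor noise.
#'
#' @param cover named percent-cover vector for one plot (zeros allowed).
#' @param library spectral library from [build_spectral_library()].
#' @param config a [scenario_config()].
#' @param seed integer seed for this plot.
#' @return list with `cube` (a [plot_cube]) and `truth` (per-pixel species
#'   mixture weight matrix, soil pixels all-zero rows, and true richness).
#' @export
render_plot_cube <- function(cover, library, config, seed = 1) {
  present <- names(cover)[cover > 0]
  if (length(present) == 0) stop("community is empty", call. = FALSE)
  wl <- library$wavelength
  B <- length(wl)
  npix <- config$grid_size^2
  sig <- library$reflectance[present, , drop = FALSE]
  p <- cover[present] / sum(cover[present])
  refl <- matrix(0, npix, B)
  weights <- matrix(0, npix, length(present), dimnames = list(NULL, present))
  soil <- soil_template(wl)
  with_seed(seed, {
    n_soil <- round(config$soil_fraction * npix)
    soil_idx <- if (n_soil > 0) sample(npix, n_soil) else integer(0)
    m <- min(config$max_species_per_pixel, length(present))
    bright_cv <- mean(library$cv[present])
    for (i in seq_len(npix)) {
      if (i %in% soil_idx) {
        refl[i, ] <- soil
        next
      }
      sp <- if (length(present) == 1) 1L else sample(length(present), m, prob = p)
      w <- p[sp] * stats::rgamma(m, shape = config$dirichlet_conc)
      if (sum(w) == 0) w <- rep(1, length(sp))
      w <- w / sum(w)
      weights[i, sp] <- w
      bright <- stats::rlnorm(1, 0, bright_cv)
      spectrum <- as.numeric(w %*% sig[sp, , drop = FALSE])
      if (config$within_species_sd > 0)
        spectrum <- spectrum + stats::rnorm(B, 0, config$within_species_sd)
      refl[i, ] <- bright * spectrum
    }
    if (config$sensor_noise_sd > 0)
      refl <- refl + matrix(stats::rnorm(npix * B, 0, config$sensor_noise_sd),
                            npix, B)
  })
  cube <- plot_cube(refl, wl, nrow = config$grid_size, ncol = config$grid_size)
  list(cube = cube,
       truth = list(weights = weights, soil = seq_len(npix) %in%
                      which(rowSums(weights) == 0),
                    richness = length(present)))
}

#' Simulate a full virtual landscape
#'
#' @param config a [scenario_config()].
#' @param render logical; render the per-plot hyperspectral cubes (the
#'   expensive part) or only pool + communities.
#' @return a `virtual_landscape`: `pool`, `community` (a `community_table`),
#'   `cubes` (list of [plot_cube]), `truth` (per-plot truth records).
#' @export
simulate_landscape <- function(config, render = TRUE) {
  pool <- simulate_species_pool(config)
  community <- assemble_communities(pool, config)
  cubes <- truth <- NULL
  if (render) {
    n_plots <- nrow(community$cover)
    cubes <- vector("list", n_plots)
    truth <- vector("list", n_plots)
    for (p in seq_len(n_plots)) {
      r <- render_plot_cube(community$cover[p, ], pool$spectral_library,
                            config, seed = child_seed(config$seed, "cubes", p))
      cubes[[p]] <- r$cube
      truth[[p]] <- r$truth
    }
    names(cubes) <- names(truth) <- rownames(community$cover)
  }
  structure(list(pool = pool, community = community, cubes = cubes,
                 truth = truth, config = config), class = "virtual_landscape")
}
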