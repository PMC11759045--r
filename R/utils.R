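#' specdiv: cross-dimensional plant biodiversity from the ground and the sky
#'
#' Analogous plot-level metrics of taxonomic, trait, phylogenetic and
#' spectral plant diversity; spectral-species estimation from plot-scale
#' hyperspectral cubes; Bayesian multilevel and quantile association models;
#' pairwise community dissimilarity (PCD); and a fully ground-truthed
#' synthetic-landscape generator.
#'
#' @section Module overview:
#' \describe{
#'   \item{Synthetic data}{[scenario_config()], [simulate_phylogeny()],
#'     [simulate_traits()], [simulate_species_pool()],
#'     [assemble_communities()], [build_spectral_library()],
#'     [render_plot_cube()], [simulate_landscape()]}
#'   \item{Trait/phylogeny preparation}{[compute_phylo_eigenvectors()],
#'     [impute_traits()], [estimate_lambda()], [adequacy_bm_ou()],
#'     [gower_distance()], [build_trait_dendrogram()]}
#'   \item{Ground metrics}{[relative_abundance()], [taxonomic_metrics()],
#'     [mean_pairwise_distance()], [faith_pd()], [patristic_matrix()],
#'     [ses_standardize()], [dispersion_qD()], [compute_ground_metrics()]}
#'   \item{Spectral processing}{[plot_cube()], [filter_bands()],
#'     [ndvi_mask()], [brightness_mask()], [vector_normalize()],
#'     [clean_plot_pipeline()]}
#'   \item{Spectral metrics}{[spectral_distance_matrix()], [msd()],
#'     [spectral_sd()], [spectral_dispersion_q0()],
#'     [estimate_cluster_number()], [pam_cluster()], [spectral_species()],
#'     [compute_spectral_metrics()]}
#'   \item{Association models}{[fit_bmlm()], [fit_bqlm()],
#'     [evidence_ratio()], [bayes_r2()], [posterior_predictive_check()],
#'     [train_test_predict()], [model_pair_registry()]}
#'   \item{Community dissimilarity}{[phylo_correlation()], [pcd_pair()],
#'     [pcd_matrix()]}
#'   \item{Pipeline}{[validate_config()], [run_pipeline()]}
#' }
#' @keywords internal
"_PACKAGE"

## Stage names used to fan a single scenario seed out into independent
## per-stage streams, so re-running one stage reproduces its draws exactly.
.SEED_STAGES <- c(
  phylogeny = 11L, traits = 23L, communities = 37L, spectra = 53L,
  cubes = 71L, nulls = 89L, imputation = 101L, clustering = 113L,
  mcmc = 131L, split = 151L, pcd = 173L
)

#' Derive a per-stage child seed from one root seed
#'
#' All randomness in the package flows from a single root seed; each pipeline
#' stage draws from its own child stream so stages are independently
#' reproducible.  The derivation is a fixed affine map modulo 2^31 - 1.
#'
#' @param seed integer root seed.
#' @param stage one of `names(specdiv:::.SEED_STAGES)`.
#' @param index optional extra offset (e.g. plot number) for per-unit streams.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage, index = 0L) {
  stage <- match.arg(stage, names(.SEED_STAGES))
  m <- 2147483647
  s <- (as.numeric(seed) %% m) * 48271 %% m
  (as.integer((s + .SEED_STAGES[[stage]] * 12347 + as.numeric(index) * 7919) %% m))
}

## Evaluate `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  invisible(x)
}

## Symmetry / distance-matrix sanity shared by several modules.
check_distance_matrix <- function(d, tol = 1e-8) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square", call. = FALSE)
  if (max(abs(d - t(d))) > tol)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(diag(d) != 0))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (any(d < 0))
    stop("distances must be non-negative", call. = FALSE)
  invisible(d)
}

## Root-to-tip depths of a rooted tree with branch lengths.
node_depths <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  depth <- numeric(n_node)
  root <- n_tip + 1L
  ## edges in preorder so parents are visited first
  ord <- reorder(tree, "postorder")$edge
  for (i in rev(seq_len(nrow(ord)))) {
    e <- which(tree$edge[, 1] == ord[i, 1] & tree$edge[, 2] == ord[i, 2])
    depth[ord[i, 2]] <- depth[ord[i, 1]] + tree$edge.length[e]
  }
  list(depth = depth, root = root, n_tip = n_tip)
}

is_ultrametric_tol <- function(tree, tol = 1e-8) {
  d <- node_depths(tree)
  tips <- d$depth[seq_len(d$n_tip)]
  diff(range(tips)) <= tol * max(tips)
}
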