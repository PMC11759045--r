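## End-to-end orchestration from a single validated configuration: simulate
## a landscape (or read supplied inputs), prepare traits, compute ground
## metrics, clean cubes, compute spectral metrics, fit association models,
## score predictions and compute PCD, writing every stage's outputs plus a
## manifest.

.CONFIG_DEFAULTS <- list(
  stages = c("simulate", "traits", "ground_metrics", "clean",
             "spectral_metrics", "associate", "predict", "pcd"),
  q_orders = c(0, 1, 2),
  n_null = 199,
  max_pixels = 400,
  k_max = 12,
  min_valid_fraction = 0.25,
  mcmc_iter = 2500,
  mcmc_chains = 4,
  pcd_reps = 500,
  seed = 1
)

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, YAML text, or a list; unknown keys are
#' rejected, defaults are filled in and echoed into the run manifest.
#' The `scenario` entry holds [scenario_config()] overrides.
#'
#' @param config path, YAML string, or list.
#' @return validated configuration list of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (file.exists(config)) yaml::read_yaml(config)
    else yaml::yaml.load(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a list or YAML", call. = FALSE)
  scenario <- config$scenario
  config$scenario <- NULL
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(.CONFIG_DEFAULTS, config)
  bad_stage <- setdiff(cfg$stages, .CONFIG_DEFAULTS$stages)
  if (length(bad_stage))
    stop("unknown stage(s): ", paste(bad_stage, collapse = ", "), call. = FALSE)
  if (!all(cfg$q_orders %in% c(0, 1, 2)))
    stop("q_orders must be a subset of {0, 1, 2}", call. = FALSE)
  if (cfg$n_null < 0 || cfg$pcd_reps < 1 || cfg$max_pixels < 2)
    stop("counts must be positive", call. = FALSE)
  cfg$scenario <- do.call(scenario_config,
                          c(if (is.null(scenario)) list() else scenario,
                            if (is.null(scenario$seed))
                              list(seed = cfg$seed) else list()))
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline on a synthetic landscape
#'
#' Executes the configured stages in their fixed order and writes per-stage
#' outputs under `out_dir` plus a JSON manifest listing inputs, seeds and
#' produced files.  A stage failure halts the run with the stage name;
#' outputs of completed stages are preserved.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @param out_dir output directory (created if missing).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("specdiv_run_")) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = cfg[setdiff(names(cfg), "scenario")],
                   scenario = unclass(cfg$scenario)[
                     c("n_sites", "plots_per_site", "pool_size", "seed")],
                   stages = list())
  state <- new.env(parent = emptyenv())
  add_stage <- function(name, outputs) {
    manifest$stages[[name]] <<- list(completed = TRUE, outputs = outputs)
  }
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  run_stage("simulate", function() {
    state$landscape <- simulate_landscape(cfg$scenario,
                                          render = "clean" %in% cfg$stages ||
                                            "spectral_metrics" %in% cfg$stages)
    f1 <- file.path(out_dir, "community.csv")
    write_community(state$landscape$community, f1)
    f2 <- file.path(out_dir, "traits.csv")
    write_traits(state$landscape$pool$traits, f2)
    f3 <- file.path(out_dir, "phylogeny.nwk")
    ape::write.tree(state$landscape$pool$phylogeny, f3)
    add_stage("simulate", c(f1, f2, f3))
  })

  run_stage("traits", function() {
    pool <- state$landscape$pool
    state$trait_dist <- gower_distance(pool$traits)
    depth <- max(node_depths(pool$phylogeny)$depth)
    state$dendrogram <- build_trait_dendrogram(state$trait_dist, depth)
    f <- file.path(out_dir, "trait_dendrogram.nwk")
    ape::write.tree(state$dendrogram, f)
    add_stage("traits", f)
  })

  run_stage("ground_metrics", function() {
    state$ground <- compute_ground_metrics(
      state$landscape$community, state$landscape$pool$phylogeny,
      state$trait_dist, n_null = cfg$n_null,
      seed = child_seed(cfg$seed, "nulls"))
    f <- file.path(out_dir, "ground_metrics.csv")
    write_metric_table(state$ground, f)
    add_stage("ground_metrics", f)
  })

  run_stage("clean", function() {
    state$clean <- lapply(state$landscape$cubes, clean_plot_pipeline,
                          min_valid_fraction = cfg$min_valid_fraction)
    qc <- data.frame(
      plot = names(state$clean),
      rejected = vapply(state$clean, inherits, logical(1), "plot_rejection"),
      valid_fraction = vapply(state$clean, function(cb)
        if (inherits(cb, "plot_rejection")) cb$valid_fraction
        else mean(cb$mask), numeric(1)))
    f <- file.path(out_dir, "cleaning_qc.csv")
    utils::write.csv(qc, f, row.names = FALSE)
    add_stage("clean", f)
  })

  run_stage("spectral_metrics", function() {
    state$spectral <- compute_spectral_metrics(
      state$clean, site = as.character(state$landscape$community$site),
      max_pixels = cfg$max_pixels, k_range = 2:cfg$k_max,
      seed = child_seed(cfg$seed, "clustering"))
    f <- file.path(out_dir, "spectral_metrics.csv")
    write_metric_table(state$spectral, f)
    add_stage("spectral_metrics", f)
  })

  run_stage("associate", function() {
    tab <- merge_metric_pair_data(state$ground, state$spectral)
    reg <- model_pair_registry()
    reg <- reg[reg$group == "spectral_species" &
                 reg$response_metric %in% c("S", "H", "D"), ]
    fits <- vector("list", nrow(reg))
    for (i in seq_len(nrow(reg))) {
      d <- pair_data(tab, reg[i, ])
      fits[[i]] <- fit_bmlm(d$y, d$x, d$site,
                            mcmc = mcmc_config(chains = cfg$mcmc_chains,
                                               iter = cfg$mcmc_iter,
                                               seed = child_seed(cfg$seed,
                                                                 "mcmc", i)),
                            strict = FALSE)
    }
    summ <- do.call(rbind, lapply(seq_len(nrow(reg)), function(i) {
      b <- fit_draws(fits[[i]], "beta")
      data.frame(response = reg$response_metric[i],
                 covariate = reg$covariate_metric[i],
                 q = reg$covariate_q[i],
                 beta_median = stats::median(b),
                 beta_lo = stats::quantile(b, 0.025),
                 beta_hi = stats::quantile(b, 0.975),
                 er = evidence_ratio(fits[[i]]),
                 r2_cond = bayes_r2(fits[[i]], TRUE)$median,
                 r2_marg = bayes_r2(fits[[i]], FALSE)$median,
                 rhat_max = max(fits[[i]]$diagnostics$rhat))
    }))
    state$fits <- fits
    state$pair_table <- tab
    f <- file.path(out_dir, "association_summaries.csv")
    utils::write.csv(summ, f, row.names = FALSE)
    add_stage("associate", f)
  })

  run_stage("predict", function() {
    tab <- state$pair_table
    d <- pair_data(tab, data.frame(response_dimension = "taxonomic",
                                   response_metric = "S", response_q = 0,
                                   covariate_metric = "SS", covariate_q = 0))
    sc <- train_test_predict(d$y, d$x, d$site, seed = cfg$seed,
                             mcmc = mcmc_config(chains = cfg$mcmc_chains,
                                                iter = cfg$mcmc_iter,
                                                seed = child_seed(cfg$seed,
                                                                  "mcmc")))
    f <- file.path(out_dir, "prediction_scores.csv")
    utils::write.csv(data.frame(response = "S", covariate = "SS_q0",
                                rho = sc$rho, smape = sc$smape,
                                rmsle = sc$rmsle,
                                mean_deviation = sc$mean_deviation), f,
                     row.names = FALSE)
    add_stage("predict", f)
  })

  run_stage("pcd", function() {
    V <- phylo_correlation(state$landscape$pool$phylogeny)
    ## PCD cost grows quadratically in plots; cap at 40 plots
    comm <- state$landscape$community
    if (nrow(comm$cover) > 40) {
      keep <- with_seed(child_seed(cfg$seed, "pcd"),
                        sort(sample(nrow(comm$cover), 40)))
      comm <- structure(list(cover = comm$cover[keep, , drop = FALSE],
                             site = comm$site[keep]),
                        class = "community_table")
    }
    res <- pcd_matrix(V, comm, reps = cfg$pcd_reps,
                      seed = child_seed(cfg$seed, "pcd"))
    f <- file.path(out_dir, "pcd_pairs.csv")
    utils::write.csv(res, f, row.names = FALSE)
    add_stage("pcd", f)
  })

  manifest$completed <- names(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(manifest)
}

#' Merge ground and spectral metric tables into wide pair data
#'
#' @param ground,spectral long metric tables sharing plot ids.
#' @return wide data.frame keyed by plot with one column per
#'   (metric, q) combination (e.g. `S`, `SS_q0`, `MTD`, `MTDz`).
#' @export
merge_metric_pair_data <- function(ground, spectral) {
  long <- rbind(ground[, c("plot", "site", "metric", "q", "value")],
                spectral[, c("plot", "site", "metric", "q", "value")])
  ## z columns become <metric>z pseudo-metrics
  gz <- ground[!is.na(ground$z) & ground$metric %in% c("MTD", "MPD", "PD"), ]
  if (nrow(gz)) {
    long <- rbind(long, data.frame(plot = gz$plot, site = gz$site,
                                   metric = paste0(gz$metric, "z"), q = NA,
                                   value = gz$z))
  }
  key <- ifelse(is.na(long$q), long$metric,
                ifelse(long$metric %in% c("SS", "qDSM"),
                       paste0(long$metric, "_q", long$q), long$metric))
  key[long$metric %in% c("qDTM", "qDPM")] <-
    paste0(long$metric[long$metric %in% c("qDTM", "qDPM")], "_q",
           long$q[long$metric %in% c("qDTM", "qDPM")])
  wide <- stats::reshape(
    data.frame(plot = long$plot, site = long$site, key = key,
               value = long$value),
    idvar = c("plot", "site"), timevar = "key", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide[stats::complete.cases(wide[, c("plot", "site")]), ]
}

#' Extract aligned (y, x, site) vectors for one registry pair
#'
#' @param tab wide table from [merge_metric_pair_data()].
#' @param pair one row of [model_pair_registry()].
#' @return list with `y`, `x`, `site` (rows with either value missing are
#'   dropped).
#' @export
pair_data <- function(tab, pair) {
  rkey <- if (pair$response_metric %in% c("qDTM", "qDPM"))
    paste0(pair$response_metric, "_q", pair$response_q) else pair$response_metric
  ckey <- if (pair$covariate_metric %in% c("SS", "qDSM"))
    paste0(pair$covariate_metric, "_q", pair$covariate_q)
  else pair$covariate_metric
  if (!rkey %in% names(tab) || !ckey %in% names(tab))
    stop(sprintf("pair columns not found: %s ~ %s", rkey, ckey), call. = FALSE)
  ok <- stats::complete.cases(tab[, c(rkey, ckey)])
  list(y = tab[[rkey]][ok], x = tab[[ckey]][ok],
       site = factor(tab$site[ok]))
}
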