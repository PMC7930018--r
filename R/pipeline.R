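#' Toy-scale pipeline configuration
#'
#' Stage sizes for the end-to-end dynamic-docking analysis on the
#' coarse-grained cryptic-site system.  The defaults are desk-scale analogs
#' of the full protocol: a high-temperature randomization run, iterative
#' bias flattening over a 280-700 K window, parallel multicanonical
#' production, reweighting to 300 K, landscape/cluster analysis, canonical
#' refinement, path construction and umbrella sampling with WHAM.
#'
#' @param window temperature window in K.
#' @param bias_iters bias-refinement iterations.
#' @param steps_rand,steps_iter randomization / first-iteration steps.
#' @param growth per-iteration length multiplier.
#' @param timestep,friction integrator settings for all 3D stages (ps, 1/ps).
#' @param burn_in fraction of each production trajectory discarded.
#' @param n_parallel_fit trajectories per bias iteration.
#' @param n_parallel,steps_prod,save_every production stage.
#' @param t_analysis reweighting temperature in K.
#' @param k_prime K-means cluster count (`NULL`: `min(1000, n/20)`).
#' @param n_replicas,steps_refine refinement stage.
#' @param window_width path window width in Angstrom.
#' @param lambda_max outer end of the reaction coordinate in Angstrom.
#' @param lambda_min inner end (negative: deeper than the bound pose).
#' @param n_min path candidate floor per window.
#' @param us_protocol an [us_protocol()] (seed is overridden by the
#'   pipeline seed).
#' @param n_boot WHAM bootstrap count.
#' @param delta_lambda WHAM bin width in Angstrom.
#' @param discard WHAM equilibration fraction discarded.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(window = c(280, 700), bias_iters = 8,
                            timestep = 0.005, friction = 1,
                            steps_rand = 60000, steps_iter = 60000, growth = 1.5,
                            n_parallel_fit = 4, n_parallel = 16,
                            steps_prod = 1500000, save_every = 200,
                            burn_in = 0.2,
                            t_analysis = 300, k_prime = NULL,
                            n_replicas = 10, steps_refine = 1000000,
                            window_width = 0.5, lambda_max = 13, lambda_min = -2.5,
                            n_min = 30, us_protocol = mcdock::us_protocol(),
                            n_boot = 200, delta_lambda = 0.05,
                            discard = 0.6) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full dynamic-docking analysis on a toy system
#'
#' Chains every stage of the McMD dynamic-docking workflow on the
#' `"cryptic3d"` preset: bias fitting, multicanonical production,
#' canonical reweighting, distance-PCA free-energy landscape, cluster
#' free-energy ranking with R-value grouping, canonical refinement of the
#' top configuration, unbinding-direction estimation, binding-path
#' construction and umbrella sampling with WHAM, ending in a standard
#' binding free energy.
#'
#' @param system a `toy_system` (default: `build_cryptic_system("cryptic3d")`).
#' @param seed master seed; all stage seeds derive from it.
#' @param config a [pipeline_config()].
#' @param verbose print stage progress.
#' @return list of class `dock_run` with the artifacts of every stage:
#'   `bias`, `ensemble` (with weights), `pca`, `fel`, `ranked`, `groups`,
#'   `representatives`, `refined`, `rc`, `path`, `us`, `pmf`, `affinity`,
#'   plus `config` and `seed`.
#' @export
dock_pipeline <- function(system = build_cryptic_system("cryptic3d"),
                          seed = 1, config = pipeline_config(),
                          verbose = interactive()) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_an <- config$t_analysis

  say("[1/8] bias fitting (%d iterations)", config$bias_iters)
  base_p <- langevin_params(n_steps = 1, timestep = config$timestep,
                            friction = config$friction, save_interval = 20)
  fb <- fit_bias(system, window = config$window, n_iter = config$bias_iters,
                 steps_rand = config$steps_rand,
                 steps_iter = config$steps_iter, growth = config$growth,
                 n_parallel = config$n_parallel_fit, params = base_p,
                 seed = seed)

  say("[2/8] multicanonical production (%d x %d steps)",
      config$n_parallel, config$steps_prod)
  p_prod <- langevin_params(config$steps_prod, timestep = config$timestep,
                            friction = config$friction,
                            temperature = fb$bias$t_sim,
                            save_interval = config$save_every,
                            rng_seed = seed + 500)
  ens <- run_mcmd(system, fb$bias, p_prod, n_parallel = config$n_parallel)
  ens <- filter(ens, .data$step > config$burn_in * config$steps_prod)
  ens <- reweight(ens, fb$bias, t_an)

  say("[3/8] distance features and weighted PCA")
  spec <- feature_spec(system)
  feats <- distance_features(ens, spec, system)
  pca <- weighted_pca(feats, ens$weight)
  fel <- build_fel(pca$scores, ens$weight, temperature = t_an)

  cc <- system$params$contact_cutoff %||% 4.5

  say("[4/8] K-means clustering and CFE ranking")
  cl <- kmeans_cluster(pca, ens$weight, k_prime = config$k_prime,
                       seed = seed + 11)
  ranked <- cluster_free_energy(cl, temperature = t_an)
  reps <- select_representative(cl, pca, ens$weight)
  # contact grouping over the clusters that could plausibly enter the
  # retained set (CFE within cutoff + merge headroom)
  pool <- ranked[ranked$cfe <= 3.5, ]
  rep_structs <- purrr::map(pool$cluster, function(k) {
    snapshot_structure(system, ens, reps$snapshot[reps$cluster == k])
  })
  names(rep_structs) <- as.character(pool$cluster)
  groups <- group_by_rvalue(pool, rep_structs, temperature = t_an,
                            contact_cutoff = cc)

  say("[5/8] canonical refinement of the top-ranked configuration")
  top_cluster <- groups$seed_cluster[1]
  r_coords <- snapshot_coords(ens, reps$snapshot[reps$cluster == top_cluster],
                              nrow(system$mobile0))
  native_ref <- pose_structure(system, system$params$bound_pose)
  refined <- refine_and_assess(system, r_coords, native_ref,
                               n_replicas = config$n_replicas,
                               params = langevin_params(
                                 config$steps_refine,
                                 timestep = config$timestep,
                                 friction = config$friction,
                                 rng_seed = seed + 900),
                               contact_cutoff = cc, superpose = FALSE)

  say("[6/8] unbinding direction and path construction")
  rc <- estimate_unbind_direction(system, refined$q_coords)
  path <- build_path(ens, system, ens$weight, refined$q_coords, rc, pca,
                     lambda_max = config$lambda_max,
                     lambda_min = config$lambda_min,
                     window_width = config$window_width,
                     n_min = config$n_min, contact_cutoff = cc,
                     seed = seed + 70)

  say("[7/8] umbrella sampling (%d windows)", nrow(path$windows))
  proto <- config$us_protocol
  proto$seed <- seed + 3000
  us <- run_us(system, path, proto)

  say("[8/8] WHAM and standard binding free energy")
  set.seed(seed + 4000)
  pmf <- wham(us, delta_lambda = config$delta_lambda, n_boot = config$n_boot,
              discard = config$discard, temperature = proto$t_prod)
  affinity <- standard_binding_free_energy(
    pmf, cylinder = list(radius = proto$cylinder_radius,
                         k = proto$cylinder_k),
    site_lambda_max = system$params$site_lambda_max,
    site_lambda_min = system$params$site_lambda_min)

  structure(list(bias = fb$bias, bias_history = fb$history, ensemble = ens,
                 pca = pca, fel = fel, clusters = cl, ranked = ranked,
                 representatives = reps, groups = groups, refined = refined,
                 rc = rc, path = path, us = us, pmf = pmf,
                 affinity = affinity, config = config, seed = seed),
            class = "dock_run")
}

#' @export
print.dock_run <- function(x, ...) {
  cat("<dock_run> seed", x$seed, "\n")
  cat("  snapshots:", nrow(x$ensemble), " retained PCs:", x$pca$m, "\n")
  cat("  groups within CFE cutoff:", nrow(x$groups), "\n")
  cat(sprintf("  dG (PMF plateau): %.2f kcal/mol;  dG_b0: %.2f kcal/mol\n",
              x$affinity$dg, x$affinity$dg_b0))
  invisible(x)
}

#' Reaction-coordinate position of the gate
#'
#' Projects the gate tether centre onto a reaction coordinate — the lambda
#' at which the cryptic gate obstructs passage, used to inspect path
#' diagnostics around the gate-opening region.
#'
#' @param system a cryptic3d `toy_system`.
#' @param rc a `reaction_coord`.
#' @return lambda of the gate in Angstrom.
#' @export
gate_lambda <- function(system, rc) {
  g <- system$ext[system$params$gate_index, 10:12]
  sum((g - rc$origin) * rc$direction)
}
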