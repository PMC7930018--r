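# shared fixtures, built once per test run and cached in this environment
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

dw_sym <- function() fixture("dw_sym", function() {
  build_cryptic_system("doublewell1d")
})

dw_tilted <- function() fixture("dw_tilted", function() {
  build_cryptic_system("doublewell1d", list(c = 0.5))
})

cryptic <- function() fixture("cryptic", function() {
  build_cryptic_system("cryptic3d")
})

# 1D integrator settings used throughout: small timestep because the
# flattened landscape has steep force-scale regions
dw_params <- function(n_steps, temperature = 300, seed = 1,
                      save_interval = 10) {
  langevin_params(n_steps, timestep = 5e-4, friction = 20,
                  temperature = temperature, save_interval = save_interval,
                  rng_seed = seed)
}

# multicanonical bias fitted on the tilted double well (heavier; shared by
# the mcmd unit tests and the reweighting acceptance check)
dw_bias_fit <- function() fixture("dw_bias_fit", function() {
  fit_bias(dw_tilted(), n_iter = 5, steps_rand = 60000, steps_iter = 100000,
           n_parallel = 2, params = dw_params(1), seed = 3)
})

# multicanonical production ensemble on the tilted double well, reweighted
# to 300 K, with per-trajectory alternating starting wells and burn-in
dw_mc_ensemble <- function() fixture("dw_mc_ensemble", function() {
  fb <- dw_bias_fit()
  init <- lapply(1:8, function(i) matrix(c(ifelse(i %% 2 == 0, 1, -1), 0, 0), 1))
  ens <- run_mcmd(dw_tilted(), fb$bias,
                  dw_params(150000, temperature = 700, seed = 11,
                            save_interval = 5),
                  n_parallel = 8, init = init)
  ens <- dplyr::filter(ens, step > 30000)
  reweight(ens, fb$bias, 300)
})

# weighted mean and per-trajectory standard error of an observable over a
# reweighted parallel ensemble
traj_mean_se <- function(ensemble, x) {
  pt <- vapply(split(seq_len(nrow(ensemble)), ensemble$traj), function(ix) {
    w <- ensemble$weight[ix]
    sum(w * x[ix]) / sum(w)
  }, numeric(1))
  list(mean = mean(pt), se = sd(pt) / sqrt(length(pt)))
}

# small deterministic 3D ensemble tibble from explicit mobile coordinates
manual_ensemble <- function(system, coord_list) {
  n <- nrow(system$mobile0)
  xs <- do.call(rbind, lapply(coord_list, function(m) as.vector(t(m))))
  colnames(xs) <- paste0(rep(c("x", "y", "z"), n), rep(seq_len(n), each = 3))
  dplyr::bind_cols(
    tibble::tibble(traj = 1L, step = seq_along(coord_list),
                   time_ps = seq_along(coord_list) * 1.0,
                   energy = 0, restraint_energy = 0, bias_energy = 0,
                   kinetic_energy = 0, biased = FALSE),
    tibble::as_tibble(xs)
  )
}
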