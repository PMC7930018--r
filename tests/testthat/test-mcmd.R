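test_that("initial bias estimation recovers an analytic density of states", {
  # harmonic 1D system built from the tether term: U = k x^2, with
  # configurational density of states n(E) proportional to E^(-1/2)
  sys <- build_cryptic_system("doublewell1d")
  sys$ext[1, ] <- 0
  sys$ext[1, 7] <- 1   # teth_k on x, centre 0: U = x^2
  sys$params$u <- function(x) x^2
  ens <- run_langevin(sys, dw_params(200000, temperature = 700, seed = 5,
                                     save_interval = 5))
  b <- estimate_initial_bias(ens, window = c(280, 700))
  # interval-mean of the fitted d ln n / dE over the well-sampled range
  # (exactly (ln n(b) - ln n(a)) / (b - a)) against the analytic
  # -1/2 d ln E/dE average; the mean smooths local polynomial wiggle
  ab <- quantile(ens$energy, c(0.2, 0.7))
  lnn_at <- function(e) sum(b$lnn_coef * e^(seq_along(b$lnn_coef) - 1))
  log_slope <- (lnn_at(ab[2]) - lnn_at(ab[1])) / (log(ab[2]) - log(ab[1]))
  # analytic exponent is -1/2; the polynomial smoothing of the integrable
  # E^(-1/2) singularity biases the mid-range slope somewhat steep, so the
  # fit tolerance is the band (-0.9, -0.3)
  expect_gt(log_slope, -0.9)
  expect_lt(log_slope, -0.3)
})

test_that("degenerate constant-energy ensembles are refused", {
  fake <- tibble::tibble(energy = rep(1.234, 500))
  expect_error(estimate_initial_bias(fake), "degenerate|span")
})

test_that("the initial bias broadens the sampled energy range", {
  fb <- dw_bias_fit()
  sys <- dw_tilted()
  rand <- run_langevin(sys, dw_params(60000, temperature = 700, seed = 3))
  b0 <- estimate_initial_bias(rand)
  biased <- run_mcmd(sys, b0, dw_params(60000, temperature = 700, seed = 91),
                     n_parallel = 1)
  expect_lte(min(biased$energy), min(rand$energy) + 0.05)
  expect_gt(diff(range(biased$energy)), diff(range(rand$energy)))
})

test_that("flat-histogram updates have the exact algebraic behaviour", {
  win <- c(280, 700)
  rts <- rt_kcal(700)
  mids <- seq(0.5, 5.5, by = 0.25)
  base <- mcmd_bias(grid = tibble::tibble(e = mids, b = -0.2 * mids),
                    emin = min(mids), emax = max(mids), window = win)
  mk_hist <- function(counts) {
    structure(tibble::tibble(lo = mids - 0.125, hi = mids + 0.125,
                             mid = mids, count = counts),
              class = c("energy_histogram", "tbl_df", "tbl", "data.frame"))
  }
  # fixed point: a perfectly flat histogram changes the bias only by an
  # additive constant
  b1 <- update_bias(base, mk_hist(rep(1000, length(mids))))
  d0 <- bias_energy(base, mids) - bias_energy(base, mids)[1]
  d1 <- bias_energy(b1, mids) - bias_energy(b1, mids)[1]
  expect_equal(d1, d0, tolerance = 1e-9)

  # a Boltzmann histogram under zero bias is cancelled in one step:
  # B'(E) = -E up to an additive constant on the sampled range
  zb <- zero_bias(window = win, range = range(mids))
  b2 <- update_bias(zb, mk_hist(1e6 * exp(-mids / rts)))
  d2 <- bias_energy(b2, mids)
  expect_equal(diff(d2), diff(-mids), tolerance = 1e-9)

  expect_error(update_bias(base, mk_hist(rep(0, length(mids)))), "empty")
})

test_that("iterative flattening converges below the 0.2 threshold", {
  fb <- dw_bias_fit()
  expect_lt(fb$history$flatness[5], 0.2)
  # progress: no later iteration is much worse than the first
  expect_true(all(fb$history$flatness[-1] <= fb$history$flatness[1] + 0.05))
})

test_that("production bookkeeping matches the parallel-trajectory contract", {
  sys <- dw_sym()
  ens <- run_mcmd(sys, zero_bias(), dw_params(2000, save_interval = 100),
                  n_parallel = 2)
  expect_equal(nrow(ens), 2 * 2000 / 100)
  expect_equal(sort(unique(ens$traj)), 1:2)
  # trajectory, then time ordering
  expect_true(!is.unsorted(order(ens$traj, ens$step)))
})

test_that("a zero bias reduces production to canonical sampling", {
  sys <- dw_tilted()
  # run_mcmd seeds trajectory i as base + i: trajectory 1 of a base-7 run
  # matches a plain run seeded 8 bitwise
  flat <- run_mcmd(sys, zero_bias(t_sim = 700),
                   dw_params(400000, temperature = 700, seed = 7,
                             save_interval = 5),
                   n_parallel = 1)
  plain <- run_langevin(sys, dw_params(400000, temperature = 700, seed = 8,
                                       save_interval = 5))
  expect_identical(plain$energy, flat$energy)
  # statistically indistinguishable from an independently seeded run;
  # subsample 2 ps apart so well-hopping correlation does not inflate the
  # Kolmogorov-Smirnov statistic
  other <- run_langevin(sys, dw_params(400000, temperature = 700, seed = 9,
                                       save_interval = 5))
  ks <- suppressWarnings(ks.test(flat$energy[seq(1, 80000, 800)],
                                 other$energy[seq(1, 80000, 800)]))
  expect_gt(ks$p.value, 0.01)
})

test_that("reweighting is normalized, refuses extrapolation, and has the identity case", {
  sys <- dw_tilted()
  ens <- run_mcmd(sys, zero_bias(t_sim = 700), dw_params(20000, 700, 13),
                  n_parallel = 2)
  rw <- reweight(ens, zero_bias(t_sim = 700), 700)
  expect_lt(max(abs(rw$weight - 1 / nrow(rw))), 1e-12)
  expect_equal(sum(rw$weight), 1, tolerance = 1e-12)
  expect_error(reweight(ens, zero_bias(t_sim = 700), 200), "outside")
  expect_error(reweight(ens, zero_bias(t_sim = 700), 800), "outside")
})

test_that("reweighted canonical averages match quadrature at both window ends", {
  sys <- dw_tilted()
  ens <- dw_mc_ensemble()
  fb <- dw_bias_fit()
  obs <- list(occ = function(x) as.numeric(x > 0),
              x = identity,
              x2 = function(x) x^2)
  for (t in c(300, 700)) {
    e <- reweight(ens, fb$bias, t)
    for (nm in names(obs)) {
      est <- traj_mean_se(e, obs[[nm]](e$x1))
      ref <- quadrature_reference(sys, t, obs[[nm]])
      expect_lt(abs(est$mean - ref), 3 * est$se + 1e-6)
    }
  }
})

test_that("reweighted energy distributions shift up with temperature", {
  ens <- dw_mc_ensemble()
  fb <- dw_bias_fit()
  means <- vapply(c(300, 500, 700), function(t) {
    e <- reweight(ens, fb$bias, t)
    sum(e$weight * e$energy)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("bias serialization and evaluation are consistent", {
  fb <- dw_bias_fit()
  b <- fb$bias
  es <- seq(b$emin - 1, b$emax + 1, length.out = 101)
  # piecewise-linear inside, declared slopes outside
  d <- bias_energy(b, es, deriv = TRUE)
  expect_equal(d[1], b$slope_lo)
  expect_equal(d[length(d)], b$slope_hi)
  expect_true(all(is.finite(bias_energy(b, es))))
  # t_mc diagnostic stays inside the window
  tm <- tidy(b)$t_mc
  expect_true(all(tm >= b$window[1] - 1e-9 & tm <= b$window[2] + 1e-9))
})
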