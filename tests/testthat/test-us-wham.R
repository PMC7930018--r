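test_that("umbrella fluctuations follow the harmonic closed form", {
  # near-free particle under a stiff umbrella: SD = sqrt(RT / (2 k_w)) for
  # the no-1/2 convention
  sys <- build_cryptic_system("doublewell1d", list(a = 1e-6))
  k_w <- 20
  umb <- restraint_umbrella(1, c(0, 0, 0), c(1, 0, 0), 0, k_w)
  p <- langevin_params(200000, timestep = 5e-4, friction = 10,
                       temperature = 300, save_interval = 1000, rng_seed = 9)
  tr <- run_langevin(sys, p, list(umb), init = matrix(0, 1, 3),
                     observer = list(idx = 1, origin = c(0, 0, 0),
                                     axis = c(1, 0, 0), every = 5))
  lam <- attr(tr, "lambda_series")
  expect_equal(sd(lam), sqrt(rt_kcal(300) / (2 * k_w)), tolerance = 0.07)
})

test_that("umbrella runs are deterministic and windows overlap", {
  ts <- us_1d(n_win = 8, steps = 8000)
  ts2 <- us_1d(n_win = 8, steps = 8000) # cached: same object
  expect_identical(ts$lambda, ts2$lambda)
  # every adjacent pair of windows shares occupied bins
  edges <- seq(min(ts$lambda), max(ts$lambda) + 0.05, by = 0.05)
  occ <- lapply(split(ts$lambda, ts$window), function(l) {
    unique(findInterval(l, edges))
  })
  for (j in seq_len(length(occ) - 1)) {
    expect_gt(length(intersect(occ[[j]], occ[[j + 1]])), 0)
  }
})

test_that("WHAM reduces to Boltzmann inversion for one unbiased window", {
  set.seed(14)
  sys <- dw_tilted()
  tr <- run_langevin(sys, langevin_params(60000, 0.002, 5, 300, 10, 31))
  ts <- tibble::tibble(window = 1L, lambda_c = 0, k_w = 0,
                       time_ps = seq_len(nrow(tr)), lambda = tr$x1)
  class(ts) <- c("us_timeseries", class(ts))
  pmf <- wham(ts, delta_lambda = 0.1, n_boot = 0, discard = 0)
  # direct histogram inversion
  edges <- seq(min(tr$x1) - 1e-9, max(tr$x1) + 0.1, by = 0.1)
  cnt <- tabulate(findInterval(tr$x1, edges), nbins = length(edges) - 1)
  ref <- -rt_kcal(300) * log(cnt[cnt > 0])
  ref <- ref - min(ref)
  expect_equal(pmf$pmf, ref, tolerance = 1e-9)
  expect_lte(attr(pmf, "residual"), attr(pmf, "tol"))
})

test_that("WHAM is invariant to relabelling data across identical windows", {
  ts <- us_1d(n_win = 8, steps = 8000)
  pmf1 <- wham(ts, n_boot = 0, discard = 0, plateau_bins = 10)
  # split window 4's production into two windows with the same bias
  ts2 <- ts
  i4 <- which(ts2$window == 4)
  ts2$window[i4[seq_along(i4) > length(i4) / 2]] <- 99L
  pmf2 <- wham(ts2, n_boot = 0, discard = 0, plateau_bins = 10)
  expect_equal(pmf1$pmf, pmf2$pmf, tolerance = 1e-6)
  # duplicating every window leaves the solution unchanged
  ts3 <- dplyr::bind_rows(ts, dplyr::mutate(ts, window = window + 100L))
  ts3 <- structure(ts3, class = c("us_timeseries", class(ts3)))
  pmf3 <- wham(ts3, n_boot = 0, discard = 0, plateau_bins = 10)
  expect_equal(pmf1$pmf, pmf3$pmf, tolerance = 1e-6)
})

test_that("disjoint window histograms are refused with an overlap report", {
  ts <- tibble::tibble(
    window = rep(1:2, each = 50), lambda_c = rep(c(0, 10), each = 50),
    k_w = 50, time_ps = 1:100,
    lambda = c(rnorm(50, 0, 0.05), rnorm(50, 10, 0.05))
  )
  class(ts) <- c("us_timeseries", class(ts))
  expect_error(wham(ts, n_boot = 0, discard = 0), "disjoint")
})

test_that("half-trajectory affinities agree within the bootstrap error", {
  ts <- us_1d()
  set.seed(20)
  p1 <- wham(ts, n_boot = 40, discard = 0.5, plateau_bins = 10)
  ts_first <- dplyr::filter(dplyr::group_by(ts, window),
                            dplyr::row_number() <= dplyr::n() / 2)
  ts_first <- structure(dplyr::ungroup(ts_first),
                        class = class(ts))
  set.seed(21)
  p2 <- wham(ts_first, n_boot = 40, discard = 0, plateau_bins = 10)
  eps <- sqrt(attr(p1, "eps")^2 + attr(p2, "eps")^2)
  expect_lt(abs(attr(p1, "dg") - attr(p2, "dg")), 3 * eps + 0.05)
})

test_that("the standard-state correction has its exact limiting cases", {
  ts <- us_1d(n_win = 8, steps = 8000)
  pmf <- wham(ts, n_boot = 0, discard = 0.2, plateau_bins = 10)
  out <- standard_binding_free_energy(pmf, v_eff_bound = 1660,
                                      v_eff_unbound = 1660,
                                      variant = "volume_ratio")
  expect_equal(out$dg_b0, -out$dg, tolerance = 1e-12)
  # cylinder effective area approaches the hard-disk limit for stiff walls
  a_soft <- mcdock:::cylinder_area(8, 0.1, 300)
  a_stiff <- mcdock:::cylinder_area(8, 100, 300)
  expect_gt(a_soft, pi * 64)
  expect_equal(a_stiff, pi * 64, tolerance = 0.01 * pi * 64)
  expect_error(standard_binding_free_energy(pmf, variant = "volume_ratio",
                                            bound_com = matrix(0, 5, 3),
                                            unbound_com = matrix(0, 5, 3)),
               "COM samples")
})
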