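# umbrella timeseries on the 1D double well, shared across WHAM tests
us_1d <- function(n_win = 20, steps = 50000, lo = -1.6, hi = 1.6, seed = 100) {
  fixture(paste0("us1d_", n_win, "_", steps, "_", seed), function() {
    sys <- dw_tilted()
    centers <- seq(lo, hi, length.out = n_win)
    ww <- diff(centers[1:2])
    k_w <- rt_kcal(300) / ww^2
    out <- lapply(seq_along(centers), function(i) {
      umb <- restraint_umbrella(1, c(0, 0, 0), c(1, 0, 0), centers[i], k_w)
      p <- langevin_params(steps, timestep = 0.002, friction = 5,
                           temperature = 300, save_interval = 10,
                           rng_seed = seed + i)
      tr <- run_langevin(sys, p, list(umb),
                         init = matrix(c(centers[i], 0, 0), 1),
                         observer = list(idx = 1, origin = c(0, 0, 0),
                                         axis = c(1, 0, 0), every = 10))
      lam <- attr(tr, "lambda_series")
      tibble::tibble(window = i, lambda_c = centers[i], k_w = k_w,
                     time_ps = seq_along(lam) * 0.02, lambda = lam)
    })
    res <- dplyr::bind_rows(out)
    structure(res, class = c("us_timeseries", class(res)))
  })
}
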