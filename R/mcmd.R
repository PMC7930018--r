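#' Multicanonical bias objects
#'
#' A multicanonical bias maps potential energy E (kcal/mol) to a bias energy
#' B(E) added to the physical potential, such that dynamics at the sampling
#' temperature `t_sim` under E + B(E) produce a flat energy histogram over
#' the energy range visited canonically between `t_low` and `t_high`.  B is
#' represented either as a piecewise-linear grid over the valid range
#' `[emin, emax]` (the default used by the fitting routines) or as a
#' polynomial, with linear extrapolation outside the range: below `emin`
#' the slope corresponds to canonical sampling at `t_low` (boosting low
#' energies), above `emax` to canonical sampling at `t_sim`.
#'
#' The effective-temperature map `t_mc(E)` is derived from the fitted
#' ln-density-of-states and clamped to the window; it is a diagnostic and is
#' not re-inserted into the bias (for low-dimensional systems the
#' configurational density of states can decrease with E, which a hard
#' temperature clamp could not flatten).
#'
#' @param coef polynomial coefficients of B(E), ascending powers (polynomial
#'   representation).
#' @param grid tibble/data frame with columns `e`, `b`: bias values on an
#'   energy grid, interpolated piecewise-linearly (the default
#'   representation used by the fitting routines; robust where a global
#'   polynomial oscillates).
#' @param lnn_coef polynomial coefficients of the fitted ln-density-of-states
#'   (diagnostic; drives the `t_mc` map).
#' @param emin,emax valid energy range (kcal/mol).
#' @param window temperature window `c(t_low, t_high)` in K.
#' @param t_sim thermostat temperature of the biased runs (defaults to
#'   `t_high`).
#' @param degree polynomial degree used for the ln-density fits.
#' @param iteration bias-refinement iteration index.
#' @param max_scale numerical-stability clamp on the force scale |1 + dB/dE|.
#' @return an object of class `mcmd_bias`.
#' @export
mcmd_bias <- function(coef = NULL, emin, emax, window, t_sim = window[2],
                      grid = NULL, lnn_coef = NULL, degree = 8L,
                      iteration = 0L, max_scale = 10) {
  stopifnot(emax > emin, window[2] > window[1])
  if (is.null(coef) && is.null(grid)) abort("need `coef` or `grid`")
  if (!is.null(grid)) {
    stopifnot(nrow(grid) >= 2)
    o <- order(grid$e)
    grid <- tibble(e = grid$e[o], b = grid$b[o])
    # the valid range is exactly the grid support; extrapolation beyond it is
    # linear with the declared edge slopes everywhere (integrator and
    # reweighting evaluate the identical function)
    emin <- grid$e[1]
    emax <- grid$e[nrow(grid)]
    # clamp segment slopes so |1 + dB/dE| <= max_scale *in the stored bias*
    # (the integrator applies the same bound, keeping the sampled ensemble
    # and the reweighting formula exactly consistent); residual beyond the
    # clamp is carried into the following segments so that sharp
    # density-of-states steps are realised over a few bins instead of being
    # discarded
    de <- diff(grid$e)
    raw <- diff(grid$b) / de
    db <- numeric(length(raw))
    carry <- 0
    for (i in seq_along(raw)) {
      want <- raw[i] + carry / de[i]
      db[i] <- pmin(pmax(want, -1 - max_scale), max_scale - 1)
      carry <- (want - db[i]) * de[i]
    }
    grid$b <- grid$b[1] + c(0, cumsum(db * de))
  }
  structure(list(
    coef = coef, grid = grid, emin = emin, emax = emax, window = window,
    t_sim = t_sim, lnn_coef = lnn_coef, degree = degree,
    iteration = as.integer(iteration), max_scale = max_scale,
    slope_lo = t_sim / window[1] - 1, slope_hi = 0
  ), class = "mcmd_bias")
}

#' @rdname mcmd_bias
#' @param range energy range covered by the zero bias.
#' @export
zero_bias <- function(window = c(280, 700), t_sim = window[2],
                      range = c(-1, 1) * 1e6) {
  mcmd_bias(coef = c(0, 0), emin = range[1], emax = range[2], window = window,
            t_sim = t_sim)
}

bias_for_cpp <- function(bias) {
  list(coef = bias$coef, grid_e = bias$grid$e, grid_b = bias$grid$b,
       emin = bias$emin, emax = bias$emax,
       slope_lo = bias$slope_lo, slope_hi = bias$slope_hi,
       max_scale = bias$max_scale %||% 4)
}

polyval <- function(coef, x) {
  v <- rep(0, length(x))
  for (i in rev(seq_along(coef))) v <- v * x + coef[i]
  v
}

polyderiv <- function(coef) {
  if (length(coef) <= 1) return(0)
  coef[-1] * seq_len(length(coef) - 1)
}

#' Evaluate a multicanonical bias
#'
#' @param bias an `mcmd_bias`.
#' @param e potential energies (kcal/mol).
#' @param deriv if `TRUE` return dB/dE instead of B.
#' @return bias energies B(e) (kcal/mol), with linear extrapolation outside
#'   the valid range.
#' @export
bias_energy <- function(bias, e, deriv = FALSE) {
  ec <- pmin(pmax(e, bias$emin), bias$emax)
  if (!is.null(bias$grid)) {
    fit <- stats::approxfun(bias$grid$e, bias$grid$b, rule = 2)
    if (deriv) {
      db <- diff(bias$grid$b) / diff(bias$grid$e)
      seg <- pmin(pmax(findInterval(ec, bias$grid$e), 1), length(db))
      v <- db[seg]
    } else {
      v <- fit(ec)
      v_lo <- fit(bias$emin); v_hi <- fit(bias$emax)
    }
  } else {
    if (deriv) {
      v <- polyval(polyderiv(bias$coef), ec)
    } else {
      v <- polyval(bias$coef, ec)
      v_lo <- polyval(bias$coef, bias$emin)
      v_hi <- polyval(bias$coef, bias$emax)
    }
  }
  lo <- e < bias$emin
  hi <- e > bias$emax
  if (deriv) {
    v[lo] <- bias$slope_lo
    v[hi] <- bias$slope_hi
  } else {
    v[lo] <- v_lo + bias$slope_lo * (e[lo] - bias$emin)
    v[hi] <- v_hi + bias$slope_hi * (e[hi] - bias$emax)
  }
  v
}

# clamped effective-temperature diagnostic from the ln n(E) fit
tmc_map <- function(bias, e) {
  if (is.null(bias$lnn_coef)) return(rep(NA_real_, length(e)))
  g <- polyval(polyderiv(bias$lnn_coef), e)
  t <- ifelse(g <= 0, bias$window[2], 1 / (R_KCAL * g))
  pmin(pmax(t, bias$window[1]), bias$window[2])
}

#' @export
print.mcmd_bias <- function(x, ...) {
  cat("<mcmd_bias> iteration", x$iteration,
      sprintf("| window %g-%g K | valid E range [%.3g, %.3g] kcal/mol\n",
              x$window[1], x$window[2], x$emin, x$emax))
  invisible(x)
}

#' @export
tidy.mcmd_bias <- function(x, n = 200, ...) {
  e <- seq(x$emin, x$emax, length.out = n)
  tibble(energy = e, bias = bias_energy(x, e), t_mc = tmc_map(x, e))
}

#' @export
glance.mcmd_bias <- function(x, ...) {
  tibble(t_low = x$window[1], t_high = x$window[2], t_sim = x$t_sim,
         emin = x$emin, emax = x$emax, degree = x$degree,
         iteration = x$iteration)
}

#' @export
autoplot.mcmd_bias <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$energy, .data$bias)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "potential energy (kcal/mol)", y = "bias B(E) (kcal/mol)",
                  title = sprintf("multicanonical bias, iteration %d",
                                  object$iteration))
}

#' Potential-energy histogram and flatness score
#'
#' Bins the `energy` column of an ensemble.  The flatness score is the
#' coefficient of variation of the bin counts within `range` (smaller is
#' flatter); bias iteration targets a score below 0.2.
#'
#' @param ensemble ensemble tibble with an `energy` column.
#' @param bin_width bin width in kcal/mol; default is Scott's rule.
#' @return a tibble of class `energy_histogram` with `mid`, `lo`, `hi`,
#'   `count` and attributes `total` and `bin_width`.
#' @export
energy_histogram <- function(ensemble, bin_width = NULL) {
  e <- ensemble$energy
  if (length(e) < 2 || diff(range(e)) < 1e-9) {
    abort("degenerate ensemble: energies span (almost) no range")
  }
  if (is.null(bin_width)) bin_width <- 3.49 * sd(e) / length(e)^(1 / 3)
  edges <- seq(min(e) - 1e-9, max(e) + bin_width, by = bin_width)
  cnt <- tabulate(findInterval(e, edges), nbins = length(edges) - 1)
  out <- tibble(lo = edges[-length(edges)], hi = edges[-1],
                mid = (edges[-1] + edges[-length(edges)]) / 2, count = cnt)
  structure(out, total = length(e), bin_width = bin_width,
            class = c("energy_histogram", class(out)))
}

#' @rdname energy_histogram
#' @param histogram an `energy_histogram`.
#' @param range optional energy range `c(lo, hi)` over which to score.
#' @export
flatness_score <- function(histogram, range = NULL) {
  h <- histogram
  if (!is.null(range)) h <- h[h$mid >= range[1] & h$mid <= range[2], ]
  if (nrow(h) == 0) return(NA_real_)
  sd(h$count) / mean(h$count)
}

#' Estimate an initial multicanonical bias from a high-temperature ensemble
#'
#' From a canonical randomization run at `t_high`, the ln-density-of-states
#' is estimated as \eqn{\ln n(E) = \ln P(E) + E/(R T_{high})} on the sampled
#' range and fitted with a polynomial; the initial bias
#' \eqn{B(E) = -E + R T_{sim} \ln n(E)} flattens the energy histogram on
#' that range, with low-energy extrapolation at `t_low` driving the sampled
#' range downward over subsequent iterations.
#'
#' @param ensemble canonical ensemble sampled at `window[2]`.
#' @param window temperature window `c(t_low, t_high)` in K.
#' @param t_sim thermostat temperature of biased runs (default `t_high`).
#' @param degree polynomial fit degree (default 8).
#' @param bin_width histogram bin width; default Scott's rule.
#' @param min_bins minimum number of populated bins required.
#' @return an `mcmd_bias` (iteration 0).
#' @export
estimate_initial_bias <- function(ensemble, window = c(280, 700),
                                  t_sim = window[2], degree = 8,
                                  bin_width = NULL, min_bins = 10,
                                  tail_quantile = 0.995) {
  h <- energy_histogram(ensemble, bin_width)
  occ <- h[h$count > 0, ]
  # the flattening target ends at the energies a canonical t_high run
  # meaningfully visits; the sparse extreme tail would destabilise the fit
  ecap <- quantile(ensemble$energy, tail_quantile)
  if (any(occ$mid <= ecap)) occ <- occ[occ$mid <= ecap, ]
  if (nrow(occ) < min_bins) {
    abort(sprintf("ensemble populates only %d bins (< %d): too small to fit a bias",
                  nrow(occ), min_bins))
  }
  deg <- min(degree, nrow(occ) - 2)
  lnn <- log(occ$count / sum(occ$count)) + occ$mid / (R_KCAL * window[2])
  fit <- lm(lnn ~ poly(e, degree = deg, raw = TRUE),
            data = data.frame(e = occ$mid, lnn = lnn), weights = occ$count)
  lnn_coef <- as.numeric(coef(fit))
  # the bias itself lives on a per-bin grid: B = -E + R t_sim ln n(E)
  b_grid <- -occ$mid + R_KCAL * t_sim * lnn
  mcmd_bias(grid = tibble(e = occ$mid, b = b_grid),
            emin = min(occ$mid), emax = max(occ$mid),
            window = window, t_sim = t_sim, lnn_coef = lnn_coef,
            degree = degree, iteration = 0L)
}

#' Flat-histogram bias update
#'
#' Applies the standard multicanonical correction
#' \eqn{B'(E) = B(E) + R T_{sim} \ln P_{mc}(E)} on the sampled range, where
#' \eqn{P_{mc}} is the energy histogram obtained under the current bias, and
#' refits the polynomial.  A perfectly flat histogram leaves the bias
#' unchanged up to an additive constant.
#'
#' @param bias current `mcmd_bias`.
#' @param histogram an [energy_histogram()] from a run under `bias`.
#' @param min_count bins with fewer samples than this take no part in the
#'   update: the valid range only extends into regions with statistical
#'   support, preventing sparsely-visited energies from acquiring spuriously
#'   attractive bias values that would trap later runs.
#' @return updated `mcmd_bias` with the valid range extended to the sampled
#'   range.
#' @export
update_bias <- function(bias, histogram, min_count = 10) {
  occ <- histogram[histogram$count > 0, ]
  if (nrow(occ) == 0) abort("empty histogram")
  if (any(occ$count >= min_count)) occ <- occ[occ$count >= min_count, ]
  # flattening targets the window's energy range only: the valid range may
  # grow downward (towards the T_low regime) but is capped above by the
  # initial T_high estimate -- beyond it sampling stays canonical at t_sim
  if (any(occ$mid <= bias$emax)) occ <- occ[occ$mid <= bias$emax, ]
  rts <- R_KCAL * bias$t_sim
  target <- bias_energy(bias, occ$mid) + rts * log(occ$count / sum(occ$count))
  # diagnostic ln-density-of-states fit: ln n = (E + B)/(R t_sim) up to const
  deg <- max(1, min(bias$degree, nrow(occ) - 2))
  lnn <- (occ$mid + target) / rts
  lf <- lm(y ~ poly(e, degree = deg, raw = TRUE),
           data = data.frame(e = occ$mid, y = lnn), weights = occ$count)
  lnn_coef <- as.numeric(coef(lf))
  lnn_coef[is.na(lnn_coef)] <- 0
  mcmd_bias(grid = tibble(e = occ$mid, b = target),
            emin = min(occ$mid), emax = bias$emax,
            window = bias$window, t_sim = bias$t_sim, lnn_coef = lnn_coef,
            degree = bias$degree, iteration = bias$iteration + 1L)
}

#' Iterative bias fitting
#'
#' Convenience driver for the full flattening protocol: a canonical
#' randomization run at `t_high`, an initial bias estimate, then `n_iter`
#' rounds of biased sampling and flat-histogram updates.  The flatness score
#' is tracked per iteration over the target range (the reweighted mean
#' energies at `t_low` and `t_high`).
#'
#' @param system a `toy_system`.
#' @param window temperature window `c(t_low, t_high)` in K.
#' @param n_iter number of update iterations.
#' @param steps_rand steps of the randomization run.
#' @param steps_iter steps of the first refinement iteration.
#' @param growth length multiplier between successive iterations (the
#'   protocol uses iterations of increasing length so that newly flattened
#'   low-energy regions accumulate adequate statistics).
#' @param n_parallel parallel trajectories per iteration.
#' @param params base [langevin_params()] (temperature/steps are overridden
#'   per stage).
#' @param restraints restraints active during all stages.
#' @param seed base seed.
#' @return list with `bias` (final `mcmd_bias`), `history` (tibble of
#'   flatness per iteration) and `ensemble` (last iteration's ensemble).
#' @export
fit_bias <- function(system, window = c(280, 700), n_iter = 5,
                     steps_rand = 20000, steps_iter = 40000, n_parallel = 2,
                     growth = 1.5,
                     params = langevin_params(n_steps = 1), restraints = list(),
                     seed = 1) {
  p_rand <- params
  p_rand$n_steps <- as.integer(steps_rand)
  p_rand$temperature <- window[2]
  p_rand$rng_seed <- seed
  rand <- run_langevin(system, p_rand, restraints)
  bias <- estimate_initial_bias(rand, window = window)

  hist_rows <- list()
  ens <- rand
  for (it in seq_len(n_iter)) {
    p_it <- params
    p_it$n_steps <- as.integer(round(steps_iter * growth^(it - 1)))
    p_it$temperature <- bias$t_sim
    p_it$rng_seed <- seed + 1000 * it
    ens <- run_mcmd(system, bias, p_it, n_parallel = n_parallel,
                    restraints = restraints)
    # bin finely over the flattening range (counts stay in the hundreds)
    h <- energy_histogram(ens, bin_width = (bias$emax - bias$emin) / 40)
    # flatness is scored over the energy range spanned by the temperature
    # window: the reweighted mean energies at t_low and t_high
    tr <- tryCatch(sort(c(
      sum(reweight(ens, bias, bias$window[1])$weight * ens$energy),
      sum(reweight(ens, bias, bias$window[2])$weight * ens$energy)
    )), error = function(e) c(bias$emin, bias$emax))
    if (diff(tr) < 1e-6) tr <- c(bias$emin, bias$emax)
    hf <- energy_histogram(ens, bin_width = diff(tr) / 10)
    hist_rows[[it]] <- tibble(iteration = it,
                              flatness = flatness_score(hf, tr),
                              target_lo = tr[1], target_hi = tr[2],
                              emin = min(ens$energy), emax = max(ens$energy))
    bias <- update_bias(bias, h)
  }
  list(bias = bias, history = dplyr::bind_rows(hist_rows), ensemble = ens)
}

#' Multicanonical production sampling
#'
#' Runs `n_parallel` biased trajectories seeded as `base seed + trajectory
#' index` and concatenates them (ordered by trajectory, then time) into one
#' multicanonical ensemble.  With a zero bias this reduces exactly to
#' canonical sampling at `t_sim`.
#'
#' @param system a `toy_system`.
#' @param bias an `mcmd_bias` (use [zero_bias()] for unbiased runs).
#' @param params [langevin_params()]; the thermostat temperature should be
#'   `bias$t_sim`, and `rng_seed` is used as the base seed.
#' @param n_parallel number of trajectories.
#' @param restraints restraints active during sampling.
#' @param init optional list of per-trajectory starting coordinate matrices.
#' @return the concatenated ensemble tibble (see [run_langevin()]).
#' @export
run_mcmd <- function(system, bias, params, n_parallel = 1, restraints = list(),
                     init = NULL) {
  stopifnot(n_parallel >= 1)
  out <- vector("list", n_parallel)
  for (i in seq_len(n_parallel)) {
    p <- params
    p$rng_seed <- params$rng_seed + i
    out[[i]] <- run_langevin(system, p, restraints, bias = bias,
                             init = if (is.null(init)) NULL else init[[i]],
                             traj = i)
  }
  ens <- dplyr::bind_rows(out)
  attr(ens, "bias") <- bias
  ens
}

#' Canonical reweighting of a multicanonical ensemble
#'
#' Computes normalized per-snapshot canonical weights at temperature `t`:
#' \deqn{w_j \propto \exp\left[\frac{E_j + B(E_j)}{R T_{sim}} -
#'   \frac{E_j}{R T}\right]}
#' where `E_j` is the recorded potential energy and B the bias the ensemble
#' was generated under.  With a zero bias and `t = t_sim` the weights are
#' uniform.
#'
#' @param ensemble multicanonical ensemble tibble.
#' @param bias the `mcmd_bias` the ensemble was generated under.
#' @param temperature target temperature in K; must lie within the bias
#'   window (extrapolation outside it is unreliable and refused).
#' @return the ensemble with a normalized `weight` column added (sums to 1).
#' @export
reweight <- function(ensemble, bias, temperature) {
  if (temperature < bias$window[1] - 1e-9 || temperature > bias$window[2] + 1e-9) {
    abort(sprintf("temperature %g K outside the bias window [%g, %g] K",
                  temperature, bias$window[1], bias$window[2]))
  }
  e <- ensemble$energy
  lw <- (e + bias_energy(bias, e)) / (R_KCAL * bias$t_sim) -
    e / (R_KCAL * temperature)
  lw <- lw - max(lw)
  w <- exp(lw)
  ensemble$weight <- w / sum(w)
  attr(ensemble, "reweight") <- list(temperature = temperature,
                                     ess = effective_sample_size(ensemble$weight))
  ensemble
}

#' Effective sample size of a normalized weight vector
#'
#' Kish effective sample size \eqn{(\sum w)^2 / \sum w^2}; used for honest
#' standard errors of reweighted averages.
#'
#' @param w weights (need not be normalized).
#' @return effective number of independent samples.
#' @export
effective_sample_size <- function(w) sum(w)^2 / sum(w^2)

#' Weighted mean with a reweighting standard error
#'
#' @param x observable values per snapshot.
#' @param w normalized weights.
#' @return tibble with `mean` and `se` (standard error based on the
#'   effective sample size).
#' @export
weighted_mean_se <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  tibble(mean = m, se = sqrt(v / effective_sample_size(w)))
}
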