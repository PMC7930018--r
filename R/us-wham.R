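#' Umbrella-sampling protocol parameters
#'
#' Stage lengths are in integration steps of the toy-scale protocol: a
#' position-restrained equilibration at the stress temperature, unrestrained
#' umbrella sampling at the stress temperature, a linear anneal down to the
#' production temperature, and the production run at the production
#' temperature, mirroring the restrained-equilibration / hot US / anneal /
#' production staging of all-atom path sampling.
#'
#' @param equil_steps restrained equilibration steps (at `t_hot`).
#' @param hot_steps unrestrained US steps at `t_hot`.
#' @param anneal_steps linear `t_hot` to `t_prod` anneal steps.
#' @param prod_steps production steps at `t_prod`.
#' @param t_hot,t_prod stage temperatures in K.
#' @param timestep,friction integrator settings.
#' @param com_every record the ligand COM reaction coordinate every this
#'   many production steps.
#' @param save_every snapshot save interval in production steps.
#' @param cylinder_radius,cylinder_k perpendicular cylinder restraint
#'   (defaults 8 Angstrom, 0.1 kcal/mol/A^2).
#' @param k_w umbrella force constant; `NULL` selects the adaptive default
#'   \eqn{k_w = RT/w^2} for window width w, matching fluctuations to the
#'   window spacing.
#' @param posres_k position-restraint force constant during equilibration.
#' @param seed base seed (window i adds i).
#' @return a list of class `us_protocol`.
#' @export
us_protocol <- function(equil_steps = 4000, hot_steps = 40000,
                        anneal_steps = 12000, prod_steps = 400000,
                        t_hot = 400, t_prod = 300, timestep = 0.005,
                        friction = 1, com_every = 10, save_every = 100,
                        cylinder_radius = 8, cylinder_k = 0.1, k_w = NULL,
                        posres_k = 10, seed = 1) {
  structure(as.list(environment()), class = "us_protocol")
}

#' Run umbrella sampling along the reaction coordinate
#'
#' One simulation per path window, started from the window's first picked
#' structure, restrained to the window centre along \eqn{\lambda} by a
#' harmonic umbrella and held perpendicularly inside a cylinder around the
#' unbinding axis.  No other distance restraints are applied.  Each window
#' follows the staged protocol of [us_protocol()]; the production
#' \eqn{\lambda} time series (recorded every `com_every` steps) is
#' returned together with the restraint parameters WHAM needs.
#'
#' @param system a `toy_system`.
#' @param path a `path_windows` from [build_path()] (or a tibble with
#'   `lambda_c` and list-column `coords` of starting structures).
#' @param protocol a [us_protocol()].
#' @param windows optional window subset (e.g. to exclude end windows).
#' @return tibble of class `us_timeseries` with columns `window`,
#'   `lambda_c`, `k_w`, `time_ps`, `lambda`; attributes `protocol`, `rc`.
#' @export
run_us <- function(system, path, protocol = us_protocol(), windows = NULL) {
  rc <- attr(path, "rc")
  ww <- attr(path, "window_width") %||% 0.5
  k_w <- protocol$k_w %||% (rt_kcal(protocol$t_prod) / ww^2)
  starts <- path$picks |>
    group_by(.data$window) |>
    slice(1) |>
    ungroup()
  starts <- left_join(starts, path$windows[, c("window", "lambda_c", "gap")],
                      by = "window")
  starts <- starts[!starts$gap, ]
  if (!is.null(windows)) starts <- starts[starts$window %in% windows, ]
  lig <- system$params$ligand_index
  out <- purrr::map(seq_len(nrow(starts)), function(i) {
    w <- starts$window[i]
    x0 <- starts$coords[[i]]
    umb <- restraint_umbrella(lig, rc$origin, rc$direction,
                              center = starts$lambda_c[i], k = k_w)
    cyl <- restraint_cylinder(lig, rc$origin, rc$direction,
                              radius = protocol$cylinder_radius,
                              k = protocol$cylinder_k)
    res <- list(umb, cyl)
    seed_i <- protocol$seed + w
    # stage 1: position-restrained equilibration at t_hot
    p1 <- langevin_params(protocol$equil_steps, protocol$timestep,
                          protocol$friction, protocol$t_hot,
                          save_interval = protocol$equil_steps,
                          rng_seed = seed_i)
    posres <- restraint_position_hold(seq_len(nrow(x0)), x0, protocol$posres_k)
    s1 <- run_langevin(system, p1, c(res, list(posres)), init = x0)
    st <- attr(s1, "final_state")
    # stage 2: hot US
    p2 <- langevin_params(protocol$hot_steps, protocol$timestep,
                          protocol$friction, protocol$t_hot,
                          save_interval = protocol$hot_steps,
                          rng_seed = seed_i + 1e4)
    s2 <- run_langevin(system, p2, res, init = st$coords, init_vel = st$vel)
    st <- attr(s2, "final_state")
    # stage 3: anneal t_hot -> t_prod
    tween <- seq(protocol$t_hot, protocol$t_prod,
                 length.out = protocol$anneal_steps)
    p3 <- langevin_params(protocol$anneal_steps, protocol$timestep,
                          protocol$friction, tween,
                          save_interval = protocol$anneal_steps,
                          rng_seed = seed_i + 2e4)
    s3 <- run_langevin(system, p3, res, init = st$coords, init_vel = st$vel)
    st <- attr(s3, "final_state")
    # stage 4: production with lambda observer
    p4 <- langevin_params(protocol$prod_steps, protocol$timestep,
                          protocol$friction, protocol$t_prod,
                          save_interval = protocol$save_every,
                          rng_seed = seed_i + 3e4)
    s4 <- run_langevin(system, p4, res, init = st$coords, init_vel = st$vel,
                       observer = list(idx = lig, origin = rc$origin,
                                       axis = rc$direction,
                                       every = protocol$com_every))
    lam <- attr(s4, "lambda_series")
    if (abs(mean(lam) - starts$lambda_c[i]) > 3 * sd(lam)) {
      warn(sprintf("window %d: mean lambda %.2f drifts > 3 sd from centre %.2f (poor overlap?)",
                   w, mean(lam), starts$lambda_c[i]))
    }
    tibble(window = w, lambda_c = starts$lambda_c[i], k_w = k_w,
           time_ps = seq_along(lam) * protocol$com_every * protocol$timestep,
           lambda = lam)
  })
  res <- dplyr::bind_rows(out)
  structure(res, protocol = protocol, rc = rc,
            class = c("us_timeseries", class(res)))
}

# WHAM self-consistent iteration; timeseries columns: window, lambda_c, k_w,
# lambda.  Returns the unnormalised density rho per bin and window free
# energies f.
wham_solve <- function(counts, n_j, bias_mat, rt, tol, max_iter = 200000,
                       f_init = NULL) {
  n_win <- length(n_j)
  f <- f_init %||% rep(0, n_win)
  c_jb <- exp(-bias_mat / rt) # n_win x n_bins
  for (it in seq_len(max_iter)) {
    denom <- colSums(n_j * exp(f / rt) * c_jb)
    rho <- counts / denom
    f_new <- -rt * log(as.numeric(c_jb %*% rho))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) {
      return(list(rho = rho, f = f, iterations = it, residual = delta))
    }
  }
  warn("WHAM did not reach tolerance within max_iter")
  list(rho = rho, f = f, iterations = max_iter, residual = delta)
}

# integrated autocorrelation time (in samples) of a series, initial positive
# sequence estimator
iact <- function(x, max_lag = min(1000, length(x) - 1)) {
  a <- acf(x, lag.max = max_lag, plot = FALSE)$acf[-1]
  pos <- which(a <= 0)
  m <- if (length(pos)) pos[1] - 1 else length(a)
  max(1, 1 + 2 * sum(a[seq_len(m)]))
}

#' Weighted histogram analysis of umbrella-sampling data
#'
#' Solves the WHAM equations over \eqn{\lambda} bins of width
#' `delta_lambda` to self-consistency `tol`, returning the min-normalized
#' potential of mean force with block-bootstrap errors.  The binding free
#' energy \eqn{\Delta G} is the average PMF over the final 50 bins (the
#' unbound plateau), \eqn{\sigma} its standard deviation over those bins
#' and \eqn{\epsilon} the average bootstrap error over the same range.
#'
#' @param timeseries a `us_timeseries` (columns `window`, `lambda_c`,
#'   `k_w`, `lambda`).
#' @param delta_lambda bin width in Angstrom (default 0.05).
#' @param tol self-consistency tolerance on the window free energies
#'   (default 1e-8 kcal/mol).
#' @param n_boot number of bootstrap resamples (default 1000; 0 disables).
#' @param discard equilibration fraction of each window discarded before
#'   analysis (default 0.6, mirroring keeping the final 100 of 250 ns).
#' @param temperature temperature in K.
#' @param plateau_bins number of final bins defining the plateau (default
#'   50).
#' @param block_factor bootstrap block length in multiples of the
#'   integrated autocorrelation time (default 10).
#' @return tibble of class `pmf_profile` with `lambda` (bin centres),
#'   `pmf`, `err`; attributes carry `dg`, `sigma`, `eps`, `dg_span`,
#'   window free energies and the WHAM iteration diagnostics.  See
#'   [glance.pmf_profile()].
#' @export
wham <- function(timeseries, delta_lambda = 0.05, tol = 1e-8, n_boot = 1000,
                 discard = 0.6, temperature = 300, plateau_bins = 50,
                 block_factor = 10) {
  rt <- rt_kcal(temperature)
  ts <- timeseries |>
    group_by(.data$window) |>
    filter(row_number() > floor(discard * n())) |>
    ungroup()
  wins <- ts |>
    group_by(.data$window) |>
    summarise(lambda_c = first(.data$lambda_c), k_w = first(.data$k_w),
              n = n(), .groups = "drop")
  edges <- seq(min(ts$lambda) - 1e-9, max(ts$lambda) + delta_lambda,
               by = delta_lambda)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bin_of <- function(x) findInterval(x, edges)
  count_hist <- function(lam) tabulate(bin_of(lam), nbins = length(mids))
  counts <- count_hist(ts$lambda)
  # windows x bins bias energy (no-1/2 harmonic convention)
  bias_mat <- outer(seq_len(nrow(wins)), seq_along(mids), function(j, b) {
    wins$k_w[j] * (mids[b] - wins$lambda_c[j])^2
  })
  # adjacent-window (in lambda order) histogram overlap check
  per_win <- purrr::map(wins$window, function(w) count_hist(ts$lambda[ts$window == w]))
  if (nrow(wins) > 1) {
    ow <- order(wins$lambda_c)
    ov <- vapply(seq_len(nrow(wins) - 1), function(j) {
      sum(pmin(per_win[[ow[j]]] > 0, per_win[[ow[j + 1]]] > 0))
    }, numeric(1))
    if (any(ov == 0)) {
      abort(paste0("disjoint histograms between adjacent windows: ",
                   paste(wins$window[ow[which(ov == 0)]], collapse = ", ")))
    }
  }
  sol <- wham_solve(counts, wins$n, bias_mat, rt, tol)
  pmf <- -rt * log(sol$rho)
  pmf <- pmf - min(pmf)

  err <- rep(NA_real_, length(mids))
  if (n_boot > 0) {
    lam_by_win <- purrr::map(wins$window, function(w) ts$lambda[ts$window == w])
    blocks <- vapply(lam_by_win, function(l) {
      max(1L, as.integer(round(block_factor * iact(l))))
    }, integer(1))
    boots <- matrix(NA_real_, n_boot, length(mids))
    for (b in seq_len(n_boot)) {
      cnt <- rep(0, length(mids))
      for (j in seq_along(lam_by_win)) {
        l <- lam_by_win[[j]]
        bl <- min(blocks[j], length(l))
        n_blk <- ceiling(length(l) / bl)
        starts <- sample.int(length(l) - bl + 1, n_blk, replace = TRUE)
        res <- unlist(lapply(starts, function(s) l[s:(s + bl - 1)]))[seq_along(l)]
        cnt <- cnt + count_hist(res)
      }
      sb <- wham_solve(cnt, wins$n, bias_mat, rt, tol = max(tol, 1e-7),
                       f_init = sol$f)
      pb <- -rt * log(sb$rho)
      boots[b, ] <- pb - min(pb[is.finite(pb)])
    }
    err <- apply(boots, 2, function(col) sd(col[is.finite(col)]))
  }
  keep <- is.finite(pmf)
  out <- tibble(lambda = mids[keep], pmf = pmf[keep], err = err[keep])
  pl <- tail(seq_len(nrow(out)), plateau_bins)
  structure(out,
            temperature = temperature, delta_lambda = delta_lambda,
            dg = mean(out$pmf[pl]), sigma = sd(out$pmf[pl]),
            eps = if (n_boot > 0) mean(out$err[pl]) else NA_real_,
            plateau_bins = plateau_bins,
            dg_span = plateau_bins * delta_lambda,
            f_windows = sol$f, iterations = sol$iterations,
            residual = sol$residual, tol = tol, n_boot = n_boot,
            discard = discard,
            class = c("pmf_profile", class(out)))
}

#' @export
glance.pmf_profile <- function(x, ...) {
  tibble(dg = attr(x, "dg"), sigma = attr(x, "sigma"), eps = attr(x, "eps"),
         dg_span = attr(x, "dg_span"), delta_lambda = attr(x, "delta_lambda"),
         temperature = attr(x, "temperature"),
         iterations = attr(x, "iterations"), residual = attr(x, "residual"))
}

#' @export
autoplot.pmf_profile <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$lambda, .data$pmf)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pmf - .data$err,
                                      ymax = .data$pmf + .data$err),
                         fill = "grey80", na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda ~ "(Å)"),
                  y = "PMF (kcal/mol)")
}

# effective cross-section area of the flat-bottom cylinder restraint:
# integral of exp(-k (rho - r)^2_+ / RT) over the plane
cylinder_area <- function(radius, k, temperature) {
  rt <- rt_kcal(temperature)
  tail_int <- integrate(function(rho) {
    exp(-k * (rho - radius)^2 / rt) * 2 * pi * rho
  }, radius, radius + 10 * sqrt(rt / max(k, 1e-12)))$value
  pi * radius^2 + tail_int
}

#' Standard binding free energy from a PMF profile
#'
#' Converts the PMF plateau height \eqn{\Delta G} into a standard-state
#' binding free energy \eqn{\Delta G_b^0} (V0 = 1660 A^3, i.e. 1 M).  Two
#' reconstructions of the volume correction are available:
#'
#' * `"cylinder_pmf"` (default): exact within the cylinder scheme.  The
#'   bulk density per unit \eqn{\lambda} corresponds to the effective
#'   cylinder cross-section \eqn{A_u} (flat interior plus Boltzmann tail of
#'   the quadratic wall), and the site contribution is the Boltzmann
#'   integral of the PMF over the bound range:
#'   \deqn{\Delta G_b^0 = -RT \ln\left[\frac{A_u}{V_0} \int_{site}
#'     e^{-(W(\lambda) - \Delta G)/RT} d\lambda\right] - \Delta G.}
#' * `"volume_ratio"`: \eqn{\Delta G_b^0 = -\Delta G + RT \ln(V_{eff,u} /
#'   V_0) + RT \ln(V_0 / V_{eff,b})} with effective volumes estimated from
#'   COM sample covariances (Gaussian equivalent volume
#'   \eqn{(2\pi)^{3/2}\sqrt{\det\Sigma}}), or passed directly.
#'
#' Sign convention: \eqn{\Delta G} is the (positive) PMF plateau height and
#' \eqn{\Delta G_b^0} is negative for binders.
#'
#' @param profile a `pmf_profile` from [wham()].
#' @param cylinder list with `radius` and `k` of the perpendicular
#'   restraint (required for `"cylinder_pmf"`).
#' @param site_lambda_max outer edge of the binding-site region along
#'   \eqn{\lambda} (default: start of the plateau window).
#' @param site_lambda_min inner edge of the site region (default: the whole
#'   sampled range); use the same bounds as any occupancy reference.
#' @param bound_com,unbound_com optional COM sample matrices (n x 3) for the
#'   `"volume_ratio"` variant.
#' @param v_eff_bound,v_eff_unbound effective volumes in A^3, overriding the
#'   sample estimates.
#' @param variant correction variant, see above.
#' @param v0 standard-state volume (1660 A^3).
#' @param min_samples minimum COM samples required for a covariance volume.
#' @return one-row tibble with `dg`, `dg_b0`, `variant` and the volume
#'   terms used.
#' @export
standard_binding_free_energy <- function(profile, cylinder = NULL,
                                         site_lambda_max = NULL,
                                         site_lambda_min = NULL,
                                         bound_com = NULL, unbound_com = NULL,
                                         v_eff_bound = NULL,
                                         v_eff_unbound = NULL,
                                         variant = c("cylinder_pmf",
                                                     "volume_ratio"),
                                         v0 = 1660, min_samples = 100) {
  variant <- match.arg(variant)
  rt <- rt_kcal(attr(profile, "temperature"))
  dg <- attr(profile, "dg")
  dl <- attr(profile, "delta_lambda")
  if (variant == "cylinder_pmf") {
    if (is.null(cylinder)) abort("cylinder parameters required for cylinder_pmf")
    if (is.null(site_lambda_max)) {
      site_lambda_max <- profile$lambda[nrow(profile) - attr(profile, "plateau_bins")]
    }
    if (is.null(site_lambda_min)) site_lambda_min <- -Inf
    a_u <- cylinder_area(cylinder$radius, cylinder$k,
                         attr(profile, "temperature"))
    site <- profile$lambda <= site_lambda_max &
      profile$lambda >= site_lambda_min
    # Boltzmann integral of the PMF over the site, referenced to the bulk
    # plateau: exp(dG/RT) is already inside, so no extra -dG term appears
    i_site <- sum(exp(-(profile$pmf[site] - dg) / rt)) * dl
    dg_b0 <- -rt * log(a_u * i_site / v0)
    return(tibble(dg = dg, dg_b0 = dg_b0, variant = variant,
                  a_unbound = a_u, l_site = i_site * exp(-dg / rt), v0 = v0))
  }
  cov_volume <- function(com) {
    if (nrow(com) < min_samples) {
      abort(sprintf("need at least %d COM samples", min_samples))
    }
    (2 * pi)^1.5 * sqrt(det(stats::cov(com)))
  }
  vb <- v_eff_bound %||% cov_volume(bound_com)
  vu <- v_eff_unbound %||% cov_volume(unbound_com)
  dg_b0 <- -dg + rt * log(vu / v0) + rt * log(v0 / vb)
  tibble(dg = dg, dg_b0 = dg_b0, variant = variant,
         v_eff_bound = vb, v_eff_unbound = vu, v0 = v0)
}

#' Direct binding-affinity reference from unbiased sampling
#'
#' Independent estimate of the standard binding free energy from a long
#' unbiased canonical run: the ratio of time spent in the binding-site
#' region (a cylinder section along the reaction coordinate) to time spent
#' in the remaining box volume, converted to standard concentration,
#' \deqn{\Delta G_b^0 = -RT \ln\left(\frac{N_{site}}{N_{out}}
#'   \frac{V_{out}}{V_0}\right).}  Used to validate the umbrella-sampling
#' route on the toy system.
#'
#' @param system a `toy_system` (cryptic3d).
#' @param rc a `reaction_coord` defining the site axis.
#' @param n_steps unbiased steps at `temperature`.
#' @param seed integer seed; several independent runs can be averaged by
#'   passing a vector of seeds.
#' @param temperature temperature in K.
#' @param radius site cylinder radius in Angstrom.
#' @param lambda_range site extent along \eqn{\lambda} (default: the
#'   system's `site_lambda_min`/`site_lambda_max`).
#' @param save_interval snapshot interval in steps.
#' @param timestep,friction integrator settings.
#' @param burn_in initial fraction of each run discarded.
#' @param alternate_starts start every other run from the bound reference
#'   pose instead of the bulk, cancelling first-order relaxation bias.
#' @param v0 standard-state volume.
#' @return one-row tibble with `f_site`, `dg_b0_direct`, `n_site`, `n_out`,
#'   `v_site`, `v_out`.
#' @export
direct_binding_reference <- function(system, rc, n_steps = 4e6, seed = 1,
                                     temperature = 300, radius = 8,
                                     lambda_range = NULL, timestep = 0.005,
                                     friction = 1, burn_in = 0.1,
                                     alternate_starts = TRUE,
                                     save_interval = 100, v0 = 1660) {
  if (is.null(lambda_range)) {
    lambda_range <- c(system$params$site_lambda_min,
                      system$params$site_lambda_max)
  }
  lig <- system$params$ligand_index
  tot_site <- 0; tot_out <- 0
  for (si in seq_along(seed)) {
    s <- seed[si]
    p <- langevin_params(n_steps, timestep = timestep, friction = friction,
                         rng_seed = s, temperature = temperature,
                         save_interval = save_interval)
    # alternating bound/unbound starts cancel first-order relaxation bias
    init <- if (alternate_starts && si %% 2 == 0) {
      system$params$bound_pose
    } else {
      NULL
    }
    tr <- run_langevin(system, p, init = init)
    tr <- filter(tr, .data$step > burn_in * n_steps)
    com <- ensemble_com(tr, system, lig)
    d <- sweep(com, 2, rc$origin)
    lam <- as.numeric(d %*% rc$direction)
    perp2 <- rowSums(d^2) - lam^2
    in_site <- lam >= lambda_range[1] & lam <= lambda_range[2] &
      perp2 <= radius^2
    tot_site <- tot_site + sum(in_site)
    tot_out <- tot_out + sum(!in_site)
  }
  v_site <- pi * radius^2 * diff(lambda_range)
  v_out <- prod(system$box) - v_site
  rt <- rt_kcal(temperature)
  tibble(f_site = tot_site / (tot_site + tot_out),
         dg_b0_direct = -rt * log((tot_site / tot_out) * v_out / v0),
         n_site = tot_site, n_out = tot_out, v_site = v_site, v_out = v_out)
}
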