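#' Distance-pair feature specification
#'
#' Defines the inter-molecular (receptor site, ligand site) and intra-ligand
#' site pairs whose distances form the feature vector for dimensionality
#' reduction.  Distance features need no prior superposition and respect
#' periodic boundaries (minimum-image convention).
#'
#' @param system a `toy_system`.
#' @param inter include receptor-ligand pairs (all receptor sites, including
#'   the mobile gate, against all ligand beads).
#' @param intra include intra-ligand pairs.
#' @return tibble of class `feature_spec` with columns `site_a`, `site_b`,
#'   `type`.
#' @export
feature_spec <- function(system, inter = TRUE, intra = TRUE) {
  s <- system$sites
  rec <- s$site[s$role == "receptor"]
  lig <- s$site[s$role == "ligand"]
  rows <- list()
  if (inter) {
    rows$inter <- tidyr::expand_grid(site_a = rec, site_b = lig) |>
      mutate(type = "inter")
  }
  if (intra && length(lig) > 1) {
    cmb <- utils::combn(lig, 2)
    rows$intra <- tibble(site_a = cmb[1, ], site_b = cmb[2, ], type = "intra")
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(paste(out$site_a, out$site_b))) abort("duplicate pairs")
  structure(out, class = c("feature_spec", class(out)))
}

site_position_block <- function(ensemble, system, site) {
  s <- system$sites[system$sites$site == site, ]
  if (nrow(s) != 1) abort(paste0("unknown site: ", site))
  if (s$kind == "fixed") {
    matrix(system$fixed[s$index, ], nrow(ensemble), 3, byrow = TRUE)
  } else {
    xs <- coords_block(ensemble, nrow(system$mobile0))
    xs[, 3 * (s$index - 1) + 1:3, drop = FALSE]
  }
}

#' Minimum-image site-pair distances for every snapshot
#'
#' @param ensemble ensemble tibble with coordinate columns.
#' @param spec a [feature_spec()].
#' @param system the `toy_system` the ensemble was sampled from.
#' @return tibble with one row per snapshot and one distance column (in
#'   Angstrom) per pair, named `d_<site_a>_<site_b>`.
#' @export
distance_features <- function(ensemble, spec, system) {
  if (!all(coord_cols(nrow(system$mobile0)) %in% names(ensemble))) {
    abort("ensemble is missing coordinate columns")
  }
  box <- system$box
  cols <- purrr::map2(spec$site_a, spec$site_b, function(a, b) {
    d <- site_position_block(ensemble, system, a) -
      site_position_block(ensemble, system, b)
    for (k in 1:3) {
      if (box[k] > 0) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    }
    sqrt(rowSums(d^2))
  })
  names(cols) <- paste0("d_", spec$site_a, "_", spec$site_b)
  as_tibble(cols)
}

#' Weighted principal component analysis
#'
#' PCA of a feature matrix under per-snapshot weights (canonical reweighting
#' weights): the covariance is weight-weighted, so the components describe
#' the canonical ensemble at the reweighting temperature rather than the raw
#' multicanonical one.  Set `weighted = FALSE` to compute ordinary PCA on
#' the raw ensemble and only carry the weights through to downstream
#' histograms.
#'
#' @param features tibble or matrix, one row per snapshot.
#' @param weights per-snapshot weights (normalized internally); `NULL` for
#'   uniform.
#' @param var_target retained components are the smallest leading set whose
#'   cumulative variance contribution exceeds this fraction (default 0.9).
#' @param weighted use the weights in the covariance (default `TRUE`).
#' @return object of class `wpca`: list with `scores` (tibble `PC1..PCp`),
#'   `variance`, `contribution`, `rotation`, `center`, `m` (number of
#'   retained components).
#' @export
weighted_pca <- function(features, weights = NULL, var_target = 0.9,
                         weighted = TRUE) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) abort("weights length must match snapshot count")
  w <- weights / sum(weights)
  wc <- if (weighted) w else rep(1 / n, n)
  ctr <- colSums(x * wc)
  xc <- sweep(x, 2, ctr)
  cv <- crossprod(xc * sqrt(wc), xc * sqrt(wc))
  if (effective_sample_size(wc) < ncol(x)) {
    abort("fewer effective snapshots than features; PCA is degenerate")
  }
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  contrib <- ev / sum(ev)
  m <- which(cumsum(contrib) > var_target)[1]
  scores <- xc %*% eg$vectors
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  structure(list(
    scores = as_tibble(scores), variance = ev, contribution = contrib,
    rotation = eg$vectors, center = ctr, m = m, weights = w,
    var_target = var_target, weighted = weighted
  ), class = "wpca")
}

#' Project new feature rows onto fitted principal axes
#'
#' @param object a `wpca` fit.
#' @param newdata feature rows with the same columns the fit was built from.
#' @param ... unused.
#' @return tibble of PC scores.
#' @export
predict.wpca <- function(object, newdata, ...) {
  x <- sweep(as.matrix(newdata), 2, object$center)
  s <- x %*% object$rotation
  colnames(s) <- paste0("PC", seq_len(ncol(s)))
  as_tibble(s)
}

#' @export
print.wpca <- function(x, ...) {
  cat("<wpca>", length(x$variance), "components;", x$m,
      sprintf("retained (cumulative contribution %.1f%% > %.0f%%)\n",
              100 * sum(x$contribution[seq_len(x$m)]), 100 * x$var_target))
  invisible(x)
}

#' @export
tidy.wpca <- function(x, ...) {
  tibble(component = seq_along(x$variance), variance = x$variance,
         contribution = x$contribution,
         cumulative = cumsum(x$contribution))
}

#' @export
glance.wpca <- function(x, ...) {
  tibble(n_components = length(x$variance), m_retained = x$m,
         cumulative_retained = sum(x$contribution[seq_len(x$m)]),
         weighted = x$weighted)
}

#' @export
autoplot.wpca <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, 100 * .data$contribution)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = object$m + 0.5, linetype = 2) +
    ggplot2::labs(x = "principal component", y = "variance contribution (%)")
}

#' Build a 2D free-energy landscape
#'
#' Bins the first two principal components, accumulates the canonical weight
#' \eqn{P_i = \sum_j w_j} of the snapshots in each bin, and converts to a
#' potential of mean force \eqn{PMF_i = -RT \ln P_i}, normalized so the
#' minimum is zero.  Bins never visited are absent from the grid (reported
#' as unsampled, not as zero or infinite PMF).
#'
#' @param projections tibble or matrix whose first two columns are the PC1
#'   and PC2 scores (e.g. `wpca$scores`).
#' @param weights normalized canonical weights from [reweight()] at the same
#'   temperature.
#' @param bins number of bins per axis (default 100).
#' @param temperature temperature in K the weights correspond to.
#' @param margin fractional range padding (default 2\%).
#' @return tibble of class `fel_grid` with `bin1`, `bin2`, `pc1`, `pc2`
#'   (bin centres), `p`, `pmf`; attributes `edges1`, `edges2`,
#'   `temperature`, `minimum` (bin centre of the global minimum).
#' @export
build_fel <- function(projections, weights, bins = 100, temperature = 300,
                      margin = 0.02) {
  x <- as.matrix(projections)[, 1:2, drop = FALSE]
  w <- weights / sum(weights)
  rng <- apply(x, 2, range)
  pad <- margin * (rng[2, ] - rng[1, ])
  pad[pad == 0] <- 1e-6
  e1 <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = bins + 1)
  e2 <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = bins + 1)
  i1 <- findInterval(x[, 1], e1, rightmost.closed = TRUE)
  i2 <- findInterval(x[, 2], e2, rightmost.closed = TRUE)
  d <- tibble(bin1 = i1, bin2 = i2, w = w) |>
    group_by(.data$bin1, .data$bin2) |>
    summarise(p = sum(.data$w), .groups = "drop") |>
    filter(.data$p > 0)
  rt <- rt_kcal(temperature)
  d$pmf <- -rt * log(d$p)
  d$pmf <- d$pmf - min(d$pmf)
  d$pc1 <- (e1[d$bin1] + e1[d$bin1 + 1]) / 2
  d$pc2 <- (e2[d$bin2] + e2[d$bin2 + 1]) / 2
  d <- d[, c("bin1", "bin2", "pc1", "pc2", "p", "pmf")]
  structure(d, edges1 = e1, edges2 = e2, temperature = temperature,
            minimum = unlist(d[which.min(d$pmf), c("pc1", "pc2")]),
            class = c("fel_grid", class(d)))
}

#' Look up landscape bins for arbitrary projections
#'
#' Maps points (for instance the projection of an experimental structure)
#' onto the landscape grid and returns the free energy of their bins;
#' unsampled bins give `NA`.
#'
#' @param fel a `fel_grid`.
#' @param pc1,pc2 coordinates of the query points.
#' @return tibble with `pc1`, `pc2`, `bin1`, `bin2`, `pmf`, `sampled`.
#' @export
fel_lookup <- function(fel, pc1, pc2) {
  e1 <- attr(fel, "edges1"); e2 <- attr(fel, "edges2")
  q <- tibble(pc1 = pc1, pc2 = pc2,
              bin1 = findInterval(pc1, e1, rightmost.closed = TRUE),
              bin2 = findInterval(pc2, e2, rightmost.closed = TRUE))
  q <- left_join(q, as_tibble(fel)[, c("bin1", "bin2", "pmf")],
                 by = c("bin1", "bin2"))
  q$sampled <- !is.na(q$pmf)
  q
}

#' @export
autoplot.fel_grid <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$pc1, .data$pc2, fill = .data$pmf)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "PMF (kcal/mol)") +
    ggplot2::labs(x = "PC1", y = "PC2",
                  title = sprintf("free-energy landscape at %g K",
                                  attr(object, "temperature")))
}
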