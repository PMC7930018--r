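#' Estimate the optimal unbinding direction of a bound ligand
#'
#' Naive geometric estimate of the association/dissociation direction:
#' candidate directions are sampled quasi-uniformly on the sphere (spherical
#' Fibonacci grid) and each is scored by the integrated steric obstruction
#' of the receptor along a straight-line sweep of the ligand out of the
#' pocket: \deqn{score(u) = \sum_{s} \sum_{r,l} \exp(-d_{rl}(s u)^2 / 2
#' \sigma^2).}  The minimum-score direction defines the reaction coordinate
#' \eqn{\lambda}, the projection of the ligand centre-of-mass displacement
#' from the bound pose onto that direction.  Deterministic for a fixed
#' direction grid; ties (e.g. an isolated ligand) break to the smallest
#' polar angle, then the grid order.
#'
#' @param system a `toy_system`.
#' @param coords mobile coordinates of the bound complex.
#' @param n_dirs number of candidate directions (default 1000).
#' @param sweep_max,sweep_step translation sweep along each direction in
#'   Angstrom (defaults 12 and 0.5).
#' @param kernel_width Gaussian obstruction kernel width in Angstrom
#'   (default: mean receptor site sigma).
#' @return object of class `reaction_coord`: list with `origin` (bound
#'   ligand COM), `direction` (unit vector), `score` of the winner and the
#'   full `score_table`.
#' @export
estimate_unbind_direction <- function(system, coords, n_dirs = 1000,
                                      sweep_max = 12, sweep_step = 0.5,
                                      kernel_width = NULL) {
  lig <- system$params$ligand_index %||% which(system$sites$role == "ligand" &
                                                 system$sites$kind == "mobile")
  coords <- as_coord_matrix(coords, nrow(system$mobile0))
  lx <- coords[lig, , drop = FALSE]
  com <- colSums(lx * system$mass[lig]) / sum(system$mass[lig])
  # receptor sites: fixed beads plus mobile non-ligand beads at their
  # current positions
  rec <- rbind(system$fixed,
               coords[setdiff(seq_len(nrow(coords)), lig), , drop = FALSE])
  if (is.null(kernel_width)) {
    kernel_width <- mean(system$sites$sigma[system$sites$role == "receptor"])
  }
  dirs <- sphere_points(n_dirs)
  sweeps <- seq(sweep_step, sweep_max, by = sweep_step)
  if (nrow(rec) == 0) {
    score <- rep(0, n_dirs)
  } else {
    score <- vapply(seq_len(n_dirs), function(q) {
      u <- dirs[q, ]
      s <- 0
      for (t in sweeps) {
        lt <- sweep(lx, 2, t * u, `+`)
        d2 <- outer(rowSums(lt^2), rowSums(rec^2), `+`) - 2 * lt %*% t(rec)
        s <- s + sum(exp(-pmax(d2, 0) / (2 * kernel_width^2)))
      }
      s
    }, numeric(1))
  }
  best <- min(score)
  tied <- which(score <= best + 1e-12)
  if (length(tied) > 1) {
    polar <- acos(pmin(pmax(dirs[tied, 3], -1), 1))
    tied <- tied[order(polar, tied)]
    if (best == 0) {
      warn("no obstruction anywhere: all directions tie; smallest polar angle used")
    }
  }
  win <- tied[1]
  structure(list(origin = com, direction = dirs[win, ], score = score[win],
                 score_table = tibble(dir = seq_len(n_dirs),
                                      ux = dirs[, 1], uy = dirs[, 2],
                                      uz = dirs[, 3], score = score)),
            class = "reaction_coord")
}

#' @export
print.reaction_coord <- function(x, ...) {
  cat(sprintf("<reaction_coord> origin (%.2f, %.2f, %.2f), direction (%.3f, %.3f, %.3f)\n",
              x$origin[1], x$origin[2], x$origin[3],
              x$direction[1], x$direction[2], x$direction[3]))
  invisible(x)
}

#' Reaction-coordinate values of an ensemble
#'
#' \eqn{\lambda} per snapshot: the ligand centre-of-mass displacement from
#' the bound origin projected on the unbinding direction.
#'
#' @param ensemble ensemble tibble.
#' @param system the `toy_system`.
#' @param rc a `reaction_coord`.
#' @return numeric vector of \eqn{\lambda} in Angstrom.
#' @export
lambda_values <- function(ensemble, system, rc) {
  lig <- system$params$ligand_index
  com <- ensemble_com(ensemble, system, lig)
  as.numeric(sweep(com, 2, rc$origin) %*% rc$direction)
}

# per-snapshot number of receptor-ligand bead contacts within the cutoff
contact_count_profile <- function(ensemble, system, cutoff = 4.5) {
  spec <- feature_spec(system, inter = TRUE, intra = FALSE)
  d <- as.matrix(distance_features(ensemble, spec, system))
  rowSums(d <= cutoff)
}

# per-snapshot fraction of the reference contacts present (vectorised R-value)
rvalue_profile <- function(ensemble, system, contacts, cutoff = 4.5) {
  if (nrow(contacts) == 0) return(rep(0, nrow(ensemble)))
  spec <- tibble(site_a = contacts$site_a, site_b = contacts$site_b,
                 type = "inter")
  d <- as.matrix(distance_features(ensemble, spec, system))
  rowMeans(d <= cutoff)
}

# per-snapshot RMSD_L of the ligand relative to reference coordinates
rmsdl_profile <- function(ensemble, system, ref_coords, rc) {
  lig <- system$params$ligand_index
  n <- nrow(system$mobile0)
  xs <- coords_block(ensemble, n)
  cols <- as.vector(vapply(lig, function(i) 3 * (i - 1) + 1:3, numeric(3)))
  q <- xs[, cols, drop = FALSE]
  r <- as.vector(t(ref_coords[lig, , drop = FALSE]))
  u <- rc$direction
  # remove the lambda component of the COM displacement, then plain RMSD
  nl <- length(lig)
  comq <- cbind(rowMeans(q[, seq(1, 3 * nl, 3), drop = FALSE]),
                rowMeans(q[, seq(2, 3 * nl, 3), drop = FALSE]),
                rowMeans(q[, seq(3, 3 * nl, 3), drop = FALSE]))
  comr <- colMeans(ref_coords[lig, , drop = FALSE])
  proj <- sweep(comq, 2, comr) %*% u
  shift <- proj %*% t(rep(u, nl))
  q <- q - shift
  diff <- sweep(q, 2, r)
  sqrt(rowSums(diff^2) / nl)
}

#' Build a binding path from the multicanonical ensemble
#'
#' Splits the reaction coordinate into windows of `window_width` and picks
#' up to `k` representative structures per window, walking outward from the
#' bound configuration `q_k`.  In every window the candidate snapshots are
#' those similar to the previous window's picks (R-value above an adaptive
#' cutoff that starts at `r_start` and relaxes in steps of `r_step` down to
#' `r_floor` until at least `n_min` candidates match); candidates are
#' clustered by K-means (k = 3) in PC space and the highest-canonical-weight
#' member of each cluster is picked.  Once the ligand approaches the
#' unbound state (mean intermolecular contact count of the window drops
#' below `contact_switch`), the similarity metric switches from the R-value
#' to RMSD_L, the RMSD that ignores translation along the reaction
#' coordinate.  In the first window the pick most similar to `q_k` is
#' replaced by `q_k` itself.
#'
#' Windows that stay empty even at the laxest cutoff get an interpolated
#' placeholder and are flagged — a diagnostic for narrow pathways in phase
#' space.
#'
#' @param ensemble multicanonical ensemble tibble.
#' @param system the `toy_system`.
#' @param weights canonical weights per snapshot (from [reweight()]).
#' @param q_coords mobile coordinates of the refined bound configuration.
#' @param rc `reaction_coord` from [estimate_unbind_direction()].
#' @param scores PC coordinates used for the per-window clustering (matrix
#'   or `wpca`).
#' @param lambda_max outer end of the path (default: 90th percentile of
#'   sampled lambda).
#' @param lambda_min inner end of the path; negative values add windows
#'   deeper in the pocket than the bound configuration (default 0).
#' @param window_width window width in Angstrom (default 0.5).
#' @param k picks per window (default 3).
#' @param r_start,r_step,r_floor adaptive R-value cutoff schedule.
#' @param n_min candidate count satisfying the cutoff search (default 30).
#' @param rmsd_start,rmsd_step,rmsd_ceiling adaptive RMSD_L cutoff schedule
#'   (Angstrom) for the far-field windows.
#' @param contact_switch mean contact count below which the similarity
#'   metric switches to RMSD_L (default 3).
#' @param contact_cutoff contact distance cutoff in Angstrom.
#' @param seed K-means seed.
#' @return object of class `path_windows`: list with `windows` (per-window
#'   diagnostics tibble: `window`, `lambda_c`, `metric`, `cutoff`,
#'   `n_candidates`, `gap`) and `picks` (tibble: `window`, `pick`,
#'   `snapshot`, `lambda`, `weight`, plus packed pick coordinates), and the
#'   reaction coordinate as attribute.
#' @export
build_path <- function(ensemble, system, weights, q_coords, rc, scores,
                       lambda_max = NULL, lambda_min = 0, window_width = 0.5,
                       k = 3, r_start = 0.7, r_step = 0.05, r_floor = 0.3,
                       n_min = 30, rmsd_start = 2, rmsd_step = 0.5,
                       rmsd_ceiling = 8, contact_switch = 3,
                       contact_cutoff = 4.5, seed = 1) {
  lam <- lambda_values(ensemble, system, rc)
  if (is.null(lambda_max)) lambda_max <- quantile(lam, 0.9)
  x <- if (inherits(scores, "wpca")) {
    as.matrix(scores$scores[, seq_len(scores$m), drop = FALSE])
  } else {
    as.matrix(scores)
  }
  n_mob <- nrow(system$mobile0)
  # windows walk outward from the bound window (centred on lambda = 0, which
  # carries q_k); optionally also inward to negative lambda, deeper in the
  # pocket than the refined pose
  centers_out <- seq(0, lambda_max, by = window_width)
  centers_in <- if (lambda_min < 0) {
    seq(-window_width, lambda_min, by = -window_width)
  } else {
    numeric(0)
  }
  centers <- c(centers_out, centers_in)
  q_struct <- pose_structure(system, q_coords)
  q_contacts <- contact_set(q_struct, cutoff = contact_cutoff,
                            inter_only = TRUE)
  prev_contacts <- list(q_contacts)
  prev_coords <- list(q_coords)
  ccount <- contact_count_profile(ensemble, system, contact_cutoff)

  win_rows <- list()
  pick_rows <- list()
  for (wi in seq_along(centers)) {
    lc <- centers[wi]
    if (length(centers_in) > 0 && wi == length(centers_out) + 1) {
      # start of the inward branch: chain restarts from the bound window
      w0 <- pick_rows[[1]]
      prev_coords <- w0$coords
      prev_contacts <- purrr::map(w0$coords, function(cc) {
        contact_set(pose_structure(system, cc), cutoff = contact_cutoff,
                    inter_only = TRUE)
      })
    }
    in_win <- which(lam >= lc - window_width / 2 & lam < lc + window_width / 2)
    metric <- if (length(in_win) > 0 &&
                  mean(ccount[in_win]) < contact_switch) "rmsd_l" else "rvalue"
    # similarity of window members to the previous picks (best over picks)
    if (length(in_win) > 0) {
      if (metric == "rvalue") {
        best <- rep(0, length(in_win))
        for (pc in prev_contacts) {
          if (nrow(pc) == 0) next
          best <- pmax(best, rvalue_profile(ensemble[in_win, ], system, pc,
                                            contact_cutoff))
        }
      } else {
        best <- rep(Inf, length(in_win))
        for (qc in prev_coords) {
          best <- pmin(best, rmsdl_profile(ensemble[in_win, ], system, qc, rc))
        }
      }
    }
    if (metric == "rvalue") {
      cutoffs <- seq(r_start, r_floor, by = -r_step)
    } else {
      cutoffs <- seq(rmsd_start, rmsd_ceiling, by = rmsd_step)
    }
    cand <- integer()
    cutoff_used <- cutoffs[length(cutoffs)]
    for (co in cutoffs) {
      if (length(in_win) > 0) {
        cand <- if (metric == "rvalue") in_win[best >= co] else in_win[best <= co]
      }
      cutoff_used <- co
      if (length(cand) >= n_min) break
    }
    gap <- length(cand) == 0
    if (gap) {
      # placeholder: translate the previous first pick to this window centre
      ref <- prev_coords[[1]]
      lig <- system$params$ligand_index
      com <- colSums(ref[lig, , drop = FALSE] * system$mass[lig]) /
        sum(system$mass[lig])
      lam_ref <- sum((com - rc$origin) * rc$direction)
      ph <- ref
      ph[lig, ] <- sweep(ref[lig, , drop = FALSE], 2,
                         (lc - lam_ref) * rc$direction, `+`)
      picks <- tibble(window = wi, pick = 1L, snapshot = NA_integer_,
                      lambda = lc, weight = NA_real_,
                      coords = list(ph))
      new_coords <- list(ph)
      new_contacts <- list(contact_set(pose_structure(system, ph),
                                       cutoff = contact_cutoff,
                                       inter_only = TRUE))
    } else {
      kk <- min(k, length(unique(cand)))
      set.seed(seed + wi)
      cl <- if (length(cand) > kk) {
        kmeans(x[cand, , drop = FALSE], centers = kk, iter.max = 30)$cluster
      } else {
        seq_along(cand)
      }
      sel <- vapply(seq_len(max(cl)), function(g) {
        mem <- cand[cl == g]
        mem[which.max(weights[mem])]
      }, numeric(1))
      sel <- sort(unique(sel))
      picks <- tibble(window = wi, pick = seq_along(sel),
                      snapshot = as.integer(sel), lambda = lam[sel],
                      weight = weights[sel],
                      coords = purrr::map(sel, function(s) {
                        snapshot_coords(ensemble, s, n_mob)
                      }))
      if (wi == 1) {
        # replace the pick most similar to q_k with q_k itself
        sims <- vapply(picks$coords, function(cc) {
          tryCatch(rvalue(pose_structure(system, cc), q_struct,
                          cutoff = contact_cutoff), error = function(e) 0)
        }, numeric(1))
        jbest <- which.max(sims)
        picks$coords[[jbest]] <- q_coords
        picks$snapshot[jbest] <- NA_integer_
        lig <- system$params$ligand_index
        com <- colSums(q_coords[lig, , drop = FALSE] * system$mass[lig]) /
          sum(system$mass[lig])
        picks$lambda[jbest] <- sum((com - rc$origin) * rc$direction)
      }
      new_coords <- picks$coords
      new_contacts <- purrr::map(picks$coords, function(cc) {
        contact_set(pose_structure(system, cc), cutoff = contact_cutoff,
                    inter_only = TRUE)
      })
    }
    win_rows[[wi]] <- tibble(window = wi, lambda_c = lc, metric = metric,
                             cutoff = cutoff_used,
                             n_candidates = length(cand), gap = gap)
    pick_rows[[wi]] <- picks
    prev_coords <- new_coords
    prev_contacts <- new_contacts
  }
  windows <- dplyr::bind_rows(win_rows)
  picks <- dplyr::bind_rows(pick_rows)
  ord <- order(windows$lambda_c)
  renum <- match(windows$window, windows$window[ord])
  windows$window <- renum
  picks$window <- renum[match(picks$window, seq_along(renum))]
  windows <- windows[order(windows$window), ]
  picks <- picks[order(picks$window, picks$pick), ]
  structure(list(windows = windows, picks = picks),
            rc = rc, window_width = window_width,
            class = "path_windows")
}

#' @export
print.path_windows <- function(x, ...) {
  cat("<path_windows>", nrow(x$windows), "windows,",
      sum(!is.na(x$picks$snapshot) | x$windows$gap[x$picks$window]),
      "picks;", sum(x$windows$gap), "flagged gap(s)\n")
  invisible(x)
}

#' @export
tidy.path_windows <- function(x, ...) x$windows

#' Export a path as an ordered structure series
#'
#' Writes the picked structures in order of increasing \eqn{\lambda} as a
#' multi-model PDB, one model per pick, with the per-model \eqn{\lambda}
#' stored in the occupancy field and the window id in the B-factor field
#' (both parse back losslessly at PDB precision).  Placeholder models from
#' flagged gap windows are omitted; the gap windows are listed in the
#' returned metadata.
#'
#' @param path a `path_windows` object.
#' @param system the `toy_system`.
#' @param file output PDB path.
#' @return (invisibly) a tibble of the exported models (`model`, `window`,
#'   `lambda`); attribute `gaps` lists omitted gap windows.
#' @export
export_path <- function(path, system, file) {
  keep <- !path$windows$gap[path$picks$window]
  picks <- path$picks[keep, ]
  picks <- picks[order(picks$lambda), ]
  structures <- purrr::map(picks$coords, function(cc) pose_structure(system, cc))
  write_structure(structures, file,
                  occupancy = picks$lambda, bfactor = picks$window)
  meta <- tibble(model = seq_len(nrow(picks)), window = picks$window,
                 lambda = picks$lambda)
  attr(meta, "gaps") <- path$windows$window[path$windows$gap]
  invisible(meta)
}
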