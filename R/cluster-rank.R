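#' K-means clustering of the retained PC coordinates
#'
#' Clusters snapshots in the retained principal-component space (the leading
#' components covering > 90\% of the variance) with `k'` clusters.  Cluster
#' probabilities are sums of the member snapshots' canonical weights.
#' Deterministic for a fixed seed.
#'
#' @param pca a `wpca` fit (its `m` retained components are used), or a
#'   numeric matrix/tibble of coordinates.
#' @param weights normalized canonical weights per snapshot.
#' @param k_prime number of clusters; the toy-scale default is
#'   `min(1000, n/20)`.
#' @param seed integer seed for the K-means initialisation.
#' @param iter_max maximum Lloyd iterations.
#' @return object of class `mcdock_clusters`: list with `assignment`
#'   (tibble `snapshot`, `cluster`), `centers`, `weight` (per-cluster
#'   probability, sums to 1), `k`, `seed`.
#' @export
kmeans_cluster <- function(pca, weights, k_prime = NULL, seed = 1,
                           iter_max = 50) {
  x <- if (inherits(pca, "wpca")) {
    as.matrix(pca$scores[, seq_len(pca$m), drop = FALSE])
  } else {
    as.matrix(pca)
  }
  n <- nrow(x)
  if (is.null(k_prime)) k_prime <- max(2L, min(1000L, floor(n / 20)))
  if (k_prime > nrow(unique(x))) {
    abort("k_prime exceeds the number of distinct points")
  }
  w <- weights / sum(weights)
  set.seed(seed)
  km <- suppressWarnings(kmeans(x, centers = k_prime, iter.max = iter_max,
                                nstart = 1, algorithm = "Lloyd"))
  pw <- vapply(seq_len(k_prime), function(k) sum(w[km$cluster == k]), numeric(1))
  structure(list(
    assignment = tibble(snapshot = seq_len(n), cluster = km$cluster),
    centers = km$centers, weight = pw, k = k_prime, seed = seed
  ), class = "mcdock_clusters")
}

#' @export
print.mcdock_clusters <- function(x, ...) {
  cat("<mcdock_clusters>", x$k, "clusters over",
      nrow(x$assignment), "snapshots\n")
  invisible(x)
}

#' Cluster free energies (CFE)
#'
#' Converts cluster probabilities \eqn{P_{k'}} into relative free energies
#' \eqn{CFE = -RT \ln P_{k'}}, normalized so the most probable cluster is at
#' zero, and ranks clusters by CFE.  Zero-weight clusters are dropped with a
#' message.
#'
#' @param clusters an `mcdock_clusters` object.
#' @param temperature temperature in K (default 300).
#' @return tibble of class `ranked_clusters` with `cluster`, `weight`,
#'   `cfe` (kcal/mol) and `rank`, sorted by CFE ascending (ties by cluster
#'   id).
#' @export
cluster_free_energy <- function(clusters, temperature = 300) {
  w <- if (inherits(clusters, "mcdock_clusters")) clusters$weight else clusters
  d <- tibble(cluster = seq_along(w), weight = as.numeric(w))
  drop <- d$weight <= 0
  if (any(drop)) {
    inform(sprintf("dropping %d zero-weight cluster(s)", sum(drop)))
    d <- d[!drop, ]
  }
  rt <- rt_kcal(temperature)
  d$cfe <- -rt * log(d$weight / max(d$weight))
  d <- arrange(d, .data$cfe, .data$cluster)
  d$rank <- seq_len(nrow(d))
  structure(d, temperature = temperature,
            class = c("ranked_clusters", class(d)))
}

#' Representative snapshot of each cluster
#'
#' Picks, for every cluster, the member snapshot nearest to the cluster's
#' weight-weighted centroid in the retained PC space (ties break to the
#' lowest snapshot id).  A `"max_weight"` rule (most probable member) is
#' available as an alternative.
#'
#' @param clusters an `mcdock_clusters` object.
#' @param pca the `wpca` fit (or coordinate matrix) used for clustering.
#' @param weights normalized canonical weights.
#' @param rule `"centroid"` (default) or `"max_weight"`.
#' @return tibble with `cluster` and `snapshot` (the representative's row
#'   index).
#' @export
select_representative <- function(clusters, pca, weights,
                                  rule = c("centroid", "max_weight")) {
  rule <- match.arg(rule)
  x <- if (inherits(pca, "wpca")) {
    as.matrix(pca$scores[, seq_len(pca$m), drop = FALSE])
  } else {
    as.matrix(pca)
  }
  asn <- clusters$assignment
  reps <- vapply(sort(unique(asn$cluster)), function(k) {
    mem <- asn$snapshot[asn$cluster == k]
    if (length(mem) == 1) return(mem)
    if (rule == "max_weight") {
      return(mem[which.max(weights[mem])])
    }
    wm <- weights[mem] / sum(weights[mem])
    ctr <- colSums(x[mem, , drop = FALSE] * wm)
    d2 <- rowSums(sweep(x[mem, , drop = FALSE], 2, ctr)^2)
    mem[which.min(d2)] # which.min takes the first (lowest id) on ties
  }, numeric(1))
  tibble(cluster = sort(unique(asn$cluster)), snapshot = as.integer(reps))
}

#' Group ranked clusters by representative-contact similarity
#'
#' Starting from the most stable cluster and walking down the CFE ranking,
#' clusters whose representative structures share intermolecular contacts
#' (R-value with respect to the group seed's representative above
#' `r_cutoff`) are merged into the seed's group.  Group weights are the sums
#' of their members' weights; groups are re-ranked by the resulting group
#' CFE and only groups within `cfe_cutoff` of the best are returned.
#'
#' Greedy order is strictly ascending CFE with ties broken by cluster id.
#'
#' @param ranked a `ranked_clusters` tibble.
#' @param structures named list (by cluster id) of representative structure
#'   tibbles.
#' @param r_cutoff R-value merge threshold (default 0.7).
#' @param cfe_cutoff retain groups with CFE at or below this value in
#'   kcal/mol (default 1.5).
#' @param contact_cutoff contact distance cutoff in Angstrom.
#' @param temperature temperature for the group CFE (default: the ranking's).
#' @return tibble of class `grouped_clusters` with one row per retained
#'   group: `group`, `seed_cluster`, `members` (list of cluster ids),
#'   `weight`, `cfe`, `rank`.  The full (unfiltered) grouping is attached as
#'   attribute `all_groups`.
#' @export
group_by_rvalue <- function(ranked, structures, r_cutoff = 0.7,
                            cfe_cutoff = 1.5, contact_cutoff = 4.5,
                            temperature = NULL) {
  if (is.null(temperature)) temperature <- attr(ranked, "temperature") %||% 300
  ord <- ranked[order(ranked$cfe, ranked$cluster), ]
  ids <- as.character(ord$cluster)
  if (!all(ids %in% names(structures))) {
    abort("`structures` must contain a representative for every ranked cluster")
  }
  # precompute, per representative, which of the universal receptor-ligand
  # site pairs are in contact: pairwise R-values then reduce to vector ops
  contact_vec <- lapply(ids, function(id) {
    st <- structures[[id]]
    rec <- st[st$role == "receptor", ]
    lig <- st[st$role == "ligand", ]
    d <- sqrt(outer(rec$x, lig$x, `-`)^2 + outer(rec$y, lig$y, `-`)^2 +
                outer(rec$z, lig$z, `-`)^2)
    as.vector(d <= contact_cutoff)
  })
  assigned <- rep(FALSE, nrow(ord))
  groups <- list()
  for (i in seq_len(nrow(ord))) {
    if (assigned[i]) next
    seed <- ord$cluster[i]
    ref <- contact_vec[[i]]
    members <- seed
    assigned[i] <- TRUE
    if (i < nrow(ord) && sum(ref) > 0) {
      for (j in seq((i + 1), nrow(ord))) {
        if (assigned[j]) next
        r <- sum(contact_vec[[j]] & ref) / sum(ref)
        if (r > r_cutoff) {
          members <- c(members, ord$cluster[j])
          assigned[j] <- TRUE
        }
      }
    }
    w_grp <- sum(ord$weight[match(members, ord$cluster)])
    groups[[length(groups) + 1]] <- tibble(
      seed_cluster = seed, members = list(members), weight = w_grp
    )
  }
  g <- dplyr::bind_rows(groups)
  rt <- rt_kcal(temperature)
  g$cfe <- -rt * log(g$weight / max(g$weight))
  g <- arrange(g, .data$cfe, .data$seed_cluster)
  g$rank <- seq_len(nrow(g))
  g$group <- seq_len(nrow(g))
  g <- g[, c("group", "seed_cluster", "members", "weight", "cfe", "rank")]
  keep <- g$cfe <= cfe_cutoff
  structure(g[keep, ], all_groups = g, temperature = temperature,
            class = c("grouped_clusters", class(g[keep, ])))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical refinement and thermal-stability assessment
#'
#' Refines a representative complex by `n_replicas` independent canonical
#' runs at `t_refine`, picks the refined structure as the nearest-to-average
#' snapshot over the final `assess_fraction` of the pooled replicas, and
#' assesses relative stability by re-running the replicas at `t_stress`
#' (mean and SD of the R-value to a reference pose over the same window at
#' each temperature).
#'
#' @param system a `toy_system`.
#' @param start mobile coordinates of the representative to refine.
#' @param reference structure tibble used as the R-value reference (for the
#'   toy system, the ground-truth bound pose).
#' @param n_replicas number of replicas (default 10).
#' @param t_refine,t_stress refinement and stress temperatures in K.
#' @param params base [langevin_params()]; `rng_seed` seeds replica i as
#'   `rng_seed + i`.
#' @param assess_fraction final fraction of each replica used for averaging
#'   and assessment (default 0.4, mirroring a 40-out-of-100 window).
#' @param contact_cutoff contact cutoff for the R-value.
#' @param superpose superpose snapshots for the nearest-to-average pick.
#' @return object of class `refined_config`: list with `q_coords` (refined
#'   mobile coordinates), `stats` (per-replica mean R at both temperatures)
#'   and `summary` (mean and SD of R per temperature).
#' @export
refine_and_assess <- function(system, start, reference, n_replicas = 10,
                              t_refine = 300, t_stress = 400,
                              params = langevin_params(n_steps = 5000),
                              assess_fraction = 0.4, contact_cutoff = 4.5,
                              superpose = TRUE) {
  if (n_replicas == 1) warn("single replica: standard deviations will be 0")
  contacts <- contact_set(reference, cutoff = contact_cutoff, inter_only = TRUE)
  run_at <- function(temp) {
    purrr::map(seq_len(n_replicas), function(i) {
      p <- params
      p$temperature <- temp
      p$rng_seed <- params$rng_seed + i + round(temp)
      tr <- tryCatch(run_langevin(system, p, init = start, traj = i),
                     error = function(e) {
                       inform(sprintf("replica %d at %g K dropped: %s",
                                      i, temp, conditionMessage(e)))
                       NULL
                     })
      if (is.null(tr)) return(NULL)
      tail(tr, max(1, round(assess_fraction * nrow(tr))))
    }) |> purrr::compact()
  }
  mean_r <- function(win) {
    mean(rvalue_profile(win, system, contacts, contact_cutoff))
  }
  w300 <- run_at(t_refine)
  w400 <- run_at(t_stress)
  pooled <- dplyr::bind_rows(w300)
  na <- nearest_to_average(pooled, system, superpose = superpose)
  stats <- dplyr::bind_rows(
    tibble(temperature = t_refine, replica = seq_along(w300),
           r_mean = vapply(w300, mean_r, numeric(1))),
    tibble(temperature = t_stress, replica = seq_along(w400),
           r_mean = vapply(w400, mean_r, numeric(1)))
  )
  summary <- stats |>
    group_by(.data$temperature) |>
    summarise(r_sd = ifelse(n() > 1, sd(.data$r_mean), 0),
              r_mean = mean(.data$r_mean), .groups = "drop") |>
    select("temperature", "r_mean", "r_sd")
  structure(list(q_coords = na$coords, q_row = na$row,
                 stats = stats, summary = summary),
            class = "refined_config")
}

#' @export
print.refined_config <- function(x, ...) {
  cat("<refined_config>\n")
  print(x$summary)
  invisible(x)
}
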