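test_that("K-means recovers separable blobs and conserves probability", {
  set.seed(3)
  blobs <- rbind(cbind(rnorm(60, 0, 0.2), rnorm(60, 0, 0.2)),
                 cbind(rnorm(60, 8, 0.2), rnorm(60, 0, 0.2)),
                 cbind(rnorm(60, 4, 0.2), rnorm(60, 7, 0.2)))
  truth <- rep(1:3, each = 60)
  w <- rep(1 / 180, 180)
  cl <- kmeans_cluster(blobs, w, k_prime = 3, seed = 7)
  # partition equals ground truth up to label permutation
  tab <- table(truth, cl$assignment$cluster)
  expect_true(all(apply(tab, 1, function(r) sum(r > 0)) == 1))
  expect_equal(sum(cl$weight), 1, tolerance = 1e-12)
  # determinism
  cl2 <- kmeans_cluster(blobs, w, k_prime = 3, seed = 7)
  expect_identical(cl$assignment, cl2$assignment)
  expect_error(kmeans_cluster(blobs[1:3, ], w[1:3], k_prime = 5), "distinct")
})

test_that("cluster free energies match the closed form and ranking", {
  cfe <- cluster_free_energy(c(0.6, 0.3, 0.1), temperature = 300)
  expect_equal(cfe$cfe, c(0, 0.413, 1.068), tolerance = 1e-3)
  expect_equal(cfe$rank, 1:3)
  expect_equal(cluster_free_energy(1, temperature = 300)$cfe, 0)
  expect_message(cluster_free_energy(c(0.5, 0, 0.5)), "zero-weight")
  # ranking is exactly an independent sort of -RT log P
  set.seed(8)
  w <- runif(40); w <- w / sum(w)
  r <- cluster_free_energy(w, 300)
  expect_equal(r$cluster, order(-0.59616 * log(w)))
})

test_that("representatives sit nearest the weighted centroid", {
  x <- rbind(c(0, 0), c(1, 0), c(2, 0), c(10, 0), c(11, 0))
  w <- c(0.1, 0.1, 0.3, 0.25, 0.25)
  cl <- list(assignment = tibble::tibble(snapshot = 1:5,
                                         cluster = c(1, 1, 1, 2, 2)))
  reps <- select_representative(cl, x, w)
  # cluster 1 centroid: (0*0.1 + 1*0.1 + 2*0.3)/0.5 = 1.4 -> point 2 (x = 1)
  # is nearest (0.4 vs 0.6 for point 3)
  expect_equal(reps$snapshot[reps$cluster == 1], 2L)
  # symmetric pair ties break to the lowest snapshot id
  expect_equal(reps$snapshot[reps$cluster == 2], 4L)
  # singleton
  cl1 <- list(assignment = tibble::tibble(snapshot = 1L, cluster = 1L))
  expect_equal(select_representative(cl1, x[1, , drop = FALSE], 1)$snapshot, 1L)
  # max-weight rule
  reps2 <- select_representative(cl, x, w, rule = "max_weight")
  expect_equal(reps2$snapshot[reps2$cluster == 1], 3L)
})

test_that("contact grouping is greedy, conservative, and weight-preserving", {
  mk <- function(lig_offsets) {
    rec <- cbind(c(0, 3, 6, 0, 3), c(0, 0, 0, 3, 3), 0)
    lig <- sweep(cbind(c(0, 3), c(1.5, 1.5), 1.5), 2, lig_offsets, `+`)
    tibble::tibble(site = c(paste0("r", 1:5), "l1", "l2"),
                   role = c(rep("receptor", 5), "ligand", "ligand"),
                   seq = c(1:5, 1:2),
                   x = c(rec[, 1], lig[, 1]), y = c(rec[, 2], lig[, 2]),
                   z = c(rec[, 3], lig[, 3]), radius = 1.25)
  }
  a <- mk(c(0, 0, 0))      # contacts with r1, r2, r4, r5 region
  b <- mk(c(0.3, 0, 0))    # nearly identical contacts to a
  c3 <- mk(c(50, 0, 0))    # no contacts at all
  ranked <- structure(tibble::tibble(cluster = 1:3,
                                     weight = c(0.5, 0.3, 0.2),
                                     cfe = c(0, 0.3, 0.55), rank = 1:3),
                      temperature = 300,
                      class = c("ranked_clusters", "tbl_df", "tbl",
                                "data.frame"))
  g <- group_by_rvalue(ranked, list(`1` = a, `2` = b, `3` = c3),
                       cfe_cutoff = 10)
  all_g <- attr(g, "all_groups")
  # identical contacts merge; zero-contact cluster never merges
  expect_equal(sort(all_g$members[[which(all_g$seed_cluster == 1)]]), c(1, 2))
  expect_true(3 %in% all_g$seed_cluster)
  expect_equal(all_g$weight[all_g$seed_cluster == 1], 0.8)
  # weights over all groups sum to 1
  expect_equal(sum(all_g$weight), 1, tolerance = 1e-12)
  # top group CFE is zero, CFE non-decreasing with rank
  expect_equal(g$cfe[1], 0)
  expect_true(all(diff(all_g$cfe) >= -1e-12))
})

test_that("chained similarities follow the documented greedy seed order", {
  # A and B share most contacts; C shares most with B but little with A.
  # Greedy from A (lowest CFE): absorbs B; C cannot join via B and seeds its
  # own group -- the brute-force expectation of the documented procedure.
  rec <- cbind(seq(0, 27, by = 3), 0, 0)
  mk <- function(keep) {
    lig <- cbind(rec[keep, 1], 1.5, 1.5)
    tibble::tibble(site = c(paste0("r", seq_len(nrow(rec))),
                            paste0("l", seq_along(keep))),
                   role = c(rep("receptor", nrow(rec)),
                            rep("ligand", length(keep))),
                   seq = c(seq_len(nrow(rec)), seq_along(keep)),
                   x = c(rec[, 1], lig[, 1]), y = c(rec[, 2], lig[, 2]),
                   z = c(rec[, 3], lig[, 3]), radius = 1.25)
  }
  a <- mk(1:5)    # contacts r1-r5
  b <- mk(2:6)    # 4/5 shared with a (R = 0.8)
  c3 <- mk(5:9)   # 2/5 shared with a (R = 0.4), 4/5 with b
  ranked <- structure(tibble::tibble(cluster = 1:3,
                                     weight = c(0.4, 0.35, 0.25),
                                     cfe = c(0, 0.1, 0.2), rank = 1:3),
                      temperature = 300,
                      class = c("ranked_clusters", "tbl_df", "tbl",
                                "data.frame"))
  g <- attr(group_by_rvalue(ranked, list(`1` = a, `2` = b, `3` = c3),
                            cfe_cutoff = 10), "all_groups")
  expect_equal(sort(g$members[[which(g$seed_cluster == 1)]]), c(1, 2))
  expect_equal(g$members[[which(g$seed_cluster == 3)]], 3)
})

test_that("refinement returns the start pose for frozen replicas and warns for one", {
  sys <- cryptic()
  native <- pose_structure(sys, sys$params$bound_pose)
  p0 <- langevin_params(200, timestep = 0.002, friction = 5, temperature = 0,
                        rng_seed = 1)
  expect_warning(
    ref <- refine_and_assess(sys, sys$params$bound_pose, native,
                             n_replicas = 1, t_refine = 0, t_stress = 0,
                             params = p0, superpose = FALSE),
    "single replica"
  )
  # the minimized ligand does not move at T = 0 (the gate, whose well is
  # tilted, may creep; it does not interact with the bound ligand)
  lig <- sys$params$ligand_index
  expect_lt(max(abs(ref$q_coords[lig, ] - sys$params$bound_pose[lig, ])), 0.05)
  expect_true(all(ref$summary$r_sd == 0))
})

test_that("bound configurations are less native at the stress temperature", {
  sys <- cryptic()
  native <- pose_structure(sys, sys$params$bound_pose)
  ref <- refine_and_assess(sys, sys$params$bound_pose, native,
                           n_replicas = 4,
                           params = langevin_params(8000, timestep = 0.005,
                                                    friction = 1,
                                                    rng_seed = 77),
                           superpose = FALSE)
  r300 <- ref$summary$r_mean[ref$summary$temperature == 300]
  r400 <- ref$summary$r_mean[ref$summary$temperature == 400]
  expect_gte(r300, r400)
  expect_gt(r300, 0.3) # the bound pose keeps native contacts at 300 K
})
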