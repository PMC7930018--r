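test_that("the unbinding direction escapes a flat wall along its normal", {
  sys <- cryptic()
  # replace the receptor with a dense wall in the yz plane at x = 0 and put
  # the ligand just in front of it; the least-obstructed escape is +x
  wall <- as.matrix(expand.grid(x = 0, y = seq(-8, 8, 2), z = seq(-8, 8, 2)))
  sys$fixed <- unname(wall)
  coords <- sys$mobile0
  coords[1, ] <- c(0, 20, 0)  # park the gate inside nothing
  coords[2:4, ] <- cbind(3, c(-2.2, 0, 2.2), 0)
  rc <- estimate_unbind_direction(sys, coords, n_dirs = 600)
  expect_equal(sqrt(sum(rc$direction^2)), 1, tolerance = 1e-12)
  expect_gt(sum(rc$direction * c(1, 0, 0)), cos(15 * pi / 180))
})

test_that("an isolated ligand ties every direction with the documented break", {
  sys <- cryptic()
  sys2 <- sys
  # no receptor at all: empty fixed set and every mobile bead counted as
  # ligand gives an all-zero obstruction surface
  sys2$fixed <- matrix(0, 0, 3)
  sys2$params$ligand_index <- 1:4
  expect_warning(rc <- estimate_unbind_direction(sys2, sys$mobile0,
                                                 n_dirs = 200),
                 "tie")
  # smallest polar angle: the winner is the most +z-pointing grid direction
  pts <- mcdock:::sphere_points(200)
  expect_equal(rc$direction, pts[which.max(pts[, 3]), ], tolerance = 1e-12)
})

test_that("the cryptic pocket's escape direction is the pocket axis", {
  sys <- cryptic()
  rc <- estimate_unbind_direction(sys, sys$params$bound_pose)
  expect_gt(sum(rc$direction * sys$params$pocket_axis), cos(25 * pi / 180))
  # determinism
  rc2 <- estimate_unbind_direction(sys, sys$params$bound_pose)
  expect_identical(rc$direction, rc2$direction)
})

test_that("a noiseless unbinding trajectory is reproduced in order", {
  sys <- cryptic()
  q <- sys$params$bound_pose
  rc <- structure(list(origin = colMeans(q[2:4, ]), direction = c(1, 0, 0),
                       score = 0), class = "reaction_coord")
  # synthetic ensemble: the bound pose slid outward in 0.25 A steps
  lams <- seq(0, 8, by = 0.25)
  coords <- lapply(lams, function(l) {
    x <- q
    x[2:4, 1] <- x[2:4, 1] + l
    x
  })
  ens <- manual_ensemble(sys, coords)
  w <- rep(1 / length(lams), length(lams))
  scores <- cbind(lams, 0)
  path <- build_path(ens, sys, w, q, rc, scores, lambda_max = 8,
                     n_min = 1, seed = 4)
  picks <- path$picks[!is.na(path$picks$snapshot), ]
  # picks come out in strictly increasing lambda (window) order
  expect_true(!is.unsorted(picks$lambda))
  # every window's picks lie inside the window
  lamv <- lambda_values(ens, sys, rc)
  for (i in seq_len(nrow(picks))) {
    lc <- path$windows$lambda_c[path$windows$window == picks$window[i]]
    expect_lt(abs(lamv[picks$snapshot[i]] - lc), 0.25 + 1e-9)
  }
  # the first window contains lambda = 0 and carries q itself
  w1 <- path$picks[path$picks$window == 1, ]
  expect_true(any(is.na(w1$snapshot)))
  expect_equal(path$windows$lambda_c[1], 0)
  # no gaps in a fully covered coordinate
  expect_false(any(path$windows$gap))
})

test_that("empty windows relax the cutoff and finally flag a gap", {
  sys <- cryptic()
  q <- sys$params$bound_pose
  rc <- structure(list(origin = colMeans(q[2:4, ]), direction = c(1, 0, 0),
                       score = 0), class = "reaction_coord")
  # ensemble only covers lambda in [0, 2]: windows beyond must flag gaps
  lams <- seq(0, 2, by = 0.25)
  coords <- lapply(lams, function(l) {
    x <- q
    x[2:4, 1] <- x[2:4, 1] + l
    x
  })
  ens <- manual_ensemble(sys, coords)
  path <- build_path(ens, sys, rep(1 / 9, 9), q, rc, cbind(lams, 0),
                     lambda_max = 5, n_min = 1, seed = 2)
  expect_true(any(path$windows$gap))
  gap_w <- path$windows$window[path$windows$gap]
  expect_true(all(path$windows$lambda_c[gap_w] > 2))
})

test_that("exported paths keep order, drop gaps, and round-trip lambda", {
  sys <- cryptic()
  q <- sys$params$bound_pose
  rc <- structure(list(origin = colMeans(q[2:4, ]), direction = c(1, 0, 0),
                       score = 0), class = "reaction_coord")
  lams <- seq(0, 4, by = 0.25)
  coords <- lapply(lams, function(l) {
    x <- q
    x[2:4, 1] <- x[2:4, 1] + l
    x
  })
  ens <- manual_ensemble(sys, coords)
  path <- build_path(ens, sys, rep(1 / length(lams), length(lams)), q, rc,
                     cbind(lams, 0), lambda_max = 6, n_min = 1, seed = 2)
  f <- tempfile(fileext = ".pdb")
  meta <- export_path(path, sys, f)
  expect_true(file.exists(f))
  expect_true(!is.unsorted(meta$lambda))
  # gap windows are omitted from the model series
  expect_false(any(meta$window %in% attr(meta, "gaps")))
  models <- read_structure(f)
  expect_equal(length(models), nrow(meta))
  # lambda annotations survive the occupancy field at PDB precision
  expect_equal(attr(models, "occupancy"), round(meta$lambda, 2),
               tolerance = 5e-3)
})
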