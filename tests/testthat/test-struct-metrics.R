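# small hand-built structures for contact and superposition fixtures
mk_struct <- function(xyz, role = NULL, radius = 1.25) {
  n <- nrow(xyz)
  if (is.null(role)) role <- rep("ligand", n)
  tibble::tibble(site = paste0("s", seq_len(n)), role = role,
                 seq = stats::ave(seq_len(n), role, FUN = seq_along),
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = radius)
}

rotate_z <- function(xyz, th) {
  r <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  xyz %*% t(r)
}

test_that("Q-value is 1 on identity, 0 on disjoint contacts, and counts fractions", {
  set.seed(2)
  ref <- mk_struct(matrix(rnorm(18, sd = 2), 6, 3),
                   role = c(rep("receptor", 3), rep("ligand", 3)))
  expect_equal(qvalue(ref, ref), 1)
  far <- ref
  far[far$role == "ligand", c("x", "y", "z")] <-
    far[far$role == "ligand", c("x", "y", "z")] + 100
  # all-receptor pairs survive; an intermolecular-only reference set dies
  expect_equal(rvalue(far, ref), 0)

  # square fixture with exactly 4 reference contacts (edges of side 3 at a
  # 3.5 A cutoff; diagonals at 4.24 A stay out), 3 preserved -> 0.75
  ref2 <- mk_struct(rbind(c(0, 0, 0), c(3, 0, 0), c(3, 3, 0), c(0, 3, 0)))
  contacts <- contact_set(ref2, cutoff = 3.5, s_min = 0)
  expect_equal(nrow(contacts), 4) # brute-force enumerated pairs within 3.5
  qry <- ref2
  qry$y[4] <- 4.5 # stretches edge s4-s1 beyond the cutoff, keeps s3-s4
  expect_equal(qvalue(qry, ref2, cutoff = 3.5, s_min = 0), 0.75)
  expect_error(qvalue(qry, far[far$role == "ligand", ][0, ]), "empty")
})

test_that("R-value counts intermolecular contacts only", {
  ref <- mk_struct(rbind(c(0, 0, 0), c(3, 0, 0),
                         c(0, 3, 0), c(3, 3, 0)),
                   role = c("receptor", "receptor", "ligand", "ligand"))
  expect_equal(rvalue(ref, ref), 1)
  half <- ref
  half$x[4] <- 50; half$y[4] <- 50 # breaks its two contacts
  ref_contacts <- contact_set(ref, inter_only = TRUE)
  broken <- contact_set(half, inter_only = TRUE)
  expect_equal(rvalue(half, ref), nrow(broken) / nrow(ref_contacts))
  # monotone non-increasing as contacts break one at a time
  vals <- c(rvalue(ref, ref), rvalue(half, ref))
  moved_all <- half
  moved_all$x[3] <- -50
  vals <- c(vals, rvalue(moved_all, ref))
  expect_true(all(diff(vals) <= 0))
  expect_equal(vals[3], 0)
  expect_error(rvalue(ref[ref$role == "receptor", ], ref), "ligand")
})

test_that("RMSD is zero under rigid motion and measures split selections", {
  set.seed(9)
  xyz <- matrix(rnorm(15, sd = 3), 5, 3)
  ref <- mk_struct(xyz)
  moved <- mk_struct(sweep(rotate_z(xyz, 0.7), 2, c(3, -2, 5), `+`))
  expect_equal(rmsd(moved, ref), 0, tolerance = 1e-9)
  expect_equal(rmsd(ref, ref), 0)

  # 3 anchors identical, a 4th site displaced 2 A: superposing on the
  # anchors leaves RMSD = 2/sqrt(4) = 1 on the full selection
  base <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(1, 1, 3))
  q <- base
  q[4, ] <- q[4, ] + c(0, 0, 2)
  r4 <- mk_struct(base)
  q4 <- mk_struct(q)
  expect_equal(rmsd(q4, r4, fit_sites = paste0("s", 1:3),
                    measure_sites = paste0("s", 1:4)), 1, tolerance = 1e-9)
  expect_error(rmsd(q4, r4, fit_sites = paste0("s", 1:2)), "3 sites")
})

test_that("superposed RMSD satisfies triangle-inequality spot checks", {
  set.seed(31)
  for (rep in 1:5) {
    a <- mk_struct(matrix(rnorm(15), 5, 3))
    b <- mk_struct(matrix(rnorm(15), 5, 3))
    c3 <- mk_struct(matrix(rnorm(15), 5, 3))
    expect_lte(rmsd(a, c3), rmsd(a, b) + rmsd(b, c3) + 1e-9)
  }
})

test_that("RMSD_lambda removes exactly the along-axis translation", {
  set.seed(5)
  xyz <- matrix(rnorm(9, sd = 2), 3, 3)
  ref <- mk_struct(xyz)
  u <- c(1, 0, 0)
  along <- mk_struct(sweep(xyz, 2, 5 * u, `+`))
  expect_equal(rmsd_lambda(along, ref, u), 0, tolerance = 1e-12)
  perp <- mk_struct(sweep(xyz, 2, c(0, 3, 0), `+`))
  expect_equal(rmsd_lambda(perp, ref, u), 3, tolerance = 1e-12)
  mixed <- mk_struct(sweep(xyz, 2, c(3, 0, 4), `+`))
  expect_equal(rmsd_lambda(mixed, ref, u), 4, tolerance = 1e-12)
  expect_error(rmsd_lambda(mixed, ref, c(0, 0, 0)), "non-zero")
})

test_that("RASA spans the exposure range and matches the spherical-cap form", {
  # isolated ligand: fully exposed
  lig <- mk_struct(rbind(c(0, 0, 0), c(2.5, 0, 0)), role = rep("ligand", 2))
  expect_equal(rasa(lig), 1, tolerance = 0.01)

  # ligand enclosed in a tight shell of large receptor spheres: buried
  sp <- sphere_pts <- local({
    i <- seq_len(30) - 0.5
    phi <- acos(1 - 2 * i / 30)
    th <- pi * (1 + sqrt(5)) * i
    cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
  })
  shell <- mk_struct(rbind(c(0, 0, 0), 4 * sp),
                     role = c("ligand", rep("receptor", 30)), radius = 2)
  expect_lt(rasa(shell, ligand_sites = "s1"), 0.02)

  # two touching equal spheres: occluded fraction (1 - d/(2R))/2 per sphere
  r <- 1.5; probe <- 1.4; R <- r + probe
  d <- R
  pair <- mk_struct(rbind(c(0, 0, 0), c(d, 0, 0)),
                    role = c("ligand", "receptor"), radius = r)
  expect_equal(rasa(pair, ligand_sites = "s1"),
               1 - (1 - d / (2 * R)) / 2, tolerance = 0.01)
  # probe growth: isolated SASA of a single sphere is analytic 4 pi (r+p)^2
  one <- mk_struct(matrix(0, 1, 3), role = "ligand", radius = 2)
  expect_equal(rasa(one), 1, tolerance = 1e-9)
})

test_that("nearest-to-average picks the central snapshot with first-tie break", {
  sys <- cryptic()
  x0 <- sys$params$bound_pose
  same <- manual_ensemble(sys, list(x0, x0, x0))
  expect_equal(nearest_to_average(same, sys)$row, 1)

  x_out <- x0; x_out[2, ] <- x_out[2, ] + 8
  win <- manual_ensemble(sys, list(x0, x_out, x0 + 0.01))
  pick <- nearest_to_average(win, sys, superpose = FALSE)
  # brute force over the window
  xs <- list(x0, x_out, x0 + 0.01)
  mean_m <- Reduce(`+`, xs) / 3
  d <- vapply(xs, function(m) sqrt(mean(rowSums((m - mean_m)^2))), numeric(1))
  expect_equal(pick$row, which.min(d))

  single <- manual_ensemble(sys, list(x_out))
  expect_equal(nearest_to_average(single, sys)$row, 1)
  expect_error(nearest_to_average(single[0, ], sys), "empty")
})
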