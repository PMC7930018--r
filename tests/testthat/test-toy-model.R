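test_that("double-well preset has the closed-form extrema", {
  sys <- build_cryptic_system("doublewell1d", list(a = 1, b = 1, c = 0))
  expect_equal(potential_energy(sys, matrix(c(1, 0, 0), 1))$total, 0)
  expect_equal(potential_energy(sys, matrix(c(-1, 0, 0), 1))$total, 0)
  expect_equal(potential_energy(sys, matrix(c(0, 0, 0), 1))$total, 1)
})

test_that("tilted double-well minima match a root-finding oracle", {
  sys <- build_cryptic_system("doublewell1d", list(c = 0.5))
  # dU/dx = 4x^3 - 4x + 0.5: stationary points by polynomial root finding
  roots <- sort(Re(polyroot(c(0.5, -4, 0, 4))))
  expect_equal(roots, c(-1.05745377, 0.12705084, 0.93040293), tolerance = 1e-6)
  u <- function(x) potential_energy(sys, matrix(c(x, 0, 0), 1))$total
  # outer roots are minima, the middle one the barrier
  expect_lt(u(roots[1]), u(roots[1] + 0.05))
  expect_lt(u(roots[3]), u(roots[3] - 0.05))
  expect_gt(u(roots[2]), u(roots[1]))
  expect_equal(u(roots[1]), -0.51475364, tolerance = 1e-6)
})

test_that("the cryptic pocket binds by >= 3 kcal/mol with the gate open", {
  sys <- cryptic()
  eb <- potential_energy(sys, sys$params$bound_pose)$total
  eu <- potential_energy(sys, sys$params$unbound_pose)$total
  expect_lte(eb, eu - 3)
  expect_equal(nrow(sys$fixed) + nrow(sys$mobile0), nrow(sys$sites))
  # the gate double well has exactly two minima along y
  gate <- sys$params$gate_index
  ygrid <- seq(-3, 10, by = 0.01)
  ug <- vapply(ygrid, function(y) {
    x <- sys$mobile0
    x[gate, 2] <- y
    potential_energy(sys, x)$total
  }, numeric(1))
  sgn <- diff(sign(diff(ug)))
  expect_equal(sum(sgn > 0), 2) # two local minima
})

test_that("unknown presets and malformed coordinates are refused", {
  expect_error(build_cryptic_system("nope"), "unknown preset")
  expect_error(potential_energy(cryptic(), matrix(0, 2, 3)), "mismatch")
})

test_that("restraint energies follow the no-1/2 quadratic convention", {
  sys <- cryptic()
  x <- sys$params$unbound_pose
  d23 <- sqrt(sum((x[2, ] - x[3, ])^2)) # a ligand bond, ~2.2 A

  # flat-bottom pair: zero inside the flat region
  r0 <- restraint_flat_bottom(2, 3, lo = 0, hi = 4.5, k = 10)
  expect_equal(potential_energy(sys, x, list(r0))$restraint, 0)
  # 1 A beyond the upper bound with k = 10 -> 10 * 1^2
  r1 <- restraint_flat_bottom(2, 3, lo = 0, hi = d23 - 1, k = 10)
  expect_equal(potential_energy(sys, x, list(r1))$restraint, 10, tolerance = 1e-9)

  # cylinder: COM at perpendicular distance 9, radius 8, k = 0.1 -> 0.1
  lig <- sys$params$ligand_index
  xc <- x
  xc[lig, 2] <- xc[lig, 2] - mean(xc[lig, 2]) + 9
  xc[lig, 3] <- xc[lig, 3] - mean(xc[lig, 3])
  rc <- restraint_cylinder(lig, origin = c(0, 0, 0), axis = c(1, 0, 0),
                           radius = 8, k = 0.1)
  expect_equal(potential_energy(sys, xc, list(rc))$restraint, 0.1,
               tolerance = 1e-9)

  # restraints vanish inside flat regions and increase strictly outside
  umb <- restraint_umbrella(lig, c(0, 0, 0), c(1, 0, 0), center = 0, k = 2)
  lam <- c(0.5, 1, 2, 4)
  es <- vapply(lam, function(l) {
    xs <- x
    xs[lig, 1] <- xs[lig, 1] - mean(xs[lig, 1]) + l
    potential_energy(sys, xs, list(umb))$restraint
  }, numeric(1))
  expect_equal(es, 2 * lam^2, tolerance = 1e-9)
  expect_true(all(diff(es) > 0))
})

test_that("quadrature reference reproduces closed forms", {
  sys <- dw_sym()
  # symmetric well: occupancy of x > 0 is exactly 1/2; normalization is 1
  expect_equal(quadrature_reference(sys, 300, function(x) as.numeric(x > 0)),
               0.5, tolerance = 1e-8)
  expect_equal(quadrature_reference(sys, 700, function(x) rep(1, length(x))),
               1, tolerance = 1e-10)
  # tilted well at 300 K: frozen value from the quadrature oracle
  expect_equal(quadrature_reference(dw_tilted(), 300,
                                    function(x) as.numeric(x > 0)),
               0.1933507599, tolerance = 1e-7)
})

test_that("Langevin sampling is canonical and deterministic", {
  sys <- dw_sym()
  p <- dw_params(150000, seed = 42, save_interval = 5)
  tr <- run_langevin(sys, p)
  # symmetry: occupancy of x > 0 is 1/2 within 3 standard errors
  occ <- mean(tr$x1 > 0)
  tau <- 2 * sum(acf(as.numeric(tr$x1 > 0), lag.max = 2000, plot = FALSE)$acf) - 1
  se <- sqrt(0.25 / (nrow(tr) / max(tau, 1)))
  expect_lt(abs(occ - 0.5), 3 * se)

  # tilted well: Boltzmann occupancy within 3 SE of quadrature
  sys2 <- dw_tilted()
  trs <- lapply(1:6, function(s) {
    run_langevin(sys2, dw_params(120000, seed = 100 + s, save_interval = 5),
                 init = matrix(c(ifelse(s %% 2 == 0, 1, -1), 0, 0), 1))
  })
  occs <- vapply(trs, function(tr) mean(tail(tr$x1, 20000) > 0), numeric(1))
  qocc <- 0.1933507599
  expect_lt(abs(mean(occs) - qocc), 3 * sd(occs) / sqrt(length(occs)))

  # identical seeds give bitwise-identical energy series
  tr2 <- run_langevin(sys, p)
  expect_identical(tr$energy, tr2$energy)
  expect_identical(tr$x1, tr2$x1)
})

test_that("zero-friction zero-temperature dynamics conserve energy", {
  sys <- dw_sym()
  p <- langevin_params(10000, timestep = 5e-4, friction = 0, temperature = 0,
                       save_interval = 10, rng_seed = 1)
  tr <- run_langevin(sys, p, init = matrix(c(0.4, 0, 0), 1),
                     init_vel = matrix(c(0.1, 0, 0), 1))
  total <- tr$energy + tr$kinetic_energy
  expect_lt(max(total) - min(total), 1e-4)
})
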