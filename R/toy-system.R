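#' Build a coarse-grained binding system
#'
#' Constructs one of the built-in bead-model presets used throughout the
#' package.  `"doublewell1d"` is a single particle in the quartic potential
#' \eqn{U(x) = a (x^2 - b^2)^2 + c x} (kcal/mol, x in Angstrom), the
#' workhorse for quadrature oracles.  `"cryptic3d"` is a rigid receptor cage
#' with a single binding pocket whose mouth is guarded by a mobile gate bead
#' carrying a double-well potential: the closed well seals the pocket
#' sterically, the open well clears it, so a bound/unbound population shift
#' emerges from the dynamics rather than being scripted.  A flexible
#' three-bead ligand binds inside the pocket through attractive
#' Lennard-Jones terms.
#'
#' Units are kcal/mol, Angstrom, ps and K throughout; bead masses are given
#' in kcal/mol ps^2/A^2 (1 unit is about 418 amu).  All quadratic energy
#' terms use the convention \eqn{E = k \Delta^2} (no 1/2 factor).
#'
#' @param preset `"doublewell1d"` or `"cryptic3d"`.
#' @param overrides named list of preset parameters to override (for
#'   `"doublewell1d"`: `a`, `b`, `c`, `mass`; for `"cryptic3d"` e.g.
#'   `eps_bind`, `gate_barrier`, `gate_bias`, `box`).
#' @return an object of class `toy_system`: a list with bead tables, bonded
#'   and nonbonded parameters, the periodic box and preset metadata
#'   (including, for `"cryptic3d"`, energy-minimised reference bound and
#'   unbound poses).
#' @examples
#' sys <- build_cryptic_system("doublewell1d", list(a = 1, b = 1, c = 0))
#' potential_energy(sys, matrix(c(1, 0, 0), 1))
#' @export
build_cryptic_system <- function(preset, overrides = list()) {
  if (!is.list(overrides)) abort("`overrides` must be a named list")
  sys <- switch(preset,
    doublewell1d = build_doublewell1d(overrides),
    cryptic3d = build_cryptic3d(overrides),
    abort(paste0("unknown preset: '", preset, "'"))
  )
  e0 <- energy_cpp(sys, sys$mobile0, list())
  if (!is.finite(e0$total)) {
    abort("overrides produce a non-finite energy at the reference configuration")
  }
  sys
}

build_doublewell1d <- function(overrides) {
  p <- modifyList(list(a = 1, b = 1, c = 0, mass = 0.05), overrides)
  ext <- matrix(0, 1, 18)
  ext[1, 1:6] <- c(1, 0, p$a, p$b, p$c, 0)
  sys <- list(
    preset = "doublewell1d",
    sites = tibble(
      site = "X", role = "ligand", kind = "mobile", index = 1L,
      sigma = 1, mass = p$mass, radius = 0.5
    ),
    fixed = matrix(0, 0, 3),
    mobile0 = matrix(c(p$b, 0, 0), 1, 3),
    mass = p$mass,
    mol = 1L,
    active_dims = 1L,
    box = c(0, 0, 0),
    bonds = matrix(0, 0, 4),
    ext = ext,
    type_mm = matrix(0L, 1, 1), eps_mm = matrix(0, 1, 1), sig_mm = matrix(1, 1, 1),
    type_mf = matrix(0L, 1, 0), eps_mf = matrix(0, 1, 0), sig_mf = matrix(0, 1, 0),
    params = p
  )
  class(sys) <- "toy_system"
  sys$params$u <- function(x) p$a * (x^2 - p$b^2)^2 + p$c * x
  sys
}

# receptor cage: pocket along +x with an open mouth at positive x, guarded by
# the gate bead tethered over the mouth.  The cage beads are purely
# repulsive (sterics and gating only); binding comes from a smooth Gaussian
# well centred in the cavity, so the cage exterior is exactly neutral and
# binding/unbinding is a clean two-state process through the mouth.
build_cryptic3d <- function(overrides) {
  p <- modifyList(list(
    well_depth = 2.6,      # Gaussian pocket well depth per ligand bead, kcal/mol
    well_width = 2.5,      # Gaussian well width, A
    eps_rep = 1.0,         # repulsive prefactor (cage, gate), kcal/mol
    sig_lining = 2.8,      # pocket lining repulsive radius, A
    sig_gate = 3.6,        # gate-ligand repulsive radius, A
    sig_shield = 2.2,      # mouth/collar repulsive radius, A
    mouth_radius = 5.0, collar_radius = 5.5,
    gate_barrier = 1.5,    # double-well barrier between gate states, kcal/mol
    gate_bias = 0.05,      # tilt c; open state sits gate_sep*c above closed
    gate_sep = 7,          # open/closed well separation along y, A
    gate_tether = 5,       # x/z tether force constant, kcal/mol/A^2
    bond_k = 10, bond_r0 = 2.2,
    mass_ligand = 0.1, mass_gate = 0.2,
    box = c(34, 22, 22),
    site_lambda_max = 8,   # outer edge of the binding-site region along lambda
    site_lambda_min = -3,
    contact_cutoff = 5.5   # bead-bead contact distance (beads are fatter
                           # than heavy atoms; the all-atom default is 4.5)
  ), overrides)

  ring <- function(x0, r, n = 6) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(x0, r * cos(th), r * sin(th))
  }
  fixed <- rbind(
    c(-8.5, 0, 0),               # back wall
    ring(-4.5, 4.0),             # inner ring
    ring(-2.0, 4.0),             # middle ring
    ring(1.5, p$mouth_radius),   # mouth ring
    ring(4.5, p$collar_radius)   # collar around the gate
  )
  m <- nrow(fixed)
  lining_idx <- 1:13
  shield_idx <- setdiff(seq_len(m), lining_idx)

  # mobile beads: gate first, then 3 ligand beads
  gate0 <- c(4.5, 0, 0)                    # closed state
  lig0 <- cbind(12, c(-2.2, 0, 2.2), 0)    # unbound start, in bulk
  mobile0 <- rbind(gate0, lig0)
  n <- 4L
  gate_i <- 1L
  lig_i <- 2:4
  pocket_center <- c(-2.4, 0, 0)

  ext <- matrix(0, n, 18)
  # gate double well along y, wells at y = 0 and y = gate_sep
  a <- p$gate_barrier / (p$gate_sep / 2)^4
  ext[gate_i, 1:12] <- c(1, 1, a, p$gate_sep / 2, p$gate_bias, p$gate_sep / 2,
                         p$gate_tether, 0, p$gate_tether, gate0[1], 0, gate0[3])
  for (i in lig_i) {
    ext[i, 13:18] <- c(1, p$well_depth, p$well_width, pocket_center)
  }

  bonds <- rbind(
    c(2, 3, p$bond_k, p$bond_r0),
    c(3, 4, p$bond_k, p$bond_r0)
  )

  type_mm <- matrix(0L, n, n); eps_mm <- matrix(0, n, n); sig_mm <- matrix(1, n, n)
  for (i in lig_i) { # gate repels the ligand: pure sterics, no coupling term
    type_mm[gate_i, i] <- type_mm[i, gate_i] <- 2L
    eps_mm[gate_i, i] <- eps_mm[i, gate_i] <- p$eps_rep
    sig_mm[gate_i, i] <- sig_mm[i, gate_i] <- p$sig_gate
  }
  type_mf <- matrix(0L, n, m); eps_mf <- matrix(0, n, m); sig_mf <- matrix(1, n, m)
  for (i in lig_i) {
    type_mf[i, ] <- 2L
    eps_mf[i, ] <- p$eps_rep
    sig_mf[i, lining_idx] <- p$sig_lining
    sig_mf[i, shield_idx] <- p$sig_shield
  }

  sites <- tibble(
    site = c("GATE", paste0("L", 1:3),
             "BACK", paste0("R1_", 1:6), paste0("R2_", 1:6), paste0("R3_", 1:6),
             paste0("C_", 1:6)),
    role = c("receptor", rep("ligand", 3), rep("receptor", m)),
    kind = c(rep("mobile", 4), rep("fixed", m)),
    index = c(1:4, seq_len(m)),
    sigma = c(p$sig_gate, rep(2.5, 3),
              rep(p$sig_lining, 13), rep(p$sig_shield, 12)),
    mass = c(p$mass_gate, rep(p$mass_ligand, 3), rep(NA_real_, m)),
    radius = c(p$sig_gate, rep(2.5, 3),
               rep(p$sig_lining, 13), rep(p$sig_shield, 12)) / 2
  )

  sys <- list(
    preset = "cryptic3d",
    sites = sites,
    fixed = fixed,
    mobile0 = mobile0,
    mass = c(p$mass_gate, rep(p$mass_ligand, 3)),
    mol = c(1L, 2L, 2L, 2L),
    active_dims = 3L,
    box = p$box,
    bonds = bonds,
    ext = ext,
    type_mm = type_mm, eps_mm = eps_mm, sig_mm = sig_mm,
    type_mf = type_mf, eps_mf = eps_mf, sig_mf = sig_mf,
    params = c(p, list(gate_index = gate_i, ligand_index = lig_i,
                       gate_open_y = p$gate_sep, pocket_center = pocket_center,
                       pocket_axis = c(1, 0, 0)))
  )
  class(sys) <- "toy_system"
  sys$params$bound_pose <- minimise_pose(sys, bound = TRUE)
  sys$params$unbound_pose <- minimise_pose(sys, bound = FALSE)
  sys
}

# reference poses by local energy minimisation with the gate pinned open
# (bound) or closed (unbound)
minimise_pose <- function(sys, bound) {
  lig <- sys$params$ligand_index
  gate <- sys$params$gate_index
  x0 <- sys$mobile0
  if (bound) {
    x0[gate, ] <- c(4.5, sys$params$gate_open_y, 0)
    x0[lig, ] <- cbind(c(-4.6, -2.4, -0.2), 0.3, 0)
  }
  free <- as.vector(t(x0[lig, , drop = FALSE]))
  fn <- function(v) {
    x <- x0
    x[lig, ] <- matrix(v, ncol = 3, byrow = TRUE)
    energy_cpp(sys, x, list())$total
  }
  opt <- optim(free, fn, method = "BFGS", control = list(maxit = 500, reltol = 1e-12))
  x <- x0
  x[lig, ] <- matrix(opt$par, ncol = 3, byrow = TRUE)
  x
}

#' @export
print.toy_system <- function(x, ...) {
  cat("<toy_system> preset:", x$preset, "\n")
  cat("  mobile beads:", nrow(x$mobile0), " fixed beads:", nrow(x$fixed), "\n")
  if (any(x$box > 0)) cat("  periodic box:", paste(x$box, collapse = " x "), "A\n")
  invisible(x)
}

#' Restraint constructors
#'
#' Restraints are extra energy terms added to a simulation.  All of them are
#' zero inside their flat region and quadratic outside with the convention
#' \eqn{E = k \Delta^2} (no 1/2 factor), continuous and once-differentiable
#' at the region boundary.
#'
#' * `restraint_flat_bottom()`: distance restraint between two beads, flat
#'   for `lo <= d <= hi`.
#' * `restraint_com_hold()`: holds the centre of mass of a bead selection
#'   within `flat_radius` of a point.
#' * `restraint_cylinder()`: restrains a selection's centre of mass
#'   perpendicularly inside a cylinder of given `radius` about an axis.
#' * `restraint_umbrella()`: harmonic umbrella on the reaction coordinate
#'   \eqn{\lambda}, the projection of the selection's centre-of-mass
#'   displacement from `origin` onto `axis`.
#' * `restraint_position_hold()`: per-bead harmonic tether to reference
#'   coordinates (used for restrained equilibration).
#'
#' @param i,j bead indices (mobile numbering); `j_kind` is `"mobile"` or
#'   `"fixed"`.
#' @param lo,hi flat region bounds in Angstrom.
#' @param k force constant in kcal/mol/A^2.
#' @param idx mobile bead indices defining the selection.
#' @param origin,axis cylinder/umbrella geometry (axis is normalised).
#' @param radius cylinder radius in Angstrom.
#' @param center umbrella window centre \eqn{\lambda_c} in Angstrom.
#' @param flat_radius flat region radius for the COM hold, Angstrom.
#' @param ref reference coordinates (length(idx) x 3 matrix).
#' @return a list of class `restraint`, suitable for `potential_energy()` and
#'   the simulation drivers (pass several as `list(r1, r2, ...)`).
#' @name restraints
NULL

new_restraint <- function(x) structure(x, class = "restraint")

#' @rdname restraints
#' @export
restraint_flat_bottom <- function(i, j, lo, hi, k, j_kind = "mobile") {
  stopifnot(lo >= 0, hi >= lo, k >= 0)
  new_restraint(list(kind = "flat_bottom_pair", i = as.integer(i),
                     j = as.integer(j), j_kind = j_kind, lo = lo, hi = hi, k = k))
}

#' @rdname restraints
#' @export
restraint_com_hold <- function(idx, origin, flat_radius, k) {
  new_restraint(list(kind = "com_hold", idx = as.integer(idx), origin = origin,
                     flat_radius = flat_radius, k = k))
}

#' @rdname restraints
#' @export
restraint_cylinder <- function(idx, origin, axis, radius, k) {
  new_restraint(list(kind = "cylinder", idx = as.integer(idx), origin = origin,
                     axis = axis / sqrt(sum(axis^2)), radius = radius, k = k))
}

#' @rdname restraints
#' @export
restraint_umbrella <- function(idx, origin, axis, center, k) {
  new_restraint(list(kind = "umbrella_lambda", idx = as.integer(idx),
                     origin = origin, axis = axis / sqrt(sum(axis^2)),
                     center = center, k = k))
}

#' @rdname restraints
#' @export
restraint_position_hold <- function(idx, ref, k) {
  ref <- as.matrix(ref)
  stopifnot(nrow(ref) == length(idx), ncol(ref) == 3)
  new_restraint(list(kind = "position_hold", idx = as.integer(idx), ref = ref, k = k))
}

as_restraint_list <- function(restraints) {
  if (inherits(restraints, "restraint")) restraints <- list(restraints)
  lapply(restraints, unclass)
}

#' Potential energy of a configuration
#'
#' Total potential energy (bonded + nonbonded + per-bead external terms) of
#' the mobile beads, with the restraint contribution reported separately.
#' Nonbonded and pair-restraint distances use the minimum-image convention
#' when the system is periodic.
#'
#' @param system a `toy_system`.
#' @param coords mobile-bead coordinates: an n x 3 matrix (for 1D presets
#'   only the x column is active) or a tibble with `x`, `y`, `z` columns.
#' @param restraints list of [restraints] (may be empty).
#' @return a one-row tibble with columns `physical`, `restraint`, `total`
#'   (kcal/mol).
#' @export
potential_energy <- function(system, coords, restraints = list()) {
  coords <- as_coord_matrix(coords, nrow(system$mobile0))
  e <- energy_cpp(system, coords, as_restraint_list(restraints))
  tibble(physical = e$physical, restraint = e$restraint, total = e$total)
}

as_coord_matrix <- function(coords, n) {
  if (is_tibble(coords) || is.data.frame(coords)) {
    coords <- as.matrix(coords[, c("x", "y", "z")])
  }
  coords <- as.matrix(coords)
  if (ncol(coords) == 1) coords <- cbind(coords, 0, 0)
  if (nrow(coords) != n || ncol(coords) != 3) {
    abort(sprintf("coordinate/selection mismatch: expected %d x 3 coordinates", n))
  }
  storage.mode(coords) <- "double"
  unname(coords)
}

#' Canonical expectation by quadrature (1D oracle)
#'
#' Deterministic Boltzmann quadrature \eqn{\langle f \rangle =
#' \int f(x) e^{-U(x)/RT} dx / Z} for the 1D presets, used as an exact
#' reference for sampled averages.  Integration bounds are chosen where the
#' potential exceeds the minimum by 80 RT; relative tolerance 1e-10.
#'
#' @param system a 1D `toy_system` (preset `"doublewell1d"`).
#' @param temperature temperature in K.
#' @param observable function of x; defaults to the identity.
#' @return the expectation value (a number).
#' @export
quadrature_reference <- function(system, temperature, observable = identity) {
  if (system$active_dims != 1L) abort("quadrature_reference() needs a 1D preset")
  u <- system$params$u
  rt <- rt_kcal(temperature)
  xm <- optimize(u, c(-50, 50))
  lo <- uniroot(function(x) u(x) - xm$objective - 80 * rt, c(-500, xm$minimum))$root
  hi <- uniroot(function(x) u(x) - xm$objective - 80 * rt, c(xm$minimum, 500))$root
  bw <- function(x) exp(-(u(x) - xm$objective) / rt)
  # integrate piecewise around 0 so step observables (well occupancies) keep
  # full quadrature accuracy
  cuts <- sort(unique(c(lo, if (lo < 0 && hi > 0) 0, hi)))
  quad <- function(f) {
    sum(vapply(seq_len(length(cuts) - 1), function(i) {
      integrate(f, cuts[i], cuts[i + 1], rel.tol = 1e-10, abs.tol = 0,
                subdivisions = 500L)$value
    }, numeric(1)))
  }
  z <- quad(bw)
  num <- quad(function(x) observable(x) * bw(x))
  num / z
}
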