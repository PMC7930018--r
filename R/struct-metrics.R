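#' Structure tables
#'
#' Structures are plain tibbles with one row per site (bead or atom) and
#' columns `site` (unique label), `role` (`"receptor"` or `"ligand"`),
#' `seq` (sequence index within its molecule, used for the intramolecular
#' contact separation rule), `x`, `y`, `z` (Angstrom) and `radius`
#' (Angstrom, used for surface-area calculations).
#'
#' `snapshot_structure()` assembles such a table for one ensemble snapshot
#' of a toy system (fixed receptor beads plus the mobile beads at their
#' recorded positions); `pose_structure()` does the same for a bare
#' coordinate matrix such as the reference bound pose.
#'
#' @param system a `toy_system`.
#' @param ensemble ensemble tibble.
#' @param i snapshot row index.
#' @param coords mobile-bead coordinate matrix.
#' @return a structure tibble.
#' @name structure_tbl
NULL

#' @rdname structure_tbl
#' @export
snapshot_structure <- function(system, ensemble, i) {
  pose_structure(system, snapshot_coords(ensemble, i, nrow(system$mobile0)))
}

#' @rdname structure_tbl
#' @export
pose_structure <- function(system, coords) {
  s <- system$sites
  xyz <- matrix(NA_real_, nrow(s), 3)
  xyz[s$kind == "fixed", ] <- system$fixed[s$index[s$kind == "fixed"], , drop = FALSE]
  xyz[s$kind == "mobile", ] <- coords[s$index[s$kind == "mobile"], , drop = FALSE]
  tibble(site = s$site, role = s$role,
         seq = stats::ave(seq_len(nrow(s)), s$role, FUN = seq_along),
         x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], radius = s$radius)
}

struct_xyz <- function(structure, sites = NULL) {
  if (!is.null(sites)) {
    structure <- structure[match(sites, structure$site), ]
    if (anyNA(structure$site)) abort("sites missing from structure")
  }
  as.matrix(structure[, c("x", "y", "z")])
}

pair_distances <- function(structure) {
  as.matrix(stats::dist(struct_xyz(structure)))
}

#' Contact set of a reference structure
#'
#' All site pairs within `cutoff` (Angstrom); intramolecular pairs are kept
#' only when their sequence separation exceeds `s_min`.  With
#' `inter_only = TRUE`, only receptor-ligand pairs are returned (the
#' representative contacts used by the R-value).
#'
#' @param structure a structure tibble.
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @param s_min minimum intramolecular sequence separation (default 3).
#' @param inter_only keep receptor-ligand contacts only.
#' @param region optional character vector of site labels restricting the
#'   contact search.
#' @return tibble with `site_a`, `site_b`, `distance`.
#' @export
contact_set <- function(structure, cutoff = 4.5, s_min = 3,
                        inter_only = FALSE, region = NULL) {
  st <- structure
  if (!is.null(region)) st <- st[st$site %in% region, ]
  n <- nrow(st)
  if (n < 2) return(tibble(site_a = character(), site_b = character(),
                           distance = numeric()))
  d <- as.matrix(stats::dist(as.matrix(st[, c("x", "y", "z")])))
  keep <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(keep) == 0) return(tibble(site_a = character(), site_b = character(),
                                     distance = numeric()))
  a <- keep[, 1]; b <- keep[, 2]
  same <- st$role[a] == st$role[b]
  sep_ok <- !same | abs(st$seq[a] - st$seq[b]) > s_min
  inter <- !same
  sel <- sep_ok & (!inter_only | inter)
  tibble(site_a = st$site[a[sel]], site_b = st$site[b[sel]],
         distance = d[keep][sel])
}

contact_fraction <- function(query, contacts, cutoff, f_tol = 1) {
  if (nrow(contacts) == 0) abort("empty reference contact set")
  xa <- struct_xyz(query, contacts$site_a)
  xb <- struct_xyz(query, contacts$site_b)
  d <- sqrt(rowSums((xa - xb)^2))
  mean(d <= cutoff * f_tol)
}

#' Fraction of native contacts (Q-value)
#'
#' Fraction of the reference structure's contacts (pairs within `cutoff`,
#' intramolecular pairs separated by more than `s_min` in sequence) that are
#' also formed (within `cutoff * f_tol`) in the query.
#'
#' @param query,reference structure tibbles sharing the site labels of
#'   `region`.
#' @param region optional site labels restricting the comparison.
#' @inheritParams contact_set
#' @param f_tol query tolerance factor on the cutoff (default 1, a hard
#'   cutoff).
#' @return fraction in \[0, 1\].
#' @export
qvalue <- function(query, reference, region = NULL, cutoff = 4.5, s_min = 3,
                   f_tol = 1) {
  contacts <- contact_set(reference, cutoff, s_min, inter_only = FALSE,
                          region = region)
  contact_fraction(query, contacts, cutoff, f_tol)
}

#' Fraction of representative intermolecular contacts (R-value)
#'
#' Intermolecular variant of the Q-value: the fraction of receptor-ligand
#' contacts of a reference complex that are preserved in the query.
#' R(native) uses the experimentally known (or, for toy systems, the
#' ground-truth) complex as the reference.
#'
#' @inheritParams qvalue
#' @return fraction in \[0, 1\].
#' @export
rvalue <- function(query, reference, cutoff = 4.5, f_tol = 1) {
  if (!any(reference$role == "ligand") || !any(query$role == "ligand")) {
    abort("both structures need ligand sites")
  }
  contacts <- contact_set(reference, cutoff, inter_only = TRUE)
  contact_fraction(query, contacts, cutoff, f_tol)
}

# least-squares (Kabsch) superposition of q onto r via bio3d; returns moved q
kabsch_move <- function(q, r, fit_idx) {
  inds <- bio3d::atom2xyz(fit_idx)
  moved <- bio3d::fit.xyz(fixed = as.vector(t(r)), mobile = as.vector(t(q)),
                          fixed.inds = inds, mobile.inds = inds)
  matrix(moved, ncol = 3, byrow = TRUE)
}

#' Root-mean-square deviation after least-squares superposition
#'
#' Superposes the query onto the reference on `fit_sites` (optimal rotation
#' and translation) and measures the RMSD over `measure_sites`, which may
#' differ from the superposition selection (for instance: superpose on the
#' receptor scaffold, measure over the binding-site region or the ligand).
#'
#' @param query,reference structure tibbles.
#' @param fit_sites site labels used for the superposition (default: all
#'   shared sites; at least 3 required).
#' @param measure_sites site labels measured (default: `fit_sites`).
#' @param superpose set to `FALSE` to measure in the original frames.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(query, reference, fit_sites = NULL, measure_sites = NULL,
                 superpose = TRUE) {
  if (is.null(fit_sites)) fit_sites <- intersect(query$site, reference$site)
  if (is.null(measure_sites)) measure_sites <- fit_sites
  all_sites <- union(fit_sites, measure_sites)
  q <- struct_xyz(query, all_sites)
  r <- struct_xyz(reference, all_sites)
  if (superpose) {
    if (length(fit_sites) < 3) abort("need at least 3 sites for superposition")
    q <- kabsch_move(q, r, match(fit_sites, all_sites))
  }
  mi <- match(measure_sites, all_sites)
  sqrt(mean(rowSums((q[mi, , drop = FALSE] - r[mi, , drop = FALSE])^2)))
}

#' RMSD ignoring translation along the reaction coordinate
#'
#' Removes the component of the ligand centre-of-mass displacement along a
#' unit direction before computing a plain (non-superposed) RMSD over the
#' ligand sites.  A query that is the reference translated purely along the
#' direction scores 0; a purely perpendicular translation by d scores d.
#'
#' @param query,reference structure tibbles.
#' @param direction the reaction-coordinate direction (normalised
#'   internally; must be non-zero).
#' @param sites site labels measured (default: ligand sites).
#' @return RMSD in Angstrom.
#' @export
rmsd_lambda <- function(query, reference, direction, sites = NULL) {
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) abort("direction must be non-zero")
  u <- direction / nrm
  if (is.null(sites)) sites <- reference$site[reference$role == "ligand"]
  q <- struct_xyz(query, sites)
  r <- struct_xyz(reference, sites)
  d <- colMeans(q) - colMeans(r)
  shift <- sum(d * u) * u
  q <- sweep(q, 2, shift)
  sqrt(mean(rowSums((q - r)^2)))
}

# deterministic quasi-uniform sphere points (golden-spiral construction)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

shrake_rupley <- function(xyz, radii, probe, n_points, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(nrow(xyz))
  pts <- sphere_points(n_points)
  rr <- radii + probe
  area <- numeric(length(subset))
  for (q in seq_along(subset)) {
    i <- subset[q]
    sp <- sweep(pts * rr[i], 2, xyz[i, ], `+`)
    occluded <- rep(FALSE, n_points)
    for (j in seq_len(nrow(xyz))) {
      if (j == i) next
      dj <- sweep(sp, 2, xyz[j, ])
      occluded <- occluded | rowSums(dj^2) < rr[j]^2
      if (all(occluded)) break
    }
    area[q] <- 4 * pi * rr[i]^2 * mean(!occluded)
  }
  area
}

#' Relative accessible surface area of the ligand
#'
#' Shrake-Rupley style sphere-point sampling: the solvent-accessible surface
#' area of the ligand in the complex divided by its SASA in isolation.
#' 1 means fully exposed, 0 fully buried.
#'
#' @param complex structure tibble containing receptor and ligand sites with
#'   `radius` assigned.
#' @param ligand_sites site labels of the ligand (default: `role ==
#'   "ligand"`).
#' @param probe probe radius in Angstrom (default 1.4).
#' @param n_points sphere sample points per site (default 960).
#' @return fraction in \[0, 1\].
#' @export
rasa <- function(complex, ligand_sites = NULL, probe = 1.4, n_points = 960) {
  if (is.null(ligand_sites)) ligand_sites <- complex$site[complex$role == "ligand"]
  xyz <- struct_xyz(complex)
  li <- match(ligand_sites, complex$site)
  a_complex <- shrake_rupley(xyz, complex$radius, probe, n_points, subset = li)
  lig <- complex[li, ]
  a_iso <- shrake_rupley(struct_xyz(lig), lig$radius, probe, n_points)
  if (sum(a_iso) <= 0) abort("isolated ligand has zero accessible surface")
  sum(a_complex) / sum(a_iso)
}

#' Nearest-to-average snapshot of a trajectory window
#'
#' Computes the mean coordinates of the selection over the window and
#' returns the snapshot minimizing the RMSD to that mean, optionally after
#' least-squares superposition of each snapshot onto the mean.  Ties break
#' to the earliest snapshot.
#'
#' @param ensemble ensemble tibble (the window).
#' @param system the `toy_system`.
#' @param idx mobile bead indices forming the selection (default: all).
#' @param superpose superpose snapshots onto the window mean first
#'   (default `TRUE`; requires at least 3 selected beads).
#' @return list with `row` (window row index), `rmsd`, and `coords` (the
#'   full mobile coordinates of the chosen snapshot).
#' @export
nearest_to_average <- function(ensemble, system, idx = NULL, superpose = TRUE) {
  n <- nrow(system$mobile0)
  if (is.null(idx)) idx <- seq_len(n)
  if (nrow(ensemble) == 0) abort("empty trajectory window")
  xs <- coords_block(ensemble, n)
  cols <- as.vector(vapply(idx, function(i) 3 * (i - 1) + 1:3, numeric(3)))
  sel <- xs[, cols, drop = FALSE]
  mean_vec <- colMeans(sel)
  if (superpose && length(idx) >= 3) {
    inds <- seq_along(mean_vec)
    sel <- bio3d::fit.xyz(fixed = mean_vec, mobile = sel,
                          fixed.inds = inds, mobile.inds = inds)
  }
  rmsds <- sqrt(rowMeans(sweep(sel, 2, mean_vec)^2) * 3)
  row <- which.min(rmsds)
  list(row = row, rmsd = rmsds[row],
       coords = snapshot_coords(ensemble, row, n))
}
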