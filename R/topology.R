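#' Rigid water model specification
#'
#' Describes the rigid water geometry used throughout the package.  The
#' default `"four_site"` model is a dispersion-corrected four-site water
#' (TIP4P-D-like geometry and charges: OH 0.09572 nm, HOH 104.52 degrees,
#' massless charge site displaced 0.01546 nm from the oxygen along the
#' bisector, qH = +0.58 e).  A `"point"` model (single Lennard-Jones-like
#' site, no rotational degrees of freedom) is available for coarse fixtures
#' such as the Langevin soft-sphere fluid.
#'
#' Site coordinates are returned in the body frame: center of mass at the
#' origin and axes aligned with the principal axes of inertia (x along the
#' H-H direction, z along the dipole/bisector, y out of the molecular
#' plane).  Internal geometry is fixed: waters are rigid by construction and
#' flexible waters are rejected everywhere in the package.
#'
#' @param type `"four_site"` (default) or `"point"`.
#' @return List with `type`, `n_sites`, `site_names`, `masses` (amu),
#'   `charges` (e), `sites` (n_sites x 3 body-frame coordinates, nm),
#'   `mass` (total, amu), `principal_moments` (amu nm^2, about x/y/z),
#'   `sigma`/`epsilon` (oxygen Lennard-Jones parameters, nm and kJ/mol) and
#'   `symmetry_number` (2 for C2v water).
#' @export
#' @examples
#' wm <- water_model()
#' wm$principal_moments          # ~0.0061, 0.0177, 0.0115 amu nm^2
water_model <- function(type = c("four_site", "point")) {
  type <- match.arg(type)
  if (type == "point") {
    return(structure(list(
      type = "point", n_sites = 1L, site_names = "OW",
      masses = 18.0154, charges = 0,
      sites = matrix(0, 1, 3), mass = 18.0154,
      principal_moments = NULL, sigma = 0.30, epsilon = 0.65,
      symmetry_number = 1L), class = "ct_water_model"))
  }
  r_oh <- 0.09572; ang <- 104.52 * pi / 180; r_om <- 0.01546
  m <- c(OW = 15.9994, HW1 = 1.008, HW2 = 1.008, MW = 0)
  xh <- r_oh * sin(ang / 2); zh <- r_oh * cos(ang / 2)
  # O at origin, bisector along +z, then shift to the center of mass
  s <- rbind(OW  = c(0, 0, 0),
             HW1 = c( xh, 0, zh),
             HW2 = c(-xh, 0, zh),
             MW  = c(0, 0, r_om))
  com <- colSums(s * m) / sum(m)
  s <- sweep(s, 2, com)
  # principal moments about x (H-H axis), y (out of plane), z (dipole)
  I <- c(sum(m * (s[, 2]^2 + s[, 3]^2)),
         sum(m * (s[, 1]^2 + s[, 3]^2)),
         sum(m * (s[, 1]^2 + s[, 2]^2)))
  structure(list(
    type = "four_site", n_sites = 4L,
    site_names = rownames(s), masses = unname(m),
    charges = c(0, 0.58, 0.58, -1.16),
    sites = unname(s), mass = sum(m),
    principal_moments = I,
    sigma = 0.3165, epsilon = 0.9368,
    symmetry_number = 2L), class = "ct_water_model")
}

#' Build a system topology
#'
#' A topology partitions the atoms of a system into protein chains, rigid
#' waters and ions, and carries the masses needed for center-of-mass and
#' inertia work.  Atom order in any associated [frame()] is: all chain atoms
#' (chain by chain), then all water sites (molecule by molecule), then ions.
#'
#' @param chains list of chain records, each a list with `id`, `atom_names`,
#'   `masses` (amu) and optionally `elements`.  May be empty.
#' @param n_waters number of rigid water molecules.
#' @param water water model from [water_model()].
#' @param ions optional data.frame with columns `name` and `mass`.
#' @return A `ct_topology` object.
#' @export
topology <- function(chains = list(), n_waters = 0L, water = water_model(),
                     ions = NULL) {
  .assert(n_waters >= 0, "n_waters must be >= 0")
  for (ch in chains) {
    .assert(!is.null(ch$id) && length(ch$masses) == length(ch$atom_names),
            "each chain needs an id and matching atom_names/masses")
    .assert(all(ch$masses > 0), "chain atom masses must be positive")
  }
  n_chain_atoms <- sum(vapply(chains, function(ch) length(ch$masses), 0L))
  n_ions <- if (is.null(ions)) 0L else nrow(ions)
  obj <- structure(list(
    chains = chains, n_waters = as.integer(n_waters), water = water,
    ions = ions,
    n_atoms = n_chain_atoms + as.integer(n_waters) * water$n_sites + n_ions
  ), class = "ct_topology")
  obj
}

#' @export
print.ct_topology <- function(x, ...) {
  cat("<ct_topology> ", length(x$chains), " chain(s), ",
      x$n_waters, " water(s) [", x$water$type, "], ",
      if (is.null(x$ions)) 0L else nrow(x$ions), " ion(s), ",
      x$n_atoms, " atoms total\n", sep = "")
  invisible(x)
}

# atom index bookkeeping -----------------------------------------------------

# rows of the position matrix occupied by chain k
.chain_rows <- function(top, k) {
  off <- 0L
  for (i in seq_len(k - 1L)) off <- off + length(top$chains[[i]]$masses)
  off + seq_len(length(top$chains[[k]]$masses))
}

.n_chain_atoms <- function(top)
  sum(vapply(top$chains, function(ch) length(ch$masses), 0L))

# rows of the position matrix occupied by water molecule i (all sites)
.water_rows <- function(top, i) {
  .n_chain_atoms(top) + (i - 1L) * top$water$n_sites + seq_len(top$water$n_sites)
}

# n_waters x 1 index of the oxygen (first site) of each water
.oxygen_rows <- function(top) {
  if (top$n_waters == 0L) return(integer(0))
  .n_chain_atoms(top) + (seq_len(top$n_waters) - 1L) * top$water$n_sites + 1L
}

#' Single simulation frame
#'
#' @param positions n_atoms x 3 matrix (nm).
#' @param box length-3 orthorhombic edge lengths (nm).  Triclinic boxes are
#'   not supported.
#' @param velocities optional n_atoms x 3 matrix (nm/ps).
#' @param time time stamp (ps).
#' @return A `ct_frame` object.
#' @export
frame <- function(positions, box, velocities = NULL, time = 0) {
  positions <- as.matrix(positions)
  .assert(ncol(positions) == 3, "positions must be an n x 3 matrix")
  .assert(all(is.finite(positions)), "positions must be finite")
  .assert(length(box) == 3 && all(box > 0), "box must be 3 positive edge lengths")
  if (!is.null(velocities)) {
    velocities <- as.matrix(velocities)
    .assert(all(dim(velocities) == dim(positions)),
            "velocities must match positions in shape")
  }
  structure(list(positions = positions, velocities = velocities,
                 box = as.numeric(box), time = time), class = "ct_frame")
}

#' @export
print.ct_frame <- function(x, ...) {
  cat("<ct_frame> ", nrow(x$positions), " atoms, box ",
      paste(signif(x$box, 4), collapse = " x "), " nm, t = ", x$time, " ps",
      if (!is.null(x$velocities)) ", with velocities" else "", "\n", sep = "")
  invisible(x)
}

# positions of water sites of molecule i, made whole (sites pulled to the
# minimum image of the oxygen); needed because trajectories may wrap sites
.whole_water <- function(fr, top, i) {
  rows <- .water_rows(top, i)
  p <- fr$positions[rows, , drop = FALSE]
  ref <- p[1, ]
  sweep(min_image(sweep(p, 2, ref), fr$box), 2, ref, "+")
}
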