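# VelocitySeries: time-ordered per-molecule center-of-mass (and, for rigid
# waters, principal-frame angular) velocities.  This is the fuel for the
# VACF/density-of-states machinery of the 2PT entropy engine.

#' Construct a velocity series
#'
#' @param dt sampling interval (ps), constant.
#' @param com_velocities array `[n_frames, n_molecules, 3]` of
#'   center-of-mass velocities (nm/ps).
#' @param angular_velocities optional array of the same shape with angular
#'   velocities about the molecular principal axes (rad/ps); present only
#'   for rigid species.
#' @param masses per-molecule masses (amu), length `n_molecules`.
#' @param principal_moments length-3 principal moments of inertia
#'   (amu nm^2), shared by all molecules of the rigid species, or `NULL`.
#' @param n_density number density (molecules/nm^3), needed by the
#'   hard-sphere fluidicity machinery; may be `NA` for fixtures that never
#'   reach it.
#' @param temperature nominal temperature (K), metadata only.
#' @return A `ct_velocity_series`.
#' @export
velocity_series <- function(dt, com_velocities, angular_velocities = NULL,
                            masses, principal_moments = NULL,
                            n_density = NA_real_, temperature = NA_real_) {
  d <- dim(com_velocities)
  .assert(length(d) == 3L && d[3] == 3L,
          "com_velocities must be an [n_frames, n_molecules, 3] array")
  .assert(d[1] >= 2L, "a velocity series needs at least 2 frames")
  .assert(is.finite(dt) && dt > 0, "dt must be a positive scalar (ps)")
  .assert(length(masses) == d[2], "one mass per molecule required")
  if (!is.null(angular_velocities)) {
    .assert(all(dim(angular_velocities) == d),
            "angular_velocities must match com_velocities in shape")
    .assert(!is.null(principal_moments) && length(principal_moments) == 3L,
            "principal_moments required alongside angular velocities")
  }
  structure(list(dt = dt, com_velocities = com_velocities,
                 angular_velocities = angular_velocities,
                 masses = masses, principal_moments = principal_moments,
                 n_density = n_density, temperature = temperature),
            class = "ct_velocity_series")
}

#' @export
print.ct_velocity_series <- function(x, ...) {
  d <- dim(x$com_velocities)
  cat("<ct_velocity_series> ", d[2], " molecules x ", d[1], " frames, dt = ",
      x$dt, " ps (", signif((d[1] - 1) * x$dt, 4), " ps)",
      if (!is.null(x$angular_velocities)) ", with angular velocities" else "",
      "\n", sep = "")
  invisible(x)
}

#' Duration of a velocity series in ps
#' @param series a [velocity_series()]
#' @return scalar ps
#' @export
series_duration <- function(series) (dim(series$com_velocities)[1] - 1) * series$dt

# body axes of one water from its (whole) site positions:
# x along H1-H2, z along the O -> H-midpoint bisector, y = z x x.
# These coincide with the principal axes of a C2v water.
.water_axes <- function(p) {
  xa <- p[2, ] - p[3, ]
  xa <- xa / sqrt(sum(xa^2))
  zr <- (p[2, ] + p[3, ]) / 2 - p[1, ]
  zr <- zr - sum(zr * xa) * xa
  za <- zr / sqrt(sum(zr^2))
  ya <- c(za[2] * xa[3] - za[3] * xa[2],
          za[3] * xa[1] - za[1] * xa[3],
          za[1] * xa[2] - za[2] * xa[1])
  cbind(xa, ya, za)  # columns are body axes in the lab frame
}

#' Convert frames with velocities into a velocity series
#'
#' Computes per-water center-of-mass velocities (mass-weighted site mean)
#' and angular velocities about the center of mass via the inertia tensor
#' (`omega = I^-1 L`), expressed in the molecular principal frame.  The
#' decomposition conserves kinetic energy exactly for rigid waters.
#'
#' @param frames list of [frame()] objects carrying velocities, uniform
#'   stride.
#' @param top the matching [topology()]; must contain rigid waters.
#' @param temperature nominal temperature (K), metadata.
#' @return A [velocity_series()] for the water molecules.
#' @export
read_velocity_frames <- function(frames, top, temperature = NA_real_) {
  .assert(length(frames) >= 2L, "need at least 2 frames")
  .assert(top$n_waters >= 1L, "topology contains no waters")
  for (fr in frames)
    if (is.null(fr$velocities))
      stop("trajectory frame has no velocities; refusing to assume zeros",
           call. = FALSE)
  times <- vapply(frames, function(f) f$time, 0)
  dts <- diff(times)
  .assert(all(abs(dts - dts[1]) < 1e-9 * max(abs(dts[1]), 1)) && dts[1] > 0,
          "nonuniform or nonpositive trajectory stride")
  wm <- top$water
  nW <- top$n_waters; nF <- length(frames)
  m <- wm$masses; M <- wm$mass
  Ib <- wm$principal_moments
  .assert(!is.null(Ib), "water model has no rotational degrees of freedom")
  comv <- array(0, c(nF, nW, 3))
  angv <- array(0, c(nF, nW, 3))
  for (f in seq_len(nF)) {
    fr <- frames[[f]]
    for (i in seq_len(nW)) {
      rows <- .water_rows(top, i)
      p <- .whole_water(fr, top, i)
      v <- fr$velocities[rows, , drop = FALSE]
      vcom <- colSums(v * m) / M
      comv[f, i, ] <- vcom
      rcom <- colSums(p * m) / M
      dr <- sweep(p, 2, rcom)
      dv <- sweep(v, 2, vcom)
      # angular momentum about the COM
      L <- c(sum(m * (dr[, 2] * dv[, 3] - dr[, 3] * dv[, 2])),
             sum(m * (dr[, 3] * dv[, 1] - dr[, 1] * dv[, 3])),
             sum(m * (dr[, 1] * dv[, 2] - dr[, 2] * dv[, 1])))
      A <- .water_axes(p)
      angv[f, i, ] <- as.numeric(crossprod(A, L)) / Ib
    }
  }
  box <- frames[[1]]$box
  velocity_series(dts[1], comv, angv, rep(M, nW), Ib,
                  n_density = nW / prod(box), temperature = temperature)
}

#' Read a plain-text velocity trajectory
#'
#' Reads a concatenated-GRO trajectory holding velocities and converts it
#' with [read_velocity_frames()].
#'
#' @param path trajectory path.
#' @param top matching [topology()].
#' @param dialect see [read_frames()].
#' @param temperature nominal temperature (K).
#' @return A [velocity_series()].
#' @export
read_velocity_trajectory <- function(path, top, dialect = "auto",
                                     temperature = NA_real_) {
  read_velocity_frames(read_frames(path, top, dialect), top, temperature)
}

#' Kinetic energy bookkeeping of a frame
#'
#' Total site kinetic energy and its rigid-body decomposition
#' `sum 1/2 m v_site^2 = 1/2 M v_com^2 + 1/2 sum I_k omega_k^2` for the
#' waters of a frame.  Used as a consistency diagnostic.
#'
#' @param fr a [frame()] with velocities.
#' @param top matching [topology()].
#' @return list with `site`, `translational`, `rotational` (kJ/mol).
#' @export
kinetic_decomposition <- function(fr, top) {
  .assert(!is.null(fr$velocities), "frame has no velocities")
  wm <- top$water; m <- wm$masses
  ke_site <- 0; ke_tr <- 0; ke_rot <- 0
  fr2 <- fr; fr2$time <- fr$time + 1
  vs <- read_velocity_frames(list(fr, fr2), top)  # reuse decomposition
  for (i in seq_len(top$n_waters)) {
    rows <- .water_rows(top, i)
    v <- fr$velocities[rows, , drop = FALSE]
    ke_site <- ke_site + 0.5 * sum(m * rowSums(v^2))
    ke_tr <- ke_tr + 0.5 * wm$mass * sum(vs$com_velocities[1, i, ]^2)
    ke_rot <- ke_rot + 0.5 * sum(wm$principal_moments * vs$angular_velocities[1, i, ]^2)
  }
  list(site = ke_site, translational = ke_tr, rotational = ke_rot)
}
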