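# The 2PT entropy engine.
#
# Pipeline: velocity autocorrelation (VACF) -> vibrational density of states
# (DoS) -> universal fluidicity -> solid/gas partition -> molar entropy.
#
# The liquid's DoS, I(nu) = 2/(kB T) * FT[C(t)], is split into a solid-like
# part treated as a continuum of harmonic oscillators and a diffusive
# gas-like part treated with Enskog hard-sphere theory (translation) or the
# rigid-rotor model (rotation).  The fluidicity f (fraction of degrees of
# freedom assigned to the gas) solves a universal equation in the
# dimensionless diffusivity Delta built from the zero-frequency intensity
# s0.  These closed forms are frozen here and covered by oracle tests:
#
#   Delta = (2 s0 / 9N) sqrt(pi kB T / m) rho^(1/3) (6/pi)^(2/3)
#   0 = 2 y^3 - 6 y^2 + (6 - f) y + 2 f - 2,   y = f^(5/2) Delta^(-3/2)
#   I_gas(nu) = s0 / (1 + (pi s0 nu / (6 f N))^2)
#   W_S^HO(nu) = x/(e^x - 1) - ln(1 - e^-x),    x = h nu / kB T
#   s_HS/kB = 5/2 + ln[(2 pi m kB T/h^2)^(3/2) z(y)/(f rho)] + y(3y-4)/(1-y)^2
#   s_RR/kB = 3/2 + ln[sqrt(pi)/sigma * (T^3/(Th_A Th_B Th_C))^(1/2)]
#
# with z(y) the Carnahan-Starling compressibility and Th_k the rotational
# temperatures of the rigid water model.

#' Velocity autocorrelation function
#'
#' Mass-weighted (translational) or inertia-weighted (rotational)
#' autocorrelation, summed over molecules and Cartesian/principal
#' components and ensemble-averaged over initial times with the unbiased
#' `1/(n-lag)` normalization.  At lag zero the translational value equals
#' `sum_i m_i <|v_i|^2>`, i.e. twice the kinetic energy (about `3 N kB T`).
#'
#' @param series a [velocity_series()].
#' @param kind `"translational"` or `"rotational"`.
#' @param max_lag maximum lag (ps); must be at most half the series
#'   duration (default: exactly half).
#' @return A `ct_correlogram` with uniform `lags` (ps) starting at 0 and
#'   `values` in amu nm^2 ps^-2 (= kJ/mol).
#' @export
compute_vacf <- function(series, kind = c("translational", "rotational"),
                         max_lag = NULL) {
  kind <- match.arg(kind)
  dur <- series_duration(series)
  if (is.null(max_lag)) max_lag <- dur / 2
  .assert(max_lag > 0 && max_lag <= dur / 2 + 1e-9,
          "max_lag must be positive and at most duration/2")
  v <- if (kind == "translational") series$com_velocities
       else series$angular_velocities
  if (is.null(v))
    stop("series has no angular velocities; rotational VACF undefined",
         call. = FALSE)
  nF <- dim(v)[1]; nM <- dim(v)[2]
  L <- floor(max_lag / series$dt + 1e-9)
  # per-(molecule, component) weights
  w <- if (kind == "translational") {
    matrix(rep(series$masses, 3), nM, 3)
  } else {
    matrix(rep(series$principal_moments, each = nM), nM, 3)
  }
  x <- matrix(v, nF, nM * 3L)  # columns ordered (molecule, component)
  n2 <- 2L^ceiling(log2(2L * nF))
  xp <- rbind(x, matrix(0, n2 - nF, ncol(x)))
  Fx <- mvfft(xp)
  ac <- Re(mvfft(Fx * Conj(Fx), inverse = TRUE))[seq_len(L + 1L), , drop = FALSE] / n2
  ac <- ac / (nF - (0:L))              # unbiased lag normalization
  vals <- as.numeric(ac %*% as.numeric(w))
  structure(list(lags = (0:L) * series$dt, values = vals, kind = kind,
                 dt = series$dt, n_molecules = nM),
            class = "ct_correlogram")
}

#' Density of states from a correlogram
#'
#' Real even-extension cosine transform scaled by `2/(kB T)`:
#' `I(nu) = 4/(kB T) * integral_0^inf C(t) cos(2 pi nu t) dt`, evaluated by
#' trapezoid-weighted FFT with two-fold zero padding.  By default the
#' correlogram is tapered with a Bartlett (triangular) window before the
#' transform: this reproduces the classical biased-autocorrelation
#' (Fejer-kernel) spectral estimate, which is essentially nonnegative, so
#' the solid/gas partition is not biased by clipped truncation sidelobes.
#' The window choice is recorded in the object.  With this one-sided
#' convention `integral_0^inf I(nu) dnu` equals the weighted degrees of
#' freedom, `3 N` for either kind (the lag-0 value is untouched by the
#' taper, so the normalization is window-independent).
#'
#' @param cg a [compute_vacf()] correlogram with uniform lags.
#' @param T temperature (K), positive.
#' @param window `"bartlett"` (default) or `"none"`.
#' @return A `ct_dos` with `frequencies` (THz), `intensity` (per THz),
#'   `s0 = I(0)`, the achieved `normalization` and its `target`.
#' @export
compute_dos <- function(cg, T, window = c("bartlett", "none")) {
  window <- match.arg(window)
  .assert(is.finite(T) && T > 0, "temperature must be positive")
  dl <- diff(cg$lags)
  .assert(all(abs(dl - dl[1]) < 1e-9), "correlogram lags must be uniform")
  dt <- dl[1]
  L <- length(cg$values) - 1L
  npad <- 2L * 2L^ceiling(log2(L + 1L))
  wts <- c(0.5, rep(1, L - 1L), 0.5)
  if (window == "bartlett") wts <- wts * (1 - (0:L) / (L + 1L))
  y <- c(cg$values * wts, rep(0, npad - L - 1L))
  I <- (4 * dt / (.ct$kB * T)) * Re(fft(y))[seq_len(npad %/% 2L + 1L)]
  freq <- (0:(npad %/% 2L)) / (npad * dt)
  structure(list(frequencies = freq, intensity = I, kind = cg$kind,
                 n_molecules = cg$n_molecules,
                 s0 = max(I[1], 0),
                 normalization = trapz(freq, I),
                 target = 3 * cg$n_molecules,
                 negative_weight = -trapz(freq, pmin(I, 0)),
                 window = window, zero_pad = 2L, temperature = T),
            class = "ct_dos")
}

#' @export
print.ct_dos <- function(x, ...) {
  cat("<ct_dos> ", x$kind, ", ", length(x$frequencies), " bins to ",
      signif(max(x$frequencies), 4), " THz; s0 = ", signif(x$s0, 5),
      "; integral ", signif(x$normalization, 5), " (target ", x$target,
      ")\n", sep = "")
  invisible(x)
}

# dimensionless normalized diffusivity
.fluidicity_delta <- function(s0, n_molecules, n_density, mass, T) {
  (2 * s0 / (9 * n_molecules)) * sqrt(pi * .ct$kB * T / mass) *
    n_density^(1 / 3) * (6 / pi)^(2 / 3)
}

# universal fluidicity polynomial, in terms of y = f^(5/2) Delta^(-3/2)
.fluidicity_poly <- function(f, delta) {
  y <- f^2.5 * delta^-1.5
  2 * y^3 - 6 * y^2 + (6 - f) * y + 2 * f - 2
}

#' Solve the universal 2PT fluidicity equation
#'
#' @param dos a `ct_dos` (supplies `s0` and the molecule count).
#' @param n_density number density (molecules/nm^3).
#' @param mass molecular mass (amu).
#' @param T temperature (K).
#' @return fluidicity `f` in `[0, 1]`, with attributes `delta` and `y`.
#'   `s0 = 0` returns `f = 0` (pure solid).
#' @export
solve_fluidicity <- function(dos, n_density, mass, T) {
  .assert(is.finite(n_density) && n_density > 0, "n_density must be positive")
  .assert(dos$s0 >= 0, "s0 must be nonnegative")
  if (dos$s0 == 0)
    return(structure(0, delta = 0, y = 0))
  delta <- .fluidicity_delta(dos$s0, dos$n_molecules, n_density, mass, T)
  lo <- 0; hi <- 1
  glo <- -2  # value at f = 0
  ghi <- .fluidicity_poly(1, delta)
  if (glo * ghi > 0)
    stop("fluidicity bracketing failed: g(0) = ", glo, ", g(1) = ", ghi,
         ", delta = ", delta, call. = FALSE)
  for (it in 1:200) {
    mid <- (lo + hi) / 2
    gm <- .fluidicity_poly(mid, delta)
    if (gm == 0) { lo <- hi <- mid; break }
    if (gm * glo < 0) hi <- mid else { lo <- mid; glo <- gm }
    if (hi - lo < 1e-12) break
  }
  f <- (lo + hi) / 2
  structure(f, delta = delta, y = f^2.5 * delta^-1.5)
}

#' Partition a DoS into solid-like and gas-like parts
#'
#' The gas part is the hard-sphere/rigid-rotor diffusive lineshape
#' `I_g(nu) = s0 / (1 + (pi s0 nu / (6 f N))^2)` carrying `3 N f` degrees
#' of freedom with `I_g(0) = s0`; the solid part is the signed remainder,
#' so `solid + gas` reproduces the input exactly.  The integrated weight
#' of any negative solid excursions is recorded on the solid component
#' (`clipped_weight`) as a QC metric and triggers a warning when large.
#'
#' @param dos a `ct_dos`.
#' @param f fluidicity from [solve_fluidicity()].
#' @return list with elements `solid` and `gas` (both `ct_dos`).
#' @export
partition_dos <- function(dos, f) {
  nu <- dos$frequencies
  gas_I <- if (f <= 0) rep(0, length(nu)) else
    dos$s0 / (1 + (pi * dos$s0 * nu / (6 * f * dos$n_molecules))^2)
  # signed remainder: where the diffusive lineshape locally exceeds the
  # spectrum the solid part goes negative; those excursions are kept so
  # that solid + gas reproduces the original exactly and finite-window
  # kernel mismatch cancels inside the smooth entropy integrals.  The
  # total negative weight is logged as a QC metric.
  solid_I <- dos$intensity - gas_I
  clipped <- -trapz(nu, pmin(solid_I, 0))
  if (clipped > 0.05 * dos$target)
    warning("diffusive lineshape exceeds the spectrum by ",
            signif(clipped, 3), " dof (negative solid remainder)",
            call. = FALSE)
  mk <- function(I, s0) {
    d <- dos
    d$intensity <- I; d$s0 <- s0; d$normalization <- trapz(nu, I)
    d
  }
  solid <- mk(solid_I, 0)
  solid$clipped_weight <- clipped
  gas <- mk(gas_I, dos$s0)
  # closed-form Lorentzian integral over [0, nu_max]; immune to the
  # quadrature error of a barely grid-resolved diffusive peak
  if (f > 0) {
    w <- 6 * as.numeric(f) * dos$n_molecules / (pi * dos$s0)
    gas$analytic_dof <- (6 * as.numeric(f) * dos$n_molecules / pi) *
      atan(max(nu) / w)
  } else gas$analytic_dof <- 0
  list(solid = solid, gas = gas)
}

# quantum harmonic oscillator entropy weight per dof, in units of kB
.w_ho_entropy <- function(nu, T) {
  x <- .ct$h * nu / (.ct$kB * T)
  w <- numeric(length(x))
  pos <- x > 0
  w[pos] <- x[pos] / expm1(x[pos]) - log1p(-exp(-x[pos]))
  w[!pos] <- 0  # I_solid(0) = 0 by construction; weight there is moot
  w
}

# Carnahan-Starling compressibility
.cs_z <- function(y) (1 + y + y^2 - y^3) / (1 - y)^3

# hard-sphere gas entropy per molecule, units of kB
.s_hs <- function(T, mass, n_density, f, y) {
  lam3 <- (.ct$h / sqrt(2 * pi * mass * .ct$kB * T))^3  # nm^3
  5 / 2 + log(.cs_z(y) / (f * n_density * lam3)) + y * (3 * y - 4) / (1 - y)^2
}

# rigid-rotor gas entropy per molecule, units of kB
.s_rr <- function(T, principal_moments, symmetry_number) {
  theta <- .ct$h^2 / (8 * pi^2 * principal_moments * .ct$kB)  # K
  3 / 2 + log(sqrt(pi) / symmetry_number) + 0.5 * log(T^3 / prod(theta))
}

#' Molar entropy from a partitioned DoS (Eq.-21-style sum)
#'
#' The solid-like part is integrated against the quantum harmonic-oscillator
#' entropy weight; the gas-like degrees of freedom carry the Enskog
#' hard-sphere entropy (translational kind; Carnahan-Starling excess at the
#' packing fraction `y = f^(5/2) Delta^(-3/2)`) or the rigid-rotor entropy
#' (rotational kind; rotational temperatures from the water model's
#' principal moments with symmetry number `sigma`).
#'
#' @param solid,gas `ct_dos` halves from [partition_dos()].
#' @param f fluidicity (with its `delta` attribute, as returned by
#'   [solve_fluidicity()]).
#' @param T temperature (K).
#' @param mass molecular mass (amu).
#' @param n_density number density (molecules/nm^3).
#' @param principal_moments length-3 moments (amu nm^2); required for
#'   rotational input.
#' @param symmetry_number rotational symmetry number (2 for C2v water).
#' @return list with `S_HO`, `S_gas`, `S` (J mol^-1 K^-1 per molecule),
#'   `gas_dof` and `kind`.
#' @export
entropy_2pt <- function(solid, gas, f, T, mass, n_density,
                        principal_moments = NULL, symmetry_number = 2) {
  .assert(is.finite(T) && T > 0, "temperature must be positive")
  kind <- solid$kind
  N <- solid$n_molecules
  nu <- solid$frequencies
  S_HO <- .ct$R * trapz(nu, solid$intensity * .w_ho_entropy(nu, T)) / N
  gdof <- gas$analytic_dof %||% trapz(gas$frequencies, gas$intensity)
  if (f <= 0 || gdof <= 0) {
    S_gas <- 0
  } else if (kind == "translational") {
    y <- attr(f, "y") %||% 0
    S_gas <- .ct$R * gdof * .s_hs(T, mass, n_density, as.numeric(f), y) / (3 * N)
  } else {
    if (is.null(principal_moments))
      stop("principal moments required for rotational entropy", call. = FALSE)
    S_gas <- .ct$R * gdof * .s_rr(T, principal_moments, symmetry_number) / (3 * N)
  }
  # components are entropies and cannot be negative; tiny negative values
  # can arise from signed solid remainders or a near-degenerate gas branch
  # (packing fraction -> 1 when f -> 0) and are floored at zero
  S_HO <- max(S_HO, 0); S_gas <- max(S_gas, 0)
  list(kind = kind, S_HO = S_HO, S_gas = S_gas, S = S_HO + S_gas,
       f = as.numeric(f), gas_dof = gdof)
}

#' Full 2PT entropy pipeline
#'
#' Composes [compute_vacf()], [compute_dos()], [solve_fluidicity()],
#' [partition_dos()] and [entropy_2pt()] for the translational and (when
#' angular velocities are present) rotational motion of a velocity series,
#' and reports the molar entropy breakdown per molecule.  Deterministic
#' given its input.  When `series` is a list of replicate series, each is
#' processed and the mean and standard deviation across replicates are
#' reported.
#'
#' @param series a [velocity_series()] or list of replicates.
#' @param T temperature (K); defaults to the series metadata.
#' @param n_density molecules/nm^3; defaults to the series metadata.
#' @param max_lag VACF length (ps), default half the duration.
#' @param symmetry_number rotational symmetry number (water: 2).
#' @return A `ct_entropy` with `S_tr`, `S_rot`, `S_tot` and components
#'   `S_tr_HO`, `S_tr_HS`, `S_rot_HO`, `S_rot_RR` (J mol^-1 K^-1 per
#'   molecule), fluidicities and diagnostics; for replicate input, the
#'   per-replicate objects plus `mean`/`sd` summaries.
#' @export
entropy_pipeline <- function(series, T = NULL, n_density = NULL,
                             max_lag = NULL, symmetry_number = 2) {
  if (is.list(series) && !inherits(series, "ct_velocity_series")) {
    reps <- lapply(series, entropy_pipeline, T = T, n_density = n_density,
                   max_lag = max_lag, symmetry_number = symmetry_number)
    pick <- function(fld) vapply(reps, function(r) r[[fld]], 0)
    flds <- c("S_tr", "S_rot", "S_tot")
    return(structure(list(replicates = reps,
                          mean = vapply(flds, function(f) mean(pick(f)), 0),
                          sd = vapply(flds, function(f) sd(pick(f)), 0)),
                     class = "ct_entropy_replicates"))
  }
  T <- T %||% series$temperature
  .assert(is.finite(T) && T > 0, "temperature must be supplied and positive")
  n_density <- n_density %||% series$n_density
  mass <- series$masses[1]
  .duplicate_frame_check(series)
  run_kind <- function(kind) {
    cg <- compute_vacf(series, kind, max_lag)
    dos <- compute_dos(cg, T)
    f <- solve_fluidicity(dos, n_density, mass, T)
    parts <- partition_dos(dos, f)
    ent <- entropy_2pt(parts$solid, parts$gas, f, T, mass, n_density,
                       principal_moments = series$principal_moments,
                       symmetry_number = symmetry_number)
    list(ent = ent, dos = dos, f = f,
         clipped = parts$solid$clipped_weight)
  }
  tr <- run_kind("translational")
  rot <- if (!is.null(series$angular_velocities)) run_kind("rotational")
  res <- list(
    S_tr = tr$ent$S, S_tr_HO = tr$ent$S_HO, S_tr_HS = tr$ent$S_gas,
    S_rot = if (is.null(rot)) 0 else rot$ent$S,
    S_rot_HO = if (is.null(rot)) 0 else rot$ent$S_HO,
    S_rot_RR = if (is.null(rot)) 0 else rot$ent$S_gas,
    f_tr = tr$ent$f, f_rot = if (is.null(rot)) NA_real_ else rot$ent$f,
    temperature = T,
    diagnostics = list(
      s0_tr = tr$dos$s0, delta_tr = attr(tr$f, "delta"),
      norm_tr = tr$dos$normalization / tr$dos$target,
      clipped_tr = tr$clipped,
      s0_rot = if (is.null(rot)) NA_real_ else rot$dos$s0,
      delta_rot = if (is.null(rot)) NA_real_ else attr(rot$f, "delta"),
      norm_rot = if (is.null(rot)) NA_real_ else rot$dos$normalization / rot$dos$target,
      clipped_rot = if (is.null(rot)) NA_real_ else rot$clipped,
      negative_weight_tr = tr$dos$negative_weight,
      window = "bartlett", zero_pad = 2L))
  res$S_tot <- res$S_tr + res$S_rot
  structure(res, class = "ct_entropy")
}

#' @export
print.ct_entropy <- function(x, ...) {
  cat("<ct_entropy> per-molecule molar entropies (J mol^-1 K^-1)\n",
      sprintf("  S_tot %8.3f = S_tr %8.3f (HO %.3f + HS %.3f, f = %.3f)\n",
              x$S_tot, x$S_tr, x$S_tr_HO, x$S_tr_HS, x$f_tr),
      sprintf("              + S_rot %7.3f (HO %.3f + RR %.3f, f = %s)\n",
              x$S_rot, x$S_rot_HO, x$S_rot_RR,
              ifelse(is.na(x$f_rot), "-", sprintf("%.3f", x$f_rot))), sep = "")
  invisible(x)
}

# Artificially duplicated frames (e.g. dt halved by repeating every frame)
# make the VACF inconsistent with the declared stride; refuse them.  A
# series in which *every* frame repeats is genuine free flight (ideal gas)
# and is allowed; the duplication signature is a mix of repeated and
# changing consecutive frames.
.duplicate_frame_check <- function(series) {
  v <- series$com_velocities
  nF <- dim(v)[1]
  n_check <- min(nF - 1L, 50L)
  dup <- 0L
  for (f in seq_len(n_check))
    if (max(abs(v[f + 1L, , ] - v[f, , ])) == 0) dup <- dup + 1L
  if (dup >= 0.4 * n_check && dup < n_check)
    stop("consecutive frames are duplicated: trajectory stride is ",
         "inconsistent with its sampling interval; refusing to proceed",
         call. = FALSE)
  invisible(TRUE)
}
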