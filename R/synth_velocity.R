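# Velocity-series generators with analytic ground truth: thermal harmonic
# ensembles (solid-like limit of 2PT) and ideal gases (gas-like limit).

#' Quantum harmonic-oscillator entropy per degree of freedom
#'
#' `S/kB = x/(e^x - 1) - ln(1 - e^-x)` with `x = h nu / kB T`; this is the
#' weight the 2PT method integrates against the solid-like DoS.
#'
#' @param nu frequency (THz), positive.
#' @param T temperature (K).
#' @return entropy in units of kB (multiply by R for J mol^-1 K^-1).
#' @export
#' @examples
#' ho_entropy(ct_constants()$kB * 300 / ct_constants()$h, 300)  # x = 1: 1.0407
ho_entropy <- function(nu, T) {
  .assert(all(nu > 0), "HO entropy diverges as nu -> 0; nu must be positive")
  .w_ho_entropy(nu, T)
}

#' Sackur-Tetrode translational entropy
#'
#' Absolute molar entropy of a monatomic ideal gas,
#' `S/R = 5/2 + ln(1/(rho Lambda^3))`.
#'
#' @param mass particle mass (amu).
#' @param T temperature (K).
#' @param n_density number density (particles/nm^3).
#' @return molar entropy (J mol^-1 K^-1).
#' @export
sackur_tetrode <- function(mass, T, n_density) {
  lam <- .ct$h / sqrt(2 * pi * mass * .ct$kB * T)  # nm
  .ct$R * (5 / 2 + log(1 / (n_density * lam^3)))
}

#' Generate a thermal ensemble of harmonic oscillators
#'
#' Each molecule/component degree of freedom is a classical harmonic
#' oscillator: `v(t) = sqrt(2 E / m) cos(2 pi nu t + phi)` with a uniform
#' random phase.  Frequencies from `frequencies` are assigned cyclically
#' across degrees of freedom.  With `amplitudes = "fixed"` (default) every
#' dof carries exactly the canonical mean time-averaged energy
#' `E = kB T`, so the attached ground truth -- the exact quantum HO
#' entropy per dof at `T`, which the 2PT pipeline must recover in its
#' `f = 0` limit -- is exact rather than realized; `"thermal"` draws
#' `E ~ Exp(kB T)` per dof (Boltzmann ensemble), adding O(1/sqrt(dof))
#' sampling scatter to the recovered entropy.
#'
#' @param frequencies oscillator frequencies (THz), all positive (the HO
#'   entropy diverges at `nu = 0`, so zero frequencies are refused).
#' @param T temperature (K).
#' @param n_molecules number of molecules (3 dof each).
#' @param duration trajectory length (ps).
#' @param dt sampling interval (ps); must satisfy Nyquist,
#'   `dt < 1/(2 max(frequencies))`.
#' @param seed RNG seed.
#' @param mass molecular mass (amu).
#' @param n_density nominal number density metadata (molecules/nm^3).
#' @param amplitudes `"fixed"` (canonical-mean energies, exact ground
#'   truth) or `"thermal"` (Boltzmann-drawn energies).
#' @return A [velocity_series()] with attribute `ground_truth`: list with
#'   `entropy_per_dof_kB` and molar `S_tr` (J mol^-1 K^-1).
#' @export
gen_harmonic_ensemble <- function(frequencies, T = 300, n_molecules = 100,
                                  duration = 20, dt = 0.004, seed = 1,
                                  mass = 18.0154, n_density = 33.33,
                                  amplitudes = c("fixed", "thermal")) {
  amplitudes <- match.arg(amplitudes)
  .assert(all(is.finite(frequencies)) && all(frequencies > 0),
          "frequencies must be positive (nu = 0 has divergent HO entropy)")
  .assert(dt < 1 / (2 * max(frequencies)),
          paste0("Nyquist violation: dt must be < ",
                 signif(1 / (2 * max(frequencies)), 4), " ps"))
  set.seed(seed)
  nF <- floor(duration / dt) + 1L
  tt <- (0:(nF - 1L)) * dt
  ndof <- n_molecules * 3L
  nu <- rep_len(frequencies, ndof)
  E <- if (amplitudes == "thermal") rexp(ndof, rate = 1 / (.ct$kB * T))
       else rep(.ct$kB * T, ndof)
  A <- sqrt(2 * E / mass)
  phi <- runif(ndof, 0, 2 * pi)
  v <- matrix(0, nF, ndof)
  for (d in seq_len(ndof)) v[, d] <- A[d] * cos(2 * pi * nu[d] * tt + phi[d])
  comv <- array(v, c(nF, n_molecules, 3))
  gt <- list(entropy_per_dof_kB = mean(.w_ho_entropy(nu, T)),
             S_tr = 3 * .ct$R * mean(.w_ho_entropy(nu, T)),
             frequencies = nu)
  structure(velocity_series(dt, comv, NULL, rep(mass, n_molecules),
                            n_density = n_density, temperature = T),
            ground_truth = gt)
}

#' Generate an ideal-gas (free-flight) velocity series
#'
#' Maxwell-Boltzmann velocities held constant over the whole trajectory
#' (free flight): the VACF never decays and the DoS concentrates at zero
#' frequency, the pure gas-like limit of 2PT.  Ground truth is the
#' Sackur-Tetrode entropy at `(mass, T, density)`.
#'
#' @param mass particle mass (amu).
#' @param T temperature (K).
#' @param density number density (molecules/nm^3), positive.
#' @param n number of molecules.
#' @param duration trajectory length (ps).
#' @param dt sampling interval (ps).
#' @param seed RNG seed.
#' @return A [velocity_series()] with attribute `ground_truth` containing
#'   `S_tr` (Sackur-Tetrode, J mol^-1 K^-1).
#' @export
gen_ideal_gas <- function(mass = 18.0154, T = 300, density = 0.01, n = 100,
                          duration = 500, dt = 0.5, seed = 1) {
  .assert(is.finite(density) && density > 0, "density must be positive")
  set.seed(seed)
  nF <- floor(duration / dt) + 1L
  v0 <- matrix(rnorm(n * 3L, sd = sqrt(.ct$kB * T / mass)), n, 3L)
  comv <- array(0, c(nF, n, 3L))
  for (f in seq_len(nF)) comv[f, , ] <- v0
  structure(velocity_series(dt, comv, NULL, rep(mass, n),
                            n_density = density, temperature = T),
            ground_truth = list(S_tr = sackur_tetrode(mass, T, density)))
}
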