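# The 2PT entropy engine against brute-force and closed-form oracles.

test_that("VACF matches the O(N^2 x lags) brute-force double loop", {
  set.seed(21)
  nF <- 100; nM <- 10
  v <- array(rnorm(nF * nM * 3), c(nF, nM, 3))
  m <- runif(nM, 10, 20)
  vs <- velocity_series(0.004, v, NULL, m)
  cg <- compute_vacf(vs, "translational", max_lag = 0.004 * 49)
  expect_equal(cg$values, brute_vacf(v, m, 0:49), tolerance = 1e-10)

  # rotational weighting by the principal moments
  I3 <- c(0.006, 0.018, 0.012)
  vs2 <- velocity_series(0.004, v, v * 2, m, principal_moments = I3)
  cg2 <- compute_vacf(vs2, "rotational", max_lag = 0.004 * 20)
  brute <- numeric(21)
  for (lag in 0:20) {
    acc <- 0
    for (mm in 1:nM) for (k in 1:3) {
      s <- 0
      for (tau in 1:(nF - lag)) s <- s + 4 * v[tau, mm, k] * v[tau + lag, mm, k]
      acc <- acc + I3[k] * s / (nF - lag)
    }
    brute[lag + 1] <- acc
  }
  expect_equal(cg2$values, brute, tolerance = 1e-10)

  expect_error(compute_vacf(vs, "rotational"), "angular")
  expect_error(compute_vacf(vs, max_lag = 1), "duration/2")

  # constant velocities: flat correlogram equal to sum m |v|^2
  vc <- array(rep(rnorm(nM * 3), each = nF), c(nF, nM, 3))
  cgc <- compute_vacf(velocity_series(0.004, vc, NULL, m), max_lag = 0.004 * 30)
  expect_lt(diff(range(cgc$values)), 1e-12)
  expect_equal(cgc$values[1], sum(m * apply(vc[1, , ]^2, 1, sum)),
               tolerance = 1e-12)
})

test_that("DoS transform matches a naive DFT oracle and known transform pairs", {
  set.seed(22)
  cvals <- rnorm(64)
  cg <- structure(list(lags = (0:63) * 0.01, values = cvals, kind = "translational",
                       dt = 0.01, n_molecules = 5), class = "ct_correlogram")
  for (w in c("bartlett", "none")) {
    d <- compute_dos(cg, 300, window = w)
    o <- naive_dos(cvals, 0.01, 300, window = w)
    expect_equal(d$intensity, o$intensity, tolerance = 1e-9)
    expect_equal(d$frequencies, o$frequencies)
  }
  expect_error(compute_dos(cg, -1), "positive")

  # cosine VACF at nu0 -> single peak at nu0, integral = total dof
  nu0 <- 12
  hs <- gen_harmonic_ensemble(nu0, T = 300, n_molecules = 60, duration = 20,
                              dt = 0.004, seed = 5)
  d2 <- compute_dos(compute_vacf(hs), 300)
  expect_equal(d2$frequencies[which.max(d2$intensity)], nu0, tolerance = 0.2)
  expect_equal(d2$normalization / d2$target, 1, tolerance = 0.02)
  # off-peak intensity is negligible
  off <- abs(d2$frequencies - nu0) > 2
  expect_lt(trapz(d2$frequencies[off], abs(d2$intensity[off])) / d2$target, 0.02)
})

test_that("fluidicity solver agrees with a grid-scan oracle and behaves in its limits", {
  mk_dos <- function(s0) structure(list(s0 = s0, n_molecules = 100),
                                   class = "ct_dos")
  # s0 = 0 -> f = 0 (pure solid)
  expect_identical(as.numeric(solve_fluidicity(mk_dos(0), 33.3, 18, 300)), 0)

  # delta = 1: root cross-checked by an independent scan over 1e6 f values
  poly <- function(f, delta) {
    y <- f^2.5 * delta^-1.5
    2 * y^3 - 6 * y^2 + (6 - f) * y + 2 * f - 2
  }
  delta_target <- 1
  # invert: choose s0 so that delta comes out at the target
  s0 <- delta_target / (2 / (9 * 100) * sqrt(pi * kB * 300 / 18) *
                          33.3^(1 / 3) * (6 / pi)^(2 / 3))
  f <- solve_fluidicity(mk_dos(s0), 33.3, 18, 300)
  expect_equal(attr(f, "delta"), 1, tolerance = 1e-12)
  grid <- seq(0, 1, length.out = 1e6 + 1)
  gv <- poly(grid, 1)
  iroot <- which(diff(sign(gv)) != 0)[1]
  expect_equal(as.numeric(f), grid[iroot], tolerance = 2e-6)
  expect_lt(abs(poly(as.numeric(f), 1)), 1e-10)

  # monotonically nondecreasing in delta over [1e-4, 10]
  deltas <- 10^seq(-4, 1, length.out = 40)
  fs <- vapply(deltas, function(d) {
    s0d <- d / (2 / (9 * 100) * sqrt(pi * kB * 300 / 18) * 33.3^(1 / 3) * (6 / pi)^(2 / 3))
    as.numeric(solve_fluidicity(mk_dos(s0d), 33.3, 18, 300))
  }, 0)
  expect_true(all(diff(fs) >= -1e-12))
  expect_true(all(fs >= 0 & fs <= 1))
})

test_that("solid/gas partition conserves the spectrum and its gas quota", {
  # liquid-like DoS from an exponentially decaying VACF
  tau <- 0.15; N <- 100
  lags <- seq(0, 10, by = 0.004)
  cg <- structure(list(lags = lags, values = 3 * N * kB * 300 * exp(-lags / tau),
                       kind = "translational", dt = 0.004, n_molecules = N),
                  class = "ct_correlogram")
  dos <- compute_dos(cg, 300)
  f <- solve_fluidicity(dos, 33.3, 18.0154, 300)
  expect_gt(as.numeric(f), 0.05); expect_lt(as.numeric(f), 1)
  parts <- partition_dos(dos, f)
  # solid + gas reproduce the original exactly
  expect_equal(parts$solid$intensity + parts$gas$intensity, dos$intensity,
               tolerance = 1e-9)
  expect_equal(parts$gas$intensity[1], dos$s0, tolerance = 1e-12)
  # gas integral = 3 N f within quadrature tolerance
  expect_equal(parts$gas$normalization, 3 * N * as.numeric(f), tolerance = 0.02 * 3 * N)
  expect_equal(parts$gas$analytic_dof, 3 * N * as.numeric(f), tolerance = 0.01 * 3 * N)

  # f = 0: gas identically zero, solid = input
  p0 <- partition_dos(dos, structure(0, delta = 0, y = 0))
  expect_true(all(p0$gas$intensity == 0))
  expect_equal(p0$solid$intensity, dos$intensity)

  # ideal-gas DoS with f ~ 1: essentially all weight is gas-like.  The
  # diffusive peak and the window kernel are both ~1 frequency bin wide,
  # so the comparison is made through the closed-form gas integral and
  # the solid weight away from the unresolved nu ~ 0 bin.
  ig <- gen_ideal_gas(density = 0.01, n = 50, duration = 500, dt = 0.5, seed = 2)
  dg <- compute_dos(compute_vacf(ig), 300)
  fg <- solve_fluidicity(dg, 0.01, 18.0154, 300)
  pg <- suppressWarnings(partition_dos(dg, fg))
  expect_gt(as.numeric(fg), 0.95)
  expect_gt(pg$gas$analytic_dof / dg$target, 0.95)
  away <- dg$frequencies > 0.02 * max(dg$frequencies)
  expect_lt(trapz(dg$frequencies[away], abs(pg$solid$intensity[away])) /
              dg$target, 0.02)
})

test_that("2PT entropy reproduces closed forms in the solid and gas limits", {
  # pure HO spike at h nu / kB T = 1 with f = 0: S per dof = 1.0407 R
  N <- 50; T <- 300
  nu1 <- kB * T / hpl
  freq <- seq(0, 40, by = 0.005)
  I <- numeric(length(freq))
  ipk <- which.min(abs(freq - nu1))
  I[ipk] <- 3 * N / 0.005          # unit-area spike carrying 3N dof
  dos <- structure(list(frequencies = freq, intensity = I, kind = "translational",
                        n_molecules = N, s0 = 0, normalization = 3 * N,
                        target = 3 * N), class = "ct_dos")
  parts <- partition_dos(dos, structure(0, delta = 0, y = 0))
  ent <- entropy_2pt(parts$solid, parts$gas, structure(0, delta = 0, y = 0),
                     T, 18.0154, 33.3)
  expect_equal(ent$S / (3 * Rgas), 1.0407,
               tolerance = 2e-3)

  # dilute ideal gas: S_tr within 2% of Sackur-Tetrode
  ig <- gen_ideal_gas(density = 0.01, n = 200, duration = 500, dt = 0.5, seed = 3)
  e <- suppressWarnings(entropy_pipeline(ig, T = 300))
  expect_equal(e$S_tr, attr(ig, "ground_truth")$S_tr,
               tolerance = 0.02 * attr(ig, "ground_truth")$S_tr)
  # rotational part absent for point particles
  expect_identical(e$S_rot, 0)
})

test_that("entropy pipeline recovers harmonic ground truth, guards input, reports replicates", {
  hs <- gen_harmonic_ensemble(c(10, 20, 30), T = 300, n_molecules = 100,
                              duration = 20, dt = 0.004, seed = 2)
  gt <- attr(hs, "ground_truth")
  e <- entropy_pipeline(hs, T = 300)
  expect_equal(e$S_tr, gt$S_tr, tolerance = 0.01 * gt$S_tr)
  expect_identical(e$S_tot, e$S_tr + e$S_rot)
  expect_lt(e$f_tr, 0.01)

  # duplicated frames (dt halved artificially) are refused
  v <- hs$com_velocities
  vdup <- v[rep(seq_len(dim(v)[1] %/% 2), each = 2), , ]
  sdup <- velocity_series(hs$dt / 2, vdup, NULL, hs$masses,
                          n_density = 33.3, temperature = 300)
  expect_error(entropy_pipeline(sdup, T = 300), "duplicated")

  # replicate trajectories: SD over replicates is reported
  reps <- lapply(1:3, function(s)
    gen_harmonic_ensemble(c(10, 20, 30), T = 300, n_molecules = 50,
                          duration = 10, dt = 0.004, seed = s,
                          amplitudes = "thermal"))
  er <- entropy_pipeline(reps, T = 300)
  expect_s3_class(er, "ct_entropy_replicates")
  expect_length(er$replicates, 3L)
  expect_true(all(er$sd >= 0) && er$sd[["S_tr"]] > 0)
})

test_that("2PT entropy is intensive and monotone in diffusive weight", {
  # intensivity: doubling the molecule count changes per-molecule S by < 1 SE
  e50 <- vapply(1:3, function(s)
    entropy_pipeline(gen_harmonic_ensemble(c(8, 16), n_molecules = 50,
                                           duration = 10, seed = s,
                                           amplitudes = "thermal"),
                     T = 300)$S_tr, 0)
  e100 <- entropy_pipeline(gen_harmonic_ensemble(c(8, 16), n_molecules = 100,
                                                 duration = 10, seed = 11,
                                                 amplitudes = "thermal"),
                           T = 300)$S_tr
  se <- sd(e50) / sqrt(3)
  expect_lt(abs(mean(e50) - e100), max(3 * se, 0.05 * mean(e50)))

  # adding diffusive (nu = 0) weight never decreases S_tr: slower VACF
  # decay means larger s0
  S_of_tau <- vapply(c(0.02, 0.05, 0.1, 0.3, 0.8), function(tau) {
    N <- 100
    lags <- seq(0, 10, by = 0.004)
    cg <- structure(list(lags = lags,
                         values = 3 * N * kB * 300 * exp(-lags / tau),
                         kind = "translational", dt = 0.004, n_molecules = N),
                    class = "ct_correlogram")
    dos <- compute_dos(cg, 300)
    f <- solve_fluidicity(dos, 33.3, 18.0154, 300)
    p <- partition_dos(dos, f)
    entropy_2pt(p$solid, p$gas, f, 300, 18.0154, 33.3)$S
  }, 0)
  expect_true(all(diff(S_of_tau) > 0))
})
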