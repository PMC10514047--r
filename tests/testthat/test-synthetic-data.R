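# Generators and their analytic ground truth.

test_that("harmonic ensemble: ground truth, Nyquist guard, equipartition", {
  # single frequency with h nu / kB T = 1: HO entropy per dof = 1.0407 kB
  nu1 <- kB * 300 / hpl
  hs <- gen_harmonic_ensemble(nu1, T = 300, n_molecules = 20, duration = 5,
                              dt = 0.004, seed = 1)
  gt <- attr(hs, "ground_truth")
  expect_equal(gt$entropy_per_dof_kB, 1.0407, tolerance = 1e-4)

  # nu = 0 is refused (HO entropy diverges), as are Nyquist violations
  expect_error(gen_harmonic_ensemble(0, dt = 0.004), "positive")
  expect_error(gen_harmonic_ensemble(200, dt = 0.004), "Nyquist")

  # equipartition: mean kinetic energy per dof ~ kB T / 2 within 3 SE
  # (thermal amplitudes, >= 1e4 samples)
  ht <- gen_harmonic_ensemble(c(5, 9), T = 300, n_molecules = 40,
                              duration = 4, dt = 0.004, seed = 7,
                              amplitudes = "thermal")
  ke <- 0.5 * 18.0154 * ht$com_velocities^2
  se <- sd(ke) / sqrt(length(ke) / 500)   # correlated in time; be generous
  expect_lt(abs(mean(ke) - 0.5 * kB * 300), 3 * se)
})

test_that("ideal gas: flat VACF, DoS at zero frequency, Sackur-Tetrode truth", {
  ig <- gen_ideal_gas(mass = 18.0154, T = 300, density = 0.02, n = 50,
                      duration = 100, dt = 0.5, seed = 2)
  cg <- compute_vacf(ig, "translational")
  expect_lt(diff(range(cg$values)) / cg$values[1], 1e-12)  # no decay
  d <- compute_dos(cg, 300)
  # all spectral weight concentrates in the nu -> 0 bins
  low <- d$frequencies <= 3 * d$frequencies[2]
  expect_gt(trapz(d$frequencies[low], d$intensity[low]) / d$target, 0.5)
  # s0 equals the analytic transform of the (tapered) flat VACF:
  # 4/(kB T) * C(0) * integral of the taper = 2 C(0) T_max / (kB T)
  expect_equal(d$s0, 2 * cg$values[1] * 50 / (kB * 300), tolerance = 0.01)

  # Sackur-Tetrode ground truth at liquid-water density is attached, positive
  igl <- gen_ideal_gas(density = 33.33, n = 10, duration = 10, dt = 0.5, seed = 1)
  st <- attr(igl, "ground_truth")$S_tr
  expect_gt(st, 0)
  expect_equal(st, Rgas * (5 / 2 + log(1 / (33.33 * (hpl / sqrt(2 * pi * 18.0154 * kB * 300))^3))),
               tolerance = 1e-12)
  expect_error(gen_ideal_gas(density = -1), "positive")
})

test_that("Langevin fluid: thermostat accuracy, determinism, disordered q", {
  lf <- gen_langevin_fluid(n_waters = 150, box = 1.8, T = 300, seed = 9,
                           duration = 5, equil_ps = 2)
  # kinetic thermometer within 5% of target over >= 5 ps
  m <- lf$topology$water$mass
  Tk <- vapply(lf$frames, function(f) sum(m * f$velocities^2) / (3 * 150 * kB), 0)
  expect_lt(abs(mean(Tk) - 300) / 300, 0.05)

  # bit-exact reproducibility under a fixed seed
  lf2 <- gen_langevin_fluid(n_waters = 150, box = 1.8, T = 300, seed = 9,
                            duration = 5, equil_ps = 2)
  expect_identical(lf$frames[[5]]$positions, lf2$frames[[5]]$positions)

  # q distribution of the disordered fluid is broad and peaked below 0.8
  q <- unlist(lapply(lf$frames[seq(1, length(lf$frames), by = 20)],
                     tetrahedral_q, top = lf$topology))
  qd <- q_distribution(q)
  expect_lt(qd$mean_q, 0.7)
  mode_q <- qd$breaks[which.max(qd$counts)]
  expect_lt(mode_q, 0.8)
  expect_gt(sd(q, na.rm = TRUE), 0.1)
})

test_that("toy condensate: box edges, scaling laws and concentration inversion", {
  tc <- gen_toy_condensate(c(175, 350), n_chains = 8, chain_mass = 17.2,
                           seed = 3, water_scale = 0.01)
  # 350 mg/mL with 8 x 17.2 kDa chains: ~8.67 nm cubic box
  expect_equal(tc[["350"]]$box_edge, 8.67, tolerance = 0.01)
  # doubling rho at fixed chain count halves the volume
  expect_equal(tc[["175"]]$box_edge^3 / tc[["350"]]$box_edge^3, 2,
               tolerance = 1e-9)
  # concentration recomputed from the emitted box matches to 0.1%
  for (s in tc)
    expect_equal(box_concentration(s$box_edge, 8, 17.2), s$rho,
                 tolerance = 1e-3)
  # water counts fall with concentration
  expect_gt(tc[["175"]]$n_waters, tc[["350"]]$n_waters)
})

test_that("concentration tables: planted lines, crossover recovery, bulk anchors", {
  ser <- gen_concentration_tables(noise_sd = 0, seed = 4)
  gt <- attr(ser, "ground_truth")
  # noiseless values sit exactly on the planted lines
  sys <- ser[!ser$is_bulk, ]
  expect_equal(sys$S_tr, gt$fun$S_tr(sys$rho), tolerance = 1e-12)
  expect_equal(sys$E_WW, gt$fun$E_WW(sys$rho), tolerance = 1e-12)
  # planted bulk S(rho -> 0) equals the requested bulk value
  expect_equal(ser$S_tot[ser$is_bulk][1], 43.8 + 10.9, tolerance = 1e-12)
  # the series satisfies every container invariant (constructor validates)
  expect_s3_class(concentration_series(as.data.frame(ser)), "ct_series")
  # fit_crossover on the noiseless table recovers the breakpoint exactly
  sm <- series_means(ser); sysm <- sm[!sm$is_bulk, ]
  cf <- fit_crossover(sysm$rho, sysm$S_tot)
  expect_equal(cf$breakpoint, 150, tolerance = 0.5)
})

test_that("torsion samples: closed-form entropies and exact MI bookkeeping", {
  ts <- gen_torsion_samples(list(list(dist = "uniform"),
                                 list(dist = "von_mises", mu = 1, kappa = 2)),
                            n_samples = 500, seed = 6)
  gt <- attr(ts, "ground_truth")
  expect_equal(gt$marginal_entropies[1], log(2 * pi))
  # von Mises closed form against a direct quadrature oracle
  kap <- 2
  dens <- function(x) exp(kap * cos(x)) / (2 * pi * besselI(kap, 0))
  Hnum <- -integrate(function(x) dens(x) * log(dens(x)), -pi, pi)$value
  expect_equal(von_mises_entropy(kap), Hnum, tolerance = 1e-8)
  expect_equal(gt$marginal_entropies[2], Hnum, tolerance = 1e-8)
  expect_true(all(ts$samples > -pi & ts$samples <= pi))

  # coupled pair: joint entropy and MI closed forms attached
  tc <- gen_torsion_samples(list(list(dist = "uniform"), list(dist = "uniform")),
                            n_samples = 500, seed = 7,
                            coupling = list(list(from = 1, to = 2, kappa = 3)))
  cp <- attr(tc, "ground_truth")$couplings[[1]]
  expect_equal(cp$H_joint, log(2 * pi) + von_mises_entropy(3))
  expect_equal(cp$mutual_information, log(2 * pi) - von_mises_entropy(3))

  # determinism under fixed seed
  ts2 <- gen_torsion_samples(list(list(dist = "uniform")), n_samples = 100, seed = 8)
  ts3 <- gen_torsion_samples(list(list(dist = "uniform")), n_samples = 100, seed = 8)
  expect_identical(ts2$samples, ts3$samples)
})
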