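# Structural water metrics.

test_that("tetrahedral order parameter hits its closed-form anchor points", {
  # perfect tetrahedral arrangement: q = 1 exactly
  fr <- perfect_tetrahedron_frame()
  q <- tetrahedral_q(fr, oxygens = 1:5)
  expect_equal(q[1], 1, tolerance = 1e-12)

  # square-planar neighbors (four 90 deg + two 180 deg angles): q = 0.5
  sq <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)) * 0.28
  fsq <- frame(rbind(c(0, 0, 0), sq) + 5, rep(10, 3))
  expect_equal(tetrahedral_q(fsq, oxygens = 1:5)[1], 0.5, tolerance = 1e-12)

  # uniformly random neighbor directions: mean q ~ 0 within 3 SE
  set.seed(31)
  nrep <- 4000
  qs <- vapply(seq_len(nrep), function(i) {
    u <- matrix(rnorm(12), 4, 3)
    u <- u / sqrt(rowSums(u^2)) * 0.28
    tetrahedral_q(frame(rbind(c(0, 0, 0), u) + 5, rep(10, 3)), oxygens = 1:5)[1]
  }, 0)
  expect_lt(abs(mean(qs)), 3 * sd(qs) / sqrt(nrep))

  # invariance under global rotation and translation
  th <- 0.77
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
  fl <- ice_lattice_frame(ncell = 2, seed = 2)
  big <- rep(50, 3)
  centered <- sweep(fl$positions, 2, colMeans(fl$positions))
  f1 <- frame(sweep(centered, 2, big / 2, "+"), big)
  f2 <- frame(sweep(centered %*% t(Rz), 2, big / 2 + 0.37, "+"), big)
  q1 <- tetrahedral_q(f1, oxygens = seq_len(nrow(centered)))
  q2 <- tetrahedral_q(f2, oxygens = seq_len(nrow(centered)))
  expect_equal(q1, q2, tolerance = 1e-12)

  expect_error(tetrahedral_q(frame(matrix(1, 3, 3), rep(5, 3)), oxygens = 1:3),
               "at least 5")
})

test_that("q distributions order fluids by structure and count every sample", {
  qi <- tetrahedral_q(ice_lattice_frame(ncell = 2, seed = 3), oxygens = 1:64)
  lf <- gen_langevin_fluid(n_waters = 120, box = 1.7, T = 300, seed = 4,
                          duration = 3, equil_ps = 1.5)
  qf <- unlist(lapply(lf$frames[c(10, 30, 50)], tetrahedral_q, top = lf$topology))
  di <- q_distribution(qi); df_ <- q_distribution(qf)
  expect_gt(di$mean_q, df_$mean_q)       # jittered ice is more tetrahedral
  expect_equal(sum(df_$counts), df_$n_samples)
  expect_error(q_distribution(NA_real_), "no finite")
  # all q = 1 -> a single occupied bin
  d1 <- q_distribution(rep(1, 10))
  expect_equal(sum(d1$counts > 0), 1L)
})

test_that("hydrogen bonds follow the geometric criterion and a brute-force oracle", {
  wm3 <- water_model3()
  place <- function(origins) {
    pos <- do.call(rbind, lapply(origins, function(o) sweep(wm3$sites, 2, o, "+")))
    frame(pos, rep(6, 3))
  }
  top2 <- topology(n_waters = 2, water = wm3)
  p1 <- sweep(wm3$sites, 2, c(1, 1, 1), "+")
  ohdir <- (p1[2, ] - p1[1, ]) / sqrt(sum((p1[2, ] - p1[1, ])^2))
  # ideal geometry: O...O 0.28 nm along the O-H bond -> 1 bond
  fr <- frame(rbind(p1, sweep(wm3$sites, 2, p1[1, ] + 0.28 * ohdir, "+")), rep(6, 3))
  expect_equal(count_hbonds(fr, top2)$n_bonds, 1L)
  # same pair at O...O 0.50 nm -> no bond
  fr2 <- frame(rbind(p1, sweep(wm3$sites, 2, p1[1, ] + 0.50 * ohdir, "+")), rep(6, 3))
  expect_equal(count_hbonds(fr2, top2)$n_bonds, 0L)

  # 5-water cluster vs exhaustive all-pairs oracle
  set.seed(33)
  tops <- topology(n_waters = 5, water = wm3)
  orig <- matrix(runif(15, 2, 3.0), 5, 3)
  frc <- place(split(orig, row(orig)))
  res <- count_hbonds(frc, tops)
  crit <- hbond_criterion()
  oracle <- 0L
  for (d_ in 1:5) for (a_ in 1:5) {
    if (d_ == a_) next
    od <- frc$positions[(d_ - 1) * 3 + 1, ]; oa <- frc$positions[(a_ - 1) * 3 + 1, ]
    vda <- min_image(oa - od, frc$box)
    if (sqrt(sum(vda^2)) > crit$dist_cutoff) next
    for (h in 2:3) {
      vdh <- frc$positions[(d_ - 1) * 3 + h, ] - od
      ang <- acos(sum(vdh * vda) / sqrt(sum(vdh^2) * sum(vda^2))) * 180 / pi
      if (ang <= crit$angle_cutoff) { oracle <- oracle + 1L; break }
    }
  }
  expect_equal(res$n_bonds, oracle)
  expect_equal(res$per_water, 2 * oracle / 5)

  expect_error(hbond_criterion(angle_cutoff = 120), "90")
  expect_error(hbond_criterion(dist_cutoff = -1), "positive")
})

test_that("hydration-layer counting: membership, normalization, cutoff monotonicity", {
  # one protein bead; waters at 0.25 and 0.40 nm -> exactly one PHL water
  ch <- list(list(id = "c1", atom_names = "CA", masses = 430))
  top <- topology(ch, n_waters = 2, water = water_model("point"))
  pos <- rbind(c(2, 2, 2), c(2.25, 2, 2), c(2.40, 2, 2))
  fr <- frame(pos, rep(5, 3))
  res <- count_phl_waters(fr, top, cutoff = 0.3)
  expect_equal(res$total, 1L)
  # self-normalization gives exactly 1
  expect_equal(count_phl_waters(fr, top, reference = res$mean_per_chain)$normalized, 1)
  expect_error(count_phl_waters(fr, top, reference = 0), "positive")

  # monotone in the cutoff
  tc <- gen_toy_condensate(350, n_chains = 2, chain_mass = 4, seed = 6,
                           water_scale = 0.5)[["350"]]
  counts <- vapply(c(0.2, 0.3, 0.45), function(co)
    count_phl_waters(tc$frame, tc$topology, cutoff = co)$total, 0L)
  expect_true(all(diff(counts) >= 0))

  # normalized PHL population decreases with concentration (crowding)
  series <- gen_toy_condensate(c(50, 150, 350), n_chains = 2, chain_mass = 4,
                               seed = 7, water_scale = 0.5)
  ref <- count_phl_waters(series[[1]]$frame, series[[1]]$topology)$mean_per_chain
  nstar <- vapply(series, function(s)
    count_phl_waters(s$frame, s$topology, reference = ref)$normalized, 0)
  expect_true(all(diff(nstar) < 0))
})

test_that("radius of gyration matches closed forms and unwraps chains", {
  expect_equal(radius_of_gyration(matrix(1, 5, 3), rep(2, 5)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(0.8, 0, 0)), c(3, 3)), 0.4)
  # random 50-bead chain against the definition
  set.seed(34)
  xyz <- matrix(rnorm(150), 50, 3); m <- runif(50, 1, 5)
  com <- colSums(xyz * m) / sum(m)
  rg_def <- sqrt(sum(m * rowSums(sweep(xyz, 2, com)^2)) / sum(m))
  expect_equal(radius_of_gyration(xyz, m), rg_def, tolerance = 1e-12)
  # wrapped chain is restored by minimum-image unwrapping
  box <- rep(2, 3)
  chain <- cbind(seq(0, 3.0, length.out = 16), 0.5, 0.5)  # crosses the box
  wrapped <- chain %% 2
  expect_equal(radius_of_gyration(wrapped, rep(1, 16), box),
               radius_of_gyration(chain, rep(1, 16)), tolerance = 1e-12)
  # a genuinely broken chain cannot be unwrapped
  broken <- rbind(c(0.1, 0.1, 0.1), c(1.05, 1.05, 1.05))
  expect_error(radius_of_gyration(broken, c(1, 1), box), "unwrapped")
})

test_that("crossover fits recover planted breakpoints and flag degenerate data", {
  ser <- gen_concentration_tables(noise_sd = 0, seed = 8, breakpoint = 150)
  sm <- series_means(ser); sys <- sm[!sm$is_bulk, ]
  cf <- fit_crossover(sys$rho, sys$S_rot)
  expect_equal(cf$breakpoint, 150, tolerance = 0.5)
  expect_equal(unname(cf$slope_ratio), 1 / 2.4, tolerance = 1e-3)
  expect_true(cf$reliable)

  # a single straight line: slope ratio ~ 1 and the fit is flagged
  x <- seq(10, 100, by = 10); y <- 2 + 0.3 * x
  cfl <- fit_crossover(x, y)
  expect_false(cfl$reliable)
  expect_equal(unname(cfl$slope_ratio), 1, tolerance = 1e-6)

  # noisy replicate recovery: breakpoint within planted +/- grid spacing
  # for generous SNR
  set.seed(35)
  rho <- seq(25, 525, by = 25)
  strue <- ifelse(rho <= 150, 55 - 0.006 * rho, 55 - 0.006 * 150 - 0.009 * (rho - 150))
  hits <- vapply(1:10, function(i) {
    fit_crossover(rho, strue + rnorm(length(rho), 0, 0.02))$breakpoint
  }, 0)
  expect_lt(max(abs(hits - 150)), 30)

  expect_error(fit_crossover(1:4, 1:4), "at least 5")
})
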