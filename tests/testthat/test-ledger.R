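# Free-energy bookkeeping: budgets, tug-of-war terms, cancellation
# identities, analytic estimators, full ledger assembly.

series_from_table2 <- function() {
  # minimal series built from the reference all-atom system table
  fs <- fus_systems()
  rows <- lapply(seq_len(nrow(fs)), function(i) data.frame(
    rho = fs$rho[i], replicate = 1L, n_chains = fs$n_chains[i],
    n_waters = fs$n_waters[i], S_tot = 50, S_tr = 40, S_rot = 10,
    E_PP = -100, E_PW = -1, E_WW = -45, is_bulk = FALSE))
  rows[[length(rows) + 1L]] <- data.frame(
    rho = 1, replicate = 1L, n_chains = 0L, n_waters = 177382,
    S_tot = 54.7, S_tr = 43.8, S_rot = 10.9, E_PP = 0, E_PW = 0,
    E_WW = -46, is_bulk = TRUE)
  concentration_series(do.call(rbind, rows))
}

test_that("water budget implements released/retained counting", {
  ser <- series_from_table2()
  expect_error(water_budget(ser, 350), "above rho_cond")
  wb <- water_budget(ser, 350, allow_above_cond = TRUE)
  # at rho = rho_cond the release vanishes
  expect_equal(wb$dN_rele[wb$rho == 350], 0)
  # the 350 mg/mL reference row (16509 waters, 8 chains): 2064 retained
  # waters per protein
  expect_equal(round(unique(wb$dN_reta)), 2064)
  # released counts above the condensate concentration would be negative
  expect_lt(wb$dN_rele[wb$rho == 525], 0)

  # plain subtraction on a synthetic series
  df <- data.frame(rho = c(25, 350, 1), replicate = 1,
                   n_chains = c(1, 1, 0), n_waters = c(5000, 2000, 1e5),
                   S_tot = 50, S_tr = 40, S_rot = 10,
                   E_PP = 0, E_PW = 0, E_WW = -45,
                   is_bulk = c(FALSE, FALSE, TRUE))
  wb2 <- water_budget(concentration_series(df), 350)
  expect_equal(wb2$dN_rele[wb2$rho == 25], 3000)
  expect_error(water_budget(concentration_series(df), 200), "not present")
})

test_that("solvation entropy and energy changes match a spreadsheet oracle", {
  ser <- gen_concentration_tables(noise_sd = 0, seed = 12)
  ser <- concentration_series(ser[ser$rho <= 350 | ser$is_bulk, ])
  wb <- water_budget(ser, 350)
  ent <- solvation_entropy_changes(ser, wb, T = 300)
  en <- solvation_energy_changes(ser, wb)
  ora <- oracle_ledger(ser, 350)
  expect_equal(ent$dS_tot, ora$dS_tot, tolerance = 1e-9)
  expect_equal(ent$TdS_solv, ora$TdS_solv, tolerance = 1e-9)
  expect_equal(en$dE_WW, ora$dE_WW, tolerance = 1e-9)
  expect_equal(en$dE_PW, ora$dE_PW, tolerance = 1e-9)
  expect_equal(en$dH_solv, ora$dH_solv, tolerance = 1e-9)

  # flat S(rho): all entropy deltas vanish
  flat <- ser
  for (cl in c("S_tot", "S_tr", "S_rot")) flat[[cl]] <- 54.7 * c(1, 0.8, 0.2)[match(cl, c("S_tot", "S_tr", "S_rot"))]
  flat <- concentration_series(as.data.frame(flat))
  ent0 <- solvation_entropy_changes(flat, water_budget(flat, 350), T = 300)
  expect_lt(max(abs(ent0$dS_rele)), 1e-9)

  # released and retained energy contributions have opposite signs for a
  # monotone E(rho) between bulk and condensate values
  expect_true(all(sign(en$dE_WW_rele[ent$rho < 350]) ==
                    -sign(en$dE_WW_reta[ent$rho < 350])))
  expect_error(solvation_energy_changes(ser, wb, components = "E_XX"),
               "missing")
})

test_that("water-water cancellation and protein energy changes behave per the identities", {
  expect_equal(apply_cancellation(10, 0)$TdS_PW, 10)
  expect_equal(apply_cancellation(7.5, 7.5)$TdS_PW, 0)
  expect_equal(apply_cancellation(3, 2)$TdS_WW, 2)

  ser <- gen_concentration_tables(noise_sd = 0, seed = 13)
  ser <- concentration_series(ser[ser$rho <= 350 | ser$is_bulk, ])
  pp <- protein_energy_change(ser, 350)
  expect_equal(pp$dE_PP[pp$rho == 350], 0)
  # decreasing E_PP(rho) makes condensation favorable from any dilute start
  expect_true(all(pp$dE_PP[pp$rho < 350] < 0))
  ora <- oracle_ledger(ser, 350)
  expect_equal(pp$dE_PP, ora$dE_PP, tolerance = 1e-9)
})

test_that("mixing free energy and interface penalty reproduce their closed forms", {
  # RT ln(350/1) at 300 K ~ 14.6 kJ/mol
  expect_equal(mixing_free_energy(350, 1, 300),
               8.314462618 * 300 * log(350) / 1000, tolerance = 1e-12)
  expect_equal(mixing_free_energy(350, 350, 300), 0)
  expect_equal(mixing_free_energy(350, 1, 600),
               2 * mixing_free_energy(350, 1, 300), tolerance = 1e-12)
  expect_error(mixing_free_energy(350, 0), "positive")

  # 3 gamma M / (c r N_A), SI arithmetic done independently
  si <- 3 * (0.5e-3) * 17.2 / (350 * 20e-9) / 1000
  expect_equal(interface_penalty(20, 0.5, 350, 17.2), si, tolerance = 1e-12)
  expect_equal(interface_penalty(40, 0.5, 350, 17.2), si / 2, tolerance = 1e-12)
  expect_lt(interface_penalty(5000, 0.5, 350, 17.2), 0.02)
  expect_error(interface_penalty(-1, 1, 1, 1), "positive")
})

test_that("ledger invariants hold on 100 randomized synthetic series", {
  for (seed in 1:100) {
    ser <- random_series(seed)
    led <- assemble_ledger(ser, rho_cond = 350, dS_P = 0, T = 300)
    tab <- led$table
    # Eq.-10-style cancellation: dE_WW - TdS_WW = 0 identically
    expect_equal(tab$dE_WW, tab$TdS_WW, tolerance = 1e-12)
    # dG_solv via enthalpy-entropy equals the protein-water route to 1e-9
    expect_equal(tab$dH_solv - tab$TdS_solv, tab$dE_PW - tab$TdS_PW,
                 tolerance = 1e-9)
    # reference-state nullity at rho_cond
    ic <- which(tab$rho == 350)
    expect_lt(max(abs(tab[ic, c("dN_rele", "dS_tot", "dE_WW", "dE_PW",
                                "dE_PP", "TdS_P", "dG_solv", "dG_total")])),
              1e-9)
    # spreadsheet-oracle equivalence
    ora <- oracle_ledger(ser, 350)
    expect_equal(tab$dG_solv, ora$dG_solv, tolerance = 1e-9)
    expect_equal(tab$dE_PP, ora$dE_PP, tolerance = 1e-9)
  }
})

test_that("assembled ledgers reproduce the expected driving-force scenario", {
  # defaults: dG_solv < 0, dE_PP < 0, small unfavorable -T dS_P, so the
  # total favors condensation from dilute starting points
  ser <- gen_concentration_tables(noise_sd = 0.05, seed = 14)
  ser <- concentration_series(ser[ser$rho <= 350 | ser$is_bulk, ])
  led <- assemble_ledger(ser, rho_cond = 350, dS_P = -291, T = 300)
  tab <- led$table
  low <- tab$rho <= 100
  expect_true(all(tab$dG_solv[low] < 0))
  expect_true(all(tab$dE_PP[tab$rho < 350] < 0))
  expect_true(all(-tab$TdS_P[tab$rho < 350] > 0))  # -T dS_P unfavorable
  expect_true(all(tab$dG_total[low] < 0))
  # replicate SDs propagate
  expect_true(all(led$sd$dG_total[tab$rho < 350] > 0))
  # mixing penalty reported, excluded by default, included on demand
  expect_equal(tab$dG_mix[1], mixing_free_energy(350, 1, 300))
  led_mix <- assemble_ledger(ser, rho_cond = 350, dS_P = -291, T = 300,
                             include_mix = TRUE)
  expect_equal(led_mix$table$dG_total, tab$dG_total + tab$dG_mix,
               tolerance = 1e-9)

  # all-flat inputs: every delta is zero
  df <- do.call(rbind, lapply(c(25, 150, 350), function(r) data.frame(
    rho = r, replicate = 1, n_chains = 8, n_waters = 16000,
    S_tot = 50, S_tr = 40, S_rot = 10, E_PP = -100, E_PW = -1, E_WW = -45,
    is_bulk = FALSE)))
  df <- rbind(df, data.frame(rho = 1, replicate = 1, n_chains = 0,
                             n_waters = 1e5, S_tot = 50, S_tr = 40,
                             S_rot = 10, E_PP = 0, E_PW = -1, E_WW = -45,
                             is_bulk = TRUE))
  tab0 <- assemble_ledger(concentration_series(df), 350, dS_P = 0)$table
  expect_lt(max(abs(as.matrix(tab0[, c("dS_tot", "dE_WW", "dE_PW", "dE_PP",
                                       "dG_solv", "dG_total")]))), 1e-9)
})

test_that("the 525 mg/mL sensitivity mode rescales the ledger with the same signs", {
  ser <- gen_concentration_tables(noise_sd = 0, seed = 15)
  led350 <- assemble_ledger(concentration_series(ser[ser$rho <= 350 | ser$is_bulk, ]),
                            rho_cond = 350)
  led525 <- assemble_ledger(ser, rho_cond = 525)
  t350 <- led350$table; t525 <- led525$table
  shared <- t350$rho[t350$rho <= 100]
  for (r in shared) {
    a <- t350[t350$rho == r, ]; b <- t525[t525$rho == r, ]
    expect_identical(sign(a$dG_solv), sign(b$dG_solv))
    expect_identical(sign(a$dE_PP), sign(b$dE_PP))
    # larger concentration gap -> larger magnitudes
    expect_gt(abs(b$dE_PP), abs(a$dE_PP))
  }
})
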