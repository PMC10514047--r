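# Concentration-series container and the planted-trend table generator.

.series_cols <- c("rho", "replicate", "n_chains", "n_waters",
                  "S_tot", "S_tr", "S_rot", "E_PP", "E_PW", "E_WW", "is_bulk")

#' Concentration-series container
#'
#' Long-format per-replicate records of a protein concentration series.
#' Normalization conventions (fixed package-wide and asserted by the
#' ledger): entropies `S_*` are per water molecule (J mol^-1 K^-1); `E_PW`
#' and `E_WW` are per water molecule (kJ/mol); `E_PP` is per protein chain
#' (kJ/mol).  Exactly the rows flagged `is_bulk` provide the dilute-phase
#' (bulk water) reference; they carry no chains.
#'
#' @param df data.frame with columns `rho` (mg/mL), `replicate`,
#'   `n_chains`, `n_waters`, `S_tot`, `S_tr`, `S_rot`, `E_PP`, `E_PW`,
#'   `E_WW`, `is_bulk`, and optionally `N_phl`, `box_edge`.
#' @return A `ct_series` (data.frame subclass).
#' @export
concentration_series <- function(df) {
  miss <- setdiff(.series_cols, names(df))
  .assert(length(miss) == 0,
          paste0("missing series columns: ", paste(miss, collapse = ", ")))
  .assert(all(df$rho > 0), "concentrations must be positive")
  .assert(all(df$n_waters >= 0, na.rm = TRUE), "n_waters must be >= 0")
  bad <- abs(df$S_tot - (df$S_tr + df$S_rot)) > 1e-6 * pmax(abs(df$S_tot), 1)
  .assert(!any(bad, na.rm = TRUE), "S_tot must equal S_tr + S_rot")
  .assert(any(df$is_bulk), "series needs at least one bulk (dilute) reference row")
  .assert(all(df$n_chains[df$is_bulk] == 0), "bulk rows must have no chains")
  class(df) <- c("ct_series", "data.frame")
  df
}

#' Replicate means and standard deviations of a concentration series
#'
#' @param series a [concentration_series()].
#' @return data.frame with one row per (rho, is_bulk) and, for every
#'   quantity, its replicate mean plus a `<name>_sd` column.
#' @export
series_means <- function(series) {
  qcols <- setdiff(names(series), c("rho", "replicate", "is_bulk"))
  key <- interaction(series$rho, series$is_bulk, drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    s <- series[key == k, , drop = FALSE]
    out <- data.frame(rho = s$rho[1], is_bulk = s$is_bulk[1])
    for (q in qcols) {
      out[[q]] <- mean(s[[q]])
      out[[paste0(q, "_sd")]] <- if (nrow(s) > 1) sd(s[[q]]) else 0
    }
    out
  })
  res <- do.call(rbind, rows)
  res[order(res$is_bulk, res$rho, decreasing = c(TRUE, FALSE), method = "radix"), ,
      drop = FALSE]
}

# planted trend functions; centralised so tests can call the same closed
# forms as an independent spreadsheet-style oracle via the ground truth
.planted_piecewise <- function(rho, bulk, slope_left, slope_right, breakpoint) {
  ifelse(rho <= breakpoint,
         bulk + slope_left * rho,
         bulk + slope_left * breakpoint + slope_right * (rho - breakpoint))
}

#' Generate a synthetic concentration table with planted trends
#'
#' Emulates the qualitative structure of the measured concentration series:
#' water entropy decreasing piecewise-linearly in concentration with a
#' slope crossover at `breakpoint`; protein-protein and protein-water
#' interaction energies decreasing; water-water energy increasing; water
#' counts falling with concentration (volume-filling geometry at fixed
#' chain count).  All planted parameters travel with the result as
#' `ground_truth`, and Gaussian replicate noise can be added on top.
#'
#' Default magnitudes are anchored at the bulk-water entropies of the
#' four-site dispersion-corrected model at 300 K (54.7 = 43.8 + 10.9
#' J mol^-1 K^-1) and a crossover at 150 mg/mL, with the rotational slope
#' above the crossover 2.4 times smaller than below it and the
#' translational entropy flat below the crossover.
#'
#' @param breakpoint crossover concentration (mg/mL).
#' @param slopes named list overriding any of `S_tr_left`, `S_tr_right`,
#'   `S_rot_left`, `S_rot_right` (J mol^-1 K^-1 per mg/mL), `E_PP`
#'   (kJ/mol per protein per mg/mL), `E_PW`, `E_WW` (kJ/mol per water per
#'   mg/mL).
#' @param noise_sd replicate noise scale: the SD applied to entropies in
#'   J mol^-1 K^-1; other quantities are scaled proportionally (energies
#'   per water x0.2, `E_PP` x20, hydration counts x0.5%).
#' @param rho_grid concentrations (mg/mL); defaults to the eight-system
#'   reference series.
#' @param n_replicates replicates per concentration.
#' @param seed RNG seed.
#' @param n_chains chains per simulated box.
#' @param chain_mass chain molar mass (kDa).
#' @param bulk named list overriding bulk anchors `S_tr`, `S_rot`, `E_WW`,
#'   `N_phl` (waters in a dilute single-chain hydration layer).
#' @return A [concentration_series()] with attribute `ground_truth`.
#' @export
gen_concentration_tables <- function(breakpoint = 150,
                                     slopes = list(),
                                     noise_sd = 0,
                                     rho_grid = c(25, 60, 100, 145, 205, 260, 350, 525),
                                     n_replicates = 3, seed = 1,
                                     n_chains = 8, chain_mass = 17.2,
                                     bulk = list()) {
  set.seed(seed)
  sl <- utils::modifyList(list(
    S_tr_left = -0.001, S_tr_right = -0.0065,
    S_rot_left = -0.005, S_rot_right = -0.005 / 2.4,
    E_PP = -1.2, E_PW = -0.004, E_WW = 0.006), slopes)
  bk <- utils::modifyList(list(S_tr = 43.8, S_rot = 10.9, E_WW = -46,
                               N_phl = 2800), bulk)
  water_density <- 33.33; protein_density <- 1.35
  truth <- list(breakpoint = breakpoint, slopes = sl, bulk = bk,
                fun = list(
    S_tr  = function(r) .planted_piecewise(r, bk$S_tr, sl$S_tr_left, sl$S_tr_right, breakpoint),
    S_rot = function(r) .planted_piecewise(r, bk$S_rot, sl$S_rot_left, sl$S_rot_right, breakpoint),
    E_PP  = function(r) sl$E_PP * r,
    E_PW  = function(r) sl$E_PW * r,
    E_WW  = function(r) bk$E_WW + sl$E_WW * r,
    N_phl = function(r) bk$N_phl * (1 - 0.06 * (r / 25)^0.55),
    n_waters = function(r) {
      vol <- n_chains * chain_mass * 1000 / .ct$NA_ / (r / 1000) * 1e21
      v_chain <- chain_mass * 1000 / (.ct$NA_ * protein_density) * 1e21
      round(pmax(vol - n_chains * v_chain, 0) * water_density)
    }))
  rows <- list()
  for (rho in rho_grid) {
    for (rep_ in seq_len(n_replicates)) {
      s_tr <- truth$fun$S_tr(rho) + rnorm(1, 0, noise_sd)
      s_rot <- truth$fun$S_rot(rho) + rnorm(1, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        rho = rho, replicate = rep_, n_chains = n_chains,
        n_waters = truth$fun$n_waters(rho),
        S_tot = s_tr + s_rot, S_tr = s_tr, S_rot = s_rot,
        E_PP = truth$fun$E_PP(rho) + rnorm(1, 0, 20 * noise_sd),
        E_PW = truth$fun$E_PW(rho) + rnorm(1, 0, 0.2 * noise_sd),
        E_WW = truth$fun$E_WW(rho) + rnorm(1, 0, 0.2 * noise_sd),
        N_phl = truth$fun$N_phl(rho) * (1 + rnorm(1, 0, 0.005 * noise_sd)),
        is_bulk = FALSE)
    }
  }
  # bulk (dilute-phase) reference rows: bulk water, no chains
  for (rep_ in seq_len(n_replicates)) {
    s_tr <- bk$S_tr + rnorm(1, 0, noise_sd)
    s_rot <- bk$S_rot + rnorm(1, 0, noise_sd)
    rows[[length(rows) + 1L]] <- data.frame(
      rho = 1, replicate = rep_, n_chains = 0, n_waters = 177382,
      S_tot = s_tr + s_rot, S_tr = s_tr, S_rot = s_rot,
      E_PP = 0, E_PW = 0,
      E_WW = bk$E_WW + rnorm(1, 0, 0.2 * noise_sd),
      N_phl = NA_real_, is_bulk = TRUE)
  }
  structure(concentration_series(do.call(rbind, rows)), ground_truth = truth)
}

#' Reference all-atom system table
#'
#' Box sizes and solvent counts of the eight all-atom reference systems
#' (eight 17.2 kDa chains each) plus the neat-water reference box, as used
#' for water-budget arithmetic.  Columns: `rho` (mg/mL), `box_edge` (nm),
#' `n_waters`, `n_na`, `n_cl`, `n_chains`.
#'
#' @return data.frame.
#' @export
fus_systems <- function() {
  data.frame(
    rho      = c(25, 60, 100, 145, 205, 260, 350, 525),
    box_edge = c(21.06, 15.79, 13.21, 11.68, 10.38, 9.58, 8.67, 7.57),
    n_waters = c(304821, 125496, 71268, 47752, 32038, 24158, 16509, 9273),
    n_na     = c(700, 379, 229, 165, 122, 101, 79, 65),
    n_cl     = c(854, 363, 213, 149, 106, 85, 63, 42),
    n_chains = 8L)
}
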