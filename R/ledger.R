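# The free-energy bookkeeping of condensate formation.
#
# Reference process: a (hypothetical) homogeneous protein solution at
# concentration rho separates into a condensate at rho_cond plus a dilute
# phase treated as bulk water.  Waters released into the dilute phase and
# waters retained inside the condensate contribute with opposite signs
# (the solvation "tug-of-war"); water-water enthalpy and entropy changes
# cancel identically (Ben-Naim compensation), leaving protein-water terms
# in the solvation free energy; protein-protein interaction energy and
# protein conformational entropy complete the ledger.  All extensive
# quantities are per protein chain; negative Delta G favors condensation.

#' Released/retained water budget
#'
#' Per-protein water counts: `dN_rele(rho) = N_W(rho) - N_W(rho_cond)`
#' (released into the dilute phase) and the constant
#' `dN_reta = N_W(rho_cond)` (retained in the condensate), with
#' `N_W(rho) = n_waters / n_chains`.
#'
#' @param series a [concentration_series()].
#' @param rho_cond condensate concentration (mg/mL); must be present in
#'   the series.
#' @param allow_above_cond keep rows with `rho > rho_cond` (these imply
#'   negative release and are rejected by default).
#' @return data.frame (`ct_water_budget`) with `rho`, `N_W`, `dN_rele`,
#'   `dN_reta`.
#' @export
water_budget <- function(series, rho_cond = 350, allow_above_cond = FALSE) {
  sm <- series_means(series)
  sys <- sm[!sm$is_bulk, , drop = FALSE]
  .assert(any(abs(sys$rho - rho_cond) < 1e-9),
          paste0("rho_cond = ", rho_cond, " not present in the series"))
  if (any(sys$rho > rho_cond + 1e-9)) {
    if (!allow_above_cond)
      stop("series rows above rho_cond imply negative water release; ",
           "drop them or set allow_above_cond = TRUE", call. = FALSE)
  }
  keep <- allow_above_cond | sys$rho <= rho_cond + 1e-9
  sys <- sys[keep, , drop = FALSE]
  NW <- sys$n_waters / sys$n_chains
  NW_cond <- NW[which.min(abs(sys$rho - rho_cond))]
  out <- data.frame(rho = sys$rho, N_W = NW,
                    dN_rele = NW - NW_cond, dN_reta = NW_cond)
  class(out) <- c("ct_water_budget", "data.frame")
  attr(out, "rho_cond") <- rho_cond
  out
}

# pull per-replicate rows for one quantity as a rho x replicate layout
.rep_split <- function(series) split(seq_len(nrow(series)), series$replicate)

#' Solvation entropy changes from released and retained waters
#'
#' Per-protein entropy changes:
#' `dS_rele(rho) = (S(rho_dil) - S(rho)) * dN_rele(rho)` and
#' `dS_reta(rho) = (S(rho_cond) - S(rho)) * dN_reta`, summed into
#' `dS_tot`; the bulk rows of the series provide `S(rho_dil)`.  With water
#' entropy decreasing in concentration the released-water term is positive
#' (favors condensation through `-T dS`).
#'
#' @param series a [concentration_series()] (replicate means are used).
#' @param budget matching [water_budget()].
#' @param T temperature (K).
#' @param quantity entropy column, default `"S_tot"`.
#' @return data.frame with `rho`, `dS_rele`, `dS_reta`, `dS_tot`
#'   (J mol^-1 K^-1 per protein) and `TdS_solv` (kJ/mol per protein).
#' @export
solvation_entropy_changes <- function(series, budget, T = 300,
                                      quantity = "S_tot") {
  sm <- series_means(series)
  bulk <- sm[sm$is_bulk, , drop = FALSE]
  .assert(nrow(bulk) >= 1L, "series has no bulk (dilute) reference row")
  S_dil <- bulk[[quantity]][1]
  sys <- sm[!sm$is_bulk, , drop = FALSE]
  sys <- sys[match(budget$rho, sys$rho), , drop = FALSE]
  S_rho <- sys[[quantity]]
  S_cond <- S_rho[which.min(abs(budget$rho - attr(budget, "rho_cond")))]
  dS_rele <- (S_dil - S_rho) * budget$dN_rele
  dS_reta <- (S_cond - S_rho) * budget$dN_reta
  data.frame(rho = budget$rho, dS_rele = dS_rele, dS_reta = dS_reta,
             dS_tot = dS_rele + dS_reta,
             TdS_solv = T * (dS_rele + dS_reta) / 1000)
}

#' Solvation energy changes from released and retained waters
#'
#' Mirrors [solvation_entropy_changes()] for the per-water interaction
#' energies: `dE_rele(rho) = (E(rho_dil) - E(rho)) * dN_rele(rho)`,
#' `dE_reta(rho) = (E(rho_cond) - E(rho)) * dN_reta`, for each of the
#' water-water (`WW`) and protein-water (`PW`) components, plus the total
#' solvation enthalpy `dH_solv = dE_PW + dE_WW`.
#'
#' @param series a [concentration_series()].
#' @param budget matching [water_budget()].
#' @param components energy columns to process.
#' @return data.frame with per-component released/retained/total columns
#'   (kJ/mol per protein) and `dH_solv`.
#' @export
solvation_energy_changes <- function(series, budget,
                                     components = c("E_WW", "E_PW")) {
  .assert(all(components %in% names(series)),
          paste0("missing energy components: ",
                 paste(setdiff(components, names(series)), collapse = ", ")))
  sm <- series_means(series)
  bulk <- sm[sm$is_bulk, , drop = FALSE]
  sys <- sm[!sm$is_bulk, , drop = FALSE]
  sys <- sys[match(budget$rho, sys$rho), , drop = FALSE]
  ic <- which.min(abs(budget$rho - attr(budget, "rho_cond")))
  out <- data.frame(rho = budget$rho)
  for (comp in components) {
    E_dil <- bulk[[comp]][1]
    E_rho <- sys[[comp]]
    E_cond <- E_rho[ic]
    rel <- (E_dil - E_rho) * budget$dN_rele
    ret <- (E_cond - E_rho) * budget$dN_reta
    nm <- sub("^E_", "", comp)
    out[[paste0("dE_", nm, "_rele")]] <- rel
    out[[paste0("dE_", nm, "_reta")]] <- ret
    out[[paste0("dE_", nm)]] <- rel + ret
  }
  if (all(c("dE_WW", "dE_PW") %in% names(out)))
    out$dH_solv <- out$dE_WW + out$dE_PW
  out
}

#' Water-water enthalpy-entropy cancellation
#'
#' Applies the compensation identity `dE_WW - T dS_WW = 0`: the water-water
#' entropy term is set equal to the water-water energy change, and the
#' noncanceling protein-water entropy remainder is
#' `T dS_PW = T dS_solv - dE_WW`.
#'
#' @param TdS_solv total solvation entropy term (kJ/mol).
#' @param dE_WW water-water energy change (kJ/mol).
#' @return list with `TdS_PW`, `TdS_WW` (= `dE_WW`).
#' @export
apply_cancellation <- function(TdS_solv, dE_WW) {
  list(TdS_PW = TdS_solv - dE_WW, TdS_WW = dE_WW)
}

#' Protein-protein interaction energy change
#'
#' `dE_PP(rho) = E_PP(rho_cond) - E_PP(rho)` per protein: with the dilute
#' phase modeled as bulk water there are no released proteins, so the
#' protein energy change is set entirely by the condensate.
#'
#' @param series a [concentration_series()].
#' @param rho_cond condensate concentration (mg/mL).
#' @param allow_above_cond see [water_budget()].
#' @return data.frame with `rho`, `dE_PP` (kJ/mol per protein).
#' @export
protein_energy_change <- function(series, rho_cond = 350,
                                  allow_above_cond = FALSE) {
  sm <- series_means(series)
  sys <- sm[!sm$is_bulk, , drop = FALSE]
  keep <- allow_above_cond | sys$rho <= rho_cond + 1e-9
  sys <- sys[keep, , drop = FALSE]
  .assert(any(abs(sys$rho - rho_cond) < 1e-9), "rho_cond not in series")
  E_cond <- sys$E_PP[which.min(abs(sys$rho - rho_cond))]
  data.frame(rho = sys$rho, dE_PP = E_cond - sys$E_PP)
}

#' Mixing free-energy estimate
#'
#' `RT ln(rho_cond / rho_dil)` in kJ/mol: the demixing penalty associated
#' with concentrating the protein from the dilute phase into the
#' condensate.
#'
#' @param rho_cond,rho_dil concentrations (mg/mL), both > 0.
#' @param T temperature (K).
#' @return kJ/mol.
#' @export
#' @examples
#' mixing_free_energy(350, 1, 300)  # ~14.6 kJ/mol
mixing_free_energy <- function(rho_cond, rho_dil, T = 300) {
  .assert(rho_dil > 0 && rho_cond > 0, "concentrations must be positive")
  .ct$R * T * log(rho_cond / rho_dil) / 1000
}

#' Interface free-energy penalty of a spherical droplet
#'
#' `3 gamma M / (c r N_A)` per molecule, reported per mole: surface free
#' energy of a droplet of radius `r` and surface tension `gamma` divided
#' by the number of proteins it contains.
#'
#' @param radius droplet radius (nm), > 0.
#' @param gamma surface tension (mN/m), > 0.
#' @param rho_cond condensate concentration (mg/mL).
#' @param chain_mass protein molar mass (kDa).
#' @return kJ/mol per protein.
#' @export
#' @examples
#' interface_penalty(20, 0.5, 350, 17.2)  # ~3.7 kJ/mol
interface_penalty <- function(radius, gamma, rho_cond, chain_mass) {
  .assert(all(c(radius, gamma, rho_cond, chain_mass) > 0),
          "all inputs must be positive")
  # SI: gamma [J/m^2] * 3 M [kg/mol] / (c [kg/m^3] * r [m]) -> J/mol
  3 * (gamma * 1e-3) * chain_mass / (rho_cond * radius * 1e-9) / 1000
}

# one ledger evaluation on a plain single-replicate series data.frame
.ledger_once <- function(series, rho_cond, dS_P, T, allow_above_cond) {
  budget <- water_budget(series, rho_cond, allow_above_cond)
  ent <- solvation_entropy_changes(series, budget, T)
  en <- solvation_energy_changes(series, budget)
  pp <- protein_energy_change(series, rho_cond, allow_above_cond)
  canc <- apply_cancellation(ent$TdS_solv, en$dE_WW)
  # scalar dS_P is the dilute-limit value; like every other delta it must
  # vanish at the reference state, so it fades linearly to 0 at rho_cond
  if (length(dS_P) == 1L) {
    span <- rho_cond - min(budget$rho)
    dS_P <- if (span > 0) dS_P * (rho_cond - budget$rho) / span
            else rep(0, nrow(budget))
  }
  .assert(length(dS_P) == nrow(budget),
          "dS_P must be scalar or one value per ledger row")
  led <- data.frame(
    rho = budget$rho,
    dN_rele = budget$dN_rele, dN_reta = budget$dN_reta,
    dS_rele = ent$dS_rele, dS_reta = ent$dS_reta, dS_tot = ent$dS_tot,
    TdS_solv = ent$TdS_solv,
    dE_WW_rele = en$dE_WW_rele, dE_WW_reta = en$dE_WW_reta, dE_WW = en$dE_WW,
    dE_PW_rele = en$dE_PW_rele, dE_PW_reta = en$dE_PW_reta, dE_PW = en$dE_PW,
    dH_solv = en$dH_solv,
    TdS_WW = canc$TdS_WW, TdS_PW = canc$TdS_PW,
    dE_PP = pp$dE_PP[match(budget$rho, pp$rho)],
    dS_P = dS_P, TdS_P = T * dS_P / 1000)
  led$dG_solv <- led$dH_solv - led$TdS_solv      # equals dE_PW - TdS_PW
  led$dG_mix <- mixing_free_energy(rho_cond, 1, T)
  led$dG_total <- led$dG_solv + led$dE_PP - led$TdS_P
  led
}

#' Assemble the full thermodynamic ledger
#'
#' Combines the water budget, the solvation entropy and energy changes,
#' the water-water cancellation, the protein interaction energy and the
#' conformational entropy into the per-concentration free-energy ledger
#' `dG = dG_solv + dE_PP - T dS_P`, with every delta vanishing at
#' `rho = rho_cond` (the reference state).  The mixing free energy (and,
#' when requested, the droplet interface penalty) are computed and
#' reported but excluded from `dG_total` by default: at the reference
#' conditions they are an order of magnitude below the leading terms.
#' Replicate SDs are propagated as the SD over per-replicate ledgers.
#'
#' @param series a [concentration_series()] with replicate rows.
#' @param rho_cond condensate concentration (mg/mL); 350 by default with a
#'   documented 525 sensitivity mode.
#' @param dS_P conformational entropy change per protein
#'   (J mol^-1 K^-1); either one value per ledger row, or a scalar giving
#'   the dilute-limit value, which is faded linearly to zero at
#'   `rho_cond` so the reference state stays null.
#' @param T temperature (K).
#' @param include_mix add `dG_mix` into `dG_total`.
#' @param include_interface optional list
#'   `list(radius = , gamma = , chain_mass = )`; when given, the interface
#'   penalty is reported (and added to `dG_total` only if
#'   `include_interface$add` is `TRUE`).
#' @param allow_above_cond keep series rows above `rho_cond`.
#' @return A `ct_ledger`: list with `table` (mean ledger, kJ/mol per
#'   protein), `sd` (replicate SDs), `rho_cond`, `T`, and `conventions`.
#' @export
assemble_ledger <- function(series, rho_cond = 350, dS_P = 0, T = 300,
                            include_mix = FALSE, include_interface = NULL,
                            allow_above_cond = FALSE) {
  reps <- sort(unique(series$replicate))
  per_rep <- lapply(reps, function(r) {
    s <- series[series$replicate == r, , drop = FALSE]
    .assert(sum(s$is_bulk) >= 1L && sum(!s$is_bulk) >= 1L,
            "inconsistent replicate structure across inputs")
    .ledger_once(concentration_series(s), rho_cond, dS_P, T, allow_above_cond)
  })
  tab <- per_rep[[1]]
  num <- vapply(tab, is.numeric, TRUE)
  arr <- simplify2array(lapply(per_rep, function(d) as.matrix(d[, num])))
  mean_tab <- tab
  mean_tab[, num] <- apply(arr, c(1, 2), mean)
  sd_tab <- tab
  sd_tab[, num] <- if (length(per_rep) > 1) apply(arr, c(1, 2), sd) else 0
  if (include_mix)
    mean_tab$dG_total <- mean_tab$dG_total + mean_tab$dG_mix
  if (!is.null(include_interface)) {
    gi <- interface_penalty(include_interface$radius, include_interface$gamma,
                            rho_cond, include_interface$chain_mass)
    mean_tab$dG_interface <- gi
    if (isTRUE(include_interface$add))
      mean_tab$dG_total <- mean_tab$dG_total + gi
  }
  structure(list(table = mean_tab, sd = sd_tab, rho_cond = rho_cond, T = T,
                 include_mix = include_mix,
                 conventions = c(
                   "all extensive deltas per protein chain",
                   "E_PW/E_WW consumed per water; converted via the budget",
                   "E_PP consumed per protein",
                   "negative dG favors condensation",
                   "dilute-phase reference: bulk water rows",
                   "dG_mix reported, excluded from dG_total unless include_mix")),
            class = "ct_ledger")
}

#' @export
print.ct_ledger <- function(x, ...) {
  cat("<ct_ledger> rho_cond = ", x$rho_cond, " mg/mL, T = ", x$T, " K\n",
      sep = "")
  cols <- c("rho", "TdS_solv", "TdS_PW", "dE_PW", "dH_solv", "dG_solv",
            "dE_PP", "TdS_P", "dG_total")
  print(format(x$table[, cols], digits = 4), row.names = FALSE)
  invisible(x)
}
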