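# System-level generators: a bulk rigid-water simulator (the fixture engine
# for 2PT validation), a Langevin soft-sphere fluid, and toy condensates.

#' Simulate a bulk box of rigid four-site water
#'
#' Runs the package's lightweight NVT engine (velocity-Verlet rigid-body
#' dynamics, CSVR thermostat, reaction-field electrostatics, molecule-based
#' 0.9 nm cutoff) on `n_waters` dispersion-corrected four-site waters at the
#' given temperature and density, then returns the production-phase
#' center-of-mass and principal-frame angular velocities as a
#' [velocity_series()] ready for [entropy_pipeline()].
#'
#' Defaults follow the reference protocol for density-of-states work: 20 ps
#' production sampled every 4 fs, preceded by staged equilibration from a
#' lattice start.  The box edge is solved from the mass density.
#'
#' @param n_waters number of water molecules (~500 is the scaled-down bulk
#'   reference).
#' @param T temperature (K).
#' @param mass_density water mass density (g/cm^3).
#' @param seed RNG seed (deterministic engine).
#' @param equil_ps total equilibration time (ps).
#' @param prod_ps production time (ps).
#' @param dt_fs integration time step (fs).
#' @param out_every_fs velocity output interval (fs).
#' @param cutoff interaction cutoff (nm).
#' @param model a four-site [water_model()].
#' @return list with `series` (a [velocity_series()]), `topology`, `frame`
#'   (final positions+velocities), and `diagnostics` (temperature and
#'   potential-energy traces).
#' @export
simulate_water_box <- function(n_waters = 500, T = 300, mass_density = 0.997,
                               seed = 1, equil_ps = 20, prod_ps = 20,
                               dt_fs = 2, out_every_fs = 4, cutoff = 0.9,
                               model = water_model()) {
  .assert(model$type == "four_site", "simulate_water_box needs the four-site model")
  vol <- n_waters * model$mass * 1.66053907e-24 / mass_density * 1e21  # nm^3
  box <- vol^(1 / 3)
  .assert(cutoff < box / 2, "cutoff exceeds half the box edge; use more waters")
  dt <- dt_fs / 1000
  out_every <- max(1L, round(out_every_fs / dt_fs))
  n_eq1 <- round(2 / 0.0005)                      # 2 ps at 0.5 fs, clamped forces
  n_eq2 <- max(0L, round((equil_ps - 2) / dt))
  n_prod <- round(prod_ps / dt)
  res <- .cpp_water_md(as.integer(n_waters), box, T, as.integer(seed), cutoff,
                       model$masses, model$sites, model$charges,
                       model$principal_moments, model$sigma, model$epsilon,
                       0.0005, as.integer(n_eq1), dt, as.integer(n_eq2),
                       as.integer(n_prod), as.integer(out_every),
                       0.1, 2.0)
  series <- velocity_series(dt * out_every, res$com_velocities,
                            res$angular_velocities,
                            rep(model$mass, n_waters),
                            model$principal_moments,
                            n_density = n_waters / vol, temperature = T)
  top <- topology(n_waters = n_waters, water = model)
  fr <- frame(res$site_positions, rep(box, 3), res$site_velocities,
              time = prod_ps)
  list(series = series, topology = top, frame = fr,
       diagnostics = list(temperature = res$temperature_series,
                          potential = res$potential_series, box = box))
}

#' Generate a Langevin soft-sphere fluid
#'
#' Purely repulsive soft spheres (`U = eps (sigma/r)^12`) with point-water
#' masses, evolved with BAOAB Langevin dynamics.  A cheap disordered-liquid
#' stand-in for structural tests: its tetrahedral order parameter
#' distribution is broad and peaked well below the ice-like regime.
#'
#' @param n_waters particle count.
#' @param box cubic box edge (nm).
#' @param T temperature (K).
#' @param gamma friction (1/ps).
#' @param duration production time (ps).
#' @param dt time step (ps).
#' @param seed RNG seed; fixed seed gives bit-identical trajectories.
#' @param equil_ps equilibration time (ps).
#' @param out_every output stride in steps.
#' @return list with `topology` (point-model waters) and `frames` (list of
#'   [frame()] with velocities).
#' @export
gen_langevin_fluid <- function(n_waters = 200, box = 2.0, T = 300, gamma = 5,
                               duration = 5, dt = 0.002, seed = 1,
                               equil_ps = 2, out_every = 25L) {
  wm <- water_model("point")
  res <- .cpp_softsphere_ld(as.integer(n_waters), box, T, gamma, wm$mass,
                            wm$sigma, wm$epsilon, dt,
                            as.integer(round(equil_ps / dt)),
                            as.integer(round(duration / dt)),
                            as.integer(out_every), as.integer(seed))
  top <- topology(n_waters = n_waters, water = wm)
  frames <- lapply(seq_len(res$n_frames), function(f)
    frame(res$positions[f, , ], rep(box, 3), res$velocities[f, , ],
          time = f * out_every * dt))
  list(topology = top, frames = frames)
}

#' Generate a toy condensate series
#'
#' For each requested protein mass concentration, solves the cubic box edge
#' from `rho = n_chains * M / (N_A * V)`, lays down `n_chains` bead-string
#' chains (random walks with 0.38 nm steps; non-physical, only geometry
#' matters downstream), and fills the remaining volume with point-model
#' waters at bulk water density, excluding a 0.25 nm shell around the
#' beads.  Water counts therefore fall with concentration like the
#' all-atom reference systems.
#'
#' @param rho_series concentrations (mg/mL).
#' @param n_chains chains per box.
#' @param chain_mass molar mass per chain (kDa).
#' @param seed RNG seed.
#' @param n_beads beads per chain.
#' @param water_scale multiplier on the water number density (use < 1 for
#'   fast tests; 1 reproduces realistic water counts).
#' @param place_waters set `FALSE` to skip water placement (geometry-only
#'   uses).
#' @return named list (one element per concentration) of lists with
#'   `topology`, `frame`, `rho`, `box_edge`, `n_waters`; the attached
#'   attribute `ground_truth` records the requested densities and box
#'   edges.
#' @export
gen_toy_condensate <- function(rho_series, n_chains = 8, chain_mass = 17.2,
                               seed = 1, n_beads = 40, water_scale = 1,
                               place_waters = TRUE) {
  .assert(all(rho_series > 0), "concentrations must be positive")
  set.seed(seed)
  water_density <- 33.33 * water_scale  # molecules/nm^3
  protein_density <- 1.35               # g/cm^3, typical protein partial density
  out <- list()
  for (rho in rho_series) {
    mass_g <- n_chains * chain_mass * 1000 / .ct$NA_
    vol <- mass_g / (rho / 1000) * 1e21          # nm^3
    box <- rep(vol^(1 / 3), 3)
    chains <- list(); bead_pos <- NULL
    bead_mass <- chain_mass * 1000 / n_beads
    for (k in seq_len(n_chains)) {
      p <- matrix(0, n_beads, 3)
      p[1, ] <- runif(3, 0, box[1])
      for (b in 2:n_beads) {
        u <- rnorm(3); u <- u / sqrt(sum(u^2))
        p[b, ] <- p[b - 1, ] + 0.38 * u
      }
      chains[[k]] <- list(id = paste0("chain", k),
                          atom_names = rep("CA", n_beads),
                          masses = rep(bead_mass, n_beads))
      bead_pos <- rbind(bead_pos, p)
    }
    v_chain <- chain_mass * 1000 / (.ct$NA_ * protein_density) * 1e21  # nm^3
    n_w <- if (place_waters)
      max(0L, round((vol - n_chains * v_chain) * water_density)) else 0L
    wpos <- NULL
    if (n_w > 0L) {
      # uniform grid candidates, protein shell excluded, then subsample
      spacing <- (1 / water_density)^(1 / 3) * 0.9
      g1 <- seq(spacing / 2, box[1] - spacing / 4, by = spacing)
      cand <- as.matrix(expand.grid(x = g1, y = g1, z = g1))
      keep <- rep(TRUE, nrow(cand))
      for (blk in split(seq_len(nrow(cand)),
                        ceiling(seq_len(nrow(cand)) / 20000))) {
        d <- .pairdist(cand[blk, , drop = FALSE], bead_pos, box)
        keep[blk] <- apply(d, 1, min) > 0.25
      }
      cand <- cand[keep, , drop = FALSE]
      .assert(nrow(cand) >= n_w,
              "not enough room to place waters; lower water_scale")
      wpos <- cand[sample.int(nrow(cand), n_w), , drop = FALSE]
    }
    top <- topology(chains, n_waters = n_w, water = water_model("point"))
    pos <- rbind(bead_pos, wpos)
    out[[as.character(rho)]] <- list(
      topology = top, frame = frame(pos, box, NULL, 0),
      rho = rho, box_edge = box[1], n_waters = n_w)
  }
  structure(out, ground_truth = list(
    rho_series = rho_series,
    box_edges = vapply(out, function(x) x$box_edge, 0),
    n_waters = vapply(out, function(x) x$n_waters, 0)))
}

#' Recompute the protein concentration implied by a toy-condensate box
#'
#' @param box_edge cubic box edge (nm).
#' @param n_chains number of chains.
#' @param chain_mass chain molar mass (kDa).
#' @return concentration (mg/mL).
#' @export
box_concentration <- function(box_edge, n_chains, chain_mass) {
  mass_g <- n_chains * chain_mass * 1000 / .ct$NA_
  mass_g / (box_edge^3 * 1e-21) * 1000  # mg/mL
}
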