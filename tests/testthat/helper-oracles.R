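# Independent oracles and fixture builders shared across the suite.  These
# deliberately re-derive quantities with the dumbest possible code (double
# loops, direct sums, spreadsheet-style arithmetic) so the package
# implementations are checked against something that cannot share their
# bugs.

kB <- ct_constants()$kB
Rgas <- ct_constants()$R
hpl <- ct_constants()$h

trapz <- function(x, y) sum(diff(x) * (y[-length(y)] + y[-1]) / 2)

# O(N^2 * lags) brute-force VACF: sum over molecules/components of
# w * mean_tau(v(tau) v(tau+t))
brute_vacf <- function(v, weights_per_mol, lags) {
  nF <- dim(v)[1]; nM <- dim(v)[2]
  out <- numeric(length(lags))
  for (li in seq_along(lags)) {
    lag <- lags[li]
    acc <- 0
    for (m in seq_len(nM)) {
      for (k in 1:3) {
        s <- 0
        for (tau in seq_len(nF - lag))
          s <- s + v[tau, m, k] * v[tau + lag, m, k]
        acc <- acc + weights_per_mol[m] * s / (nF - lag)
      }
    }
    out[li] <- acc
  }
  out
}

# direct (naive) discrete cosine transform matching compute_dos's
# definition, including the trapezoid endpoint weights, optional Bartlett
# taper and the padded frequency grid
naive_dos <- function(cvals, dt, T, window = "bartlett") {
  L <- length(cvals) - 1L
  npad <- 2L * 2L^ceiling(log2(L + 1L))
  w <- c(0.5, rep(1, L - 1L), 0.5)
  if (window == "bartlett") w <- w * (1 - (0:L) / (L + 1L))
  freq <- (0:(npad %/% 2L)) / (npad * dt)
  tj <- (0:L) * dt
  I <- vapply(freq, function(nu)
    (4 * dt / (kB * T)) * sum(w * cvals * cos(2 * pi * nu * tj)), 0)
  list(frequencies = freq, intensity = I)
}

# rigid-water frame with prescribed COM velocities and body angular
# velocities; returns frames plus the exact kinetic decomposition
make_rigid_water_frames <- function(n_waters, seed = 1, dt = 0.002,
                                    box = rep(4, 3)) {
  set.seed(seed)
  wm <- water_model()
  vcom <- matrix(rnorm(n_waters * 3, sd = 0.4), n_waters, 3)
  wbody <- matrix(rnorm(n_waters * 3, sd = 15), n_waters, 3)
  coms <- matrix(runif(n_waters * 3, 0.5, box[1] - 0.5), n_waters, 3)
  rots <- lapply(seq_len(n_waters), function(i) {
    th <- runif(3, 0, 2 * pi)
    Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, byrow = TRUE)
    Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
    Rz(th[1]) %*% Rx(th[2]) %*% Rz(th[3])
  })
  mk_frame <- function(tt) {
    pos <- NULL; vel <- NULL
    for (i in seq_len(n_waters)) {
      A <- rots[[i]]
      wl <- A %*% wbody[i, ]                       # lab angular velocity
      th <- sqrt(sum(wl^2)) * tt
      # rotate the molecule about its (fixed) lab angular velocity axis
      if (th > 0) {
        u <- wl / sqrt(sum(wl^2))
        K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, byrow = TRUE)
        Rt <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      } else Rt <- diag(3)
      At <- Rt %*% A
      sites <- t(At %*% t(water_model()$sites))
      com_t <- coms[i, ] + vcom[i, ] * tt
      pos <- rbind(pos, sweep(sites, 2, com_t, "+"))
      wlt <- Rt %*% wl
      svel <- t(apply(sites, 1, function(s)
        vcom[i, ] + c(wlt[2] * s[3] - wlt[3] * s[2],
                      wlt[3] * s[1] - wlt[1] * s[3],
                      wlt[1] * s[2] - wlt[2] * s[1])))
      vel <- rbind(vel, svel)
    }
    frame(pos, box, vel, time = tt)
  }
  ke_tr <- 0.5 * wm$mass * sum(vcom^2)
  ke_rot <- 0.5 * sum(sweep(wbody^2, 2, wm$principal_moments, "*"))
  list(top = topology(n_waters = n_waters),
       frames = list(mk_frame(0), mk_frame(dt)),
       vcom = vcom, wbody = wbody, ke_tr = ke_tr, ke_rot = ke_rot)
}

# perfect tetrahedral neighbor frame: central oxygen + 4 ideal neighbors
perfect_tetrahedron_frame <- function(d = 0.28, box = rep(10, 3)) {
  dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  frame(rbind(c(0, 0, 0), dirs * d) + box[1] / 2, box)
}

# jittered diamond (ice-like) oxygen lattice
ice_lattice_frame <- function(ncell = 2, a = 0.637, jitter = 0.01, seed = 1) {
  set.seed(seed)
  base <- rbind(c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0))
  base <- rbind(base, sweep(base, 2, c(.25, .25, .25), "+"))
  pts <- NULL
  for (i in 0:(ncell - 1)) for (j in 0:(ncell - 1)) for (k in 0:(ncell - 1))
    pts <- rbind(pts, sweep(base, 2, c(i, j, k), "+"))
  pts <- pts * a + matrix(rnorm(length(pts), 0, jitter), nrow(pts), 3)
  frame(pts, rep(ncell * a, 3))
}

# spreadsheet-style ledger oracle: plain arithmetic on the replicate-mean
# table, written independently of the package's ledger code
oracle_ledger <- function(series, rho_cond, T = 300) {
  sm <- series_means(series)
  bulk <- sm[sm$is_bulk, ]
  sys <- sm[!sm$is_bulk & sm$rho <= rho_cond + 1e-9, ]
  sys <- sys[order(sys$rho), ]
  NW <- sys$n_waters / sys$n_chains
  ic <- which(abs(sys$rho - rho_cond) < 1e-9)
  rel <- NW - NW[ic]; ret <- NW[ic]
  dS <- (bulk$S_tot - sys$S_tot) * rel + (sys$S_tot[ic] - sys$S_tot) * ret
  dEww <- (bulk$E_WW - sys$E_WW) * rel + (sys$E_WW[ic] - sys$E_WW) * ret
  dEpw <- (bulk$E_PW - sys$E_PW) * rel + (sys$E_PW[ic] - sys$E_PW) * ret
  dEpp <- sys$E_PP[ic] - sys$E_PP
  TdS <- T * dS / 1000
  data.frame(rho = sys$rho, dN_rele = rel, dS_tot = dS, TdS_solv = TdS,
             dE_WW = dEww, dE_PW = dEpw, dH_solv = dEww + dEpw,
             TdS_PW = TdS - dEww, dE_PP = dEpp,
             dG_solv = (dEww + dEpw) - TdS)
}

# random valid concentration series for property sweeps
random_series <- function(seed) {
  set.seed(seed)
  rho <- sort(runif(5, 20, 340)); rho <- c(rho, 350)
  n_rep <- sample(1:3, 1)
  rows <- list()
  for (r in rho) {
   nw <- round(3e5 / r + runif(1, -50, 50))   # composition is per system
   for (k in seq_len(n_rep)) {
    s_tr <- runif(1, 30, 50); s_rot <- runif(1, 5, 15)
    rows[[length(rows) + 1L]] <- data.frame(
      rho = r, replicate = k, n_chains = 8,
      n_waters = nw,
      S_tot = s_tr + s_rot, S_tr = s_tr, S_rot = s_rot,
      E_PP = runif(1, -500, 0), E_PW = runif(1, -5, 0),
      E_WW = runif(1, -50, -40), is_bulk = FALSE)
   }
  }
  for (k in seq_len(n_rep)) {
    s_tr <- runif(1, 40, 46); s_rot <- runif(1, 9, 12)
    rows[[length(rows) + 1L]] <- data.frame(
      rho = 1, replicate = k, n_chains = 0, n_waters = 177382,
      S_tot = s_tr + s_rot, S_tr = s_tr, S_rot = s_rot,
      E_PP = 0, E_PW = 0, E_WW = runif(1, -50, -40), is_bulk = TRUE)
  }
  concentration_series(do.call(rbind, rows))
}
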