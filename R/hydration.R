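# Structural water metrics: tetrahedral order parameter, hydrogen bonds,
# hydration-layer populations, chain radius of gyration, and the
# piecewise-linear crossover fit used for entropy-vs-concentration trends.

#' Tetrahedral order parameter of water oxygens
#'
#' For each water oxygen, its four nearest water oxygens (minimum image, no
#' distance cutoff: the standard Errington-Debenedetti convention) define
#' six angles `psi_jk` at the central oxygen and
#' `q = 1 - 3/8 sum_j sum_(k>j) (cos psi_jk + 1/3)^2`.
#' `q = 1` for a perfect tetrahedron; the mean vanishes for uniformly
#' random neighbor directions.
#'
#' @param fr a [frame()].
#' @param top matching [topology()] with at least 5 waters.
#' @param oxygens optional explicit row indices of the oxygen positions
#'   (overrides the topology bookkeeping; useful for bare point sets).
#' @return numeric vector of q values, one per water; `NA` where fewer
#'   than 4 neighbors were available.
#' @export
tetrahedral_q <- function(fr, top = NULL, oxygens = NULL) {
  rows <- oxygens %||% .oxygen_rows(top)
  .assert(length(rows) >= 5L, "need at least 5 water oxygens (center + 4)")
  O <- fr$positions[rows, , drop = FALSE]
  n <- nrow(O)
  D <- .pairdist(O, O, fr$box)
  diag(D) <- Inf
  q <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[1:4]
    if (any(!is.finite(D[i, nb]))) next
    u <- min_image(sweep(O[nb, , drop = FALSE], 2, O[i, ]), fr$box)
    u <- u / sqrt(rowSums(u^2))
    s <- 0
    for (j in 1:3) for (k in (j + 1):4)
      s <- s + (sum(u[j, ] * u[k, ]) + 1 / 3)^2
    q[i] <- 1 - 3 / 8 * s
  }
  q
}

#' Histogram summary of tetrahedral order values
#'
#' @param q numeric q values (possibly from several frames pooled); `NA`s
#'   dropped.
#' @param bins number of bins over `[-3, 1]` (q can go negative for
#'   pathological geometries).
#' @return A `ct_qdist`: list with `breaks`, `counts`, `density`, `mean_q`,
#'   `n_samples`.
#' @export
q_distribution <- function(q, bins = 80L) {
  q <- q[is.finite(q)]
  .assert(length(q) > 0L, "no finite q values supplied")
  q <- pmin(pmax(q, -3), 1)
  h <- graphics::hist(q, breaks = seq(-3, 1, length.out = bins + 1L),
                      plot = FALSE)
  structure(list(breaks = h$breaks, counts = h$counts, density = h$density,
                 mean_q = mean(q), n_samples = length(q)),
            class = "ct_qdist")
}

#' Hydrogen-bond geometric criterion
#'
#' Defaults: donor-acceptor heavy-atom distance <= 0.35 nm and
#' H-donor-acceptor angle <= 30 degrees (the criterion is configurable and
#' is logged in every report that uses it).
#'
#' @param dist_cutoff donor-acceptor distance cutoff (nm), > 0.
#' @param angle_cutoff H-donor-acceptor angle cutoff (degrees), in
#'   `(0, 90]`.
#' @return A `ct_hbond_criterion`.
#' @export
hbond_criterion <- function(dist_cutoff = 0.35, angle_cutoff = 30) {
  .assert(dist_cutoff > 0, "distance cutoff must be positive")
  .assert(angle_cutoff > 0 && angle_cutoff <= 90,
          "angle cutoff must lie in (0, 90] degrees")
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "ct_hbond_criterion")
}

#' Count water-water hydrogen bonds
#'
#' Applies the geometric donor-H...acceptor criterion with minimum-image
#' distances; each D-H...A is counted once.  The per-water mean uses the
#' symmetric accounting `2 x bonds / N_waters` (each bond is shared by its
#' donor and acceptor water); this convention is recorded in the result.
#'
#' @param fr a [frame()].
#' @param top matching [topology()] with 3- or 4-site waters.
#' @param criterion a [hbond_criterion()].
#' @return list with `n_bonds`, `per_water` mean, `per_water_counts`
#'   (participations per water) and `convention`.
#' @export
count_hbonds <- function(fr, top, criterion = hbond_criterion()) {
  wm <- top$water
  .assert(wm$n_sites >= 3L, "hydrogen-bond counting needs explicit hydrogens")
  nW <- top$n_waters
  Orows <- .oxygen_rows(top)
  O <- fr$positions[Orows, , drop = FALSE]
  D <- .pairdist(O, O, fr$box)
  diag(D) <- Inf
  cand <- which(D <= criterion$dist_cutoff, arr.ind = TRUE)  # ordered pairs
  nb <- 0L
  counts <- integer(nW)
  cosmin <- cos(criterion$angle_cutoff * pi / 180)
  for (r in seq_len(nrow(cand))) {
    d_ <- cand[r, 1]; a_ <- cand[r, 2]   # donor water, acceptor water
    pd <- .whole_water(fr, top, d_)
    oa <- O[a_, ]
    vda <- min_image(oa - pd[1, ], fr$box)
    nda <- sqrt(sum(vda^2))
    for (h in 2:3) {
      vdh <- pd[h, ] - pd[1, ]
      ca <- sum(vdh * vda) / (sqrt(sum(vdh^2)) * nda)
      if (ca >= cosmin) {
        nb <- nb + 1L
        counts[d_] <- counts[d_] + 1L
        counts[a_] <- counts[a_] + 1L
        break  # one bond per ordered D -> A pair
      }
    }
  }
  list(n_bonds = nb, per_water = 2 * nb / nW, per_water_counts = counts,
       convention = "per-water mean = 2 x bonds / N_waters; D-H...A counted once")
}

#' Count hydration-layer waters
#'
#' A water belongs to the protein hydration layer (PHL) when any of its
#' atoms lies within `cutoff` of any protein atom (minimum image;
#' hydrogens included on both sides -- the inclusive surface definition,
#' configurable only through the cutoff).  Waters are assigned to their
#' nearest chain for per-chain counts.
#'
#' @param fr a [frame()].
#' @param top matching [topology()] with >= 1 chain.
#' @param cutoff shell thickness (nm), default 0.3 (first hydration
#'   shell).
#' @param reference hydration-water count of a dilute single-chain system
#'   (> 0), used for normalization; `NULL` skips normalization.
#' @return list with `per_chain` counts, `total`, `mean_per_chain` and
#'   `normalized` (`mean_per_chain / reference`, `NA` when no reference).
#' @export
count_phl_waters <- function(fr, top, cutoff = 0.3, reference = NULL) {
  .assert(length(top$chains) >= 1L, "topology has no protein chains")
  if (!is.null(reference))
    .assert(reference > 0, "dilute single-chain reference must be positive")
  nC <- length(top$chains)
  prot_rows <- unlist(lapply(seq_len(nC), function(k) .chain_rows(top, k)))
  chain_of <- rep(seq_len(nC),
                  vapply(top$chains, function(ch) length(ch$masses), 0L))
  P <- fr$positions[prot_rows, , drop = FALSE]
  nW <- top$n_waters
  per_chain <- integer(nC)
  ns <- top$water$n_sites
  wat_rows <- .n_chain_atoms(top) + seq_len(nW * ns)
  W <- fr$positions[wat_rows, , drop = FALSE]
  Dw <- .pairdist(W, P, fr$box)             # (nW*ns) x nProt
  for (i in seq_len(nW)) {
    rows <- (i - 1L) * ns + seq_len(ns)
    d <- Dw[rows, , drop = FALSE]
    if (min(d) <= cutoff) {
      k <- chain_of[which.min(apply(d, 2, min))]
      per_chain[k] <- per_chain[k] + 1L
    }
  }
  mean_pc <- sum(per_chain) / nC
  list(per_chain = per_chain, total = sum(per_chain),
       mean_per_chain = mean_pc,
       normalized = if (is.null(reference)) NA_real_ else mean_pc / reference)
}

#' Mass-weighted radius of gyration of a chain
#'
#' The chain is first made whole by minimum-image unwrapping along its
#' bonded sequence; a chain that cannot be unwrapped (consecutive atoms
#' farther than half the box even after imaging) is an error.
#'
#' @param coords n x 3 chain coordinates (nm).
#' @param masses atom masses (amu).
#' @param box optional box for unwrapping; `NULL` treats coordinates as
#'   already whole.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses, box = NULL) {
  coords <- as.matrix(coords)
  .assert(length(masses) == nrow(coords), "one mass per atom required")
  if (!is.null(box)) {
    for (i in seq_len(nrow(coords))[-1]) {
      d <- min_image(coords[i, ] - coords[i - 1, ], box)
      if (sqrt(sum(d^2)) > min(box) / 2 - 1e-9)
        stop("chain cannot be unwrapped within half the box", call. = FALSE)
      coords[i, ] <- coords[i - 1, ] + d
    }
  }
  com <- colSums(coords * masses) / sum(masses)
  sqrt(sum(masses * rowSums(sweep(coords, 2, com)^2)) / sum(masses))
}

#' Continuous two-segment (crossover) fit
#'
#' Least-squares fit of `y(x)` by two straight lines forced to meet at a
#' breakpoint: `y = b0 + b1 x + b2 (x - x*)_+`.  The breakpoint is found
#' by scanning every interior interval of the data grid and refining the
#' knot continuously within the best intervals, so a noiseless planted
#' crossover is recovered exactly.  With replicate noise available, a
#' parametric resampling gives a breakpoint spread.
#'
#' @param x ordinates (e.g. concentration, mg/mL), >= 5 points.
#' @param y observable.
#' @param weights optional least-squares weights.
#' @param y_sd optional per-point SD for resampling confidence.
#' @param n_boot resampling draws when `y_sd` is given.
#' @return A `ct_crossover`: `breakpoint`, `slopes` (left, right),
#'   `slope_ratio` (right/left), `rss`, `reliable` flag (FALSE when a
#'   single line explains the data essentially as well), optional
#'   `breakpoint_sd`.
#' @export
fit_crossover <- function(x, y, weights = NULL, y_sd = NULL, n_boot = 200L) {
  .assert(length(x) == length(y), "x and y lengths differ")
  .assert(length(x) >= 5L, "need at least 5 points for a two-segment fit")
  o <- order(x); x <- x[o]; y <- y[o]
  w <- weights[o] %||% rep(1, length(x))
  fit_at <- function(knot) {
    X <- cbind(1, x, pmax(x - knot, 0))
    b <- tryCatch(stats::lm.wfit(X, y, w)$coefficients, error = function(e) NULL)
    if (is.null(b) || anyNA(b)) return(list(rss = Inf, beta = NULL))
    r <- y - X %*% b
    list(rss = sum(w * r^2), beta = b)
  }
  one_fit <- function(x, y) {
    lo <- 2L; hi <- length(x) - 2L   # >= 2 points on each side
    best <- list(rss = Inf, knot = NA_real_, beta = NULL)
    for (i in lo:hi) {
      opt <- optimize(function(k) fit_at(k)$rss, c(x[i], x[i + 1L]))
      if (opt$objective < best$rss) {
        f <- fit_at(opt$minimum)
        best <- list(rss = f$rss, knot = opt$minimum, beta = f$beta)
      }
      f2 <- fit_at(x[i])  # knot exactly on a grid point
      if (f2$rss < best$rss) best <- list(rss = f2$rss, knot = x[i], beta = f2$beta)
    }
    best
  }
  best <- one_fit(x, y)
  sl_l <- best$beta[2]; sl_r <- best$beta[2] + best$beta[3]
  # single-line comparison for the degenerate-data flag
  X1 <- cbind(1, x)
  r1 <- y - X1 %*% stats::lm.wfit(X1, y, w)$coefficients
  rss1 <- sum(w * r1^2)
  reliable <- is.finite(best$rss) &&
    (rss1 - best$rss) > 0.2 * max(rss1, 1e-300) &&
    abs(sl_r - sl_l) > 0.1 * max(abs(sl_l), abs(sl_r), 1e-300)
  bp_sd <- NA_real_
  if (!is.null(y_sd) && n_boot > 0L) {
    bps <- vapply(seq_len(n_boot), function(b) {
      one_fit(x, y + rnorm(length(y), 0, y_sd))$knot
    }, 0)
    bp_sd <- sd(bps)
  }
  structure(list(breakpoint = best$knot, slopes = c(left = sl_l, right = sl_r),
                 slope_ratio = sl_r / sl_l, rss = best$rss,
                 rss_single_line = rss1, reliable = reliable,
                 breakpoint_sd = bp_sd),
            class = "ct_crossover")
}

#' @export
print.ct_crossover <- function(x, ...) {
  cat("<ct_crossover> breakpoint ", signif(x$breakpoint, 5),
      " (slopes ", signif(x$slopes[1], 4), " -> ", signif(x$slopes[2], 4),
      ", ratio ", signif(x$slope_ratio, 4), ")",
      if (!x$reliable) " [degenerate: single line fits as well]", "\n",
      sep = "")
  invisible(x)
}
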