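# Protein conformational entropy from torsion-angle distributions:
# Kozachenko-Leonenko k-nearest-neighbor estimation with circular
# (wrap-around) metric, pairwise mutual information on the torus, and
# first-order maximum-information-spanning-tree (MIST) aggregation.

#' Dihedral angle of four points
#'
#' Standard signed dihedral in radians, `(-pi, pi]`; returns `NA` (flagged
#' missing) when three consecutive points are collinear so the dihedral is
#' undefined.
#'
#' @param p 4 x 3 matrix of positions.
#' @return angle in radians or `NA`.
#' @export
dihedral <- function(p) {
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20) return(NA_real_)
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  bn <- sqrt(sum(b2^2))
  atan2(sum(m1 * n2) / bn, sum(n1 * n2))
}

#' Extract backbone torsions from chain trajectories
#'
#' Computes the dihedral of every four consecutive chain atoms for every
#' chain and frame.  Identical chains are pooled: observations are (frame,
#' chain) pairs.  The `cutoff` does not select torsions; it defines the
#' spatial neighborhood (distance between torsion central bonds, first
#' frame) within which pairwise correlations are later considered by
#' [mist_total()].
#'
#' @param frames list of [frame()] objects.
#' @param top matching [topology()] with at least one chain; all chains
#'   must have equal length.
#' @param cutoff neighborhood distance for correlated treatment (nm).
#' @return A [torsion_samples()] whose `positions` field holds per-torsion
#'   reference coordinates and with attribute `cutoff`.
#' @export
extract_torsions <- function(frames, top, cutoff = 0.8) {
  .assert(length(top$chains) >= 1L, "topology has no chains")
  lens <- vapply(top$chains, function(ch) length(ch$masses), 0L)
  .assert(length(unique(lens)) == 1L, "chains must have equal length to pool")
  nb <- lens[1]
  .assert(nb >= 4L, "need at least 4 atoms per chain for a torsion")
  nt <- nb - 3L
  nC <- length(top$chains); nF <- length(frames)
  samples <- matrix(NA_real_, nF * nC, nt)
  for (f in seq_len(nF)) {
    fr <- frames[[f]]
    for (c_ in seq_len(nC)) {
      rows <- .chain_rows(top, c_)
      p <- fr$positions[rows, , drop = FALSE]
      for (t_ in seq_len(nt))
        samples[(f - 1L) * nC + c_, t_] <- dihedral(p[t_ + 0:3, , drop = FALSE])
    }
  }
  # torsion reference position: midpoint of the central bond, first frame,
  # first chain (identical chains assumed similar enough for gating)
  p1 <- frames[[1]]$positions[.chain_rows(top, 1L), , drop = FALSE]
  cpos <- t(vapply(seq_len(nt),
                   function(t_) (p1[t_ + 1L, ] + p1[t_ + 2L, ]) / 2,
                   numeric(3)))
  structure(torsion_samples(samples,
                            labels = paste0("tor", seq_len(nt)),
                            n_frames = nF, n_chains = nC, positions = cpos),
            cutoff = cutoff)
}

# deterministic de-duplication jitter, logged by callers
.jitter_dups <- function(x, tol = 0) {
  n <- length(x)
  dup <- duplicated(x)
  if (any(dup)) {
    idx <- which(dup)
    x[idx] <- x[idx] + 1e-10 * ((idx %% 97) + 1)
    warning(sum(dup), " duplicate torsion samples jittered by ~1e-10 rad",
            call. = FALSE)
  }
  x
}

#' k-nearest-neighbor entropy of a circular variable
#'
#' Kozachenko-Leonenko estimator with wrap-around distance on the circle:
#' `H = psi(n) - psi(k) + ln(2) + mean(ln eps_i)` (nats), where `eps_i` is
#' the distance to the k-th nearest neighbor.  Exact duplicates are
#' deterministically jittered by ~1e-10 rad with a warning.
#'
#' @param x samples in radians.
#' @param k neighbor order (default 1).
#' @return entropy in nats.
#' @export
knn_entropy <- function(x, k = 1L) {
  n <- length(x)
  .assert(n > k + 1L, "need more than k + 1 samples")
  x <- .jitter_dups(.wrap_angle(x))
  eps <- .cpp_knn_torus(matrix(x, ncol = 1), as.integer(k), 2 * pi)
  eps <- pmax(eps, 1e-300)
  digamma(n) - digamma(k) + log(2) + mean(log(eps))
}

# joint KL entropy on the 2-torus (Euclidean balls, c_2 = pi)
.knn_entropy_2d <- function(x, y, k = 1L) {
  n <- length(x)
  xy <- cbind(.jitter_dups(.wrap_angle(x)), .jitter_dups(.wrap_angle(y)))
  eps <- .cpp_knn_torus(xy, as.integer(k), 2 * pi)
  eps <- pmax(eps, 1e-300)
  digamma(n) - digamma(k) + log(pi) + 2 * mean(log(eps))
}

#' Mutual information of two circular variables
#'
#' Plug-in kNN estimate `I = H(X) + H(Y) - H(X, Y)`, clipped to
#' `[0, min(H(X), H(Y))]` when the marginals are informative (the upper
#' clip guards the near-deterministic coupling limit, where the joint
#' differential entropy is unbounded below and the spanning-tree total
#' should collapse onto a single marginal).
#'
#' @param x,y samples in radians.
#' @param k neighbor order.
#' @return mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y, k = 1L) {
  hx <- knn_entropy(x, k); hy <- knn_entropy(y, k)
  mi <- hx + hy - .knn_entropy_2d(x, y, k)
  cap <- min(hx, hy)
  if (cap > 0) mi <- min(mi, cap)
  max(mi, 0)
}

#' MIST conformational entropy of a torsion set
#'
#' First-order maximum-information-spanning-tree total:
#' `S = sum_i H_i - sum_(edges) I_ij`, with the maximum spanning tree taken
#' over the pairwise mutual-information graph (restricted, when the
#' samples carry positions, to torsion pairs whose central bonds lie
#' within the extraction cutoff).  Marginal entropies and MI are kNN
#' estimates on the circle/torus.
#'
#' @param ts a [torsion_samples()].
#' @param k neighbor order.
#' @param T temperature (K) used for the J mol^-1 K^-1 conversion.
#' @return A `ct_entropy_estimate`: list with `marginals` (nats),
#'   `mi_edges` (data.frame of retained tree edges), `total_nats`,
#'   `S_conf` (J mol^-1 K^-1) and `per_variable` table.
#' @export
mist_total <- function(ts, k = 1L, T = 300) {
  x <- ts$samples
  p <- ncol(x)
  keep <- stats::complete.cases(x)
  x <- x[keep, , drop = FALSE]
  H <- vapply(seq_len(p), function(j) knn_entropy(x[, j], k), 0)
  if (p == 1L) {
    return(structure(list(marginals = H, mi_edges = NULL,
                          total_nats = H, S_conf = .ct$R * H,
                          labels = ts$labels),
                     class = "ct_entropy_estimate"))
  }
  allowed <- matrix(TRUE, p, p)
  cutoff <- attr(ts, "cutoff")
  if (!is.null(ts$positions) && !is.null(cutoff)) {
    d <- as.matrix(stats::dist(ts$positions))
    allowed <- d <= cutoff
  }
  mi <- matrix(0, p, p)
  for (i in seq_len(p - 1L))
    for (j in (i + 1L):p)
      if (allowed[i, j])
        mi[i, j] <- mi[j, i] <- mutual_information(x[, i], x[, j], k)
  # Prim's algorithm for the maximum spanning tree over MI weights
  intree <- c(1L, rep(NA_integer_, p - 1L))
  best_w <- mi[1L, ]; best_from <- rep(1L, p)
  edges <- data.frame(from = integer(0), to = integer(0), mi = numeric(0))
  for (step in seq_len(p - 1L)) {
    cand <- setdiff(seq_len(p), intree)
    j <- cand[which.max(best_w[cand])]
    edges <- rbind(edges, data.frame(from = best_from[j], to = j, mi = best_w[j]))
    intree <- c(intree[!is.na(intree)], j)
    upd <- cand[mi[j, cand] > best_w[cand]]
    best_w[upd] <- mi[j, upd]; best_from[upd] <- j
  }
  total <- sum(H) - sum(edges$mi)
  structure(list(marginals = H, mi_edges = edges, total_nats = total,
                 S_conf = .ct$R * total, labels = ts$labels),
            class = "ct_entropy_estimate")
}

#' @export
print.ct_entropy_estimate <- function(x, ...) {
  cat("<ct_entropy_estimate> ", length(x$marginals), " torsions; total ",
      signif(x$total_nats, 6), " nats = ", signif(x$S_conf, 6),
      " J mol^-1 K^-1 (rough estimate)\n", sep = "")
  invisible(x)
}

#' Conformational entropy change between dense and dilute states
#'
#' `Delta S_P = S_P(dense) - S_P(dilute)` with the free-energy contribution
#' `-T Delta S_P` in kJ/mol.  Positive `-T Delta S_P` means the
#' conformational restriction in the condensate opposes its formation.
#' The result is declared a rough estimate in reports: torsion-based
#' estimators inherit the sampling limitations of the underlying
#' trajectories.
#'
#' @param dense,dilute `ct_entropy_estimate` objects over the same
#'   variable set.
#' @param T temperature (K).
#' @return list with `dS_P` (J mol^-1 K^-1), `minus_TdS` (kJ/mol),
#'   `dS_nats`.
#' @export
delta_conf_entropy <- function(dense, dilute, T = 300) {
  .assert(length(dense$marginals) == length(dilute$marginals) &&
            identical(dense$labels, dilute$labels),
          paste0("variable sets differ: dense has ",
                 length(dense$marginals), ", dilute has ",
                 length(dilute$marginals)))
  d_nats <- dense$total_nats - dilute$total_nats
  dS <- .ct$R * d_nats
  list(dS_nats = d_nats, dS_P = dS, minus_TdS = -T * dS / 1000,
       note = "rough estimate; torsion-based NN/MIST entropy")
}
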