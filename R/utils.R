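`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoid-rule quadrature
#' @param x abscissae (sorted, uniform not required)
#' @param y ordinates
#' @return scalar integral
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Minimum-image displacement
#'
#' Wraps Cartesian displacement components into `[-box/2, box/2)` for an
#' orthorhombic box.  All geometric operations in the package use this
#' convention; atoms themselves are allowed to lie outside the box.
#'
#' @param dx numeric vector or matrix of displacement components (nm); if a
#'   matrix, columns are x/y/z.
#' @param box length-3 numeric, orthorhombic edge lengths (nm).
#' @return object of the same shape as `dx`.
#' @export
min_image <- function(dx, box) {
  if (is.matrix(dx)) {
    for (k in seq_len(ncol(dx))) dx[, k] <- dx[, k] - box[k] * round(dx[, k] / box[k])
    dx
  } else {
    dx - box * round(dx / box)
  }
}

#' Minimum-image distance between two points
#' @param p1,p2 length-3 positions (nm)
#' @param box orthorhombic edge lengths (nm)
#' @return scalar distance (nm)
#' @export
min_image_dist <- function(p1, p2, box) {
  d <- min_image(p2 - p1, box)
  sqrt(sum(d * d))
}

# All-pairs minimum-image distance matrix between rows of a and rows of b.
# Returns length(a) x length(b) matrix.  Fine for the desk-scale systems
# this package targets (<= a few thousand points).
.pairdist <- function(a, b, box) {
  n <- nrow(a); m <- nrow(b)
  d2 <- matrix(0, n, m)
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}

# wrap angles into (-pi, pi]
.wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi  # map exactly -pi to +pi so support is (-pi, pi]
  y
}

.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
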