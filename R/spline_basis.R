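#' Place spline knots at empirical quantiles
#'
#' Builds the knot set used by the M-spline and I-spline bases of the two
#' baseline functions. Interior knots sit at the `j/(J+1)` empirical
#' quantiles of the supplied times (linear-interpolation quantiles);
#' boundary knots sit at the data range, expanded by a tiny symmetric
#' margin so every datum evaluates strictly inside the support.
#'
#' @param times numeric vector of time points driving knot placement
#'   (observation times for the longitudinal baseline, finite interval
#'   endpoints for the survival baseline).
#' @param n_interior number of interior knots `J >= 0`.
#' @param degree spline degree, 1 (linear), 2 (quadratic) or 3 (cubic).
#'   The basis has `K = J + degree + 1` functions.
#' @return an object of class `"knot_vector"`: a list with elements
#'   `interior`, `boundary` (length 2), `degree` and `n_basis`.
#' @examples
#' kn <- place_knots(c(1, 2, 3, 4, 5), n_interior = 3, degree = 3)
#' kn$n_basis  # 7
#' @export
place_knots <- function(times, n_interior = 3L, degree = 3L) {
  times <- as.numeric(times)
  stopifnot(length(times) >= 1L, all(is.finite(times)),
            n_interior >= 0L, degree %in% 1:3)
  rng <- range(times)
  if (rng[1] == rng[2]) stop("degenerate knot range: all times identical")
  pad <- 1e-8 * diff(rng)
  interior <- if (n_interior > 0L) {
    probs <- seq_len(n_interior) / (n_interior + 1)
    unname(stats::quantile(times, probs = probs, type = 7))
  } else numeric(0)
  if (any(interior <= rng[1] + pad) || any(interior >= rng[2] - pad) ||
      any(diff(interior) <= 0)) {
    # collapse duplicated quantiles (heavily tied data); keep unique, in-range
    interior <- unique(interior[interior > rng[1] & interior < rng[2]])
  }
  structure(list(interior = interior,
                 boundary = c(rng[1] - pad, rng[2] + pad),
                 degree = as.integer(degree),
                 n_basis = length(interior) + as.integer(degree) + 1L),
            class = "knot_vector")
}

#' @export
print.knot_vector <- function(x, ...) {
  cat(sprintf("knot_vector: degree %d, %d interior knot(s), %d basis functions\n",
              x$degree, length(x$interior), x$n_basis))
  cat("  boundary: [", format(x$boundary[1]), ", ", format(x$boundary[2]), "]\n", sep = "")
  if (length(x$interior)) cat("  interior:", paste(format(x$interior), collapse = " "), "\n")
  invisible(x)
}

# augmented knot sequence with `order` replicates of each boundary knot
.aug_knots <- function(knots, order) {
  c(rep(knots$boundary[1], order), knots$interior, rep(knots$boundary[2], order))
}

# Raw M-spline recursion on an augmented knot sequence `s` for a given order
# (order = degree + 1). Returns a length(x) x (length(s) - order) matrix.
# Order-1 functions are the normalized indicators 1/(s[i+1]-s[i]) on
# [s_i, s_{i+1}); recursion:
#   M_i^k(x) = k [ (x - s_i) M_i^{k-1}(x) + (s_{i+k} - x) M_{i+1}^{k-1}(x) ]
#              / ( (k-1) (s_{i+k} - s_i) )
.mspline_raw <- function(x, s, order) {
  nb <- length(s) - order
  n <- length(x)
  # order 1 bases over the full augmented sequence
  nb1 <- length(s) - 1L
  M <- matrix(0, n, nb1)
  for (i in seq_len(nb1)) {
    w <- s[i + 1L] - s[i]
    if (w > 0) {
      inside <- x >= s[i] & x < s[i + 1L]
      # close the last nonempty interval on the right
      if (s[i + 1L] == s[length(s)]) inside <- inside | (x == s[i + 1L])
      M[inside, i] <- 1 / w
    }
  }
  if (order == 1L) return(M[, seq_len(nb), drop = FALSE])
  for (k in 2:order) {
    nbk <- length(s) - k
    Mk <- matrix(0, n, nbk)
    for (i in seq_len(nbk)) {
      span <- s[i + k] - s[i]
      if (span > 0) {
        Mk[, i] <- k * ((x - s[i]) * M[, i] + (s[i + k] - x) * M[, i + 1L]) /
          ((k - 1) * span)
      }
    }
    M <- Mk
  }
  M[, seq_len(nb), drop = FALSE]
}

#' Evaluate an M-spline basis
#'
#' M-splines are nonnegative piecewise polynomials, each normalized to unit
#' integral over its local support, so nonnegative combinations behave like
#' mixtures of densities. Used for the longitudinal baseline mean.
#'
#' @param t numeric vector of evaluation points, inside the knot boundaries.
#' @param knots a [place_knots()] object.
#' @return numeric matrix, `length(t)` rows by `knots$n_basis` columns.
#' @export
mspline_basis <- function(t, knots) {
  stopifnot(inherits(knots, "knot_vector"))
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < knots$boundary[1]) || any(t > knots$boundary[2]))
    stop("evaluation points outside the spline boundaries")
  order <- knots$degree + 1L
  .mspline_raw(t, .aug_knots(knots, order), order)
}

#' Evaluate an I-spline basis
#'
#' Each I-spline is the running integral of the matching M-spline: 0 up to
#' the start of its support, increasing to 1, then flat at 1. Nonnegative
#' combinations are nondecreasing, which is what makes them suitable for the
#' monotone survival baseline. Evaluation above the upper boundary (including
#' `Inf`) returns the plateau value 1.
#'
#' @inheritParams mspline_basis
#' @return numeric matrix, `length(t)` rows by `knots$n_basis` columns,
#'   entries in `[0, 1]`, columnwise nondecreasing in `t`.
#' @export
ispline_basis <- function(t, knots) {
  stopifnot(inherits(knots, "knot_vector"))
  t <- as.numeric(t)
  if (any(is.na(t)) || any(t < knots$boundary[1] & is.finite(t)))
    stop("evaluation points below the spline lower boundary")
  hi <- t > knots$boundary[2]          # plateau region, Inf included
  tc <- ifelse(hi, knots$boundary[2], t)
  order <- knots$degree + 1L
  # integral identity: I_i(x) = sum_{m > i} B_{m, order+1}(x) on the knot
  # sequence augmented for order + 1, with B = span * M / order
  s2 <- .aug_knots(knots, order + 1L)
  M2 <- .mspline_raw(tc, s2, order + 1L)
  nb2 <- ncol(M2)
  B2 <- M2 * matrix((s2[(1:nb2) + order + 1L] - s2[1:nb2]) / (order + 1),
                    nrow(M2), nb2, byrow = TRUE)
  # tail cumulative sums: column i of the I-basis = sum of B2 columns i+1..nb2
  revcs <- t(apply(B2[, rev(seq_len(nb2)), drop = FALSE], 1L, cumsum))
  if (nrow(B2) == 1L) revcs <- matrix(revcs, 1L)
  out <- revcs[, rev(seq_len(nb2)), drop = FALSE][, -1L, drop = FALSE]
  out[hi, ] <- 1
  # clamp tiny numerical excursions
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}
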