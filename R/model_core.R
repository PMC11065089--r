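#' Construct a joint longitudinal / interval-censored dataset
#'
#' Bundles the three tables of a joint analysis into one validated object:
#' longitudinal measurements (subject id, time, response), censoring
#' intervals `(L, R]` with `L = 0` encoding left censoring and `R = Inf`
#' right censoring, and a shared covariate matrix used by both submodels.
#'
#' @param longitudinal data.frame with columns `id`, `time`, `y`.
#' @param survival data.frame with columns `id`, `left`, `right`. `right`
#'   may be `Inf`/`NA` for right-censored subjects.
#' @param covariates data.frame with column `id` plus `p` numeric covariate
#'   columns, one row per subject.
#' @param standardize logical; if `TRUE`, covariate columns with more than
#'   two distinct values are centered and scaled to unit variance.
#' @return an object of class `"joint_dataset"`: list with `id`, `times`
#'   and `y` (per-subject lists), `m` (visit counts), `left`, `right`,
#'   `delta` (1 = left-, 2 = interval-, 3 = right-censored), `X` (n x p
#'   matrix), `n`, `p`.
#' @export
joint_dataset <- function(longitudinal, survival, covariates, standardize = FALSE) {
  stopifnot(all(c("id", "time", "y") %in% names(longitudinal)),
            all(c("id", "left", "right") %in% names(survival)),
            "id" %in% names(covariates))
  ids <- survival$id
  if (anyDuplicated(ids)) stop("duplicated subject ids in the survival table")
  if (!setequal(ids, covariates$id))
    stop("subject ids differ between survival and covariate tables")
  if (!all(longitudinal$id %in% ids))
    stop("longitudinal table contains ids absent from the survival table")
  covariates <- covariates[match(ids, covariates$id), , drop = FALSE]
  X <- as.matrix(covariates[, setdiff(names(covariates), "id"), drop = FALSE])
  storage.mode(X) <- "double"
  if (standardize) {
    for (j in seq_len(ncol(X))) {
      if (length(unique(X[, j])) > 2L) X[, j] <- as.numeric(scale(X[, j]))
    }
  }
  L <- as.numeric(survival$left)
  R <- as.numeric(survival$right)
  R[is.na(R)] <- Inf
  bad <- which(!(L >= 0 & L < R))
  if (length(bad))
    stop("invalid censoring interval (need 0 <= L < R) at survival row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (any(longitudinal$time < 0))
    stop("negative observation times in the longitudinal table")
  delta <- ifelse(L == 0, 1L, ifelse(is.infinite(R), 3L, 2L))
  if (any(delta == 1L & is.infinite(R)))
    stop("subjects with L = 0 and R = Inf carry no event information")
  ord <- order(longitudinal$id, longitudinal$time)
  longitudinal <- longitudinal[ord, ]
  sp <- split(seq_len(nrow(longitudinal)), factor(longitudinal$id, levels = ids))
  m <- lengths(sp)
  if (any(m < 1L)) stop("every subject needs at least one longitudinal record")
  structure(list(id = ids,
                 times = lapply(sp, function(ix) longitudinal$time[ix]),
                 y = lapply(sp, function(ix) longitudinal$y[ix]),
                 m = as.integer(m),
                 left = L, right = R, delta = delta,
                 X = X, n = length(ids), p = ncol(X)),
            class = "joint_dataset")
}

#' @export
print.joint_dataset <- function(x, ...) {
  cat(sprintf("joint_dataset: %d subjects, %d covariates, %d longitudinal records\n",
              x$n, x$p, sum(x$m)))
  cat(sprintf("  censoring: %d left / %d interval / %d right\n",
              sum(x$delta == 1L), sum(x$delta == 2L), sum(x$delta == 3L)))
  invisible(x)
}

# anchor time t_i: R_i for left-censored subjects, L_i otherwise
anchor_times <- function(dataset) {
  ifelse(dataset$delta == 1L, dataset$right, dataset$left)
}

#' Evaluate the longitudinal baseline mean
#'
#' The baseline mean is a free linear combination of M-splines,
#' `mu(t) = sum_h eta_h M_h(t)`.
#'
#' @param eta spline coefficient vector (length `knots$n_basis`).
#' @param knots [place_knots()] object for the longitudinal baseline.
#' @param t evaluation points.
#' @return numeric vector of baseline values.
#' @export
mu_eval <- function(eta, knots, t) {
  stopifnot(length(eta) == knots$n_basis)
  drop(mspline_basis(t, knots) %*% eta)
}

#' Evaluate the monotone survival baseline
#'
#' `alpha(t) = r0 + sum_k r_k b_k(t)` with I-spline bases `b_k` and
#' nonnegative coefficients `r_k`, so the function is nondecreasing.
#'
#' @param r0 unconstrained intercept.
#' @param r nonnegative spline coefficient vector (length `knots$n_basis`).
#' @param knots [place_knots()] object for the survival baseline.
#' @param t evaluation points; `Inf` allowed (plateau).
#' @return numeric vector of baseline values.
#' @export
alpha_eval <- function(r0, r, knots, t) {
  stopifnot(length(r) == knots$n_basis)
  if (any(r < 0)) stop("negative I-spline coefficients: alpha would not be monotone")
  r0 + drop(ispline_basis(t, knots) %*% r)
}

#' Censoring region of the latent probit variable
#'
#' In the augmented model each subject carries a unit-variance normal latent
#' variable constrained to a region determined by its censoring type:
#' `(0, Inf)` when left-censored, `(alpha(L) - alpha(R), 0)` when
#' interval-censored, `(-Inf, 0)` when right-censored.
#'
#' @param delta censoring indicator (1, 2 or 3).
#' @param alpha_L,alpha_R baseline values at the interval endpoints (only
#'   used for interval-censored subjects).
#' @return two-column matrix of region bounds (`lower`, `upper`).
#' @export
region_C <- function(delta, alpha_L = NULL, alpha_R = NULL) {
  n <- length(delta)
  lo <- rep(-Inf, n); hi <- rep(0, n)
  lo[delta == 1L] <- 0; hi[delta == 1L] <- Inf
  ic <- which(delta == 2L)
  if (length(ic)) {
    if (is.null(alpha_L) || is.null(alpha_R))
      stop("interval-censored subjects need alpha at both endpoints")
    dif <- alpha_L[ic] - alpha_R[ic]
    if (any(dif >= 0)) stop("nonmonotone alpha: alpha(L) >= alpha(R)")
    lo[ic] <- dif
  }
  cbind(lower = lo, upper = hi)
}

#' Closed-form Kendall's tau between the two responses
#'
#' Under the joint model the association between a longitudinal measurement
#' and the probit-transformed event time is free of covariates:
#' `rho = -sigma_u^2 / sqrt((1 + sigma_u^2)(sigma_eps^2 + sigma_xi^2 + sigma_u^2))`
#' and `tau = (2/pi) asin(rho)`. Both lie in `(-1, 0]`; a shared frailty of
#' zero variance gives independence, and tau decreases toward -1 as the
#' shared-frailty variance grows.
#'
#' @param sigma_u2 shared-frailty variance (>= 0).
#' @param sigma_xi2 longitudinal-frailty variance (> 0).
#' @param sigma_eps2 measurement-error variance (> 0).
#' @return list with `rho` (Pearson correlation) and `tau` (Kendall).
#' @export
kendall_tau <- function(sigma_u2, sigma_xi2, sigma_eps2) {
  if (any(sigma_u2 < 0) || any(sigma_xi2 <= 0) || any(sigma_eps2 <= 0))
    stop("variances must be positive (sigma_u2 may be zero)")
  rho <- -sigma_u2 / sqrt((1 + sigma_u2) * (sigma_eps2 + sigma_xi2 + sigma_u2))
  list(rho = rho, tau = 2 / pi * asin(rho))
}

#' Complete-data log likelihood
#'
#' Log of the augmented-data likelihood: normal densities of the
#' longitudinal measurements given the baseline mean, covariate effects and
#' frailties; unit-variance normal densities of the latent probit variables
#' centered at `alpha(t_i) + X_i'beta + u_i`; and the frailty densities.
#' The region indicator contributes 0 when every latent variable lies in its
#' censoring region and `-Inf` otherwise.
#'
#' @param dataset a [joint_dataset()].
#' @param state list with elements `z`, `eta`, `r0`, `r`, `beta`, `theta`,
#'   `u`, `xi`, `sigma_u2`, `sigma_xi2`, `sigma_eps2`.
#' @param knots_mu,knots_alpha [place_knots()] objects for the two baselines.
#' @return scalar log likelihood (possibly `-Inf`).
#' @export
complete_log_likelihood <- function(dataset, state, knots_mu, knots_alpha) {
  ti <- anchor_times(dataset)
  a_ti <- alpha_eval(state$r0, state$r, knots_alpha, ti)
  ic <- dataset$delta == 2L
  aL <- aR <- rep(NA_real_, dataset$n)
  if (any(ic)) {
    aL[ic] <- alpha_eval(state$r0, state$r, knots_alpha, dataset$left[ic])
    aR[ic] <- alpha_eval(state$r0, state$r, knots_alpha, dataset$right[ic])
  }
  Cb <- region_C(dataset$delta, aL, aR)
  if (any(state$z <= Cb[, 1] | state$z >= Cb[, 2])) return(-Inf)
  xb <- drop(dataset$X %*% state$beta)
  xt <- drop(dataset$X %*% state$theta)
  ll <- sum(stats::dnorm(state$z, a_ti + xb + state$u, 1, log = TRUE)) +
    sum(stats::dnorm(state$u, 0, sqrt(state$sigma_u2), log = TRUE)) +
    sum(stats::dnorm(state$xi, 0, sqrt(state$sigma_xi2), log = TRUE))
  for (i in seq_len(dataset$n)) {
    mu_ij <- mu_eval(state$eta, knots_mu, dataset$times[[i]])
    ll <- ll + sum(stats::dnorm(dataset$y[[i]],
                                mu_ij + xt[i] + state$u[i] + state$xi[i],
                                sqrt(state$sigma_eps2), log = TRUE))
  }
  ll
}
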