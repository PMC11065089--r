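#' Simulation design for joint longitudinal / interval-censored data
#'
#' Captures the data-generating conditions of the package's simulation
#' engine: Poisson visit counts (`min(Pois(3) + 1, 10)` by default),
#' exponential gap times (mean 0.5), baseline functions
#' `mu(t) = 4 log(t + 1) - 2 t` and `alpha(t) = 2 log(t) + t^2`, normal
#' frailties and errors, and probit-link event times. Two built-in
#' coefficient scenarios: `"I"` has p = 10 with
#' `theta = (1,0,1,0,1,0,1,0,1,0)` and `beta = (1,1,0,0,1,1,0,0,1,0)`;
#' `"II"` has p = 30 with `theta = (rep(1,10), rep(0,20))` and
#' `beta = (rep(1,5), rep(0,5), rep(1,5), rep(0,15))`. Half the covariates
#' are Bernoulli(0.5) (the leading block), half N(0,1).
#'
#' @param n number of subjects.
#' @param scenario `"I"`, `"II"`, or `"custom"` (then supply `theta_true`
#'   and `beta_true`).
#' @param theta_true,beta_true coefficient vectors for a custom scenario.
#' @param sigma_u2,sigma_xi2,sigma_eps2 true variances.
#' @param visit_rate_mean Poisson mean of the visit-count distribution.
#' @param visit_cap maximum number of visits per subject.
#' @param gap_mean mean of the exponential gap times between visits.
#' @param mu_true,alpha_true baseline functions; `alpha_true` must be
#'   strictly increasing with range covering the needed probit scores.
#' @return an object of class `"sim_design"`.
#' @export
simulation_design <- function(n = 500L, scenario = c("I", "II", "custom"),
                              theta_true = NULL, beta_true = NULL,
                              sigma_u2 = 0.25, sigma_xi2 = 0.25,
                              sigma_eps2 = 1,
                              visit_rate_mean = 3, visit_cap = 10L,
                              gap_mean = 0.5,
                              mu_true = function(t) 4 * log(t + 1) - 2 * t,
                              alpha_true = function(t) 2 * log(t) + t^2) {
  scenario <- match.arg(scenario)
  if (scenario == "I") {
    theta_true <- rep(c(1, 0), 5)
    beta_true <- c(1, 1, 0, 0, 1, 1, 0, 0, 1, 0)
  } else if (scenario == "II") {
    theta_true <- c(rep(1, 10), rep(0, 20))
    beta_true <- c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 15))
  } else if (is.null(theta_true) || is.null(beta_true) ||
             length(theta_true) != length(beta_true)) {
    stop("custom scenario needs theta_true and beta_true of equal length")
  }
  stopifnot(n >= 1L, visit_cap >= 1L, gap_mean > 0,
            sigma_u2 >= 0, sigma_xi2 > 0, sigma_eps2 > 0)
  structure(list(n = as.integer(n), scenario = scenario,
                 theta_true = as.numeric(theta_true),
                 beta_true = as.numeric(beta_true),
                 p = length(theta_true),
                 sigma_u2 = sigma_u2, sigma_xi2 = sigma_xi2,
                 sigma_eps2 = sigma_eps2,
                 visit_rate_mean = visit_rate_mean,
                 visit_cap = as.integer(visit_cap), gap_mean = gap_mean,
                 mu_true = mu_true, alpha_true = alpha_true),
            class = "sim_design")
}

#' Simulate the examination schedule
#'
#' Visit counts are `min(Pois(visit_rate_mean) + 1, visit_cap)`; visit times
#' are cumulative sums of iid exponential gaps. Uses the current RNG state.
#'
#' @param design a [simulation_design()].
#' @return list of strictly increasing visit-time vectors, one per subject.
#' @export
simulate_schedule <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  m <- pmin(stats::rpois(design$n, design$visit_rate_mean) + 1L,
            design$visit_cap)
  lapply(m, function(mi)
    cumsum(stats::rexp(mi, rate = 1 / design$gap_mean)))
}

#' Invert a strictly increasing baseline function
#'
#' Bracketing bisection with geometric bracket expansion, used to transform
#' probit scores into event times. Converges to `|alpha(t) - c| < 1e-10`.
#'
#' @param c target value (vectorized).
#' @param alpha_true strictly increasing function with
#'   `alpha_true(t) -> -Inf` as `t -> 0`.
#' @return time(s) `t` with `alpha_true(t) = c`.
#' @export
invert_alpha <- function(c, alpha_true = function(t) 2 * log(t) + t^2) {
  vapply(c, function(ci) {
    lo <- 1; hi <- 1
    for (k in 1:200) { if (alpha_true(lo) < ci) break; lo <- lo / 2 }
    if (alpha_true(lo) >= ci) stop("invert_alpha: cannot bracket from below")
    for (k in 1:200) { if (alpha_true(hi) > ci) break; hi <- hi * 2 }
    if (alpha_true(hi) <= ci) stop("invert_alpha: cannot bracket from above")
    while (hi - lo > 1e-13 * max(1, hi)) {
      mid <- 0.5 * (lo + hi)
      if (alpha_true(mid) < ci) lo <- mid else hi <- mid
    }
    0.5 * (lo + hi)
  }, numeric(1))
}

#' Simulate a joint dataset with known truth
#'
#' Generates covariates (first half Bernoulli(0.5), second half N(0,1)),
#' frailties and errors, longitudinal responses from the mixed-effects
#' submodel, and event times by probit-CDF inversion:
#' `T = alpha^{-1}(qnorm(U) - X'beta - u)` with `U ~ Unif(0,1)`. The
#' observed interval is formed by the two adjacent points of
#' `{0, t_1, ..., t_m, Inf}` that bracket `T` (`T` in `(L, R]`), which also
#' fixes the censoring type.
#'
#' @param design a [simulation_design()].
#' @param seed optional integer seed.
#' @return list with `dataset` (a [joint_dataset()]) and `truth` (true
#'   coefficient vectors, variances, per-subject event times and frailties).
#' @export
simulate_joint <- function(design, seed = NULL) {
  stopifnot(inherits(design, "sim_design"))
  if (!is.null(seed)) set.seed(seed)
  n <- design$n; p <- design$p
  times <- simulate_schedule(design)
  m <- lengths(times)
  p_bin <- floor(p / 2)
  X <- cbind(matrix(stats::rbinom(n * p_bin, 1L, 0.5), n, p_bin),
             matrix(stats::rnorm(n * (p - p_bin)), n, p - p_bin))
  colnames(X) <- paste0("x", seq_len(p))
  u <- stats::rnorm(n, 0, sqrt(design$sigma_u2))
  xi <- stats::rnorm(n, 0, sqrt(design$sigma_xi2))
  xb <- drop(X %*% design$beta_true)
  xt <- drop(X %*% design$theta_true)
  y <- vector("list", n)
  for (i in seq_len(n)) {
    y[[i]] <- design$mu_true(times[[i]]) + xt[i] + u[i] + xi[i] +
      stats::rnorm(m[i], 0, sqrt(design$sigma_eps2))
  }
  U <- stats::runif(n)
  Tev <- invert_alpha(stats::qnorm(U) - xb - u, design$alpha_true)
  L <- R <- numeric(n)
  for (i in seq_len(n)) {
    grid <- c(0, times[[i]])
    k <- findInterval(Tev[i], grid, left.open = TRUE)  # T in (grid[k], grid[k+1]]
    L[i] <- grid[k]
    R[i] <- if (k == length(grid)) Inf else grid[k + 1L]
  }
  long <- data.frame(id = rep(seq_len(n), m),
                     time = unlist(times, use.names = FALSE),
                     y = unlist(y, use.names = FALSE))
  surv <- data.frame(id = seq_len(n), left = L, right = R)
  cov <- data.frame(id = seq_len(n), X)
  list(dataset = joint_dataset(long, surv, cov),
       truth = list(theta = design$theta_true, beta = design$beta_true,
                    sigma_u2 = design$sigma_u2,
                    sigma_xi2 = design$sigma_xi2,
                    sigma_eps2 = design$sigma_eps2,
                    tau = kendall_tau(design$sigma_u2, design$sigma_xi2,
                                      design$sigma_eps2)$tau,
                    T = Tev, u = u, xi = xi))
}
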