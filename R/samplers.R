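#' Truncated normal random draws
#'
#' Draws from `N(mean, sd^2)` restricted to `(lower, upper)`. The sampler is
#' tail-robust: regions lying many standard deviations from the mean are
#' handled by a tail-parametrized inverse CDF with an exponential-rejection
#' fallback, not naive rejection.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters (recycled).
#' @param lower,upper truncation bounds (recycled; either may be infinite).
#' @return numeric vector of `n` draws inside `(lower, upper)`.
#' @export
rtruncnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  if (any(lower >= upper)) stop("rtruncnorm: lower >= upper")
  cpp_rtruncnorm(as.integer(n), as.numeric(mean), as.numeric(sd),
                 as.numeric(lower), as.numeric(upper))
}

#' Inverse-Gaussian random draws
#'
#' Mean/shape parametrization: density proportional to
#' `x^{-3/2} exp(-shape (x - mean)^2 / (2 mean^2 x))`, with `E X = mean` and
#' `Var X = mean^3 / shape`.
#'
#' @param n number of draws.
#' @param mean,shape positive parameters (recycled).
#' @return numeric vector of `n` strictly positive draws.
#' @export
rinvgauss <- function(n, mean, shape) {
  if (any(mean <= 0) || any(shape <= 0))
    stop("rinvgauss: mean and shape must be positive")
  cpp_rinvgauss(as.integer(n), as.numeric(mean), as.numeric(shape))
}

#' Prior configuration for the joint Gibbs samplers
#'
#' Assembles every hyperparameter of the four sampler variants. The defaults
#' are weakly informative: Ga(0.1, 0.1) on the three precisions, N(-6, 1) on
#' the survival-baseline intercept, Ga(1, 1) on the exponential rate of the
#' monotone-spline coefficients, N(0, 100 I) on the longitudinal-baseline
#' spline coefficients, Ga(1, 2) on the Lasso penalties, Beta(1, 1) on the
#' spike-and-slab inclusion probabilities with spike/slab variances
#' 0.01 / 100 (one Beta-distributed inclusion probability per coefficient),
#' and N(0, 100 I) on both coefficient vectors under the general normal
#' ("GB") variant.
#'
#' @param variant one of `"BL"` (Bayesian Lasso), `"BAL"` (Bayesian adaptive
#'   Lasso), `"SS"` (spike-and-slab), `"GB"` (general normal priors).
#' @param a_u,b_u,a_xi,b_xi,a_eps,b_eps gamma hyperparameters of the
#'   shared-frailty, longitudinal-frailty and error precisions.
#' @param m0,v0 normal prior mean and precision of the baseline intercept.
#' @param a_rho,b_rho gamma hyperparameters of the exponential rate on the
#'   monotone-spline coefficients.
#' @param eta0,Sigma_eta prior mean and covariance of the longitudinal
#'   spline coefficients; scalars are expanded at fit time.
#' @param a_lambda,b_lambda gamma hyperparameters of the Lasso penalties.
#' @param a_omega,b_omega beta hyperparameters of the inclusion
#'   probabilities (spike-and-slab).
#' @param sigma_spike2,sigma_slab2 spike and slab variances; the spike must
#'   be the smaller.
#' @param beta0,Sigma_beta,theta0,Sigma_theta normal prior parameters of the
#'   regression coefficients under the `"GB"` variant.
#' @return an object of class `"jm_prior"`.
#' @export
prior_config <- function(variant = c("BL", "BAL", "SS", "GB"),
                         a_u = 0.1, b_u = 0.1, a_xi = 0.1, b_xi = 0.1,
                         a_eps = 0.1, b_eps = 0.1,
                         m0 = -6, v0 = 1, a_rho = 1, b_rho = 1,
                         eta0 = 0, Sigma_eta = 100,
                         a_lambda = 1, b_lambda = 2,
                         a_omega = 1, b_omega = 1,
                         sigma_spike2 = 0.01, sigma_slab2 = 100,
                         beta0 = 0, Sigma_beta = 100,
                         theta0 = 0, Sigma_theta = 100) {
  variant <- match.arg(variant)
  scalars <- c(a_u = a_u, b_u = b_u, a_xi = a_xi, b_xi = b_xi,
               a_eps = a_eps, b_eps = b_eps, v0 = v0,
               a_rho = a_rho, b_rho = b_rho,
               a_lambda = a_lambda, b_lambda = b_lambda,
               a_omega = a_omega, b_omega = b_omega,
               sigma_spike2 = sigma_spike2, sigma_slab2 = sigma_slab2)
  if (any(scalars <= 0))
    stop("nonpositive prior hyperparameter: ",
         paste(names(scalars)[scalars <= 0], collapse = ", "))
  if (sigma_spike2 >= sigma_slab2)
    stop("the spike variance must be smaller than the slab variance")
  structure(list(variant = variant,
                 variant_code = match(variant, c("BL", "BAL", "SS", "GB")),
                 a_u = a_u, b_u = b_u, a_xi = a_xi, b_xi = b_xi,
                 a_eps = a_eps, b_eps = b_eps, m0 = m0, v0 = v0,
                 a_rho = a_rho, b_rho = b_rho,
                 eta0 = eta0, Sigma_eta = Sigma_eta,
                 a_lambda = a_lambda, b_lambda = b_lambda,
                 a_omega = a_omega, b_omega = b_omega,
                 sigma_spike2 = sigma_spike2, sigma_slab2 = sigma_slab2,
                 beta0 = beta0, Sigma_beta = Sigma_beta,
                 theta0 = theta0, Sigma_theta = Sigma_theta),
            class = "jm_prior")
}

# expand scalar prior settings to the dimensions of a prepared dataset and
# pre-invert the fixed covariance matrices
expand_prior <- function(prior, p, K_mu) {
  ex <- function(x, d) if (length(x) == 1L) rep(x, d) else {
    stopifnot(length(x) == d); as.numeric(x)
  }
  exm <- function(x, d) {
    if (is.matrix(x)) { stopifnot(nrow(x) == d, ncol(x) == d); solve(x) }
    else diag(1 / ex(x, d), d)
  }
  out <- unclass(prior)
  out$eta0 <- ex(prior$eta0, K_mu)
  out$Sigma_eta_inv <- exm(prior$Sigma_eta, K_mu)
  out$beta0 <- ex(prior$beta0, p)
  out$theta0 <- ex(prior$theta0, p)
  out$Sigma_beta_inv <- exm(prior$Sigma_beta, p)
  out$Sigma_theta_inv <- exm(prior$Sigma_theta, p)
  out
}

#' Precompute the fixed quantities a Gibbs chain needs
#'
#' Evaluates the two spline bases at all the time points the sampler touches
#' (longitudinal observation times; anchor times; interval endpoints of
#' interval-censored subjects) and the cross-product matrices of the two
#' normal-linear updates. Knot placement follows the study convention: the
#' longitudinal-baseline knots come from the observation times, the
#' survival-baseline knots from the finite interval endpoints.
#'
#' @param dataset a [joint_dataset()].
#' @param n_interior,degree spline settings shared by both baselines.
#' @param knots_mu,knots_alpha optional pre-built [place_knots()] objects
#'   overriding the data-driven placement.
#' @return list with the basis matrices, index vectors, cross-products and
#'   the two knot objects; input to [update_blocks()] and the chain runner.
#' @export
prepare_joint <- function(dataset, n_interior = 3L, degree = 3L,
                          knots_mu = NULL, knots_alpha = NULL) {
  stopifnot(inherits(dataset, "joint_dataset"))
  all_t <- unlist(dataset$times, use.names = FALSE)
  if (is.null(knots_mu)) knots_mu <- place_knots(all_t, n_interior, degree)
  if (is.null(knots_alpha)) {
    ep <- c(dataset$left[dataset$left > 0],
            dataset$right[is.finite(dataset$right)])
    knots_alpha <- place_knots(ep, n_interior, degree)
  }
  ti <- anchor_times(dataset)
  ic <- which(dataset$delta == 2L)
  Banchor <- ispline_basis(ti, knots_alpha)
  Bdiff <- if (length(ic)) {
    ispline_basis(dataset$right[ic], knots_alpha) -
      ispline_basis(dataset$left[ic], knots_alpha)
  } else matrix(0, 0L, knots_alpha$n_basis)
  Mlong <- mspline_basis(all_t, knots_mu)
  subj <- rep(seq_len(dataset$n), dataset$m) - 1L
  list(y = unlist(dataset$y, use.names = FALSE),
       subj = as.integer(subj),
       Mlong = Mlong,
       X = dataset$X,
       m = as.numeric(dataset$m),
       delta = as.integer(dataset$delta),
       Banchor = Banchor,
       ic = as.integer(ic - 1L),
       Bdiff = Bdiff,
       A = crossprod(Mlong),
       XtX = crossprod(dataset$X),
       XtmX = crossprod(dataset$X * sqrt(dataset$m)),
       knots_mu = knots_mu, knots_alpha = knots_alpha,
       n = dataset$n, p = dataset$p)
}

#' Initial chain state
#'
#' Deterministic except for the latent probit variables, which are drawn by
#' one pass of their truncated-normal update so every region constraint
#' holds from the first sweep: coefficients and frailties start at zero,
#' variances and scale mixtures at one, the baseline intercept at its prior
#' mean, and the monotone-spline coefficients at 0.1.
#'
#' @param prep output of [prepare_joint()].
#' @param prior a [prior_config()] object.
#' @return named list holding every latent variable and parameter of one
#'   Gibbs sweep.
#' @export
init_state <- function(prep, prior) {
  p <- prep$p
  K_alpha <- prep$knots_alpha$n_basis
  K_mu <- prep$knots_mu$n_basis
  n_lambda <- if (prior$variant == "BAL") p else 1L
  state <- list(z = numeric(prep$n),
                r0 = prior$m0, r = rep(0.1, K_alpha), rho = 1,
                beta = numeric(p), theta = numeric(p),
                tau_s2 = rep(1, p), tau_l2 = rep(1, p),
                lambda2_s = rep(1, n_lambda), lambda2_l = rep(1, n_lambda),
                delta_s = rep(1L, p), delta_l = rep(1L, p),
                omega_s = rep(0.5, p), omega_l = rep(0.5, p),
                eta = numeric(K_mu), u = numeric(prep$n), xi = numeric(prep$n),
                sigma_u2 = 1, sigma_xi2 = 1, sigma_eps2 = 1)
  update_blocks(state, prep, prior, "z")
}

#' Run selected full-conditional updates once
#'
#' Low-level access to the Gibbs blocks, mainly for testing the full
#' conditionals one at a time. Blocks: `"z"`, `"r0"`, `"r"`, `"rho"`,
#' `"beta"`, `"shrink_s"`, `"theta"`, `"shrink_l"`, `"eta"`, `"u"`,
#' `"sigma_u"`, `"xi"`, `"sigma_xi"`, `"sigma_eps"`, or `"all"` for one full
#' sweep in the variant's own order.
#'
#' @param state a chain state as produced by [init_state()].
#' @param prep output of [prepare_joint()].
#' @param prior a [prior_config()] object.
#' @param blocks character vector of block names.
#' @return the updated state list.
#' @export
update_blocks <- function(state, prep, prior, blocks = "all") {
  ep <- expand_prior(prior, prep$p, prep$knots_mu$n_basis)
  cpp_sweep(prep, state, ep, blocks)
}

#' @rdname update_blocks
#' @export
update_z <- function(state, prep, prior) update_blocks(state, prep, prior, "z")
#' @rdname update_blocks
#' @export
update_r0 <- function(state, prep, prior) update_blocks(state, prep, prior, "r0")
#' @rdname update_blocks
#' @export
update_r <- function(state, prep, prior) update_blocks(state, prep, prior, "r")
#' @rdname update_blocks
#' @export
update_rho_spline <- function(state, prep, prior) update_blocks(state, prep, prior, "rho")
#' @rdname update_blocks
#' @export
update_beta <- function(state, prep, prior) update_blocks(state, prep, prior, "beta")
#' @rdname update_blocks
#' @export
update_shrinkage_survival <- function(state, prep, prior)
  update_blocks(state, prep, prior, "shrink_s")
#' @rdname update_blocks
#' @export
update_theta <- function(state, prep, prior) update_blocks(state, prep, prior, "theta")
#' @rdname update_blocks
#' @export
update_shrinkage_longitudinal <- function(state, prep, prior)
  update_blocks(state, prep, prior, "shrink_l")
#' @rdname update_blocks
#' @export
update_eta <- function(state, prep, prior) update_blocks(state, prep, prior, "eta")
#' @rdname update_blocks
#' @export
update_u <- function(state, prep, prior) update_blocks(state, prep, prior, "u")
#' @rdname update_blocks
#' @export
update_xi <- function(state, prep, prior) update_blocks(state, prep, prior, "xi")
#' @rdname update_blocks
#' @export
update_variances <- function(state, prep, prior)
  update_blocks(state, prep, prior, c("sigma_u", "sigma_xi", "sigma_eps"))

#' Fit the joint model by Gibbs sampling
#'
#' Runs one Gibbs chain of the selected prior variant. Each sweep updates,
#' in order: the latent probit variables, the survival baseline (intercept,
#' monotone-spline coefficients, their exponential rate), the survival-side
#' coefficients and shrinkage quantities, the longitudinal-side coefficients
#' and shrinkage quantities, the longitudinal baseline, the two frailty
#' vectors, and the three variances. Under the spike-and-slab variant the
#' inclusion indicators and probabilities are refreshed before the
#' coefficients they govern.
#'
#' @param dataset a [joint_dataset()].
#' @param prior a [prior_config()] object (default Bayesian Lasso).
#' @param iters total sweeps.
#' @param burnin sweeps to discard.
#' @param thin keep every `thin`-th retained sweep.
#' @param seed optional integer seed for full reproducibility.
#' @param n_interior,degree,knots_mu,knots_alpha spline settings, see
#'   [prepare_joint()].
#' @return an object of class `"jm_fit"`: list with `draws` (matrices of
#'   retained samples, plus the derived per-draw Kendall's tau), `prior`,
#'   `knots_mu`, `knots_alpha`, `config`, and the final chain `state`.
#' @examples
#' \donttest{
#' sim <- simulate_joint(simulation_design(n = 120, scenario = "I"), seed = 1)
#' fit <- joint_gibbs(sim$dataset, prior_config("BL"),
#'                    iters = 400, burnin = 100, seed = 1)
#' summarize_fit(fit)
#' }
#' @export
joint_gibbs <- function(dataset, prior = prior_config("BL"),
                        iters = 5000L, burnin = 1000L, thin = 1L, seed = NULL,
                        n_interior = 3L, degree = 3L,
                        knots_mu = NULL, knots_alpha = NULL) {
  stopifnot(inherits(dataset, "joint_dataset"), inherits(prior, "jm_prior"),
            iters > burnin, burnin >= 0L, thin >= 1L)
  if (!is.null(seed)) set.seed(seed)
  prep <- prepare_joint(dataset, n_interior, degree, knots_mu, knots_alpha)
  ep <- expand_prior(prior, prep$p, prep$knots_mu$n_basis)
  state <- init_state(prep, prior)
  res <- cpp_chain(prep, state, ep, as.integer(iters), as.integer(burnin),
                   as.integer(thin))
  draws <- res$draws
  kt <- kendall_tau(draws$sigma_u2, draws$sigma_xi2, draws$sigma_eps2)
  draws$tau <- kt$tau
  cn <- colnames(dataset$X)
  if (!is.null(cn)) colnames(draws$beta) <- colnames(draws$theta) <- cn
  structure(list(draws = draws, prior = prior,
                 knots_mu = prep$knots_mu, knots_alpha = prep$knots_alpha,
                 config = list(iters = iters, burnin = burnin, thin = thin,
                               seed = seed, n_interior = n_interior,
                               degree = degree, n = dataset$n, p = dataset$p),
                 state = res$final_state),
            class = "jm_fit")
}

#' @export
print.jm_fit <- function(x, ...) {
  cat(sprintf("jm_fit: %s sampler, %d retained draws (%d iterations, %d burn-in)\n",
              x$prior$variant, nrow(x$draws$beta),
              x$config$iters, x$config$burnin))
  cat(sprintf("  data: n = %d subjects, p = %d covariates\n",
              x$config$n, x$config$p))
  invisible(x)
}
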