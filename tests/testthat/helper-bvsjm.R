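# Shared fixtures and oracles, all built in code.

# Tiny deterministic dataset: three subjects, one of each censoring type,
# one covariate. Used by the full-conditional and likelihood tests.
tiny_dataset <- function() {
  long <- data.frame(id = c(1L, 1L, 2L, 3L, 3L),
                     time = c(0.4, 1.1, 0.6, 0.5, 1.5),
                     y = c(0.9, 0.3, -0.4, 1.2, 0.7))
  surv <- data.frame(id = 1:3,
                     left = c(0, 0.6, 1.5),
                     right = c(0.8, 1.3, Inf))
  cov <- data.frame(id = 1:3, x1 = c(0.5, -1, 0.3))
  joint_dataset(long, surv, cov)
}

# degree-1, no-interior-knot bases (K = 2 for both baselines) keep every
# hand calculation small
tiny_prep <- function(dataset = tiny_dataset()) {
  prepare_joint(dataset, n_interior = 0L, degree = 1L)
}

# fixed, feasible chain state for the tiny problem
tiny_state <- function(prep) {
  st <- list(z = c(0.7, -0.05, -0.3),
             r0 = -0.5, r = c(0.3, 0.8), rho = 1.2,
             beta = 0.4, theta = -0.3,
             tau_s2 = 0.7, tau_l2 = 1.3,
             lambda2_s = 1.5, lambda2_l = 0.9,
             delta_s = 1L, delta_l = 0L,
             omega_s = 0.5, omega_l = 0.5,
             eta = c(0.2, -0.1), u = c(0.1, -0.2, 0.15),
             xi = c(0.05, 0.1, -0.1),
             sigma_u2 = 0.5, sigma_xi2 = 0.4, sigma_eps2 = 0.8)
  # the interval-censored subject's latent value must sit inside its region
  aL <- alpha_eval(st$r0, st$r, prep$knots_alpha, 0.6)
  aR <- alpha_eval(st$r0, st$r, prep$knots_alpha, 1.3)
  stopifnot(aL - aR < st$z[2], st$z[2] < 0)
  st
}

# grid-normalized KS check of scalar draws against an unnormalized log
# density: map draws through the numeric CDF, test uniformity
ks_grid_pvalue <- function(draws, logdens, lo, hi, n_grid = 4001L) {
  g <- seq(lo, hi, length.out = n_grid)
  ld <- vapply(g, logdens, numeric(1))
  ld <- ld - max(ld[is.finite(ld)])
  f <- exp(ld)
  cdf <- cumsum((f[-1] + f[-n_grid]) / 2 * diff(g))
  cdf <- c(0, cdf / cdf[n_grid - 1L])
  u <- stats::approx(g, cdf, xout = draws, rule = 2)$y
  suppressWarnings(stats::ks.test(u, "punif")$p.value)
}

# repeated single-block draws from a fixed state, via the same compiled
# entry point the chain runner uses
draw_block <- function(n_draws, prep, state, prior, block, extract) {
  ep <- bvsjm:::expand_prior(prior, prep$p, prep$knots_mu$n_basis)
  vapply(seq_len(n_draws), function(i) {
    extract(bvsjm:::cpp_sweep(prep, state, ep, block))
  }, numeric(1))
}

# closed-form inverse-Gaussian CDF (mean/shape), used as an independent
# oracle for the sampler
pinvgauss_oracle <- function(q, mean, shape) {
  a <- sqrt(shape / q)
  stats::pnorm(a * (q / mean - 1)) +
    exp(2 * shape / mean) * stats::pnorm(-a * (q / mean + 1))
}
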