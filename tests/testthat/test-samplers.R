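test_that("truncated-normal sampler matches closed-form moments", {
  expect_error(rtruncnorm(1, lower = 1, upper = 1), "lower >= upper")
  set.seed(31)
  x <- rtruncnorm(1e5)
  expect_equal(mean(x), 0, tolerance = 0.02)
  expect_equal(sd(x), 1, tolerance = 0.02)
  # half normal
  x <- rtruncnorm(1e5, lower = 0)
  expect_true(all(x > 0))
  expect_equal(mean(x), sqrt(2 / pi), tolerance = 0.01)
  # far-tail region: mean equals the Mills-ratio formula
  x <- rtruncnorm(1e5, lower = 5)
  expect_true(all(x > 5))
  expect_equal(mean(x), dnorm(5) / pnorm(-5), tolerance = 0.005)
  # two-sided far tail and the underflow fallback regime
  x <- rtruncnorm(5e3, lower = 8, upper = 8.5)
  expect_true(all(x > 8 & x < 8.5))
  x <- rtruncnorm(5e3, lower = 40, upper = 41)
  expect_true(all(x > 40 & x < 41))
  x <- rtruncnorm(5e3, mean = 2, sd = 0.5, upper = -1)
  expect_true(all(x < -1))
})

test_that("truncated-normal sampler passes a KS test against its CDF", {
  set.seed(32)
  for (b in list(c(-1, 2), c(0.5, Inf), c(-Inf, -3), c(4, 6))) {
    x <- rtruncnorm(2e4, mean = 0.3, sd = 1.2, lower = b[1], upper = b[2])
    a <- (b - 0.3) / 1.2
    u <- (pnorm((x - 0.3) / 1.2) - pnorm(a[1])) / (pnorm(a[2]) - pnorm(a[1]))
    expect_gt(suppressWarnings(ks.test(u, "punif")$p.value), 1e-4)
  }
})

test_that("inverse-Gaussian sampler matches moments and CDF", {
  expect_error(rinvgauss(1, -1, 1), "positive")
  set.seed(33)
  x <- rinvgauss(2e5, 2, 8)
  expect_true(all(x > 0))
  expect_equal(mean(x), 2, tolerance = 0.02)        # mean parameter
  expect_equal(var(x), 2^3 / 8, tolerance = 0.05)   # mean^3 / shape
  for (par in list(c(1, 1), c(2, 8), c(0.5, 3))) {
    x <- rinvgauss(2e4, par[1], par[2])
    expect_gt(suppressWarnings(
      ks.test(x, pinvgauss_oracle, mean = par[1], shape = par[2])$p.value),
      1e-4)
  }
  # extreme mean/shape ratios must not produce nonpositive or infinite draws
  x <- rinvgauss(1e4, 1e12, 2)
  expect_true(all(x > 0 & is.finite(x)))
})

test_that("latent-variable update respects every censoring region", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  pr <- prior_config("BL")
  set.seed(41)
  for (rep in 1:200) {
    st2 <- update_z(st, prep, pr)
    expect_gt(st2$z[1], 0)                       # left-censored
    aLR <- sum((ispline_basis(0.6, prep$knots_alpha) -
                ispline_basis(1.3, prep$knots_alpha)) * st$r)
    expect_gt(st2$z[2], aLR)                     # interval-censored
    expect_lt(st2$z[2], 0)
    expect_lt(st2$z[3], 0)                       # right-censored
  }
  # conditional mean of the right-censored draw matches the Mills formula
  set.seed(42)
  zs <- draw_block(2e4, prep, st, pr, "z", function(s) s$z[3])
  mean3 <- sum(prep$Banchor[3, ] * st$r) + st$r0 +
    prep$X[3, 1] * st$beta + st$u[3]
  mills <- mean3 - dnorm(-mean3) / pnorm(-mean3)  # E[N(m,1) | z < 0]
  expect_equal(mean(zs), mills, tolerance = 0.02)
})

test_that("baseline-intercept update matches its normal full conditional", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  pr <- prior_config("BL")
  W0 <- pr$v0 + prep$n
  E0 <- (pr$v0 * pr$m0 +
         sum(st$z - prep$Banchor %*% st$r - prep$X[, 1] * st$beta - st$u)) / W0
  set.seed(43)
  r0s <- draw_block(2e4, prep, st, pr, "r0", function(s) s$r0)
  expect_equal(mean(r0s), E0, tolerance = 0.02)
  expect_equal(var(r0s), 1 / W0, tolerance = 0.01)
  # an overwhelming prior precision pins the intercept at its prior mean
  pr2 <- prior_config("BL", v0 = 1e10)
  r0s <- draw_block(50, prep, st, pr2, "r0", function(s) s$r0)
  expect_equal(mean(r0s), pr2$m0, tolerance = 1e-3)
})

test_that("monotone-spline update keeps latent variables feasible", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  pr <- prior_config("BL")
  # hand-derived feasibility bound for the single interval-censored subject:
  # z_2 + r_1 bd_1 + r_2 bd_2 > 0, so updating r_1 requires
  # r_1 > (-z_2 - r_2 bd_2) / bd_1 whenever bd_1 > 0
  bd <- as.numeric(prep$Bdiff)
  cstar1 <- (-st$z[2] - st$r[2] * bd[2]) / bd[1]
  dstar1 <- max(cstar1, 0)
  set.seed(44)
  rs <- matrix(NA_real_, 500, 2)
  for (i in 1:500) {
    st2 <- update_r(st, prep, pr)
    rs[i, ] <- st2$r
    aLR <- -sum(bd * st2$r)
    expect_true(st$z[2] > aLR)           # region updated consistently
    expect_true(all(st2$r >= 0))
  }
  expect_true(all(rs[, 1] >= dstar1))
})

test_that("zero-information spline coefficients fall back to their prior", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  pr <- prior_config("BL")
  # zero out one basis column at the anchor times: W_k = 0 for that k
  prep$Banchor[, 2] <- 0
  prep$Bdiff[, 2] <- 0
  set.seed(45)
  r2 <- draw_block(2e4, prep, st, pr, "r", function(s) s$r[2])
  expect_equal(mean(r2), 1 / st$rho, tolerance = 0.02)  # Exp(rho) mean
  expect_equal(var(r2), 1 / st$rho^2, tolerance = 0.03)
})

test_that("spline-rate update is the conjugate gamma", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  pr <- prior_config("BL")
  set.seed(46)
  rhos <- draw_block(2e4, prep, st, pr, "rho", function(s) s$rho)
  Kstar <- length(st$r)
  expect_equal(mean(rhos), (pr$a_rho + Kstar) / (pr$b_rho + sum(st$r)),
               tolerance = 0.02)
})

test_that("survival-coefficient update matches the hand posterior", {
  # one subject, one covariate, X = 1, residual 1.5, tau^2 = 1:
  # precision = 1/tau^2 + x^2 = 2, mean = 1.5 / 2 = 0.75, var = 0.5
  long <- data.frame(id = 1L, time = 0.5, y = 0)
  surv <- data.frame(id = 1L, left = 0.4, right = Inf)
  cov <- data.frame(id = 1L, x1 = 1)
  d1 <- joint_dataset(long, surv, cov)
  prep <- prepare_joint(d1, n_interior = 0L, degree = 1L,
                        knots_mu = place_knots(c(0.1, 0.9), 0, 1),
                        knots_alpha = place_knots(c(0.1, 0.9), 0, 1))
  st <- tiny_state(tiny_prep())
  st$z <- 1.5 + sum(prep$Banchor[1, ] * c(0.3, 0.8)) + st$r0  # u = 0 below
  st$u <- 0; st$xi <- 0
  st$tau_s2 <- 1; st$tau_l2 <- 1
  pr <- prior_config("BL")
  set.seed(47)
  bs <- draw_block(2e4, prep, st, pr, "beta", function(s) s$beta)
  expect_equal(mean(bs), 0.75, tolerance = 0.015)
  expect_equal(var(bs), 0.5, tolerance = 0.02)
  # infinite shrinkage concentrates the draw at zero
  st$tau_s2 <- 1e-12
  bs <- draw_block(200, prep, st, pr, "beta", function(s) s$beta)
  expect_lt(max(abs(bs)), 1e-4)
})

test_that("Bayesian Lasso shrinkage updates have the stated gamma means", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  pr <- prior_config("BL")
  p <- prep$p
  set.seed(48)
  l2 <- draw_block(2e4, prep, st, pr, "shrink_s", function(s) s$lambda2_s[1])
  expect_equal(mean(l2), (p + pr$a_lambda) / (0.5 * sum(st$tau_s2) + pr$b_lambda),
               tolerance = 0.03)
  # latent scales stay positive, and so do the BAL per-coefficient rates
  pr2 <- prior_config("BAL")
  st2 <- st
  for (i in 1:200) {
    st2 <- update_shrinkage_survival(st2, prep, pr2)
    expect_true(all(st2$tau_s2 > 0) && all(st2$lambda2_s > 0))
  }
})

test_that("spike-and-slab inclusion matches the closed-form probability", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  st$beta <- 0          # zero coefficient: R_j = sd ratio = 100
  st$omega_s <- 0.5
  pr <- prior_config("SS")
  set.seed(49)
  ds <- draw_block(2e4, prep, st, pr, "shrink_s", function(s) s$delta_s[1])
  expect_equal(mean(ds), 1 / 101, tolerance = 0.05)   # P = 1/(1 + 100)
  # large coefficient: inclusion is near certain
  st$beta <- 3
  ds <- draw_block(500, prep, st, pr, "shrink_s", function(s) s$delta_s[1])
  expect_equal(mean(ds), 1, tolerance = 1e-8)
  # longitudinal mirror with theta = 0
  st$theta <- 0; st$omega_l <- 0.5
  dl <- draw_block(2e4, prep, st, pr, "shrink_l", function(s) s$delta_l[1])
  expect_equal(mean(dl), 1 / 101, tolerance = 0.05)
})

test_that("longitudinal-coefficient update matches the hand posterior", {
  # one subject, two visits, X = 1; residuals known in closed form
  long <- data.frame(id = c(1L, 1L), time = c(0.4, 0.8), y = c(1.1, 0.7))
  surv <- data.frame(id = 1L, left = 0.5, right = Inf)
  cov <- data.frame(id = 1L, x1 = 1)
  d1 <- joint_dataset(long, surv, cov)
  prep <- prepare_joint(d1, n_interior = 0L, degree = 1L,
                        knots_alpha = place_knots(c(0.1, 0.9), 0, 1))
  st <- tiny_state(tiny_prep())
  st$z <- -0.2; st$u <- 0.1; st$xi <- -0.05
  st$tau_l2 <- 0.8; st$sigma_eps2 <- 0.6
  pr <- prior_config("BL")
  mu_ij <- mu_eval(st$eta, prep$knots_mu, c(0.4, 0.8))
  res <- sum(d1$y[[1]] - mu_ij - st$u - st$xi)
  prec_unscaled <- 1 / st$tau_l2 + 2          # D^{-1} + m x^2
  set.seed(50)
  ths <- draw_block(2e4, prep, st, pr, "theta", function(s) s$theta)
  expect_equal(mean(ths), res / prec_unscaled, tolerance = 0.02)
  expect_equal(var(ths), st$sigma_eps2 / prec_unscaled, tolerance = 0.02)
})

test_that("longitudinal-baseline update matches its normal full conditional", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  pr <- prior_config("BL")
  # the Gram matrix of the update equals the brute-force double sum
  A_loop <- matrix(0, 2, 2)
  for (o in seq_along(prep$y)) {
    A_loop <- A_loop + tcrossprod(prep$Mlong[o, ])
  }
  expect_equal(prep$A, A_loop, tolerance = 1e-12)
  # dominant prior pins eta at its prior mean
  pr2 <- prior_config("BL", eta0 = 0.7, Sigma_eta = 1e-10)
  es <- draw_block(50, prep, st, pr2, "eta", function(s) s$eta[1])
  expect_equal(mean(es), 0.7, tolerance = 1e-3)
  # hand mean for the full conditional
  ep <- bvsjm:::expand_prior(pr, prep$p, 2)
  resid <- prep$y - (prep$X[prep$subj + 1, 1] * st$theta +
                     st$u[prep$subj + 1] + st$xi[prep$subj + 1])
  P <- ep$Sigma_eta_inv + prep$A / st$sigma_eps2
  mean_eta <- solve(P, crossprod(prep$Mlong, resid) / st$sigma_eps2)
  set.seed(51)
  es <- vapply(1:2e4, function(i)
    bvsjm:::cpp_sweep(prep, st, ep, "eta")$eta, numeric(2))
  expect_equal(rowMeans(es), as.numeric(mean_eta), tolerance = 0.02)
})

test_that("frailty updates pool the stated residuals and precisions", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  pr <- prior_config("BL")
  set.seed(52)
  us <- draw_block(2e4, prep, st, pr, "u", function(s) s$u[1])
  V1 <- prep$m[1] / st$sigma_eps2 + 1 / st$sigma_u2 + 1
  expect_equal(var(us), 1 / V1, tolerance = 0.02)
  mu_ij <- mu_eval(st$eta, prep$knots_mu, c(0.4, 1.1))
  sres <- sum(tiny_dataset()$y[[1]] - mu_ij - prep$X[1, 1] * st$theta - st$xi[1])
  zres <- st$z[1] - (st$r0 + sum(prep$Banchor[1, ] * st$r)) -
    prep$X[1, 1] * st$beta
  expect_equal(mean(us), (sres / st$sigma_eps2 + zres) / V1, tolerance = 0.02)

  # xi ignores the survival side entirely
  xis <- draw_block(2e4, prep, st, pr, "xi", function(s) s$xi[1])
  Vx <- prep$m[1] / st$sigma_eps2 + 1 / st$sigma_xi2
  sresx <- sum(tiny_dataset()$y[[1]] - mu_ij - prep$X[1, 1] * st$theta - st$u[1])
  expect_equal(var(xis), 1 / Vx, tolerance = 0.04)
  expect_equal(mean(xis), (sresx / st$sigma_eps2) / Vx, tolerance = 0.03)
  # a degenerate frailty variance pins the frailty at zero
  st2 <- st; st2$sigma_xi2 <- 1e-12
  xis <- draw_block(100, prep, st2, pr, "xi", function(s) s$xi[1])
  expect_lt(max(abs(xis)), 1e-4)
})

test_that("variance updates are the stated conjugate gammas", {
  prep <- tiny_prep()
  st <- tiny_state(prep)
  pr <- prior_config("BL")
  n <- prep$n
  set.seed(53)
  # u = 0: the shared-frailty precision reduces to Ga(n/2 + a_u, b_u)
  st0 <- st; st0$u <- rep(0, n)
  pu <- draw_block(2e4, prep, st0, pr, "sigma_u", function(s) 1 / s$sigma_u2)
  expect_equal(mean(pu), (n / 2 + pr$a_u) / pr$b_u, tolerance = 0.05)
  # general gamma-mean check at the current state
  pu <- draw_block(2e4, prep, st, pr, "sigma_u", function(s) 1 / s$sigma_u2)
  expect_equal(mean(pu),
               (n / 2 + pr$a_u) / (0.5 * sum(st$u^2) + pr$b_u),
               tolerance = 0.05)
  px <- draw_block(2e4, prep, st, pr, "sigma_xi", function(s) 1 / s$sigma_xi2)
  expect_equal(mean(px),
               (n / 2 + pr$a_xi) / (0.5 * sum(st$xi^2) + pr$b_xi),
               tolerance = 0.05)

  # error precision: the Lasso variants carry the extra p/2 shape and the
  # theta quadratic form; the general-normal variant drops both
  mu_ij <- unlist(lapply(1:3, function(i)
    mu_eval(st$eta, prep$knots_mu, tiny_dataset()$times[[i]])))
  resid <- prep$y - mu_ij - prep$X[prep$subj + 1, 1] * st$theta -
    st$u[prep$subj + 1] - st$xi[prep$subj + 1]
  ssr <- sum(resid^2)
  m_tot <- sum(prep$m); p <- prep$p
  pe_bl <- draw_block(2e4, prep, st, pr, "sigma_eps", function(s) 1 / s$sigma_eps2)
  expect_equal(mean(pe_bl),
               (pr$a_eps + m_tot / 2 + p / 2) /
                 (pr$b_eps + ssr / 2 + 0.5 * sum(st$theta^2 / st$tau_l2)),
               tolerance = 0.05)
  pr_gb <- prior_config("GB")
  pe_gb <- draw_block(2e4, prep, st, pr_gb, "sigma_eps",
                      function(s) 1 / s$sigma_eps2)
  expect_equal(mean(pe_gb),
               (pr_gb$a_eps + m_tot / 2) / (pr_gb$b_eps + ssr / 2),
               tolerance = 0.05)
})

test_that("chains are reproducible and preserve every state invariant", {
  sim <- simulate_joint(simulation_design(n = 80, scenario = "I"), seed = 5)
  for (v in c("BL", "BAL", "SS", "GB")) {
    f1 <- joint_gibbs(sim$dataset, prior_config(v), iters = 120, burnin = 40,
                      seed = 99)
    f2 <- joint_gibbs(sim$dataset, prior_config(v), iters = 120, burnin = 40,
                      seed = 99)
    expect_identical(f1$draws, f2$draws)
    expect_true(all(f1$draws$r >= 0))
    expect_true(all(f1$draws$sigma_u2 > 0))
    expect_true(all(f1$draws$sigma_xi2 > 0))
    expect_true(all(f1$draws$sigma_eps2 > 0))
    expect_equal(nrow(f1$draws$beta), 80L)
  }
})

test_that("latent variables stay inside their regions across full sweeps", {
  sim <- simulate_joint(simulation_design(n = 60, scenario = "I"), seed = 6)
  prep <- prepare_joint(sim$dataset)
  pr <- prior_config("BL")
  set.seed(7)
  st <- init_state(prep, pr)
  ic <- prep$ic + 1L
  for (it in 1:50) {
    st <- update_blocks(st, prep, pr, "all")
    lowers <- -(prep$Bdiff %*% st$r)
    expect_true(all(st$z[prep$delta == 1L] > 0))
    expect_true(all(st$z[prep$delta == 3L] < 0))
    expect_true(all(st$z[ic] > lowers & st$z[ic] < 0))
  }
})
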