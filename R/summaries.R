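#' Posterior summary of one fit
#'
#' Posterior means and equal-tailed 95% credible intervals for every scalar
#' parameter of interest: both coefficient vectors, the three variances, and
#' Kendall's tau (computed per retained draw from the variance triplet, then
#' summarized).
#'
#' @param fit a [joint_gibbs()] fit.
#' @param level credible level (default 0.95, equal-tailed).
#' @return an object of class `"jm_summary"`: data.frame with columns
#'   `parameter`, `block` (`"theta"`, `"beta"`, `"variance"`, `"association"`),
#'   `mean`, `lower`, `upper`.
#' @export
summarize_fit <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "jm_fit"))
  if (nrow(fit$draws$beta) == 0L) stop("no retained draws to summarize")
  a <- (1 - level) / 2
  one <- function(x) c(mean(x), unname(stats::quantile(x, c(a, 1 - a), type = 7)))
  p <- ncol(fit$draws$theta)
  cols <- cbind(fit$draws$theta, fit$draws$beta,
                fit$draws$sigma_u2, fit$draws$sigma_xi2, fit$draws$sigma_eps2,
                fit$draws$tau)
  sm <- t(apply(cols, 2L, one))
  out <- data.frame(
    parameter = c(paste0("theta", seq_len(p)), paste0("beta", seq_len(p)),
                  "sigma_u2", "sigma_xi2", "sigma_eps2", "tau"),
    block = c(rep("theta", p), rep("beta", p), rep("variance", 3), "association"),
    mean = sm[, 1], lower = sm[, 2], upper = sm[, 3],
    row.names = NULL)
  class(out) <- c("jm_summary", "data.frame")
  out
}

#' @export
print.jm_summary <- function(x, digits = 3, ...) {
  y <- x
  y$mean <- round(y$mean, digits)
  y$lower <- round(y$lower, digits)
  y$upper <- round(y$upper, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Label coefficients by credible-interval selection
#'
#' A coefficient is labeled `"positive"` (selected) when its credible
#' interval excludes 0 and `"negative"` otherwise; containment is tested on
#' the closed interval, so an endpoint exactly at 0 counts as containing.
#'
#' @param summary a [summarize_fit()] result.
#' @param block which coefficient block to label (`"theta"` or `"beta"`).
#' @return character vector of `"positive"` / `"negative"` labels.
#' @export
selection_labels <- function(summary, block = c("theta", "beta")) {
  block <- match.arg(block)
  s <- summary[summary$block == block, ]
  ifelse(s$lower <= 0 & s$upper >= 0, "negative", "positive")
}

#' Operating characteristics across simulated replicates
#'
#' Aggregates a list of per-replicate posterior summaries against the known
#' truth into the usual simulation report: per coefficient and variance,
#' BIAS (mean of the posterior-mean estimates minus truth), RMSE, and CP95
#' (fraction of credible intervals containing the truth); per submodel, the
#' average selection size (coefficients labeled positive), average true
#' negatives (truly-zero coefficients labeled negative) and average false
#' negatives (truly-nonzero coefficients labeled negative), both as raw
#' counts and as percentages of the relevant truth counts.
#'
#' @param summaries list of [summarize_fit()] results.
#' @param truth list with `theta`, `beta`, `sigma_u2`, `sigma_xi2`,
#'   `sigma_eps2` (as in the `truth` element of [simulate_joint()]).
#' @return an object of class `"jm_report"`: list with `estimation`
#'   (data.frame of BIAS/RMSE/CP95), `selection` (data.frame with one row
#'   per submodel), `n_replicates`, and the per-replicate label matrices.
#' @export
replicate_metrics <- function(summaries, truth) {
  stopifnot(length(summaries) >= 1L)
  p <- length(truth$theta)
  if (sum(summaries[[1]]$block == "theta") != p ||
      length(truth$beta) != p)
    stop("summary / truth dimension mismatch")
  tv <- c(truth$theta, truth$beta,
          truth$sigma_u2, truth$sigma_xi2, truth$sigma_eps2)
  keep <- c(paste0("theta", seq_len(p)), paste0("beta", seq_len(p)),
            "sigma_u2", "sigma_xi2", "sigma_eps2")
  est <- sapply(summaries, function(s) s$mean[match(keep, s$parameter)])
  lo <- sapply(summaries, function(s) s$lower[match(keep, s$parameter)])
  hi <- sapply(summaries, function(s) s$upper[match(keep, s$parameter)])
  if (nrow(est) != length(tv)) stop("summary / truth dimension mismatch")
  estimation <- data.frame(
    parameter = keep,
    truth = tv,
    BIAS = rowMeans(est) - tv,
    RMSE = sqrt(rowMeans((est - tv)^2)),
    CP95 = rowMeans(lo <= tv & tv <= hi),
    row.names = NULL)
  lab <- function(block, tr) {
    L <- sapply(summaries, function(s) selection_labels(s, block) == "positive")
    if (is.null(dim(L))) L <- matrix(L, nrow = p)
    data.frame(submodel = if (block == "theta") "longitudinal" else "survival",
               aver_size = mean(colSums(L)),
               TN = mean(colSums(!L & tr == 0)),
               FN = mean(colSums(!L & tr != 0)),
               aver_size_pct = 100 * mean(colSums(L)) / sum(tr != 0),
               TN_pct = 100 * mean(colSums(!L & tr == 0)) / sum(tr == 0),
               FN_pct = 100 * mean(colSums(!L & tr != 0)) / sum(tr != 0))
  }
  Ltheta <- sapply(summaries, function(s) selection_labels(s, "theta") == "positive")
  Lbeta <- sapply(summaries, function(s) selection_labels(s, "beta") == "positive")
  structure(list(estimation = estimation,
                 selection = rbind(lab("theta", truth$theta),
                                   lab("beta", truth$beta)),
                 n_replicates = length(summaries),
                 positives_theta = Ltheta, positives_beta = Lbeta),
            class = "jm_report")
}

#' @export
print.jm_report <- function(x, digits = 3, ...) {
  cat(sprintf("jm_report over %d replicates\n", x$n_replicates))
  est <- x$estimation
  est[, 3:5] <- round(est[, 3:5], digits)
  print.data.frame(est, row.names = FALSE)
  cat("\nselection:\n")
  sel <- x$selection
  sel[, -1] <- round(sel[, -1], digits)
  print.data.frame(sel, row.names = FALSE)
  invisible(x)
}

#' Simulate-fit-summarize replicate study
#'
#' Loops `simulate -> fit -> summarize` over independent replicates of one
#' simulation design and returns the operating-characteristic report along
#' with the per-replicate summaries (so several priors can be compared on
#' the same replicates via the `datasets` argument).
#'
#' @param design a [simulation_design()].
#' @param prior a [prior_config()].
#' @param reps number of replicates.
#' @param iters,burnin,thin chain settings per replicate.
#' @param seed integer; replicate `r` uses `seed + r` for both data
#'   generation and the chain.
#' @param datasets optional list of pre-simulated `simulate_joint()` results
#'   to reuse (must have length `reps`).
#' @return list with `report` (a [replicate_metrics()] result), `summaries`,
#'   and `truth`.
#' @export
replicate_study <- function(design, prior, reps = 50L,
                            iters = 3000L, burnin = 500L, thin = 1L,
                            seed = 1L, datasets = NULL) {
  if (!is.null(datasets)) stopifnot(length(datasets) == reps)
  summaries <- vector("list", reps)
  truth <- NULL
  for (r in seq_len(reps)) {
    sim <- if (is.null(datasets)) simulate_joint(design, seed = seed + r)
           else datasets[[r]]
    truth <- sim$truth
    fit <- joint_gibbs(sim$dataset, prior, iters = iters, burnin = burnin,
                       thin = thin, seed = seed + r)
    summaries[[r]] <- summarize_fit(fit)
  }
  list(report = replicate_metrics(summaries, truth),
       summaries = summaries, truth = truth)
}
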