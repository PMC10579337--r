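#' Confidence intervals and Wald tests for a copula mixed-model fit
#'
#' Two methods are available.
#'
#' `"simulated-jacobian-wald"` (default): the indirect-inference sandwich.
#' The binding function `B(theta) = E[pi(sim(theta))]` is differentiated
#' numerically (central differences, common random numbers) at the
#' estimate; the auxiliary-statistic covariance `Sigma` is estimated from
#' `B` independent datasets simulated at the estimate. Then
#' \deqn{Var(\hat\theta) = (1 + 1/H)\, J^{-1} \Sigma J^{-\top}}
#' with the `1/H` term accounting for the simulation noise in the matched
#' average. Intervals are Wald intervals on the transformed scale,
#' back-transformed coordinate-wise (monotone maps preserve coverage).
#'
#' `"parametric-bootstrap"`: refits `B` datasets simulated at the estimate
#' and reports percentile intervals. Slower; kept as a cross-check.
#'
#' Wald p-values test zero on scale-appropriate nulls: `beta`/`gamma`
#' coordinates against 0 and `rho` against 0 (via `atanh rho = 0`).
#' `tau`, `alpha` and `nu` are boundary/positivity parameters for which a
#' zero null is not meaningful; their p-values are `NA`.
#'
#' @param fit a converged [fit_iterative_bootstrap()] result.
#' @param method see above.
#' @param B simulated datasets for `Sigma` (or bootstrap refits).
#' @param level confidence level.
#' @param seed RNG seed.
#' @param h finite-difference step on the transformed scale.
#' @param H_jac simulations per Jacobian evaluation.
#' @return tibble: `parameter`, `estimate` (natural scale), `se`
#'   (transformed scale), `lower`, `upper` (natural scale), `p_wald`.
#' @export
estimate_uncertainty <- function(fit, method = c("simulated-jacobian-wald",
                                                 "parametric-bootstrap"),
                                 B = 200L, level = 0.95, seed = 1L,
                                 h = 0.05, H_jac = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(fit, "copula_lmm_fit"))
  if (!fit$converged) {
    stop("fit did not converge; refusing to build intervals on a moving estimate")
  }
  p <- ncol(fit$design$x)
  if (method == "parametric-bootstrap") {
    if (B < 50L) warning("B < 50 gives unstable percentile intervals")
    return(pboot_ci(fit, B, level, seed))
  }
  if (is.null(H_jac)) H_jac <- fit$H

  theta <- fit$theta
  d <- length(theta)
  jac_seed <- substream_seed(seed, "wald", "jacobian")
  J <- matrix(0, d, d)
  for (j in seq_len(d)) {
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (sim_aux_mean(up, fit$design, H_jac, jac_seed) -
                 sim_aux_mean(dn, fit$design, H_jac, jac_seed)) / (2 * h)
  }

  params_hat <- fit$estimates
  sig_seed <- substream_seed(seed, "wald", "sigma")
  sims <- withr::with_seed(sig_seed,
                           simulate_ca_matrix(params_hat, fit$design, as.integer(B)))
  pis <- aux_stats_multi(sims$y, fit$design)
  Sigma <- stats::cov(t(pis))

  Jinv <- tryCatch(solve(J), error = function(e) {
    stop("simulated Jacobian of the binding function is not invertible: ",
         conditionMessage(e))
  })
  V <- (1 + 1 / fit$H) * Jinv %*% Sigma %*% t(Jinv)
  se <- sqrt(pmax(diag(V), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)

  lower_t <- theta - z * se
  upper_t <- theta + z * se
  est_nat <- vapply(seq_len(d), function(j) theta_coord_to_natural(theta[j], j, p), 0)
  low_nat <- vapply(seq_len(d), function(j) theta_coord_to_natural(lower_t[j], j, p), 0)
  upp_nat <- vapply(seq_len(d), function(j) theta_coord_to_natural(upper_t[j], j, p), 0)

  testable <- c(rep(TRUE, 2 * p), FALSE, FALSE, TRUE, FALSE)  # beta, gamma, rho
  p_wald <- ifelse(testable & se > 0,
                   2 * stats::pnorm(-abs(theta / se)), NA_real_)

  tibble::tibble(
    parameter = natural_names(p),
    estimate = est_nat, se_transformed = se,
    lower = low_nat, upper = upp_nat, p_wald = p_wald,
    level = level, method = method
  )
}

pboot_ci <- function(fit, B, level, seed) {
  p <- ncol(fit$design$x)
  d <- length(fit$theta)
  boot <- matrix(NA_real_, B, d)
  for (b in seq_len(B)) {
    sim_seed <- substream_seed(seed, "pboot", b)
    y_b <- simulate_ca_dataset(fit$estimates, fit$design, seed = sim_seed)
    fb <- tryCatch(
      fit_iterative_bootstrap(y_b, fit$design, H = fit$H,
                              damping = fit$damping,
                              seed = substream_seed(seed, "pboot-fit", b),
                              init = fit$estimates),
      error = function(e) NULL)
    if (!is.null(fb) && fb$converged) boot[b, ] <- fb$theta
  }
  ok <- stats::complete.cases(boot)
  if (sum(ok) < 0.5 * B) warning("fewer than half the bootstrap refits converged")
  a <- (1 - level) / 2
  qs <- apply(boot[ok, , drop = FALSE], 2, stats::quantile, probs = c(a, 1 - a))
  est_nat <- vapply(seq_len(d), function(j)
    theta_coord_to_natural(fit$theta[j], j, p), 0)
  low_nat <- vapply(seq_len(d), function(j)
    theta_coord_to_natural(qs[1, j], j, p), 0)
  upp_nat <- vapply(seq_len(d), function(j)
    theta_coord_to_natural(qs[2, j], j, p), 0)
  tibble::tibble(
    parameter = natural_names(p), estimate = est_nat,
    se_transformed = apply(boot[ok, , drop = FALSE], 2, stats::sd),
    lower = low_nat, upper = upp_nat, p_wald = NA_real_,
    level = level, method = "parametric-bootstrap"
  )
}

#' Monte-Carlo coverage and bias experiment for the copula mixed model
#'
#' Simulates `n_rep` datasets at known parameters, fits each by
#' [fit_iterative_bootstrap()], builds confidence intervals, and reports
#' per-parameter empirical coverage, bias and the Monte-Carlo standard
#' error of the coverage. Non-convergent replicates are counted and
#' excluded from the coverage denominator.
#'
#' @param true_params a [copula_lmm_params()]: the simulation truth.
#' @param design a [ca_design()].
#' @param n_rep number of Monte-Carlo replicates (>= 100 for a meaningful
#'   coverage estimate).
#' @param level nominal coverage.
#' @param seed root seed; each replicate uses a named substream.
#' @param H,damping,max_iter,tol passed to the fitter.
#' @param B_sigma simulations for the Wald covariance.
#' @param ci_method passed to [estimate_uncertainty()].
#' @return list with `coverage` (tibble: parameter, truth, coverage,
#'   mc_se, bias, mean_ci_width), `n_rep`, `n_converged`,
#'   `estimates` (replicates x parameters, natural scale).
#' @export
coverage_experiment <- function(true_params, design, n_rep = 200L,
                                level = 0.95, seed = 1L, H = 100L,
                                damping = 0.5, max_iter = 100L, tol = 0.01,
                                B_sigma = 200L,
                                ci_method = "simulated-jacobian-wald") {
  if (n_rep < 100L) stop("n_rep >= 100 required for a stable coverage estimate")
  p <- ncol(design$x)
  d <- 2 * p + 4
  truth_nat <- c(true_params$beta, true_params$gamma, true_params$tau,
                 true_params$alpha, true_params$rho, true_params$nu)
  names(truth_nat) <- natural_names(p)

  hits <- matrix(NA, n_rep, d)
  ests <- matrix(NA_real_, n_rep, d, dimnames = list(NULL, natural_names(p)))
  widths <- matrix(NA_real_, n_rep, d)
  n_conv <- 0L

  for (r in seq_len(n_rep)) {
    y_r <- simulate_ca_dataset(true_params, design,
                               seed = substream_seed(seed, "cov-data", r))
    fit <- tryCatch(
      fit_iterative_bootstrap(y_r, design, H = H, max_iter = max_iter,
                              tol = tol, damping = damping,
                              seed = substream_seed(seed, "cov-fit", r)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    ci <- tryCatch(
      estimate_uncertainty(fit, method = ci_method, B = B_sigma,
                           level = level,
                           seed = substream_seed(seed, "cov-ci", r)),
      error = function(e) NULL)
    if (is.null(ci)) next
    n_conv <- n_conv + 1L
    ests[r, ] <- ci$estimate
    hits[r, ] <- ci$lower <= truth_nat & truth_nat <= ci$upper
    widths[r, ] <- ci$upper - ci$lower
  }

  cov_hat <- colMeans(hits, na.rm = TRUE)
  coverage <- tibble::tibble(
    parameter = natural_names(p),
    truth = unname(truth_nat),
    coverage = cov_hat,
    mc_se = sqrt(cov_hat * (1 - cov_hat) / n_conv),
    bias = colMeans(ests, na.rm = TRUE) - truth_nat,
    mean_ci_width = colMeans(widths, na.rm = TRUE)
  )
  list(coverage = coverage, n_rep = n_rep, n_converged = n_conv,
       convergence_rate = n_conv / n_rep, estimates = ests, level = level)
}

#' Estimator bias across replicate fits (consistency experiment)
#'
#' Simulates and refits `n_rep` datasets at known parameters without
#' building confidence intervals — the cheap core of the consistency
#' check, used to show per-parameter bias shrinking as the tissue count
#' grows.
#'
#' @inheritParams coverage_experiment
#' @return list: `bias` tibble (parameter, truth, bias, mc_se),
#'   `estimates` matrix (natural scale), `n_converged`.
#' @export
bias_experiment <- function(true_params, design, n_rep = 50L, seed = 1L,
                            H = 100L, damping = 0.5, max_iter = 100L,
                            tol = 0.01) {
  p <- ncol(design$x)
  d <- 2 * p + 4
  truth_nat <- c(true_params$beta, true_params$gamma, true_params$tau,
                 true_params$alpha, true_params$rho, true_params$nu)
  ests <- matrix(NA_real_, n_rep, d, dimnames = list(NULL, natural_names(p)))
  for (r in seq_len(n_rep)) {
    y_r <- simulate_ca_dataset(true_params, design,
                               seed = substream_seed(seed, "bias-data", r))
    fit <- tryCatch(
      fit_iterative_bootstrap(y_r, design, H = H, max_iter = max_iter,
                              tol = tol, damping = damping,
                              seed = substream_seed(seed, "bias-fit", r)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    est <- fit$estimates
    ests[r, ] <- c(est$beta, est$gamma, est$tau, est$alpha, est$rho, est$nu)
  }
  ok <- stats::complete.cases(ests)
  bias <- tibble::tibble(
    parameter = natural_names(p), truth = truth_nat,
    bias = colMeans(ests[ok, , drop = FALSE]) - truth_nat,
    mc_se = apply(ests[ok, , drop = FALSE], 2, stats::sd) / sqrt(sum(ok)))
  list(bias = bias, estimates = ests, n_converged = sum(ok), n_rep = n_rep)
}
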