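# Hierarchical mean-variance copula mixed model: simulation moments,
# auxiliary statistics, fitter behaviour.

# small-sample excess kurtosis used by the Gaussian-limit test
moments_kurtosis <- function(x) mean((x - mean(x))^4) / stats::var(x)^2 - 3

test_that("parameter validation names the violated constraint", {
  expect_error(copula_lmm_params(c(0, 1), -0.1, c(0, 0), 4, 0.5, 8), "tau")
  expect_error(copula_lmm_params(c(0, 1), 0.3, c(0, 0), 0, 0.5, 8), "alpha")
  expect_error(copula_lmm_params(c(0, 1), 0.3, c(0, 0), 4, 1, 8), "rho")
  expect_error(copula_lmm_params(c(0, 1), 0.3, c(0, 0), 4, 0.5, 2), "nu")
  expect_error(copula_lmm_params(c(0, 1), 0.3, c(0), 4, 0.5, 8), "equal length")
  expect_error(ca_design(cbind(1, c(1, 1, 1)), c(5, 5, 5)), "rank")
  expect_error(ca_design(cbind(c(1, 1), c(0, 1)), c(5, 1)), "n_i >= 2")
})

test_that("Gaussian limit: iid normal moments at the degenerate corner", {
  p <- copula_lmm_params(beta = c(0.7, 0), tau = 0, gamma = c(log(0.4), 0),
                         alpha = Inf, rho = 0, nu = Inf)
  des <- two_group_design(2, 2, 25000)
  y <- simulate_ca_dataset(p, des, seed = 8)
  ft <- y$y[grepl("^FT", y$tissue_id)]
  expect_equal(mean(ft), 0.7, tolerance = 0.02)
  expect_equal(sd(ft), 0.4, tolerance = 0.02)
  expect_lt(abs(moments_kurtosis(ft)), 0.1)
})

test_that("random scales have mean exp(x'gamma) and copula-linked ranks", {
  p <- study_params()
  des <- two_group_design(3000, 3000, 2)
  y <- simulate_ca_dataset(p, des, seed = 5)
  lat <- attr(y, "latent")
  is_t <- grepl("^tumour", lat$tissue_id)
  # E[sigma_i] = exp(x_i' gamma): mean-1 gamma construction
  expect_equal(mean(lat$sigma[!is_t]), exp(-1), tolerance = 0.03)
  expect_equal(mean(lat$sigma[is_t]), exp(-0.5), tolerance = 0.03)
  # rho > 0 induces positive rank correlation between b_i and sigma_i;
  # oracle: the Gaussian rank correlation 6/pi * asin(rho/2). Compare
  # within one tissue group, where exp(x'gamma) is constant and the
  # ranks of sigma_i are those of the copula score v_i
  implied <- 6 / pi * asin(p$rho / 2)
  expect_equal(cor(lat$b[!is_t], lat$sigma[!is_t], method = "spearman"),
               implied, tolerance = 0.05)
})

test_that("auxiliary statistics are exchangeable and respond to tau", {
  p <- study_params()
  des <- study_design()
  y <- simulate_ca_dataset(p, des, seed = 2)
  pi1 <- auxiliary_stats(y, des)
  yperm <- y[order(y$tissue_id, -y$field), ]
  expect_equal(auxiliary_stats(yperm, des), pi1)
  # tau = 0: the intercept-variance proxy vanishes as n_i grows
  p0 <- copula_lmm_params(beta = c(0, 0.5), tau = 0, gamma = c(-1, 0.5),
                          alpha = 4, rho = 0, nu = 8)
  proxies <- vapply(c(10L, 100L, 1000L), function(n) {
    d <- two_group_design(30, 30, n)
    exp(auxiliary_stats(simulate_ca_dataset(p0, d, seed = 3), d)[["log_tau"]])
  }, 0)
  # non-increasing in n_i (ties allowed once the numerical floor binds)
  # and negligible relative to the study-condition tau = 0.3
  expect_true(all(diff(proxies) <= 1e-12))
  expect_lt(max(proxies), 0.05)
  # Gaussian-limit data: kurtosis proxy ~ 0, i.e. nu proxy large
  pg <- copula_lmm_params(beta = c(0, 0.5), tau = 0.3, gamma = c(-1, 0.5),
                          alpha = Inf, rho = 0, nu = Inf)
  dg <- two_group_design(50, 50, 200)
  pig <- auxiliary_stats(simulate_ca_dataset(pg, dg, seed = 4), dg)
  expect_gt(2 + exp(pig[["log_nu_minus_2"]]), 50)
  expect_error(ca_design(matrix(1, 2, 1), c(2, 1)), "n_i >= 2")
})

test_that("fitter is a near-fixed-point at the truth and recovers parameters", {
  p <- study_params()
  des <- study_design()
  y <- simulate_ca_dataset(p, des, seed = 21)
  fit0 <- fit_iterative_bootstrap(y, des, max_iter = 1L, seed = 6, init = p)
  # initialised at the truth, the first damped update is within simulation
  # noise (loose bound: each coordinate moves < 0.15 on the transformed scale)
  expect_lt(max(abs(fit0$trace[2, ] - fit0$trace[1, ])), 0.15)
  fit <- fit_iterative_bootstrap(y, des, seed = 6)
  expect_true(fit$converged)
  est <- fit$estimates
  expect_equal(est$beta, p$beta, tolerance = 0.25)
  expect_equal(est$tau, p$tau, tolerance = 0.25)
  expect_equal(est$rho, p$rho, tolerance = 0.45)
})

test_that("location and scale equivariance on the observation scale", {
  p <- study_params()
  des <- study_design(10L)
  y <- simulate_ca_dataset(p, des, seed = 31)
  fit <- fit_iterative_bootstrap(y, des, seed = 9)
  shifted <- y; shifted$y <- y$y + 3
  fit_s <- fit_iterative_bootstrap(shifted, des, seed = 9)
  expect_equal(fit_s$estimates$beta[1], fit$estimates$beta[1] + 3,
               tolerance = 0.05)
  expect_equal(fit_s$estimates$beta[2], fit$estimates$beta[2],
               tolerance = 0.05)
  scaled <- y; scaled$y <- y$y * 2
  fit_k <- fit_iterative_bootstrap(scaled, des, seed = 9)
  expect_equal(fit_k$estimates$gamma[1], fit$estimates$gamma[1] + log(2),
               tolerance = 0.08)
  expect_equal(fit_k$estimates$tau, fit$estimates$tau * 2, tolerance = 0.08)
})

test_that("uncertainty: CIs contain the point estimate; rho null p is uniform-ish", {
  p <- study_params()
  des <- study_design()
  y <- simulate_ca_dataset(p, des, seed = 41)
  fit <- fit_iterative_bootstrap(y, des, seed = 11)
  ci <- estimate_uncertainty(fit, seed = 12)
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  expect_true(all(is.na(ci$p_wald[ci$parameter %in% c("tau", "alpha", "nu")])))
  expect_true(all(!is.na(ci$p_wald[grepl("beta|gamma|rho", ci$parameter)])))
  unfit <- fit; unfit$converged <- FALSE
  expect_error(estimate_uncertainty(unfit), "converge")
})
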