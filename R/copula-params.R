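#' Parameters of the hierarchical mean-variance copula mixed model
#'
#' The model describes per-field log CA scores `y_ij` for tissue `i`, field
#' `j`:
#' \deqn{y_{ij} = x_i'\beta + b_i + \sigma_i \epsilon_{ij}}
#' with
#' * `b_i = tau * u_i` — Gaussian random tissue intercepts,
#' * `sigma_i = exp(x_i' gamma) * Q_Gamma(Phi(v_i); shape alpha, mean 1)` —
#'   gamma-distributed random within-tissue standard deviations whose
#'   log-mean depends on tissue-type fixed effects `gamma`,
#' * `(u_i, v_i)` standard bivariate normal with correlation `rho` (the
#'   Gaussian copula linking the random location and the random scale),
#' * `eps_ij` iid standardized Student-t with `nu` degrees of freedom
#'   (unit variance; `nu = Inf` gives the Gaussian limit).
#'
#' `alpha = Inf` collapses the random scale to its mean `exp(x_i' gamma)`;
#' at `rho = 0, alpha = Inf, nu = Inf` the model is an ordinary
#' homoscedastic Gaussian linear mixed model.
#'
#' @param beta numeric vector of mean fixed effects (log-CA units).
#' @param tau random-intercept standard deviation, `>= 0`.
#' @param gamma numeric vector of scale fixed effects (log-SD units); must
#'   have the same length as `beta`.
#' @param alpha gamma shape of the random standard deviations, `> 0`
#'   (`Inf` allowed: degenerate scales).
#' @param rho copula correlation between the location and scale normal
#'   scores, in `(-1, 1)`.
#' @param nu residual tail parameter (degrees of freedom), `> 2`
#'   (`Inf` allowed: Gaussian residuals).
#' @return an object of class `copula_lmm_params`.
#' @seealso [simulate_ca_dataset()], [fit_iterative_bootstrap()]
#' @export
copula_lmm_params <- function(beta, tau, gamma, alpha, rho, nu) {
  stopifnot(is.numeric(beta), is.numeric(gamma))
  if (length(beta) != length(gamma)) {
    stop("`beta` and `gamma` must have equal length (one design, two linear predictors)")
  }
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("`tau` must be a single number >= 0")
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha <= 0) {
    stop("`alpha` must be a single number > 0 (Inf allowed)")
  }
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) >= 1) {
    stop("`rho` must lie strictly inside (-1, 1)")
  }
  if (!is.numeric(nu) || length(nu) != 1L || is.na(nu) || nu <= 2) {
    stop("`nu` must exceed 2 so residuals have finite variance (Inf allowed)")
  }
  structure(
    list(beta = as.numeric(beta), tau = as.numeric(tau),
         gamma = as.numeric(gamma), alpha = as.numeric(alpha),
         rho = as.numeric(rho), nu = as.numeric(nu)),
    class = "copula_lmm_params"
  )
}

#' @export
print.copula_lmm_params <- function(x, ...) {
  cat("Copula LMM parameters\n")
  cat("  beta  (mean FE):", format(x$beta, digits = 4), "\n")
  cat("  gamma (scale FE):", format(x$gamma, digits = 4), "\n")
  cat(sprintf("  tau = %.4g  alpha = %.4g  rho = %.4g  nu = %.4g\n",
              x$tau, x$alpha, x$rho, x$nu))
  invisible(x)
}

#' Study design for the copula mixed model
#'
#' @param x design matrix (tissues x covariates), first column typically an
#'   intercept; must be full rank.
#' @param n_i integer vector of field counts per tissue (all `>= 2`).
#' @param tissue_id optional tissue identifiers.
#' @return an object of class `ca_design`.
#' @export
ca_design <- function(x, n_i, tissue_id = NULL) {
  x <- as.matrix(x)
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank deficient")
  n_i <- as.integer(n_i)
  if (length(n_i) != nrow(x)) stop("length(n_i) must equal nrow(x)")
  if (any(n_i < 2L)) stop("every tissue needs n_i >= 2 fields for scale estimation")
  if (is.null(tissue_id)) tissue_id <- paste0("tissue_", seq_len(nrow(x)))
  structure(list(x = x, n_i = n_i, tissue_id = as.character(tissue_id)),
            class = "ca_design")
}

#' Two-group tissue design (e.g. fallopian tube vs tumour)
#'
#' Convenience constructor for the design used throughout the simulation
#' experiments: an intercept plus a single group indicator.
#'
#' @param n_group1,n_group2 tissue counts in the reference and contrast
#'   groups.
#' @param n_fields fields per tissue (scalar or per-tissue vector).
#' @param labels group labels used in tissue ids.
#' @export
two_group_design <- function(n_group1, n_group2, n_fields,
                             labels = c("FT", "tumour")) {
  m <- n_group1 + n_group2
  x <- cbind(intercept = 1, group = rep(c(0, 1), c(n_group1, n_group2)))
  ids <- c(paste0(labels[1], "_", seq_len(n_group1)),
           paste0(labels[2], "_", seq_len(n_group2)))
  ca_design(x, rep_len(n_fields, m), ids)
}

# --- transformed (unconstrained) parameter scale used by the fitter -------
# theta_t = (beta, gamma, log tau, log alpha, atanh rho, log(nu - 2))
# Bounds keep the iterative-bootstrap recursion inside a numerically safe
# box; the boundary values act as the practical identifiability limits.
param_bounds <- function(p) {
  list(lower = c(rep(-20, 2 * p), log(1e-4), log(0.05), -atanh(0.995), log(0.05)),
       upper = c(rep(20, 2 * p), log(20), log(1e5), atanh(0.995), log(1e5)))
}

params_to_theta <- function(params) {
  c(params$beta, params$gamma, log(max(params$tau, 1e-4)),
    log(min(params$alpha, 1e5)), atanh(max(min(params$rho, 0.995), -0.995)),
    log(min(params$nu, 1e5 + 2) - 2))
}

theta_to_params <- function(theta, p) {
  copula_lmm_params(
    beta = theta[seq_len(p)],
    gamma = theta[p + seq_len(p)],
    tau = exp(theta[2 * p + 1]),
    alpha = exp(theta[2 * p + 2]),
    rho = tanh(theta[2 * p + 3]),
    nu = 2 + exp(theta[2 * p + 4])
  )
}

theta_names <- function(p) {
  c(paste0("beta", seq_len(p) - 1L), paste0("gamma", seq_len(p) - 1L),
    "log_tau", "log_alpha", "atanh_rho", "log_nu_minus_2")
}

natural_names <- function(p) {
  c(paste0("beta", seq_len(p) - 1L), paste0("gamma", seq_len(p) - 1L),
    "tau", "alpha", "rho", "nu")
}

# back-transform one transformed coordinate to the natural scale
theta_coord_to_natural <- function(value, coord, p) {
  if (coord <= 2 * p) return(value)
  switch(coord - 2 * p, exp(value), exp(value), tanh(value), 2 + exp(value))
}
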