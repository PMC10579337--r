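#' Fit the copula mixed model by indirect inference with an iterative
#' bootstrap
#'
#' The estimator matches the observed auxiliary statistics
#' [auxiliary_stats()] to their simulated expectation under the model.
#' Because each parameter is matched to one auxiliary coordinate on the
#' transformed scale, the iterative bootstrap takes the fixed-point form
#' \deqn{\theta^{(k+1)} = \theta^{(k)} + \lambda\,[\hat\pi_{obs} -
#'   \bar\pi_H(\theta^{(k)})]}
#' where `\bar\pi_H` averages the plug-in map over `H` datasets simulated
#' at the current parameter. Common random numbers (the same simulation
#' seed at every iteration) keep `\bar\pi_H` a smooth function of `\theta`
#' and stabilise the recursion; the fixed point is the indirect-inference
#' estimate and inherits its consistency.
#'
#' @param data long tibble (`tissue_id`, `y`) or tissues-by-fields matrix
#'   of log CA scores.
#' @param design a [ca_design()].
#' @param H simulated datasets per iteration.
#' @param max_iter iteration cap.
#' @param tol sup-norm convergence tolerance on the damped update
#'   (transformed scale).
#' @param damping step factor `lambda` in (0, 1].
#' @param seed seed for the common random numbers.
#' @param init optional [copula_lmm_params()] starting value; default is
#'   the plug-in map of the observed data.
#' @return object of class `copula_lmm_fit`: `estimates`
#'   ([copula_lmm_params()]), `theta` (transformed scale), `trace` (matrix
#'   of iterates), `converged`, `n_iter`, plus the inputs needed by
#'   [estimate_uncertainty()].
#' @export
fit_iterative_bootstrap <- function(data, design, H = 100L, max_iter = 100L,
                                    tol = 0.01, damping = 0.5, seed = 1L,
                                    init = NULL) {
  stopifnot(inherits(design, "ca_design"))
  y_obs <- data_to_matrix(data, design)
  p <- ncol(design$x)
  pi_obs <- auxiliary_stats(y_obs, design)
  bounds <- param_bounds(p)

  theta <- if (is.null(init)) {
    pmin(pmax(unname(pi_obs), bounds$lower), bounds$upper)
  } else {
    params_to_theta(init)
  }
  crn_seed <- substream_seed(seed, "ib", "crn")

  trace <- matrix(NA_real_, max_iter + 1L, length(theta),
                  dimnames = list(NULL, theta_names(p)))
  trace[1L, ] <- theta
  converged <- FALSE
  grow_count <- 0L
  last_norm <- Inf
  n_iter <- 0L

  for (k in seq_len(max_iter)) {
    pi_sim <- sim_aux_mean(theta, design, H, crn_seed)
    step <- damping * (unname(pi_obs) - pi_sim)
    theta_new <- pmin(pmax(theta + step, bounds$lower), bounds$upper)
    norm_k <- max(abs(theta_new - theta))
    n_iter <- k
    trace[k + 1L, ] <- theta_new
    theta <- theta_new
    if (norm_k < tol) {
      converged <- TRUE
      break
    }
    if (norm_k > last_norm * (1 + 1e-8)) grow_count <- grow_count + 1L else grow_count <- 0L
    if (grow_count >= 5L) {
      stop("iterative bootstrap diverging (update norm grew 5 iterations in a row); ",
           "retry with stronger damping (smaller `damping`)")
    }
    last_norm <- norm_k
  }

  structure(
    list(estimates = theta_to_params(theta, p), theta = theta,
         theta_names = theta_names(p),
         trace = trace[seq_len(n_iter + 1L), , drop = FALSE],
         converged = converged, n_iter = n_iter,
         pi_obs = pi_obs, design = design, H = H, damping = damping,
         seed = seed, data_matrix = y_obs),
    class = "copula_lmm_fit"
  )
}

# mean of the auxiliary map over H simulations at theta, under common
# random numbers (same seed whatever theta).
sim_aux_mean <- function(theta, design, H, crn_seed) {
  params <- theta_to_params(theta, ncol(design$x))
  sims <- withr::with_seed(crn_seed, simulate_ca_matrix(params, design, H))
  rowMeans(aux_stats_multi(sims$y, design))
}

#' @export
print.copula_lmm_fit <- function(x, ...) {
  cat(sprintf("Copula LMM fit (%s after %d iterations, H = %d)\n",
              if (x$converged) "converged" else "NOT converged", x$n_iter, x$H))
  print(x$estimates)
  invisible(x)
}
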