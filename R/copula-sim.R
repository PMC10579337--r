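#' Simulate per-field log CA scores from the copula mixed model
#'
#' Draws one dataset from the hierarchical mean-variance copula model (see
#' [copula_lmm_params()] for the generative form). Observations are on the
#' log-CA scale, the scale on which the additive mixed model is coherent
#' for a positive, right-skewed score.
#'
#' @param params a [copula_lmm_params()] object.
#' @param design a [ca_design()] object.
#' @param seed integer seed; the draw is deterministic given
#'   `(params, design, seed)`.
#' @return a tibble with columns `tissue_id`, `field`, `y` (log CA), plus
#'   the latent `b_i` and `sigma_i` as attributes `"latent"` for
#'   diagnostics.
#' @export
simulate_ca_dataset <- function(params, design, seed = 1L) {
  stopifnot(inherits(params, "copula_lmm_params"), inherits(design, "ca_design"))
  if (length(params$beta) != ncol(design$x)) {
    stop("parameter dimension does not match design: length(beta) != ncol(x)")
  }
  sim <- withr::with_seed(as.integer(seed),
                          simulate_ca_matrix(params, design, n_rep = 1L))
  m <- nrow(design$x)
  n <- design$n_i
  y <- sim$y[, , 1L]
  keep <- rep(seq_len(m), n)
  out <- tibble::tibble(
    tissue_id = design$tissue_id[keep],
    field = unlist(lapply(n, seq_len)),
    y = y[cbind(keep, unlist(lapply(n, seq_len)))]
  )
  attr(out, "latent") <- tibble::tibble(
    tissue_id = design$tissue_id, b = sim$b[, 1L], sigma = sim$sigma[, 1L]
  )
  out
}

# Vectorized engine: draws n_rep independent datasets at once using the
# current RNG stream. Fields are stored in an m x max(n_i) x n_rep array;
# ragged designs leave trailing NA cells (column j valid for tissue i iff
# j <= n_i[i]). All downstream summaries respect the validity mask.
simulate_ca_matrix <- function(params, design, n_rep) {
  x <- design$x
  m <- nrow(x)
  n <- design$n_i
  nmax <- max(n)
  mu <- drop(x %*% params$beta)           # length m
  log_scale <- drop(x %*% params$gamma)   # length m

  u <- matrix(stats::rnorm(m * n_rep), m, n_rep)
  w <- matrix(stats::rnorm(m * n_rep), m, n_rep)
  v <- params$rho * u + sqrt(1 - params$rho^2) * w
  b <- params$tau * u
  if (is.infinite(params$alpha)) {
    g <- matrix(1, m, n_rep)
  } else {
    # mean-1 gamma through the copula's normal score
    g <- stats::qgamma(stats::pnorm(v), shape = params$alpha, rate = params$alpha)
  }
  sigma <- exp(log_scale) * g

  if (is.infinite(params$nu)) {
    eps <- array(stats::rnorm(m * nmax * n_rep), c(m, nmax, n_rep))
  } else {
    eps <- array(stats::rt(m * nmax * n_rep, df = params$nu) *
                   sqrt((params$nu - 2) / params$nu), c(m, nmax, n_rep))
  }
  y <- eps
  for (r in seq_len(n_rep)) {
    y[, , r] <- mu + b[, r] + sigma[, r] * eps[, , r]
  }
  if (any(n < nmax)) {
    mask <- outer(n, seq_len(nmax), `>=`)
    for (r in seq_len(n_rep)) y[, , r][!mask] <- NA_real_
  }
  list(y = y, b = b, sigma = sigma)
}
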