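#' Auxiliary statistics for indirect inference
#'
#' Maps a dataset to a plug-in estimate of the full parameter vector on the
#' fitter's transformed scale. Each model parameter is matched to exactly
#' one auxiliary coordinate:
#'
#' * mean-regression coefficients of tissue means on the design -> `beta`;
#' * log-SD-regression coefficients of `log s_i` on the design -> `gamma`;
#' * between-tissue variance of the mean residuals minus the average
#'   within-tissue sampling variance `mean(s_i^2 / n_i)`, floored at a
#'   small positive value -> `log tau` (via `0.5 * log`);
#' * trigamma-inverse of the log-SD residual variance -> `log alpha`
#'   (for a mean-1 gamma scale, `var(log sigma_i) = trigamma(alpha)`);
#' * correlation between the mean-residual and log-SD-residual series ->
#'   `atanh rho`;
#' * pooled excess kurtosis of within-tissue standardized residuals ->
#'   `log(nu - 2)` (for standardized t, excess kurtosis is `6 / (nu - 4)`).
#'
#' The plug-in map is deliberately crude — every coordinate is biased in
#' finite samples — because the iterative bootstrap matches observed and
#' simulated auxiliary statistics under the same map, which removes the
#' bias without requiring the map itself to be unbiased.
#'
#' @param data a tibble with columns `tissue_id` and `y` (log CA), or a
#'   numeric matrix of fields (tissues x fields, NA-padded).
#' @param design a [ca_design()] object; every tissue must have `n_i >= 2`.
#' @return named numeric vector of length `2 p + 4` on the transformed
#'   parameter scale.
#' @export
auxiliary_stats <- function(data, design) {
  y <- data_to_matrix(data, design)
  counts <- rowSums(!is.na(y))
  if (any(counts < 2)) {
    stop("tissues with fewer than 2 fields: ",
         paste(design$tissue_id[counts < 2], collapse = ", "))
  }
  stats <- aux_stats_multi(array(y, c(dim(y), 1L)), design)
  stats::setNames(stats[, 1L], theta_names(ncol(design$x)))
}

# Convert a long tibble (tissue_id, y) to the m x nmax NA-padded matrix in
# design tissue order.
data_to_matrix <- function(data, design) {
  if (is.matrix(data)) return(data)
  stopifnot(all(c("tissue_id", "y") %in% names(data)))
  idx <- match(data$tissue_id, design$tissue_id)
  if (anyNA(idx)) stop("data contains tissue ids absent from the design")
  nmax <- max(tabulate(idx, nbins = nrow(design$x)))
  y <- matrix(NA_real_, nrow(design$x), nmax)
  ord <- order(idx)
  pos <- sequence(tabulate(idx, nbins = nrow(design$x)))
  y[cbind(idx[ord], pos)] <- data$y[ord]
  y
}

# Vectorized auxiliary statistics over the replicate slices of an
# m x nmax x n_rep array. Returns a (2p + 4) x n_rep matrix on the
# transformed parameter scale. This is the single code path used for both
# observed data and simulated data (self-consistency by construction).
aux_stats_multi <- function(y_arr, design) {
  x <- design$x
  p <- ncol(x)
  m <- nrow(x)
  n_rep <- dim(y_arr)[3]
  n_i <- design$n_i

  nmax <- dim(y_arr)[2]

  # Per-tissue means/SDs per replicate, without per-cell function calls:
  # collapse the field dimension by summing the (field, tissue, rep)
  # permutation of the array.
  sums <- colSums(aperm(y_arr, c(2, 1, 3)), na.rm = TRUE)     # m x n_rep
  ybar <- sums / n_i
  ybar_full <- aperm(array(ybar, c(m, n_rep, nmax)), c(1, 3, 2))
  dev <- y_arr - ybar_full
  s2 <- colSums(aperm(dev * dev, c(2, 1, 3)), na.rm = TRUE) / (n_i - 1)
  s <- sqrt(pmax(s2, 1e-12))
  logs <- log(s)

  xtx_inv_xt <- solve(crossprod(x), t(x))          # p x m, reused for both fits
  beta_hat <- xtx_inv_xt %*% ybar                  # p x n_rep
  gamma_hat <- xtx_inv_xt %*% logs                 # p x n_rep
  r_mean <- ybar - x %*% beta_hat                  # m x n_rep residual series
  r_logs <- logs - x %*% gamma_hat

  denom <- m - 1
  var_rm <- colSums(r_mean^2) / denom
  var_rs <- colSums(r_logs^2) / denom
  samp_var <- colMeans(s2 / n_i)
  tau2 <- pmax(var_rm - samp_var, 1e-6)

  corr <- colSums(r_mean * r_logs) / denom / sqrt(var_rm * var_rs)
  corr <- pmax(pmin(corr, 0.99), -0.99)

  alpha_hat <- limma::trigammaInverse(pmax(var_rs, 1e-6))
  alpha_hat <- pmax(pmin(alpha_hat, 1e5), 0.05)

  # pooled excess kurtosis of (y - ybar_i) / s_i, per replicate
  s_full <- aperm(array(s, c(m, n_rep, nmax)), c(1, 3, 2))
  z <- dev / s_full
  z2 <- matrix(z * z, m * nmax, n_rep)
  n_tot <- sum(n_i)
  m2 <- colSums(z2, na.rm = TRUE) / n_tot
  m4 <- colSums(z2 * z2, na.rm = TRUE) / n_tot
  kurt <- m4 / (m2 * m2) - 3
  nu_hat <- 4 + 6 / pmax(pmin(kurt, 100), 0.02)

  rbind(beta_hat, gamma_hat,
        0.5 * log(tau2), log(alpha_hat), atanh(corr), log(nu_hat - 2))
}
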