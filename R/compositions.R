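#' Additive log-ratio transform of signature compositions
#'
#' Maps samples x 7 copy-number-signature exposures (rows on the unit
#' simplex) to samples x 6 unconstrained coordinates
#' `coord_k = ln(s_k / s_D)` with denominator part `D` (signature 7 by
#' convention). Zeros are replaced by half the smallest positive entry of
#' the matrix before taking ratios — the standard compositional
#' zero-handling — and the replacement is recorded as an attribute.
#' Coordinates are invariant to rescaling a row by a positive constant
#' (closure invariance).
#'
#' @param compositions samples x K matrix (K >= 2), non-negative rows.
#' @param denominator index of the denominator part (default: last
#'   column).
#' @return samples x (K-1) matrix of ALR coordinates; attribute
#'   `"denominator"`, and `"zero_replacement"` when zeros were replaced.
#' @export
alr_transform <- function(compositions, denominator = ncol(compositions)) {
  x <- as.matrix(compositions)
  if (any(x < 0)) stop("compositions must be non-negative")
  eps <- NULL
  if (any(x == 0)) {
    pos <- x[x > 0]
    if (length(pos) == 0L) stop("all-zero composition matrix")
    eps <- min(pos) / 2
    x[x == 0] <- eps
  }
  if (any(x[, denominator] <= 0)) {
    stop("denominator part non-positive after zero replacement")
  }
  out <- log(x[, -denominator, drop = FALSE] / x[, denominator])
  colnames(out) <- colnames(x)[-denominator]
  attr(out, "denominator") <- denominator
  if (!is.null(eps)) attr(out, "zero_replacement") <- eps
  out
}

#' Inverse additive log-ratio transform
#'
#' Restores closed compositions (rows summing to 1) from ALR coordinates;
#' `alr_inverse(alr_transform(x))` reproduces a closed `x` to machine
#' precision.
#'
#' @param coords samples x (K-1) ALR coordinate matrix.
#' @param denominator position of the denominator part in the output.
#' @return samples x K composition matrix, rows summing to 1.
#' @export
alr_inverse <- function(coords, denominator = ncol(coords) + 1L) {
  z <- as.matrix(coords)
  k <- ncol(z) + 1L
  full <- matrix(1, nrow(z), k)
  full[, setdiff(seq_len(k), denominator)] <- exp(z)
  full / rowSums(full)
}

#' Global Wald test for a compositional group shift
#'
#' Regresses all ALR coordinates jointly on a two-level group indicator
#' (multivariate linear model) and tests that the six group coefficients
#' are simultaneously zero, using the estimated coefficient covariance
#' across coordinates. The statistic is Hotelling's T^2 form of the Wald
#' statistic; the p-value uses the exact F reference
#' `F(q, n - q - 1)` (with `q` coordinates and `n` samples), which is
#' exact under Gaussian coordinate errors and matches the chi-square
#' Wald asymptotically.
#'
#' @param alr_coords samples x q coordinate matrix (from
#'   [alr_transform()]).
#' @param groups two-level factor/vector, `>= 2` samples per group.
#' @return tibble with one row per coordinate (`coefficient`, `se`,
#'   `t`, `p`) plus attributes `"wald"` (global statistic), `"p_global"`,
#'   `"df"`.
#' @export
wald_composition_test <- function(alr_coords, groups) {
  z <- as.matrix(alr_coords)
  g <- factor(groups)
  if (nlevels(g) != 2L) stop("`groups` must have exactly two levels")
  if (any(table(g) < 2L)) stop("need >= 2 samples per group")
  n <- nrow(z)
  q <- ncol(z)
  xg <- cbind(1, as.numeric(g == levels(g)[2]))
  fit <- stats::lm.fit(xg, z)
  coefs <- fit$coefficients[2L, ]            # group contrasts, length q
  res <- z - xg %*% fit$coefficients
  df_res <- n - 2L
  Sigma <- crossprod(res) / df_res           # coordinate error covariance
  xtx_inv <- solve(crossprod(xg))
  v_scale <- xtx_inv[2L, 2L]                 # variance factor of the contrast
  V <- Sigma * v_scale
  Vc <- tryCatch(solve(V, coefs), error = function(e) {
    stop("singular coefficient covariance; prune collinear ALR coordinates")
  })
  t2 <- drop(crossprod(coefs, Vc))
  f_stat <- t2 * (df_res - q + 1) / (df_res * q)
  p_global <- stats::pf(f_stat, q, df_res - q + 1, lower.tail = FALSE)

  se <- sqrt(diag(V))
  per <- tibble::tibble(
    coordinate = colnames(z) %||% paste0("alr", seq_len(q)),
    coefficient = unname(coefs), se = se, t = unname(coefs) / se,
    p = 2 * stats::pt(-abs(unname(coefs) / se), df_res))
  attr(per, "wald") <- t2
  attr(per, "p_global") <- p_global
  attr(per, "df") <- c(q = q, df_res = df_res)
  per
}
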