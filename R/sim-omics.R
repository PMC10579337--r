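#' Simulate a gene-expression matrix with a planted CA20 signal
#'
#' Generates a log2-scale genes x samples matrix containing all CA20 and
#' CIN25 signature genes plus unrelated filler genes. Half the samples
#' (labelled `"high"`) receive `planted_effect` log2 units of extra
#' expression on every CA20 gene, so the expected CA20 score gap between
#' the groups is `20 * planted_effect` (median-centring subtracts a
#' per-gene constant and cannot change a between-group gap). With
#' `noise_sd = 0` the gap is exact.
#'
#' @param n_samples number of samples (`>= 4`; median-centring over fewer
#'   is degenerate).
#' @param planted_effect log2 shift added to CA20 genes in "high" samples.
#' @param noise_sd iid Gaussian noise SD (log2 units).
#' @param n_filler unrelated genes to append.
#' @param seed RNG seed.
#' @return list: `matrix` (genes x samples, log2 scale), `labels`
#'   (`"high"`/`"low"` per sample), `baseline` per-gene means.
#' @export
simulate_expression_matrix <- function(n_samples, planted_effect = 1,
                                       noise_sd = 0.5, n_filler = 200L,
                                       seed = 1L) {
  if (n_samples < 4L) stop("n_samples must be >= 4 (median-centring degenerate)")
  genes <- unique(c(ca20_genes, cin25_genes,
                    sprintf("FILLER%03d", seq_len(n_filler))))
  withr::with_seed(seed, {
    base <- stats::runif(length(genes), 3, 9)  # per-gene baseline, log2 scale
    mat <- matrix(base, length(genes), n_samples) +
      matrix(stats::rnorm(length(genes) * n_samples, 0, noise_sd),
             length(genes), n_samples)
    labels <- rep(c("high", "low"), length.out = n_samples)
    mat[genes %in% ca20_genes, labels == "high"] <-
      mat[genes %in% ca20_genes, labels == "high"] + planted_effect
    dimnames(mat) <- list(genes, sprintf("S%03d", seq_len(n_samples)))
    list(matrix = mat, labels = labels,
         baseline = stats::setNames(base, genes))
  })
}

#' Simulate copy-number-signature compositions with a planted group shift
#'
#' Draws 7-part signature exposure vectors from a logistic-normal model:
#' additive log-ratio (ALR) coordinates (denominator = signature 7) are
#' Gaussian around `alr(base)`, with SD `1 / sqrt(concentration)`; group
#' B's coordinates are shifted by `alr_shift` before back-transforming.
#' Rows sum to 1 by construction. As `concentration` grows the
#' compositions concentrate on the closed-form ALR inverse of the group
#' means.
#'
#' @param n_per_group samples per group.
#' @param base 7-part composition (positive, sums to 1) for group A.
#' @param alr_shift length-6 shift applied in ALR space for group B.
#' @param concentration inverse-variance of the ALR coordinates.
#' @param seed RNG seed.
#' @return list: `exposures` (2 n x 7 matrix, rows sum to 1), `group`
#'   (factor `"A"`/`"B"`).
#' @export
simulate_signature_compositions <- function(n_per_group,
                                            base = c(0.20, 0.15, 0.15, 0.15,
                                                     0.10, 0.10, 0.15),
                                            alr_shift = rep(0, 6),
                                            concentration = 25,
                                            seed = 1L) {
  if (length(base) != 7L) stop("`base` must have 7 parts")
  if (any(base <= 0)) stop("all `base` entries must be positive")
  if (abs(sum(base) - 1) > 1e-9) stop("`base` must sum to 1")
  if (length(alr_shift) != 6L) stop("`alr_shift` must have length 6")
  mu <- alr_transform(matrix(base, 1))[1, ]
  sd <- 1 / sqrt(concentration)
  withr::with_seed(seed, {
    n <- 2L * n_per_group
    coords <- matrix(stats::rnorm(n * 6L, 0, sd), n, 6L, byrow = FALSE)
    coords <- sweep(coords, 2, mu, `+`)
    grp <- rep(c("A", "B"), each = n_per_group)
    coords[grp == "B", ] <- sweep(coords[grp == "B", , drop = FALSE], 2,
                                  alr_shift, `+`)
    expo <- alr_inverse(coords)
    colnames(expo) <- paste0("s", 1:7)
    rownames(expo) <- sprintf("%s%03d", grp, c(seq_len(n_per_group),
                                               seq_len(n_per_group)))
    list(exposures = expo, group = factor(grp))
  })
}
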