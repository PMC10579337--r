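#' Signature gene sets
#'
#' `ca20_genes`: the 20-gene centrosome-amplification expression
#' signature. `cin25_genes`: the 25-gene chromosomal-instability
#' signature (the first entry, C20orf24, is also known as TGIF2).
#' The same lists ship as TSV files under
#' `inst/extdata/signatures/` for use outside R.
#'
#' @format character vectors of HGNC symbols.
#' @export
ca20_genes <- c("AURKA", "CCNA2", "CCND1", "CCNE2", "CDK1", "CEP63",
                "CEP152", "E2F1", "E2F2", "LMO4", "MDM2", "MYCN", "NDRG1",
                "NEK2", "PIN1", "PLK1", "PLK4", "SASS6", "STIL", "TUBG1")

#' @rdname ca20_genes
#' @export
cin25_genes <- c("C20orf24", "CCNB2", "CCT5", "CDC45", "CDC2", "ESPL1",
                 "FEN1", "FOXM1", "H2AFZ", "KIF20A", "MAD2L1", "MCM2",
                 "MCM7", "MELK", "NCAPD2", "PCNA", "PRC1", "RAD51AP1",
                 "RFC4", "RNASEH2A", "TOP2A", "TPX2", "TRIP13", "TTK",
                 "UBE2C")

#' Build a signature definition
#'
#' @param name signature name.
#' @param genes character vector of gene symbols.
#' @return list of class `signature_definition`.
#' @export
signature_definition <- function(name, genes) {
  stopifnot(is.character(genes), length(genes) > 0L, !anyDuplicated(genes))
  structure(list(name = name, genes = genes), class = "signature_definition")
}

#' Quantile-normalize a genes x samples matrix
#'
#' Forces every sample (column) to share the same sorted value vector —
#' the row-wise mean of the per-sample sorted columns — while preserving
#' within-sample ranks; ties receive the average of the tied reference
#' values. Delegates to `limma::normalizeQuantiles`.
#'
#' @param mat numeric genes x samples matrix, `>= 2` columns,
#'   non-negative.
#' @return normalized matrix with the same dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("quantile normalization needs >= 2 samples")
  if (any(mat < 0)) stop("expression values must be non-negative")
  limma::normalizeQuantiles(mat, ties = TRUE)
}

#' Score an expression signature (CA20 / CIN25 convention)
#'
#' The score of a sample is the sum over the signature genes of the
#' log2 median-centred expression: optionally quantile-normalize,
#' optionally `log2(x + 0.5)`, subtract each gene's median across
#' samples, and sum the signature rows. Samples are labelled
#' `"high"`/`"low"` by a median split of the scores; samples exactly at
#' the median go to `"low"` (deterministic tie rule).
#'
#' @param mat genes x samples matrix. Use `normalize = "quantile"` and
#'   `log2_transform = TRUE` for count-scale input; both off for data
#'   already on a normalized log2 scale.
#' @param signature a [signature_definition()], or one of `"CA20"`,
#'   `"CIN25"`.
#' @param normalize `"quantile"` or `"none"`.
#' @param log2_transform apply `log2(x + 0.5)` after normalization.
#' @param allow_partial proceed when signature genes are missing
#'   (scores then sum over the present subset); default refuses and
#'   lists the missing genes.
#' @return tibble: `sample`, `score`, `label`; attribute `"signature"`.
#' @export
score_signature <- function(mat, signature = "CA20",
                            normalize = c("quantile", "none"),
                            log2_transform = TRUE,
                            allow_partial = FALSE) {
  normalize <- match.arg(normalize)
  if (is.character(signature)) {
    signature <- switch(signature,
      CA20 = signature_definition("CA20", ca20_genes),
      CIN25 = signature_definition("CIN25", cin25_genes),
      stop("unknown signature name: ", signature))
  }
  mat <- as.matrix(mat)
  missing <- setdiff(signature$genes, rownames(mat))
  if (length(missing) > 0L && !allow_partial) {
    stop("matrix is missing ", length(missing), " ", signature$name,
         " gene(s): ", paste(missing, collapse = ", "),
         " (set allow_partial = TRUE to score the present subset)")
  }
  if (normalize == "quantile") mat <- quantile_normalize(mat)
  if (log2_transform) mat <- log2(mat + 0.5)
  med <- apply(mat, 1, stats::median)
  centred <- mat - med
  rows <- intersect(signature$genes, rownames(mat))
  scores <- unname(colSums(centred[rows, , drop = FALSE]))
  split_at <- stats::median(scores)
  out <- tibble::tibble(
    sample = colnames(mat) %||% as.character(seq_along(scores)),
    score = scores,
    label = ifelse(scores > split_at, "high", "low"))
  attr(out, "signature") <- signature$name
  out
}
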