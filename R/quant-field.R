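#' Quantify one imaging field: CA score and per-cell metrics
#'
#' Orchestrates the full per-field analysis: maximum projection, nuclei
#' segmentation with border/area QC, mitotic classification (pHH3 channel,
#' when present), centrosome spot detection with nucleus ownership,
#' CEP164 positivity (when present) and micronucleus detection. The field
#' CA score is the assay's printed formula: total detected centrosomes
#' divided by total detected (whole, non-border) nuclei. Per-cell metrics
#' follow the cell-line conventions: CA frequency is the share of
#' non-mitotic cells with two or more centrosomes; MN frequency the share
#' of non-mitotic cells with at least one micronucleus; the mitotic index
#' is mitotic / whole cells.
#'
#' @param stack a `ca_image_stack` with at least DNA and PCM channels.
#' @param params nested parameter list: `nuclei`, `spots`, `micronuclei`,
#'   `mitotic_threshold`, `marker_rule` (see the stage functions).
#' @param field_id identifier carried into the output.
#' @return list with `field` (one-row tibble: `field_id`, `n_nuclei`,
#'   `n_centrosomes`, `ca_score`, `ca_frequency`, `mitotic_index`,
#'   `mn_frequency`, `cep164_fraction`, `mean_spot_size_px2`,
#'   `passes_qc`, `qc_reason`) and `cells` (per whole cell: `label`,
#'   `n_centrosomes`, `is_mitotic`, `n_micronuclei`), plus `spots` and
#'   `nuclei` tables. Zero whole nuclei gives `ca_score = NA`,
#'   `passes_qc = FALSE`, reason `"no_whole_nuclei"`.
#' @export
quantify_field <- function(stack, params = list(), field_id = "field_1") {
  stopifnot(inherits(stack, "ca_image_stack"))
  ch <- stack$channel_names
  if (!all(c("DNA", "PCM") %in% ch)) stop("stack needs DNA and PCM channels")
  proj <- max_project(stack)

  nuc_params <- params$nuclei %||% list()
  nuclei <- segment_nuclei(proj$DNA, nuc_params)

  if ("pHH3" %in% ch) {
    nuclei <- classify_mitotic(nuclei, proj$pHH3, threshold = params$mitotic_threshold)
  } else {
    nuclei$is_mitotic <- rep(FALSE, nrow(nuclei))
    nuclei$phh3_mean <- rep(NA_real_, nrow(nuclei))
  }
  nuclei <- detect_micronuclei(proj$DNA, nuclei, params$micronuclei %||% list())

  spot_params <- params$spots %||% list()
  spot_params$pixel_size_um <- stack$pixel_size_um
  spots <- detect_spots(proj$PCM, nuclei, spot_params)
  if ("CEP164" %in% ch) {
    spots <- score_marker_positivity(spots, proj$CEP164,
                                     params$marker_rule %||% list(k = 6))
  } else {
    spots$cep164_positive <- rep(NA, nrow(spots))
  }

  whole <- nuclei[!nuclei$touches_border, , drop = FALSE]
  n_whole <- nrow(whole)
  owned <- spots[spots$nucleus_label %in% whole$label, , drop = FALSE]

  cells <- tibble::tibble(
    label = whole$label,
    n_centrosomes = vapply(whole$label, function(l)
      sum(owned$nucleus_label == l), 0L),
    is_mitotic = whole$is_mitotic,
    n_micronuclei = whole$n_micronuclei,
    gammaH2AX_positive = rep(NA, n_whole))

  non_mit <- cells[!cells$is_mitotic, , drop = FALSE]
  field <- tibble::tibble(
    field_id = field_id,
    n_nuclei = n_whole,
    n_centrosomes = nrow(owned),
    ca_score = if (n_whole > 0L) nrow(owned) / n_whole else NA_real_,
    ca_frequency = if (nrow(non_mit) > 0L)
      mean(non_mit$n_centrosomes >= 2L) else NA_real_,
    mitotic_index = if (n_whole > 0L) mean(cells$is_mitotic) else NA_real_,
    mn_frequency = if (nrow(non_mit) > 0L)
      mean(non_mit$n_micronuclei >= 1L) else NA_real_,
    cep164_fraction = if (nrow(owned) > 0L)
      mean(owned$cep164_positive) else NA_real_,
    mean_spot_size_px2 = if (nrow(owned) > 0L)
      mean(owned$size_px2) else NA_real_,
    passes_qc = n_whole > 0L,
    qc_reason = if (n_whole > 0L) NA_character_ else "no_whole_nuclei")

  list(field = field, cells = cells, spots = spots, nuclei = nuclei)
}

#' Remove low-CA imaging fields (assay QC rule)
#'
#' Fields with CA score below `qc_min` are removed before any downstream
#' analysis — the assay's guard against staining background and false
#' positive detections. Fields with undefined CA score (no whole nuclei)
#' are always removed. Raising `qc_min` can only shrink the retained set.
#'
#' @param fields tibble with a `ca_score` column (one row per field).
#' @param qc_min minimum CA score retained (default 0.1, the assay
#'   cutoff); scores `< qc_min` are dropped.
#' @return the retained subset, with attribute `"excluded"` recording the
#'   dropped rows and reasons. All fields removed raises a warning, not an
#'   error.
#' @export
qc_filter_fields <- function(fields, qc_min = 0.1) {
  undefined <- is.na(fields$ca_score)
  low <- !undefined & fields$ca_score < qc_min
  keep <- !undefined & !low
  excluded <- fields[!keep, , drop = FALSE]
  excluded$qc_reason <- ifelse(is.na(fields$ca_score[!keep]),
                               "undefined_ca_score", "ca_below_qc_min")
  out <- fields[keep, , drop = FALSE]
  if (nrow(out) == 0L && nrow(fields) > 0L) {
    warning("all imaging fields removed by QC (qc_min = ", qc_min, ")")
  }
  attr(out, "excluded") <- excluded
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
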