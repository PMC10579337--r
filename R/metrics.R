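#' Aggregate QC-filtered imaging fields into a per-sample CA profile
#'
#' The sample summary is the median of the per-field CA scores (each
#' boxplot in the cohort figures is one sample's fields); tissue
#' heterogeneity is the standard deviation of log-transformed CA scores
#' across the sample's fields (natural log by default — the log base only
#' rescales all heterogeneity scores by a constant). Heterogeneity needs
#' at least two retained fields, and is invariant to multiplying all
#' fields by a constant.
#'
#' @param fields numeric vector of post-QC field CA scores, or a tibble
#'   with a `ca_score` column.
#' @param metadata named list/tibble row of sample annotations carried
#'   through (`sample_id`, `patient_id`, `cohort`, `tissue_type`, ...).
#' @param log_base base for the heterogeneity log (default natural).
#' @return one-row tibble: metadata columns + `n_fields`, `median_ca`,
#'   `heterogeneity`, `mean_spot_size` (when provided in `fields`).
#'   Zero fields is an error: the sample must be excluded upstream with a
#'   reason, not silently summarised.
#' @export
aggregate_sample <- function(fields, metadata = list(sample_id = "sample"),
                             log_base = exp(1)) {
  scores <- if (is.data.frame(fields)) fields$ca_score else fields
  if (length(scores) == 0L) {
    stop("no retained fields for sample '",
         metadata$sample_id %||% "?", "': exclude the sample with a reason")
  }
  if (any(is.na(scores) | scores < 0)) stop("field CA scores must be non-negative and defined")
  het <- if (length(scores) >= 2L) stats::sd(log(scores, base = log_base)) else NA_real_
  spot <- if (is.data.frame(fields) && "mean_spot_size_px2" %in% names(fields)) {
    mean(fields$mean_spot_size_px2, na.rm = TRUE)
  } else NA_real_
  dplyr::bind_cols(
    tibble::as_tibble(metadata),
    tibble::tibble(n_fields = length(scores), median_ca = stats::median(scores),
                   heterogeneity = het, mean_spot_size = spot))
}

#' Normalize sample CA scores to cohort controls
#'
#' Divides each sample's median CA by the median of the control samples'
#' medians within the same cohort, so batch effects between cohorts drop
#' out and a normalized score of 1 means "like normal control tissue".
#' The operation is idempotent: renormalizing already-normalized data
#' with the same controls is the identity.
#'
#' @param samples tibble from [aggregate_sample()] rows, with `cohort`
#'   and `median_ca` columns.
#' @param is_control logical vector (or a predicate taking the tibble and
#'   returning one) selecting control samples.
#' @return `samples` with a `normalized_ca` column; attribute
#'   `"control_medians"` records the per-cohort divisor.
#' @export
normalize_to_controls <- function(samples, is_control) {
  ctrl <- if (is.function(is_control)) is_control(samples) else is_control
  stopifnot(length(ctrl) == nrow(samples))
  cohorts <- unique(samples$cohort)
  missing <- cohorts[!cohorts %in% unique(samples$cohort[ctrl])]
  if (length(missing) > 0L) {
    stop("no control samples in cohort(s): ", paste(missing, collapse = ", "))
  }
  ctrl_med <- vapply(cohorts, function(co)
    stats::median(samples$median_ca[ctrl & samples$cohort == co]), 0)
  names(ctrl_med) <- cohorts
  samples$normalized_ca <- unname(samples$median_ca / ctrl_med[samples$cohort])
  attr(samples, "control_medians") <- ctrl_med
  samples
}

#' Derive the cohort CA threshold from normal fallopian-tube samples
#'
#' Selects the normal-FT sample with the highest median normalized CA and
#' returns the upper bound of the boxplot-notch 95% confidence interval
#' for its median over its retained fields:
#' `median + 1.58 * IQR / sqrt(n)`. A bootstrap percentile CI of the
#' median is available as an alternative.
#'
#' @param ft_samples tibble of normal-FT samples: columns `sample_id`,
#'   `normalized_ca`, and a `fields` list-column of per-field normalized
#'   CA scores (each with `>= 2` fields).
#' @param method `"notch"` (default) or `"bootstrap"`.
#' @param boot_reps,seed bootstrap settings.
#' @return list of class `ca_threshold`: `threshold`, `source_sample`,
#'   `n_fields`, `method`.
#' @export
derive_ca_threshold <- function(ft_samples, method = c("notch", "bootstrap"),
                                boot_reps = 2000L, seed = 1L) {
  method <- match.arg(method)
  if (nrow(ft_samples) == 0L) stop("no normal-FT samples: cannot derive a CA threshold")
  top <- which.max(ft_samples$normalized_ca)
  fields <- ft_samples$fields[[top]]
  if (length(fields) < 2L) stop("top FT sample has fewer than 2 retained fields")
  thr <- if (method == "notch") {
    stats::median(fields) + 1.58 * stats::IQR(fields) / sqrt(length(fields))
  } else {
    med_boot <- withr::with_seed(seed, vapply(seq_len(boot_reps), function(b)
      stats::median(sample(fields, replace = TRUE)), 0))
    stats::quantile(med_boot, 0.975, names = FALSE)
  }
  structure(list(threshold = thr,
                 source_sample = ft_samples$sample_id[top],
                 n_fields = length(fields), method = method),
            class = "ca_threshold")
}

#' @export
print.ca_threshold <- function(x, ...) {
  cat(sprintf("CA threshold %.4g (%s; source sample %s, %d fields)\n",
              x$threshold, x$method, x$source_sample, x$n_fields))
  invisible(x)
}

#' Call CA status against the cohort threshold
#'
#' A sample is CA-positive iff its normalized median CA strictly exceeds
#' the threshold (scores exactly at the cutoff are negative).
#'
#' @param samples tibble with `normalized_ca`.
#' @param threshold a [derive_ca_threshold()] result or a number.
#' @return `samples` with logical `ca_positive` added.
#' @export
call_ca_status <- function(samples, threshold) {
  thr <- if (inherits(threshold, "ca_threshold")) threshold$threshold else threshold
  samples$ca_positive <- samples$normalized_ca > thr
  samples
}

#' Per-patient CA summary across multiple tissue samples
#'
#' For patients with several tissues, the patient-level CA score is the
#' median of the samples' normalized CA, called against the same
#' threshold. Per-sample calls are preserved so intra-patient
#' discordance stays visible.
#'
#' @param samples tibble with `patient_id`, `normalized_ca` (and
#'   optionally `ca_positive`).
#' @param threshold as in [call_ca_status()].
#' @return tibble: `patient_id`, `n_samples`, `patient_ca`,
#'   `ca_positive`, `discordant` (TRUE when the patient's samples carry
#'   mixed calls).
#' @export
patient_level_summary <- function(samples, threshold) {
  thr <- if (inherits(threshold, "ca_threshold")) threshold$threshold else threshold
  if (!"ca_positive" %in% names(samples)) {
    samples <- call_ca_status(samples, thr)
  }
  samples |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_samples = dplyr::n(),
      patient_ca = stats::median(.data$normalized_ca),
      # per-sample calls first: `ca_positive` below shadows the column
      discordant = dplyr::n_distinct(.data$ca_positive) > 1L,
      ca_positive = stats::median(.data$normalized_ca) > thr,
      .groups = "drop")
}

#' Rank-based comparison of CA metrics between groups
#'
#' Two groups: Wilcoxon rank-sum (or signed-rank when `paired`); more
#' than two: Kruskal-Wallis. `exact` forces the exact small-sample null
#' where available.
#'
#' @param values numeric vector.
#' @param groups factor/vector of group labels (>= 2 non-empty groups).
#' @param paired paired two-group comparison.
#' @param exact exact p-value for small samples.
#' @return tibble: `statistic`, `p_value`, `method`, `n_groups`.
#' @export
compare_groups <- function(values, groups, paired = FALSE, exact = NULL) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L || any(table(groups) == 0L)) {
    stop("need at least two non-empty groups")
  }
  if (stats::var(values) == 0) {
    # all observations identical: no evidence against any null
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          method = "degenerate (constant values)",
                          n_groups = nlevels(groups)))
  }
  if (nlevels(groups) == 2L) {
    sp <- split(values, groups)
    ht <- stats::wilcox.test(sp[[1]], sp[[2]], paired = paired, exact = exact)
  } else {
    if (paired) stop("paired comparison is only defined for two groups")
    ht <- stats::kruskal.test(values, groups)
  }
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 method = ht$method, n_groups = nlevels(groups))
}
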