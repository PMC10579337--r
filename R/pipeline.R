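#' Pipeline configuration
#'
#' Central container for every stage parameter, with defaults equal to
#' the assay's published settings where one exists: field QC cutoff
#' `qc_min = 0.1`, confidence level `0.95`, the notch constant `1.58`
#' inside [derive_ca_threshold()], strict `>` CA calls.
#'
#' @param ... overrides of the defaults listed below.
#' @return list of class `ca_pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    qc_min = 0.1,
    ci_level = 0.95,
    control_tissue_types = c("normal-FT", "normal-other"),
    ft_tissue_type = "normal-FT",
    threshold_method = "notch",
    threshold_on_normalized = TRUE,
    fit_model = FALSE,
    model_H = 100L,
    model_damping = 0.5,
    seed = 1L,
    quant_params = list())
  cfg <- utils::modifyList(defaults, list(...))
  structure(cfg, class = "ca_pipeline_config")
}

#' Hash a pipeline configuration
#'
#' Stable content hash embedded in every output for provenance; changes
#' iff any parameter changes.
#'
#' @param config a [pipeline_config()].
#' @return character hash.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config)[order(names(unclass(config)))])
}

#' Read and validate a long-format per-field CA table
#'
#' Required columns: `sample`, `cohort`, `tissue_type`, `field`,
#' `ca_score`. Rows with missing or negative CA scores are rejected and
#' reported with their line numbers; a missing column is an error naming
#' it.
#'
#' @param path CSV/TSV file path, or a data frame to validate in place.
#' @return tibble of valid records; attribute `"rejected"` holds the bad
#'   rows with a `reason` and `line` column.
#' @export
read_field_table <- function(path) {
  tab <- if (is.data.frame(path)) {
    tibble::as_tibble(path)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                        stringsAsFactors = FALSE))
  }
  required <- c("sample", "cohort", "tissue_type", "field", "ca_score")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0L) {
    stop("field table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- is.na(tab$ca_score) | !is.numeric(tab$ca_score) | tab$ca_score < 0
  rejected <- tab[bad, , drop = FALSE]
  if (nrow(rejected) > 0L) {
    rejected$line <- which(bad) + 1L  # +1 for the header line
    rejected$reason <- "ca_score missing or negative"
    warning(nrow(rejected), " row(s) rejected (missing/negative ca_score)")
  }
  out <- tab[!bad, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Write a per-field CA table (canonical CSV form)
#'
#' @param tab field table.
#' @param path output CSV path.
#' @export
write_field_table <- function(tab, path) {
  cols <- c("sample", "cohort", "tissue_type", "field", "ca_score")
  extra <- setdiff(names(tab), cols)
  utils::write.csv(tab[, c(cols, extra)], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the cohort CA pipeline
#'
#' End-to-end orchestration on a per-field CA table (quantified imaging
#' fields or simulator output): field QC, per-sample aggregation,
#' control normalization within cohort, FT-based threshold derivation,
#' CA calls, per-patient summary, and (optionally) the copula mixed-model
#' fit on log normalized field scores. Every output carries the config
#' hash and seed; QC exclusions are collected in an audit log.
#'
#' @param field_table long table as accepted by [read_field_table()];
#'   an optional `patient` column enables the per-patient summary.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes
#'   `cohort_summary.json`, `sample_profiles.csv` and `audit_log.csv`.
#' @return list: `samples`, `threshold`, `patients`, `model_fit`
#'   (or `NULL`), `audit` (exclusion log), `provenance`.
#' @export
run_pipeline <- function(field_table, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "ca_pipeline_config"))
  tab <- read_field_table(field_table)
  audit <- list()
  rej <- attr(tab, "rejected")
  if (!is.null(rej) && nrow(rej) > 0L) audit$rejected_rows <- rej

  kept <- qc_filter_fields(tab, qc_min = config$qc_min)
  excl <- attr(kept, "excluded")
  if (!is.null(excl) && nrow(excl) > 0L) audit$qc_excluded_fields <- excl

  has_patient <- "patient" %in% names(kept)
  samples <- kept |>
    dplyr::group_by(.data$sample) |>
    dplyr::group_map(function(rows, key) {
      meta <- list(sample_id = key$sample,
                   cohort = rows$cohort[1], tissue_type = rows$tissue_type[1])
      if (has_patient) meta$patient_id <- rows$patient[1]
      prof <- aggregate_sample(rows$ca_score, meta)
      prof$fields <- list(rows$ca_score)
      prof
    }) |>
    dplyr::bind_rows()

  samples <- normalize_to_controls(
    samples, samples$tissue_type %in% config$control_tissue_types)
  ctrl_med <- attr(samples, "control_medians")
  # per-field normalized scores feed the threshold's notch formula
  samples$fields_normalized <- lapply(seq_len(nrow(samples)), function(i)
    samples$fields[[i]] / ctrl_med[[samples$cohort[i]]])

  ft <- samples[samples$tissue_type == config$ft_tissue_type, , drop = FALSE]
  if (nrow(ft) == 0L) stop("no samples of FT tissue type '",
                           config$ft_tissue_type, "' to derive the threshold")
  ft_in <- ft
  ft_in$fields <- if (config$threshold_on_normalized) ft$fields_normalized else ft$fields
  threshold <- derive_ca_threshold(ft_in, method = config$threshold_method,
                                   seed = config$seed)
  samples <- call_ca_status(samples, threshold)

  patients <- if (has_patient) {
    patient_level_summary(samples, threshold)
  } else NULL

  model_fit <- NULL
  if (isTRUE(config$fit_model)) {
    model_fit <- fit_cohort_model(samples, config)
  }

  provenance <- list(config_hash = config_hash(config), seed = config$seed,
                     n_samples = nrow(samples),
                     timestamp = format(Sys.time(), tz = "UTC"))
  result <- list(samples = samples, threshold = threshold,
                 patients = patients, model_fit = model_fit,
                 audit = audit, provenance = provenance)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

# copula LMM on log normalized field scores; design: intercept + tumour
fit_cohort_model <- function(samples, config) {
  is_tumour <- !(samples$tissue_type %in% config$control_tissue_types)
  n_i <- lengths(samples$fields_normalized)
  usable <- n_i >= 2L
  des <- ca_design(cbind(intercept = 1, tumour = as.numeric(is_tumour[usable])),
                   n_i[usable], samples$sample_id[usable])
  dat <- tibble::tibble(
    tissue_id = rep(samples$sample_id[usable], n_i[usable]),
    y = log(unlist(samples$fields_normalized[usable])))
  fit <- fit_iterative_bootstrap(dat, des, H = config$model_H,
                                 damping = config$model_damping,
                                 seed = config$seed)
  ci <- tryCatch(estimate_uncertainty(fit, level = config$ci_level,
                                      seed = config$seed),
                 error = function(e) NULL)
  list(fit = fit, ci = ci)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  flat <- result$samples[, setdiff(names(result$samples),
                                   c("fields", "fields_normalized"))]
  flat$config_hash <- result$provenance$config_hash
  flat$seed <- result$provenance$seed
  utils::write.csv(flat, file.path(out_dir, "sample_profiles.csv"),
                   row.names = FALSE)
  summary <- list(
    provenance = result$provenance,
    threshold = unclass(result$threshold),
    n_ca_positive = sum(result$samples$ca_positive),
    n_samples = nrow(result$samples),
    ca_prevalence = mean(result$samples$ca_positive))
  jsonlite::write_json(summary, file.path(out_dir, "cohort_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (length(result$audit) > 0L) {
    aud <- dplyr::bind_rows(lapply(names(result$audit), function(nm) {
      a <- result$audit[[nm]]
      a$stage <- nm
      a
    }))
    utils::write.csv(aud, file.path(out_dir, "audit_log.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}
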