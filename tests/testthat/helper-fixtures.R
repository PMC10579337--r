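# Shared fixtures: small, fast configurations used across test files.

# study-condition parameters for the copula LMM experiments
study_params <- function() {
  copula_lmm_params(beta = c(0, 0.5), tau = 0.3, gamma = c(-1, 0.5),
                    alpha = 4, rho = 0.5, nu = 8)
}

study_design <- function(n_fields = 25L) {
  two_group_design(20L, 40L, n_fields)
}

# small noise-free imaging field (fast: fewer nuclei, smaller frame)
small_field_config <- function(seed = 1L, n_nuclei = 10L, ...) {
  image_sim_config(field_shape = c(16L, 256L, 256L), n_nuclei = n_nuclei,
                   seed = seed, ...)
}

# genes x samples matrix whose per-gene sample ordering is identical, so
# bumping the top sample provably leaves every per-gene median unchanged
median_stable_cohort <- function(n_samples = 9L, seed = 1L) {
  genes <- unique(c(ca20_genes, cin25_genes))
  withr::with_seed(seed, {
    base <- runif(length(genes), 3, 9)
    deltas <- sort(runif(n_samples, -0.5, 0.5))
    m <- outer(base, deltas, `+`)
    dimnames(m) <- list(genes, sprintf("S%02d", seq_len(n_samples)))
    m
  })
}

# truth-derived per-field expectations for whole (non-border) nuclei
truth_expectations <- function(truth) {
  nb <- truth$nuclei[!truth$nuclei$is_border, ]
  owned <- truth$spots[truth$spots$nucleus_id %in% nb$id, ]
  list(
    n_nuclei = nrow(nb),
    n_spots = sum(nb$n_spots),
    ca_score = sum(nb$n_spots) / nrow(nb),
    mitotic_index = mean(nb$is_mitotic),
    mn_frequency = mean(nb$n_micronuclei[!nb$is_mitotic] >= 1),
    cep164_fraction = mean(owned$cep164_positive))
}

# long-format synthetic cohort field table built from lognormal field
# scores (no imaging), for metrics/pipeline tests
toy_cohort_table <- function(seed = 1L, n_tumour = 8L, n_ft = 4L,
                             n_fields = 12L) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in seq_len(n_ft)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = sprintf("FT%02d", i), patient = sprintf("PF%02d", i),
        cohort = ifelse(i %% 2 == 0, "OV04", "BriTROC"),
        tissue_type = "normal-FT", field = seq_len(n_fields),
        ca_score = exp(rnorm(n_fields, log(0.3), 0.25)))
    }
    for (i in seq_len(n_tumour)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample = sprintf("T%02d", i), patient = sprintf("PT%02d", (i + 1L) %/% 2L),
        cohort = ifelse(i %% 2 == 0, "OV04", "BriTROC"),
        tissue_type = "tumour", field = seq_len(n_fields),
        ca_score = exp(rnorm(n_fields, log(0.3) + 0.9, 0.45)))
    }
    dplyr::bind_rows(rows)
  })
}
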