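# Cohort-level CA statistics: aggregation, normalization, threshold,
# calls, per-patient summaries, rank comparisons.

test_that("sample aggregation: median, heterogeneity, scale invariance", {
  prof <- aggregate_sample(c(2, 2, 2), list(sample_id = "s"))
  expect_equal(prof$median_ca, 2)
  expect_equal(prof$heterogeneity, 0)
  # fields (1, 2, 4): heterogeneity = sd(log 1, log 2, log 4) = log 2
  prof2 <- aggregate_sample(c(1, 2, 4), list(sample_id = "s"))
  expect_equal(prof2$median_ca, 2)
  expect_equal(prof2$heterogeneity, log(2))
  # multiplying all fields by k leaves heterogeneity unchanged
  prof3 <- aggregate_sample(c(1, 2, 4) * 7.7, list(sample_id = "s"))
  expect_equal(prof3$heterogeneity, prof2$heterogeneity)
  # log base only rescales by a constant
  prof4 <- aggregate_sample(c(1, 2, 4), list(sample_id = "s"), log_base = 2)
  expect_equal(prof4$heterogeneity, prof2$heterogeneity / log(2))
  expect_error(aggregate_sample(numeric(0), list(sample_id = "s")), "exclude")
  expect_true(is.na(aggregate_sample(1.5, list(sample_id = "s"))$heterogeneity))
})

test_that("control normalization divides by the per-cohort control median", {
  samples <- tibble::tibble(
    sample_id = c("c1", "c2", "c3", "t1"),
    cohort = "A",
    median_ca = c(0.8, 1.0, 1.2, 2.0))
  out <- normalize_to_controls(samples, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$normalized_ca, c(0.8, 1.0, 1.2, 2.0))
  # a control at the control median normalizes to exactly 1
  expect_equal(out$normalized_ca[2], 1)
  # two cohorts: independent divisors
  two <- tibble::tibble(
    sample_id = c("a1", "a2", "b1", "b2"),
    cohort = c("A", "A", "B", "B"),
    median_ca = c(0.5, 1.5, 2.0, 5.0))
  res <- normalize_to_controls(two, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res$normalized_ca, c(1, 3, 1, 2.5))
  # idempotence with the same controls
  again <- two
  again$median_ca <- res$normalized_ca
  res2 <- normalize_to_controls(again, c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(res2$normalized_ca, res$normalized_ca)
  expect_error(normalize_to_controls(two, rep(FALSE, 4)), "cohort")
})

test_that("CA threshold equals the notch upper bound of the top FT sample", {
  # equal fields: IQR 0, threshold = the common value
  ft <- tibble::tibble(sample_id = "ft1", normalized_ca = 1,
                       fields = list(rep(1.0, 10)))
  expect_equal(derive_ca_threshold(ft)$threshold, 1.0)
  # hand oracle: 21 evenly spaced values on [1, 2]
  f <- seq(1, 2, length.out = 21)
  ft2 <- tibble::tibble(sample_id = "ft2", normalized_ca = 1.5,
                        fields = list(f))
  expect_equal(derive_ca_threshold(ft2)$threshold,
               median(f) + 1.58 * IQR(f) / sqrt(21))
  # adding a lower-median FT sample never changes the result
  both <- dplyr::bind_rows(ft2, tibble::tibble(
    sample_id = "ft3", normalized_ca = 0.9, fields = list(f * 0.6)))
  expect_equal(derive_ca_threshold(both)$threshold,
               derive_ca_threshold(ft2)$threshold)
  expect_equal(derive_ca_threshold(both)$source_sample, "ft2")
  # shifting the top sample's fields by delta shifts the threshold by delta
  shifted <- ft2
  shifted$fields <- list(f + 0.25)
  shifted$normalized_ca <- 1.75
  expect_equal(derive_ca_threshold(shifted)$threshold,
               derive_ca_threshold(ft2)$threshold + 0.25)
  expect_error(derive_ca_threshold(ft2[0, ]), "no normal-FT")
})

test_that("CA calls use a strict greater-than rule", {
  s <- tibble::tibble(normalized_ca = c(1.84, 1.83, 0.5))
  out <- call_ca_status(s, 1.83)
  expect_equal(out$ca_positive, c(TRUE, FALSE, FALSE))
})

test_that("patient summary takes the median across tissues and keeps discordance", {
  s <- tibble::tibble(
    patient_id = c("p1", "p2", "p2", "p2"),
    normalized_ca = c(2.5, 1.0, 2.0, 3.0))
  out <- patient_level_summary(s, threshold = 1.83)
  expect_equal(out$patient_ca[out$patient_id == "p1"], 2.5)
  expect_equal(out$patient_ca[out$patient_id == "p2"], 2.0)
  expect_true(out$ca_positive[out$patient_id == "p2"])
  expect_true(out$discordant[out$patient_id == "p2"])
  expect_false(out$discordant[out$patient_id == "p1"])
})

test_that("group comparisons: degenerate, identical and shifted inputs", {
  expect_error(compare_groups(1:5, rep("a", 5)), "two non-empty|at least two")
  same <- compare_groups(rep(1, 6), rep(c("a", "b"), each = 3))
  expect_equal(same$p_value, 1)
  three <- compare_groups(c(rnorm(5), rnorm(5), rnorm(5)),
                          rep(c("a", "b", "c"), each = 5))
  expect_match(three$method, "Kruskal")
  # power: a 2-SD shift at n = 50/50 is detected essentially always
  detected <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      v <- c(rnorm(50), rnorm(50, 2))
      compare_groups(v, rep(c("a", "b"), each = 50))$p_value < 0.001
    })
  }, NA)
  expect_gte(mean(detected), 0.99)
})

test_that("rank-test p-values are uniform under the null", {
  pvals <- vapply(1:200, function(s) {
    withr::with_seed(s, compare_groups(rnorm(40), rep(c("a", "b"), each = 20),
                                       exact = FALSE)$p_value)
  }, 0)
  # rank-test p-values are discrete; the KS tie warning is expected and
  # only makes the check conservative
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})
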