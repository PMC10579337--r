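# Synthetic-data generators: determinism, planted-object bookkeeping,
# closed-form expectations.

test_that("config validation enforces the generator invariants", {
  expect_error(image_sim_config(field_shape = c(8, 320, 320)), ">= 16")
  expect_error(image_sim_config(ca_distribution = c(0.5, 0.4)), "sum")
  expect_error(image_sim_config(snr = 0), "snr")
  expect_silent(image_sim_config())
})

test_that("identical config and seed reproduce bit-identical fields and truth", {
  cfg <- small_field_config(seed = 7)
  a <- simulate_image_field(cfg)
  b <- simulate_image_field(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$stack$voxels, b$stack$voxels)
})

test_that("empty field: zero nuclei gives background-only stack and empty truth", {
  cfg <- small_field_config(n_nuclei = 0L, mn_rate = 0)
  sim <- simulate_image_field(cfg)
  expect_equal(nrow(sim$truth$nuclei), 0L)
  expect_equal(nrow(sim$truth$spots), 0L)
  expect_equal(max(sim$stack$voxels) - min(sim$stack$voxels), 0)
})

test_that("degenerate ca_distribution plants exactly one spot per cell", {
  cfg <- small_field_config(seed = 2, ca_distribution = c(0, 1), mn_rate = 0)
  sim <- simulate_image_field(cfg)
  expect_equal(nrow(sim$truth$spots), nrow(sim$truth$nuclei))
  expect_true(all(sim$truth$nuclei$n_spots == 1L))
})

test_that("planted spot totals follow the per-cell count distribution", {
  # ca_distribution (0, .5, .5): total spots ~ n + Binomial(n, .5);
  # oracle: re-draw the counts from the same distribution many times to
  # get the 99% band, then check the planted totals fall inside
  cfg <- image_sim_config(field_shape = c(16, 480, 480), n_nuclei = 40L,
                          ca_distribution = c(0, 0.5, 0.5), mn_rate = 0,
                          seed = 31)
  totals <- vapply(1:5, function(s) {
    cfg$seed <- s + 100L
    nrow(simulate_image_field(cfg)$truth$spots)
  }, 0L)
  n <- 40L * 5L
  band <- n + stats::qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(sum(totals), band[1])
  expect_lte(sum(totals), band[2])
  # conservation: truth spot count equals the sum of per-nucleus draws
  sim <- simulate_image_field(cfg)
  expect_equal(nrow(sim$truth$spots), sum(sim$truth$nuclei$n_spots))
  expect_true(all(sim$truth$spots$nucleus_id %in% sim$truth$nuclei$id))
})

test_that("micronucleus truth respects the geometry invariants", {
  cfg <- small_field_config(seed = 5, mn_rate = 1.2)
  tr <- simulate_image_field(cfg)$truth
  expect_gt(nrow(tr$micronuclei), 0L)
  owners <- match(tr$micronuclei$nucleus_id, tr$nuclei$id)
  expect_true(all(tr$micronuclei$radius_px < tr$nuclei$radius_px[owners]))
  d <- sqrt((tr$micronuclei$y - tr$nuclei$y[owners])^2 +
              (tr$micronuclei$x - tr$nuclei$x[owners])^2)
  expect_true(all(d <= 2 * tr$nuclei$radius_px[owners]))
})

test_that("multi-field wells use independent substreams and are reproducible", {
  cfg <- small_field_config(seed = 9)
  well <- simulate_cellline_well(cfg, n_fields = 5L)
  expect_length(well, 5L)
  truths <- lapply(well, function(f) f$truth$nuclei)
  for (i in 2:5) expect_false(identical(truths[[1]], truths[[i]]))
  well2 <- simulate_cellline_well(cfg, n_fields = 5L)
  expect_identical(lapply(well, `[[`, "truth"), lapply(well2, `[[`, "truth"))
  # singleton well equals a single field simulated on substream 1
  one <- simulate_cellline_well(cfg, n_fields = 1L)
  cfg1 <- cfg; cfg1$seed <- substream_seed(cfg$seed, "field", 1L)
  expect_identical(one[[1]]$truth, simulate_image_field(cfg1)$truth)
})

test_that("expression generator: gene content, exact gap, degenerate errors", {
  expect_error(simulate_expression_matrix(3), ">= 4")
  sim <- simulate_expression_matrix(12, planted_effect = 1, noise_sd = 0, seed = 4)
  expect_true(all(ca20_genes %in% rownames(sim$matrix)))
  expect_true(all(cin25_genes %in% rownames(sim$matrix)))
  sc <- score_signature(sim$matrix, "CA20", normalize = "none",
                        log2_transform = FALSE)
  gap <- mean(sc$score[sim$labels == "high"]) -
    mean(sc$score[sim$labels == "low"])
  expect_equal(gap, 20, tolerance = 1e-12)
})

test_that("null expression generator gives nominal type-I error on CA20 scores", {
  pvals <- vapply(1:200, function(s) {
    sim <- simulate_expression_matrix(20, planted_effect = 0, noise_sd = 0.5,
                                      n_filler = 10L, seed = s)
    sc <- score_signature(sim$matrix, "CA20", normalize = "none",
                          log2_transform = FALSE)
    stats::t.test(sc$score[sim$labels == "high"],
                  sc$score[sim$labels == "low"])$p.value
  }, 0)
  rej <- mean(pvals < 0.05)
  # 99% binomial band around 0.05 at 200 draws
  expect_gte(rej, stats::qbinom(0.005, 200, 0.05) / 200)
  expect_lte(rej, stats::qbinom(0.995, 200, 0.05) / 200)
})

test_that("composition generator: simplex closure and closed-form ALR shift", {
  expect_error(simulate_signature_compositions(5, base = rep(1, 7)), "sum to 1")
  expect_error(
    simulate_signature_compositions(5, base = c(0, 0.2, 0.2, 0.2, 0.2, 0.1, 0.1)),
    "positive")
  sim <- simulate_signature_compositions(10, seed = 3)
  expect_equal(unname(rowSums(sim$exposures)), rep(1, 20), tolerance = 1e-9)
  # near-degenerate noise: group B signature-1 : signature-7 ratio doubles
  sh <- c(log(2), 0, 0, 0, 0, 0)
  sim2 <- simulate_signature_compositions(6, alr_shift = sh,
                                          concentration = 1e8, seed = 5)
  ratio <- sim2$exposures[, 1] / sim2$exposures[, 7]
  rA <- mean(ratio[sim2$group == "A"])
  rB <- mean(ratio[sim2$group == "B"])
  expect_equal(rB / rA, 2, tolerance = 1e-3)
})
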