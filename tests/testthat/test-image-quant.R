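# Image quantification: projection, segmentation, spot detection,
# per-field metrics, QC filtering.

test_that("max projection handles trivial and degenerate inputs", {
  a <- array(runif(2 * 5 * 4), c(2, 5, 4))
  expect_equal(max_project(a), pmax(a[1, , ], a[2, , ]))
  one <- array(3.5, c(1, 6, 6))
  expect_equal(max_project(one), matrix(3.5, 6, 6))
  const <- array(2, c(4, 6, 6))
  expect_equal(max_project(const), matrix(2, 6, 6))
})

test_that("projected peak positions match planted spot centres within 1 px", {
  sim <- simulate_image_field(small_field_config(seed = 11))
  pcm <- max_project(sim$stack)$PCM
  for (i in seq_len(nrow(sim$truth$spots))) {
    sp <- sim$truth$spots[i, ]
    win <- pcm[max(1, round(sp$y) - 2):min(nrow(pcm), round(sp$y) + 2),
               max(1, round(sp$x) - 2):min(ncol(pcm), round(sp$x) + 2)]
    peak <- which(win == max(win), arr.ind = TRUE)[1, ]
    expect_lte(abs(peak[1] - 3 + round(sp$y) - sp$y), 1)
    expect_lte(abs(peak[2] - 3 + round(sp$x) - sp$x), 1)
  }
})

test_that("segmentation: blank image yields no nuclei, not an error", {
  expect_equal(nrow(segment_nuclei(matrix(0, 64, 64))), 0L)
  expect_equal(nrow(segment_nuclei(matrix(5, 64, 64))), 0L)
})

test_that("noise-free segmentation recovers the planted nuclei count", {
  for (s in c(21, 22)) {
    sim <- simulate_image_field(small_field_config(seed = s, mn_rate = 0))
    nuc <- segment_nuclei(max_project(sim$stack)$DNA)
    expect_equal(nrow(nuc[!nuc$touches_border, ]),
                 sum(!sim$truth$nuclei$is_border))
  }
})

test_that("border-clipped nuclei are flagged and excluded from whole cells", {
  cfg <- small_field_config(seed = 13, n_nuclei = 6L, n_border_nuclei = 3L,
                            mn_rate = 0)
  sim <- simulate_image_field(cfg)
  expect_equal(sum(sim$truth$nuclei$is_border), 3L)
  q <- quantify_field(sim$stack)
  expect_equal(q$field$n_nuclei, 6L)
  expect_gte(sum(q$nuclei$touches_border), 1L)
})

test_that("spot detection is exact on resolvable noise-free fields", {
  sim <- simulate_image_field(small_field_config(seed = 31))
  proj <- max_project(sim$stack)
  nuc <- segment_nuclei(proj$DNA)
  spots <- detect_spots(proj$PCM, nuc)
  expect_equal(nrow(spots) + nrow(attr(spots, "discarded")),
               nrow(sim$truth$spots))
  # centres within 0.5 px of the planted subpixel positions
  for (i in seq_len(nrow(spots))) {
    d <- sqrt((sim$truth$spots$y - spots$y[i])^2 +
                (sim$truth$spots$x - spots$x[i])^2)
    expect_lte(min(d), 0.5)
  }
  # ellipse fit: width <= length and positive sizes
  expect_true(all(spots$width_px <= spots$length_px + 1e-9))
  expect_true(all(spots$size_px2 > 0))
})

test_that("blank PCM channel yields zero spots", {
  sim <- simulate_image_field(small_field_config(seed = 3))
  nuc <- segment_nuclei(max_project(sim$stack)$DNA)
  expect_equal(nrow(detect_spots(matrix(0, 256, 256), nuc)), 0L)
})

test_that("spot detection and merge rule are deterministic", {
  sim <- simulate_image_field(small_field_config(seed = 17))
  proj <- max_project(sim$stack)
  nuc <- segment_nuclei(proj$DNA)
  s1 <- detect_spots(proj$PCM, nuc)
  s2 <- detect_spots(proj$PCM, nuc)
  expect_identical(s1, s2)
})

test_that("counts are invariant to global intensity rescaling", {
  sim <- simulate_image_field(small_field_config(seed = 23))
  q1 <- quantify_field(sim$stack)
  scaled <- sim$stack
  scaled$voxels <- scaled$voxels * 7.3
  q2 <- quantify_field(scaled)
  expect_equal(q1$field$n_nuclei, q2$field$n_nuclei)
  expect_equal(q1$field$n_centrosomes, q2$field$n_centrosomes)
  expect_equal(q1$field$mitotic_index, q2$field$mitotic_index)
  expect_equal(q1$field$mn_frequency, q2$field$mn_frequency)
})

test_that("marker positivity: zero channel scores 0%, saturated prob scores 100%", {
  sim <- simulate_image_field(small_field_config(seed = 7,
                                                 cep164_positive_prob = 1))
  proj <- max_project(sim$stack)
  nuc <- segment_nuclei(proj$DNA)
  spots <- detect_spots(proj$PCM, nuc)
  pos <- score_marker_positivity(spots, proj$CEP164)
  expect_true(all(pos$cep164_positive))
  zero <- score_marker_positivity(spots, matrix(0, 256, 256))
  expect_false(any(zero$cep164_positive))
  und <- score_marker_positivity(spots, NULL)
  expect_true(all(is.na(und$cep164_positive)))
})

test_that("marker positivity tracks planted labels at intermediate probability", {
  hits <- 0L; total <- 0L
  for (s in 41:43) {
    sim <- simulate_image_field(small_field_config(seed = s,
                                                   cep164_positive_prob = 0.5))
    proj <- max_project(sim$stack)
    nuc <- segment_nuclei(proj$DNA)
    spots <- score_marker_positivity(detect_spots(proj$PCM, nuc), proj$CEP164)
    # match each detected spot to its planted label
    for (i in seq_len(nrow(spots))) {
      d <- sqrt((sim$truth$spots$y - spots$y[i])^2 +
                  (sim$truth$spots$x - spots$x[i])^2)
      j <- which.min(d)
      if (d[j] <= 1) {
        total <- total + 1L
        hits <- hits + as.integer(spots$cep164_positive[i] ==
                                    sim$truth$spots$cep164_positive[j])
      }
    }
  }
  expect_equal(hits, total)  # noise-free: positivity recovered exactly
})

test_that("mitotic classification recovers the planted fraction exactly", {
  sim <- simulate_image_field(small_field_config(seed = 19,
                                                 mitotic_fraction = 0.3))
  q <- quantify_field(sim$stack)
  nb <- sim$truth$nuclei[!sim$truth$nuclei$is_border, ]
  expect_equal(q$field$mitotic_index, mean(nb$is_mitotic))
  # all-zero pHH3 channel: no cell is mitotic
  proj <- max_project(sim$stack)
  nuc <- segment_nuclei(proj$DNA)
  cls <- classify_mitotic(nuc, matrix(0, 256, 256))
  expect_false(any(cls$is_mitotic))
})

test_that("micronucleus frequency matches planted truth on clean fields", {
  for (s in c(2, 5)) {
    sim <- simulate_image_field(small_field_config(seed = s, mn_rate = 0.8))
    q <- quantify_field(sim$stack)
    nb <- sim$truth$nuclei[!sim$truth$nuclei$is_border, ]
    expect_equal(q$field$mn_frequency, mean(nb$n_micronuclei[!nb$is_mitotic] >= 1))
  }
})

test_that("field CA score follows the printed formula and QC rules", {
  sim <- simulate_image_field(small_field_config(seed = 29))
  q <- quantify_field(sim$stack)
  expect_equal(q$field$ca_score, q$field$n_centrosomes / q$field$n_nuclei)
  expect_equal(q$field$ca_frequency,
               mean(q$cells$n_centrosomes[!q$cells$is_mitotic] >= 2))
  exp_truth <- truth_expectations(sim$truth)
  expect_equal(q$field$ca_score, exp_truth$ca_score)
})

test_that("QC filter removes exactly the low/undefined-CA fields", {
  fields <- tibble::tibble(field_id = 1:4,
                           ca_score = c(0.05, 0.2, 1.1, NA))
  kept <- qc_filter_fields(fields)
  expect_equal(kept$ca_score, c(0.2, 1.1))
  excl <- attr(kept, "excluded")
  expect_setequal(excl$qc_reason, c("ca_below_qc_min", "undefined_ca_score"))
  # qc_min = 0 retains every defined-score field
  all_def <- qc_filter_fields(fields, qc_min = 0)
  expect_equal(all_def$ca_score, c(0.05, 0.2, 1.1))
  # raising qc_min never enlarges the retained set (monotonicity)
  sizes <- suppressWarnings(vapply(c(0, 0.1, 0.3, 1.2), function(q)
    nrow(qc_filter_fields(fields, qc_min = q)), 0L))
  expect_true(all(diff(sizes) <= 0))
  expect_warning(qc_filter_fields(fields, qc_min = 10), "all imaging fields")
})

test_that("field TIFF round trip preserves the stack and metadata", {
  sim <- simulate_image_field(small_field_config(seed = 37, n_nuclei = 4L))
  tmp <- withr::local_tempfile(fileext = ".tif")
  write_field_tiff(sim$stack, tmp)
  back <- read_field_tiff(tmp)
  expect_equal(back$channel_names, sim$stack$channel_names)
  expect_equal(back$pixel_size_um, sim$stack$pixel_size_um)
  expect_equal(back$voxels, sim$stack$voxels, tolerance = 1e-6)
  cfg <- small_field_config(seed = 37)
  cfg_path <- withr::local_tempfile(fileext = ".yml")
  write_sim_config(cfg, cfg_path)
  expect_equal(read_sim_config(cfg_path), cfg)
})
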