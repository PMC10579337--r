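#' Simulate one multichannel immunofluorescence field with ground truth
#'
#' Renders a 4-channel z-stack (`DNA`, `PCM`, `pHH3`, `CEP164`) of planted
#' nuclei, perinuclear centrosome spots, micronuclei and mitotic cells,
#' plus a truth table of every planted object. Signal is additive:
#' nuclei/micronuclei as soft-edged discs (super-Gaussian radial profile),
#' centrosomes as isotropic 3-D Gaussians placed within 1.5 nuclear radii
#' of the owner centroid (centrosomes are perinuclear). Noise, when
#' `snr < Inf`, is Poisson shot noise on signal-plus-background with
#' additive Gaussian read noise; `snr` is the peak spot amplitude over the
#' background SD. Mitotic nuclei get a condensed (smaller, brighter) DNA
#' profile and a pHH3 signal, but their centrosomes are still planted —
#' mitotic exclusion is a downstream analysis step, as in the assay.
#'
#' RNG layout: everything derives from `config$seed` through named
#' substreams (`"placement"`, `"noise"`), so truth tables are reproducible
#' independently of the noise draw.
#'
#' @param config an [image_sim_config()].
#' @return list with elements `stack` (a `ca_image_stack`: `voxels`
#'   `(channel, z, y, x)`, `channel_names`, `pixel_size_um`) and `truth`
#'   (list of tibbles `nuclei`, `spots`, `micronuclei`). Positions are
#'   1-based pixel coordinates.
#' @export
simulate_image_field <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  truth <- withr::with_seed(substream_seed(config$seed, "placement"),
                            plant_objects(config))
  stack <- render_field(config, truth)
  if (is.finite(config$snr)) {
    stack$voxels <- withr::with_seed(
      substream_seed(config$seed, "noise"),
      add_camera_noise(stack$voxels, config))
  } else {
    stack$voxels <- stack$voxels + config$background_level
  }
  list(stack = stack, truth = truth)
}

#' Simulate a multi-field well (cell-line assay layout)
#'
#' Fields share one configuration but use independent, named RNG
#' substreams (`field 1..n_fields`), mirroring repeated imaging fields of
#' one well. Deterministic given `config$seed`.
#'
#' @param config an [image_sim_config()].
#' @param n_fields number of fields, `>= 1` (the cell-line screen images
#'   five per well).
#' @return list of `simulate_image_field()` results.
#' @export
simulate_cellline_well <- function(config, n_fields = 5L) {
  stopifnot(n_fields >= 1L)
  lapply(seq_len(n_fields), function(f) {
    cf <- config
    cf$seed <- substream_seed(config$seed, "field", f)
    simulate_image_field(cf)
  })
}

# ---- placement ----------------------------------------------------------

plant_objects <- function(config) {
  ny <- config$field_shape[2]
  nx <- config$field_shape[3]
  nz <- config$field_shape[1]
  r_px <- config$nucleus_radius_um / config$pixel_size_um  # (mean, sd)

  n_int <- config$n_nuclei
  n_bord <- config$n_border_nuclei
  radii <- pmax(stats::rnorm(n_int + n_bord, r_px[1], r_px[2]), 0.5 * r_px[1])
  margin <- radii + 4 * config$spot_sigma_px + 2

  centres <- matrix(NA_real_, n_int + n_bord, 2)  # (y, x)
  sep_factor <- 2.0
  tries <- 0L
  for (i in seq_len(n_int)) {
    repeat {
      tries <- tries + 1L
      if (tries > 5000L) {
        stop("could not place ", n_int, " nuclei of radius ~", round(r_px[1], 1),
             " px in a ", ny, "x", nx, " field at separation factor ", sep_factor,
             "; enlarge the field or reduce n_nuclei")
      }
      cand <- c(stats::runif(1, margin[i], ny - margin[i]),
                stats::runif(1, margin[i], nx - margin[i]))
      if (i == 1L) break
      prev <- seq_len(i - 1L)
      d <- sqrt(colSums((t(centres[prev, , drop = FALSE]) - cand)^2))
      if (all(d >= sep_factor * (radii[prev] + radii[i]))) break
    }
    centres[i, ] <- cand
  }
  # border nuclei: centre within one radius of an edge so the mask is clipped
  for (i in n_int + seq_len(n_bord)) {
    edge <- sample(4L, 1L)
    off <- stats::runif(1, 0, 0.6 * radii[i])
    pos <- stats::runif(1, margin[i], (if (edge <= 2L) nx else ny) - margin[i])
    centres[i, ] <- switch(edge,
      c(1 + off, pos), c(ny - off, pos), c(pos, 1 + off), c(pos, nx - off))
  }

  n_all <- n_int + n_bord
  is_border <- rep(c(FALSE, TRUE), c(n_int, n_bord))
  is_mitotic <- stats::runif(n_all) < config$mitotic_fraction
  zc <- nz / 2 + stats::runif(n_all, -1.5, 1.5)

  nuclei <- tibble::tibble(
    id = seq_len(n_all), y = centres[, 1], x = centres[, 2], z = zc,
    radius_px = radii, is_mitotic = is_mitotic, is_border = is_border)

  # centrosome spots: counts from ca_distribution, placed within 1.5 r of
  # the owner centroid with a minimum pairwise separation so the planted
  # configuration is resolvable (>= 4 PSF sigma)
  counts <- sample.int(length(config$ca_distribution), n_all, replace = TRUE,
                       prob = config$ca_distribution) - 1L
  min_sep <- 4 * config$spot_sigma_px
  spot_rows <- list()
  sid <- 0L
  for (i in seq_len(n_all)) {
    k <- counts[i]
    if (k == 0L) next
    pts <- matrix(NA_real_, k, 2)
    for (s in seq_len(k)) {
      for (attempt in seq_len(400L)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- 1.5 * radii[i] * sqrt(stats::runif(1))
        cand <- centres[i, ] + rad * c(sin(ang), cos(ang))
        ok <- cand[1] > 3 && cand[1] < ny - 2 && cand[2] > 3 && cand[2] < nx - 2
        if (ok && s > 1L) {
          dd <- sqrt(colSums((t(pts[seq_len(s - 1L), , drop = FALSE]) - cand)^2))
          ok <- all(dd >= min_sep)
        }
        if (ok) { pts[s, ] <- cand; break }
      }
      if (anyNA(pts[s, ])) {
        stop("could not place spot ", s, " of nucleus ", i,
             " at minimum separation ", round(min_sep, 1), " px")
      }
    }
    sz <- zc[i] + stats::runif(k, -1, 1)
    for (s in seq_len(k)) {
      sid <- sid + 1L
      spot_rows[[sid]] <- tibble::tibble(
        id = sid, nucleus_id = i, y = pts[s, 1], x = pts[s, 2], z = sz[s],
        cep164_positive = stats::runif(1) < config$cep164_positive_prob)
    }
  }
  spots <- if (sid > 0L) dplyr::bind_rows(spot_rows) else tibble::tibble(
    id = integer(), nucleus_id = integer(), y = double(), x = double(),
    z = double(), cep164_positive = logical())

  # micronuclei: small DNA discs fully outside every nucleus, within the
  # ownership annulus of a non-mitotic, non-border owner
  mn_rows <- list()
  mid <- 0L
  mn_counts <- stats::rpois(n_all, config$mn_rate)
  mn_counts[is_mitotic | is_border] <- 0L
  placed_mn <- matrix(numeric(0), 0, 3)  # y, x, r
  for (i in seq_len(n_all)) {
    for (s in seq_len(mn_counts[i])) {
      # resolvability floor: below ~1.8 px radius a DNA body is smaller
      # than the optical grain and no detector could resolve it
      mr <- max(radii[i] * stats::runif(1, 0.10, 0.35), 1.8)
      lo <- radii[i] + mr + 3
      hi <- 1.9 * radii[i]
      if (lo >= hi) next
      ok_pt <- NULL
      for (attempt in seq_len(400L)) {
        ang <- stats::runif(1, 0, 2 * pi)
        d <- stats::runif(1, lo, hi)
        cand <- centres[i, ] + d * c(sin(ang), cos(ang))
        if (cand[1] < mr + 2 || cand[1] > ny - mr - 1 ||
            cand[2] < mr + 2 || cand[2] > nx - mr - 1) next
        dn <- sqrt(colSums((t(centres) - cand)^2))
        if (any(dn < radii + mr + 3)) next
        if (nrow(placed_mn) > 0L) {
          dm <- sqrt(colSums((t(placed_mn[, 1:2, drop = FALSE]) - cand)^2))
          if (any(dm < placed_mn[, 3] + mr + 3)) next
        }
        ok_pt <- cand
        break
      }
      if (is.null(ok_pt)) next  # crowded neighbourhood: drop this micronucleus
      mid <- mid + 1L
      placed_mn <- rbind(placed_mn, c(ok_pt, mr))
      mn_rows[[mid]] <- tibble::tibble(
        nucleus_id = i, y = ok_pt[1], x = ok_pt[2], z = zc[i],
        radius_px = mr)
    }
  }
  micronuclei <- if (mid > 0L) dplyr::bind_rows(mn_rows) else tibble::tibble(
    nucleus_id = integer(), y = double(), x = double(), z = double(),
    radius_px = double())

  nuclei$n_spots <- tabulate(spots$nucleus_id, nbins = n_all)
  nuclei$n_micronuclei <- tabulate(micronuclei$nucleus_id, nbins = n_all)
  list(nuclei = nuclei, spots = spots, micronuclei = micronuclei)
}

# ---- rendering ----------------------------------------------------------

channel_names_default <- c("DNA", "PCM", "pHH3", "CEP164")

signal_amplitudes <- function(config) {
  bg_sd <- sqrt(config$background_level + config$read_noise_sd^2)
  a_spot <- if (is.finite(config$snr)) config$snr * bg_sd else 100
  list(spot = a_spot, dna = 1.5 * a_spot, phh3 = 1.5 * a_spot,
       cep164 = a_spot)
}

render_field <- function(config, truth) {
  nz <- config$field_shape[1]; ny <- config$field_shape[2]; nx <- config$field_shape[3]
  amp <- signal_amplitudes(config)
  # accumulate per channel to avoid repeated full-stack copies
  dna <- array(0, c(nz, ny, nx)); pcm <- array(0, c(nz, ny, nx))
  phh3 <- array(0, c(nz, ny, nx)); cep <- array(0, c(nz, ny, nx))

  for (i in seq_len(nrow(truth$nuclei))) {
    nuc <- truth$nuclei[i, ]
    r_eff <- if (nuc$is_mitotic) 0.75 * nuc$radius_px else nuc$radius_px
    a_eff <- if (nuc$is_mitotic) 1.8 * amp$dna else amp$dna
    dna <- add_super_disc(dna, nuc$z, nuc$y, nuc$x, r_eff,
                          sigma_z = 2.5, amplitude = a_eff)
    if (nuc$is_mitotic) {
      phh3 <- add_super_disc(phh3, nuc$z, nuc$y, nuc$x, r_eff,
                             sigma_z = 2.5, amplitude = amp$phh3)
    }
  }
  for (i in seq_len(nrow(truth$micronuclei))) {
    mn <- truth$micronuclei[i, ]
    dna <- add_super_disc(dna, mn$z, mn$y, mn$x, mn$radius_px,
                          sigma_z = 2, amplitude = amp$dna)
  }
  for (i in seq_len(nrow(truth$spots))) {
    sp <- truth$spots[i, ]
    pcm <- add_gaussian_spot(pcm, sp$z, sp$y, sp$x, config$spot_sigma_px, amp$spot)
    if (sp$cep164_positive) {
      cep <- add_gaussian_spot(cep, sp$z, sp$y, sp$x, config$spot_sigma_px,
                               amp$cep164)
    }
  }
  vox <- array(0, c(4L, nz, ny, nx))
  vox[1L, , , ] <- dna; vox[2L, , , ] <- pcm
  vox[3L, , , ] <- phh3; vox[4L, , , ] <- cep
  structure(list(voxels = vox, channel_names = channel_names_default,
                 pixel_size_um = config$pixel_size_um),
            class = "ca_image_stack")
}

# add an isotropic 3-D Gaussian of peak `amplitude` into a (z, y, x) array
add_gaussian_spot <- function(arr, zc, yc, xc, sigma, amplitude) {
  dz <- dim(arr)[1]; dy <- dim(arr)[2]; dx <- dim(arr)[3]
  w <- ceiling(4 * sigma)
  zi <- max(1, floor(zc - w)):min(dz, ceiling(zc + w))
  yi <- max(1, floor(yc - w)):min(dy, ceiling(yc + w))
  xi <- max(1, floor(xc - w)):min(dx, ceiling(xc + w))
  gz <- exp(-((zi - zc)^2) / (2 * sigma^2))
  gy <- exp(-((yi - yc)^2) / (2 * sigma^2))
  gx <- exp(-((xi - xc)^2) / (2 * sigma^2))
  arr[zi, yi, xi] <- arr[zi, yi, xi] + amplitude * (gz %o% gy %o% gx)
  arr
}

# soft-edged disc: radial super-Gaussian exp(-(d/r)^8) in (y, x), Gaussian
# in z — near-flat plateau with a steep but smooth edge, so thresholded
# masks recover the nominal radius
add_super_disc <- function(arr, zc, yc, xc, radius, sigma_z, amplitude) {
  dz <- dim(arr)[1]; dy <- dim(arr)[2]; dx <- dim(arr)[3]
  w <- ceiling(1.4 * radius)
  zi <- max(1, floor(zc - 3 * sigma_z)):min(dz, ceiling(zc + 3 * sigma_z))
  yi <- max(1, floor(yc - w)):min(dy, ceiling(yc + w))
  xi <- max(1, floor(xc - w)):min(dx, ceiling(xc + w))
  gz <- exp(-((zi - zc)^2) / (2 * sigma_z^2))
  d2 <- outer((yi - yc)^2, (xi - xc)^2, `+`)
  disc <- exp(-(sqrt(d2) / radius)^8)
  arr[zi, yi, xi] <- arr[zi, yi, xi] +
    amplitude * array(rep(gz, length(disc)) *
                        rep(as.vector(disc), each = length(gz)),
                      c(length(zi), length(yi), length(xi)))
  arr
}

add_camera_noise <- function(vox, config) {
  lambda <- pmax(vox + config$background_level, 0)
  noisy <- stats::rpois(length(lambda), as.vector(lambda))
  if (config$read_noise_sd > 0) {
    noisy <- noisy + stats::rnorm(length(noisy), 0, config$read_noise_sd)
  }
  array(noisy, dim(vox))
}
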