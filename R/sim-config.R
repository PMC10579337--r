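#' Configuration for the synthetic immunofluorescence field generator
#'
#' Describes one multichannel z-stack the way the tissue/cell-line assay
#' acquires it: a DNA channel (nuclei + micronuclei), a pericentriolar
#' material (PCM) channel carrying the centrosome spots, a pHH3 channel
#' marking mitotic cells and a CEP164 channel carrying the
#' distal-appendage co-signal on a subset of spots.
#'
#' @param field_shape integer `(z, y, x)` voxel counts, each `>= 16`.
#' @param pixel_size_um micrometres per (x, y) pixel.
#' @param n_nuclei nuclei to plant.
#' @param nucleus_radius_um length-2 `(mean, sd)` of the nuclear radius in
#'   micrometres.
#' @param ca_distribution probability vector over per-cell centrosome
#'   counts `0, 1, ..., K`; must sum to 1 within `1e-9`. The true
#'   distribution in tissues is unknown, so this is a free parameter; the
#'   default is a unimodal mix around one centrosome with a supernumerary
#'   tail.
#' @param spot_sigma_px PSF sigma of a centrosome spot, in pixels.
#' @param mitotic_fraction probability a cell is pHH3-positive.
#' @param mn_rate expected micronuclei per (non-mitotic) cell.
#' @param cep164_positive_prob probability a planted spot carries the
#'   CEP164 co-signal (the assay reports >95% in cell lines).
#' @param snr peak spot amplitude divided by the background standard
#'   deviation; `Inf` disables noise entirely (noise-free fields).
#' @param background_level mean background photon count.
#' @param read_noise_sd additive Gaussian read noise SD (counts).
#' @param n_border_nuclei nuclei deliberately planted across the frame
#'   edge (flagged `is_border` in the truth table).
#' @param seed RNG seed; identical config + seed reproduces bit-identical
#'   stacks and truth tables.
#' @return validated list of class `image_sim_config`.
#' @export
image_sim_config <- function(field_shape = c(16L, 320L, 320L),
                             pixel_size_um = 0.3,
                             n_nuclei = 16L,
                             nucleus_radius_um = c(4.0, 0.4),
                             ca_distribution = c(0.10, 0.55, 0.20, 0.10, 0.05),
                             spot_sigma_px = 1.6,
                             mitotic_fraction = 0.08,
                             mn_rate = 0.25,
                             cep164_positive_prob = 0.95,
                             snr = Inf,
                             background_level = 40,
                             read_noise_sd = 3,
                             n_border_nuclei = 0L,
                             seed = 1L) {
  field_shape <- as.integer(field_shape)
  if (length(field_shape) != 3L || any(field_shape < 16L)) {
    stop("`field_shape` must be 3 integers (z, y, x), all >= 16")
  }
  if (abs(sum(ca_distribution) - 1) > 1e-9 || any(ca_distribution < 0)) {
    stop("`ca_distribution` must be a non-negative vector summing to 1 (within 1e-9)")
  }
  if (!is.numeric(snr) || snr <= 0) stop("`snr` must be > 0 (Inf for noise-free)")
  if (length(nucleus_radius_um) != 2L || nucleus_radius_um[1] <= 0) {
    stop("`nucleus_radius_um` must be (mean, sd) with positive mean")
  }
  stopifnot(pixel_size_um > 0, n_nuclei >= 0, spot_sigma_px > 0,
            mitotic_fraction >= 0, mitotic_fraction <= 1,
            mn_rate >= 0, cep164_positive_prob >= 0, cep164_positive_prob <= 1,
            background_level >= 0, read_noise_sd >= 0, n_border_nuclei >= 0)
  structure(
    list(field_shape = field_shape, pixel_size_um = pixel_size_um,
         n_nuclei = as.integer(n_nuclei),
         nucleus_radius_um = as.numeric(nucleus_radius_um),
         ca_distribution = as.numeric(ca_distribution),
         spot_sigma_px = spot_sigma_px,
         mitotic_fraction = mitotic_fraction, mn_rate = mn_rate,
         cep164_positive_prob = cep164_positive_prob, snr = snr,
         background_level = background_level, read_noise_sd = read_noise_sd,
         n_border_nuclei = as.integer(n_border_nuclei),
         seed = as.integer(seed)),
    class = "image_sim_config"
  )
}

#' Write / read a generator configuration as YAML
#' @param config an [image_sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "image_sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(image_sim_config, yaml::read_yaml(path))
}
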