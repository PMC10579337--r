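#' Write / read a simulated field as multi-page TIFF with a YAML sidecar
#'
#' Pages are ordered z-within-channel; the sidecar records channel names,
#' pixel size, stack shape and the intensity scale (pages are stored as
#' 32-bit floats normalized to the stack maximum).
#'
#' @param stack a `ca_image_stack`.
#' @param path output `.tif` path; the sidecar is `<path>.yml`.
#' @export
write_field_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "ca_image_stack"))
  vox <- stack$voxels
  scale <- max(vox, 1e-12)
  pages <- list()
  k <- 0L
  for (ch in seq_len(dim(vox)[1])) {
    for (z in seq_len(dim(vox)[2])) {
      k <- k + 1L
      pages[[k]] <- vox[ch, z, , ] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  yaml::write_yaml(list(channel_names = stack$channel_names,
                        pixel_size_um = stack$pixel_size_um,
                        shape = dim(vox), intensity_scale = scale),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_field_tiff
#' @export
read_field_tiff <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  shape <- as.integer(meta$shape)
  vox <- array(0, shape)
  k <- 0L
  for (ch in seq_len(shape[1])) {
    for (z in seq_len(shape[2])) {
      k <- k + 1L
      vox[ch, z, , ] <- pages[[k]] * meta$intensity_scale
    }
  }
  structure(list(voxels = vox, channel_names = unlist(meta$channel_names),
                 pixel_size_um = meta$pixel_size_um),
            class = "ca_image_stack")
}

#' Write ground-truth tables as CSV
#'
#' Three files are written: `<prefix>_nuclei.csv` (id, y, x, z, radius_px,
#' is_mitotic, is_border, n_spots, n_micronuclei), `<prefix>_spots.csv`
#' (id, nucleus_id, y, x, z, cep164_positive) and
#' `<prefix>_micronuclei.csv` (nucleus_id, y, x, z, radius_px).
#' Coordinates are 1-based pixels.
#'
#' @param truth truth list from [simulate_image_field()].
#' @param prefix path prefix.
#' @export
write_truth_tables <- function(truth, prefix) {
  utils::write.csv(truth$nuclei, paste0(prefix, "_nuclei.csv"), row.names = FALSE)
  utils::write.csv(truth$spots, paste0(prefix, "_spots.csv"), row.names = FALSE)
  utils::write.csv(truth$micronuclei, paste0(prefix, "_micronuclei.csv"),
                   row.names = FALSE)
  invisible(prefix)
}
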