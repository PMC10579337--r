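#' Segment nuclei from a projected DNA image
#'
#' Automatic, intensity-relative segmentation: Gaussian smoothing, Otsu
#' global threshold, hole filling, distance-transform watershed to split
#' touching objects, then morphology QC. Objects outside the area band are
#' removed (small DNA bodies are candidate micronuclei, not nuclei);
#' objects touching the frame are flagged `touches_border` and excluded
#' from whole-cell metrics downstream. All thresholds are data-relative,
#' so segmentation is invariant to global intensity rescaling.
#'
#' @param dna_image 2-D `(y, x)` matrix.
#' @param params list of segmentation parameters: `smooth_sigma` (px),
#'   `min_area`/`max_area` (px^2), `watershed_tolerance`.
#' @return tibble of nucleus objects (`label`, `area_px`, `y`, `x`,
#'   `mean_dna`, `touches_border`), with the full label mask as attribute
#'   `"mask"` (0 = background) and the pre-area-filter mask as
#'   `"raw_mask"` for micronucleus detection. Blank images give an empty
#'   tibble, not an error.
#' @export
segment_nuclei <- function(dna_image, params = list()) {
  p <- utils::modifyList(list(smooth_sigma = 2, min_area = 150,
                              max_area = 6000, watershed_tolerance = 1), params)
  img <- as.matrix(dna_image)
  rng <- range(img)
  if (diff(rng) <= 0) {
    return(empty_nuclei_table(matrix(0L, nrow(img), ncol(img))))
  }
  norm <- (img - rng[1]) / diff(rng)
  sm <- as.matrix(EBImage::gblur(EBImage::Image(norm), sigma = p$smooth_sigma))
  thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
  bin <- sm > thr
  if (!any(bin)) return(empty_nuclei_table(matrix(0L, nrow(img), ncol(img))))
  bin <- EBImage::fillHull(EBImage::Image(bin))
  dm <- EBImage::distmap(bin)
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = p$watershed_tolerance))
  storage.mode(labels) <- "integer"

  areas <- tabulate(labels[labels > 0L])
  keep <- which(areas >= p$min_area & areas <= p$max_area)
  if (length(keep) == 0L) return(empty_nuclei_table(labels))

  mask <- matrix(0L, nrow(img), ncol(img))
  rows <- vector("list", length(keep))
  new_lab <- 0L
  for (k in keep) {
    pix <- which(labels == k, arr.ind = TRUE)
    new_lab <- new_lab + 1L
    mask[pix] <- new_lab
    touches <- any(pix[, 1] %in% c(1L, nrow(img))) ||
      any(pix[, 2] %in% c(1L, ncol(img)))
    rows[[new_lab]] <- tibble::tibble(
      label = new_lab, area_px = nrow(pix),
      y = mean(pix[, 1]), x = mean(pix[, 2]),
      mean_dna = mean(img[pix]),
      touches_border = touches)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "mask") <- mask
  attr(out, "raw_mask") <- labels
  out
}

empty_nuclei_table <- function(mask) {
  out <- tibble::tibble(label = integer(), area_px = integer(), y = double(),
                        x = double(), mean_dna = double(),
                        touches_border = logical())
  attr(out, "mask") <- mask
  attr(out, "raw_mask") <- mask
  out
}

#' Classify mitotic nuclei from the pHH3 channel
#'
#' Computes the mean pHH3 intensity over each nucleus mask and splits the
#' per-nucleus means into pHH3-negative / pHH3-positive. By default the
#' split point is an automatic two-class (Otsu) threshold on the means,
#' accepted only if the putative positive class is clearly separated
#' (mean above 1.5x the negative-class mean) — otherwise no cell is
#' called mitotic. Pass `threshold` for a fixed, reproducible cut.
#'
#' @param nuclei tibble from [segment_nuclei()] (needs the `"mask"`
#'   attribute).
#' @param phh3_image 2-D matrix registered to the DNA channel.
#' @param threshold optional explicit intensity threshold; mean pHH3 above
#'   it calls the cell mitotic.
#' @return `nuclei` with columns `phh3_mean` and `is_mitotic` added.
#' @export
classify_mitotic <- function(nuclei, phh3_image, threshold = NULL) {
  mask <- attr(nuclei, "mask")
  if (is.null(mask)) stop("`nuclei` must carry the segmentation mask attribute")
  if (nrow(nuclei) == 0L) {
    nuclei$phh3_mean <- double()
    nuclei$is_mitotic <- logical()
    return(nuclei)
  }
  img <- as.matrix(phh3_image)
  means <- vapply(nuclei$label, function(l) mean(img[mask == l]), 0)
  if (!is.null(threshold)) {
    mitotic <- means > threshold
  } else if (diff(range(means)) <= 0) {
    mitotic <- rep(FALSE, length(means))
  } else {
    rng <- range(means)
    sc <- (means - rng[1]) / diff(rng)
    cut <- tryCatch(
      EBImage::otsu(EBImage::Image(matrix(sc, 1)), range = c(0, 1), levels = 256),
      error = function(e) 0.5)
    mitotic <- sc > cut
    lo <- means[!mitotic]
    hi <- means[mitotic]
    # reject a split that only carves noise off a single population
    if (length(hi) == 0L || length(lo) == 0L || mean(hi) < 1.5 * mean(lo)) {
      mitotic <- rep(FALSE, length(means))
    }
  }
  nuclei$phh3_mean <- means
  nuclei$is_mitotic <- mitotic
  nuclei
}

#' Detect micronuclei and assign them to owner nuclei
#'
#' Micronuclei are DNA-positive objects below the nucleus area band whose
#' area lies within a fraction band of the owner's area and whose centroid
#' falls within an ownership radius (in units of the owner's equivalent
#' radius) of a segmented nucleus. Owners must be whole (non-border)
#' cells; the mitotic-owner exclusion is applied downstream when
#' frequencies are computed.
#'
#' @param dna_image projected DNA matrix.
#' @param nuclei tibble from [segment_nuclei()] (with mask attributes).
#' @param params list: `mn_area_frac` length-2 fraction band of owner
#'   area, `ownership_radii` max centroid distance in owner equivalent
#'   radii (default 2.2: thresholded masks underestimate the geometric
#'   radius by a few percent, so the cap is slightly wider than the
#'   biological 2-radius annulus), `smooth_sigma` for the fine-scale DNA
#'   mask (smaller than the
#'   nucleus-segmentation blur so few-pixel DNA bodies survive).
#' @return `nuclei` with an `n_micronuclei` column added; the micronucleus
#'   table (owner, centroid, area) as attribute `"micronuclei"`.
#' @export
detect_micronuclei <- function(dna_image, nuclei, params = list()) {
  p <- utils::modifyList(list(mn_area_frac = c(0.005, 0.15),
                              ownership_radii = 2.2, smooth_sigma = 1), params)
  raw <- attr(nuclei, "raw_mask")
  if (is.null(raw)) stop("`nuclei` must carry the raw segmentation mask")
  nuclei$n_micronuclei <- rep(0L, nrow(nuclei))
  mn_rows <- list()
  img <- as.matrix(dna_image)
  if (nrow(nuclei) > 0L && diff(range(img)) > 0) {
    # fine-scale mask: mild blur keeps few-pixel micronuclei above the
    # Otsu cut that separates background from DNA plateau
    rng <- range(img)
    sm <- as.matrix(EBImage::gblur(EBImage::Image((img - rng[1]) / diff(rng)),
                                   sigma = p$smooth_sigma))
    thr <- EBImage::otsu(EBImage::Image(sm), range = c(0, 1))
    fine <- EBImage::bwlabel(EBImage::Image(sm > thr))
    fine <- EBImage::imageData(fine)
    storage.mode(fine) <- "integer"
    labs <- sort(unique(fine[fine > 0L]))
    r_eq <- sqrt(nuclei$area_px / pi)
    for (l in labs) {
      pix <- which(fine == l, arr.ind = TRUE)
      cy <- mean(pix[, 1]); cx <- mean(pix[, 2])
      d <- sqrt((nuclei$y - cy)^2 + (nuclei$x - cx)^2)
      # a micronucleus sits outside the owner nucleus proper but inside
      # the ownership annulus; the lower bound also rejects the nuclei
      # themselves (their fine-mask centroids fall at the nucleus centre)
      within <- d > r_eq & d <= p$ownership_radii * r_eq
      if (!any(within)) next
      owner <- which(within)[which.min(d[within])]
      frac <- nrow(pix) / nuclei$area_px[owner]
      if (frac <= p$mn_area_frac[1] || frac >= p$mn_area_frac[2]) next
      if (nuclei$touches_border[owner]) next
      nuclei$n_micronuclei[owner] <- nuclei$n_micronuclei[owner] + 1L
      mn_rows[[length(mn_rows) + 1L]] <- tibble::tibble(
        owner_label = nuclei$label[owner], y = cy, x = cx, area_px = nrow(pix))
    }
  }
  mn <- if (length(mn_rows)) dplyr::bind_rows(mn_rows) else tibble::tibble(
    owner_label = integer(), y = double(), x = double(), area_px = integer())
  attr(nuclei, "micronuclei") <- mn
  nuclei
}
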