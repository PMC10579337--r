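#' Detect centrosome spots in a projected PCM image
#'
#' Multiscale Laplacian-of-Gaussian blob detection: the image is filtered
#' with scale-normalized LoG kernels at `sigma * {0.8, 1, 1.25}`, the
#' per-pixel maximum response is thresholded data-relatively (robust
#' background statistics of the response map), and candidate maxima are
#' greedily non-max-suppressed so that maxima closer than `2 sigma` count
#' as one spot (the declared merge rule). Each accepted spot gets a
#' subpixel centre (intensity-weighted centroid of a local window), an
#' ellipse fitted to the above-half-maximum region (second moments;
#' `size = width x length` in px^2, the projected-PCM size convention),
#' and is assigned to the nearest segmented nucleus within
#' `ownership_radii` equivalent radii — unassigned spots are discarded as
#' stromal/background.
#'
#' @param pcm_image 2-D `(y, x)` matrix.
#' @param nuclei tibble from [segment_nuclei()].
#' @param params list: `sigma` (expected PSF sigma, px), `k_mad`
#'   (detection threshold in background MADs of the LoG response),
#'   `rel_floor` (threshold floor as a fraction of the peak response),
#'   `ownership_radii`.
#' @return tibble of spot objects: `y`, `x` (subpixel), `peak_intensity`,
#'   `width_px`, `length_px`, `size_px2`, `size_um2` (`NA` without pixel
#'   size), `nucleus_label` (`NA` for discarded/stromal spots retained in
#'   the attribute `"discarded"`).
#' @export
detect_spots <- function(pcm_image, nuclei, params = list()) {
  p <- utils::modifyList(list(sigma = 1.6, k_mad = 8, rel_floor = 0.15,
                              ownership_radii = 2, pixel_size_um = NA_real_),
                         params)
  img <- as.matrix(pcm_image)
  empty <- tibble::tibble(y = double(), x = double(), peak_intensity = double(),
                          width_px = double(), length_px = double(),
                          size_px2 = double(), size_um2 = double(),
                          nucleus_label = integer())
  if (diff(range(img)) <= 0) {
    attr(empty, "discarded") <- empty
    return(empty)
  }

  resp <- multiscale_log(img, p$sigma)
  bg_med <- stats::median(resp)
  bg_mad <- stats::mad(resp)
  thr <- max(bg_med + p$k_mad * bg_mad, p$rel_floor * max(resp))

  cand <- local_maxima(resp, radius = max(1L, ceiling(p$sigma)), threshold = thr)
  if (nrow(cand) == 0L) {
    attr(empty, "discarded") <- empty
    return(empty)
  }
  # merge rule: maxima closer than 2 sigma are one spot (keep the stronger)
  ord <- order(-cand$value)
  keep <- logical(nrow(cand))
  min_d2 <- (2 * p$sigma)^2
  for (i in ord) {
    kept <- which(keep)
    if (length(kept) == 0L ||
        all((cand$y[kept] - cand$y[i])^2 + (cand$x[kept] - cand$x[i])^2 >= min_d2)) {
      keep[i] <- TRUE
    }
  }
  cand <- cand[keep, , drop = FALSE]

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    fit <- fit_spot(img, cand$y[i], cand$x[i], p$sigma)
    tibble::tibble(y = fit$y, x = fit$x, peak_intensity = fit$peak,
                   width_px = fit$width, length_px = fit$length,
                   size_px2 = fit$width * fit$length,
                   size_um2 = fit$width * fit$length * p$pixel_size_um^2)
  })
  spots <- dplyr::bind_rows(rows)

  if (nrow(nuclei) > 0L) {
    r_eq <- sqrt(nuclei$area_px / pi)
    owner <- integer(nrow(spots))
    for (i in seq_len(nrow(spots))) {
      d <- sqrt((nuclei$y - spots$y[i])^2 + (nuclei$x - spots$x[i])^2)
      j <- which.min(d)
      owner[i] <- if (d[j] <= p$ownership_radii * r_eq[j]) nuclei$label[j] else NA_integer_
    }
    spots$nucleus_label <- owner
  } else {
    spots$nucleus_label <- rep(NA_integer_, nrow(spots))
  }
  discarded <- spots[is.na(spots$nucleus_label), , drop = FALSE]
  spots <- spots[!is.na(spots$nucleus_label), , drop = FALSE]
  attr(spots, "discarded") <- discarded
  spots
}

# scale-normalized negative-LoG response, max over scales
multiscale_log <- function(img, sigma, scales = c(0.8, 1, 1.25)) {
  resp <- NULL
  for (s in scales) {
    sg <- sigma * s
    sm <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sg))
    lap <- sg^2 * neg_laplacian(sm)
    resp <- if (is.null(resp)) lap else pmax(resp, lap)
  }
  resp
}

neg_laplacian <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  up <- m[c(1, seq_len(ny - 1)), ]
  dn <- m[c(seq_len(ny - 1) + 1, ny), ]
  lf <- m[, c(1, seq_len(nx - 1))]
  rt <- m[, c(seq_len(nx - 1) + 1, nx)]
  4 * m - up - dn - lf - rt
}

local_maxima <- function(resp, radius, threshold) {
  dil <- as.matrix(EBImage::dilate(EBImage::Image(resp),
                                   EBImage::makeBrush(2L * radius + 1L, "box")))
  is_max <- (resp >= dil) & (resp > threshold)
  idx <- which(is_max, arr.ind = TRUE)
  tibble::tibble(y = idx[, 1], x = idx[, 2],
                 value = resp[idx])
}

# subpixel centre + half-max ellipse from a local window
fit_spot <- function(img, y0, x0, sigma) {
  w <- max(3L, ceiling(3 * sigma))
  yi <- max(1, y0 - w):min(nrow(img), y0 + w)
  xi <- max(1, x0 - w):min(ncol(img), x0 + w)
  win <- img[yi, xi, drop = FALSE]
  bg <- stats::quantile(win, 0.1, names = FALSE)
  sig <- pmax(win - bg, 0)
  peak <- img[y0, x0]
  half <- (peak - bg) / 2
  above <- sig >= half
  wts <- sig * above
  tot <- sum(wts)
  if (tot <= 0) {  # degenerate: flat window
    return(list(y = y0, x = x0, peak = peak, width = 1, length = 1))
  }
  yy <- matrix(yi, length(yi), length(xi))
  xx <- matrix(xi, length(yi), length(xi), byrow = TRUE)
  cy <- sum(wts * yy) / tot
  cx <- sum(wts * xx) / tot
  vyy <- sum(wts * (yy - cy)^2) / tot
  vxx <- sum(wts * (xx - cx)^2) / tot
  vyx <- sum(wts * (yy - cy) * (xx - cx)) / tot
  ev <- eigen(matrix(c(vyy, vyx, vyx, vxx), 2), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-3)
  list(y = cy, x = cx, peak = peak,
       length = 4 * sqrt(ev[1]), width = 4 * sqrt(ev[2]))
}

#' Score marker positivity (CEP164 / CETN3) for detected spots
#'
#' A spot is positive iff the mean marker intensity in a 3x3 pixel window
#' at its centre exceeds the threshold rule. The default rule is
#' data-relative: background median plus `k` background MADs of the
#' marker image, with a strict `>` so an all-zero channel scores 0%
#' positive.
#'
#' @param spots tibble from [detect_spots()].
#' @param marker_image 2-D matrix registered to the PCM channel; `NULL`
#'   marks positivity undefined (`NA`).
#' @param threshold_rule either a single number (explicit threshold) or a
#'   list `list(k = 6, rel_floor = 0.05)`: background median plus `k`
#'   MADs, floored at `rel_floor` times the channel maximum (the floor
#'   guards against PSF leakage from neighbouring positive spots when the
#'   background is exactly flat).
#' @param column name of the logical column to fill
#'   (`"cep164_positive"` or `"cetn3_positive"`).
#' @return `spots` with the positivity column set.
#' @export
score_marker_positivity <- function(spots, marker_image,
                                    threshold_rule = list(k = 6, rel_floor = 0.05),
                                    column = "cep164_positive") {
  if (is.null(marker_image)) {
    spots[[column]] <- rep(NA, nrow(spots))
    return(spots)
  }
  img <- as.matrix(marker_image)
  thr <- if (is.numeric(threshold_rule) && length(threshold_rule) == 1L) {
    threshold_rule
  } else {
    rel <- threshold_rule$rel_floor %||% 0.05
    max(stats::median(img) + threshold_rule$k * stats::mad(img),
        rel * (max(img) - stats::median(img)) + stats::median(img))
  }
  pos <- vapply(seq_len(nrow(spots)), function(i) {
    yi <- max(1, round(spots$y[i]) - 1):min(nrow(img), round(spots$y[i]) + 1)
    xi <- max(1, round(spots$x[i]) - 1):min(ncol(img), round(spots$x[i]) + 1)
    mean(img[yi, xi]) > thr
  }, NA)
  spots[[column]] <- pos
  spots
}
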