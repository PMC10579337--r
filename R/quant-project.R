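#' Maximum-intensity projection of a multichannel z-stack
#'
#' Collapses the z axis per channel, the reconstruction step the assay
#' applies before all 2-D analysis.
#'
#' @param stack a `ca_image_stack` (`voxels` indexed channel, z, y, x) or
#'   a bare 3-D `(z, y, x)` array for a single channel.
#' @return named list of 2-D `(y, x)` matrices, one per channel (a single
#'   matrix for bare-array input). Idempotent on single-plane input.
#' @export
max_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3L) {
    return(mip_z(stack))
  }
  stopifnot(inherits(stack, "ca_image_stack"))
  vox <- stack$voxels
  if (length(dim(vox)) != 4L || dim(vox)[2] < 1L) {
    stop("stack must contain at least one z-plane")
  }
  if (!all(is.finite(vox))) stop("stack intensities must be finite")
  out <- lapply(seq_len(dim(vox)[1]), function(ch) {
    sub <- vox[ch, , , ]  # drops to (z, y, x), or (y, x) when z == 1
    if (length(dim(sub)) == 2L) sub else mip_z(sub)
  })
  names(out) <- stack$channel_names
  out
}

# pmax across z-slices (much faster than apply over 10^5 cells)
mip_z <- function(a) {
  if (length(dim(a)) != 3L || dim(a)[1] < 1L) stop("need a (z, y, x) array")
  out <- a[1L, , ]
  nz <- dim(a)[1]
  if (nz > 1L) for (z in 2:nz) out <- pmax(out, a[z, , ])
  out
}
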