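#' Split a frame stack into processing blocks
#'
#' Consecutive, non-overlapping blocks of `block_size` frames. A trailing
#' remainder shorter than one block is discarded with a warning; a stack
#' shorter than one block is an error.
#'
#' @param stack a [frame_stack()].
#' @param block_size frames per block.
#' @return A list of `frame_block` objects (`$values`, `$index`,
#'   `$start_frame`, `$svd_cut`).
#' @export
iter_blocks <- function(stack, block_size = 200L) {
  nf <- n_frames(stack)
  if (nf < block_size)
    abort(sprintf("stack has %d frames, shorter than one block (%d)",
                  nf, block_size))
  block_size <- as.integer(block_size)
  nb <- nf %/% block_size
  dropped <- nf - nb * block_size
  if (dropped > 0)
    warn(sprintf("dropping trailing %d frames (< one block)", dropped))
  lapply(seq_len(nb), function(b) {
    idx <- ((b - 1L) * block_size + 1L):(b * block_size)
    structure(list(values = stack$values[, , idx, drop = FALSE],
                   index = b - 1L,
                   start_frame = (b - 1L) * block_size,
                   svd_cut = NA_integer_),
              class = "frame_block")
  })
}

#' SVD spatiotemporal clutter filter
#'
#' Unfolds the block to its space x time Casorati matrix, removes the
#' `n_remove` largest singular components (the spatiotemporally coherent
#' tissue signal) and refolds. The removed and kept components are
#' orthogonal, so input energy equals output energy plus removed energy.
#'
#' @param block a `frame_block` from [iter_blocks()].
#' @param n_remove number of leading singular values to discard
#'   (20 for ULM, 60 for power Doppler with the defaults).
#' @return The filtered `frame_block` (with `svd_cut` set).
#' @export
svd_filter <- function(block, n_remove) {
  v <- block$values
  d <- dim(v)
  if (n_remove < 0 || n_remove >= d[3])
    abort("n_remove must satisfy 0 <= n_remove < block size")
  if (!all(is.finite(v))) abort("block contains non-finite values")
  out <- block
  out$svd_cut <- as.integer(n_remove)
  if (n_remove == 0) return(out)
  M <- matrix(v, d[1] * d[2], d[3])
  sv <- La.svd(M)
  if (n_remove >= length(sv$d)) {   # cut exceeds the matrix rank bound
    out$values <- array(0, d)
    return(out)
  }
  keep <- (n_remove + 1L):length(sv$d)
  filt <- sv$u[, keep, drop = FALSE] %*%
    (sv$d[keep] * sv$vt[keep, , drop = FALSE])
  out$values <- array(filt, d)
  out
}

#' Filter a whole stack block-by-block
#'
#' @param stack a [frame_stack()].
#' @param n_remove singular values removed per block.
#' @param block_size frames per block.
#' @return A filtered [frame_stack()] (trailing remainder dropped).
#' @export
svd_filter_stack <- function(stack, n_remove, block_size = 200L) {
  blocks <- iter_blocks(stack, block_size)
  v <- array(0, c(dim(stack$values)[1:2], length(blocks) * block_size))
  for (b in blocks) {
    fb <- svd_filter(b, n_remove)
    v[, , b$start_frame + seq_len(block_size)] <- fb$values
  }
  frame_stack(v, stack$grid, stack$frame_rate_hz, provenance = "filtered")
}

block_energy <- function(block) sum(block$values^2)
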