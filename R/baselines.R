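# Comparator reconstructions: unregularized low-rank inversion (LRI) for the
# subspace fingerprinting problem, and locally-low-rank (LLR) via the same
# ADMM driver with the patch denoiser swapped for per-block Casorati
# singular-value thresholding.

#' Low-rank inversion reconstruction
#'
#' Plain least-squares solve of `min ||E X - Y||^2` by a fixed number of
#' conjugate gradient iterations on the normal equations (no regularization,
#' no stopping tolerance: the fixed iteration count is the regularizer).
#'
#' @param Y k-space data.
#' @param op an `encoding_operator` (typically the radial subspace operator).
#' @param cg_iters fixed CG iteration count.
#' @return complex image stack.
#' @export
lri_recon <- function(Y, op, cg_iters = 10L) {
  x0 <- if (op$mode == "radial") op$dc_adjoint(Y) else op$adjoint(Y)
  solve_data_consistency(Y, op, mu = 0, cg_eps = 0, cg_iters = cg_iters,
                         x0 = x0)
}

#' Locally-low-rank parameters
#'
#' @param block_edge side of the non-overlapping image blocks, voxels.
#' @param threshold_frac singular values below this fraction of each block's
#'   largest singular value are zeroed.
#' @param admm_iters,mu ADMM loop controls.
#' @return `llr_params` list.
#' @export
llr_params <- function(block_edge = 8L, threshold_frac = 0.05,
                       admm_iters = 5L, mu = 5e-3) {
  stopifnot(block_edge >= 2, threshold_frac >= 0, threshold_frac < 1,
            admm_iters >= 1, mu > 0)
  structure(list(block_edge = as.integer(block_edge),
                 threshold_frac = threshold_frac,
                 admm_iters = as.integer(admm_iters), mu = mu),
            class = "llr_params")
}

#' Blockwise Casorati singular value thresholding
#'
#' Tiles the image into non-overlapping `block_edge` blocks (clipped at the
#' boundary), forms each block's Casorati matrix (voxels x contrasts), zeroes
#' singular values below `threshold_frac` times the block's largest singular
#' value, and rebuilds.  An optional circular `shift` implements cycle
#' spinning.
#'
#' @param X complex Mx x My x L image stack, L >= 2.
#' @param block_edge block side, voxels.
#' @param threshold_frac relative singular value cutoff in [0, 1).
#' @param shift integer length-2 circular pre-shift (undone on output).
#' @return thresholded image stack.
#' @export
block_svt <- function(X, block_edge = 8L, threshold_frac = 0.05,
                      shift = c(0L, 0L)) {
  X <- as_image_stack(X)
  d <- dim(X)
  if (d[3] < 2) stop("block_svt needs at least 2 contrasts", call. = FALSE)
  roll <- function(A, s) {
    if (s[1] != 0) A <- A[c((d[1] - s[1] + 1):d[1], 1:(d[1] - s[1])), , ,
                          drop = FALSE]
    if (s[2] != 0) A <- A[, c((d[2] - s[2] + 1):d[2], 1:(d[2] - s[2])), ,
                          drop = FALSE]
    A
  }
  shift <- as.integer(shift) %% d[1:2]
  Xs <- roll(X, shift)
  out <- Xs
  xb <- c(seq.int(1L, d[1], by = block_edge), d[1] + 1L)
  yb <- c(seq.int(1L, d[2], by = block_edge), d[2] + 1L)
  for (i in seq_len(length(xb) - 1L)) {
    for (j in seq_len(length(yb) - 1L)) {
      ix <- xb[i]:(xb[i + 1L] - 1L); iy <- yb[j]:(yb[j + 1L] - 1L)
      blk <- Xs[ix, iy, , drop = FALSE]
      C <- matrix(blk, prod(dim(blk)[1:2]), d[3])
      s <- svd(C)
      keep <- s$d >= threshold_frac * s$d[1]
      dd <- s$d * keep
      Cr <- s$u %*% (dd * Conj(t(s$v)))
      out[ix, iy, ] <- array(Cr, dim(blk))
    }
  }
  roll(out, (d[1:2] - shift) %% d[1:2])
}

#' Locally-low-rank reconstruction
#'
#' Identical ADMM loop to [hd_prost_recon()] with the patch-tensor denoiser
#' replaced by [block_svt()]; the block grid is circularly shifted each
#' iteration (cycle spinning), with shifts derived deterministically from
#' `cfg$seed`.
#'
#' @param Y k-space data.
#' @param op an `encoding_operator`.
#' @param cfg a [recon_config()] (supplies mu, admm_iters, CG controls, seed).
#' @param params an [llr_params()] (block size and threshold).
#' @param verbose log per-iteration diagnostics.
#' @return complex image stack with attribute `"admm_diag"`.
#' @export
llr_recon <- function(Y, op, cfg, params = llr_params(mu = cfg$mu),
                      verbose = FALSE) {
  be <- params$block_edge
  shifts <- matrix(
    (cfg$seed + 7919L * seq_len(2L * cfg$admm_iters)) %% be,
    ncol = 2)
  denoiser <- function(W, it)
    block_svt(W, be, params$threshold_frac, shift = shifts[it, ])
  admm_recon(Y, op, cfg, denoiser, verbose = verbose)
}
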