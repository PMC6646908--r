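# High-order patch-tensor denoising: block matching of complex multi-contrast
# patches, truncated complex HOSVD per patch group, and uniform-weight
# sliding-window aggregation.  This is the ADMM denoising sub-problem; the
# singular-value cutoff tau = 2*lambda/mu comes from the nuclear-norm weight
# and the ADMM penalty.

#' Denoiser parameters
#'
#' @param patch_edge odd patch side length.
#' @param K patches per group (reference included).
#' @param search_radius Chebyshev block-matching radius, voxels.
#' @param patch_offset reference-grid stride, voxels.
#' @param tau nonnegative singular value cutoff, applied per tensor mode to
#'   the working image after normalization to unit maximum magnitude.
#' @return `denoise_params` list.
#' @export
denoise_params <- function(patch_edge = 7L, K = 20L, search_radius = 20L,
                           patch_offset = 3L, tau = 0) {
  stopifnot(patch_edge >= 1, patch_edge %% 2 == 1, K >= 1,
            search_radius >= patch_edge, patch_offset >= 1, tau >= 0)
  structure(list(patch_edge = as.integer(patch_edge), K = as.integer(K),
                 N = as.integer(patch_edge)^2,
                 search_radius = as.integer(search_radius),
                 patch_offset = as.integer(patch_offset), tau = tau),
            class = "denoise_params")
}

as_image_stack <- function(X) {
  X <- as.array(X)
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  X
}

#' Block matching around one reference patch
#'
#' Finds the `K` patches (the reference plus `K - 1` nearest candidates)
#' minimizing the complex squared l2 distance summed over all patch voxels
#' and all contrasts, inside a Chebyshev window of `search_radius` around the
#' reference corner (clipped at image bounds).  Ties are broken by scan order
#' (column-major linear index of the corner); the reference is always first.
#' If the clipped window holds fewer than `K` patches the selection shrinks
#' with a warning.
#'
#' @param X complex Mx x My x L image stack.
#' @param ref_coord 1-based (x, y) corner of the reference patch.
#' @param params [denoise_params()].
#' @return integer matrix K x 2 of 1-based corners, reference first.
#' @export
block_match <- function(X, ref_coord, params) {
  X <- as_image_stack(X)
  edge <- params$patch_edge
  ncand <- prod(pmin(dim(X)[1:2] - edge, ref_coord - 1 + params$search_radius) -
                pmax(0, ref_coord - 1 - params$search_radius) + 1)
  K <- params$K
  if (ncand < K) {
    warning(sprintf("search window holds only %d patches; shrinking K from %d",
                    ncand, K))
    K <- ncand
  }
  cc <- .bm_all(X, matrix(as.integer(ref_coord) - 1L, 1, 2), edge,
                as.integer(K), params$search_radius)
  cc + 1L
}

#' Build a patch tensor from matched coordinates
#'
#' `data[n, k, l]` is voxel `n` (column-major within the patch) of patch `k`
#' in contrast `l`.
#'
#' @param X complex image stack.
#' @param coords K x 2 matrix of 1-based patch corners, reference first.
#' @param params [denoise_params()].
#' @return `patch_tensor`: list with `data` (N x K x L), `member_coords`,
#'   `reference_coord`.
#' @export
build_patch_tensor <- function(X, coords, params) {
  X <- as_image_stack(X)
  d <- dim(X); edge <- params$patch_edge
  coords <- matrix(as.integer(coords), ncol = 2)
  if (any(coords < 1L) || any(coords[, 1] > d[1] - edge + 1L) ||
      any(coords[, 2] > d[2] - edge + 1L))
    stop("patch corner out of image bounds", call. = FALSE)
  tmpl <- as.vector(outer(0:(edge - 1), 0:(edge - 1) * d[1], `+`))
  base <- coords[, 1] + (coords[, 2] - 1L) * d[1]
  idx <- outer(tmpl, base, `+`)                       # N x K
  plane <- d[1] * d[2]
  data <- array(0i, c(length(tmpl), nrow(coords), d[3]))
  for (l in seq_len(d[3])) data[, , l] <- X[idx + (l - 1L) * plane]
  structure(list(data = data, member_coords = coords,
                 reference_coord = coords[1, ]), class = "patch_tensor")
}

unfold <- function(A, mode) {
  d <- dim(A)
  perm <- switch(mode, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  matrix(aperm(A, perm), d[mode])
}

refold <- function(M, mode, d) {
  perm <- switch(mode, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  aperm(array(M, d[perm]), order(perm))
}

#' Truncated complex higher-order SVD
#'
#' Per mode, keeps the left singular vectors of the mode unfolding whose
#' singular values are `>= tau` (at least one), then projects the tensor onto
#' the retained subspaces: hard multilinear truncation, no core shrinkage.
#'
#' @param T3 `patch_tensor` or bare complex 3-way array.
#' @param tau nonnegative singular value cutoff.
#' @return same type as the input, with attribute `"mode_sv"` (list of the
#'   mode singular values) and `"mode_ranks"` on the array.
#' @export
hosvd_truncate <- function(T3, tau) {
  is_pt <- inherits(T3, "patch_tensor")
  A <- if (is_pt) T3$data else as.array(T3)
  stopifnot(length(dim(A)) == 3, tau >= 0)
  if (any(!is.finite(Re(A))) || any(!is.finite(Im(A))))
    stop("non-finite values in patch tensor", call. = FALSE)
  d <- dim(A)
  sv <- vector("list", 3)
  out <- A
  for (mode in 1:3) {
    Um <- unfold(A, mode)
    s <- svd(Um, nu = min(dim(Um)), nv = 0)
    sv[[mode]] <- s$d
    keep <- max(1L, sum(s$d >= tau))
    U <- s$u[, seq_len(keep), drop = FALSE]
    proj <- U %*% (Conj(t(U)) %*% unfold(out, mode))
    out <- refold(proj, mode, d)
  }
  attr(out, "mode_sv") <- sv
  attr(out, "mode_ranks") <- vapply(sv, function(s) max(1L, sum(s >= tau)), 1L)
  if (is_pt) {
    T3$data <- out
    T3
  } else out
}

#' Aggregate denoised patch groups into an image
#'
#' Every voxel/contrast estimate is the arithmetic mean of all patch
#' estimates covering it.  Errors if any voxel is covered by no patch.
#'
#' @param groups list of `patch_tensor`s (denoised).
#' @param img_dim integer c(Mx, My, L).
#' @param patch_edge patch side length.
#' @return complex array of `img_dim`.
#' @export
aggregate_groups <- function(groups, img_dim, patch_edge) {
  acc <- array(0i, img_dim)
  hits <- array(0, img_dim[1:2])
  edge <- patch_edge
  tmpl <- as.vector(outer(0:(edge - 1), 0:(edge - 1) * img_dim[1], `+`))
  plane <- img_dim[1] * img_dim[2]
  for (g in groups) {
    base <- g$member_coords[, 1] + (g$member_coords[, 2] - 1L) * img_dim[1]
    idx <- as.vector(outer(tmpl, base, `+`))          # N*K spatial indices
    K <- nrow(g$member_coords)
    for (l in seq_len(img_dim[3])) {
      off <- (l - 1L) * plane
      acc[idx + off] <- acc[idx + off] + as.vector(g$data[, , l])
    }
    hits[idx] <- hits[idx] + 1
  }
  if (any(hits == 0))
    stop("aggregation left uncovered voxels: reference grid bug",
         call. = FALSE)
  acc / as.vector(hits)   # hits recycles over the contrast dimension
}

reference_grid <- function(M, edge, offset) {
  unique(c(seq.int(1L, M - edge + 1L, by = offset), M - edge + 1L))
}

#' Multi-contrast patch-tensor denoiser
#'
#' Sweeps reference patches over a grid with stride `patch_offset` (last
#' row/column shifted to touch the boundary), block-matches `K` similar
#' complex patches per reference, hard-truncates the HOSVD of each
#' N x K x L patch group at `tau`, and aggregates overlapping estimates by
#' averaging.  The input is pre-normalized to unit maximum magnitude so that
#' `tau` is scale-free; the scale is restored on output.
#'
#' @param X complex Mx x My x L image stack.
#' @param params [denoise_params()].
#' @return denoised complex array, same shape as `X`.
#' @export
denoise_multicontrast <- function(X, params) {
  X <- as_image_stack(X)
  d <- dim(X)
  edge <- params$patch_edge
  if (any(d[1:2] < edge)) stop("patch larger than image", call. = FALSE)
  scale <- max(Mod(X))
  if (scale == 0) return(X)
  Xn <- X / scale
  xs <- reference_grid(d[1], edge, params$patch_offset)
  ys <- reference_grid(d[2], edge, params$patch_offset)
  refs <- cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  # uniform K across groups: the most clipped corner window bounds it
  min_cand <- prod(pmin(params$search_radius, d[1:2] - edge) + 1L)
  K <- min(params$K, min_cand)
  if (K < params$K)
    warning(sprintf("image too small for K=%d; using K=%d", params$K, K))
  cc <- .bm_all(Xn, refs - 1L, edge, as.integer(K), params$search_radius) + 1L
  groups <- vector("list", nrow(refs))
  for (g in seq_len(nrow(refs))) {
    coords <- cc[(g - 1L) * K + seq_len(K), , drop = FALSE]
    pt <- build_patch_tensor(Xn, coords, params)
    groups[[g]] <- hosvd_truncate(pt, params$tau)
  }
  scale * aggregate_groups(groups, d, edge)
}
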