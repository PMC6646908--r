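#' Gridding non-uniform FFT plan
#'
#' Type-2 NUFFT (uniform image -> arbitrary k-space samples) by Kaiser-Bessel
#' gridding: the image is deapodized, zero-padded onto a 2x oversampled grid,
#' FFT'd, and interpolated at the sample locations through a sparse
#' interpolation matrix.  Because forward and adjoint share the one real
#' sparse matrix (and the FFT/padding/deapodization factors are applied as
#' exact adjoints), the operator pair is adjoint to machine precision; the
#' kernel only controls how accurately the forward model approximates the
#' exact discrete-time Fourier sum.
#'
#' Conventions: sample coordinates in cycles/sample within `[-0.5, 0.5)` per
#' axis; the exact model is `s(nu) = (1/N) sum_x X(x) exp(-2i pi nu . x)`
#' with `x` integer voxel offsets centred on the grid (unitary scaling for an
#' `N x N` image, consistent with [fft2c()] on the Cartesian path).
#'
#' @param coords M x 2 matrix of sample locations, cycles/sample.
#' @param matrix_size image side length N (even).
#' @param os oversampling factor (grid side `os * N`).
#' @param width kernel support in oversampled grid cells.
#' @return a `nufft_plan` object.
#' @export
nufft_plan <- function(coords, matrix_size, os = 2, width = 5L) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  if (any(!is.finite(coords)) || any(abs(coords) > 0.5))
    stop("sample coordinates must be finite and within [-0.5, 0.5]",
         call. = FALSE)
  N <- as.integer(matrix_size)
  stopifnot_even(N, "matrix_size")
  G <- as.integer(round(os * N))
  stopifnot_even(G, "oversampled grid")
  w <- as.integer(width)
  hw <- w / 2
  beta <- pi * sqrt((w / os)^2 * (os - 0.5)^2 - 0.8)

  kb <- function(t) {
    v <- numeric(length(t))
    ok <- abs(t) <= hw
    v[ok] <- besselI(beta * sqrt(1 - (t[ok] / hw)^2), 0) / besselI(beta, 0)
    v
  }

  M <- nrow(coords)
  noff <- 2L * floor(w / 2) + 1L
  offs <- seq.int(-floor(w / 2), floor(w / 2))
  build_axis <- function(u) {
    # u: sample position in oversampled-grid units; returns list(idx, wgt)
    base <- round(u)
    m <- outer(base, rep(1, noff)) + outer(rep(1, M), offs)
    wgt <- matrix(kb(as.vector(m - u)), M)  # u recycles down columns
    idx <- ((m + G / 2) %% G) + 1L          # wrap: the DFT grid is periodic
    list(idx = idx, wgt = wgt)
  }
  ax <- build_axis(coords[, 1] * G)
  ay <- build_axis(coords[, 2] * G)

  rows <- rep(seq_len(M), times = noff * noff)
  cols <- integer(0); vals <- numeric(0)
  cols <- matrix(0L, M, noff * noff)
  vals <- matrix(0, M, noff * noff)
  for (jx in seq_len(noff)) {
    for (jy in seq_len(noff)) {
      k <- (jx - 1L) * noff + jy
      cols[, k] <- ax$idx[, jx] + (ay$idx[, jy] - 1L) * G
      vals[, k] <- ax$wgt[, jx] * ay$wgt[, jy]
    }
  }
  P <- Matrix::sparseMatrix(i = rep(seq_len(M), noff * noff),
                            j = as.vector(cols), x = as.vector(vals),
                            dims = c(M, G * G))
  Pt <- Matrix::t(P)

  # deapodization: Fourier transform of the kernel at image positions x/G
  xs <- seq.int(-N / 2, N / 2 - 1)
  tq <- seq(-hw, hw, length.out = 4001L)
  dt <- tq[2] - tq[1]
  kbt <- kb(tq)
  apod1 <- vapply(xs / G, function(xi) sum(kbt * cos(2 * pi * xi * tq)) * dt,
                  numeric(1))
  apod2 <- outer(apod1, apod1) * N   # includes the 1/N unitary factor

  structure(list(P = P, Pt = Pt, N = N, G = G, width = w, beta = beta,
                 apod2 = apod2, M = M,
                 pad_idx = (G / 2 - N / 2 + 1):(G / 2 + N / 2)),
            class = "nufft_plan")
}

#' @export
print.nufft_plan <- function(x, ...) {
  cat(sprintf("<nufft_plan> %d samples, image %dx%d, grid %dx%d, width %d\n",
              x$M, x$N, x$N, x$G, x$G, x$width))
  invisible(x)
}

# oversampled centred DFT of a deapodized, zero-padded image -> G^2 vector
grid_fwd <- function(plan, img) {
  Cpad <- matrix(0i, plan$G, plan$G)
  Cpad[plan$pad_idx, plan$pad_idx] <- img / plan$apod2
  as.vector(fftshift2(stats::fft(ifftshift2(Cpad))))
}

# exact adjoint of grid_fwd
grid_adj <- function(plan, vecG2) {
  C <- matrix(vecG2, plan$G, plan$G)
  xf <- fftshift2(stats::fft(ifftshift2(C), inverse = TRUE))
  xf[plan$pad_idx, plan$pad_idx] / plan$apod2
}

#' Apply a NUFFT plan
#'
#' @param plan a [nufft_plan()].
#' @param img complex N x N image.
#' @return complex vector of M samples.
#' @export
nufft_forward <- function(plan, img) {
  stopifnot(all(dim(img) == plan$N))
  drop(sp_cmult(plan$P, grid_fwd(plan, img)))
}

#' @rdname nufft_forward
#' @param y complex vector of M samples.
#' @return complex N x N image (exact adjoint of [nufft_forward()]).
#' @export
nufft_adjoint <- function(plan, y) {
  stopifnot(length(y) == plan$M)
  grid_adj(plan, drop(sp_cmult(plan$Pt, y)))
}
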