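# Centred unitary FFT helpers.  All k-space grids in the package put DC at
# index N/2 + 1 (even N), matching frequency nu = (i - 1 - N/2)/N in
# cycles/sample.

fftshift2 <- function(x) {
  d <- dim(x)
  x[c((d[1] / 2 + 1):d[1], 1:(d[1] / 2)), c((d[2] / 2 + 1):d[2], 1:(d[2] / 2))]
}

ifftshift2 <- fftshift2  # even sizes only: shift is its own inverse

#' Centred unitary 2D FFT
#'
#' Forward transform with DC at the centre of the grid and 1/sqrt(N)
#' normalisation in both directions, so the transform is unitary.
#'
#' @param x complex matrix with even dimensions.
#' @return complex matrix of the same shape.
#' @keywords internal
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

#' @rdname fft2c
#' @keywords internal
ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

# complex inner product <a, b> = sum(conj(a) * b)
cdot <- function(a, b) sum(Conj(a) * b)

l2 <- function(x) sqrt(sum(Mod(x)^2))

rel_err <- function(x, ref) l2(x - ref) / l2(ref)

# real sparse matrix applied to a complex dense matrix / vector
sp_cmult <- function(P, M) {
  M <- as.matrix(M)
  as.matrix(P %*% Re(M)) + 1i * as.matrix(P %*% Im(M))
}

stopifnot_even <- function(n, what) {
  if (n %% 2 != 0) stop(what, " must be even, got ", n, call. = FALSE)
}
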