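# Multi-coil encoding operators E = A F S (Cartesian) and E = A Ur F S
# (radial with temporal subspace).  Each constructor returns a closure-based
# operator with exact forward/adjoint pairing, the contract every solver in
# the package relies on.

#' Multi-coil Cartesian encoding operator
#'
#' Forward model `y[.,l,c] = mask_l .* FFT(S_c .* X_l)` with the centred
#' unitary FFT; the adjoint is `X_l = sum_c conj(S_c) .* IFFT(mask_l .* y)`.
#' K-space is stored on the full grid with zeros at unsampled locations.
#'
#' @param sens complex Mx x My x Nc coil sensitivity array.
#' @param masks 0/1 array Mx x My x L, one undersampling mask per contrast.
#' @return an `encoding_operator` with elements `forward(X)`, `adjoint(Y)`,
#'   `img_dim`, `mode`.
#' @export
cartesian_operator <- function(sens, masks) {
  sens <- as.array(sens); masks <- as.array(masks)
  if (length(dim(sens)) == 2L) dim(sens) <- c(dim(sens), 1L)
  if (length(dim(masks)) == 2L) dim(masks) <- c(dim(masks), 1L)
  if (!all(dim(sens)[1:2] == dim(masks)[1:2]))
    stop("sensitivities and masks disagree on matrix size", call. = FALSE)
  if (!all(masks %in% c(0, 1)))
    stop("masks must be binary", call. = FALSE)
  Nc <- dim(sens)[3]; L <- dim(masks)[3]
  Mx <- dim(sens)[1]; My <- dim(sens)[2]
  masks <- masks != 0

  forward <- function(X) {
    X <- as.array(X)
    if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
    if (!all(dim(X) == c(Mx, My, L)))
      stop("image has wrong dimensions for this operator", call. = FALSE)
    Y <- array(0i, c(Mx, My, L, Nc))
    for (l in seq_len(L)) {
      ml <- masks[, , l]
      for (cc in seq_len(Nc)) {
        k <- fft2c(sens[, , cc] * X[, , l])
        k[!ml] <- 0i
        Y[, , l, cc] <- k
      }
    }
    Y
  }
  adjoint <- function(Y) {
    Y <- as.array(Y)
    if (!all(dim(Y) == c(Mx, My, L, Nc)))
      stop("k-space has wrong dimensions for this operator", call. = FALSE)
    X <- array(0i, c(Mx, My, L))
    for (l in seq_len(L)) {
      ml <- masks[, , l]
      acc <- matrix(0i, Mx, My)
      for (cc in seq_len(Nc)) {
        k <- Y[, , l, cc]
        k[!ml] <- 0i
        acc <- acc + Conj(sens[, , cc]) * ifft2c(k)
      }
      X[, , l] <- acc
    }
    X
  }
  structure(list(forward = forward, adjoint = adjoint,
                 img_dim = c(Mx, My, L), mode = "cartesian",
                 sens = sens, masks = masks),
            class = "encoding_operator")
}

#' Radial subspace encoding operator
#'
#' Forward model for temporally compressed fingerprinting data: the sample at
#' time point `t`, coil `c`, location `k` is
#' `y = sum_j Ur[t, j] * NUFFT(S_c .* X_j)(k)` where `X_j` are the r subspace
#' coefficient images.  The adjoint applies `conj(Ur)` weights, the NUFFT
#' adjoint, and coil combination, and is the exact adjoint of the forward.
#'
#' @param sens complex Mx x My x Nc coil sensitivities.
#' @param traj radial sampling description: list with `coords` (Z x 2,
#'   cycles/sample), `time_of_sample` (Z, 1-based time point per sample) and
#'   `n_timepoints`; see [golden_angle_trajectory()].
#' @param basis subspace basis: list with complex matrix `Ur`
#'   (n_timepoints x r, orthonormal columns); see [compress_dictionary()].
#' @param plan optional pre-built [nufft_plan()] for `traj$coords`.
#' @return an `encoding_operator` with `forward(X)` mapping Mx x My x r to
#'   Z x Nc samples, `adjoint(Y)`, and `dc_adjoint(Y)` (ramp-weighted adjoint
#'   used only for initialization).
#' @export
radial_subspace_operator <- function(sens, traj, basis, plan = NULL) {
  sens <- as.array(sens)
  if (length(dim(sens)) == 2L) dim(sens) <- c(dim(sens), 1L)
  Mx <- dim(sens)[1]; Nc <- dim(sens)[3]
  stopifnot(Mx == dim(sens)[2])
  Ur <- as.matrix(basis$Ur)
  r <- ncol(Ur)
  if (nrow(Ur) != traj$n_timepoints)
    stop("basis rows must equal the number of acquisition time points",
         call. = FALSE)
  ortho <- Conj(t(Ur)) %*% Ur
  if (max(Mod(ortho - diag(r))) > 1e-10)
    stop("subspace basis columns are not orthonormal", call. = FALSE)
  if (is.null(plan)) plan <- nufft_plan(traj$coords, Mx)
  Z <- plan$M
  Urow <- Ur[traj$time_of_sample, , drop = FALSE]   # Z x r

  forward <- function(X) {
    X <- as.array(X)
    if (!all(dim(X) == c(Mx, Mx, r)))
      stop("subspace image stack has wrong dimensions", call. = FALSE)
    Cmat <- matrix(0i, plan$G^2, r * Nc)
    for (cc in seq_len(Nc)) {
      for (j in seq_len(r)) {
        Cmat[, (cc - 1L) * r + j] <- grid_fwd(plan, sens[, , cc] * X[, , j])
      }
    }
    S <- sp_cmult(plan$P, Cmat)                      # Z x (r * Nc)
    Y <- matrix(0i, Z, Nc)
    for (cc in seq_len(Nc)) {
      block <- S[, (cc - 1L) * r + seq_len(r), drop = FALSE]
      Y[, cc] <- rowSums(Urow * block)
    }
    Y
  }

  adjoint_weighted <- function(Y, wt = NULL) {
    Y <- as.matrix(Y)
    if (nrow(Y) != Z || ncol(Y) != Nc)
      stop("sample matrix has wrong dimensions", call. = FALSE)
    if (!is.null(wt)) Y <- Y * wt
    V <- matrix(0i, Z, r * Nc)
    for (cc in seq_len(Nc)) {
      for (j in seq_len(r)) {
        V[, (cc - 1L) * r + j] <- Conj(Urow[, j]) * Y[, cc]
      }
    }
    W <- sp_cmult(plan$Pt, V)                        # G^2 x (r * Nc)
    X <- array(0i, c(Mx, Mx, r))
    for (j in seq_len(r)) {
      acc <- matrix(0i, Mx, Mx)
      for (cc in seq_len(Nc)) {
        acc <- acc + Conj(sens[, , cc]) * grid_adj(plan, W[, (cc - 1L) * r + j])
      }
      X[, , j] <- acc
    }
    X
  }

  dcw <- radial_density_weights(traj)
  structure(list(
    forward = forward,
    adjoint = function(Y) adjoint_weighted(Y),
    dc_adjoint = function(Y) Mx * Mx * adjoint_weighted(Y, wt = dcw),
    img_dim = c(Mx, Mx, r), mode = "radial", plan = plan,
    sens = sens, traj = traj, basis = basis),
    class = "encoding_operator")
}

#' Ramp density-compensation weights for radial sampling
#'
#' Weight proportional to `|k|` (the local sample-density reciprocal of a
#' radial pattern) with a finite floor at DC, scaled by the angular and
#' readout increments so the weighted adjoint approximates the inverse on
#' well-sampled data.  Used only to initialize iterative solvers, never
#' inside the adjoint-consistent operator pair.
#'
#' @param traj radial sampling description (see [golden_angle_trajectory()]).
#' @return numeric weight per sample.
#' @export
radial_density_weights <- function(traj) {
  kr <- sqrt(rowSums(traj$coords^2))
  dnu <- 1 / traj$samples_per_spoke
  dth <- pi / length(unique(round(traj$spoke_angle_deg %% 180, 8)))
  pmax(kr, dnu / 4) * dth * dnu
}

#' Randomized adjointness check
#'
#' Draws random complex `X`, `Y` and returns
#' `|<EX, Y> - <X, E^H Y>| / (||EX|| ||Y||)`.
#'
#' @param op an `encoding_operator`.
#' @param ydraw function returning a random element of the data space.
#' @return nonnegative scalar.
#' @export
adjointness_gap <- function(op, ydraw = NULL) {
  X <- array(complex(real = rnorm(prod(op$img_dim)),
                     imaginary = rnorm(prod(op$img_dim))), op$img_dim)
  EX <- op$forward(X)
  if (is.null(ydraw)) {
    Y <- array(complex(real = rnorm(length(EX)),
                       imaginary = rnorm(length(EX))), dim(EX))
  } else Y <- ydraw()
  Mod(cdot(EX, Y) - cdot(X, op$adjoint(Y))) / (l2(EX) * l2(Y))
}
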