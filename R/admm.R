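# ADMM outer loop: alternate (1) a CG-SENSE + Tikhonov data-consistency
# solve, (2) the patch-tensor denoiser, (3) the dual ascent step
# b <- b + mu (X - T), in unscaled dual form.

#' Regularized data-consistency solve
#'
#' Approximately solves `(E^H E + mu I) X = E^H Y + mu T - b` (the normal
#' equations of the SENSE + Tikhonov sub-problem) by conjugate gradient,
#' stopping when the relative residual drops below `cg_eps` or after
#' `cg_iters` iterations.
#'
#' @param Y k-space data in the operator's data space.
#' @param op an `encoding_operator`.
#' @param T_prior prior image (same shape as the solution); `NULL` means 0.
#' @param b dual variable (image-shaped); `NULL` means 0.
#' @param mu nonnegative Tikhonov/ADMM weight.
#' @param cg_eps relative residual tolerance.
#' @param cg_iters maximum CG iterations.
#' @param x0 warm-start image; `NULL` starts from zero.
#' @return image-shaped solution with attribute `"cg_relres"`.
#' @export
solve_data_consistency <- function(Y, op, T_prior = NULL, b = NULL, mu = 0,
                                   cg_eps = 1e-6, cg_iters = 15L, x0 = NULL) {
  dimX <- op$img_dim
  zero <- array(0i, dimX)
  if (is.null(T_prior)) T_prior <- zero
  if (is.null(b)) b <- zero
  rhs <- op$adjoint(Y) + mu * T_prior - b
  normal <- function(X) op$adjoint(op$forward(X)) + mu * X
  x <- if (is.null(x0)) zero else x0
  r <- rhs - normal(x)
  p <- r
  rs <- Re(cdot(r, r))
  bnorm <- l2(rhs)
  if (bnorm == 0) return(structure(zero, cg_relres = 0))
  for (it in seq_len(cg_iters)) {
    if (sqrt(rs) / bnorm < cg_eps) break
    Ap <- normal(p)
    alpha <- rs / Re(cdot(p, Ap))
    if (!is.finite(alpha))
      stop("CG breakdown (non-finite step) at iteration ", it, call. = FALSE)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- Re(cdot(r, r))
    if (!is.finite(rs_new))
      stop("CG residual became non-finite at iteration ", it, call. = FALSE)
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  structure(x, cg_relres = sqrt(rs) / bnorm)
}

#' Dual ascent step
#'
#' @param b dual variable.
#' @param X current data-consistent image.
#' @param T_prior current denoised image.
#' @param mu ADMM penalty.
#' @return updated dual `b + mu * (X - T_prior)`.
#' @export
update_dual <- function(b, X, T_prior, mu) {
  stopifnot(all(dim(b) == dim(X)), all(dim(X) == dim(T_prior)))
  b + mu * (X - T_prior)
}

# Shared ADMM driver: hd_prost_recon and llr_recon differ only in `denoiser`,
# a function(W, iter) -> denoised image.
admm_recon <- function(Y, op, cfg, denoiser, verbose = FALSE) {
  validate_recon_config(cfg)
  mu <- cfg$mu
  X <- if (op$mode == "radial") op$dc_adjoint(Y) else op$adjoint(Y)
  T_prior <- X
  b <- array(0i, op$img_dim)
  ynorm <- l2(Y)
  diag_df <- data.frame(iter = integer(0), data_res = numeric(0),
                        cons_res = numeric(0), elapsed_s = numeric(0))
  prev_res <- Inf
  for (it in seq_len(cfg$admm_iters)) {
    t0 <- proc.time()[["elapsed"]]
    X <- solve_data_consistency(Y, op, T_prior, b, mu,
                                cg_eps = cfg$cg_eps, cg_iters = cfg$cg_iters,
                                x0 = X)
    T_prior <- denoiser(X + b / mu, it)
    b <- update_dual(b, X, T_prior, mu)
    data_res <- l2(op$forward(X) - Y) / ynorm
    cons_res <- l2(X - T_prior) / l2(X)
    el <- proc.time()[["elapsed"]] - t0
    diag_df[it, ] <- list(it, data_res, cons_res, el)
    if (verbose)
      message(sprintf("admm %d/%d  data %.4g  ||X-T||/||X|| %.4g  %.1fs",
                      it, cfg$admm_iters, data_res, cons_res, el))
    if (data_res > prev_res && it > 1)
      warning(sprintf("data residual increased at ADMM iteration %d", it))
    prev_res <- data_res
  }
  structure(X, admm_diag = diag_df)
}

#' HD-PROST reconstruction
#'
#' Joint multi-contrast reconstruction alternating the CG-SENSE data
#' consistency solve with block-matched patch-tensor HOSVD denoising inside
#' an ADMM loop.  Initialization is the (density-compensated, for radial)
#' adjoint image for both `X` and the prior `T`; the dual starts at zero.
#' The denoiser threshold is `tau = 2 * lambda / mu`.
#'
#' @param Y k-space data matching `op`'s data space.
#' @param op an `encoding_operator`.
#' @param cfg a [recon_config()].  A `NULL` `cfg$lambda` on the radial path
#'   is derived with [mrf_lambda()] from the number of time points.
#' @param verbose log one line per ADMM iteration.
#' @return complex image stack with attribute `"admm_diag"` (per-iteration
#'   data and constraint residuals).
#' @export
hd_prost_recon <- function(Y, op, cfg, verbose = FALSE) {
  lambda <- cfg$lambda
  if (is.null(lambda)) {
    if (op$mode != "radial")
      stop("lambda must be set for the Cartesian mode", call. = FALSE)
    lambda <- as.numeric(mrf_lambda(op$traj$n_timepoints))
    if (verbose)
      message(sprintf("lambda rule: raw %.4g, floored %.4g",
                      attr(mrf_lambda(op$traj$n_timepoints), "raw"), lambda))
  }
  dp <- denoise_params(cfg$patch_edge, cfg$K, cfg$search_radius,
                       cfg$patch_offset, tau = 2 * lambda / cfg$mu)
  admm_recon(Y, op, cfg, function(W, it) denoise_multicontrast(W, dp),
             verbose = verbose)
}
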