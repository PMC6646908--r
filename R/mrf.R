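# Magnetic resonance fingerprinting: EPG signal simulation with slice-profile
# correction, dictionary construction and temporal compression, and
# inner-product parameter matching.

#' MRF sequence description
#'
#' A gradient-dephased (unbalanced) RF train with fixed TR/TE, optional
#' initial adiabatic inversion, and per-pulse RF phase (0/180 degree
#' alternation by default).
#'
#' @param fa_deg flip angle train, degrees (one entry per time point).
#' @param tr_ms repetition time, ms.
#' @param te_ms echo time, ms (must be < `tr_ms`).
#' @param invert apply a perfect 180 inversion before the first pulse.
#' @param rf_phase_deg per-pulse RF phase, degrees; default alternates 0/180.
#' @return `sequence_params` list.
#' @export
sequence_params <- function(fa_deg, tr_ms = 4.4, te_ms = 2, invert = TRUE,
                            rf_phase_deg = NULL) {
  fa_deg <- as.numeric(fa_deg)
  n <- length(fa_deg)
  stopifnot(n >= 1, all(fa_deg >= 0), all(fa_deg <= 180), te_ms < tr_ms,
            te_ms > 0)
  if (is.null(rf_phase_deg)) rf_phase_deg <- rep(c(0, 180), length.out = n)
  stopifnot(length(rf_phase_deg) == n)
  structure(list(fa_deg = fa_deg, tr_ms = tr_ms, te_ms = te_ms,
                 invert = isTRUE(invert),
                 rf_phase_deg = as.numeric(rf_phase_deg), n = n),
            class = "sequence_params")
}

#' Default variable flip-angle train
#'
#' Smooth repeating lobes, `fa(i) = peak * |sin(pi * i / period)|`, played
#' after one inversion: a compact stand-in with the repetitive-loop structure
#' of optimized fingerprinting trains.  Any train can be substituted via a
#' one-value-per-line CSV (degrees) with [read_flip_train()].
#'
#' @param n train length.
#' @param peak_deg lobe peak flip angle, degrees.
#' @param period_tp lobe period in time points.
#' @return numeric vector of flip angles, degrees.
#' @export
default_flip_train <- function(n, peak_deg = 70, period_tp = 250) {
  peak_deg * abs(sin(pi * seq_len(n) / period_tp))
}

#' @rdname default_flip_train
#' @param path CSV path, one flip angle (degrees) per line, no header.
#' @export
read_flip_train <- function(path) {
  v <- scan(path, what = numeric(), quiet = TRUE, sep = ",")
  if (any(v < 0 | v > 180)) stop("flip angles outside [0, 180]", call. = FALSE)
  v
}

#' @rdname default_flip_train
#' @param fa_deg flip angle train to write.
#' @export
write_flip_train <- function(fa_deg, path) {
  writeLines(format(fa_deg, digits = 12, trim = TRUE), path)
  invisible(path)
}

#' EPG signal simulation
#'
#' Evolves the configuration states (F+, F-, Z) of a gradient-dephased RF
#' train: optional inversion (Z0 -> -Z0), then per TR an RF rotation by
#' (flip angle, phase), readout of the transverse F0 state at TE (with T2
#' decay over TE), relaxation and recovery over the full TR, and a unit
#' gradient dephasing shift.  Dephasing orders are truncated at
#' `min(n, kmax)`.
#'
#' @param t1_ms,t2_ms relaxation times, ms (scalars or equal-length vectors;
#'   vectors are simulated in one vectorised pass).
#' @param seq a [sequence_params()].
#' @param kmax maximum dephasing order retained.
#' @return complex signal: a vector of length `n` for scalar (t1, t2), else
#'   an `n x length(t1_ms)` matrix.
#' @export
epg_simulate <- function(t1_ms, t2_ms, seq, kmax = 64L) {
  stopifnot(inherits(seq, "sequence_params"))
  if (any(t1_ms <= 0) || any(t2_ms <= 0))
    stop("relaxation times must be positive", call. = FALSE)
  sig <- .epg_sim_batch(seq$fa_deg, seq$rf_phase_deg, seq$tr_ms, seq$te_ms,
                        as.numeric(t1_ms), as.numeric(t2_ms), seq$invert,
                        as.integer(kmax))
  if (length(t1_ms) == 1L) drop(sig) else sig
}

#' Excitation slice profile
#'
#' Small-tip-angle profile of a Hann-windowed 3-lobe sinc pulse: the Fourier
#' transform of the RF envelope, normalized to 1 at slice centre, evaluated
#' at `n_iso` positions uniformly across the nominal slice (the band between
#' the profile's nominal edges).
#'
#' @param n_iso number of isochromats (odd keeps one at slice centre).
#' @return numeric vector of `n_iso` relative flip-angle scales in (0, 1].
#' @export
slice_profile <- function(n_iso = 51L) {
  stopifnot(n_iso >= 1)
  tau <- seq(-1.5, 1.5, length.out = 4001L)
  b <- ifelse(tau == 0, 1, sin(pi * tau) / (pi * tau)) *
    (0.5 + 0.5 * cos(pi * tau / 1.5))
  z <- if (n_iso == 1L) 0 else seq(-0.5, 0.5, length.out = n_iso)
  prof <- vapply(z, function(f) sum(b * cos(2 * pi * f * tau)), numeric(1))
  prof / sum(b)
}

#' Slice-profile-corrected EPG signal
#'
#' Mean over isochromats of [epg_simulate()] with the flip angles scaled by
#' the slice profile, emulating the through-slice flip-angle variation of a
#' 2D excitation.
#'
#' @inheritParams epg_simulate
#' @param n_iso number of isochromats across the slice.
#' @param profile optional explicit vector of flip-angle scales (overrides
#'   `n_iso`); `rep(1, n)` reproduces the ideal-profile signal exactly.
#' @return as [epg_simulate()].
#' @export
slice_profile_correct <- function(t1_ms, t2_ms, seq, n_iso = 51L,
                                  profile = NULL, kmax = 64L) {
  p <- if (is.null(profile)) slice_profile(n_iso) else profile
  acc <- 0
  for (pi_ in p) {
    si <- sequence_params(seq$fa_deg * pi_, seq$tr_ms, seq$te_ms, seq$invert,
                          seq$rf_phase_deg)
    acc <- acc + epg_simulate(t1_ms, t2_ms, si, kmax = kmax)
  }
  acc / length(p)
}

#' Published dictionary grids
#'
#' The piecewise T1 and T2 ranges of the original fingerprinting dictionary
#' (152 T1 values, 77 T2 values; 11704 atoms over the full product grid).
#'
#' @return numeric vector of grid values, ms.
#' @export
dictionary_t1_grid <- function() {
  c(seq(50, 1400, by = 10), seq(1430, 1600, by = 30),
    seq(1700, 2200, by = 100), seq(2400, 3000, by = 200))
}

#' @rdname dictionary_t1_grid
#' @export
dictionary_t2_grid <- function() {
  c(seq(5, 80, by = 2), seq(85, 150, by = 5),
    seq(160, 300, by = 10), seq(330, 600, by = 30))
}

#' Build an MRF dictionary
#'
#' Simulates one fingerprint per (T1, T2) pair of the full Cartesian product
#' grid (pairs with T2 > T1 are retained; duplicates are kept verbatim) and
#' stores unit-L2-normalized atoms together with the pre-normalization
#' scales.
#'
#' @param t1_grid_ms,t2_grid_ms grid values, ms.
#' @param seq a [sequence_params()].
#' @param slice_correct apply [slice_profile_correct()] per atom.
#' @param n_iso isochromats for the slice correction.
#' @param kmax maximum EPG dephasing order.
#' @return `mrf_dictionary`: list with `atoms` (n x D unit columns), `norms`,
#'   per-atom `t1_ms`/`t2_ms`, the grids, `seq`, and (after
#'   [compress_dictionary()]) `basis` and `atoms_compressed`.
#' @export
build_dictionary <- function(t1_grid_ms, t2_grid_ms, seq,
                             slice_correct = TRUE, n_iso = 51L, kmax = 64L) {
  stopifnot(length(t1_grid_ms) >= 1, length(t2_grid_ms) >= 1)
  grid <- expand.grid(t1 = t1_grid_ms, t2 = t2_grid_ms,
                      KEEP.OUT.ATTRS = FALSE)
  atoms <- if (slice_correct) {
    slice_profile_correct(grid$t1, grid$t2, seq, n_iso = n_iso, kmax = kmax)
  } else {
    epg_simulate(grid$t1, grid$t2, seq, kmax = kmax)
  }
  atoms <- matrix(atoms, nrow = seq$n)
  norms <- sqrt(colSums(Mod(atoms)^2))
  if (any(norms == 0)) stop("zero-energy atom in dictionary", call. = FALSE)
  atoms <- sweep(atoms, 2, norms, "/")
  structure(list(atoms = atoms, norms = norms,
                 t1_ms = grid$t1, t2_ms = grid$t2,
                 t1_grid_ms = t1_grid_ms, t2_grid_ms = t2_grid_ms,
                 seq = seq, basis = NULL, atoms_compressed = NULL),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat(sprintf("<mrf_dictionary> %d atoms (%d T1 x %d T2), train length %d%s\n",
              ncol(x$atoms), length(x$t1_grid_ms), length(x$t2_grid_ms),
              nrow(x$atoms),
              if (!is.null(x$basis)) sprintf(", compressed r=%d",
                                             ncol(x$basis$Ur)) else ""))
  invisible(x)
}

#' Temporal compression of a dictionary
#'
#' `Ur` holds the first `r` left singular vectors of the atom matrix; the
#' compressed atoms are `Ur^H atoms`.  If the atom matrix has numerical rank
#' below `r` the achievable rank is used with a warning.
#'
#' @param dict an [build_dictionary()] result.
#' @param r subspace rank.
#' @return the dictionary with `basis` (list `Ur`, `r`, `sv`) and
#'   `atoms_compressed` (r x D) filled in.
#' @export
compress_dictionary <- function(dict, r) {
  n <- nrow(dict$atoms)
  stopifnot(r >= 1, r <= n)
  s <- svd(dict$atoms, nu = n, nv = 0)
  rank_eff <- sum(s$d > s$d[1] * 1e-12)
  if (rank_eff < r) {
    warning(sprintf("atom matrix rank %d < requested r=%d; using %d",
                    rank_eff, r, rank_eff))
    r <- rank_eff
  }
  Ur <- s$u[, seq_len(r), drop = FALSE]
  dict$basis <- list(Ur = Ur, r = r, sv = s$d)
  dict$atoms_compressed <- Conj(t(Ur)) %*% dict$atoms
  dict
}

#' Inner-product fingerprint matching
#'
#' Per voxel, selects `j* = argmax_j |<atom_j, x>|` and reads T1/T2 off the
#' grid; the proton-density scale is `m0 = <atom_j*, x> / norm_j*` (complex,
#' relative to the raw un-normalized fingerprint; the raw coefficient
#' `<atom_j*, x>` is returned as `m0_coeff`).  Signals of dimension r are
#' matched against the compressed atoms, full-length signals against the raw
#' atoms.
#'
#' @param signals complex `Mx x My x dim` array or `V x dim` matrix of voxel
#'   signals.
#' @param dict an `mrf_dictionary` (compressed if `dim == r`).
#' @param mask optional logical `Mx x My` (or length-V) mask; voxels outside
#'   are left `NA`.
#' @param chunk voxels per matching block (memory control).
#' @return `parameter_maps`: list with `t1_ms`, `t2_ms`, `m0`, `m0_coeff`,
#'   `match_index`, `mask`, `zero_signal`, each shaped like the voxel grid.
#' @export
match_fingerprints <- function(signals, dict, mask = NULL, chunk = 2048L) {
  arr <- is.array(signals) && length(dim(signals)) == 3L
  if (arr) {
    d <- dim(signals)
    Xv <- matrix(signals, d[1] * d[2], d[3])
    grid_dim <- d[1:2]
  } else {
    Xv <- as.matrix(signals)
    grid_dim <- NULL
  }
  p <- ncol(Xv)
  A <- if (!is.null(dict$atoms_compressed) &&
           p == nrow(dict$atoms_compressed)) {
    dict$atoms_compressed
  } else if (p == nrow(dict$atoms)) {
    dict$atoms
  } else {
    stop("signal dimension matches neither raw nor compressed atoms",
         call. = FALSE)
  }
  V <- nrow(Xv)
  if (is.null(mask)) mask <- rep(TRUE, V)
  mask <- as.logical(mask)
  stopifnot(length(mask) == V)
  idx <- rep(NA_integer_, V)
  coeff <- rep(NA_complex_, V)
  Ah <- Conj(t(A))                                    # D x p
  vsel <- which(mask)
  for (st in seq(1, length(vsel), by = chunk)) {
    vv <- vsel[st:min(st + chunk - 1L, length(vsel))]
    Mblk <- Ah %*% t(Xv[vv, , drop = FALSE])          # D x |vv|
    am <- Mod(Mblk)
    j <- max.col(t(am), ties.method = "first")
    idx[vv] <- j
    coeff[vv] <- Mblk[cbind(j, seq_along(vv))]
  }
  zero <- mask & rowSums(Mod(Xv)^2) == 0
  idx[zero] <- NA_integer_
  coeff[zero] <- 0i
  shape <- function(v) if (is.null(grid_dim)) v else array(v, grid_dim)
  structure(list(
    t1_ms = shape(dict$t1_ms[idx]),
    t2_ms = shape(dict$t2_ms[idx]),
    m0 = shape(ifelse(is.na(idx), coeff, coeff / dict$norms[idx])),
    m0_coeff = shape(coeff),
    match_index = shape(idx),
    mask = shape(mask),
    zero_signal = shape(zero)), class = "parameter_maps")
}
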