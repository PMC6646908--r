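# Synthetic fixtures: digital T1/T2 vial phantom, smooth coil maps,
# golden-angle radial trajectories, variable-density Cartesian masks, and
# noisy multi-coil k-space for both applications.  Every generator is a pure
# function of (parameters, seed).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

crandn <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))

norm_grid <- function(N) {
  v <- (seq_len(N) - 1 - N / 2) / N       # [-0.5, 0.5)
  list(x = outer(v, rep(1, N)), y = outer(rep(1, N), v))
}

#' Digital T1/T2 vial phantom
#'
#' Nine (by default) disjoint circular vials on a ring plus one at the centre
#' of a background disc, emulating a standardized relaxometry phantom: vial
#' T1 log-spaced over 255-1489 ms and T2 log-spaced over 44-243 ms, paired by
#' sorted index; background T1 = 300 ms, T2 = 50 ms.  Proton density is 1
#' inside the support with a smooth phase.
#'
#' @param matrix_size image side N (>= 32, even).
#' @param n_vials number of vials (at most 9 fit the default layout).
#' @param seed recorded with the phantom (the geometry is deterministic).
#' @return `digital_phantom`: list of `t1_ms`, `t2_ms`, `m0` (complex),
#'   `label` (0 = air, 1 = background, 2.. = vials), `vial_t1_ms`,
#'   `vial_t2_ms`, `vial_centers`, `vial_radius`, `support`.
#' @export
make_vial_phantom <- function(matrix_size, n_vials = 9L, seed = 1L) {
  N <- as.integer(matrix_size)
  stopifnot(N >= 32)
  stopifnot_even(N, "matrix_size")
  g <- norm_grid(N)
  bg_r <- 0.45; vial_r <- 0.085; ring_r <- 0.28
  if (n_vials > 9) stop("default layout holds at most 9 vials", call. = FALSE)
  centers <- if (n_vials == 1) {
    cbind(0, 0)
  } else {
    th <- 2 * pi * (seq_len(n_vials - 1) - 1) / (n_vials - 1)
    rbind(cbind(ring_r * cos(th), ring_r * sin(th)), c(0, 0))
  }
  if (n_vials > 2) {
    dmin <- min(dist(centers))
    if (dmin <= 2 * vial_r) stop("vials cannot be placed disjointly",
                                 call. = FALSE)
  }
  t1v <- exp(seq(log(255), log(1489), length.out = n_vials))
  t2v <- exp(seq(log(44), log(243), length.out = n_vials))
  support <- (g$x^2 + g$y^2) <= bg_r^2
  label <- matrix(0L, N, N)
  label[support] <- 1L
  for (v in seq_len(n_vials)) {
    inv <- ((g$x - centers[v, 1])^2 + (g$y - centers[v, 2])^2) <= vial_r^2
    label[inv] <- v + 1L
  }
  t1 <- matrix(0, N, N); t2 <- matrix(0, N, N)
  t1[label == 1L] <- 300; t2[label == 1L] <- 50
  for (v in seq_len(n_vials)) {
    t1[label == v + 1L] <- t1v[v]
    t2[label == v + 1L] <- t2v[v]
  }
  phase <- 2 * pi * (0.08 * g$x + 0.05 * g$y + 0.15 * (g$x^2 + g$y^2))
  m0 <- ifelse(support, 1, 0) * exp(1i * phase)
  structure(list(t1_ms = t1, t2_ms = t2, m0 = m0, label = label,
                 vial_t1_ms = t1v, vial_t2_ms = t2v, vial_centers = centers,
                 vial_radius = vial_r, support = support,
                 matrix_size = N, seed = as.integer(seed)),
            class = "digital_phantom")
}

#' Smooth synthetic coil sensitivity maps
#'
#' Gaussian sensitivity lobes centred at `Nc` points around the field of
#' view, each with a mild linear phase ramp, normalized so the
#' root-sum-of-squares is exactly 1 everywhere.  `Nc = 1` returns the unit
#' map.
#'
#' @param matrix_size image side N.
#' @param Nc number of coils.
#' @param seed jitters lobe placement and phase slopes.
#' @return complex N x N x Nc array.
#' @export
simulate_coils <- function(matrix_size, Nc, seed = 1L) {
  N <- as.integer(matrix_size)
  stopifnot(Nc >= 1)
  if (Nc == 1L) return(array(1 + 0i, c(N, N, 1L)))
  g <- norm_grid(N)
  S <- array(0i, c(N, N, Nc))
  with_seed(seed, {
    th0 <- runif(1, 0, 2 * pi)
    for (cc in seq_len(Nc)) {
      th <- th0 + 2 * pi * (cc - 1) / Nc + rnorm(1, 0, 0.05)
      cx <- 0.55 * cos(th); cy <- 0.55 * sin(th)
      mag <- exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * 0.35^2))
      slope <- rnorm(2, 0, 0.8)
      S[, , cc] <- mag * exp(2i * pi * (slope[1] * g$x + slope[2] * g$y))
    }
  })
  rss <- sqrt(apply(Mod(S)^2, c(1, 2), sum))
  S / array(rss, dim(S))
}

#' Spoke count for a fully sampled radial acquisition
#'
#' Nyquist criterion for radial sampling of an N x N matrix:
#' `round(pi/2 * N)` uniformly spaced spokes.
#'
#' @param matrix_size image side N.
#' @return integer spoke count.
#' @export
nyquist_spoke_count <- function(matrix_size) as.integer(round(pi / 2 * matrix_size))

#' Golden-angle radial trajectory
#'
#' Spoke `i` lies at angle `(i - 1) * 111.246` degrees; each spoke is a
#' diameter through DC with `samples_per_spoke` uniform samples spanning
#' `[-0.5, 0.5)` cycles/sample (readout oversampling 2 when
#' `samples_per_spoke = 2 * matrix_size`), and every time point owns
#' `spokes_per_tp` consecutive spokes.
#'
#' @param n_timepoints number of acquisition time points.
#' @param spokes_per_tp spokes per time point (1 for fingerprinting).
#' @param samples_per_spoke even sample count per spoke; default
#'   `2 * matrix_size`.
#' @param matrix_size image side N.
#' @return `radial_sampling`: list with `coords` (Z x 2), `spoke_of_sample`,
#'   `time_of_sample`, `spoke_angle_deg`, `n_timepoints`,
#'   `samples_per_spoke`, `matrix_size`.
#' @export
golden_angle_trajectory <- function(n_timepoints, spokes_per_tp = 1L,
                                    samples_per_spoke = NULL, matrix_size) {
  if (is.null(samples_per_spoke)) samples_per_spoke <- 2L * matrix_size
  ns <- as.integer(samples_per_spoke)
  stopifnot_even(ns, "samples_per_spoke")
  n_spokes <- n_timepoints * spokes_per_tp
  ang <- (seq_len(n_spokes) - 1) * 111.246
  kr <- (seq_len(ns) - 1 - ns / 2) / ns            # [-0.5, 0.5), DC included
  coords <- cbind(as.vector(outer(kr, cospi(ang / 180))),
                  as.vector(outer(kr, sinpi(ang / 180))))
  spoke <- rep(seq_len(n_spokes), each = ns)
  structure(list(coords = coords, spoke_of_sample = spoke,
                 time_of_sample = ((spoke - 1L) %/% spokes_per_tp) + 1L,
                 spoke_angle_deg = ang, n_timepoints = n_timepoints,
                 samples_per_spoke = ns, matrix_size = as.integer(matrix_size),
                 type = "radial"), class = "radial_sampling")
}

#' Variable-density Cartesian masks with golden-ratio shifts
#'
#' Per contrast: a fully sampled centre disc plus points drawn from
#' variable-density spiral arms on the Cartesian phase-encode grid (radial
#' density ~ 1/r via log-uniform radius placement), successive arms rotated
#' by the golden ratio and every contrast carrying a global golden-angle
#' offset, so the masks differ across contrasts.  Arms are added until the
#' sampled fraction reaches `1/target_accel`; the achieved acceleration must
#' land within 5% of the target.
#'
#' @param matrix_size phase-encode grid side N.
#' @param L number of contrasts.
#' @param target_accel target acceleration (total/sampled points).
#' @param center_fraction fully sampled disc radius as a fraction of the
#'   grid radius.
#' @param seed seeds the arm angle jitter.
#' @return `cartesian_sampling`: list with binary `masks` (N x N x L) and
#'   `accel` (achieved acceleration per contrast).
#' @export
vd_caspr_masks <- function(matrix_size, L, target_accel = 6.5,
                           center_fraction = 0.08, seed = 1L) {
  N <- as.integer(matrix_size)
  stopifnot(target_accel > 1, L >= 1)
  rc <- center_fraction * N / 2
  rmax <- N / 2 - 1
  gr <- (sqrt(5) - 1) / 2
  ij <- norm_grid(N)
  kr_cells <- sqrt(ij$x^2 + ij$y^2) * N
  center <- kr_cells <= rc
  target_frac <- 1 / target_accel
  npa <- max(16L, N %/% 2L)
  masks <- array(FALSE, c(N, N, L))
  with_seed(seed, {
    for (l in seq_len(L)) {
      m <- center
      off <- (l - 1) * 111.246 * pi / 180 + runif(1, 0, 2 * pi / 1e3)
      arm <- 0L
      while (mean(m) < target_frac) {
        arm <- arm + 1L
        if (arm > 50L * N) stop("unreachable sampling density",
                                call. = FALSE)
        th0 <- off + 2 * pi * ((arm * gr) %% 1)
        tt <- (seq_len(npa) - 0.5) / npa
        r <- pmax(rc * 0.9, rc * 0.9 * (rmax / (rc * 0.9))^tt)
        th <- th0 + pi * tt                 # half-turn spiral arm
        px <- round(r * cos(th)) + N / 2 + 1
        py <- round(r * sin(th)) + N / 2 + 1
        ok <- px >= 1 & px <= N & py >= 1 & py <= N
        m[cbind(px[ok], py[ok])] <- TRUE
      }
      masks[, , l] <- m
    }
  })
  accel <- 1 / apply(masks, 3, mean)
  if (any(abs(accel - target_accel) / target_accel > 0.05))
    stop(sprintf("achieved acceleration %s misses target %.2f by > 5%%",
                 paste(round(accel, 2), collapse = "/"), target_accel),
         call. = FALSE)
  structure(list(masks = masks * 1L, accel = accel, type = "cartesian"),
            class = "cartesian_sampling")
}

noise_sigma_for_snr <- function(y, snr_db) {
  sqrt(mean(Mod(y)^2) * 10^(-snr_db / 10) / 2)
}

#' Simulate a radial fingerprinting acquisition
#'
#' Per-voxel fingerprints come from the slice-profile-corrected EPG model
#' scaled by the phantom's complex proton density; the time-point image at
#' `t` is sampled on the spoke(s) of `t` through the NUFFT for each coil;
#' complex Gaussian noise is added.  Ground truth is stored alongside.
#'
#' @param phantom a [make_vial_phantom()].
#' @param seq a [sequence_params()] with `seq$n == traj$n_timepoints`.
#' @param traj a [golden_angle_trajectory()].
#' @param sens complex coil maps (N x N x Nc).
#' @param noise_sigma per-component complex Gaussian noise SD; alternatively
#'   give `snr_db` and the SD is derived from the clean data power.
#' @param snr_db target SNR in dB (used when `noise_sigma` is `NULL`).
#' @param seed noise seed.
#' @param n_iso slice-profile isochromats.
#' @param kmax EPG truncation order.
#' @return `hdprost_dataset`: list with `kspace` (Z x 1 x Nc), `sampling`,
#'   `sens`, `sequence`, `truth`, `meta`.
#' @export
simulate_mrf_kspace <- function(phantom, seq, traj, sens, noise_sigma = NULL,
                                snr_db = NULL, seed = 1L, n_iso = 51L,
                                kmax = 64L) {
  stopifnot(seq$n == traj$n_timepoints)
  N <- phantom$matrix_size
  sens <- as.array(sens)
  if (length(dim(sens)) == 2L) dim(sens) <- c(dim(sens), 1L)
  Nc <- dim(sens)[3]
  labs <- sort(unique(phantom$label[phantom$label > 0L]))
  t1s <- vapply(labs, function(l) phantom$t1_ms[phantom$label == l][1],
                numeric(1))
  t2s <- vapply(labs, function(l) phantom$t2_ms[phantom$label == l][1],
                numeric(1))
  fp <- slice_profile_correct(t1s, t2s, seq, n_iso = n_iso, kmax = kmax)
  fp <- matrix(fp, nrow = seq$n)                    # n x nlab
  plan <- nufft_plan(traj$coords, N)
  nlab <- length(labs)
  Cmat <- matrix(0i, plan$G^2, nlab * Nc)
  for (cc in seq_len(Nc)) {
    for (jl in seq_len(nlab)) {
      img <- phantom$m0 * (phantom$label == labs[jl])
      Cmat[, (cc - 1L) * nlab + jl] <- grid_fwd(plan, sens[, , cc] * img)
    }
  }
  Sall <- sp_cmult(plan$P, Cmat)                    # Z x (nlab * Nc)
  Ft <- fp[traj$time_of_sample, , drop = FALSE]     # Z x nlab
  Z <- nrow(Sall)
  Y <- matrix(0i, Z, Nc)
  for (cc in seq_len(Nc)) {
    Y[, cc] <- rowSums(Ft * Sall[, (cc - 1L) * nlab + seq_len(nlab),
                                 drop = FALSE])
  }
  if (is.null(noise_sigma)) {
    noise_sigma <- if (is.null(snr_db)) 0 else noise_sigma_for_snr(Y, snr_db)
  }
  if (noise_sigma > 0) {
    Y <- Y + with_seed(seed, matrix(noise_sigma * crandn(Z * Nc), Z, Nc))
  }
  kspace <- array(Y, c(Z, 1L, Nc))
  structure(list(
    kspace = kspace, sampling = traj, sens = sens, sequence = seq,
    truth = list(t1_ms = phantom$t1_ms, t2_ms = phantom$t2_ms,
                 m0 = phantom$m0, label = phantom$label),
    meta = list(mode = "radial-mrf", matrix_size = N, seed = as.integer(seed),
                noise_sigma = noise_sigma,
                provenance = "synthetic radial fingerprinting acquisition")),
    class = "hdprost_dataset")
}

#' Magnetization-transfer weighting parameters for the synthetic stack
#'
#' A documented surrogate (not a physical two-pool model): contrast `l`
#' attenuates tissue `t` by `exp(-k_t * alpha_l / 800)`, giving the
#' multi-contrast stack the shared-structure / varying-contrast statistics a
#' joint reconstruction exploits.
#'
#' @param alpha_mt_deg MT preparation flip angles, degrees.
#' @param k_t per-tissue attenuation rates (recycled over tissue labels).
#' @return `mt_params` list.
#' @export
mt_params <- function(alpha_mt_deg = c(0, 160, 320, 480, 640, 800),
                      k_t = NULL) {
  stopifnot(all(alpha_mt_deg >= 0))
  structure(list(alpha_mt_deg = alpha_mt_deg, k_t = k_t),
            class = "mt_params")
}

#' Simulate an undersampled multi-contrast Cartesian acquisition
#'
#' Contrast `l`'s image is the phantom proton density attenuated per tissue
#' by the surrogate MT model of [mt_params()]; each contrast is masked in
#' k-space by its own variable-density mask; complex Gaussian noise is added
#' to the sampled points.
#'
#' @param phantom a [make_vial_phantom()].
#' @param mt an [mt_params()].
#' @param sampling a [vd_caspr_masks()] result (L masks).
#' @param sens complex coil maps.
#' @param noise_sigma per-component complex noise SD; alternatively give
#'   `snr_db` and the SD is derived from the power of the sampled points.
#' @param snr_db target SNR in dB (used when `noise_sigma` is `NULL`).
#' @param seed noise seed.
#' @return `hdprost_dataset` with Cartesian `kspace` (Mx x My x L x Nc,
#'   zeros where unsampled) and the clean contrast images under
#'   `truth$images`.
#' @export
simulate_mt_kspace <- function(phantom, mt = mt_params(), sampling, sens,
                               noise_sigma = NULL, snr_db = NULL, seed = 1L) {
  N <- phantom$matrix_size
  masks <- sampling$masks
  L <- dim(masks)[3]
  stopifnot(length(mt$alpha_mt_deg) == L)
  sens <- as.array(sens)
  if (length(dim(sens)) == 2L) dim(sens) <- c(dim(sens), 1L)
  labs <- sort(unique(phantom$label[phantom$label > 0L]))
  kt <- mt$k_t
  if (is.null(kt)) kt <- seq(0.2, 1.5, length.out = length(labs))
  kt <- rep_len(kt, length(labs))
  if (any(kt < 0)) stop("attenuation rates must be >= 0", call. = FALSE)
  kmap <- matrix(0, N, N)
  for (jl in seq_along(labs)) kmap[phantom$label == labs[jl]] <- kt[jl]
  X <- array(0i, c(N, N, L))
  for (l in seq_len(L)) {
    X[, , l] <- phantom$m0 * exp(-kmap * mt$alpha_mt_deg[l] / 800)
  }
  op <- cartesian_operator(sens, masks)
  Y <- op$forward(X)
  if (is.null(noise_sigma)) {
    noise_sigma <- if (is.null(snr_db)) 0 else {
      sel <- array(masks == 1, dim(Y)[1:3])
      noise_sigma_for_snr(Y[array(sel, dim(Y))], snr_db)
    }
  }
  if (noise_sigma > 0) {
    noise <- with_seed(seed, array(noise_sigma * crandn(length(Y)), dim(Y)))
    sel <- array(masks == 1, dim(Y)[1:3])
    for (cc in seq_len(dim(Y)[4])) {
      yk <- Y[, , , cc]; nk <- noise[, , , cc]
      yk[sel] <- yk[sel] + nk[sel]
      Y[, , , cc] <- yk
    }
  }
  structure(list(
    kspace = Y, sampling = sampling, sens = sens, sequence = NULL,
    truth = list(images = X, t1_ms = phantom$t1_ms, t2_ms = phantom$t2_ms,
                 m0 = phantom$m0, label = phantom$label),
    meta = list(mode = "cartesian-multicontrast", matrix_size = N,
                seed = as.integer(seed), noise_sigma = noise_sigma,
                alpha_mt_deg = mt$alpha_mt_deg,
                provenance = "synthetic multi-contrast MT-weighted stack")),
    class = "hdprost_dataset")
}
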