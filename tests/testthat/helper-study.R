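# The desk-scale phantom fingerprinting study shared by the acceptance
# tests: 9-vial phantom at 128x128, 500 single-spoke golden-angle time
# points, 8 coils, 30 dB SNR, seed 1; slice-profile-corrected dictionary
# (T1 100:20:2000 ms, T2 10:10:310 ms, 51 isochromats, rank 10); HD-PROST at
# its published radial operating point and LRI with 10 CG iterations.
# Computed once per test run and cached (several minutes of CPU).

.study_cache <- new.env(parent = emptyenv())

mrf_phantom_study <- function() {
  if (!is.null(.study_cache$res)) return(.study_cache$res)
  N <- 128; tp <- 500; Nc <- 8
  ph <- make_vial_phantom(N, seed = 1)
  sq <- sequence_params(default_flip_train(tp))
  traj <- golden_angle_trajectory(tp, matrix_size = N)
  sens <- simulate_coils(N, Nc, seed = 1)
  ds <- simulate_mrf_kspace(ph, sq, traj, sens, snr_db = 30, seed = 1,
                            n_iso = 51)
  dict <- compress_dictionary(
    build_dictionary(seq(100, 2000, 20), seq(10, 310, 10), sq, n_iso = 51),
    10)
  op <- radial_subspace_operator(ds$sens, ds$sampling, dict$basis)
  Y <- matrix(ds$kspace, dim(ds$kspace)[1], Nc)
  cfg <- recon_config("radial-mrf", seed = 1)
  Xh <- suppressWarnings(hd_prost_recon(Y, op, cfg))
  Xl <- lri_recon(Y, op, cg_iters = 10)
  maps_h <- match_fingerprints(Xh, dict, mask = ph$support)
  maps_l <- match_fingerprints(Xl, dict, mask = ph$support)
  vial_stats <- function(maps) {
    labs <- 2:10
    list(t1_mean = vapply(labs, function(l)
           mean(maps$t1_ms[ph$label == l]), numeric(1)),
         t1_sd = vapply(labs, function(l)
           sd(maps$t1_ms[ph$label == l]), numeric(1)),
         t2_sd = vapply(labs, function(l)
           sd(maps$t2_ms[ph$label == l]), numeric(1)))
  }
  .study_cache$res <- list(phantom = ph, hd = vial_stats(maps_h),
                           lri = vial_stats(maps_l))
  .study_cache$res
}
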