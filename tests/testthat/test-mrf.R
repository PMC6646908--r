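# EPG simulation against closed forms and a rotation-matrix Bloch oracle;
# dictionary construction, compression, and inner-product matching.

test_that("zero flip train after inversion follows inversion recovery", {
  sq <- sequence_params(rep(0, 25), tr_ms = 100, te_ms = 2, invert = TRUE)
  s <- epg_simulate(700, 45, sq)
  expect_equal(max(Mod(s)), 0)
  z <- hdprost:::.epg_z0_free_recovery(25, 100, 700, TRUE)
  expect_lt(max(abs(z - (1 - 2 * exp(-(1:25) * 100 / 700)))), 1e-10)
})

test_that("a single 90-degree pulse decays as exp(-TE/T2)", {
  sq <- sequence_params(90, tr_ms = 10, te_ms = 2, invert = FALSE)
  s <- epg_simulate(700, 45, sq)
  expect_lt(abs(Mod(s) - exp(-2 / 45)), 1e-10)
})

test_that("constant-train steady state matches the spoiled closed form", {
  # strong spoiling regime (T2 << TR) where transverse coherences vanish and
  # the gradient-dephased EPG converges to the Ernst expression
  al <- 25; TR <- 100; T1 <- 700; T2 <- 10; TE <- 2
  sq <- sequence_params(rep(al, 500), tr_ms = TR, te_ms = TE, invert = FALSE,
                        rf_phase_deg = rep(0, 500))
  s <- epg_simulate(T1, T2, sq)
  E1 <- exp(-TR / T1)
  ernst <- sin(al * pi / 180) * (1 - E1) / (1 - E1 * cos(al * pi / 180)) *
    exp(-TE / T2)
  expect_lt(abs(Mod(s[500]) - ernst) / ernst, 1e-3)
})

test_that("EPG agrees with a 200-isochromat Bloch simulation", {
  fa <- rep(30, 400); phase <- rep(c(0, 180), 200)
  sq <- sequence_params(fa, tr_ms = 4.4, te_ms = 2, invert = TRUE,
                        rf_phase_deg = phase)
  e <- epg_simulate(700, 45, sq)
  b <- bloch_isochromat(700, 45, fa, phase, 4.4, 2, TRUE, n_iso = 200)
  expect_lt(max(Mod(e - b)), 1e-3)
  # and on the package's variable default train
  fa2 <- default_flip_train(300)
  sq2 <- sequence_params(fa2)
  e2 <- epg_simulate(1000, 100, sq2)
  b2 <- bloch_isochromat(1000, 100, fa2, sq2$rf_phase_deg, 4.4, 2, TRUE, 200)
  expect_lt(max(Mod(e2 - b2)), 1e-3)
})

test_that("EPG rejects nonpositive relaxation times", {
  sq <- sequence_params(rep(10, 5))
  expect_error(epg_simulate(-1, 45, sq), "positive")
  expect_error(epg_simulate(700, 0, sq), "positive")
})

test_that("EPG signal is continuous in T1", {
  sq <- sequence_params(default_flip_train(400))
  s0 <- epg_simulate(700, 45, sq)
  s1 <- epg_simulate(707, 45, sq)
  expect_lt(fnorm(s1 - s0) / fnorm(s0), 0.05)
})

test_that("slice-profile correction degenerates correctly", {
  sq <- sequence_params(default_flip_train(100))
  ideal <- slice_profile_correct(700, 45, sq, profile = rep(1, 7))
  expect_equal(ideal, epg_simulate(700, 45, sq))
  centre <- slice_profile_correct(700, 45, sq, n_iso = 1)
  p0 <- slice_profile(1)
  sq0 <- sequence_params(sq$fa_deg * p0, sq$tr_ms, sq$te_ms, sq$invert,
                         sq$rf_phase_deg)
  expect_equal(centre, epg_simulate(700, 45, sq0))
})

test_that("51 isochromats approximate a dense slice profile", {
  sq <- sequence_params(default_flip_train(150))
  s51 <- slice_profile_correct(700, 45, sq, n_iso = 51)
  s501 <- slice_profile_correct(700, 45, sq, n_iso = 501)
  expect_lt(fnorm(s51 - s501) / fnorm(s501), 1e-2)
})

test_that("published grids enumerate to 152 x 77 = 11704 atoms", {
  expect_length(dictionary_t1_grid(), 152)
  expect_length(dictionary_t2_grid(), 77)
  expect_equal(length(dictionary_t1_grid()) * length(dictionary_t2_grid()),
               11704)
})

test_that("dictionaries have unit atoms and keep duplicates verbatim", {
  sq <- sequence_params(default_flip_train(60))
  d <- build_dictionary(c(300, 700, 700), c(40, 80), sq,
                        slice_correct = FALSE)
  expect_equal(ncol(d$atoms), 6)
  expect_lt(max(abs(sqrt(colSums(Mod(d$atoms)^2)) - 1)), 1e-10)
  # duplicated T1 produces identical duplicated atoms
  expect_equal(d$atoms[, 2], d$atoms[, 3])
})

test_that("compression is lossless at full rank and orthonormal", {
  sq <- sequence_params(default_flip_train(40))
  d <- build_dictionary(seq(300, 1500, 200), seq(30, 150, 30), sq,
                        slice_correct = FALSE)
  # requesting more vectors than the atom matrix's rank falls back with a
  # warning; the achievable-rank basis is still lossless
  expect_warning(dc <- compress_dictionary(d, 40), "rank")
  Ur <- dc$basis$Ur
  expect_lt(max(Mod(Conj(t(Ur)) %*% Ur - diag(ncol(Ur)))), 1e-12)
  back <- Ur %*% dc$atoms_compressed
  expect_lt(relerr(back, d$atoms), 1e-10)
})

test_that("rank-r truncation error equals the dense-SVD tail", {
  sq <- sequence_params(default_flip_train(80))
  d <- build_dictionary(seq(200, 2000, 100), seq(20, 250, 20), sq,
                        slice_correct = FALSE)
  r <- 5
  dc <- compress_dictionary(d, r)
  approx <- dc$basis$Ur %*% dc$atoms_compressed
  err <- fnorm(approx - d$atoms) / fnorm(d$atoms)
  sv <- svd(d$atoms)$d   # independent dense SVD
  expect_equal(err, sqrt(sum(sv[-(1:r)]^2) / sum(sv^2)), tolerance = 1e-8)
})

test_that("matching recovers exact atoms, scale and phase included", {
  set.seed(43)
  sq <- sequence_params(default_flip_train(60))
  d <- build_dictionary(seq(200, 1600, 100), seq(20, 200, 20), sq,
                        slice_correct = FALSE)
  dc <- compress_dictionary(d, 8)
  js <- sample(ncol(d$atoms), 25)
  X <- t(dc$atoms_compressed[, js])            # voxels x r
  maps <- match_fingerprints(X, dc)
  expect_equal(maps$match_index, js)
  expect_equal(maps$t1_ms, d$t1_ms[js])
  expect_equal(maps$t2_ms, d$t2_ms[js])
  # complex scaling moves m0 and nothing else; on full-length atoms the
  # recovered scale is exact, on compressed ones it carries the (tiny)
  # subspace-truncation factor ||Ur^H atom||^2
  sc <- 3.7 * exp(1i * pi / 5)
  maps2 <- match_fingerprints(t(sc * d$atoms[, js]), d)
  expect_equal(maps2$match_index, js)
  expect_lt(max(abs(Mod(maps2$m0 * d$norms[js]) - 3.7)), 1e-10)
  maps3 <- match_fingerprints(t(sc * dc$atoms_compressed[, js]), dc)
  expect_equal(maps3$match_index, js)
  expect_lt(max(abs(Mod(maps3$m0 * d$norms[js]) - 3.7)), 1e-3)
})

test_that("noisy matching equals the brute-force argmax", {
  set.seed(11)
  sq <- sequence_params(default_flip_train(60))
  d <- build_dictionary(seq(200, 1600, 200), seq(20, 200, 40), sq,
                        slice_correct = FALSE)
  dc <- compress_dictionary(d, 6)
  js <- sample(ncol(d$atoms), 100, replace = TRUE)
  X <- t(dc$atoms_compressed[, js]) + 0.01 * matrix(crnorm(600), 100, 6)
  maps <- match_fingerprints(X, dc)
  brute <- apply(X, 1, function(x)
    which.max(abs(colSums(Conj(dc$atoms_compressed) * x))))
  expect_equal(maps$match_index, unname(brute))
})

test_that("zero-signal voxels inside the mask are flagged with m0 = 0", {
  sq <- sequence_params(default_flip_train(40))
  d <- compress_dictionary(
    build_dictionary(c(300, 900), c(50, 100), sq, slice_correct = FALSE), 4)
  X <- rbind(t(d$atoms_compressed[, 1]), rep(0i, 4))
  maps <- match_fingerprints(X, d)
  expect_true(maps$zero_signal[2])
  expect_equal(maps$m0[2], 0i)
  expect_true(is.na(maps$match_index[2]))
})

test_that("compression at r = 10 preserves noiseless matches", {
  set.seed(47)
  sq <- sequence_params(default_flip_train(120))
  d <- build_dictionary(seq(150, 2000, 50), seq(15, 300, 15), sq,
                        slice_correct = FALSE)
  dc <- compress_dictionary(d, 10)
  js <- sample(ncol(d$atoms), 500, replace = TRUE)
  full <- match_fingerprints(t(d$atoms[, js]), dc)
  comp <- match_fingerprints(t(dc$atoms_compressed[, js]), dc)
  expect_gte(mean(full$match_index == comp$match_index), 0.99)
})
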