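# Block matching, patch-tensor construction, truncated complex HOSVD, and
# sliding-window aggregation.

test_that("block matching ties resolve to scan order on a constant image", {
  X <- array(1 + 1i, c(12, 12, 2))
  dp <- denoise_params(patch_edge = 3, K = 4, search_radius = 3,
                       patch_offset = 1, tau = 0)
  sel <- block_match(X, c(5, 5), dp)
  expect_equal(sel[1, ], c(5, 5))
  # all distances zero: candidates in column-major scan order of the window
  win <- expand.grid(x = 2:8, y = 2:8)
  win <- win[order((win$y - 1) * 12 + win$x), ]
  win <- win[!(win$x == 5 & win$y == 5), ]
  expect_equal(unname(sel[2:4, ]), unname(as.matrix(win[1:3, ])))
})

test_that("an exact translated copy ranks directly after the reference", {
  set.seed(5)
  X <- array(crnorm(20 * 20 * 2), c(20, 20, 2))
  X[11:13, 4:6, ] <- X[3:5, 3:5, ]       # plant a copy of the patch at (3,3)
  dp <- denoise_params(patch_edge = 3, K = 3, search_radius = 12,
                       patch_offset = 1, tau = 0)
  sel <- block_match(X, c(3, 3), dp)
  expect_equal(sel[2, ], c(11, 4))
})

test_that("block matching equals exhaustive brute-force search", {
  set.seed(6)
  N <- 32
  X <- array(crnorm(N * N * 2), c(N, N, 2))
  dp <- denoise_params(patch_edge = 5, K = 7, search_radius = 6,
                       patch_offset = 1, tau = 0)
  for (ref in list(c(1, 1), c(10, 17), c(N - 4, N - 4))) {
    sel <- block_match(X, ref, dp)
    cand <- expand.grid(x = max(1, ref[1] - 6):min(N - 4, ref[1] + 6),
                        y = max(1, ref[2] - 6):min(N - 4, ref[2] + 6))
    d <- apply(cand, 1, function(cc)
      sum(Mod(X[ref[1]:(ref[1] + 4), ref[2]:(ref[2] + 4), ] -
              X[cc[1]:(cc[1] + 4), cc[2]:(cc[2] + 4), ])^2))
    ord <- order(d, (cand$y - 1) * N + cand$x)
    expect_equal(unname(sel), unname(as.matrix(cand[ord[1:7], ])))
  }
})

test_that("tiny search windows shrink K with a warning", {
  X <- array(crnorm(8 * 8 * 2), c(8, 8, 2))
  dp <- denoise_params(patch_edge = 5, K = 30, search_radius = 5,
                       patch_offset = 1, tau = 0)
  expect_warning(sel <- block_match(X, c(2, 2), dp), "shrinking")
  expect_equal(nrow(sel), 16)   # only 4x4 corners exist
})

test_that("patch tensors have the documented layout", {
  set.seed(7)
  X <- array(crnorm(64 * 64 * 10), c(64, 64, 10))
  dp <- denoise_params(patch_edge = 7, K = 20, search_radius = 20,
                       patch_offset = 3, tau = 0)
  sel <- block_match(X, c(20, 20), dp)
  pt <- build_patch_tensor(X, sel, dp)
  expect_equal(dim(pt$data), c(49, 20, 10))
  # K = 1: the vectorized reference patch
  pt1 <- build_patch_tensor(X, matrix(c(4, 9), 1), dp)
  expect_equal(pt1$data[, 1, 3], as.vector(X[4:10, 9:15, 3]))
  expect_error(build_patch_tensor(X, matrix(c(63, 1), 1), dp), "bounds")
})

test_that("unfold and refold are inverse for every mode", {
  A <- crarray(c(5, 4, 3))
  for (m in 1:3) {
    expect_identical(hdprost:::refold(hdprost:::unfold(A, m), m, dim(A)), A)
  }
})

test_that("HOSVD mode singular values match dense unfolding SVDs", {
  set.seed(8)
  A <- crarray(c(20, 8, 4))
  out <- hosvd_truncate(A, 0)
  sv <- attr(out, "mode_sv")
  for (m in 1:3) {
    expect_lt(max(abs(sv[[m]] - svd(dense_unfold(A, m))$d)), 1e-10)
  }
  expect_lt(relerr(out, A), 1e-10)   # tau = 0 keeps everything
})

test_that("an invariant rank-(1,1,1) tensor is recovered exactly", {
  set.seed(9)
  a <- crnorm(10); b <- crnorm(6); cc <- crnorm(3)
  T1 <- array(outer(outer(a, b), cc), c(10, 6, 3))
  out <- hosvd_truncate(T1, 0.5 * fnorm(T1))
  expect_lt(relerr(out, T1), 1e-10)
  expect_equal(unname(attr(out, "mode_ranks")), c(1L, 1L, 1L))
})

test_that("truncation is non-expansive mode-wise and in Frobenius norm", {
  set.seed(10)
  for (rep in 1:5) {
    A <- crarray(c(12, 7, 4))
    tau <- runif(1, 0, 10)
    out <- hosvd_truncate(A, tau)
    expect_lte(fnorm(out), fnorm(A) + 1e-12)
    for (m in 1:3) {
      expect_true(all(svd(dense_unfold(out, m))$d <=
                      svd(dense_unfold(A, m))$d + 1e-10))
    }
  }
})

test_that("non-finite tensors are rejected", {
  A <- crarray(c(4, 3, 2)); A[1] <- NaN + 0i
  expect_error(hosvd_truncate(A, 0), "non-finite")
})

test_that("aggregation averages overlapping estimates uniformly", {
  dp <- denoise_params(patch_edge = 3, K = 1, search_radius = 3,
                       patch_offset = 1, tau = 0)
  img_dim <- c(5, 3, 1)
  g1 <- list(member_coords = matrix(c(1, 1), 1),
             data = array(2 + 0i, c(9, 1, 1)))
  g2 <- list(member_coords = matrix(c(3, 1), 1),
             data = array(6 + 0i, c(9, 1, 1)))
  out <- aggregate_groups(list(g1, g2), img_dim, 3)
  expect_equal(out[2, 2, 1], 2 + 0i)       # covered once
  expect_equal(out[3, 2, 1], 4 + 0i)       # covered by both: (2 + 6)/2
  # a grid that misses voxels is an error
  expect_error(aggregate_groups(list(g1), img_dim, 3), "uncovered")
})

test_that("the full denoiser at tau = 0 is the identity (partition of unity)", {
  set.seed(12)
  X <- array(crnorm(24 * 24 * 2), c(24, 24, 2))
  dp <- denoise_params(patch_edge = 5, K = 6, search_radius = 6,
                       patch_offset = 3, tau = 0)
  expect_lt(relerr(denoise_multicontrast(X, dp), X), 1e-10)
  # zero image stays zero
  Z <- array(0i, c(24, 24, 2))
  expect_equal(denoise_multicontrast(Z, dp), Z)
})

test_that("denoising reduces the error of a noisy piecewise-constant phantom", {
  set.seed(3)
  N <- 32
  clean <- array(0i, c(N, N, 2))
  clean[9:24, 9:24, 1] <- 1; clean[9:24, 9:24, 2] <- 0.5
  clean[13:20, 13:20, 1] <- 0.3; clean[13:20, 13:20, 2] <- 0.9
  noisy <- clean + 0.05 * array(crnorm(N * N * 2), c(N, N, 2))
  dp <- denoise_params(patch_edge = 5, K = 12, search_radius = 8,
                       patch_offset = 2, tau = 0.8)
  out <- denoise_multicontrast(noisy, dp)
  expect_lt(mean(Mod(out - clean)^2), mean(Mod(noisy - clean)^2))
})

test_that("a noise-free motif image passes through a small threshold", {
  set.seed(4)
  motifs <- lapply(1:5, function(i) matrix(crnorm(16), 4, 4))
  N <- 40
  X <- array(0i, c(N, N, 2))
  for (bx in seq(1, N - 3, by = 4)) {
    for (by in seq(1, N - 3, by = 4)) {
      m <- motifs[[1 + (bx + by) %% 5]]
      X[bx:(bx + 3), by:(by + 3), 1] <- m
      X[bx:(bx + 3), by:(by + 3), 2] <- 2 * m
    }
  }
  dp <- denoise_params(patch_edge = 5, K = 10, search_radius = 10,
                       patch_offset = 2, tau = 1e-4)
  expect_lt(relerr(denoise_multicontrast(X, dp), X), 1e-3)
})

test_that("aggregation is equivariant to permuting the matched candidates", {
  set.seed(13)
  X <- array(crnorm(16 * 16 * 2), c(16, 16, 2))
  dp <- denoise_params(patch_edge = 3, K = 5, search_radius = 5,
                       patch_offset = 2, tau = 0.5)
  sel <- block_match(X, c(7, 7), dp)
  perm <- c(1, 5, 3, 2, 4)   # reference stays first
  d1 <- hosvd_truncate(build_patch_tensor(X, sel, dp), 0.5)
  d2 <- hosvd_truncate(build_patch_tensor(X, sel[perm, ], dp), 0.5)
  # denoising commutes with permuting the K candidates, so each patch gets
  # the same estimate and the aggregated image is unchanged
  expect_lt(max(Mod(d2$data[, order(perm), ] - d1$data)) /
            max(Mod(d1$data)), 1e-10)
})
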