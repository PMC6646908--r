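# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: direct Fourier sums, dense unfolding SVDs, dense
# normal-equation solves, rotation-matrix Bloch simulation.

crnorm <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))

crarray <- function(dim) array(crnorm(prod(dim)), dim)

relerr <- function(x, ref) {
  sqrt(sum(Mod(x - ref)^2)) / sqrt(sum(Mod(ref)^2))
}

fnorm <- function(x) sqrt(sum(Mod(x)^2))

# direct (slow) non-uniform Fourier sum, the NUFFT accuracy oracle
direct_nuft <- function(img, coords) {
  N <- nrow(img)
  xs <- seq_len(N) - 1 - N / 2
  vapply(seq_len(nrow(coords)), function(s) {
    ph <- exp(-2i * pi * (coords[s, 1] * outer(xs, rep(1, N)) +
                          coords[s, 2] * outer(rep(1, N), xs)))
    sum(img * ph) / N
  }, complex(1))
}

# dense mode-i unfolding of a 3-way array (oracle for the HOSVD internals)
dense_unfold <- function(A, mode) {
  d <- dim(A)
  perm <- switch(mode, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  matrix(aperm(A, perm), d[mode])
}

# Bloch simulation of a gradient-dephased RF train by explicit rotation
# matrices over n_iso isochromats uniformly dephased across 2*pi per TR.
# Signal recorded at TE as in the EPG convention (transverse decay over TE,
# full-TR relaxation applied to the state).
bloch_isochromat <- function(t1, t2, fa_deg, phase_deg, tr, te, invert,
                             n_iso = 200) {
  n <- length(fa_deg)
  theta <- 2 * pi * (seq_len(n_iso) - 1) / n_iso
  e1 <- exp(-tr / t1); e2 <- exp(-tr / t2); e2te <- exp(-te / t2)
  M <- matrix(0, 3, n_iso)
  M[3, ] <- if (invert) -1 else 1
  rot_rf <- function(alpha, phi) {
    ca <- cos(alpha); sa <- sin(alpha)
    cp <- cos(phi); sp <- sin(phi)
    Rz <- matrix(c(cp, sp, 0, -sp, cp, 0, 0, 0, 1), 3)
    Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3)
    Rz %*% Rx %*% t(Rz)
  }
  sig <- complex(n)
  for (p in seq_len(n)) {
    R <- rot_rf(fa_deg[p] * pi / 180, phase_deg[p] * pi / 180)
    M <- R %*% M
    sig[p] <- mean(complex(real = M[1, ], imaginary = M[2, ])) * e2te
    M[1:2, ] <- M[1:2, ] * e2
    M[3, ] <- M[3, ] * e1 + (1 - e1)
    for (i in seq_len(n_iso)) {
      c_ <- cos(theta[i]); s_ <- sin(theta[i])
      xy <- c(c_ * M[1, i] - s_ * M[2, i], s_ * M[1, i] + c_ * M[2, i])
      M[1:2, i] <- xy
    }
  }
  sig
}

# tiny shared fixtures -------------------------------------------------------

tiny_cartesian_problem <- function(N = 6, L = 2, Nc = 2, seed = 7,
                                   mask_p = 0.5) {
  set.seed(seed)
  sens <- crarray(c(N, N, Nc))
  masks <- array(rbinom(N * N * L, 1, mask_p), c(N, N, L))
  masks[N / 2 + 1, N / 2 + 1, ] <- 1   # keep DC so the system is sensible
  list(op = cartesian_operator(sens, masks), sens = sens, masks = masks,
       N = N, L = L, Nc = Nc)
}

dense_encoding_matrix <- function(op) {
  nx <- prod(op$img_dim)
  probe <- array(0i, op$img_dim)
  probe[1] <- 1
  ny <- length(op$forward(probe))
  E <- matrix(0i, ny, nx)
  for (j in seq_len(nx)) {
    ej <- array(0i, op$img_dim); ej[j] <- 1
    E[, j] <- as.vector(op$forward(ej))
  }
  E
}
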