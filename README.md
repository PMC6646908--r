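# hdprost

Joint reconstruction of highly undersampled multi-contrast MRI by
high-order patch-tensor denoising (HD-PROST), with a full magnetic
resonance fingerprinting (MRF) pathway and the standard comparator
reconstructions.

## What problem this solves, and for whom

Quantitative MRI acquires many images of one anatomy under different
contrast weightings — multiple magnetization-transfer preparations, or the
thousands of time-point images of a fingerprinting scan — and long scan
times force aggressive k-space undersampling.  The images are individually
incomplete but collectively hugely redundant: locally (within a patch),
non-locally (similar patches elsewhere), and across the contrast dimension.
This package is for researchers in MR image reconstruction and quantitative
mapping who want a complete, self-contained implementation of a joint
multi-contrast reconstruction that exploits all three redundancies, plus
everything needed to study it without scanner data: a digital phantom,
coil/trajectory/mask simulators, an EPG fingerprint simulator and
dictionary, and the low-rank inversion (LRI) and locally-low-rank (LLR)
baselines.

## The method

The multi-contrast stack `X` (contrasts `l = 1..L`) is encoded per coil by
`E = A F S` — coil sensitivities `S`, unitary FFT `F`, sampling `A`
(per-contrast Cartesian masks, or a gridding NUFFT onto golden-angle radial
spokes).  HD-PROST solves

```
min_X  1/2 ||E X - Y||_F^2  +  sum_p lambda ||T_p||_*
s.t.   T_p = P_p X
```

where `P_p X` stacks a reference patch, its `K-1` best-matching neighbour
patches, and all `L` contrasts into an `N x K x L` tensor whose multilinear
rank is low.  ADMM alternates (1) a warm-started conjugate-gradient SENSE
solve `(E^H E + mu I) X = E^H Y + mu T - b`, (2) patch-group denoising by
complex truncated HOSVD with threshold `tau = 2 lambda / mu`, aggregated by
averaging, and (3) the dual update `b <- b + mu (X - T)`.  For MRF, the
encoding operator becomes `E = A U_r F S` with `U_r` the rank-`r` temporal
subspace of the EPG dictionary; the reconstructed subspace images are
matched voxel-wise to the compressed dictionary by inner product to give
T1, T2 and proton-density maps.

See `vignettes/hdprost-methods.Rmd` for the model assumptions, all
parameter defaults, and the numerical design choices.

## Worked example

A desk-scale fingerprinting experiment: 9-vial phantom, one golden-angle
spoke per time point (200 time points, 4 coils, 30 dB SNR), rank-10
subspace reconstruction, dictionary matching.

```r
library(hdprost)

phantom <- make_vial_phantom(64, seed = 1)
train   <- sequence_params(default_flip_train(200))
traj    <- golden_angle_trajectory(200, matrix_size = 64)
coils   <- simulate_coils(64, 4, seed = 1)
data    <- simulate_mrf_kspace(phantom, train, traj, coils,
                               snr_db = 30, seed = 1, n_iso = 11)

dict <- build_dictionary(seq(100, 2000, 25), seq(10, 310, 10), train,
                         n_iso = 11)
dict <- compress_dictionary(dict, 10)

op  <- radial_subspace_operator(data$sens, data$sampling, dict$basis)
Y   <- matrix(data$kspace, nrow = dim(data$kspace)[1])
cfg <- recon_config("radial-mrf")
X   <- hd_prost_recon(Y, op, cfg)

maps <- match_fingerprints(X, dict, mask = phantom$support)
roi  <- sapply(2:10, function(l) mean(maps$t1_ms[phantom$label == l]))
data.frame(vial = 1:9, true_T1 = round(phantom$vial_t1_ms),
           est_T1 = round(roi))
```

```
  vial true_T1 est_T1
1    1     255    257
2    2     318    320
3    3     396    387
4    4     494    475
5    5     616    587
6    6     768    732
7    7     958    918
8    8    1194   1146
9    9    1489   1420
```

The per-vial ROI means track the ground truth closely (`R^2 = 0.9998` for
the linear fit): the estimated T1 is read off the dictionary grid at each
voxel's best-matching atom, so residual deviations combine grid
quantization, noise, and the regularization bias of the reconstruction.
The small systematic underestimate at long T1 comes from the strong
denoising threshold the published weight rule implies at 200 time points —
see the calibration discussion in the methods vignette.

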