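# Shared fixture specs, built in code.

# Downscaled single-lesion phantom used for fast pipeline tests and the
# parameter sweeps: 64 x 64, three sequences, one 8-pixel-radius lesion.
small_tumor_spec <- function(seed = 303L) {
  phantom_spec(shape = c(64L, 64L),
               sequence_names = c("T1", "T2", "FLAIR"),
               noise_sigma = 5, pv_sigma = 1,
               lesions = list(list(center = c(42, 38), radius = 8,
                                   offsets = c(-30, 60, 90))),
               geometry = list(brain = c(27, 22), gm_inner = c(23, 18),
                               csf = c(9, 6)),
               seed = seed)
}

# Piecewise-constant (no partial volume) variant for generator-contract
# tests.
flat_spec <- function(noise_sigma = 0, lesions = list(), seed = 7L,
                      k = 2L) {
  phantom_spec(shape = c(64L, 64L),
               sequence_names = c("T1", "T2")[seq_len(k)],
               noise_sigma = noise_sigma, pv_sigma = 0,
               lesions = lesions,
               geometry = list(brain = c(27, 22), gm_inner = c(23, 18),
                               csf = c(9, 6)),
               seed = seed)
}

# Planted-outlier instance: a dictionary spanning a 5-dimensional subspace,
# inlier columns inside the span, outlier columns orthogonal to it with
# comparable column norms.
planted_outlier_instance <- function(seed, N = 20L, atoms = 40L,
                                     inliers = 60L, outliers = 8L) {
  set.seed(seed)
  B <- qr.Q(qr(matrix(rnorm(N * 5), N, 5)))
  D <- B %*% matrix(rnorm(5 * atoms), 5, atoms)
  Xin <- B %*% matrix(rnorm(5 * inliers), 5, inliers)
  Bp <- qr.Q(qr(cbind(B, matrix(rnorm(N * (N - 5)), N, N - 5))))[, 6:N]
  Xout <- Bp %*% matrix(rnorm((N - 5) * outliers), N - 5, outliers)
  Xout <- Xout * rep(mean(sqrt(colSums(Xin^2))) / sqrt(colSums(Xout^2)),
                     each = N)
  list(Y = cbind(Xin, Xout), D = D,
       outlier_cols = inliers + seq_len(outliers))
}
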