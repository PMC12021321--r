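# Independent oracles used across the test files.

# brute-force nonuniform DFT: adjoint (k-space -> image) and forward
# (image -> k-space), image coordinates = voxel indices relative to the
# FFT-centre voxel, matching the package's convention
ndft_phase_matrix <- function(kcoords, geometry) {
  ax <- lapply(1:3, function(d)
    seq_len(geometry$shape[d]) - 1 - floor(geometry$shape[d] / 2))
  X <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  ktilde <- sweep(kcoords, 2, geometry$voxel_size, `*`)
  exp(2i * pi * (X %*% t(ktilde)))   # n_vox x n_samples
}

ndft_adjoint_oracle <- function(kcoords, values, geometry) {
  ph <- ndft_phase_matrix(kcoords, geometry)
  array(ph %*% values, dim = geometry$shape)
}

ndft_forward_oracle <- function(image, kcoords, geometry) {
  ph <- ndft_phase_matrix(kcoords, geometry)
  as.vector(t(Conj(ph)) %*% as.vector(image))
}

# Bloch steady state of the two-TR AFI cycle: signal right after the
# excitation following the long delay and the one following the short
# delay (longitudinal recovery only, perfect spoiling)
afi_bloch_oracle <- function(fa_deg, t1, tr_long, tr_short) {
  a <- fa_deg * pi / 180
  e_s <- exp(-tr_short / t1)
  e_l <- exp(-tr_long / t1)
  den <- 1 - e_s * e_l * cos(a)^2
  mz_after_long <- (1 - e_l + (1 - e_s) * e_l * cos(a)) / den
  mz_after_short <- (1 - e_s + (1 - e_l) * e_s * cos(a)) / den
  c(s_long = mz_after_long * sin(a), s_short = mz_after_short * sin(a))
}

# exhaustive 1-degree phase grid search for a 2-channel shim
phase_grid_oracle_2ch <- function(A) {
  stopifnot(ncol(A) == 2)
  phis <- seq(0, 359) * pi / 180
  costs <- vapply(phis, function(p) {
    f <- Mod(A %*% c(1, exp(1i * p)))
    m <- mean(f)
    sqrt(mean((f - m)^2)) / m
  }, 0)
  min(costs)
}

# population CV helper for expected values
cv_pop <- function(x) sqrt(mean((x - mean(x))^2)) / mean(x)
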