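test_that("reconstruction equals the weighted DFT-sum oracle on a tiny grid", {
  g <- grid_geometry(16, 6)
  np <- 30
  traj <- build_trajectory(
    golden_angle_directions(np, "half"),
    da_radial_readout(nyquist_kmax(g), 20, 5, 0.2, "half"), g)
  set.seed(11)
  n <- np * traj$n_samples
  samples <- array(complex(real = rnorm(n), imaginary = rnorm(n)),
                   dim = c(np, traj$n_samples, 1))
  acq <- structure(list(samples = samples, noise_sigma = 0, seed = 1,
                        nucleus = "na"), class = "acquired_data")
  kc <- cbind(as.vector(traj$coords[, , 1]), as.vector(traj$coords[, , 2]),
              as.vector(traj$coords[, , 3]))
  for (hamming in c(TRUE, FALSE)) {
    rec <- reconstruct(acq, traj, hamming = hamming)[[1]]
    w <- as.vector(traj$dcf)
    if (hamming)
      w <- w * hamming_radial(sqrt(rowSums(kc^2)), traj$kmax)
    oracle <- ndft_adjoint_oracle(kc, as.vector(samples[, , 1]) * w, g)
    expect_lt(max(abs(rec$data - oracle)) / max(abs(oracle)), 1e-6)
  }
  # a noiseless centre delta reconstructs with its peak at the centre voxel
  img0 <- array(0, g$shape)
  ctr <- floor(g$shape / 2) + 1L
  img0[ctr[1], ctr[2], ctr[3]] <- 1
  s_delta <- nufft_forward(img0 + 0i, kc, g)
  acq$samples[, , 1] <- s_delta
  rec <- reconstruct(acq, traj)[[1]]
  expect_equal(which.max(Mod(rec$data)),
               ctr[1] + (ctr[2] - 1) * 16 + (ctr[3] - 1) * 256)
  expect_error(reconstruct(acq, build_trajectory(
    golden_angle_directions(2 * np, "half"),
    da_radial_readout(nyquist_kmax(g), 20, 5, 0.2, "half"), g)), "shape")
})

test_that("the Hamming filter suppresses the first PSF sidelobe", {
  # 1D radial PSF of the 3D readout: integral of k^2 w(k) j0(2 pi k r)
  ro <- da_radial_readout(1 / 12, 512, 5, 0.2, "half")
  g <- grid_geometry(16, 6)
  traj <- build_trajectory(golden_angle_directions(1, "half"), ro, g)
  k <- ro$k_mags
  dcf <- traj$dcf[1, ]
  psf <- function(r, w) {
    x <- 2 * pi * k * r
    j0 <- ifelse(abs(x) < 1e-12, 1, sin(x) / x)
    sum(dcf * w * j0)
  }
  r <- seq(0.01, 30, by = 0.05)
  p_plain <- sapply(r, psf, w = rep(1, length(k)))
  p_hamm <- sapply(r, psf, w = hamming_radial(k, ro$kmax))
  first_sidelobe <- function(p) {
    s <- which(diff(sign(p)) != 0)[1]      # first zero crossing
    max(abs(p[(s + 1):(s + 200)]))
  }
  expect_lt(first_sidelobe(p_hamm / p_hamm[1]),
            first_sidelobe(p_plain / p_plain[1]))
})

test_that("root-sum-of-squares combination behaves as a norm", {
  g <- tiny_geometry(6, 6)
  set.seed(2)
  mk <- function() image_volume(
    array(complex(real = rnorm(216), imaginary = rnorm(216)), g$shape), g)
  a <- mk(); b <- mk()
  one <- combine_channels(list(a))
  expect_equal(one$data, Mod(a$data))
  two_same <- combine_channels(list(a, a))
  expect_equal(two_same$data, sqrt(2) * Mod(a$data), tolerance = 1e-12)
  two <- combine_channels(list(a, b))
  expect_true(all(two$data >= Mod(a$data) - 1e-12))
  expect_true(all(two$data >= Mod(b$data) - 1e-12))
  expect_error(combine_channels(list()), "at least one")
})

test_that("trilinear resampling is exact where it should be", {
  g6 <- grid_geometry(16, 6)
  # identity geometry: image unchanged
  img <- image_volume(array(rnorm(16^3), g6$shape), g6)
  expect_equal(resample_to(img, g6)$data, img$data)

  # (6 mm)^3 grid onto a (2 mm)^3 target triples each axis dimension
  g2 <- grid_geometry(48, 2)
  up <- resample_to(img, g2)
  expect_equal(dim(up$data), c(48L, 48L, 48L))

  # exact on a voxelwise-linear ramp in the interior
  xyz <- voxel_coordinates(g6)
  ramp <- array(2 + 0.25 * xyz[, 1] + 0.1 * xyz[, 2] - 0.05 * xyz[, 3],
                g6$shape)
  up_ramp <- resample_to(image_volume(ramp, g6), g2)
  xyz2 <- voxel_coordinates(g2)
  expected <- 2 + 0.25 * xyz2[, 1] + 0.1 * xyz2[, 2] - 0.05 * xyz2[, 3]
  interior <- ellipsoid_mask(g2, c(0, 0, 0), 36)
  expect_equal(up_ramp$data[interior], array(expected, g2$shape)[interior],
               tolerance = 1e-12)

  # out-of-FOV voxels are zero when the target extends beyond the source
  g_big <- grid_geometry(16, 12)
  down <- resample_to(img, g_big)
  corner_xyz <- voxel_coordinates(g_big)
  outside <- abs(corner_xyz[, 1]) > 50 & abs(corner_xyz[, 2]) > 50
  expect_true(all(down$data[array(outside, g_big$shape)] == 0))
})

test_that("relative difference maps implement (x - y)/y with exclusions", {
  g <- tiny_geometry(6, 6)
  y <- image_volume(array(runif(216, 1, 2), g$shape), g)
  expect_equal(relative_difference_map(y, y)$mean, 0)
  expect_equal(relative_difference_map(y, y)$sd, 0)

  # forced scaling: x = 0.811 y -> mean relative difference -18.9 %
  x <- image_volume(0.811 * y$data, g)
  r <- relative_difference_map(x, y)
  expect_equal(r$mean, -0.189, tolerance = 1e-12)

  # x = 1.002 y -> +0.2 %
  r2 <- mean_relative_difference(image_volume(1.002 * y$data, g), y)
  expect_equal(r2$mean, 0.002, tolerance = 1e-9)

  # zero-valued reference voxels are excluded and counted
  y0 <- y; y0$data[1, 1, 1] <- 0
  r3 <- relative_difference_map(x, y0)
  expect_equal(r3$n_excluded, 1)
  expect_true(is.na(r3$map[1, 1, 1]))
  expect_error(relative_difference_map(x, y, array(FALSE, g$shape)), "empty")
})

test_that("two-compartment concentration ratio is recovered from recon", {
  inst <- recovery_instance()
  ph <- inst$phantom
  img <- inst$image
  m_low <- erode_mask(ph$labels == 1, 2)
  m_high <- erode_mask(ph$labels == 2, 2)
  ratio <- mean(img$data[m_high]) / mean(img$data[m_low])
  expect_lt(abs(ratio / (140 / 43) - 1), 0.05)
})

test_that("interleaved and single-nuclear reconstructions are bit-identical", {
  g <- tiny_geometry(12, 8)
  ph <- make_torso_phantom(
    g, list(compartment_spec("t", c(0, 0, 0), 36, 300, t1 = 35, t2star = 12)),
    "na")
  fields <- make_birdcage_field(g, "asymmetric")
  np <- 50
  params <- sequence_params("na", 82, 60, 1.15, 2, 5, np)
  params_h <- sequence_params("h", 10, c(13.08, 20.76), 2.5, 2, 2, 4 * np)
  traj <- build_trajectory(
    golden_angle_directions(np, "half"),
    da_radial_readout(nyquist_kmax(g), 40, 5, 0.2, "half"), g)
  a_il <- simulate_acquisition(ph, fields, traj,
                               build_interleaved_schedule(params, params_h),
                               noise_sigma = 3, seed = 21)
  a_sn <- simulate_acquisition(ph, fields, traj,
                               single_nuclear_schedule(params),
                               noise_sigma = 3, seed = 21)
  r_il <- combine_channels(reconstruct(a_il, traj))
  r_sn <- combine_channels(reconstruct(a_sn, traj))
  expect_identical(r_il$data, r_sn$data)
  d <- mean_relative_difference(r_il, r_sn, ph$m0 > 0)
  expect_identical(d$mean, 0)
})
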