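test_that("double-angle mapping inverts the sine model exactly", {
  g <- tiny_geometry(6, 6)
  mk <- function(x) image_volume(array(x, g$shape), g)

  # S_2a = 0 with S_a > 0 -> 90 degrees
  fm <- fa_map_double_angle(mk(1), mk(0))
  expect_true(all(fm$fa == 90))

  # true alpha = 60: ratio sin(120)/(2 sin(60)) = 1/2 -> 60 degrees
  fm60 <- fa_map_double_angle(mk(sin(pi / 3)), mk(sin(2 * pi / 3)))
  expect_equal(fm60$fa[1, 1, 1], 60, tolerance = 1e-12)

  # round trip across the working range
  alphas <- seq(10, 85, by = 2.5)
  fa_true <- array(rep_len(alphas, prod(g$shape)), g$shape)
  s1 <- mk(sin(fa_true * pi / 180))
  s2 <- mk(sin(2 * fa_true * pi / 180))
  rt <- fa_map_double_angle(s1, s2)
  expect_lt(max(abs(rt$fa - fa_true)), 1e-9)

  # zero-signal voxels are masked, not propagated
  s1z <- s1; s1z$data[1, 1, 1] <- 0
  fmz <- fa_map_double_angle(s1z, s2)
  expect_false(fmz$valid[1, 1, 1])
  expect_true(is.na(fmz$fa[1, 1, 1]))
})

test_that("AFI inverts the two-TR steady state", {
  g <- tiny_geometry(6, 6)
  mk <- function(x) image_volume(array(x, g$shape), g)
  n <- 75 / 15

  # r n = 1 -> 90 degrees; r = 1 -> 0 degrees
  expect_true(all(fa_map_afi(mk(1), mk(1 / n), 75, 15)$fa == 90))
  expect_true(all(fa_map_afi(mk(1), mk(1), 75, 15)$fa == 0))

  # Bloch steady-state oracle at 70 degrees, T1 = 1000 ms, TR 75/15 ms
  s <- afi_bloch_oracle(70, 1000, 75, 15)
  fm <- fa_map_afi(mk(s["s_long"]), mk(s["s_short"]), 75, 15)
  expect_lt(abs(fm$fa[1, 1, 1] - 70), 0.5)

  # across the protocol range the first-order inversion stays within 0.5 deg
  errs <- vapply(seq(10, 85, by = 5), function(fa) {
    ss <- afi_bloch_oracle(fa, 1000, 75, 15)
    abs(fa_map_afi(mk(ss["s_long"]), mk(ss["s_short"]), 75, 15)$fa[1] - fa)
  }, 0)
  expect_lt(max(errs), 0.5)

  expect_error(fa_map_afi(mk(1), mk(1), 15, 75), "exceed")
})

test_that("flip-angle error from noisy mapping scales with the noise level", {
  g <- tiny_geometry(8, 6)
  set.seed(14)
  fa_true <- array(runif(prod(g$shape), 30, 80), g$shape)
  err_at <- function(sigma) {
    s1 <- array(sin(fa_true * pi / 180) + rnorm(prod(g$shape), 0, sigma),
                g$shape)
    s2 <- array(sin(2 * fa_true * pi / 180) + rnorm(prod(g$shape), 0, sigma),
                g$shape)
    fm <- fa_map_double_angle(image_volume(abs(s1), g), image_volume(abs(s2), g))
    sqrt(mean((fm$fa[fm$valid] - fa_true[fm$valid])^2))
  }
  e1 <- err_at(0.001); e2 <- err_at(0.002)
  expect_lt(abs(e2 / e1 - 2), 0.5)   # error roughly proportional to sigma
})

test_that("receive maps recover the profile behind a known flip angle", {
  g <- grid_geometry(16, 6)
  xyz <- voxel_coordinates(g)
  rx_true <- array(1 + 0.3 * sin(2 * pi * xyz[, 1] / 96) +
                     0.2 * cos(2 * pi * xyz[, 2] / 96), g$shape)
  set.seed(8)
  fa_true <- array(runif(prod(g$shape), 40, 80), g$shape)
  signal <- image_volume(rx_true * sin(fa_true * pi / 180), g)
  fm <- fa_map(fa_true, g)
  b1m <- b1_minus_map(signal, fm)

  # S = B1- sin(FA): normalized map equals the normalized true profile
  ref <- rx_true / mean(rx_true[b1m$valid])
  expect_lt(sqrt(mean((b1m$map[b1m$valid] / ref[b1m$valid] - 1)^2)), 0.01)
  expect_equal(mean(b1m$map[b1m$valid]), 1, tolerance = 1e-12)

  # doubling the signal doubles the raw (unnormalized) map
  b1m2 <- b1_minus_map(image_volume(2 * signal$data, g), fm)
  expect_equal(b1m2$raw, 2 * b1m$raw, tolerance = 1e-12)
  expect_equal(b1m2$map, b1m$map, tolerance = 1e-12)

  # S = sin(FA) exactly -> constant map of 1
  b1c <- b1_minus_map(image_volume(array(sin(fa_true * pi / 180), g$shape), g), fm)
  expect_equal(b1c$map[b1c$valid], rep(1, sum(b1c$valid)), tolerance = 1e-12)

  # low flip angles are excluded from the valid mask
  fa_low <- fa_true; fa_low[1, 1, 1] <- 2
  b1l <- b1_minus_map(signal, fa_map(fa_low, g))
  expect_false(b1l$valid[1, 1, 1])
})

test_that("transmit efficiency implements FA / (2 pi gamma T U)", {
  g <- tiny_geometry(4, 6)
  fm <- fa_map(array(82, g$shape), g)
  eff <- b1_plus_efficiency(fm, t_pulse = 2, u_applied = 100,
                            gamma = GYRO_MHZ_PER_T[["na"]])
  # 82 deg, 2 ms, 100 V, 11.262 MHz/T -> ~101.1 nT/V
  expect_equal(eff$eta[1, 1, 1], 101.1, tolerance = 5e-4)

  expect_true(all(b1_plus_efficiency(fa_map(array(0, g$shape), g),
                                     2, 100, 11.262)$eta == 0))
  # doubling the voltage halves the efficiency for a fixed FA map
  eff2 <- b1_plus_efficiency(fm, 2, 200, GYRO_MHZ_PER_T[["na"]])
  expect_equal(eff2$eta, eff$eta / 2, tolerance = 1e-12)
  expect_error(b1_plus_efficiency(fm, -1, 100, 11.262), "positive")
})

test_that("relative channel maps normalize to the sum of magnitudes", {
  g <- tiny_geometry(6, 6)
  set.seed(4)
  mkc <- function() image_volume(
    array(complex(real = rnorm(216), imaginary = rnorm(216)), g$shape), g)

  # identical channels: each relative magnitude is 1/4
  a <- mkc()
  rel4 <- relative_channel_maps(list(a, a, a, a))
  expect_equal(Mod(rel4$maps[[1]][rel4$valid]),
               rep(0.25, sum(rel4$valid)), tolerance = 1e-12)

  # sum of relative magnitudes is 1 on valid voxels
  chans <- list(mkc(), mkc(), mkc())
  rel <- relative_channel_maps(chans)
  total <- Reduce(`+`, lapply(rel$maps, Mod))
  expect_equal(total[rel$valid], rep(1, sum(rel$valid)), tolerance = 1e-12)

  # ground truth recovered up to the per-voxel positive reference scale
  ref <- Reduce(`+`, lapply(chans, function(x) Mod(x$data)))
  for (i in 1:3)
    expect_equal(rel$maps[[i]][rel$valid],
                 (chans[[i]]$data / ref)[rel$valid], tolerance = 1e-12)
  expect_error(relative_channel_maps(chans[1]), "2 channels")
})

test_that("simulated flip-angle maps follow the small-tip pulse model", {
  inst <- ptx_instance()
  fields <- inst$fields

  # single channel, unit weight: FA proportional to |B1+|
  g <- fields$geometry
  one <- structure(list(geometry = g, tx_fields = fields$tx_fields[1],
                        rx_fields = fields$rx_fields[1], nucleus = "h"),
                   class = "channel_field_set")
  fa1 <- simulate_fa_map(one, u_ref = 50)
  b <- Mod(fields$tx_fields[[1]])
  expect_lt(max(abs(fa1$fa / b - mean(fa1$fa / b))) / mean(fa1$fa / b), 1e-9)

  # two identical channels double the flip angle of one
  two <- one; two$tx_fields <- list(fields$tx_fields[[1]], fields$tx_fields[[1]])
  fa2 <- simulate_fa_map(two, u_ref = 50)
  expect_equal(fa2$fa, pmin(2 * fa1$fa, 180), tolerance = 1e-9)

  # K = 1 kT pulse with zero blip reduces to the shim result
  w <- exp(1i * seq(0, 2, length.out = 8))
  shim <- shim_solution(w)
  kt1 <- kt_pulse(matrix(w, 1), matrix(0, 1, 3), subpulse_durations_ms = 2)
  fa_shim <- simulate_fa_map(fields, shim, u_ref = 20, t_pulse = 2)
  fa_kt <- simulate_fa_map(fields, kt1, u_ref = 20, t_pulse = 2)
  expect_equal(fa_kt$fa, fa_shim$fa, tolerance = 1e-12)

  # efficiency of a simulated map reproduces the field magnitude (Eq. 2
  # consistency): eta from FA at u_ref equals |sum_c B_c|
  fa_u <- simulate_fa_map(fields, NULL, u_ref = 10, t_pulse = 2)
  eff <- b1_plus_efficiency(fa_u, t_pulse = 2, u_applied = 10,
                            gamma = GYRO_MHZ_PER_T[["h"]])
  combined <- Mod(combine_tx_fields(fields))
  sel <- combined > 1e-6 & fa_u$fa < 179
  expect_lt(max(abs(eff$eta[sel] / combined[sel] - 1)), 1e-6)
})

test_that("flip-angle normalization fixes the ROI mean at one", {
  inst <- ptx_instance()
  fa <- simulate_fa_map(inst$fields, NULL, nominal_fa = 10)
  roi <- inst$roi
  norm <- normalize_fa(fa, roi)
  expect_equal(mean(norm$fa[roi]), 1, tolerance = 1e-12)
  expect_equal(cv(norm, roi), cv(fa, roi), tolerance = 1e-12)

  const <- normalize_fa(fa_map(array(7, inst$g$shape), inst$g), roi)
  expect_true(all(const$fa == 1))
  expect_error(normalize_fa(fa, array(FALSE, inst$g$shape)), "empty")
})
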