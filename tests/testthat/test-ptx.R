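test_that("phase-shim optimizer matches the exhaustive grid oracle", {
  # 2-channel instances with up to 4 voxels: exhaustive 1-degree search
  set.seed(31)
  for (i in 1:5) {
    nv <- sample(1:4, 1)
    A <- matrix(complex(real = rnorm(2 * nv), imaginary = rnorm(2 * nv)),
                ncol = 2)
    g <- grid_geometry(c(nv, 1, 1), 6)
    fields <- structure(
      list(geometry = g,
           tx_fields = lapply(1:2, function(c) array(A[, c], g$shape)),
           rx_fields = list(), nucleus = "h"),
      class = "channel_field_set")
    sol <- design_phase_shim(fields, array(TRUE, g$shape), n_restarts = 6,
                             seed = i)
    expect_lte(sol$cost, phase_grid_oracle_2ch(A) + 1e-3)
    expect_equal(Mod(sol$weights), c(1, 1), tolerance = 1e-12)
    expect_equal(Arg(sol$weights)[1], 0)   # gauge: first phase fixed
  }
})

test_that("degenerate shims behave per the gauge convention", {
  # single channel: any phase is equivalent; phi = 0 returned
  g <- grid_geometry(c(2, 2, 1), 6)
  one <- structure(
    list(geometry = g, tx_fields = list(array(1 + 1i, g$shape)),
         rx_fields = list(), nucleus = "h"),
    class = "channel_field_set")
  sol <- design_phase_shim(one, array(TRUE, g$shape))
  expect_equal(sol$weights, complex(real = 1))

  # 2 channels, 1 voxel, fields (1, -1): optimum realigns to magnitude 2
  g1 <- grid_geometry(c(1, 1, 1), 6)
  two <- structure(
    list(geometry = g1,
         tx_fields = list(array(1 + 0i, c(1, 1, 1)),
                          array(-1 + 0i, c(1, 1, 1))),
         rx_fields = list(), nucleus = "h"),
    class = "channel_field_set")
  sol2 <- design_phase_shim(two, array(TRUE, c(1, 1, 1)), n_restarts = 4,
                            seed = 2)
  combined <- Mod(sol2$weights[1] * 1 + sol2$weights[2] * (-1))
  expect_equal(combined, 2, tolerance = 1e-6)
  expect_error(design_phase_shim(two, array(FALSE, c(1, 1, 1))), "empty")
})

test_that("a global phase offset leaves every CV cost unchanged", {
  inst <- ptx_instance()
  ips <- design_phase_shim(inst$fields, inst$roi, n_restarts = 2, seed = 3)
  base <- cv(Mod(combine_tx_fields(inst$fields, ips$weights)), inst$roi)
  for (phi0 in c(0.7, 2.1, -1.3)) {
    rotated <- cv(Mod(combine_tx_fields(inst$fields,
                                        ips$weights * exp(1i * phi0))),
                  inst$roi)
    expect_equal(rotated, base, tolerance = 1e-12)
  }
})

test_that("universal shims relate to individual shims as a library optimum", {
  inst <- ptx_instance()
  lib1 <- subject_library(list(list(fields = inst$fields, roi = inst$roi)))
  ips <- design_phase_shim(inst$fields, inst$roi, n_restarts = 6, seed = 5)
  ups1 <- design_universal_shim(lib1, n_restarts = 6, seed = 5)
  # a one-subject library reduces to the individual problem
  expect_lt(abs(ups1$cost - ips$cost), 1e-6)

  g <- inst$g
  lib <- make_subject_library(g, n_subjects = 4, n_ch = 8, seed = 77)
  ups <- design_universal_shim(lib, n_restarts = 4, seed = 6)
  # on any individual the universal shim cannot beat that subject's shim
  for (s in lib$subjects[1:2]) {
    A <- vapply(s$fields$tx_fields, function(f) f[which(s$roi)],
                complex(sum(s$roi)))
    cv_ups <- cv_pop(Mod(A %*% ups$weights))
    own <- design_phase_shim(s$fields, s$roi, n_restarts = 6, seed = 8)
    expect_gte(cv_ups, own$cost - 1e-9)
  }

  # permutation of the library leaves the achieved cost unchanged
  lib_perm <- subject_library(rev(lib$subjects))
  ups_perm <- design_universal_shim(lib_perm, n_restarts = 4, seed = 6)
  expect_lt(abs(ups_perm$cost - ups$cost), 1e-6)

  # determinism under a fixed seed
  ups_again <- design_universal_shim(lib, n_restarts = 4, seed = 6)
  expect_identical(ups$weights, ups_again$weights)
})

test_that("kT-points designs dominate phase shims and nest in K", {
  inst <- ptx_instance()
  ips <- design_phase_shim(inst$fields, inst$roi, n_restarts = 6, seed = 1)

  # K = 1, zero blip: a complex-weight shim, at least as good as phase-only
  kt1 <- design_kt_points(inst$fields, inst$roi, K = 1, seed = 1)
  expect_lte(kt1$cost, ips$cost + 1e-9)
  expect_true(all(kt1$blips == 0))

  # nested candidate blips: cost is monotone non-increasing in K
  costs <- vapply(1:4, function(K)
    design_kt_points(inst$fields, inst$roi, K = K, seed = 1)$cost, 0)
  expect_true(all(diff(costs) <= 1e-9))

  # determinism
  kt_a <- design_kt_points(inst$fields, inst$roi, K = 3, seed = 1)
  kt_b <- design_kt_points(inst$fields, inst$roi, K = 3, seed = 1)
  expect_identical(kt_a$weights, kt_b$weights)
})

test_that("kT-points design is scale-homogeneous in the transmit maps", {
  inst <- ptx_instance()
  kt <- design_kt_points(inst$fields, inst$roi, K = 2, seed = 4)
  c0 <- 2.5
  scaled <- inst$fields
  scaled$tx_fields <- lapply(scaled$tx_fields, function(f) c0 * f)
  kt_s <- design_kt_points(scaled, inst$roi, K = 2, seed = 4)
  expect_equal(kt_s$weights, kt$weights / c0, tolerance = 1e-3)

  fa <- normalize_fa(simulate_fa_map(inst$fields, kt), inst$roi)
  fa_s <- normalize_fa(simulate_fa_map(scaled, kt_s), inst$roi)
  expect_equal(fa_s$fa, fa$fa, tolerance = 1e-4)
})

test_that("the pulse hierarchy orders DPS, UPS, IPS and 4kT", {
  inst <- ptx_instance()
  lib <- make_subject_library(inst$g, n_subjects = 5, n_ch = 8, seed = 42)
  ups <- design_universal_shim(lib, n_restarts = 6, seed = 2)
  ips <- design_phase_shim(inst$fields, inst$roi, n_restarts = 6, seed = 2,
                           extra_starts = list(Arg(ups$weights)[-1]))
  kt <- design_kt_points(inst$fields, inst$roi, K = 4, seed = 2)

  cv_of <- function(w) cv(Mod(combine_tx_fields(inst$fields, w)), inst$roi)
  cv_dps <- cv_of(rep(1 + 0i, 8))
  cv_ups <- cv_of(ups$weights)
  cv_ips <- ips$cost
  cv_kt <- kt$cost
  expect_lte(cv_kt, cv_ips + 1e-9)
  expect_lte(cv_ips, cv_ups + 1e-9)
  expect_lte(cv_ups, cv_dps + 1e-9)
})

test_that("reference-voltage calibration is an exact least-squares fit", {
  # noiseless data on the printed calibration line
  w <- seq(50, 100, by = 5)
  u <- 9.4 * w + 542.5
  fit <- reference_voltage_fit(w, u)
  expect_equal(fit$slope_v_per_kg, 9.4, tolerance = 1e-12)
  expect_equal(fit$intercept_v, 542.5, tolerance = 1e-12)
  expect_equal(fit$predict(70), 1200.5, tolerance = 1e-9)
  expect_equal(fit$mean_rel_abs_dev, 0, tolerance = 1e-12)
  expect_equal(fit$correlation, 1, tolerance = 1e-12)

  # degenerate designs rejected
  expect_error(reference_voltage_fit(c(70, 70), c(1200, 1300)), "degenerate")
  expect_error(reference_voltage_fit(70, 1200), ">= 2")
})

test_that("pulses survive a YAML round trip", {
  w <- exp(1i * c(0, 0.4, 1.1, 2.2))
  shim <- shim_solution(w, cost = 0.123)
  p1 <- tempfile(fileext = ".yaml")
  write_pulse(shim, p1)
  back <- read_pulse(p1)
  expect_equal(back$weights, shim$weights, tolerance = 1e-12)
  expect_equal(back$cost, 0.123)

  kt <- kt_pulse(matrix(complex(real = rnorm(8), imaginary = rnorm(8)), 2),
                 matrix(c(0.01, 0, 0, 0, -0.01, 0), 2, byrow = TRUE),
                 subpulse_durations_ms = c(0.4, 0.47), cost = 0.05)
  p2 <- tempfile(fileext = ".yaml")
  write_pulse(kt, p2)
  back2 <- read_pulse(p2)
  expect_equal(back2$weights, kt$weights, tolerance = 1e-12)
  expect_equal(back2$blips, kt$blips, tolerance = 1e-12)
  expect_equal(back2$total_duration_ms, 0.87, tolerance = 1e-12)
  unlink(c(p1, p2))
})
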