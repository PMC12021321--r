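# Shared fixtures, built in code. Heavy objects are memoised so that the
# module tests and the acceptance suite share one computation.

tiny_geometry <- function(n = 8, voxel = 6) grid_geometry(n, voxel)

random_kcoords <- function(n, geometry, seed = 1) {
  set.seed(seed)
  sweep(matrix(runif(3 * n, -0.5, 0.5), ncol = 3), 2,
        geometry$voxel_size, `/`)
}

local_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = local_cache)) {
    assign(key, force(expr), envir = local_cache)
  }
  get(key, envir = local_cache)
}

# fields + heart ROI used by the pTx tests
ptx_instance <- function() {
  cached("ptx_instance", {
    g <- grid_geometry(16, 6)
    fields <- make_array_fields(g, n_ch = 8, seed = 7)
    roi <- ellipsoid_mask(g, c(-0.05, 0.05, 0) * g$fov, 0.22 * g$fov)
    list(g = g, fields = fields, roi = roi)
  })
}

# the full demo pipeline report (shared by demo and acceptance tests)
demo_report <- function() {
  cached("demo_report", run_demo())
}

# simulate -> reconstruct a two-compartment phantom at adequate sampling;
# shared by the recon module test and the acceptance suite
recovery_instance <- function() {
  cached("recovery_instance", {
    g <- grid_geometry(32, 3)
    comps <- list(
      compartment_spec("low", c(-26, 0, 0), 24, 43, t1 = 35, t2star = 1e6),
      compartment_spec("high", c(26, 0, 0), 24, 140, t1 = 35, t2star = 1e6))
    ph <- make_torso_phantom(g, comps, "na")
    fields <- make_birdcage_field(g, "uniform")
    np <- 2200
    ns <- recommended_n_samples(nyquist_kmax(g), g$fov[1])
    params <- sequence_params("na", 82, 60, 1.15, 2, 5, np)
    sched <- single_nuclear_schedule(params)
    traj <- build_trajectory(
      golden_angle_directions(np, "half"),
      da_radial_readout(nyquist_kmax(g), ns, 5, 0.2, "half"), g)
    acq <- simulate_acquisition(ph, fields, traj, sched, noise_sigma = 0,
                                nufft_width = 8L)
    img <- combine_channels(reconstruct(acq, traj, nufft_width = 8L))
    list(geometry = g, phantom = ph, image = img)
  })
}
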