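#' Write / read an image volume as NIfTI
#'
#' Magnitude (real) volumes are written directly; complex volumes are
#' written as a magnitude/phase file pair with \code{_mag}/\code{_phase}
#' suffixes. Voxel size is stored in the NIfTI pixdim and restored on
#' read; the grid is re-centred on the origin when reading (the package's
#' k-space-centre convention).
#'
#' @param img an \code{image_volume}.
#' @param path output path (.nii or .nii.gz); for complex data the
#'   suffixed pair is derived from it.
#' @return \code{write_nifti}: the path(s), invisibly;
#'   \code{read_nifti}: an \code{image_volume}.
#' @export
write_nifti <- function(img, path) {
  as_nifti <- function(arr) {
    nif <- RNifti::asNifti(arr)
    RNifti::`pixdim<-`(nif, img$geometry$voxel_size)
  }
  if (is.complex(img$data)) {
    pm <- sub("(\\.nii(\\.gz)?)$", "_mag\\1", path)
    pp <- sub("(\\.nii(\\.gz)?)$", "_phase\\1", path)
    RNifti::writeNifti(as_nifti(Mod(img$data)), pm)
    RNifti::writeNifti(as_nifti(Arg(img$data)), pp)
    return(invisible(c(pm, pp)))
  }
  RNifti::writeNifti(as_nifti(img$data), path)
  invisible(path)
}

#' @rdname write_nifti
#' @param nucleus optional nucleus tag for the returned volume.
#' @export
read_nifti <- function(path, nucleus = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  nif <- RNifti::readNifti(path)
  data <- array(as.numeric(nif), dim = dim(nif))
  vs <- RNifti::pixdim(nif)[seq_len(3)]
  image_volume(data, grid_geometry(dim(data), vs), nucleus)
}

#' Default run configuration
#'
#' Nested configuration mirroring the acquisition-parameter table of the
#' interleaved protocol (per-nucleus resolution, flip angle, TRs, TE,
#' pulse and readout durations, projection counts) plus the mapping
#' protocols and the desk-scale simulation sizes used by
#' \code{\link{run_demo}}.
#'
#' @return nested named list.
#' @export
default_run_config <- function() {
  list(
    interleaved = list(
      n_h_per_tr = 4,
      na = list(resolution_mm = 6, fa_deg = 82, tr_ms = 60, te_ms = 1.15,
                t_pulse_ms = 2, t_ro_ms = 5, projections = 15000),
      h = list(resolution_mm = 2, fa_deg = 10,
               tr_a_ms = 13.08, tr_b_ms = 20.76, te_ms = 2.5,
               t_pulse_ms = 2, t_ro_ms = 2, projections = 60000)),
    double_angle = list(resolution_mm = 12, fa_deg = c(45, 90), tr_ms = 250,
                        te_ms = 1.15, t_pulse_ms = 2, t_ro_ms = 5,
                        projections = 4000),
    afi = list(resolution_mm = 4, fa_deg = 70, tr_long_ms = 75,
               tr_short_ms = 15, te_ms = 3.03, t_pulse_ms = 1,
               t_ro_ms = 2.5, projections = 7500),
    rel_b1 = list(resolution_mm = 4, fa_deg = 8, tr_ms = 4.5, te_ms = 2.02,
                  t_pulse_ms = 0.5, t_ro_ms = 2.5, projections = 10000,
                  n_channels = 8),
    rf_limits = list(h_channel_limit_w = 1.195, impedance_ohm = 50),
    phantom = list(fov_mm = 96, na_concentration_mm = 300),
    sim = list(
      na = list(grid = 16, n_proj = 400, n_samples = 136, noise_sigma = 6000),
      h = list(grid = 24, resolution_mm = 4, n_proj = 1600, n_samples = 256,
               noise_sigma = 1),
      n_library_subjects = 5,
      subject_weight_kg = 70,
      nufft_width = 6,
      seed = 1),
    ptx = list(n_restarts = 6, kt_points = 4))
}

#' Validate a run configuration
#'
#' Checks physical plausibility of the configuration tree (positive
#' durations, flip angles within (0, 180], positive counts) and the
#' interleave timing identity. Errors name the offending key path.
#'
#' @param config nested list as from \code{\link{default_run_config}}.
#' @return the config, invisibly, if valid.
#' @export
validate_run_config <- function(config) {
  fail <- function(path, msg) stop("config error at ", path, ": ", msg,
                                   call. = FALSE)
  need_pos <- function(x, path) {
    if (is.null(x) || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
      fail(path, "must be a positive number")
  }
  need_fa <- function(x, path) {
    need_pos(x, path)
    if (any(x > 180)) fail(path, "flip angle exceeds 180 degrees")
  }
  il <- config$interleaved
  if (is.null(il)) fail("interleaved", "section missing")
  need_pos(il$na$tr_ms, "interleaved.na.tr_ms")
  need_pos(il$na$projections, "interleaved.na.projections")
  need_fa(il$na$fa_deg, "interleaved.na.fa_deg")
  need_fa(il$h$fa_deg, "interleaved.h.fa_deg")
  need_pos(il$h$tr_a_ms, "interleaved.h.tr_a_ms")
  need_pos(il$h$tr_b_ms, "interleaved.h.tr_b_ms")
  need_pos(il$n_h_per_tr, "interleaved.n_h_per_tr")
  identity_gap <- (il$n_h_per_tr - 1) * il$h$tr_a_ms + il$h$tr_b_ms -
    il$na$tr_ms
  if (abs(identity_gap) > 1e-6)
    fail("interleaved.h", sprintf(
      "1H TR pattern does not fill the 23Na TR (off by %.4g ms)", identity_gap))
  if (il$h$projections != il$n_h_per_tr * il$na$projections)
    fail("interleaved.h.projections",
         "must equal n_h_per_tr * na.projections")
  for (sec in c("double_angle", "afi", "rel_b1")) {
    s <- config[[sec]]
    if (is.null(s)) fail(sec, "section missing")
    need_pos(s$projections, paste0(sec, ".projections"))
    need_fa(s$fa_deg, paste0(sec, ".fa_deg"))
  }
  need_pos(config$afi$tr_long_ms, "afi.tr_long_ms")
  need_pos(config$afi$tr_short_ms, "afi.tr_short_ms")
  if (config$afi$tr_long_ms <= config$afi$tr_short_ms)
    fail("afi", "tr_long_ms must exceed tr_short_ms")
  need_pos(config$rf_limits$h_channel_limit_w, "rf_limits.h_channel_limit_w")
  invisible(config)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return \code{read_run_config}: validated config list (missing keys
#'   filled from \code{\link{default_run_config}}).
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  validate_run_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param config configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Protocol timing arithmetic
#'
#' Total durations of the acquisition protocols implied by a
#' configuration: the interleaved scan (n_Na projections x TR_Na), the
#' double-angle protocol per flip angle (n x TR), the two-TR AFI protocol
#' (n x (TR_long + TR_short)) and the channel-wise relative transmit
#' mapping (n_ch x n x TR).
#'
#' @param config configuration list (default
#'   \code{\link{default_run_config}}).
#' @return list of durations in seconds: \code{interleaved_s},
#'   \code{double_angle_per_fa_s}, \code{afi_s}, \code{rel_b1_s}, plus
#'   \code{h_projections} and \code{h_tr_pattern_sum_ms}.
#' @export
protocol_timings <- function(config = default_run_config()) {
  il <- config$interleaved
  list(
    interleaved_s = il$na$projections * il$na$tr_ms / 1000,
    h_projections = il$n_h_per_tr * il$na$projections,
    h_tr_pattern_sum_ms = (il$n_h_per_tr - 1) * il$h$tr_a_ms + il$h$tr_b_ms,
    double_angle_per_fa_s = config$double_angle$projections *
      config$double_angle$tr_ms / 1000,
    afi_s = config$afi$projections *
      (config$afi$tr_long_ms + config$afi$tr_short_ms) / 1000,
    rel_b1_s = config$rel_b1$n_channels * config$rel_b1$projections *
      config$rel_b1$tr_ms / 1000)
}
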