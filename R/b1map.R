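#' Flip-angle map container
#'
#' @param fa degrees per voxel (3D array).
#' @param geometry a \code{grid_geometry}.
#' @param nominal_fa nominal flip angle, degrees.
#' @param valid logical array of valid voxels.
#' @return object of class \code{fa_map}.
#' @export
fa_map <- function(fa, geometry, nominal_fa = NA_real_, valid = NULL) {
  if (is.null(valid)) valid <- is.finite(fa)
  if (!all(dim(fa) == geometry$shape)) stop("fa dimensions do not match geometry")
  v <- fa[valid]
  if (length(v) && (min(v) < 0 || max(v) > 180))
    stop("flip angles must lie in [0, 180] degrees on valid voxels")
  structure(list(fa = fa, geometry = geometry, nominal_fa = nominal_fa,
                 valid = valid),
            class = "fa_map")
}

#' Double-angle flip-angle mapping
#'
#' Two magnitude acquisitions at nominal flip angles alpha and 2*alpha with
#' a long repetition time give \eqn{S_\alpha \propto \sin\alpha},
#' \eqn{S_{2\alpha} \propto \sin 2\alpha}, so
#' \deqn{FA = \arccos\!\left(\frac{S_{2\alpha}}{2 S_\alpha}\right).}
#' Voxels with \eqn{S_\alpha = 0} or |ratio| > 1 are masked invalid. The T1
#' bias of the method is ignored (long-TR regime, TR = 250 ms for the
#' sodium protocol).
#'
#' @param img_alpha magnitude \code{image_volume} at flip angle alpha.
#' @param img_2alpha magnitude \code{image_volume} at flip angle 2*alpha.
#' @param nominal_fa nominal alpha, degrees (metadata only).
#' @return an \code{fa_map} (degrees).
#' @export
fa_map_double_angle <- function(img_alpha, img_2alpha, nominal_fa = NA_real_) {
  if (!same_geometry(img_alpha$geometry, img_2alpha$geometry))
    stop("geometries differ")
  s1 <- Mod(img_alpha$data)
  s2 <- Mod(img_2alpha$data)
  ratio <- ifelse(s1 > 0, s2 / (2 * s1), NA_real_)
  valid <- is.finite(ratio) & abs(ratio) <= 1
  fa <- array(NA_real_, dim = dim(s1))
  fa[valid] <- acos(ratio[valid]) * 180 / pi
  fa_map(fa, img_alpha$geometry, nominal_fa, valid)
}

#' Actual flip angle imaging (AFI)
#'
#' Two excitations cycle with alternating repetition delays. With
#' \eqn{n = TR_{long}/TR_{short}} and \eqn{r} the ratio of the signal
#' acquired after the short delay to that acquired after the long delay,
#' the steady state gives (to first order in TR/T1)
#' \deqn{\cos FA = \frac{r n - 1}{n - r}.}
#' Arguments are keyed explicitly on (long, short) because protocol tables
#' sometimes list the long interval first.
#'
#' @param img_tr_long magnitude \code{image_volume}: the excitation
#'   \emph{following} the long delay (the more recovered signal).
#' @param img_tr_short magnitude \code{image_volume}: the excitation
#'   following the short delay.
#' @param tr_long,tr_short the two repetition delays, ms
#'   (\code{tr_long > tr_short > 0}).
#' @param nominal_fa nominal flip angle, degrees (metadata only).
#' @return an \code{fa_map} (degrees); voxels with |argument| > 1 or zero
#'   denominators masked invalid.
#' @export
fa_map_afi <- function(img_tr_long, img_tr_short, tr_long, tr_short,
                       nominal_fa = NA_real_) {
  if (!(tr_long > tr_short && tr_short > 0))
    stop("'tr_long' must exceed 'tr_short' > 0")
  if (!same_geometry(img_tr_long$geometry, img_tr_short$geometry))
    stop("geometries differ")
  n <- tr_long / tr_short
  s_long <- Mod(img_tr_long$data)   # signal after the long delay
  s_short <- Mod(img_tr_short$data) # signal after the short delay
  r <- ifelse(s_long > 0, s_short / s_long, NA_real_)
  arg <- (r * n - 1) / (n - r)
  valid <- is.finite(arg) & abs(arg) <= 1
  fa <- array(NA_real_, dim = dim(s_long))
  fa[valid] <- acos(arg[valid]) * 180 / pi
  fa_map(fa, img_tr_long$geometry, nominal_fa, valid)
}

#' Relative receive-sensitivity map
#'
#' In a sample of homogeneous spin density the measured signal factorizes
#' into transmit (through sin FA) and receive profiles, so
#' \deqn{B_1^-(x) \propto S(x)/\sin(FA(x)).}
#' The proportionality constant is not observable; the map is normalized
#' to mean 1 over the valid mask. Voxels with FA outside
#' [\code{fa_min}, 180 - \code{fa_min}] degrees are masked to avoid the
#' sin(FA) blow-up.
#'
#' @param signal magnitude \code{image_volume}.
#' @param fa an \code{fa_map} on the same geometry.
#' @param fa_min validity threshold, degrees (default 5).
#' @return list: \code{map} (array, NA invalid; mean 1 over valid),
#'   \code{raw} (unnormalized S/sin(FA)), \code{valid} (logical array).
#' @export
b1_minus_map <- function(signal, fa, fa_min = 5) {
  if (!same_geometry(signal$geometry, fa$geometry)) stop("geometries differ")
  valid <- fa$valid & is.finite(fa$fa) &
    fa$fa >= fa_min & fa$fa <= 180 - fa_min
  if (!any(valid)) stop("no valid voxels for the receive map")
  raw <- array(NA_real_, dim = dim(fa$fa))
  raw[valid] <- Mod(signal$data)[valid] / sin(fa$fa[valid] * pi / 180)
  m <- mean(raw[valid])
  if (m == 0) stop("degenerate signal: mean receive profile is zero")
  list(map = raw / m, raw = raw, valid = valid)
}

#' Transmit-field efficiency from a flip-angle map
#'
#' \deqn{\eta(x) = \frac{B_1^+(x)}{U_{applied}}
#'   = \frac{FA(x)}{2\pi\gamma\, T_{pulse}\, U_{applied}}}
#' for a rectangular pulse, with FA in radians, gamma the reduced
#' gyromagnetic ratio (MHz/T), T_pulse in ms and U in volts; reported in
#' nT/V.
#'
#' @param fa an \code{fa_map} (degrees).
#' @param t_pulse pulse duration, ms (> 0).
#' @param u_applied applied pulse voltage, V (> 0).
#' @param gamma gyromagnetic ratio, MHz/T (> 0); see
#'   \code{\link{GYRO_MHZ_PER_T}}.
#' @return object of class \code{efficiency_map}: \code{eta} (nT/V array),
#'   \code{geometry}, \code{u_applied}, \code{t_pulse}, \code{gamma},
#'   \code{valid}.
#' @export
b1_plus_efficiency <- function(fa, t_pulse, u_applied, gamma) {
  if (t_pulse <= 0 || u_applied <= 0 || gamma <= 0)
    stop("'t_pulse', 'u_applied' and 'gamma' must be positive")
  fa_rad <- fa$fa * pi / 180
  # 2*pi*gamma[Hz/T] * T_pulse[s] * U[V]; result T/V -> nT/V
  eta_t_per_v <- fa_rad / (2 * pi * gamma * 1e6 * t_pulse * 1e-3 * u_applied)
  structure(
    list(eta = eta_t_per_v * 1e9, geometry = fa$geometry,
         u_applied = u_applied, t_pulse = t_pulse, gamma = gamma,
         valid = fa$valid),
    class = "efficiency_map")
}

#' Relative channel-wise transmit maps
#'
#' Divides each complex channel image by the voxelwise sum of channel
#' magnitudes, giving per-channel relative magnitude and phase with the
#' sum-of-magnitudes as common reference (so the relative magnitudes sum
#' to 1 on valid voxels). The absolute transmit scale is not recoverable
#' from relative maps.
#'
#' @param channel_images list of complex \code{image_volume}s, one per
#'   transmit channel (>= 2).
#' @return list: \code{maps} (list of complex arrays, NA where the
#'   reference is zero), \code{valid} (logical array).
#' @export
relative_channel_maps <- function(channel_images) {
  if (length(channel_images) < 2) stop("at least 2 channels required")
  g <- channel_images[[1]]$geometry
  ref <- array(0, g$shape)
  for (im in channel_images) {
    if (!same_geometry(im$geometry, g)) stop("channel geometries differ")
    ref <- ref + Mod(im$data)
  }
  valid <- ref > 0
  maps <- lapply(channel_images, function(im) {
    out <- array(NA_complex_, g$shape)
    out[valid] <- im$data[valid] / ref[valid]
    out
  })
  list(maps = maps, valid = valid, geometry = g)
}

#' Simulate a flip-angle map from channel transmit maps and a pulse
#'
#' Small-tip-angle model. For a phase/amplitude shim with per-channel
#' complex weights \eqn{w_c},
#' \deqn{FA(x) = 2\pi\gamma\, T_{pulse} U_{ref}\,
#'   \bigl|\textstyle\sum_c w_c B_{1,c}^+(x)\bigr|;}
#' for a kT-points pulse of K rectangular sub-pulses with weights
#' \eqn{w_{c,k}} and excitation k-space offsets \eqn{\kappa_k} (cycles/mm),
#' the sub-pulse contributions add with the spatial phase
#' \eqn{e^{2\pi i \kappa_k \cdot x}}:
#' \deqn{FA(x) \propto \bigl|\sum_k \sum_c w_{c,k} B_{1,c}^+(x)
#'   e^{2\pi i\kappa_k\cdot x}\bigr|.}
#'
#' With \code{pulse = NULL} the channels are summed with unit weights.
#' If \code{nominal_fa} is given the map is instead calibrated so that the
#' mean FA over \code{support} (or the whole grid) equals the nominal
#' value, mirroring a transmitter voltage adjustment; otherwise the
#' physical scaling with \code{u_ref} volts is used.
#'
#' @param channel_maps a \code{channel_field_set} (transmit fields, nT/V).
#' @param pulse a \code{shim_solution}, \code{kt_pulse}, or NULL.
#' @param u_ref reference voltage, V.
#' @param t_pulse pulse duration, ms; defaults to the pulse's own duration
#'   or 2 ms.
#' @param gamma gyromagnetic ratio MHz/T; default chosen from
#'   \code{channel_maps$nucleus}.
#' @param nominal_fa if non-NULL, calibrate mean FA over \code{support} to
#'   this value (degrees).
#' @param support logical array used for the calibration mean.
#' @return an \code{fa_map} (degrees).
#' @export
simulate_fa_map <- function(channel_maps, pulse = NULL, u_ref = 100,
                            t_pulse = NULL, gamma = NULL,
                            nominal_fa = NULL, support = NULL) {
  g <- channel_maps$geometry
  gamma <- if (is.null(gamma)) GYRO_MHZ_PER_T[[channel_maps$nucleus]] else gamma
  field <- combined_pulse_field(channel_maps, pulse)
  t_p <- if (!is.null(t_pulse)) t_pulse
         else if (!is.null(pulse) && !is.null(pulse$total_duration_ms)) pulse$total_duration_ms
         else 2
  # |field| in nT/V -> FA in radians at u_ref volts
  fa_rad <- 2 * pi * gamma * 1e6 * (Mod(field) * 1e-9) * t_p * 1e-3 * u_ref
  if (!is.null(nominal_fa)) {
    if (is.null(support) || !any(support)) support <- array(TRUE, g$shape)
    m <- mean(fa_rad[support])
    if (m <= 0) stop("cannot calibrate: zero mean field over support")
    fa_rad <- fa_rad * (nominal_fa * pi / 180) / m
  }
  fa_deg <- pmin(fa_rad * 180 / pi, 180)
  fa_map(fa_deg, g, nominal_fa = if (is.null(nominal_fa)) NA_real_ else nominal_fa)
}

# complex combined transmit field for a shim / kT-points pulse / unit sum
combined_pulse_field <- function(channel_maps, pulse) {
  if (is.null(pulse)) return(combine_tx_fields(channel_maps))
  if (inherits(pulse, "shim_solution"))
    return(combine_tx_fields(channel_maps, pulse$weights))
  if (inherits(pulse, "kt_pulse")) {
    g <- channel_maps$geometry
    xyz <- voxel_coordinates(g)
    out <- array(0i, g$shape)
    for (k in seq_len(pulse$K)) {
      ph <- array(exp(2i * pi * as.vector(xyz %*% pulse$blips[k, ])), g$shape)
      out <- out + combine_tx_fields(channel_maps, pulse$weights[k, ]) * ph
    }
    return(out)
  }
  stop("'pulse' must be NULL, a shim_solution or a kt_pulse")
}

#' Normalize a flip-angle map to its ROI mean
#'
#' Divides by the mean flip angle inside the region of interest so the ROI
#' mean becomes exactly 1; the coefficient of variation is unchanged.
#'
#' @param fa an \code{fa_map}.
#' @param roi_mask non-empty logical array.
#' @return an \code{fa_map}-like object whose \code{fa} is dimensionless.
#' @export
normalize_fa <- function(fa, roi_mask) {
  sel <- roi_mask & fa$valid
  if (!any(sel)) stop("ROI is empty (or contains no valid voxels)")
  m <- mean(fa$fa[sel])
  if (m == 0) stop("ROI mean flip angle is zero")
  out <- fa
  out$fa <- fa$fa / m
  out$normalized <- TRUE
  class(out) <- class(fa)
  out
}
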