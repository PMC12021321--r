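#' Sequence parameter set for one nucleus
#'
#' Excitation/readout parameters of a spoiled 3D radial acquisition for one
#' nucleus. For the proton channel of the interleaved scheme the repetition
#' time alternates between two classes: \code{tr_a} between consecutive 1H
#' projections inside one sodium period and \code{tr_b} for the last 1H
#' projection, which absorbs the sodium excitation/readout block, so that
#' \code{(n_h_per_tr - 1) * tr_a + tr_b = tr_na}.
#'
#' @param nucleus \code{"na"} or \code{"h"}.
#' @param nominal_fa nominal flip angle, degrees (0 < fa <= 180).
#' @param tr repetition time, ms. For 1H pass \code{tr = c(tr_a, tr_b)}.
#' @param te echo time, ms.
#' @param t_pulse excitation pulse duration, ms.
#' @param t_ro readout duration, ms.
#' @param n_proj number of projections.
#' @param resolution_mm nominal isotropic resolution, mm.
#' @return object of class \code{sequence_params}.
#' @export
sequence_params <- function(nucleus = c("na", "h"), nominal_fa, tr, te,
                            t_pulse, t_ro, n_proj, resolution_mm = NULL) {
  nucleus <- match.arg(nucleus)
  if (nominal_fa <= 0 || nominal_fa > 180) stop("'nominal_fa' must be in (0, 180]")
  if (any(tr <= 0)) stop("'tr' must be positive")
  if (te < t_pulse / 2) stop("'te' must be >= t_pulse/2")
  if (n_proj < 1) stop("'n_proj' must be >= 1")
  structure(
    list(nucleus = nucleus, nominal_fa = nominal_fa, tr = as.numeric(tr),
         te = te, t_pulse = t_pulse, t_ro = t_ro,
         n_proj = as.integer(n_proj), resolution_mm = resolution_mm),
    class = "sequence_params")
}

#' Default interleaved sequence parameters
#'
#' The acquisition parameters of the interleaved 23Na/1H protocol: sodium at
#' (6 mm)^3, flip angle 82 deg, TR 60 ms, TE 1.15 ms, 15 000 half
#' projections; proton at (2 mm)^3, flip angle 10 deg, TR pair
#' 13.08/20.76 ms, TE 2.5 ms, 60 000 full projections.
#'
#' @return named list with elements \code{na} and \code{h}
#'   (\code{sequence_params}).
#' @export
default_interleaved_params <- function() {
  list(
    na = sequence_params("na", nominal_fa = 82, tr = 60, te = 1.15,
                         t_pulse = 2, t_ro = 5, n_proj = 15000L,
                         resolution_mm = 6),
    h = sequence_params("h", nominal_fa = 10, tr = c(13.08, 20.76),
                        te = 2.5, t_pulse = 2, t_ro = 2, n_proj = 60000L,
                        resolution_mm = 2))
}

#' Build the interleaved dual-nuclear event schedule
#'
#' Each sodium repetition period opens with one 23Na excitation/readout;
#' the remaining idle time carries \code{n_h_per_tr} 1H projections. The 1H
#' repetition times within one period follow the pattern
#' (tr_a, ..., tr_a, tr_b) by default -- tr_b, the longer interval, absorbs
#' the sodium block -- giving the identity
#' \code{(n_h_per_tr - 1) * tr_a + tr_b = tr_na}. Whether tr_b comes last
#' or first in the period is configurable (\code{order}); both satisfy the
#' identity.
#'
#' @param params_na \code{sequence_params} for 23Na.
#' @param params_h \code{sequence_params} for 1H with \code{tr = c(tr_a,
#'   tr_b)}; \code{params_h$n_proj} must equal
#'   \code{n_h_per_tr * params_na$n_proj}.
#' @param n_h_per_tr 1H projections per sodium TR (>= 0).
#' @param order \code{"aab"} (tr_b last, default) or \code{"baa"}.
#' @return object of class \code{interleave_schedule}: \code{events}
#'   (data.frame: t_start_ms, nucleus, projection_index, tr_class),
#'   \code{n_h_per_tr}, \code{total_duration_s}, \code{params_na},
#'   \code{params_h}.
#' @examples
#' p <- default_interleaved_params()
#' s <- build_interleaved_schedule(p$na, p$h)
#' s$total_duration_s  # 900
#' @export
build_interleaved_schedule <- function(params_na, params_h = NULL,
                                       n_h_per_tr = 4L,
                                       order = c("aab", "baa")) {
  order <- match.arg(order)
  n_h_per_tr <- as.integer(n_h_per_tr)
  if (n_h_per_tr < 0L) stop("'n_h_per_tr' must be >= 0")
  if (n_h_per_tr > 0L) {
    if (is.null(params_h)) stop("'params_h' required when n_h_per_tr > 0")
    if (params_h$n_proj != n_h_per_tr * params_na$n_proj)
      stop(sprintf(
        "projection-count mismatch: %d 1H projections != %d per TR x %d 23Na projections",
        params_h$n_proj, n_h_per_tr, params_na$n_proj))
  }
  tr_na <- params_na$tr[1]
  n_na <- params_na$n_proj
  t_period <- (seq_len(n_na) - 1) * tr_na

  na_events <- data.frame(
    t_start_ms = t_period, nucleus = "na",
    projection_index = seq_len(n_na), tr_class = "na",
    stringsAsFactors = FALSE)

  if (n_h_per_tr > 0L) {
    tr_a <- params_h$tr[1]
    tr_b <- if (length(params_h$tr) >= 2) params_h$tr[2]
            else tr_na - (n_h_per_tr - 1) * tr_a
    if (abs((n_h_per_tr - 1) * tr_a + tr_b - tr_na) > 1e-6)
      stop(sprintf(
        "1H TR pattern does not fill the 23Na TR: %d x %.4f + %.4f != %.4f ms",
        n_h_per_tr - 1, tr_a, tr_b, tr_na))
    # tr_class = the repetition interval FOLLOWING each 1H excitation;
    # tr_b absorbs the sodium excitation/readout block
    cls <- if (order == "aab") c(rep("a", n_h_per_tr - 1), "b")
           else c("b", rep("a", n_h_per_tr - 1))
    gaps <- ifelse(cls == "a", tr_a, tr_b)[seq_len(max(n_h_per_tr - 1, 0))]
    # centre the 1H pulse train in the idle time after the sodium block
    o1 <- (tr_na - sum(gaps)) / 2
    offs <- o1 + cumsum(c(0, gaps))
    h_events <- data.frame(
      t_start_ms = rep(t_period, each = n_h_per_tr) + offs,
      nucleus = "h",
      projection_index = seq_len(n_h_per_tr * n_na),
      tr_class = rep(cls, n_na),
      stringsAsFactors = FALSE)
    events <- rbind(na_events, h_events)
  } else {
    events <- na_events
  }
  events <- events[order(events$t_start_ms, events$nucleus), ]
  rownames(events) <- NULL
  structure(
    list(events = events, n_h_per_tr = n_h_per_tr,
         total_duration_s = n_na * tr_na / 1000,
         params_na = params_na, params_h = params_h,
         order = order),
    class = "interleave_schedule")
}

#' Single-nuclear schedule
#'
#' Degenerate schedule with no interleaved second nucleus; used for the
#' interleaved-versus-single-nuclear comparison and for protocol timing
#' arithmetic (total duration = n_proj * TR, or n_proj * sum(TRs) for
#' multi-TR protocols such as actual flip angle imaging).
#'
#' @param params a \code{sequence_params}; all values of \code{params$tr}
#'   are applied once per projection.
#' @return an \code{interleave_schedule} with only one nucleus.
#' @export
single_nuclear_schedule <- function(params) {
  tr_cycle <- sum(params$tr)
  n <- params$n_proj
  events <- data.frame(
    t_start_ms = (seq_len(n) - 1) * tr_cycle, nucleus = params$nucleus,
    projection_index = seq_len(n), tr_class = params$nucleus,
    stringsAsFactors = FALSE)
  structure(
    list(events = events, n_h_per_tr = 0L,
         total_duration_s = n * tr_cycle / 1000,
         params_na = if (params$nucleus == "na") params else NULL,
         params_h = if (params$nucleus == "h") params else NULL,
         order = "aab"),
    class = "interleave_schedule")
}

#' Spoiled gradient-echo steady-state signal
#'
#' \deqn{S = m_0 \sin\alpha \frac{1 - E_1}{1 - E_1\cos\alpha}
#'        e^{-TE/T_2^*}, \qquad E_1 = e^{-TR/T_1}}
#'
#' Relaxation during the readout is collapsed into the single echo-time
#' factor; per-sample decay is not modelled.
#'
#' @param m0 equilibrium magnetization (arbitrary units); vectorized.
#' @param fa flip angle, degrees.
#' @param tr repetition time, ms.
#' @param t1 longitudinal relaxation time, ms (> 0).
#' @param te echo time, ms.
#' @param t2star effective transverse relaxation time, ms (> 0).
#' @return signal amplitude, same shape as the broadcast inputs.
#' @export
spgr_signal <- function(m0, fa, tr, t1, te = 0, t2star = Inf) {
  if (any(t1 <= 0) || any(t2star <= 0)) stop("'t1' and 't2star' must be positive")
  a <- fa * pi / 180
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te / t2star)
}

#' Simulate a multi-channel radial acquisition
#'
#' Forward model: the voxelwise flip angle is evaluated from the transmit
#' fields and the applied pulse (via \code{\link{simulate_fa_map}}; with
#' \code{pulse = NULL} the channel sum with unit weights is used, scaled so
#' that the mean flip angle over the phantom support equals the nominal
#' value). The transverse magnetization is the spoiled steady-state signal
#' per voxel, weighted by each receive field, and sampled at the trajectory
#' coordinates with the forward nonuniform Fourier transform. Complex
#' Gaussian noise (std \code{noise_sigma} per real/imaginary part, per
#' channel) is added reproducibly from \code{seed}.
#'
#' The two nuclei do not interact in this simulator, so the per-nucleus
#' data are identical whether the events were scheduled interleaved or
#' single-nuclear; only the sequence parameters matter.
#'
#' @param phantom a \code{phantom_volume}.
#' @param fields a \code{channel_field_set} on the same geometry.
#' @param traj a \code{trajectory_set} on the same geometry.
#' @param schedule an \code{interleave_schedule} providing the sequence
#'   parameters for \code{phantom$nucleus}.
#' @param pulse optional \code{shim_solution} or \code{kt_pulse}.
#' @param noise_sigma per-channel complex Gaussian noise std.
#' @param seed integer seed for the noise stream.
#' @param nufft_width gridding kernel width (accuracy/speed trade-off).
#' @return object of class \code{acquired_data}: \code{samples} (complex
#'   n_proj x n_samples x n_rx), \code{noise_sigma}, \code{seed},
#'   \code{nucleus}.
#' @export
simulate_acquisition <- function(phantom, fields, traj, schedule,
                                 pulse = NULL, noise_sigma = 0, seed = 1L,
                                 nufft_width = 10L) {
  if (!same_geometry(phantom$geometry, fields$geometry) ||
      !same_geometry(phantom$geometry, traj$geometry))
    stop("phantom, fields and trajectory geometries must agree")
  params <- if (phantom$nucleus == "na") schedule$params_na else schedule$params_h
  if (is.null(params))
    stop("schedule carries no parameters for nucleus ", phantom$nucleus)
  if (params$n_proj != traj$n_proj)
    stop("trajectory projection count does not match sequence parameters")

  fa <- simulate_fa_map(fields, pulse = pulse,
                        nominal_fa = params$nominal_fa,
                        support = phantom$m0 > 0)
  # effective TR for the steady state: 1H uses the mean TR of its pattern
  tr_eff <- mean(params$tr)
  sig <- spgr_signal(phantom$m0, fa$fa, tr_eff, phantom$t1_map,
                     params$te, phantom$t2star_map)

  kc <- cbind(as.vector(traj$coords[, , 1]),
              as.vector(traj$coords[, , 2]),
              as.vector(traj$coords[, , 3]))
  n_rx <- length(fields$rx_fields)
  samples <- array(0i, dim = c(traj$n_proj, traj$n_samples, n_rx))
  for (ch in seq_len(n_rx)) {
    img <- sig * fields$rx_fields[[ch]]
    samples[, , ch] <- nufft_forward(img + 0i, kc, phantom$geometry,
                                     width = nufft_width)
  }
  if (noise_sigma > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    # noise stream depends only on (seed, nucleus), not on the schedule
    set.seed(as.integer(seed) + if (phantom$nucleus == "na") 0L else 1L)
    n <- length(samples)
    samples <- samples + complex(real = rnorm(n, 0, noise_sigma),
                                 imaginary = rnorm(n, 0, noise_sigma))
  }
  structure(
    list(samples = samples, noise_sigma = noise_sigma, seed = seed,
         nucleus = phantom$nucleus),
    class = "acquired_data")
}

#' Time-averaged per-channel RF power check
#'
#' For rectangular hard pulses into a matched load,
#' \eqn{P_c = D_c \cdot U_c^2 / (2 Z)} with duty cycle
#' \eqn{D_c = n_{pulses} T_{pulse} / T_{period}}. Checked against the
#' per-channel time-averaged power limit of the proton transmit array
#' (1.195 W).
#'
#' @param pulse_voltages per-channel peak voltages, V.
#' @param t_pulse pulse duration, ms.
#' @param schedule an \code{interleave_schedule}; the duty cycle is the
#'   number of 1H excitations per total duration.
#' @param impedance load impedance, ohm.
#' @param limit_w per-channel limit, W.
#' @return list with \code{power_w} (per channel), \code{duty_cycle},
#'   \code{passes} (logical vector), \code{limit_w}.
#' @export
time_averaged_power <- function(pulse_voltages, t_pulse, schedule,
                                impedance = 50, limit_w = 1.195) {
  if (impedance <= 0) stop("'impedance' must be positive")
  n_pulses <- sum(schedule$events$nucleus == "h")
  if (n_pulses == 0) n_pulses <- nrow(schedule$events)
  duty <- n_pulses * t_pulse / (schedule$total_duration_s * 1000)
  p <- duty * pulse_voltages^2 / (2 * impedance)
  list(power_w = p, duty_cycle = duty, passes = p <= limit_w,
       limit_w = limit_w)
}
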