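#' Phase-shim solution
#'
#' Per-channel complex weights of a static transmit shim. In phase-only
#' mode all weights have unit magnitude and the first channel's phase is
#' fixed to 0 (global-phase gauge).
#'
#' @param weights complex per-channel weights.
#' @param cost achieved coefficient of variation over the design ROI.
#' @param roi_descriptor label or mask reference.
#' @param phase_only logical.
#' @return object of class \code{shim_solution}.
#' @export
shim_solution <- function(weights, cost = NA_real_, roi_descriptor = NULL,
                          phase_only = TRUE) {
  if (phase_only && any(abs(Mod(weights) - 1) > 1e-12))
    stop("phase-only shim weights must have unit magnitude")
  structure(list(weights = weights, cost = cost,
                 roi_descriptor = roi_descriptor, phase_only = phase_only),
            class = "shim_solution")
}

#' kT-points pulse
#'
#' K rectangular sub-pulses with per-channel complex weights, separated by
#' gradient blips that shift the excitation k-space position. Blips are
#' expressed as the accumulated excitation k-space offset of each sub-pulse
#' in cycles/mm.
#'
#' @param weights K x n_ch complex matrix.
#' @param blips K x 3 matrix of excitation k-space offsets (cycles/mm).
#' @param subpulse_durations_ms per-sub-pulse durations.
#' @param cost achieved CV.
#' @return object of class \code{kt_pulse} with fields \code{K},
#'   \code{weights}, \code{blips}, \code{subpulse_durations_ms},
#'   \code{total_duration_ms}, \code{cost}.
#' @export
kt_pulse <- function(weights, blips, subpulse_durations_ms, cost = NA_real_) {
  weights <- as.matrix(weights)
  blips <- as.matrix(blips)
  K <- nrow(weights)
  if (K < 1) stop("'K' must be >= 1")
  if (nrow(blips) != K || ncol(blips) != 3) stop("'blips' must be K x 3")
  if (length(subpulse_durations_ms) == 1)
    subpulse_durations_ms <- rep(subpulse_durations_ms, K)
  structure(list(K = K, weights = weights, blips = blips,
                 subpulse_durations_ms = subpulse_durations_ms,
                 total_duration_ms = sum(subpulse_durations_ms),
                 cost = cost),
            class = "kt_pulse")
}

# CV of |A w| where A is the nvox x n_ch ROI field matrix
shim_cv <- function(A, w) {
  f <- Mod(A %*% w)
  m <- mean(f)
  if (m == 0) return(Inf)
  sqrt(mean((f - m)^2)) / m
}

roi_field_matrix <- function(maps, roi) {
  if (!any(roi)) stop("ROI is empty")
  sel <- which(roi)
  matrix(vapply(maps$tx_fields, function(f) f[sel], complex(length(sel))),
         nrow = length(sel))
}

# multi-start local minimization of cv over channel phases (phase 1 = 0)
optimize_phases <- function(cost_fn, n_ch, n_restarts, seed,
                            extra_starts = list()) {
  if (n_ch == 1L) return(list(phases = 0, cost = cost_fn(numeric(0))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  starts <- c(list(rep(0, n_ch - 1)), extra_starts,
              lapply(seq_len(n_restarts), function(i)
                runif(n_ch - 1, 0, 2 * pi)))
  if (n_ch == 2L) {
    # one free phase: coarse scan plus local refinement in each basin
    grid <- seq(0, 2 * pi, length.out = 181)[-181]
    cg <- vapply(grid, cost_fn, 0)
    seeds <- unique(c(grid[which.min(cg)], unlist(starts)))
    best <- NULL
    for (s0 in seeds) {
      fit <- tryCatch(
        stats::optimize(cost_fn, interval = c(s0 - 0.1, s0 + 0.1),
                        tol = 1e-12),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$objective) &&
          (is.null(best) || fit$objective < best$objective)) best <- fit
    }
    if (is.null(best)) stop("phase optimization failed from every start")
    return(list(phases = best$minimum %% (2 * pi), cost = best$objective))
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch({
      {
        f1 <- stats::optim(s, cost_fn, method = "Nelder-Mead",
                           control = list(maxit = 2000, reltol = 1e-12))
        stats::optim(f1$par, cost_fn, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14))
      }
    }, error = function(e) NULL)   # e.g. start at exact cancellation
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("phase optimization failed from every start")
  list(phases = best$par %% (2 * pi), cost = best$value)
}

#' Design an individual phase shim (IPS)
#'
#' Finds per-channel phases (unit amplitudes, first phase fixed to 0)
#' minimizing the coefficient of variation of the combined transmit
#' magnitude \eqn{|\sum_c e^{i\phi_c} B_{1,c}^+(x)|} over the region of
#' interest, by multi-start local optimization. Deterministic given
#' \code{seed}.
#'
#' @param maps a \code{channel_field_set}.
#' @param roi non-empty logical array on the same geometry.
#' @param n_restarts random restarts in addition to the zero start.
#' @param seed integer seed.
#' @param extra_starts optional list of phase vectors (length n_ch - 1,
#'   radians) used as additional starting points.
#' @return a \code{shim_solution}; \code{cost} is the achieved CV.
#' @export
design_phase_shim <- function(maps, roi, n_restarts = 8L, seed = 1L,
                              extra_starts = list()) {
  A <- roi_field_matrix(maps, roi)
  A <- A / sqrt(mean(Mod(A)^2))   # scale-invariant optimization path
  n_ch <- ncol(A)
  if (nrow(A) == 1L && n_ch > 1L) {
    # homogeneity over a single voxel is trivial; align all channels
    # constructively (the degenerate limit of the CV objective)
    ph <- Arg(A[1, 1]) - Arg(A[1, -1])
    w <- exp(1i * c(0, ph))
    return(shim_solution(w, cost = 0, roi_descriptor = "roi",
                         phase_only = TRUE))
  }
  cost_fn <- function(ph) shim_cv(A, exp(1i * c(0, ph)))
  opt <- optimize_phases(cost_fn, n_ch, n_restarts, seed, extra_starts)
  w <- exp(1i * c(0, opt$phases))[seq_len(n_ch)]
  shim_solution(w, cost = opt$cost, roi_descriptor = "roi",
                phase_only = TRUE)
}

#' Synthetic subject library
#'
#' @param subjects list of lists with elements \code{fields}
#'   (\code{channel_field_set}), \code{roi} (logical array) and optional
#'   \code{weight_kg}.
#' @return object of class \code{subject_library}.
#' @export
subject_library <- function(subjects) {
  if (!length(subjects)) stop("subject library must be non-empty")
  n_ch <- length(subjects[[1]]$fields$tx_fields)
  for (s in subjects) {
    if (length(s$fields$tx_fields) != n_ch)
      stop("all subjects must have the same channel count")
    if (!any(s$roi)) stop("every subject needs a non-empty ROI")
  }
  structure(list(subjects = subjects, n_ch = n_ch),
            class = "subject_library")
}

#' Generate a synthetic subject library
#'
#' Perturbed copies of the default array-field generator (different phase
#' jitters and decay lengths per subject) with an ellipsoidal heart-like
#' ROI, emulating a library of previously acquired cardiac transmit maps
#' used to train a universal shim.
#'
#' @param geometry a \code{grid_geometry}.
#' @param n_subjects number of subjects.
#' @param n_ch transmit channels.
#' @param seed integer seed.
#' @return a \code{subject_library}; subjects carry plausible body weights
#'   (60-100 kg) for the reference-voltage calibration.
#' @export
make_subject_library <- function(geometry, n_subjects = 5L, n_ch = 8L,
                                 seed = 42L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  subj_seeds <- sample.int(1e6, n_subjects)
  decays <- runif(n_subjects, 0.65, 0.95)
  weights <- round(runif(n_subjects, 60, 100), 1)
  roi <- ellipsoid_mask(geometry, center = c(-0.05, 0.05, 0) * geometry$fov,
                        semi_axes = 0.22 * geometry$fov)
  subs <- lapply(seq_len(n_subjects), function(i) {
    f <- make_array_fields(geometry, n_ch = n_ch, seed = subj_seeds[i],
                           decay_mm = decays[i] * max(geometry$fov) / 2)
    list(fields = f, roi = roi, weight_kg = weights[i])
  })
  subject_library(subs)
}

#' Design a universal phase shim (UPS)
#'
#' One phase set minimizing the mean over library subjects of each
#' subject's ROI CV. Same gauge (first phase 0) and determinism rules as
#' \code{\link{design_phase_shim}}.
#'
#' @param library a \code{subject_library}.
#' @param n_restarts,seed as in \code{\link{design_phase_shim}}.
#' @return a \code{shim_solution}; \code{cost} is the mean CV over
#'   subjects.
#' @export
design_universal_shim <- function(library, n_restarts = 8L, seed = 1L) {
  As <- lapply(library$subjects, function(s)
    roi_field_matrix(s$fields, s$roi))
  n_ch <- library$n_ch
  cost_fn <- function(ph) {
    w <- exp(1i * c(0, ph))
    mean(vapply(As, shim_cv, 0, w = w))
  }
  opt <- optimize_phases(cost_fn, n_ch, n_restarts, seed)
  shim_solution(exp(1i * c(0, opt$phases))[seq_len(n_ch)], cost = opt$cost,
                roi_descriptor = "library", phase_only = TRUE)
}

#' Design an individual kT-points pulse
#'
#' Dynamic pTx pulse of K rectangular sub-pulses with complex weights and
#' intervening gradient blips. The design alternates (i) greedy selection
#' of each sub-pulse's excitation k-space offset from a small candidate set
#' and (ii) regularized magnitude-least-squares (variable-exchange) fitting
#' of the complex weights toward a uniform target over the ROI under the
#' small-tip model. The search is initialized from the individual phase
#' shim with all blips zero and the best-CV iterate is returned, so the
#' achieved CV never exceeds the phase-shim CV on the same maps.
#'
#' @param maps a \code{channel_field_set}.
#' @param roi non-empty logical array.
#' @param K number of sub-pulses.
#' @param target_fa target flip angle, degrees (sets the least-squares
#'   target amplitude; the CV is scale-invariant).
#' @param candidate_blips m x 3 matrix of candidate offsets (cycles/mm);
#'   default: zero and +/- 1 cycle/FOV per axis.
#' @param seed integer seed (passed to the phase-shim initialization).
#' @param subpulse_duration_ms duration per sub-pulse; default 0.87/K * K
#'   -- i.e. a 0.87 ms total split evenly.
#' @param lambda_rel relative Tikhonov weight on pulse power.
#' @param n_mls magnitude-least-squares iterations per candidate.
#' @return a \code{kt_pulse}; \code{cost} is the achieved CV.
#' @export
design_kt_points <- function(maps, roi, K = 4L, target_fa = 10,
                             candidate_blips = NULL, seed = 1L,
                             subpulse_duration_ms = 0.87 / 4,
                             lambda_rel = 1e-6, n_mls = 30L,
                             u_ref = 100, gamma = NULL) {
  gamma <- if (is.null(gamma)) GYRO_MHZ_PER_T[[maps$nucleus]] else gamma
  # uniform target amplitude in field units (nT/V) under the small-tip model
  t0 <- (target_fa * pi / 180) /
    (2 * pi * gamma * 1e6 * K * subpulse_duration_ms * 1e-3 * u_ref) * 1e9
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be >= 1")
  g <- maps$geometry
  A <- roi_field_matrix(maps, roi)
  # normalize the field scale so the whole design, including the greedy
  # blip selection, is exactly homogeneous in the map amplitude
  a_scale <- sqrt(mean(Mod(A)^2))
  A <- A / a_scale        # solved in normalized units; weights rescaled below
  n_ch <- ncol(A)
  xyz <- voxel_coordinates(g)[which(roi), , drop = FALSE]
  if (is.null(candidate_blips)) {
    b <- 1 / g$fov
    candidate_blips <- rbind(c(0, 0, 0),
                             c(b[1], 0, 0), c(-b[1], 0, 0),
                             c(0, b[2], 0), c(0, -b[2], 0),
                             c(0, 0, b[3]), c(0, 0, -b[3]))
  }

  ips <- design_phase_shim(maps, roi, seed = seed)
  # state: blips (K x 3) and weights (K x n_ch); start = shim in sub-pulse 1
  blips <- matrix(0, K, 3)
  W <- matrix(0i, K, n_ch)
  W[1, ] <- ips$weights
  best <- list(W = W, blips = blips, cv = ips$cost)

  cv_of <- function(W, blips) {
    f <- kt_field(A, xyz, W, blips)
    m <- mean(Mod(f))
    if (m == 0) return(Inf)
    sqrt(mean((Mod(f) - m)^2)) / m
  }
  mls_fit <- function(W, blips, active_k) {
    # regularized magnitude least squares over sub-pulses 1..active_k
    Akt <- do.call(cbind, lapply(seq_len(active_k), function(k) {
      ph <- exp(2i * pi * as.vector(xyz %*% blips[k, ]))
      A * ph
    }))
    lambda <- lambda_rel * mean(Mod(Akt)^2) * nrow(Akt)
    AtA <- Conj(t(Akt)) %*% Akt + diag(lambda, ncol(Akt))
    w <- as.vector(t(W[seq_len(active_k), , drop = FALSE]))
    for (it in seq_len(n_mls)) {
      z <- Akt %*% w
      b <- t0 * exp(1i * Arg(z))
      w <- solve(AtA, Conj(t(Akt)) %*% b)
    }
    Wout <- W
    Wout[seq_len(active_k), ] <- matrix(w, nrow = active_k, byrow = TRUE)
    Wout
  }

  # refine sub-pulse 1 weights (complex shim) first
  W1 <- mls_fit(W, blips, 1L)
  if (cv_of(W1, blips) < best$cv) best <- list(W = W1, blips = blips, cv = cv_of(W1, blips))
  W <- best$W; blips <- best$blips

  for (k in seq_len(K)[-1]) {
    cand_best <- NULL
    for (ci in seq_len(nrow(candidate_blips))) {
      bl <- blips
      bl[k, ] <- candidate_blips[ci, ]
      Wc <- mls_fit(W, bl, k)
      cvc <- cv_of(Wc, bl)
      if (is.null(cand_best) || cvc < cand_best$cv - 1e-12)
        cand_best <- list(W = Wc, blips = bl, cv = cvc)
    }
    if (cand_best$cv < best$cv - 1e-12) best <- cand_best
    W <- best$W; blips <- best$blips
  }

  kt_pulse(best$W / a_scale, best$blips,
           subpulse_durations_ms = rep(subpulse_duration_ms, K),
           cost = best$cv)
}

# combined small-tip field of a kT pulse on the ROI sample matrix
kt_field <- function(A, xyz, W, blips) {
  out <- numeric(nrow(A)) + 0i
  for (k in seq_len(nrow(W))) {
    ph <- exp(2i * pi * as.vector(xyz %*% blips[k, ]))
    out <- out + (A %*% W[k, ]) * ph
  }
  out
}

#' Reference-voltage calibration fit
#'
#' Ordinary least-squares fit of the transmitter reference voltage against
#' body weight, \eqn{U_{ref} = a\,\mathrm{weight} + b}, used to estimate a
#' subject-specific reference voltage when no inline calibration is
#' available. Also reports Pearson correlation and the mean relative
#' absolute deviation \eqn{|U_{fit} - U_{meas}|/U_{meas}} over the inputs.
#'
#' @param weights_kg body weights, kg (>= 2 distinct values).
#' @param voltages_v measured reference voltages, V.
#' @return list: \code{slope_v_per_kg}, \code{intercept_v},
#'   \code{correlation}, \code{mean_rel_abs_dev}, \code{predict}
#'   (function of weight).
#' @export
reference_voltage_fit <- function(weights_kg, voltages_v) {
  if (length(weights_kg) < 2 || length(weights_kg) != length(voltages_v))
    stop("need >= 2 (weight, voltage) pairs of equal length")
  if (length(unique(weights_kg)) < 2)
    stop("degenerate design: all weights identical")
  fit <- stats::lm(voltages_v ~ weights_kg)
  a <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  pred <- a * weights_kg + b
  list(slope_v_per_kg = a, intercept_v = b,
       correlation = stats::cor(weights_kg, voltages_v),
       mean_rel_abs_dev = mean(abs(pred - voltages_v) / voltages_v),
       predict = function(w) a * w + b)
}

#' Write / read a pulse as YAML
#'
#' Complex weights are serialized as [re, im] pairs.
#'
#' @param pulse a \code{shim_solution} or \code{kt_pulse}.
#' @param path file path.
#' @return \code{write_pulse}: the path invisibly; \code{read_pulse}: the
#'   pulse object.
#' @export
write_pulse <- function(pulse, path) {
  c2l <- function(z) lapply(as.vector(z), function(v) c(Re(v), Im(v)))
  obj <- if (inherits(pulse, "shim_solution")) {
    list(type = "shim", weights = c2l(pulse$weights), cost = pulse$cost,
         phase_only = pulse$phase_only)
  } else if (inherits(pulse, "kt_pulse")) {
    list(type = "kt", K = pulse$K, n_ch = ncol(pulse$weights),
         weights = c2l(t(pulse$weights)),  # channel-fastest
         blips = apply(pulse$blips, 1, as.list),
         subpulse_durations_ms = as.list(pulse$subpulse_durations_ms),
         cost = pulse$cost)
  } else stop("unsupported pulse type")
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' @rdname write_pulse
#' @export
read_pulse <- function(path) {
  obj <- yaml::read_yaml(path)
  l2c <- function(l) vapply(l, function(p) complex(real = p[[1]], imaginary = p[[2]]),
                            complex(1))
  if (identical(obj$type, "shim")) {
    shim_solution(l2c(obj$weights), cost = obj$cost %||% NA_real_,
                  phase_only = isTRUE(obj$phase_only))
  } else if (identical(obj$type, "kt")) {
    W <- matrix(l2c(obj$weights), nrow = obj$K, byrow = TRUE)
    blips <- do.call(rbind, lapply(obj$blips, unlist))
    kt_pulse(W, blips, unlist(obj$subpulse_durations_ms),
             cost = obj$cost %||% NA_real_)
  } else stop("malformed pulse file")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
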