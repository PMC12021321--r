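#' Golden-means projection directions on the sphere
#'
#' Generates the direction of every radial projection using the
#' two-dimensional golden means, the 3D generalisation of the golden-angle
#' ordering: any contiguous subset of projections covers the sphere
#' near-uniformly, which makes the ordering robust to interruption and
#' suitable for retrospective data sharing. The constants are
#' \eqn{\lambda_2 \approx 0.6823} (the real root of \eqn{x^3 + x = 1})
#' and \eqn{\lambda_1 = \lambda_2^2 \approx 0.4656}. The full-precision
#' irrational values are used by default: the four-decimal roundings often
#' quoted are rational (period 10000), which would make long projection
#' series repeat exactly.
#'
#' The construction is
#' \deqn{z_n = 2\,\mathrm{frac}(n\lambda_1) - 1,\quad
#'       \phi_n = 2\pi\,\mathrm{frac}(n\lambda_2)}
#' for centre-out (half) projections, which must cover the full sphere.
#' Centre-through (full) projections pass through the k-space centre, so the
#' antipodal direction is sampled implicitly and the polar coordinate only
#' needs to cover a hemisphere: \eqn{z_n = \mathrm{frac}(n\lambda_1)}.
#' The hemisphere convention for full projections is an assumption of this
#' package (see the methods vignette).
#'
#' @param n number of projections (>= 1).
#' @param scheme \code{"half"} (centre-out) or \code{"full"}
#'   (centre-through).
#' @param lambda1,lambda2 the 2D golden means; defaults are the exact
#'   roots (printed elsewhere rounded to 0.4656 and 0.6823).
#' @return object of class \code{projection_directions}: list with \code{n},
#'   \code{unit_vectors} (n x 3, unit rows), \code{scheme}, \code{lambda1},
#'   \code{lambda2}.
#' @examples
#' d <- golden_angle_directions(100, "half")
#' range(sqrt(rowSums(d$unit_vectors^2)))  # all 1
#' @export
golden_angle_directions <- function(n, scheme = c("half", "full"),
                                    lambda1 = 0.4655712318767680,
                                    lambda2 = 0.6823278038280193) {
  scheme <- match.arg(scheme)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  idx <- seq_len(n)
  fz <- (idx * lambda1) %% 1
  z <- if (scheme == "half") 2 * fz - 1 else fz
  phi <- 2 * pi * ((idx * lambda2) %% 1)
  s <- sqrt(pmax(0, 1 - z^2))
  uv <- unname(cbind(s * cos(phi), s * sin(phi), z))
  structure(
    list(n = n, unit_vectors = uv, scheme = scheme,
         lambda1 = lambda1, lambda2 = lambda2),
    class = "projection_directions")
}

#' Density-adapted radial readout
#'
#' Radial k-space sample positions versus time for one projection of a
#' density-adapted 3D radial (DA-3D-RAD) readout. The magnitude |k(t)| grows
#' linearly (constant gradient) up to \code{k0 = k0_fraction * kmax}; beyond
#' k0 the gradient is shaped so that \eqn{k^2\,dk/dt} is constant, which
#' makes the sampling density per k-space volume uniform and compensates the
#' \eqn{1/k^2} dilution of radial sampling:
#' \deqn{k(t) = \left(k_0^3 + 3 k_0^2\, g_0 (t - t_0)\right)^{1/3}}
#' with \eqn{g_0} the (continuous) gradient at \eqn{k_0}. \eqn{g_0} is
#' solved so that the last sample reaches \code{kmax} at \code{t_ro}.
#'
#' Half (centre-out) readouts run 0 -> kmax; full (centre-through) readouts
#' run -kmax -> +kmax with the same density-adapted shape mirrored about the
#' centre, stored as signed magnitudes.
#'
#' @param kmax maximum sampled spatial frequency, 1/mm. For a nominal
#'   resolution \eqn{\Delta x} this is \eqn{1/(2\Delta x)}.
#' @param n_samples samples per projection (>= 2), uniform in time.
#' @param t_ro readout duration, ms.
#' @param k0_fraction fraction of kmax at which density adaptation begins,
#'   in (0, 1).
#' @param mode \code{"half"} or \code{"full"}.
#' @return object of class \code{radial_readout}: \code{k_mags} (signed,
#'   1/mm, non-decreasing), \code{t_samples} (ms), \code{kmax},
#'   \code{k0_fraction}, \code{mode}.
#' @export
da_radial_readout <- function(kmax, n_samples, t_ro, k0_fraction = 0.2,
                              mode = c("half", "full")) {
  mode <- match.arg(mode)
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L) stop("'n_samples' must be >= 2")
  if (!is.finite(k0_fraction) || k0_fraction <= 0 || k0_fraction >= 1)
    stop("'k0_fraction' must lie in (0, 1)")
  if (kmax <= 0 || t_ro <= 0) stop("'kmax' and 't_ro' must be positive")

  k0 <- k0_fraction * kmax
  half_profile <- function(t, t_half) {
    # |k|(t) on a centre-out ramp of duration t_half
    g0 <- (kmax^3 + 2 * k0^3) / (3 * k0^2 * t_half)
    t0 <- k0 / g0
    ifelse(t <= t0, g0 * t, (k0^3 + 3 * k0^2 * g0 * (t - t0))^(1 / 3))
  }
  t <- seq(0, t_ro, length.out = n_samples)
  if (mode == "half") {
    k <- half_profile(t, t_ro)
  } else {
    # centre-through: ramp down from -kmax, cross zero at t_ro/2, up to +kmax
    th <- t_ro / 2
    k <- ifelse(t <= th, -half_profile(th - t, th), half_profile(t - th, th))
  }
  # guard rounding so max |k| is exactly kmax
  k[n_samples] <- kmax
  if (mode == "full") k[1] <- -kmax
  structure(
    list(k_mags = k, t_samples = t, kmax = kmax,
         k0_fraction = k0_fraction, mode = mode),
    class = "radial_readout")
}

#' Assemble a full 3D trajectory with density compensation
#'
#' Outer product of projection directions and the radial readout, plus
#' analytic density-compensation factors (DCF). Each sample's DCF is the
#' volume of its radial Voronoi shell divided by the number of projections
#' sharing the sphere, so that DCF is proportional to \eqn{k^2 \Delta k}:
#' \eqn{\propto k^2} in the inner (constant-gradient) region and constant
#' per unit time in the density-adapted region. The centre sample's shell
#' extends from 0 to the first midpoint, giving a finite positive weight.
#'
#' @param dirs a \code{projection_directions} object.
#' @param readout a \code{radial_readout}; \code{readout$mode} must equal
#'   \code{dirs$scheme}.
#' @param geometry the target \code{grid_geometry} (carried for
#'   reconstruction; also used to sanity-check Nyquist).
#' @return object of class \code{trajectory_set}: \code{coords}
#'   (n_proj x n_samples x 3, 1/mm), \code{dcf} (n_proj x n_samples, >= 0),
#'   \code{t_ms} (sample times), \code{geometry}, \code{kmax},
#'   \code{n_proj}, \code{n_samples}, \code{mode}.
#' @export
build_trajectory <- function(dirs, readout, geometry) {
  if (!inherits(dirs, "projection_directions")) stop("'dirs' must be projection_directions")
  if (!inherits(readout, "radial_readout")) stop("'readout' must be a radial_readout")
  if (!inherits(geometry, "grid_geometry")) stop("'geometry' must be a grid_geometry")
  if (dirs$scheme != readout$mode)
    stop(sprintf("readout mode '%s' does not match direction scheme '%s'",
                 readout$mode, dirs$scheme))
  np <- dirs$n
  ns <- length(readout$k_mags)
  coords <- array(0, dim = c(np, ns, 3))
  for (d in 1:3)
    coords[, , d] <- outer(dirs$unit_vectors[, d], readout$k_mags)

  # radial Voronoi shells on the signed profile
  k <- readout$k_mags
  mid <- (k[-1] + k[-ns]) / 2
  if (readout$mode == "half") {
    lo <- c(0, mid)
    hi <- c(mid, k[ns])
    shell <- (4 * pi / 3) * abs(hi^3 - lo^3)
  } else {
    lo <- c(k[1], mid)
    hi <- c(mid, k[ns])
    # cells straddling zero contribute the union of both half-shells
    shell <- ifelse(lo * hi >= 0,
                    (4 * pi / 3) * abs(abs(hi)^3 - abs(lo)^3),
                    (4 * pi / 3) * (abs(hi)^3 + abs(lo)^3))
  }
  dcf_row <- shell / np
  dcf <- matrix(rep(dcf_row, each = np), nrow = np)
  structure(
    list(coords = coords, dcf = dcf, t_ms = readout$t_samples,
         geometry = geometry, kmax = readout$kmax,
         n_proj = np, n_samples = ns, mode = readout$mode),
    class = "trajectory_set")
}

#' Recommended readout sample count
#'
#' The density-adapted readout traverses the k-space centre at its maximum
#' speed \eqn{g_0}, so the radial sample spacing is largest there. For
#' alias-free reconstruction the spacing must stay below 1/FOV, and -- as
#' is standard for radial MRI -- the readout should be oversampled beyond
#' that, since the accuracy of the analytic density-compensation
#' quadrature for off-centre structures is governed by the radial sampling
#' rate. This returns the smallest sample count whose maximum radial step
#' is at most \code{1/(oversampling * fov)}.
#'
#' @param kmax maximum spatial frequency, 1/mm.
#' @param fov_mm field of view, mm.
#' @param k0_fraction density-adaptation onset fraction.
#' @param oversampling readout oversampling factor (default 2).
#' @param mode \code{"half"} or \code{"full"} (a full projection covers the
#'   centre-out path twice, doubling the required count).
#' @return integer sample count.
#' @export
recommended_n_samples <- function(kmax, fov_mm, k0_fraction = 0.2,
                                  oversampling = 2, mode = c("half", "full")) {
  mode <- match.arg(mode)
  k0 <- k0_fraction * kmax
  k_path <- (kmax^3 + 2 * k0^3) / (3 * k0^2)  # g0 * t(half), 1/mm
  if (mode == "full") k_path <- 2 * k_path
  as.integer(ceiling(oversampling * fov_mm * k_path)) + 1L
}

#' Nyquist kmax for a grid geometry
#'
#' @param geometry a \code{grid_geometry} (isotropic voxel assumed for the
#'   radial readout; the smallest voxel dimension is used).
#' @return kmax = 1 / (2 * voxel_size), 1/mm.
#' @export
nyquist_kmax <- function(geometry) {
  1 / (2 * min(geometry$voxel_size))
}

#' Flatten a trajectory to a per-sample table
#'
#' @param traj a \code{trajectory_set}.
#' @return data.frame with columns proj_index, sample_index, kx, ky, kz,
#'   dcf, t_ms.
#' @export
trajectory_table <- function(traj) {
  np <- traj$n_proj; ns <- traj$n_samples
  data.frame(
    proj_index = rep(seq_len(np), times = ns),
    sample_index = rep(seq_len(ns), each = np),
    kx = as.vector(traj$coords[, , 1]),
    ky = as.vector(traj$coords[, , 2]),
    kz = as.vector(traj$coords[, , 3]),
    dcf = as.vector(traj$dcf),
    t_ms = rep(traj$t_ms, each = np))
}

#' Write / read a trajectory as tab-separated text
#'
#' Columnar plain-text exchange format: one row per sample with projection
#' index, k-space coordinates (1/mm), DCF and sample time. Grid geometry is
#' stored in '#' header lines.
#'
#' @param traj a \code{trajectory_set}.
#' @param path output file.
#' @return \code{write_trajectory}: the path, invisibly;
#'   \code{read_trajectory}: a \code{trajectory_set}.
#' @export
write_trajectory <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  g <- traj$geometry
  writeLines(c(
    sprintf("# mrduet trajectory v1"),
    sprintf("# shape %d %d %d", g$shape[1], g$shape[2], g$shape[3]),
    sprintf("# voxel_size %.17g %.17g %.17g",
            g$voxel_size[1], g$voxel_size[2], g$voxel_size[3]),
    sprintf("# origin %.17g %.17g %.17g", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("# kmax %.17g", traj$kmax),
    sprintf("# mode %s", traj$mode),
    sprintf("# n_proj %d n_samples %d", traj$n_proj, traj$n_samples)), con)
  utils::write.table(trajectory_table(traj), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @param path input file.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path, n = 20L)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (!length(ln)) stop("malformed trajectory file: missing ", key)
    strsplit(sub(paste0("^# ", key, " "), "", ln[1]), " ")[[1]]
  }
  shape <- as.integer(get("shape"))
  vs <- as.numeric(get("voxel_size"))
  origin <- as.numeric(get("origin"))
  kmax <- as.numeric(get("kmax"))
  mode <- get("mode")[1]
  npns <- get("n_proj")
  np <- as.integer(npns[1]); ns <- as.integer(npns[3])
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  ord <- order(tab$sample_index, tab$proj_index)
  tab <- tab[ord, ]
  coords <- array(c(tab$kx, tab$ky, tab$kz), dim = c(np, ns, 3))
  dcf <- matrix(tab$dcf, nrow = np)
  t_ms <- tab$t_ms[seq(1, np * ns, by = np)]
  structure(
    list(coords = coords, dcf = dcf, t_ms = t_ms,
         geometry = grid_geometry(shape, vs, origin), kmax = kmax,
         n_proj = np, n_samples = ns, mode = mode),
    class = "trajectory_set")
}
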