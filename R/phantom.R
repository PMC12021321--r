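#' Gyromagnetic ratios (MHz/T)
#'
#' Reduced gyromagnetic ratios gamma/2pi of the two nuclei handled by the
#' package, in MHz per tesla.
#' @export
GYRO_MHZ_PER_T <- c(h = 42.577, na = 11.262)

#' Specify a phantom compartment
#'
#' An ellipsoidal compartment with its tissue parameters. Compartments are
#' voxelized in list order, later compartments overwriting earlier ones, so
#' nested structures (blood pool inside myocardium) are expressed by
#' listing the inner compartment last.
#'
#' @param name label.
#' @param center mm centre of the ellipsoid.
#' @param semi_axes mm semi-axes (length 1 or 3, > 0).
#' @param concentration sodium concentration, mM (>= 0); used as m0 for the
#'   23Na nucleus.
#' @param t1 longitudinal relaxation time, ms (> 0).
#' @param t2star effective transverse relaxation time, ms (> 0).
#' @param proton_density relative proton density (m0 for 1H).
#' @return object of class \code{compartment_spec}.
#' @export
compartment_spec <- function(name, center, semi_axes, concentration,
                             t1, t2star, proton_density = 1) {
  if (concentration < 0) stop("'concentration' must be >= 0")
  if (t1 <= 0 || t2star <= 0) stop("'t1' and 't2star' must be positive")
  structure(
    list(name = name, center = as.numeric(center),
         semi_axes = as.numeric(semi_axes),
         concentration = concentration, t1 = t1, t2star = t2star,
         proton_density = proton_density),
    class = "compartment_spec")
}

#' Voxelize a digital torso phantom
#'
#' Builds per-voxel m0, T1 and T2* maps from a priority-ordered list of
#' ellipsoidal compartments. A voxel belongs to a compartment if its centre
#' lies inside the ellipsoid (centre-in/out test); background voxels have
#' m0 = 0 (relaxation times set to 1 ms there, never used because m0 = 0).
#' For the 23Na nucleus m0 is the sodium concentration (mM); for 1H it is
#' the relative proton density.
#'
#' @param geometry a \code{grid_geometry}.
#' @param compartments list of \code{compartment_spec}, later entries
#'   overwrite earlier ones.
#' @param nucleus \code{"na"} or \code{"h"}.
#' @return object of class \code{phantom_volume}: \code{geometry},
#'   \code{m0}, \code{t1_map}, \code{t2star_map} (3D arrays), \code{nucleus},
#'   \code{labels} (integer array, 0 = background, i = compartment i).
#' @export
make_torso_phantom <- function(geometry, compartments, nucleus = c("na", "h")) {
  nucleus <- match.arg(nucleus)
  if (length(compartments) == 0) stop("'compartments' must be non-empty")
  if (inherits(compartments, "compartment_spec"))
    compartments <- list(compartments)
  m0 <- array(0, geometry$shape)
  t1 <- array(1, geometry$shape)
  t2s <- array(1, geometry$shape)
  labels <- array(0L, geometry$shape)
  for (i in seq_along(compartments)) {
    cs <- compartments[[i]]
    if (!inherits(cs, "compartment_spec")) stop("compartments must be compartment_spec objects")
    inside <- ellipsoid_mask(geometry, cs$center, cs$semi_axes)
    m0[inside] <- if (nucleus == "na") cs$concentration else cs$proton_density
    t1[inside] <- cs$t1
    t2s[inside] <- cs$t2star
    labels[inside] <- i
  }
  structure(
    list(geometry = geometry, m0 = m0, t1_map = t1, t2star_map = t2s,
         nucleus = nucleus, labels = labels,
         compartments = compartments),
    class = "phantom_volume")
}

#' Default torso and cardiac phantom compartments
#'
#' \code{torso_compartments()} is the in vitro analogue: one homogeneous
#' ellipsoid at ~300 mM sodium. \code{cardiac_compartments()} adds an
#' in vivo-like two-compartment heart (myocardial shell around a blood
#' pool); the concentrations (blood 140 mM, myocardium 43 mM) are
#' illustrative textbook-scale values, not measurements.
#'
#' @param fov_mm physical extent available, mm (ellipsoids scaled to fit).
#' @return list of \code{compartment_spec}.
#' @export
torso_compartments <- function(fov_mm = c(96, 96, 96)) {
  list(compartment_spec("torso", c(0, 0, 0), 0.42 * fov_mm,
                        concentration = 300, t1 = 35, t2star = 12,
                        proton_density = 1))
}

#' @rdname torso_compartments
#' @export
cardiac_compartments <- function(fov_mm = c(96, 96, 96)) {
  c(torso_compartments(fov_mm),
    list(
      compartment_spec("myocardium", c(-0.08, 0.06, 0) * fov_mm,
                       0.20 * fov_mm, concentration = 43,
                       t1 = 30, t2star = 10, proton_density = 0.8),
      compartment_spec("blood", c(-0.08, 0.06, 0) * fov_mm,
                       0.12 * fov_mm, concentration = 140,
                       t1 = 40, t2star = 15, proton_density = 0.95)))
}

#' Synthetic birdcage transmit/receive field
#'
#' Phenomenological stand-in for a sodium volume (birdcage) coil field. In
#' \code{uniform} mode the field is constant; in \code{asymmetric} mode a
#' smooth linear + quadratic taper is applied toward one upper corner,
#' emulating the corner drop-off of a birdcage with asymmetric end rings
#' loaded by a second coil. \code{asymmetry} scales the taper; the ROI CV of
#' the result grows monotonically with it. On the default central torso ROI
#' the default asymmetry of 1.0 yields a CV of about 0.15 (the combined-coil
#' condition); 0.7 yields about 0.09 (the stand-alone condition).
#'
#' @param geometry a \code{grid_geometry}.
#' @param mode \code{"uniform"} or \code{"asymmetric"}.
#' @param asymmetry taper strength, >= 0.
#' @param amplitude field amplitude at the centre, nT/V.
#' @return object of class \code{channel_field_set} with one transmit and
#'   one receive channel (identical profiles up to the receive map being
#'   dimensionless relative sensitivity).
#' @export
make_birdcage_field <- function(geometry, mode = c("uniform", "asymmetric"),
                                asymmetry = 1.0, amplitude = 10) {
  mode <- match.arg(mode)
  if (asymmetry < 0) stop("'asymmetry' must be >= 0")
  xyz <- voxel_coordinates(geometry)
  ext <- geometry$fov / 2
  if (mode == "uniform" || asymmetry == 0) {
    mag <- rep(1, nrow(xyz))
  } else {
    # normalized coordinates in [-1, 1]; drop-off toward (-x, +y) corner
    xn <- xyz[, 1] / ext[1]
    yn <- xyz[, 2] / ext[2]
    taper <- 1 - asymmetry * (0.25 * (1 - xn) / 2 + 0.25 * (1 + yn) / 2 +
                              0.5 * ((1 - xn) / 2) * ((1 + yn) / 2)^2)
    mag <- pmax(taper, 0.05)
  }
  fld <- array(complex(real = amplitude * mag), dim = geometry$shape)
  structure(
    list(geometry = geometry,
         tx_fields = list(fld),
         rx_fields = list(fld / amplitude),
         nucleus = "na"),
    class = "channel_field_set")
}

#' Synthetic multi-channel transceiver array fields
#'
#' Phenomenological complex per-channel fields of a body transceiver array:
#' loop-like magnitude profiles decaying exponentially with distance from
#' each channel centre, with smooth phase ramps. Channels are arranged half
#' anterior (+y face) and half posterior (-y face). The default per-channel
#' phases are chosen so that the channel sum interferes destructively near
#' the middle of the torso, reproducing the central signal dropout that a
#' fixed default phase setting can produce at 7 T. Fields are normalized so
#' the sum of channel magnitudes is ~1 at the grid centre.
#'
#' @param geometry a \code{grid_geometry}.
#' @param n_ch number of transmit channels (>= 2, default 8: 4 + 4).
#' @param n_rx number of receive channels (default \code{n_ch}).
#' @param decay_mm magnitude decay length, mm.
#' @param seed integer seed for the reproducible phase jitter.
#' @param amplitude overall transmit scale, nT/V at the centre
#'   (sum of magnitudes).
#' @return a \code{channel_field_set} with \code{n_ch} transmit and
#'   \code{n_rx} receive complex field arrays.
#' @export
make_array_fields <- function(geometry, n_ch = 8L, n_rx = n_ch,
                              decay_mm = NULL, seed = 7L, amplitude = 3.5) {
  n_ch <- as.integer(n_ch)
  if (n_ch < 2L) stop("'n_ch' must be >= 2")
  xyz <- voxel_coordinates(geometry)
  ext <- geometry$fov / 2
  if (is.null(decay_mm)) decay_mm <- 0.8 * max(ext)

  centers <- array_channel_centers(n_ch, ext)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  jitter <- runif(n_ch, -0.3, 0.3)

  make_one <- function(i) {
    ctr <- centers[i, ]
    d <- sqrt((xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
              (xyz[, 3] - ctr[3])^2)
    mag <- exp(-d / decay_mm)
    # smooth phase ramp along the channel normal (y) plus a per-channel
    # offset engineered to interfere destructively at the grid centre:
    # channels are split into two groups pi out of phase there
    group <- if (i %% 2L == 0L) pi else 0
    ramp <- 1.8 * pi * (xyz[, 2] - ctr[2]) / geometry$fov[2]
    ph <- group + jitter[i] + ramp
    array(complex(modulus = mag, argument = ph), dim = geometry$shape)
  }
  tx <- lapply(seq_len(n_ch), make_one)
  # normalize: sum of magnitudes at centre voxel = amplitude
  cidx <- floor(geometry$shape / 2) + 1L
  s <- sum(vapply(tx, function(f) Mod(f[cidx[1], cidx[2], cidx[3]]), 0))
  tx <- lapply(tx, function(f) f * (amplitude / s))
  rx <- lapply(seq_len(as.integer(n_rx)), function(i)
    tx[[((i - 1L) %% n_ch) + 1L]] / amplitude)
  structure(
    list(geometry = geometry, tx_fields = tx, rx_fields = rx,
         nucleus = "h", channel_centers = centers),
    class = "channel_field_set")
}

array_channel_centers <- function(n_ch, ext) {
  n_ant <- ceiling(n_ch / 2)
  n_post <- n_ch - n_ant
  place <- function(n, yside) {
    if (n == 0) return(NULL)
    xs <- seq(-0.6, 0.6, length.out = max(n, 2))[seq_len(n)]
    cbind(xs * ext[1], rep(yside * 1.1 * ext[2], n), rep(0, n))
  }
  rbind(place(n_ant, +1), place(n_post, -1))
}

#' Combine transmit channels with complex weights
#'
#' @param fields a \code{channel_field_set}.
#' @param weights complex per-channel weights (default all 1).
#' @return complex 3D array, the weighted channel sum.
#' @export
combine_tx_fields <- function(fields, weights = NULL) {
  n <- length(fields$tx_fields)
  if (is.null(weights)) weights <- rep(1 + 0i, n)
  if (length(weights) != n) stop("one weight per transmit channel required")
  out <- array(0i, dim = fields$geometry$shape)
  for (i in seq_len(n)) out <- out + weights[i] * fields$tx_fields[[i]]
  out
}

# save/restore the global RNG state so seeded generators do not disturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
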