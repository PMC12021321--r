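#' Image volume container
#'
#' @param data 3D numeric or complex array.
#' @param geometry a \code{grid_geometry} with matching shape.
#' @param nucleus \code{"na"}, \code{"h"} or \code{NA}.
#' @param meta provenance list (filter on/off, dcf used, ...).
#' @return object of class \code{image_volume}.
#' @export
image_volume <- function(data, geometry, nucleus = NA_character_,
                         meta = list()) {
  if (!all(dim(data) == geometry$shape))
    stop("data dimensions do not match geometry shape")
  structure(list(data = data, geometry = geometry, nucleus = nucleus,
                 meta = meta),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume> %s, %d x %d x %d, %s\n",
              ifelse(is.na(x$nucleus), "?", x$nucleus),
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              if (is.complex(x$data)) "complex" else "real"))
  invisible(x)
}

#' Radial Hamming window
#'
#' \eqn{w(k) = 0.54 + 0.46\cos(\pi |k| / k_{max})}: 1 at the k-space centre,
#' 0.08 at the edge. Applied as a radial apodization of the acquired
#' samples before gridding to suppress ringing sidelobes.
#'
#' @param k_mag sample |k| values, 1/mm.
#' @param kmax maximum |k|, 1/mm.
#' @return window weights in [0.08, 1].
#' @export
hamming_radial <- function(k_mag, kmax) {
  0.54 + 0.46 * cos(pi * pmin(abs(k_mag) / kmax, 1))
}

#' Gridding reconstruction of radial data
#'
#' Density-compensates the samples (and optionally applies the radial
#' Hamming window), then maps them onto the image grid with the adjoint
#' nonuniform Fourier transform, channel by channel.
#'
#' @param acq an \code{acquired_data} object.
#' @param traj the matching \code{trajectory_set}.
#' @param hamming apply the radial Hamming filter (default TRUE).
#' @param nufft_width gridding kernel width (accuracy/speed trade-off).
#' @return list of per-channel complex \code{image_volume}s, class
#'   \code{channel_images}.
#' @export
reconstruct <- function(acq, traj, hamming = TRUE, nufft_width = 10L) {
  d <- dim(acq$samples)
  if (d[1] != traj$n_proj || d[2] != traj$n_samples)
    stop("acquired data shape does not match trajectory")
  kc <- cbind(as.vector(traj$coords[, , 1]),
              as.vector(traj$coords[, , 2]),
              as.vector(traj$coords[, , 3]))
  kmag <- sqrt(rowSums(kc^2))
  w <- as.vector(traj$dcf)
  if (hamming) w <- w * hamming_radial(kmag, traj$kmax)
  imgs <- lapply(seq_len(d[3]), function(ch) {
    vals <- as.vector(acq$samples[, , ch]) * w
    image_volume(nufft_adjoint(kc, vals, traj$geometry, width = nufft_width),
                 traj$geometry, acq$nucleus,
                 meta = list(hamming = hamming, channel = ch))
  })
  class(imgs) <- "channel_images"
  imgs
}

#' Root-sum-of-squares channel combination
#'
#' @param images a \code{channel_images} list (or plain list of
#'   \code{image_volume}s) on a common geometry.
#' @return magnitude \code{image_volume}.
#' @export
combine_channels <- function(images) {
  if (inherits(images, "image_volume")) images <- list(images)
  if (length(images) < 1) stop("at least one channel required")
  g <- images[[1]]$geometry
  acc <- array(0, g$shape)
  for (im in images) {
    if (!same_geometry(im$geometry, g)) stop("channel geometries differ")
    acc <- acc + Mod(im$data)^2
  }
  image_volume(sqrt(acc), g, images[[1]]$nucleus,
               meta = c(images[[1]]$meta, list(combined = "rss",
                                               n_channels = length(images))))
}

#' Trilinear resampling onto a target grid
#'
#' Interpolates an image at the voxel centres of a target geometry using
#' the physical (mm) coordinates of both grids; target voxels outside the
#' source field of view are 0. Used to bring the low-resolution sodium
#' image onto the proton grid.
#'
#' @param img an \code{image_volume}.
#' @param target a \code{grid_geometry}.
#' @return \code{image_volume} on \code{target}.
#' @export
resample_to <- function(img, target) {
  src <- img$geometry
  if (same_geometry(src, target)) {
    out <- img
    out$geometry <- target
    return(out)
  }
  xyz <- voxel_coordinates(target)
  # continuous source voxel coordinate (1-based)
  cc <- sapply(1:3, function(d) (xyz[, d] - src$origin[d]) / src$voxel_size[d] + 1)
  i0 <- floor(cc)
  fr <- cc - i0
  n <- src$shape
  val <- numeric(nrow(xyz))
  cplx <- is.complex(img$data)
  if (cplx) val <- complex(real = val)
  inb <- function(i, d) i >= 1 & i <= n[d]
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- i0[, 1] + dx; iy <- i0[, 2] + dy; iz <- i0[, 3] + dz
    wt <- (if (dx) fr[, 1] else 1 - fr[, 1]) *
          (if (dy) fr[, 2] else 1 - fr[, 2]) *
          (if (dz) fr[, 3] else 1 - fr[, 3])
    ok <- inb(ix, 1) & inb(iy, 2) & inb(iz, 3) & wt > 0
    if (any(ok)) {
      lin <- ix[ok] + (iy[ok] - 1) * n[1] + (iz[ok] - 1) * n[1] * n[2]
      val[ok] <- val[ok] + wt[ok] * img$data[lin]
    }
  }
  image_volume(array(val, target$shape), target, img$nucleus,
               meta = c(img$meta, list(resampled_from = src$voxel_size)))
}

#' Shift an image by a rigid translation
#'
#' Convenience rigid-translation utility (trilinear): returns the image
#' evaluated at \code{x + shift_mm}. No deformable registration is
#' provided; in simulation the grids are exactly aligned by construction.
#'
#' @param img an \code{image_volume}.
#' @param shift_mm length-3 translation in mm.
#' @return translated \code{image_volume} on the same geometry.
#' @export
translate_image <- function(img, shift_mm) {
  g2 <- img$geometry
  g2$origin <- g2$origin + as.numeric(shift_mm)
  out <- resample_to(image_volume(img$data, g2, img$nucleus, img$meta),
                     img$geometry)
  out
}

#' Voxelwise relative difference map
#'
#' \eqn{(x - y)/y} inside a mask; voxels where y = 0 are excluded from the
#' map and counted. The mean over the remaining voxels is reported, the
#' statistic used to compare coil setups and sequence variants.
#'
#' @param x,y \code{image_volume}s (magnitudes) on the same geometry.
#' @param mask logical array; default: everywhere.
#' @return list: \code{map} (array, NA outside mask/excluded),
#'   \code{mean}, \code{sd}, \code{n_excluded}.
#' @export
relative_difference_map <- function(x, y, mask = NULL) {
  if (!same_geometry(x$geometry, y$geometry)) stop("geometries differ")
  if (is.null(mask)) mask <- array(TRUE, x$geometry$shape)
  if (!any(mask)) stop("mask is empty")
  xv <- Mod(x$data); yv <- Mod(y$data)
  valid <- mask & yv != 0
  n_excl <- sum(mask) - sum(valid)
  if (!any(valid)) stop("all masked voxels have y = 0")
  map <- array(NA_real_, x$geometry$shape)
  map[valid] <- (xv[valid] - yv[valid]) / yv[valid]
  vals <- map[valid]
  list(map = map, mean = mean(vals), sd = stats::sd(vals),
       n_excluded = n_excl)
}
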