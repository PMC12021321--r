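#' Define an image grid geometry
#'
#' A grid geometry ties a voxel array to physical space: the number of voxels
#' per axis, the voxel size in mm, and the physical position (mm) of the
#' centre of the first voxel. By default the grid is centred on the origin,
#' so that the voxel with 0-based index \code{floor(shape/2)} sits closest to
#' (0,0,0); this voxel is the image-space counterpart of the k-space centre
#' in all Fourier operations of the package.
#'
#' @param shape integer vector of length 3, voxels per axis (>= 1).
#' @param voxel_size numeric length 1 or 3, voxel edge length(s) in mm (> 0).
#' @param origin numeric length 3, mm position of the centre of voxel
#'   (1,1,1); default centres the grid such that the FFT-centre voxel is at 0.
#' @return object of class \code{grid_geometry} with fields \code{shape},
#'   \code{voxel_size}, \code{origin}.
#' @examples
#' g <- grid_geometry(c(16, 16, 16), 6)
#' g$fov  # 96 96 96 mm
#' @export
grid_geometry <- function(shape, voxel_size, origin = NULL) {
  shape <- as.integer(shape)
  if (length(shape) == 1L) shape <- rep(shape, 3L)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be 3 positive integers")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be positive (mm)")
  if (is.null(origin)) {
    # centre voxel index (0-based) floor(n/2) lands on physical 0
    origin <- -floor(shape / 2) * voxel_size
  }
  origin <- as.numeric(origin)
  if (length(origin) != 3L) stop("'origin' must have length 3")
  structure(
    list(shape = shape, voxel_size = voxel_size, origin = origin,
         fov = shape * voxel_size),
    class = "grid_geometry")
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf("<grid_geometry> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

same_geometry <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Physical coordinates of all voxel centres
#'
#' @param geometry a \code{grid_geometry}.
#' @return matrix (prod(shape) x 3) of mm coordinates, voxel index varying
#'   fastest along the first axis (R array order).
#' @export
voxel_coordinates <- function(geometry) {
  ax <- lapply(1:3, function(d)
    geometry$origin[d] + (seq_len(geometry$shape[d]) - 1) * geometry$voxel_size[d])
  n <- geometry$shape
  cbind(rep(ax[[1]], times = n[2] * n[3]),
        rep(rep(ax[[2]], each = n[1]), times = n[3]),
        rep(ax[[3]], each = n[1] * n[2]))
}

#' Ellipsoid voxel mask
#'
#' Voxels whose centres lie inside the ellipsoid
#' ((x-c1)/a1)^2 + ((y-c2)/a2)^2 + ((z-c3)/a3)^2 <= 1.
#'
#' @param geometry a \code{grid_geometry}.
#' @param center mm centre of the ellipsoid (length 3).
#' @param semi_axes mm semi-axis lengths (length 1 or 3, > 0).
#' @return logical array of dimension \code{geometry$shape}.
#' @export
ellipsoid_mask <- function(geometry, center = c(0, 0, 0), semi_axes) {
  semi_axes <- as.numeric(semi_axes)
  if (length(semi_axes) == 1L) semi_axes <- rep(semi_axes, 3L)
  if (any(semi_axes <= 0)) stop("'semi_axes' must be positive")
  xyz <- voxel_coordinates(geometry)
  r2 <- ((xyz[, 1] - center[1]) / semi_axes[1])^2 +
        ((xyz[, 2] - center[2]) / semi_axes[2])^2 +
        ((xyz[, 3] - center[3]) / semi_axes[3])^2
  array(r2 <= 1, dim = geometry$shape)
}

#' Central box region of interest
#'
#' Axis-aligned box of given physical dimensions centred on a point, the
#' shape used for the central evaluation ROI on the torso phantom.
#'
#' @param geometry a \code{grid_geometry}.
#' @param dims_mm box edge lengths in mm (length 1 or 3).
#' @param center mm centre, default c(0,0,0).
#' @return logical array of dimension \code{geometry$shape}.
#' @export
box_roi <- function(geometry, dims_mm, center = c(0, 0, 0)) {
  dims_mm <- as.numeric(dims_mm)
  if (length(dims_mm) == 1L) dims_mm <- rep(dims_mm, 3L)
  xyz <- voxel_coordinates(geometry)
  inside <- abs(xyz[, 1] - center[1]) <= dims_mm[1] / 2 &
            abs(xyz[, 2] - center[2]) <= dims_mm[2] / 2 &
            abs(xyz[, 3] - center[3]) <= dims_mm[3] / 2
  array(inside, dim = geometry$shape)
}

#' Erode a logical mask
#'
#' Removes \code{iterations} layers of boundary voxels (6-connected), used
#' to evaluate compartment interiors away from partial-volume boundaries.
#'
#' @param mask logical 3D array.
#' @param iterations number of one-voxel erosions.
#' @return logical array of the same dimension.
#' @export
erode_mask <- function(mask, iterations = 1L) {
  m <- mask
  d <- dim(m)
  for (i in seq_len(iterations)) {
    shifted <- m
    pad <- function(arr, axis, dir) {
      out <- array(FALSE, d)
      idx_src <- lapply(d, seq_len)
      idx_dst <- idx_src
      if (dir > 0) { idx_dst[[axis]] <- 2:d[axis]; idx_src[[axis]] <- 1:(d[axis] - 1) }
      else         { idx_dst[[axis]] <- 1:(d[axis] - 1); idx_src[[axis]] <- 2:d[axis] }
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
      out
    }
    for (axis in 1:3) for (dir in c(-1, 1))
      shifted <- shifted & pad(m, axis, dir)
    m <- shifted
  }
  m
}
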