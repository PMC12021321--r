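#' Nonuniform Fourier transforms by Kaiser-Bessel gridding
#'
#' The package's Fourier engine: a gridding/regridding implementation of the
#' nonuniform discrete Fourier transform between arbitrary k-space sample
#' positions (1/mm) and a Cartesian image grid. Samples are spread onto a
#' 2x-oversampled grid with a Kaiser-Bessel window, transformed with an FFT
#' and deapodized by the window's analytic Fourier transform; with the
#' default window width of 10 grid cells the result agrees with direct DFT
#' summation to ~1e-9 relative error.
#'
#' Image-space coordinates are voxel indices relative to the FFT centre
#' voxel (0-based index \code{floor(shape/2)}); the k-space phase convention
#' is \eqn{s_j = \sum_x f(x) e^{-2\pi i k_j \cdot x}} for the forward
#' transform and its conjugate transpose for the adjoint.
#'
#' @param kcoords n x 3 matrix of k-space positions in 1/mm; must satisfy
#'   |k * voxel_size| <= 0.5 (Nyquist) per axis.
#' @param values complex vector of n k-space samples (adjoint) .
#' @param image complex/numeric 3D array of dimension \code{geometry$shape}
#'   (forward).
#' @param geometry a \code{grid_geometry}.
#' @param width kernel width in oversampled grid cells.
#' @param oversamp grid oversampling factor.
#' @return \code{nufft_adjoint}: complex array of dimension
#'   \code{geometry$shape}; \code{nufft_forward}: complex vector of length
#'   \code{nrow(kcoords)}.
#' @name nufft
NULL

kb_beta <- function(width, oversamp) {
  # Beatty, Nishimura & Pauly's minimum-aliasing choice
  pi * sqrt((width / oversamp)^2 * (oversamp - 0.5)^2 - 0.8)
}

# analytic Fourier transform of the KB window (normalised psi(0)=1),
# evaluated at s cycles per grid cell
kb_ft <- function(s, width, beta) {
  r <- beta^2 - (pi * width * s)^2
  out <- numeric(length(r))
  pos <- r > 0
  sq <- sqrt(abs(r))
  out[pos] <- sinh(sq[pos]) / sq[pos]
  out[!pos] <- ifelse(sq[!pos] == 0, 1, sin(sq[!pos]) / sq[!pos])
  width * out / besselI(beta, 0)
}

nufft_prepare <- function(kcoords, geometry, width, oversamp) {
  shape <- geometry$shape
  nos <- as.integer(2 * ceiling(oversamp * shape / 2))  # even oversampled dims
  ktilde <- sweep(kcoords, 2, geometry$voxel_size, `*`)
  if (max(abs(ktilde)) > 0.5 + 1e-9)
    stop("k-space coordinates exceed the Nyquist limit of the grid")
  u <- sweep(ktilde, 2, as.numeric(nos), `*`)
  # deapodization per axis at image indices relative to the FFT centre
  deap <- lapply(1:3, function(d) {
    x <- seq_len(shape[d]) - 1L - floor(shape[d] / 2)
    kb_ft(x / nos[d], width, kb_beta(width, oversamp))
  })
  list(nos = nos, u = u, deap = deap, shape = shape)
}

# index map: image voxel (0-based, relative to centre c = floor(n/2)) into
# the FFT output array of size nos (R 1-based)
fft_crop_index <- function(shape_d, nos_d) {
  x <- seq_len(shape_d) - 1L - floor(shape_d / 2)
  (x %% nos_d) + 1L
}

#' @rdname nufft
#' @export
nufft_adjoint <- function(kcoords, values, geometry, width = 10L,
                          oversamp = 2) {
  prep <- nufft_prepare(kcoords, geometry, width, oversamp)
  beta <- kb_beta(width, oversamp)
  grid <- .nufft_spread3(prep$u, as.complex(values), prep$nos,
                         as.integer(width), beta)
  img_big <- stats::fft(grid, inverse = TRUE)
  ix <- fft_crop_index(prep$shape[1], prep$nos[1])
  iy <- fft_crop_index(prep$shape[2], prep$nos[2])
  iz <- fft_crop_index(prep$shape[3], prep$nos[3])
  img <- img_big[ix, iy, iz]
  img <- sweep(img, 1, prep$deap[[1]], `/`)
  img <- sweep(img, 2, prep$deap[[2]], `/`)
  img <- sweep(img, 3, prep$deap[[3]], `/`)
  img
}

#' @rdname nufft
#' @export
nufft_forward <- function(image, kcoords, geometry, width = 10L,
                          oversamp = 2) {
  if (!all(dim(image) == geometry$shape))
    stop("image dimensions do not match geometry")
  prep <- nufft_prepare(kcoords, geometry, width, oversamp)
  beta <- kb_beta(width, oversamp)
  img <- image
  img <- sweep(img, 1, prep$deap[[1]], `/`)
  img <- sweep(img, 2, prep$deap[[2]], `/`)
  img <- sweep(img, 3, prep$deap[[3]], `/`)
  big <- array(0i, dim = prep$nos)
  ix <- fft_crop_index(prep$shape[1], prep$nos[1])
  iy <- fft_crop_index(prep$shape[2], prep$nos[2])
  iz <- fft_crop_index(prep$shape[3], prep$nos[3])
  big[ix, iy, iz] <- img
  kgrid <- stats::fft(big)
  .nufft_interp3(kgrid, prep$nos, prep$u, as.integer(width), beta)
}
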