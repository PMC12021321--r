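#' Noise level from noise-only magnitude scans
#'
#' The standard deviation of magnitude samples acquired without excitation.
#' For complex Gaussian noise the magnitude is Rayleigh distributed with
#' \eqn{sd = \sigma\sqrt{(4-\pi)/2}}, so the Gaussian-equivalent sigma is
#' also returned as \code{std_mag / sqrt((4-pi)/2)}.
#'
#' @param noise_images one magnitude \code{image_volume}, a list of them,
#'   or a numeric array/vector of noise magnitudes.
#' @return list: \code{std_mag} (the raw magnitude std),
#'   \code{sigma_gaussian}, \code{n}.
#' @export
noise_sigma_from_scans <- function(noise_images) {
  vals <- collect_magnitudes(noise_images)
  if (length(vals) < 100)
    warning("fewer than 100 noise samples; the estimate will be unstable")
  s <- stats::sd(vals)
  if (length(vals) == 1 || all(vals == vals[1])) s <- 0
  list(std_mag = s, sigma_gaussian = s / sqrt((4 - pi) / 2),
       n = length(vals))
}

collect_magnitudes <- function(x) {
  if (inherits(x, "image_volume")) return(as.vector(Mod(x$data)))
  if (is.list(x)) return(unlist(lapply(x, collect_magnitudes)))
  as.vector(Mod(x))
}

#' Rayleigh-corrected SNR map
#'
#' \deqn{SNR(x) = \frac{image(x)}{std_{noise}} \sqrt{\frac{4-\pi}{2}}}
#' where \code{std_noise} is the standard deviation of magnitude noise
#' scans; the \eqn{\sqrt{(4-\pi)/2}} factor converts it to the underlying
#' Gaussian noise level.
#'
#' @param image magnitude \code{image_volume}.
#' @param std_noise magnitude noise standard deviation (> 0).
#' @return \code{image_volume} of SNR values.
#' @export
snr_map <- function(image, std_noise) {
  if (!is.numeric(std_noise) || std_noise <= 0)
    stop("'std_noise' must be a positive number")
  image_volume(Mod(image$data) / std_noise * sqrt((4 - pi) / 2),
               image$geometry, image$nucleus,
               meta = c(image$meta, list(std_noise = std_noise)))
}

#' Coefficient of variation over a region of interest
#'
#' Population standard deviation divided by mean of the values in the ROI,
#' the homogeneity metric used throughout the package.
#'
#' @param x numeric array/vector, an \code{image_volume}, or an
#'   \code{fa_map}.
#' @param roi logical mask (same shape); default: all values.
#' @return CV (dimensionless).
#' @export
cv <- function(x, roi = NULL) {
  vals <- if (inherits(x, "image_volume")) Mod(x$data)
          else if (inherits(x, "fa_map")) x$fa
          else x
  if (!is.null(roi)) {
    if (!any(roi)) stop("ROI is empty")
    vals <- vals[roi]
  }
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stop("no finite values in ROI")
  m <- mean(vals)
  if (m == 0) stop("ROI mean is zero; CV undefined")
  sqrt(mean((vals - m)^2)) / m
}

#' Mean relative difference between two images
#'
#' Mean and standard deviation of \eqn{(x-y)/y} over a mask, the statistic
#' used for interleaved-versus-single-nuclear and combined-versus-
#' uncombined comparisons. Wrapper around
#' \code{\link{relative_difference_map}}.
#'
#' @param x,y magnitude \code{image_volume}s on the same geometry.
#' @param mask logical array (default: everywhere).
#' @return list: \code{mean}, \code{sd}, \code{n_excluded}.
#' @export
mean_relative_difference <- function(x, y, mask = NULL) {
  r <- relative_difference_map(x, y, mask)
  list(mean = r$mean, sd = r$sd, n_excluded = r$n_excluded)
}
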