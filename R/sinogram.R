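#' Dynamic PET sinogram container
#'
#' A 4-D stack of projection counts with frame timing. Array dimensions follow
#' the package-wide convention `[angle, radial bin, slice, frame]`.
#'
#' @param counts nonnegative 4-D array of counts `[angle, bin, slice, frame]`.
#' @param frame_durations numeric vector of per-frame durations in minutes,
#'   length equal to the number of frames.
#' @param clean optional noiseless expectation sinogram of the same shape
#'   (kept alongside simulated data so ground-truth reconstructions can be
#'   formed without re-simulating).
#' @return an object of class `dynamic_sinogram`.
#' @export
dynamic_sinogram <- function(counts, frame_durations, clean = NULL) {
  if (length(dim(counts)) != 4L)
    stop_input("counts must be a 4-D array [angle, bin, slice, frame], got %d dims",
               length(dim(counts)))
  if (anyNA(counts) || any(counts < 0))
    stop_input("counts must be nonnegative and free of missing values")
  if (length(frame_durations) != dim(counts)[4])
    stop_input("frame_durations has length %d but the sinogram has %d frames",
               length(frame_durations), dim(counts)[4])
  if (!is.null(clean) && !identical(dim(clean), dim(counts)))
    stop_input("clean sinogram shape must match counts")
  structure(list(counts = counts, frame_durations = as.numeric(frame_durations),
                 clean = clean),
            class = "dynamic_sinogram")
}

#' @export
print.dynamic_sinogram <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("dynamic_sinogram: %d angles x %d bins x %d slices x %d frames\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  total counts: %.4g; frame durations (min): %s\n",
              sum(x$counts), paste(x$frame_durations, collapse = ", ")))
  invisible(x)
}

#' Variance-stabilized sinogram container
#'
#' Holds the real-valued sinogram after the Anscombe transform, where the
#' Poisson noise is approximately Gaussian with standard deviation `sigma`
#' (unity for ideal Poisson counts).
#'
#' @param data finite 4-D array `[angle, bin, slice, frame]`.
#' @param sigma positive noise standard deviation in the stabilized domain.
#' @param frame_durations per-frame durations in minutes.
#' @return an object of class `stabilized_sinogram`.
#' @export
stabilized_sinogram <- function(data, sigma = 1, frame_durations = NULL) {
  if (length(dim(data)) != 4L)
    stop_input("data must be a 4-D array [angle, bin, slice, frame]")
  if (!all(is.finite(data)))
    stop_input("stabilized sinogram must be finite everywhere")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop_input("sigma must be a single positive number")
  if (is.null(frame_durations)) frame_durations <- rep(1, dim(data)[4])
  structure(list(data = data, sigma = sigma,
                 frame_durations = as.numeric(frame_durations)),
            class = "stabilized_sinogram")
}

#' @export
print.stabilized_sinogram <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("stabilized_sinogram: %d x %d x %d slices x %d frames, sigma = %g\n",
              d[1], d[2], d[3], d[4], x$sigma))
  invisible(x)
}

#' Stabilize a dynamic sinogram for Gaussian-noise filtering
#'
#' Applies [anscombe_forward()] to the counts and wraps the result with the
#' stabilized-domain noise level (`sigma = 1` for pure Poisson counts).
#'
#' @param sino a [dynamic_sinogram()].
#' @param sigma stabilized-domain noise standard deviation; the default 1 is
#'   exact for ideal Poisson data.
#' @return a [stabilized_sinogram()].
#' @export
stabilize <- function(sino, sigma = 1) {
  stopifnot(inherits(sino, "dynamic_sinogram"))
  stabilized_sinogram(anscombe_forward(sino$counts), sigma = sigma,
                      frame_durations = sino$frame_durations)
}

#' Return a stabilized sinogram to the count domain
#'
#' Applies the exact unbiased inverse Anscombe transform
#' ([anscombe_inverse_exact_unbiased()]) elementwise.
#'
#' @param stab a [stabilized_sinogram()].
#' @return nonnegative 4-D array of estimated Poisson means.
#' @export
unstabilize <- function(stab) {
  stopifnot(inherits(stab, "stabilized_sinogram"))
  anscombe_inverse_exact_unbiased(stab$data)
}
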