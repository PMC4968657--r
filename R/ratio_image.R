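#' Pixel-wise acceptor/donor ratio image
#'
#' Divides the acceptor-channel image by the donor-channel image pixel by
#' pixel, the core of ratiometric FRET imaging: the ratio is independent of
#' carrier concentration and illumination, so it reads out the spectral
#' state of the carriers alone. Pixels where either channel falls below the
#' intensity floor carry no reliable signal and are marked invalid rather
#' than divided.
#'
#' @param acceptor,donor \code{\link{channel_frame}}s on the same grid at
#'   the same time, with matching channel tags.
#' @param intensity_floor Minimum counts in both channels for a pixel to be
#'   valid. See \code{\link{estimate_intensity_floor}} for the default
#'   policy (background mean + 2 SD from a pre-injection frame).
#' @return An object of class \code{"ratio_image"}: list with \code{ratio}
#'   (matrix, \code{NA} where invalid), \code{valid} (logical matrix),
#'   \code{time_h}, \code{subject}, \code{display_range}.
#' @export
compute_ratio_image <- function(acceptor, donor, intensity_floor = 0) {
  stopifnot(inherits(acceptor, "channel_frame"),
            inherits(donor, "channel_frame"))
  if (acceptor$channel != "acceptor" || donor$channel != "donor")
    stop("channel tags do not match the argument roles")
  if (!all(dim(acceptor$data) == dim(donor$data)))
    stop("acceptor and donor frames have different grid shapes")
  if (acceptor$time_h != donor$time_h)
    stop("acceptor and donor frames are from different timepoints")
  valid <- donor$data >= intensity_floor & acceptor$data >= intensity_floor &
    donor$data > 0
  ratio <- matrix(NA_real_, nrow(donor$data), ncol(donor$data))
  ratio[valid] <- acceptor$data[valid] / donor$data[valid]
  structure(list(ratio = ratio, valid = valid, time_h = donor$time_h,
                 subject = donor$subject,
                 display_range = default_display_range()),
            class = "ratio_image")
}

#' Intensity floor from a pre-injection frame
#'
#' The display and division threshold below which a channel is considered
#' background-limited: mean + 2 standard deviations of the pre-injection
#' frame of that channel.
#'
#' @param pre_frame Pre-injection \code{\link{channel_frame}}.
#' @return Counts threshold (scalar).
#' @export
estimate_intensity_floor <- function(pre_frame) {
  stopifnot(inherits(pre_frame, "channel_frame"))
  mean(pre_frame$data) + 2 * stats::sd(pre_frame$data)
}

#' Default A/D display range
#'
#' Maps the pseudocolor scale onto the integrity extremes of the
#' calibration law: for ratio \eqn{R} at 0% and 100% integrity, the A/D
#' endpoints are \eqn{R/(1-R)}.
#'
#' @param params A \code{\link{calibration_params}}.
#' @return \code{c(min, max)} of A/D values.
#' @export
default_display_range <- function(params = calibration_params()) {
  r <- eval_calibration(params, c(0, 100))
  r / (1 - r)
}

#' Render a ratio image as intensity-modulated pseudocolor
#'
#' Hue encodes the A/D ratio linearly over the display range, blue (low
#' FRET, disintegrated) through green and yellow to red (high FRET,
#' intact); per-pixel brightness is the summed two-channel intensity
#' normalized by its 99th percentile and clipped to \[0, 1\], so dim pixels
#' fade to black regardless of their ratio. Invalid pixels are black.
#'
#' @param ratio A \code{"ratio_image"}.
#' @param donor,acceptor The source \code{\link{channel_frame}}s.
#' @param display_range \code{c(min, max)} of the hue scale; must be
#'   non-degenerate.
#' @return Numeric array \code{nrow x ncol x 3} of RGB in \[0, 1\].
#' @export
render_pseudocolor <- function(ratio, donor, acceptor,
                               display_range = ratio$display_range) {
  stopifnot(inherits(ratio, "ratio_image"),
            inherits(donor, "channel_frame"),
            inherits(acceptor, "channel_frame"))
  if (!all(dim(donor$data) == dim(ratio$ratio)) ||
      !all(dim(acceptor$data) == dim(ratio$ratio)))
    stop("frames and ratio image are not aligned")
  if (diff(display_range) <= 0)
    stop("degenerate display range: min must be < max")
  total <- donor$data + acceptor$data
  p99 <- stats::quantile(total, 0.99, names = FALSE)
  bright <- if (p99 > 0) pmin(total / p99, 1) else total * 0
  # hue 2/3 (blue) at range min -> 0 (red) at range max
  frac <- (ratio$ratio - display_range[1]) / diff(display_range)
  frac <- pmin(pmax(frac, 0), 1)
  hue <- (1 - frac) * 2 / 3
  hue[!ratio$valid] <- 0
  bright[!ratio$valid] <- 0
  cols <- grDevices::hsv(h = as.vector(hue), s = 1, v = as.vector(bright))
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, c(nrow(ratio$ratio), ncol(ratio$ratio), 3))
  out[, , 1] <- rgb[1, ]
  out[, , 2] <- rgb[2, ]
  out[, , 3] <- rgb[3, ]
  out
}

#' Write a rendered pseudocolor image as PNG
#'
#' @param rgb RGB array from \code{\link{render_pseudocolor}}.
#' @param path Destination \code{.png}.
#' @export
write_pseudocolor_png <- function(rgb, path) {
  atomic_write(path, function(tmp) png::writePNG(rgb, tmp))
  invisible(path)
}

#' Optional 3x3 median filter
#'
#' Off by default throughout the pipeline: ratio images are computed from
#' raw channels. Provided for exploratory smoothing of noisy frames; edges
#' are handled by shrinking the window.
#'
#' @param frame A \code{\link{channel_frame}}.
#' @return The frame with median-filtered data.
#' @export
median_filter3 <- function(frame) {
  stopifnot(inherits(frame, "channel_frame"))
  d <- frame$data
  nr <- nrow(d); nc <- ncol(d)
  out <- d
  for (i in seq_len(nr)) {
    ri <- max(1, i - 1):min(nr, i + 1)
    for (j in seq_len(nc)) {
      out[i, j] <- stats::median(d[ri, max(1, j - 1):min(nc, j + 1)])
    }
  }
  frame$data <- out
  frame
}
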