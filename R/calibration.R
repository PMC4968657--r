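#' Calibration law parameters for the ratiometric integrity response
#'
#' Constructs and validates the parameter set \code{(a, b, c)} of the
#' exponential law \deqn{y = a + b e^{c x}} that maps nanocarrier integrity
#' \eqn{x} (percent of dye pairs still co-encapsulated, 0--100) to the
#' proximity ratio \eqn{y = A/(A+D)} measured on a two-channel NIR imaging
#' setup. The defaults are the constants determined for the reference
#' whole-animal luminograph from a mixture calibration series of intact
#' FRET carriers and carriers loaded with donor or acceptor alone.
#'
#' The law must be strictly increasing in integrity (\code{b > 0},
#' \code{c > 0}), have a positive floor (\code{a > 0}, the residual ratio of
#' fully disintegrated carriers) and stay below 1 at full integrity
#' (\code{a + b < 1}, since the proximity ratio is a fraction).
#'
#' @param a Ratio offset at complete disintegration limit (dimensionless,
#'   \code{> 0}).
#' @param b Ratio amplitude (dimensionless, \code{> 0}).
#' @param c Rate per integrity percentage point (\code{> 0}).
#' @param rss Optional residual sum of squares from a fit.
#' @param n_points Optional number of calibration points behind the fit.
#' @return An object of class \code{"calibration_params"}.
#' @examples
#' cal <- calibration_params()
#' eval_calibration(cal, 100)
#' @export
calibration_params <- function(a = 0.14572, b = 0.1254, c = 0.01748,
                               rss = NA_real_, n_points = NA_integer_) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (!is.finite(a) || a <= 0)
    stop("calibration offset 'a' must be finite and > 0")
  if (!is.finite(b) || b <= 0)
    stop("calibration amplitude 'b' must be finite and > 0")
  if (!is.finite(c) || c <= 0)
    stop("calibration rate 'c' must be finite and > 0")
  if (a + b >= 1)
    stop("'a + b' must be < 1: the proximity ratio at 100% integrity is a fraction")
  structure(list(a = a, b = b, c = c, rss = rss, n_points = n_points),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf("Ratiometric calibration law: ratio = %.5g + %.5g * exp(%.5g * integrity)\n",
              x$a, x$b, x$c))
  if (is.finite(x$rss))
    cat(sprintf("  fit: rss = %.4g over %d points\n", x$rss, x$n_points))
  invisible(x)
}

#' Evaluate the calibration law
#'
#' Maps integrity (percent) to the expected proximity ratio
#' \eqn{A/(A+D) = a + b e^{c x}}.
#'
#' @param params A \code{\link{calibration_params}} object.
#' @param integrity Numeric vector of integrity percentages in \[0, 100\].
#' @return Numeric vector of proximity ratios, strictly increasing in
#'   integrity.
#' @export
eval_calibration <- function(params, integrity) {
  stopifnot(inherits(params, "calibration_params"), is.numeric(integrity))
  if (any(!is.finite(integrity)) || any(integrity < 0) || any(integrity > 100))
    stop("integrity must lie in [0, 100]")
  params$a + params$b * exp(params$c * integrity)
}

#' Invert the calibration law: proximity ratio to integrity
#'
#' Solves \eqn{x = \ln((y - a)/b)/c} and clamps the result to \[0, 100\].
#' In-vivo ratios from fully disintegrated carriers can fall at or below the
#' floor \eqn{a + b} of the law; those are clamped rather than rejected, and
#' the clamping is reported through flags so downstream summaries can
#' distinguish model-range saturation from genuine intermediate values.
#'
#' @param params A \code{\link{calibration_params}} object.
#' @param ratio Numeric vector of proximity ratios (finite).
#' @return Numeric vector of integrity percentages in \[0, 100\] with an
#'   attribute \code{"flag"}: \code{"ok"}, \code{"below_floor"} (ratio at or
#'   under the 0%-integrity value) or \code{"above_ceiling"} (ratio at or
#'   over the 100%-integrity value).
#' @export
invert_calibration <- function(params, ratio) {
  stopifnot(inherits(params, "calibration_params"), is.numeric(ratio))
  if (any(!is.finite(ratio))) stop("ratio must be finite")
  lo <- eval_calibration(params, 0)
  hi <- eval_calibration(params, 100)
  flag <- rep("ok", length(ratio))
  out <- numeric(length(ratio))
  below <- ratio <= lo
  above <- ratio >= hi
  mid <- !below & !above
  out[below] <- 0
  flag[below] <- "below_floor"
  out[above] <- 100
  flag[above] <- "above_ceiling"
  out[mid] <- log((ratio[mid] - params$a) / params$b) / params$c
  attr(out, "flag") <- flag
  out
}

#' Assemble a mixture calibration series
#'
#' A calibration series pairs known integrity levels (fraction of dye pairs
#' in intact FRET carriers within a mixture, percent) with measured proximity
#' ratios, typically acquired in triplicate on a well plate under the imaging
#' setup.
#'
#' @param integrity_percent Numeric vector in \[0, 100\].
#' @param ratio Numeric vector of proximity ratios in (0, 1).
#' @param sem Optional dispersion per record.
#' @return A \code{data.frame} of class \code{"calibration_series"} with
#'   columns \code{integrity_percent}, \code{ratio}, \code{sem}.
#' @export
calibration_series <- function(integrity_percent, ratio, sem = NA_real_) {
  stopifnot(is.numeric(integrity_percent), is.numeric(ratio),
            length(integrity_percent) == length(ratio))
  if (any(!is.finite(integrity_percent)) ||
      any(integrity_percent < 0) || any(integrity_percent > 100))
    stop("integrity levels must lie in [0, 100]")
  if (any(!is.finite(ratio)) || any(ratio <= 0) || any(ratio >= 1))
    stop("ratios must lie in (0, 1)")
  out <- data.frame(integrity_percent = integrity_percent, ratio = ratio,
                    sem = sem)
  class(out) <- c("calibration_series", "data.frame")
  out
}

#' Fit the exponential calibration law to a mixture series
#'
#' Least-squares fit of \eqn{y = a + b e^{c x}} by damped (Levenberg-
#' Marquardt) least squares. At least 4 distinct integrity levels are
#' required; with only three the three-parameter model is exactly determined
#' and the fit carries no information about lack of fit.
#'
#' The default initial guess is built from the data so that \code{b} and
#' \code{c} start positive: \code{a0 = min(ratio)/2},
#' \code{b0 = min(ratio) - a0}, and \code{c0} the log-slope that carries
#' \code{b0} to the observed ratio range across the integrity range.
#'
#' @param series A \code{\link{calibration_series}} (or data.frame with
#'   columns \code{integrity_percent} and \code{ratio}).
#' @param initial_guess Optional \code{\link{calibration_params}} start.
#' @return A \code{\link{calibration_params}} with \code{rss} and
#'   \code{n_points} filled in.
#' @export
fit_calibration <- function(series, initial_guess = NULL) {
  stopifnot(is.data.frame(series),
            all(c("integrity_percent", "ratio") %in% names(series)))
  x <- series$integrity_percent
  y <- series$ratio
  if (length(unique(x)) < 4L)
    stop("calibration fitting requires at least 4 distinct integrity levels")
  if (any(!is.finite(x)) || any(x < 0) || any(x > 100))
    stop("integrity levels must lie in [0, 100]")
  if (is.null(initial_guess)) {
    a0 <- min(y) / 2
    b0 <- min(y) - a0
    xr <- max(x) - min(x)
    c0 <- log(max((max(y) - a0) / b0, 1.001)) / max(xr, 1)
    start <- list(a = a0, b = b0, c = c0)
  } else {
    stopifnot(inherits(initial_guess, "calibration_params"))
    start <- list(a = initial_guess$a, b = initial_guess$b, c = initial_guess$c)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * exp(c * x),
                      start = start,
                      lower = c(a = 1e-12, b = 1e-12, c = 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("calibration fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  calibration_params(a = est[["a"]], b = est[["b"]], c = est[["c"]],
                     rss = sum(stats::resid(fit)^2),
                     n_points = length(y))
}

#' Read / write a calibration series as CSV
#'
#' CSV with header columns \code{integrity_percent}, \code{ratio} and
#' optionally \code{sem}; UTF-8, "." decimal.
#'
#' @param path File path.
#' @param series A \code{\link{calibration_series}}.
#' @return \code{read_calibration_csv} returns a
#'   \code{\link{calibration_series}}; the writer returns \code{path}
#'   invisibly.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path)
  if (!all(c("integrity_percent", "ratio") %in% names(df)))
    stop("calibration CSV must have columns 'integrity_percent' and 'ratio'")
  calibration_series(df$integrity_percent, df$ratio,
                     if ("sem" %in% names(df)) df$sem else NA_real_)
}

#' @rdname read_calibration_csv
#' @export
write_calibration_csv <- function(series, path) {
  atomic_write_csv(as.data.frame(series), path)
  invisible(path)
}

#' Read / write calibration parameters as JSON
#'
#' JSON record \code{{a, b, c, rss, n_points}}.
#'
#' @param params A \code{\link{calibration_params}}.
#' @param path File path.
#' @export
write_calibration_json <- function(params, path) {
  stopifnot(inherits(params, "calibration_params"))
  atomic_write_json(unclass(params), path)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_params(a = rec$a, b = rec$b, c = rec$c,
                     rss = if (is.null(rec$rss)) NA_real_ else rec$rss,
                     n_points = if (is.null(rec$n_points)) NA_integer_
                                else as.integer(rec$n_points))
}
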