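#' Logistic fit of an integrity time course
#'
#' Fits the four-parameter logistic
#' \deqn{y(t) = a_2 + \frac{a_1 - a_2}{1 + (t/x_0)^p}}
#' to an integrity time course by damped (Levenberg-Marquardt) least
#' squares under the physical bounds \eqn{0 \le a_2 \le a_1 \le 110},
#' \eqn{x_0 > 0}, \eqn{p > 0}. The upper plateau is allowed a modest
#' overshoot above 100% so noise around full integrity does not pin the
#' fit to the boundary. Initialization: \eqn{a_1} = first value,
#' \eqn{a_2} = last value, \eqn{x_0} = time of the point nearest the
#' half-way value, \eqn{p = 2}.
#'
#' @param tc Data frame with columns \code{time_h} and \code{value}
#'   (integrity percent); at least 4 post-injection points with
#'   \code{time_h > 0}.
#' @return An object of class \code{"logistic_fit"}: list with \code{a1},
#'   \code{a2}, \code{x0}, \code{p}, \code{rss}, \code{n}.
#' @export
fit_logistic <- function(tc) {
  stopifnot(is.data.frame(tc), all(c("time_h", "value") %in% names(tc)))
  tc <- tc[tc$time_h > 0, ]
  t <- tc$time_h
  y <- tc$value
  if (length(t) < 4L)
    stop("logistic fitting requires at least 4 post-injection points")
  if (stats::sd(y) < 1e-8 * max(1, abs(mean(y))))
    stop("degenerate fit: series is constant, a1 = a2 and x0 is unidentifiable")
  mid <- (max(y) + min(y)) / 2
  start <- list(a1 = y[1], a2 = y[length(y)],
                x0 = t[which.min(abs(y - mid))], p = 2)
  # keep the start strictly inside the bounds
  start$a1 <- min(max(start$a1, 1), 110)
  start$a2 <- min(max(start$a2, 0), start$a1 - 0.5)
  residual <- function(par)
    y - (par[2] + (par[1] - par[2]) / (1 + (t / par[3])^par[4]))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = unlist(start), fn = residual,
                       lower = c(0, 0, 1e-6, 1e-6),
                       upper = c(110, 110, 1e3, 50),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("logistic fit did not converge: ",
                             conditionMessage(e)))
  if (fit$info == 0 || fit$info == 9)
    stop("logistic fit did not converge after bounded iterations (last iterate: ",
         paste(sprintf("%.4g", fit$par), collapse = ", "), ")")
  est <- fit$par
  if (est[2] > est[1])
    stop("degenerate fit: increasing series, a2 > a1")
  structure(list(a1 = est[[1]], a2 = est[[2]], x0 = est[[3]],
                 p = est[[4]], rss = sum(fit$fvec^2), n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  hl <- half_life(x)
  cat(sprintf(
    "Logistic integrity fit: a1 = %.2f, a2 = %.2f, x0 = %.3f h, p = %.3f (rss %.3g, n %d)\n",
    x$a1, x$a2, x$x0, x$p, x$rss, x$n))
  cat(if (is.na(hl)) "  half-life: not reached\n"
      else sprintf("  half-life: %.2f h\n", hl))
  invisible(x)
}

#' Integrity half-life from a logistic fit
#'
#' The smallest \eqn{t > 0} at which the fitted curve crosses 50 absolute
#' integrity percent, in closed form
#' \deqn{t_{1/2} = x_0 \left(\frac{a_1 - a_2}{50 - a_2} - 1\right)^{1/p}.}
#' When the final plateau sits at or above 50% (or the initial plateau
#' below it) the curve never crosses and \code{NA} is returned rather than
#' an extrapolation.
#'
#' @param fit A \code{"logistic_fit"}.
#' @return Half-life in hours, or \code{NA} (not reached).
#' @export
half_life <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (fit$a2 >= 50 || fit$a1 <= 50) return(NA_real_)
  fit$x0 * ((fit$a1 - fit$a2) / (50 - fit$a2) - 1)^(1 / fit$p)
}

#' Evaluate a fitted logistic curve
#'
#' @param fit A \code{"logistic_fit"}.
#' @param t Times in hours.
#' @return Fitted integrity values.
#' @export
predict_logistic <- function(fit, t) {
  stopifnot(inherits(fit, "logistic_fit"))
  fit$a2 + (fit$a1 - fit$a2) / (1 + (t / fit$x0)^fit$p)
}

#' Mono-exponential clearance fit
#'
#' Fits \eqn{I(t) = I_0 \, 2^{-t/h}} to a background-corrected intensity
#' time course, estimating the amplitude \eqn{I_0} and the half-time
#' \eqn{h} (hours) by least squares. Used for the blood-circulation
#' half-time of donor-only control carriers.
#'
#' @param tc Data frame with columns \code{time_h} (\code{> 0}) and
#'   \code{value} (corrected counts); at least 3 points.
#' @return An object of class \code{"clearance_fit"}: list with \code{i0},
#'   \code{half_time_h}, \code{rss}, \code{n}. A series with no detectable
#'   decay returns \code{half_time_h = Inf} flagged via \code{no_decay}.
#' @export
fit_clearance <- function(tc) {
  stopifnot(is.data.frame(tc), all(c("time_h", "value") %in% names(tc)))
  tc <- tc[tc$time_h > 0, ]
  t <- tc$time_h
  y <- tc$value
  if (length(t) < 3L)
    stop("clearance fitting requires at least 3 post-injection points")
  if (all(y <= 0))
    stop("no positive intensities: nothing to fit")
  if (stats::sd(y) < 1e-10 * max(1, abs(mean(y)))) {
    return(structure(list(i0 = mean(y), half_time_h = Inf, rss = 0,
                          n = length(y), no_decay = TRUE),
                     class = "clearance_fit"))
  }
  # log-linear start where possible
  pos <- y > 0
  sl <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))
  h0 <- if (sl[2] < 0) -log(2) / sl[2] else max(t)
  start <- list(i0 = max(y), h = min(max(h0, 1e-3), 1e3))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ i0 * 2^(-t / h), start = start,
                      lower = c(i0 = 1e-12, h = 1e-6),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("clearance fit did not converge: ",
                             conditionMessage(e)))
  est <- stats::coef(fit)
  structure(list(i0 = est[["i0"]], half_time_h = est[["h"]],
                 rss = sum(stats::resid(fit)^2), n = length(y),
                 no_decay = FALSE),
            class = "clearance_fit")
}

#' @export
print.clearance_fit <- function(x, ...) {
  cat(if (x$no_decay)
        sprintf("Clearance fit: no detectable decay (I0 = %.1f counts)\n", x$i0)
      else sprintf("Clearance fit: I0 = %.1f counts, half-time = %.2f h (rss %.3g, n %d)\n",
                   x$i0, x$half_time_h, x$rss, x$n))
  invisible(x)
}

#' Write kinetics fits as JSON
#'
#' One record per region: \code{{a1, a2, x0, p, rss, half_life_h}}.
#'
#' @param fits Named list of \code{"logistic_fit"}s (name = region).
#' @param path Destination JSON path.
#' @export
write_fits_json <- function(fits, path) {
  recs <- lapply(fits, function(f) {
    stopifnot(inherits(f, "logistic_fit"))
    c(unclass(f), list(half_life_h = half_life(f)))
  })
  atomic_write_json(recs, path)
  invisible(path)
}
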