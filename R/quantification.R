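#' Mean intensity over a region of interest
#'
#' @param frame A \code{\link{channel_frame}}.
#' @param rois An \code{\link{roi_set}} on the same grid.
#' @param region Region name.
#' @return List with \code{mean} (raw mean counts) and \code{n_pixels}.
#' @export
roi_mean <- function(frame, rois, region) {
  stopifnot(inherits(frame, "channel_frame"), inherits(rois, "roi_set"))
  if (!all(dim(rois$mask) == dim(frame$data)))
    stop("ROI mask and frame grids differ")
  sel <- region_mask(rois, region)
  if (!any(sel)) stop("region '", region, "' selects no pixels")
  list(mean = mean(frame$data[sel]), n_pixels = sum(sel))
}

#' Background correction against the pre-injection frame
#'
#' Subtracts the ROI-matched pre-injection mean from the raw ROI mean.
#' Corrections that come out non-positive indicate the region has no signal
#' above autofluorescence; they are floored at 0 and flagged so downstream
#' ratios are never built from negative intensities.
#'
#' @param raw Raw ROI mean (counts, \code{>= 0}).
#' @param pre_injection Pre-injection ROI mean of the same region and
#'   channel (counts, \code{>= 0}).
#' @return List with \code{corrected} and logical
#'   \code{insufficient_signal}.
#' @export
background_correct <- function(raw, pre_injection) {
  stopifnot(is.numeric(raw), is.numeric(pre_injection),
            raw >= 0, pre_injection >= 0)
  corrected <- raw - pre_injection
  if (corrected <= 0) {
    list(corrected = 0, insufficient_signal = TRUE)
  } else {
    list(corrected = corrected, insufficient_signal = FALSE)
  }
}

#' FRET proximity ratio
#'
#' \eqn{E = A/(A+D)} from background-corrected acceptor and donor
#' intensities: a semi-quantitative surrogate for FRET efficiency, bounded
#' in \[0, 1\] and monotone in the acceptor share.
#'
#' @param acceptor_corrected,donor_corrected Corrected intensities
#'   (\code{>= 0}); their sum must be positive.
#' @return The ratio \eqn{E}.
#' @export
proximity_ratio <- function(acceptor_corrected, donor_corrected) {
  stopifnot(acceptor_corrected >= 0, donor_corrected >= 0)
  total <- acceptor_corrected + donor_corrected
  if (total == 0)
    stop("proximity ratio undefined: corrected acceptor + donor is 0")
  acceptor_corrected / total
}

#' ROI integrity time course from a phantom or animal study
#'
#' The quantification chain of the method, per region and post-injection
#' time: ROI mean per channel, background correction against the
#' pre-injection frame of the same region and channel, proximity ratio
#' \eqn{A/(A+D)}, and inversion of the calibration law into integrity
#' percent. Records where both channels are background-limited are dropped
#' with a warning; ratios outside the calibration range are clamped and
#' flagged.
#'
#' @param study An \code{"nc_study"} (from \code{\link{simulate_study}} or
#'   \code{\link{read_study}}); its time grid must start with the
#'   pre-injection time 0 for both channels.
#' @param calibration A \code{\link{calibration_params}}.
#' @param regions Regions to quantify; defaults to all ROI regions except
#'   \code{"body"}.
#' @return Data frame: \code{region}, \code{quantity} = "integrity",
#'   \code{time_h}, \code{value} (integrity percent), \code{ratio}
#'   (proximity ratio), \code{flag}.
#' @export
integrity_timecourse <- function(study, calibration = calibration_params(),
                                 regions = NULL) {
  stopifnot(inherits(study, "nc_study"))
  if (!0 %in% study$times)
    stop("study has no pre-injection (t = 0) frames for background correction")
  if (is.null(regions))
    regions <- setdiff(names(study$rois$labels), "body")
  out <- list()
  for (region in regions) {
    pre_d <- roi_mean(study_frame(study, 0, "donor"), study$rois, region)$mean
    pre_a <- roi_mean(study_frame(study, 0, "acceptor"), study$rois, region)$mean
    for (t in setdiff(study$times, 0)) {
      d <- background_correct(
        roi_mean(study_frame(study, t, "donor"), study$rois, region)$mean, pre_d)
      a <- background_correct(
        roi_mean(study_frame(study, t, "acceptor"), study$rois, region)$mean, pre_a)
      if (d$insufficient_signal && a$insufficient_signal) {
        warning("region '", region, "' at t = ", t,
                " h: no signal above background in either channel; record dropped")
        next
      }
      E <- proximity_ratio(a$corrected, d$corrected)
      integ <- invert_calibration(calibration, E)
      flag <- attr(integ, "flag")
      if (d$insufficient_signal || a$insufficient_signal)
        flag <- paste0(flag, "+insufficient_signal")
      out[[length(out) + 1L]] <- data.frame(
        region = region, quantity = "integrity", time_h = t,
        value = as.numeric(integ), ratio = E, flag = flag)
    }
  }
  do.call(rbind, out)
}

#' Background-corrected ROI intensity time course for one channel
#'
#' Used for clearance kinetics of donor-only control carriers, where the
#' donor intensity itself (not a ratio) tracks carrier concentration.
#'
#' @param study An \code{"nc_study"}.
#' @param region Region name.
#' @param channel \code{"donor"} or \code{"acceptor"}.
#' @return Data frame: \code{region}, \code{quantity} = "intensity",
#'   \code{time_h}, \code{value} (corrected counts), \code{flag}.
#' @export
intensity_timecourse <- function(study, region, channel = "donor") {
  stopifnot(inherits(study, "nc_study"))
  if (!0 %in% study$times)
    stop("study has no pre-injection (t = 0) frames for background correction")
  pre <- roi_mean(study_frame(study, 0, channel), study$rois, region)$mean
  recs <- lapply(setdiff(study$times, 0), function(t) {
    bc <- background_correct(
      roi_mean(study_frame(study, t, channel), study$rois, region)$mean, pre)
    data.frame(region = region, quantity = "intensity", time_h = t,
               value = bc$corrected,
               flag = if (bc$insufficient_signal) "insufficient_signal"
                      else "ok")
  })
  do.call(rbind, recs)
}

#' Average time courses over replicate subjects
#'
#' Subject-level ROI means are the unit of analysis; the dispersion
#' reported is the standard error of the mean over the n replicates, per
#' region and time.
#'
#' @param tc_list List of time-course data frames from replicate studies
#'   (same regions and time grid).
#' @return Data frame: \code{region}, \code{quantity}, \code{time_h},
#'   \code{value} (mean), \code{sem}, \code{n}.
#' @export
summarize_replicates <- function(tc_list) {
  stopifnot(is.list(tc_list), length(tc_list) >= 1L)
  all_tc <- do.call(rbind, tc_list)
  grp <- split(all_tc, list(all_tc$region, all_tc$quantity, all_tc$time_h),
               drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) {
    n <- nrow(g)
    data.frame(region = g$region[1], quantity = g$quantity[1],
               time_h = g$time_h[1], value = mean(g$value),
               sem = if (n > 1) stats::sd(g$value) / sqrt(n) else NA_real_,
               n = n)
  }))
  out <- out[order(out$region, out$quantity, out$time_h), ]
  rownames(out) <- NULL
  out
}

#' Two-sample comparison of group means
#'
#' Student's two-sample t-test (equal variances pooled) with a two-sided
#' alternative; the Welch unequal-variance variant is available behind a
#' flag. Differences are conventionally called significant at p < 0.05.
#'
#' @param values_a,values_b Numeric vectors, each of length \code{>= 2}.
#' @param welch Use the Welch unequal-variance t-test instead?
#' @return List with \code{statistic} (t), \code{df}, \code{p_value}.
#' @export
compare_groups <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 observations")
  ht <- stats::t.test(values_a, values_b, var.equal = !welch,
                      alternative = "two.sided")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}
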