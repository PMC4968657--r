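#' Expected two-channel signal of a region
#'
#' Forward model for one region at one time: the total carrier signal is
#' \eqn{S = brightness \times concentration(t)}; the calibration law gives
#' the proximity ratio \eqn{R} at the region's scheduled integrity, and the
#' signal splits as acceptor \eqn{= R S}, donor \eqn{= (1-R) S}. Donor-only
#' regions (no FRET pair) put the whole signal in the donor channel.
#' Channel backgrounds are added downstream by the frame generator, so
#' donor + acceptor always equals \eqn{S} here.
#'
#' @param region A \code{\link{region_spec}}.
#' @param t Time in hours (\code{>= 0}).
#' @param calibration A \code{\link{calibration_params}}.
#' @return Named numeric vector \code{c(donor = , acceptor = )}.
#' @export
expected_signal <- function(region, t, calibration = calibration_params()) {
  stopifnot(inherits(region, "region_spec"), t >= 0)
  S <- region$brightness * schedule_concentration(region, t)
  if (is.null(region$integrity)) {
    return(c(donor = S, acceptor = 0))
  }
  R <- eval_calibration(calibration, schedule_integrity(region, t))
  c(donor = (1 - R) * S, acceptor = R * S)
}

#' Generate one phantom frame
#'
#' Builds the expected-count image (channel background everywhere, plus the
#' region signal on each region's footprint) and applies the scenario's
#' noise model: Poisson shot noise on the expected counts, Gaussian read
#' noise, rounding to integer counts and clipping to the camera bit depth.
#' With the noise model fully off the continuous expected counts are
#' returned unquantized.
#'
#' @param scn A \code{\link{scenario}}.
#' @param t A time from \code{scn$times}.
#' @param channel \code{"donor"} or \code{"acceptor"}.
#' @param calibration A \code{\link{calibration_params}}.
#' @param subject Subject tag for the frame.
#' @return A \code{\link{channel_frame}}. Uses the current RNG state; seed
#'   upstream with \code{set.seed()} for reproducibility.
#' @export
generate_frame <- function(scn, t, channel, calibration = calibration_params(),
                           subject = scn$name) {
  stopifnot(inherits(scn, "scenario"))
  channel <- match.arg(channel, c("donor", "acceptor"))
  if (!t %in% scn$times)
    stop("t = ", t, " is not in the scenario time grid")
  bg <- if (channel == "donor") scn$background_donor else scn$background_acceptor
  expected <- matrix(bg, scn$dim[1], scn$dim[2])
  # t = 0 is the pre-injection frame: background and noise only, no carrier
  if (t > 0) {
    for (region in scn$regions) {
      sig <- expected_signal(region, t, calibration)[[channel]]
      expected[region$mask] <- expected[region$mask] + sig
    }
  }
  nm <- scn$noise
  if (is_noiseless(nm)) {
    counts <- expected
  } else {
    counts <- expected
    if (nm$shot) counts[] <- stats::rpois(length(counts), counts)
    if (nm$read_sd > 0)
      counts <- counts + stats::rnorm(length(counts), 0, nm$read_sd)
    counts <- pmin(pmax(round(counts), 0), 2^nm$bit_depth - 1)
  }
  channel_frame(counts, channel, t, subject)
}

#' Simulate a complete phantom study in memory
#'
#' One frame per (time, channel) plus the scenario ROI set, bundled as an
#' \code{"nc_study"}: the in-memory equivalent of an acquisition manifest.
#' Identical seeds give bit-identical studies.
#'
#' @param scn A \code{\link{scenario}}.
#' @param seed Integer seed for the acquisition noise.
#' @param calibration A \code{\link{calibration_params}}.
#' @param subject Subject tag.
#' @return An object of class \code{"nc_study"}: list with \code{frames}
#'   (list of \code{\link{channel_frame}}s keyed \code{"<t>_<channel>"}),
#'   \code{rois}, \code{times}, \code{scenario_name}, \code{subject},
#'   \code{seed}.
#' @export
simulate_study <- function(scn, seed = 1L, calibration = calibration_params(),
                           subject = paste0(scn$name, "_s", seed)) {
  stopifnot(inherits(scn, "scenario"))
  set.seed(seed)
  frames <- list()
  for (t in scn$times) {
    for (ch in c("donor", "acceptor")) {
      frames[[frame_key(t, ch)]] <-
        generate_frame(scn, t, ch, calibration, subject)
    }
  }
  structure(list(frames = frames, rois = scenario_rois(scn),
                 times = scn$times, scenario_name = scn$name,
                 subject = subject, seed = seed),
            class = "nc_study")
}

frame_key <- function(t, channel) sprintf("%gh_%s", t, channel)

#' Fetch one frame from a study
#'
#' @param study An \code{"nc_study"}.
#' @param t Time in hours.
#' @param channel \code{"donor"} or \code{"acceptor"}.
#' @return A \code{\link{channel_frame}}.
#' @export
study_frame <- function(study, t, channel) {
  stopifnot(inherits(study, "nc_study"))
  key <- frame_key(t, channel)
  if (is.null(study$frames[[key]]))
    stop("study has no frame for ", key)
  study$frames[[key]]
}

#' Write / read a phantom study to disk
#'
#' Writes one 16-bit grayscale TIFF (+ JSON sidecar) per (time, channel),
#' named \code{{scenario}_{t}h_{channel}.tif}, an 8-bit ROI label TIFF with
#' its JSON name table, and a manifest JSON listing files, times, channels,
#' seed and scenario name. \code{read_study} reconstructs the same
#' \code{"nc_study"}; a missing frame file is reported by name.
#'
#' @param study An \code{"nc_study"} from \code{\link{simulate_study}}.
#' @param dir Destination directory (created if needed).
#' @return \code{write_study} returns the manifest path invisibly;
#'   \code{read_study} returns an \code{"nc_study"}.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "nc_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- list()
  for (key in names(study$frames)) {
    fn <- sprintf("%s_%s.tif", study$scenario_name, key)
    write_frame(study$frames[[key]], file.path(dir, fn))
    files[[key]] <- fn
  }
  write_roiset(study$rois, file.path(dir, "rois.tif"),
               file.path(dir, "rois.json"))
  manifest <- list(scenario = study$scenario_name, subject = study$subject,
                   seed = study$seed, times = study$times,
                   channels = c("donor", "acceptor"), frames = files,
                   roi_mask = "rois.tif", roi_names = "rois.json")
  path <- file.path(dir, "manifest.json")
  atomic_write_json(manifest, path)
  invisible(path)
}

#' @rdname write_study
#' @param manifest_path Path to a study \code{manifest.json}.
#' @export
read_study <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("no such manifest: ", manifest_path)
  dir <- dirname(manifest_path)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  frames <- list()
  for (key in names(man$frames)) {
    fp <- file.path(dir, man$frames[[key]])
    if (!file.exists(fp))
      stop("manifest names a missing frame file: ", man$frames[[key]],
           " (", key, ")")
    frames[[key]] <- read_frame(fp)
  }
  shape <- dim(frames[[1]]$data)
  rois <- read_roiset(file.path(dir, man$roi_mask),
                      file.path(dir, man$roi_names), frame_shape = shape)
  structure(list(frames = frames, rois = rois, times = man$times,
                 scenario_name = man$scenario, subject = man$subject,
                 seed = man$seed),
            class = "nc_study")
}

#' Simulate a well-plate calibration series
#'
#' Triplicate proximity-ratio measurements at given integrity levels:
#' \code{ratio = eval_calibration(params, level) + N(0, sd)}. Ratios are
#' kept inside (0, 1) by clipping at machine-epsilon margins (relevant only
#' at unrealistically large noise).
#'
#' @param params A \code{\link{calibration_params}}.
#' @param levels Integrity levels in \[0, 100\].
#' @param sd Gaussian ratio noise standard deviation (\code{0} for a
#'   noiseless plate).
#' @param replicates Measurements per level.
#' @return A \code{\link{calibration_series}}.
#' @export
generate_calibration_plate <- function(params = calibration_params(),
                                       levels = seq(0, 100, by = 20),
                                       sd = 0.005, replicates = 3L) {
  if (any(levels < 0) || any(levels > 100))
    stop("integrity levels must lie in [0, 100]")
  lev <- rep(levels, each = replicates)
  ratio <- eval_calibration(params, lev)
  if (sd > 0) ratio <- ratio + stats::rnorm(length(ratio), 0, sd)
  ratio <- pmin(pmax(ratio, 1e-6), 1 - 1e-6)
  calibration_series(lev, ratio)
}
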