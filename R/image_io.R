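#' One channel frame of a two-channel NIR acquisition
#'
#' A frame is a 2-D grid of non-negative intensities (counts) from one
#' emission channel (donor, ~700 nm, or acceptor, ~820 nm) at one timepoint
#' for one subject or phantom. Pixel coordinates are 0-based, row-major,
#' origin top-left; time is always in hours; the nominal wavelength is
#' advisory metadata only.
#'
#' @param data Numeric matrix of counts, all \code{>= 0}, non-empty.
#' @param channel \code{"donor"} or \code{"acceptor"}.
#' @param time_h Acquisition time in hours (pre-injection frames are at 0).
#' @param subject Subject / scenario identifier string.
#' @param wavelength_nm Nominal emission wavelength; defaults to 700 for the
#'   donor channel and 820 for the acceptor channel.
#' @return An object of class \code{"channel_frame"}.
#' @export
channel_frame <- function(data, channel, time_h, subject = "phantom",
                          wavelength_nm = NULL) {
  if (!is.matrix(data) || !is.numeric(data) || length(data) == 0L)
    stop("frame data must be a non-empty numeric matrix")
  if (any(!is.finite(data)) || any(data < 0))
    stop("frame intensities must be finite and >= 0")
  channel <- match.arg(channel, c("donor", "acceptor"))
  if (is.null(wavelength_nm))
    wavelength_nm <- if (channel == "donor") 700 else 820
  stopifnot(is.numeric(time_h), length(time_h) == 1L, time_h >= 0)
  structure(list(data = data, channel = channel, time_h = time_h,
                 subject = as.character(subject),
                 wavelength_nm = wavelength_nm),
            class = "channel_frame")
}

#' @export
print.channel_frame <- function(x, ...) {
  cat(sprintf("channel_frame: %s (%g nm), t = %g h, subject '%s', %d x %d px, mean %.1f counts\n",
              x$channel, x$wavelength_nm, x$time_h, x$subject,
              nrow(x$data), ncol(x$data), mean(x$data)))
  invisible(x)
}

#' A labelled region-of-interest set
#'
#' Integer label mask on the same grid as the frames it annotates, plus a
#' mapping from label value to region name (e.g. tail_vein, liver, tumor,
#' body). Label 0 is reserved for unassigned pixels. Regions in living-mouse
#' work are delimited manually; synthetic masks carry provenance
#' \code{"synthetic"}.
#'
#' @param mask Integer matrix of labels (0 = none).
#' @param labels Named integer vector or list mapping region name -> label.
#' @param provenance \code{"manual"} or \code{"synthetic"}.
#' @return An object of class \code{"roi_set"}.
#' @export
roi_set <- function(mask, labels, provenance = c("synthetic", "manual")) {
  provenance <- match.arg(provenance)
  if (!is.matrix(mask) || length(mask) == 0L)
    stop("ROI mask must be a non-empty matrix")
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  labels <- unlist(labels)
  if (is.null(names(labels)) || any(!nzchar(names(labels))))
    stop("ROI labels must be a named vector: region name -> label value")
  missing <- setdiff(as.integer(labels), unique(as.vector(mask)))
  if (length(missing) > 0L)
    stop("labels not present in mask: ",
         paste(names(labels)[labels %in% missing], collapse = ", "))
  structure(list(mask = mask, labels = labels, provenance = provenance),
            class = "roi_set")
}

#' Region mask lookup
#'
#' @param rois An \code{\link{roi_set}}.
#' @param region Region name present in the label table.
#' @return Logical matrix selecting the region's pixels.
#' @export
region_mask <- function(rois, region) {
  stopifnot(inherits(rois, "roi_set"))
  if (!region %in% names(rois$labels))
    stop("unknown region '", region, "'; available: ",
         paste(names(rois$labels), collapse = ", "))
  rois$mask == rois$labels[[region]]
}

# ---- TIFF frame I/O -------------------------------------------------------

frame_sidecar_path <- function(path) paste0(path, ".json")

#' Write / read a channel frame as 16-bit grayscale TIFF + JSON sidecar
#'
#' Intensities are stored as 16-bit unsigned integers (counts 0..65535);
#' non-integer data (noise-free simulations) are stored as 32-bit float
#' TIFF instead so round trips are lossless either way. Frame metadata
#' (channel, time, subject, wavelength) lives in a JSON sidecar next to the
#' TIFF; vendor TIFF tags are not used. Writes are atomic
#' (write-then-rename).
#'
#' @param frame A \code{\link{channel_frame}}.
#' @param path Destination \code{.tif} path.
#' @return \code{read_frame} returns a \code{\link{channel_frame}};
#'   \code{write_frame} returns \code{path} invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "channel_frame"))
  d <- frame$data
  integerish <- all(d == round(d)) && max(d) <= 65535
  scale <- if (integerish) 65535 else max(1, max(d))
  atomic_write(path, function(tmp) {
    if (integerish) {
      tiff::writeTIFF(d / 65535, tmp, bits.per.sample = 16L,
                      compression = "none")
    } else {
      # float frames (noise-free simulations) are stored as 32-bit float
      # scaled into [0,1]; the scale lives in the sidecar
      tiff::writeTIFF(d / scale, tmp, bits.per.sample = 32L,
                      compression = "none")
    }
  })
  meta <- list(channel = frame$channel, time_h = frame$time_h,
               subject = frame$subject, wavelength_nm = frame$wavelength_nm,
               encoding = if (integerish) "uint16" else "float32",
               scale = scale)
  atomic_write_json(meta, frame_sidecar_path(path))
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stop("no such frame file: ", path)
  sidecar <- frame_sidecar_path(path)
  if (!file.exists(sidecar))
    stop("missing metadata sidecar for frame: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  img <- tryCatch(tiff::readTIFF(path, info = TRUE),
                  error = function(e) stop("malformed TIFF at ", path, ": ",
                                           conditionMessage(e)))
  if (length(dim(img)) == 3L)
    stop("multi-channel (RGB) TIFF not supported: channels must be separate files")
  bits <- attr(img, "bits.per.sample")
  if (identical(meta$encoding, "uint16")) {
    if (!is.null(bits) && bits == 8L) {
      warning("8-bit frame promoted to 16-bit counts")
      img <- round(img * 255)
    } else {
      img <- round(img * 65535)
    }
  } else {
    img <- img * meta$scale
  }
  attributes(img) <- list(dim = dim(img))
  channel_frame(img, meta$channel, meta$time_h, meta$subject,
                meta$wavelength_nm)
}

#' Write / read an ROI label set (8-bit TIFF + JSON name table)
#'
#' @param rois An \code{\link{roi_set}} with labels in 0..255.
#' @param mask_path Destination label-mask \code{.tif} path.
#' @param names_path Destination JSON path for the name -> label table.
#' @export
write_roiset <- function(rois, mask_path, names_path) {
  stopifnot(inherits(rois, "roi_set"))
  if (max(rois$mask) > 255L) stop("ROI labels must fit in 8 bits")
  atomic_write(mask_path, function(tmp)
    tiff::writeTIFF(rois$mask / 255, tmp, bits.per.sample = 8L,
                    compression = "none"))
  atomic_write_json(list(labels = as.list(rois$labels),
                         provenance = rois$provenance), names_path)
  invisible(mask_path)
}

#' @rdname write_roiset
#' @param frame_shape Optional \code{c(nrow, ncol)} to validate against.
#' @export
read_roiset <- function(mask_path, names_path, frame_shape = NULL) {
  if (!file.exists(mask_path)) stop("no such ROI mask: ", mask_path)
  if (!file.exists(names_path)) stop("no such ROI name table: ", names_path)
  mask <- round(tiff::readTIFF(mask_path) * 255)
  meta <- jsonlite::read_json(names_path, simplifyVector = TRUE)
  if (!is.null(frame_shape) && !all(dim(mask) == frame_shape))
    stop("ROI mask shape ", paste(dim(mask), collapse = "x"),
         " does not match frame shape ", paste(frame_shape, collapse = "x"))
  roi_set(mask, unlist(meta$labels),
          provenance = if (is.null(meta$provenance)) "synthetic"
                       else meta$provenance)
}

# ---- time-course tables ---------------------------------------------------

#' Write / read a time-course table as CSV
#'
#' Columns: \code{region}, \code{quantity} (ratio | integrity | intensity),
#' \code{time_h}, \code{value}, \code{sem}, \code{n}, \code{flag}. Times must
#' be strictly increasing within each region/quantity group.
#'
#' @param tc Data frame with at least \code{region}, \code{quantity},
#'   \code{time_h}, \code{value}.
#' @param path CSV destination.
#' @export
write_timecourse_csv <- function(tc, path) {
  check_timecourse(tc)
  atomic_write_csv(tc, path)
  invisible(path)
}

#' @rdname write_timecourse_csv
#' @export
read_timecourse_csv <- function(path) {
  if (!file.exists(path)) stop("no such time-course file: ", path)
  tc <- utils::read.csv(path)
  check_timecourse(tc)
  tc
}

check_timecourse <- function(tc) {
  need <- c("region", "quantity", "time_h", "value")
  if (!all(need %in% names(tc)))
    stop("time course must have columns: ", paste(need, collapse = ", "))
  by_grp <- split(tc$time_h, paste(tc$region, tc$quantity))
  bad <- vapply(by_grp, function(t) any(diff(t) <= 0), logical(1))
  if (any(bad))
    stop("times must be strictly increasing within region/quantity: ",
         paste(names(by_grp)[bad], collapse = ", "))
  invisible(tc)
}
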