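#' Emission spectrum container
#'
#' Wavelength grid (nm, strictly increasing, at least 20 points) and
#' non-negative intensities, with the excitation wavelength and optionally
#' the absorbance at excitation. Relative quantum-yield work requires the
#' absorbance, which must stay at or below 0.1 so inner-filter effects are
#' negligible.
#'
#' @param wavelength_nm Strictly increasing numeric vector (>= 20 points).
#' @param intensity Non-negative intensities (a.u.), same length.
#' @param excitation_nm Excitation wavelength; must be below the first
#'   emission wavelength.
#' @param label Sample label.
#' @param absorbance Optional absorbance at the excitation wavelength, in
#'   (0, 0.1].
#' @return An object of class \code{"emission_spectrum"}.
#' @export
emission_spectrum <- function(wavelength_nm, intensity, excitation_nm,
                              label = "sample", absorbance = NULL) {
  stopifnot(is.numeric(wavelength_nm), is.numeric(intensity),
            length(wavelength_nm) == length(intensity))
  if (length(wavelength_nm) < 20L)
    stop("spectrum needs at least 20 wavelength points")
  if (any(diff(wavelength_nm) <= 0))
    stop("wavelength grid must be strictly increasing")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be finite and >= 0")
  if (excitation_nm >= wavelength_nm[1])
    stop("excitation wavelength must be below the first emission wavelength")
  if (!is.null(absorbance)) {
    if (!is.finite(absorbance) || absorbance <= 0 || absorbance > 0.1)
      stop("absorbance at excitation must lie in (0, 0.1]")
  }
  structure(list(wavelength_nm = wavelength_nm, intensity = intensity,
                 excitation_nm = excitation_nm, label = label,
                 absorbance = absorbance),
            class = "emission_spectrum")
}

default_donor_window <- c(690, 760)
default_acceptor_window <- c(790, 900)

in_window <- function(spec, window) {
  sel <- spec$wavelength_nm >= window[1] & spec$wavelength_nm <= window[2]
  if (!any(sel))
    stop("window [", window[1], ", ", window[2],
         "] nm lies outside the spectrum grid")
  sel
}

#' Donor and acceptor band maxima of a two-band spectrum
#'
#' Maximum intensity within each emission window. Defaults (donor
#' 690--760 nm, acceptor 790--900 nm) bracket the ~700 nm donor and
#' ~820--840 nm acceptor emission bands of the NIR cyanine pair.
#'
#' @param spec An \code{\link{emission_spectrum}}.
#' @param donor_window,acceptor_window \code{c(min, max)} in nm; must be
#'   disjoint and within the grid.
#' @return Named vector \code{c(D = , A = )} of band maxima.
#' @export
band_maxima <- function(spec, donor_window = default_donor_window,
                        acceptor_window = default_acceptor_window) {
  stopifnot(inherits(spec, "emission_spectrum"))
  if (donor_window[2] >= acceptor_window[1] &&
      acceptor_window[2] >= donor_window[1])
    stop("donor and acceptor windows must be disjoint")
  c(D = max(spec$intensity[in_window(spec, donor_window)]),
    A = max(spec$intensity[in_window(spec, acceptor_window)]))
}

#' Proximity ratio from an emission spectrum
#'
#' \eqn{E = A/(A+D)} where A and D are the band maxima of the acceptor and
#' donor emission windows.
#'
#' @inheritParams band_maxima
#' @return The ratio \eqn{E} in \[0, 1\].
#' @export
spectrum_proximity_ratio <- function(spec,
                                     donor_window = default_donor_window,
                                     acceptor_window = default_acceptor_window) {
  m <- band_maxima(spec, donor_window, acceptor_window)
  proximity_ratio(m[["A"]], m[["D"]])
}

#' Serum/water stability series of the proximity ratio
#'
#' Computes \eqn{E = A/(A+D)} for spectra recorded at increasing incubation
#' times, the cuvette-level stability readout of FRET carriers in serum or
#' water.
#'
#' @param spectra List of \code{\link{emission_spectrum}}s.
#' @param times_h Strictly increasing incubation times (hours), one per
#'   spectrum.
#' @inheritParams band_maxima
#' @return Data frame: \code{time_h}, \code{value} (E), \code{quantity} =
#'   "ratio".
#' @export
stability_series <- function(spectra, times_h,
                             donor_window = default_donor_window,
                             acceptor_window = default_acceptor_window) {
  stopifnot(is.list(spectra), length(spectra) == length(times_h))
  if (any(diff(times_h) <= 0))
    stop("incubation times must be strictly increasing")
  E <- vapply(spectra, spectrum_proximity_ratio, numeric(1),
              donor_window = donor_window, acceptor_window = acceptor_window)
  data.frame(time_h = times_h, value = E, quantity = "ratio")
}

#' Relative fluorescence quantum yield
#'
#' The standard relative method against a reference fluorophore of known
#' yield under matched low absorbance:
#' \deqn{QY = QY_{ref} \cdot \frac{\int F_{sample}}{\int F_{ref}} \cdot
#'       \frac{Abs_{ref}}{Abs_{sample}} \cdot \frac{n_{sample}^2}{n_{ref}^2}}
#' with integrals over the full emission band (trapezoidal rule). Both
#' spectra must carry their absorbance at excitation (<= 0.1). The
#' refractive-index correction defaults to unity indices and is
#' configurable. Note the distinction from the proximity ratio: the yield
#' uses integrated band areas, the ratio uses band maxima.
#'
#' @param sample,reference \code{\link{emission_spectrum}}s with absorbance
#'   set.
#' @param reference_qy Known quantum yield of the reference (fraction).
#' @param refractive_indices \code{c(sample = , reference = )}.
#' @return Quantum yield of the sample (fraction).
#' @export
relative_quantum_yield <- function(sample, reference, reference_qy = 0.33,
                                   refractive_indices = c(sample = 1,
                                                          reference = 1)) {
  stopifnot(inherits(sample, "emission_spectrum"),
            inherits(reference, "emission_spectrum"),
            reference_qy > 0, reference_qy <= 1)
  if (is.null(sample$absorbance) || is.null(reference$absorbance))
    stop("both spectra must carry the absorbance at excitation")
  area <- function(s) {
    w <- s$wavelength_nm
    sum(diff(w) * (s$intensity[-1] + s$intensity[-length(s$intensity)]) / 2)
  }
  ref_area <- area(reference)
  if (ref_area <= 0) stop("reference spectrum has zero integrated intensity")
  reference_qy * (area(sample) / ref_area) *
    (reference$absorbance / sample$absorbance) *
    (refractive_indices[["sample"]]^2 / refractive_indices[["reference"]]^2)
}

#' Read / write an emission spectrum (two-column CSV + JSON sidecar)
#'
#' CSV columns \code{wavelength_nm}, \code{intensity}; the sidecar holds
#' \code{excitation_nm}, \code{label} and optional \code{absorbance}.
#'
#' @param spec An \code{\link{emission_spectrum}}.
#' @param path CSV destination.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "emission_spectrum"))
  atomic_write_csv(data.frame(wavelength_nm = spec$wavelength_nm,
                              intensity = spec$intensity), path)
  atomic_write_json(list(excitation_nm = spec$excitation_nm,
                         label = spec$label,
                         absorbance = spec$absorbance),
                    paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop("no such spectrum file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing spectrum sidecar: ", sidecar)
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  emission_spectrum(df$wavelength_nm, df$intensity, meta$excitation_nm,
                    label = meta$label, absorbance = meta$absorbance)
}

#' Synthetic two-band emission spectrum
#'
#' Sum of two Gaussian bands (donor ~700 nm, acceptor ~840 nm) on a regular
#' grid; a convenience generator for spectroscopy tests and examples.
#'
#' @param donor_peak,acceptor_peak Peak intensities.
#' @param donor_center,acceptor_center Band centers (nm).
#' @param width Gaussian sigma (nm).
#' @param excitation_nm Excitation wavelength.
#' @param absorbance Optional absorbance at excitation.
#' @param grid Wavelength grid (nm).
#' @return An \code{\link{emission_spectrum}}.
#' @export
two_band_spectrum <- function(donor_peak = 100, acceptor_peak = 300,
                              donor_center = 700, acceptor_center = 840,
                              width = 20, excitation_nm = 670,
                              absorbance = NULL,
                              grid = seq(680, 920, by = 2)) {
  intensity <- donor_peak * exp(-(grid - donor_center)^2 / (2 * width^2)) +
    acceptor_peak * exp(-(grid - acceptor_center)^2 / (2 * width^2))
  emission_spectrum(grid, intensity, excitation_nm,
                    label = "synthetic two-band", absorbance = absorbance)
}
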