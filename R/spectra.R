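#' Construct a DRIFT spectrum
#'
#' A mid-infrared spectrum is a wavenumber grid (cm^-1) with matching
#' absorbance values. Grids may be supplied ascending or descending; they
#' are canonicalised to descending (instrument convention, 4000 to 400).
#'
#' @param wavenumber Numeric grid, cm^-1, strictly monotone.
#' @param absorbance Numeric vector of the same length.
#' @param normalised Logical flag: `TRUE` once the maximum has been scaled
#'   to exactly 1 (see [normalize_max()]).
#' @return A `drift_spectrum` object.
#' @export
drift_spectrum <- function(wavenumber, absorbance, normalised = FALSE) {
  stopifnot(is.numeric(wavenumber), is.numeric(absorbance),
            length(wavenumber) == length(absorbance),
            length(wavenumber) >= 2)
  d <- diff(wavenumber)
  if (all(d > 0)) {
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  } else if (!all(d < 0)) {
    stop("`wavenumber` must be strictly monotone")
  }
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 normalised = isTRUE(normalised)),
            class = "drift_spectrum")
}

#' @export
print.drift_spectrum <- function(x, ...) {
  cat("DRIFT spectrum:", length(x$wavenumber), "points,",
      max(x$wavenumber), "to", min(x$wavenumber), "cm-1",
      if (x$normalised) "(max-normalised)" else "", "\n")
  invisible(x)
}

#' Diagnostic absorbance band windows
#'
#' Named wavenumber windows (cm^-1) used to read maximum peak absorbance
#' for litter-quality compound ratios: aliphatic C-H stretch, aromatic
#' C=C/COO-, amide I-III, lignin C=C and polysaccharide C-O. Note that the
#' narrow amide I window lies inside the aromatic window; both are always
#' evaluated independently.
#'
#' @return Named list of `c(low, high)` windows.
#' @export
default_bands <- function() {
  list(
    Aliphatic = c(2915, 2990),
    Aromatic = c(1600, 1660),
    AmideI = c(1652, 1658),
    AmideII = c(1540, 1548),
    Lignin = c(1504, 1512),
    AmideIII = c(1230, 1320),
    Polysaccharides = c(1140, 1180))
}

#' Normalise a spectrum to its maximum absorbance
#'
#' @param spec A [drift_spectrum()].
#' @return The spectrum divided by its maximum (so the maximum is exactly
#'   1), with the `normalised` flag set. Idempotent.
#' @export
normalize_max <- function(spec) {
  stopifnot(inherits(spec, "drift_spectrum"))
  m <- max(spec$absorbance)
  if (m <= 0) stop("cannot normalise: maximum absorbance is not positive")
  drift_spectrum(spec$wavenumber, spec$absorbance / m, normalised = TRUE)
}

#' Maximum absorbance within a band window
#'
#' Both window ends are inclusive; ties in the maximum resolve toward the
#' lower wavenumber (irrelevant for the value itself).
#'
#' @param spec A [drift_spectrum()].
#' @param band `c(low, high)` window in cm^-1, or the name of a band in
#'   `bands`.
#' @param bands Named band list used when `band` is a name.
#' @return The maximum absorbance over grid points inside the window.
#' @export
band_max <- function(spec, band, bands = default_bands()) {
  stopifnot(inherits(spec, "drift_spectrum"))
  name <- NULL
  if (is.character(band)) {
    name <- band
    if (is.null(bands[[name]])) stop("unknown band: ", name)
    band <- bands[[name]]
  }
  if (length(band) != 2 || band[1] >= band[2])
    stop("band window must be c(low, high) with low < high")
  inside <- spec$wavenumber >= band[1] & spec$wavenumber <= band[2]
  if (!any(inside))
    stop("band ", if (is.null(name)) paste(band, collapse = "-") else name,
         " does not intersect the wavenumber grid")
  max(spec$absorbance[inside])
}

#' Litter-quality compound ratios from a spectrum
#'
#' Each ratio is the maximum absorbance of the numerator band divided by
#' that of the denominator band. Ratios are invariant to any positive
#' scaling of the spectrum, so raw and max-normalised spectra give the
#' same result.
#'
#' @param spec A [drift_spectrum()].
#' @param bands Band windows, see [default_bands()].
#' @return One-row tibble with `aliphatic_aromatic`,
#'   `polysaccharide_lignin`, `aliphatic_amide1`, `aliphatic_amide2` and
#'   `aliphatic_amide3`.
#' @export
compound_ratios <- function(spec, bands = default_bands()) {
  bm <- vapply(names(bands), function(b) band_max(spec, b, bands),
               numeric(1))
  ratio <- function(num, den) {
    if (bm[[den]] <= 0) stop("zero maximum absorbance in band ", den)
    bm[[num]] / bm[[den]]
  }
  tibble::tibble(
    aliphatic_aromatic = ratio("Aliphatic", "Aromatic"),
    polysaccharide_lignin = ratio("Polysaccharides", "Lignin"),
    aliphatic_amide1 = ratio("Aliphatic", "AmideI"),
    aliphatic_amide2 = ratio("Aliphatic", "AmideII"),
    aliphatic_amide3 = ratio("Aliphatic", "AmideIII"))
}

#' Pointwise mean of replicate spectra
#'
#' @param spectra List of [drift_spectrum()] objects sharing the same grid.
#' @return A single averaged spectrum.
#' @export
average_replicates <- function(spectra) {
  stopifnot(length(spectra) >= 1,
            all(vapply(spectra, inherits, logical(1), "drift_spectrum")))
  grid <- spectra[[1]]$wavenumber
  for (sp in spectra[-1])
    if (!isTRUE(all.equal(sp$wavenumber, grid)))
      stop("replicate spectra are on different wavenumber grids")
  abs_mat <- vapply(spectra, `[[`, numeric(length(grid)), "absorbance")
  drift_spectrum(grid, rowMeans(abs_mat))
}

# Target band maxima as a function of litter C:N. The aliphatic target is
# affine in C:N; every other band's target follows from the calibrated
# compound-ratio curves, which interpolate the reference ratio table
# (reference_compound_ratios()) monotonically through the four measured
# litters with flat extrapolation outside [50, 124]. The lignin level is
# only constrained relative to polysaccharides, so its absolute target is
# tied to the aromatic one.
spectrum_band_targets <- function(cn_ratio) {
  ref <- reference_compound_ratios()
  interp <- function(col) stats::approx(ref$cn_ratio, ref[[col]],
                                        xout = cn_ratio, rule = 2)$y
  aliphatic <- 0.55 + 0.002 * cn_ratio
  aromatic <- aliphatic / interp("aliphatic_aromatic")
  lignin <- 0.40 * aromatic
  c(Aliphatic = aliphatic,
    Aromatic = aromatic,
    AmideI = aliphatic / interp("aliphatic_amide1"),
    AmideII = aliphatic / interp("aliphatic_amide2"),
    Lignin = lignin,
    AmideIII = aliphatic / interp("aliphatic_amide3"),
    Polysaccharides = lignin * interp("polysaccharide_lignin"))
}

spectrum_peak_centres <- c(
  Aliphatic = 2925, Aromatic = 1620, AmideI = 1655, AmideII = 1544,
  Lignin = 1508, AmideIII = 1270, Polysaccharides = 1160)
spectrum_peak_widths <- c(
  Aliphatic = 25, Aromatic = 16, AmideI = 3, AmideII = 4,
  Lignin = 4, AmideIII = 30, Polysaccharides = 15)

#' Generate a synthetic litter DRIFT spectrum
#'
#' Builds a smooth spectrum on the instrument grid (4000 to 400 cm^-1 at
#' 4 cm^-1, descending) as a sum of Gaussian peaks centred inside the
#' diagnostic band windows plus a broad low baseline, with optional
#' additive noise drawn from the current RNG state. Peak amplitudes are
#' solved numerically (fixed-point, accounting for band overlap and the
#' baseline) so that the in-band maxima hit C:N-dependent targets
#' calibrated to the reference compound-ratio table; at zero noise the
#' compound ratios of the generated spectrum therefore reproduce the
#' reference values at the measured C:N ratios.
#'
#' @param cn_ratio Litter C:N, in \[20, 200\].
#' @param noise_sd SD of additive absorbance noise; 0 for a clean spectrum.
#' @return A raw (non-normalised) [drift_spectrum()].
#' @export
generate_spectrum <- function(cn_ratio, noise_sd = 0.002) {
  if (!is.numeric(cn_ratio) || cn_ratio < 20 || cn_ratio > 200)
    stop("`cn_ratio` must lie in [20, 200]")
  grid <- seq(4000, 400, by = -4)
  baseline <- 0.01 + 0.02 * exp(-((grid - 2000) / 900)^2)
  bands <- default_bands()
  targets <- spectrum_band_targets(cn_ratio)
  gauss <- vapply(names(targets), function(b)
    exp(-((grid - spectrum_peak_centres[[b]])^2 /
            (2 * spectrum_peak_widths[[b]]^2))),
    numeric(length(grid)))
  amps <- targets
  for (i in 1:40) {
    clean <- baseline + drop(gauss %*% amps)
    sp <- drift_spectrum(grid, clean)
    measured <- vapply(names(targets), function(b) band_max(sp, b, bands),
                       numeric(1))
    amps <- pmax(1e-6, amps * (targets / measured))
    if (max(abs(measured - targets) / targets) < 1e-10) break
  }
  clean <- baseline + drop(gauss %*% amps)
  if (noise_sd > 0) clean <- clean + stats::rnorm(length(grid), 0, noise_sd)
  drift_spectrum(grid, clean)
}

#' Read and write spectra as CSV
#'
#' Columns `wavenumber_cm1, absorbance`, one file per spectrum.
#'
#' @param spec A [drift_spectrum()].
#' @param path File path.
#' @return `read_spectrum()` returns a [drift_spectrum()].
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "drift_spectrum"))
  readr::write_csv(tibble::tibble(wavenumber_cm1 = spec$wavenumber,
                                  absorbance = spec$absorbance), path)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("wavenumber_cm1", "absorbance") %in% names(d)))
    stop("spectrum file needs columns wavenumber_cm1, absorbance")
  drift_spectrum(d$wavenumber_cm1, d$absorbance)
}
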