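#' Wavelength grid
#'
#' A regular wavelength grid defined by start, stop and step. The grid holds
#' `floor((stop - start) / step) + 1` points; when binning, consecutive points
#' act as bin edges so the grid carries `floor((stop - start) / step)` bins.
#'
#' @param start First wavelength (nm).
#' @param stop Last wavelength (nm); must exceed `start`.
#' @param step Increment (nm); must be positive.
#' @return An object of class `wavelength_grid` with elements `start`, `stop`,
#'   `step` and `wavelengths` (the grid points).
#' @examples
#' g <- wavelength_grid(460, 625, 7.5)
#' length(g$wavelengths)  # 23 points -> 22 bins
#' @export
wavelength_grid <- function(start, stop, step) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step))
  if (!(start < stop)) stop("wavelength grid requires start < stop")
  if (!(step > 0)) stop("wavelength grid requires step > 0")
  n <- floor((stop - start) / step + 1e-9) + 1L
  structure(
    list(start = start, stop = stop, step = step,
         wavelengths = start + (seq_len(n) - 1L) * step),
    class = "wavelength_grid"
  )
}

#' Common working grid for inter-spectrum arithmetic
#'
#' All spectral arithmetic (overlap integrals, emission simulation) is done on
#' a 1 nm grid from 300 to 800 nm, finer than any bundled spectrum, so linear
#' interpolation onto it introduces negligible integration error.
#'
#' @return A `wavelength_grid`.
#' @export
working_grid <- function() wavelength_grid(300, 800, 1)

#' Fluorophore record
#'
#' Bundles the reference data of one fluorophore: its unit-area emission
#' density f(lambda) (1/nm), molar extinction epsilon(lambda)
#' (M^-1 cm^-1), quantum yield Q, and unquenched excited-state lifetime tau
#' (ns). Emission and extinction are stored resampled onto the common working
#' grid; outside their native support they are zero (physical spectra vanish
#' outside the measured range).
#'
#' @param name Identifier.
#' @param emission_wl,emission Wavelengths (nm, strictly increasing) and
#'   non-negative emission values; renormalised to unit area (trapezoid).
#' @param extinction_wl,extinction Wavelengths (nm, strictly increasing) and
#'   non-negative molar extinction values (M^-1 cm^-1).
#' @param quantum_yield Q in \[0, 1\].
#' @param lifetime Unquenched lifetime tau (ns), positive.
#' @param maturation_note Free-text metadata; not used in computation.
#' @return An object of class `fluorophore`.
#' @export
fluorophore_record <- function(name, emission_wl, emission,
                               extinction_wl, extinction,
                               quantum_yield, lifetime,
                               maturation_note = NULL) {
  check_spectrum_columns(emission_wl, emission, "emission")
  check_spectrum_columns(extinction_wl, extinction, "extinction")
  if (!is.numeric(quantum_yield) || length(quantum_yield) != 1 ||
      is.na(quantum_yield) || quantum_yield < 0 || quantum_yield > 1)
    stop("quantum_yield must be a single value in [0, 1]")
  if (!is.numeric(lifetime) || length(lifetime) != 1 || is.na(lifetime) ||
      lifetime <= 0)
    stop("lifetime must be a single positive value (ns)")

  grid <- working_grid()
  wl <- grid$wavelengths
  em <- interp_zero(emission_wl, emission, wl)
  ex <- interp_zero(extinction_wl, extinction, wl)
  area <- trapz_int(wl, em)
  if (area <= 0) stop("emission spectrum has zero area on the working grid")
  em <- em / area

  structure(
    list(name = name, wavelengths = wl, emission_shape = em, extinction = ex,
         quantum_yield = quantum_yield, lifetime = lifetime,
         maturation_note = maturation_note),
    class = "fluorophore"
  )
}

#' @export
print.fluorophore <- function(x, ...) {
  peak_em <- x$wavelengths[which.max(x$emission_shape)]
  peak_ex <- x$wavelengths[which.max(x$extinction)]
  cat(sprintf(
    "<fluorophore> %s  em peak %g nm  abs peak %g nm  Q = %.3g  tau = %.3g ns\n",
    x$name, peak_em, peak_ex, x$quantum_yield, x$lifetime))
  invisible(x)
}

#' Load a fluorophore from spectrum CSV files
#'
#' Reads an emission spectrum CSV (header `wavelength_nm,value`, strictly
#' increasing wavelengths, non-negative values) and optionally an extinction
#' spectrum CSV in the same format. The extinction values are rescaled so
#' their maximum equals `metadata$extinction_max`; if no extinction file is
#' given the extinction is zero everywhere.
#'
#' @param path Emission spectrum CSV path.
#' @param metadata List with `name`, `quantum_yield`, `lifetime_ns`, and,
#'   when `extinction_path` is given, `extinction_max` (M^-1 cm^-1).
#' @param extinction_path Optional extinction/absorbance CSV path.
#' @return A [fluorophore_record()].
#' @export
load_spectrum <- function(path, metadata, extinction_path = NULL) {
  for (key in c("name", "quantum_yield", "lifetime_ns")) {
    if (is.null(metadata[[key]]))
      stop("metadata is missing required field '", key, "'")
  }
  em <- read_spectrum_csv(path)
  if (!is.null(extinction_path)) {
    if (is.null(metadata$extinction_max))
      stop("metadata is missing required field 'extinction_max'")
    ex <- read_spectrum_csv(extinction_path)
    mx <- max(ex$value)
    if (mx <= 0) stop("extinction spectrum is identically zero")
    ex$value <- ex$value / mx * metadata$extinction_max
  } else {
    ex <- data.frame(wavelength_nm = em$wavelength_nm,
                     value = rep(0, nrow(em)))
  }
  fluorophore_record(
    name = metadata$name,
    emission_wl = em$wavelength_nm, emission = em$value,
    extinction_wl = ex$wavelength_nm, extinction = ex$value,
    quantum_yield = metadata$quantum_yield,
    lifetime = metadata$lifetime_ns,
    maturation_note = metadata$maturation_note
  )
}

#' Resample a fluorophore onto a wavelength grid
#'
#' Linear interpolation inside the source range, zero outside; the emission
#' density is renormalised to unit area on the new grid.
#'
#' @param record A `fluorophore`.
#' @param grid A [wavelength_grid()]; must overlap the record's support.
#' @return A `fluorophore` whose `wavelengths` are the new grid points.
#' @export
resample <- function(record, grid) {
  stopifnot(inherits(record, "fluorophore"), inherits(grid, "wavelength_grid"))
  wl <- grid$wavelengths
  if (max(wl) < min(record$wavelengths) || min(wl) > max(record$wavelengths))
    stop("target grid is disjoint from the record's grid")
  em <- interp_zero(record$wavelengths, record$emission_shape, wl)
  area <- trapz_int(wl, em)
  if (area <= 0)
    stop("target grid does not overlap the emission support")
  out <- record
  out$wavelengths <- wl
  out$emission_shape <- em / area
  out$extinction <- interp_zero(record$wavelengths, record$extinction, wl)
  out
}

#' Built-in synthetic Gaussian stand-in fluorophores
#'
#' Gaussian stand-ins for the mTRQ2 (donor), mVEN (intermediate acceptor) and
#' mRFP (terminal acceptor) triple: emission peaks at 474 / 528 / 607 nm,
#' absorption peaks at 434 / 515 / 584 nm, with quantum yields, peak
#' extinctions and lifetimes in the range reported for the real proteins.
#' These are synthetic shapes for simulation and testing, not digitized
#' published spectra; real spectra can always be supplied via
#' [load_spectrum()].
#'
#' @param name One of `"mTRQ2"`, `"mVEN"`, `"mRFP"` (case-insensitive).
#' @return A `fluorophore`.
#' @examples
#' d <- synthetic_fluorophore("mTRQ2")
#' @export
synthetic_fluorophore <- function(name = c("mTRQ2", "mVEN", "mRFP")) {
  key <- toupper(match.arg(toupper(name), c("MTRQ2", "MVEN", "MRFP")))
  p <- switch(key,
    MTRQ2 = list(name = "mTRQ2", abs_peak = 434, abs_sd = 30, eps_max = 30000,
                 em_peak = 474, em_sd = 26, qy = 0.93, tau = 3.99),
    MVEN  = list(name = "mVEN", abs_peak = 515, abs_sd = 30, eps_max = 92200,
                 em_peak = 528, em_sd = 16, qy = 0.64, tau = 3.0),
    MRFP  = list(name = "mRFP", abs_peak = 584, abs_sd = 30, eps_max = 50000,
                 em_peak = 607, em_sd = 22, qy = 0.25, tau = 2.0)
  )
  wl <- working_grid()$wavelengths
  fluorophore_record(
    name = p$name,
    emission_wl = wl, emission = dnorm(wl, p$em_peak, p$em_sd),
    extinction_wl = wl,
    extinction = p$eps_max * exp(-(wl - p$abs_peak)^2 / (2 * p$abs_sd^2)),
    quantum_yield = p$qy, lifetime = p$tau,
    maturation_note = "synthetic Gaussian stand-in"
  )
}

# ---- internal helpers -------------------------------------------------------

read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("spectrum CSV must have columns 'wavelength_nm' and 'value': ", path)
  check_spectrum_columns(df$wavelength_nm, df$value, path)
  df[c("wavelength_nm", "value")]
}

check_spectrum_columns <- function(wl, value, what) {
  if (length(wl) != length(value) || length(wl) < 2)
    stop("spectrum '", what, "' needs >= 2 (wavelength, value) pairs")
  if (anyNA(wl) || anyNA(value))
    stop("spectrum '", what, "' contains missing values")
  if (any(diff(wl) <= 0))
    stop("wavelengths in '", what, "' must be strictly increasing")
  if (any(value < 0))
    stop("spectrum '", what, "' contains negative values")
  invisible(TRUE)
}

# linear interpolation, zero outside the source range
interp_zero <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, method = "linear", yleft = 0, yright = 0,
                ties = "ordered")$y
}

# trapezoidal integral on a (possibly irregular) grid
trapz_int <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# integral of a sampled spectrum over [from, to], trapezoid with
# interpolated endpoints
integrate_band <- function(x, y, from, to) {
  if (to <= from) stop("band requires from < to")
  inside <- x > from & x < to
  xe <- c(from, x[inside], to)
  ye <- stats::approx(x, y, xout = xe, yleft = 0, yright = 0,
                      ties = "ordered")$y
  trapz_int(xe, ye)
}

# run code with a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
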