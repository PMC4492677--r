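#' Built-in difference-spectra extinction coefficients
#'
#' Reduced-minus-oxidised wavelength pairs and millimolar extinction
#' coefficients for whole-cell cytochrome quantitation: cytochrome b at
#' 560-575 nm (epsilon 17.5 /mM/cm) and cytochrome d at 630-655 nm
#' (epsilon 19 /mM/cm).
#'
#' @param name `"cytochrome_b"` or `"cytochrome_d"`, or build a custom
#'   coefficient by supplying `wavelength_pair_nm` and `epsilon_mM_cm`.
#' @param wavelength_pair_nm Numeric (peak, trough) pair in nm.
#' @param epsilon_mM_cm Positive millimolar extinction coefficient.
#' @return List of class `extinction_coefficient`.
#' @export
extinction_coefficient <- function(name = c("cytochrome_b", "cytochrome_d"),
                                   wavelength_pair_nm = NULL,
                                   epsilon_mM_cm = NULL) {
  if (is.null(epsilon_mM_cm)) {
    name <- match.arg(name)
    built_in <- list(cytochrome_b = list(pair = c(560, 575), eps = 17.5),
                     cytochrome_d = list(pair = c(630, 655), eps = 19))
    b <- built_in[[name]]
    wavelength_pair_nm <- b$pair
    epsilon_mM_cm <- b$eps
  } else {
    name <- if (is.character(name) && length(name) == 1L) name else "custom"
    check_positive(epsilon_mM_cm, "epsilon_mM_cm")
    stopifnot(is.numeric(wavelength_pair_nm), length(wavelength_pair_nm) == 2L)
  }
  structure(list(name = name, wavelength_pair_nm = wavelength_pair_nm,
                 epsilon_mM_cm = epsilon_mM_cm),
            class = "extinction_coefficient")
}

#' Cytochrome concentration from a difference-spectrum absorbance
#'
#' Beer-Lambert quantitation of reduced-minus-oxidised difference spectra:
#' `concentration_mM = delta_A / (epsilon * path)`, expressed per mg of
#' protein as `1000 * concentration_mM / protein_mg_per_ml` nmol/mg.
#'
#' @param delta_A Peak-minus-trough absorbance difference (non-negative; a
#'   negative value signals swapped reduced/oxidised spectra and is an
#'   error).
#' @param coeff An [extinction_coefficient()].
#' @param path_cm Optical path length in cm (default 1).
#' @param protein_mg_per_ml Protein concentration of the suspension.
#' @return Cytochrome content in nmol per mg protein.
#' @export
cytochrome_concentration <- function(delta_A,
                                     coeff = extinction_coefficient("cytochrome_b"),
                                     path_cm = 1,
                                     protein_mg_per_ml = 1) {
  stopifnot(inherits(coeff, "extinction_coefficient"))
  if (!is.numeric(delta_A) || any(delta_A < 0))
    stop("'delta_A' is negative: oxidised baseline exceeds reduced ",
         "spectrum (swapped spectra?)", call. = FALSE)
  check_positive(path_cm, "path_cm")
  check_positive(protein_mg_per_ml, "protein_mg_per_ml")
  conc_mM <- delta_A / (coeff$epsilon_mM_cm * path_cm)
  1000 * conc_mM / protein_mg_per_ml
}

#' Colony-forming units per ml from spot-plate counts
#'
#' `colony_count / spot_volume_ml / dilution_factor`, with the spot volume
#' defaulting to the 10 microlitre drop (0.01 ml). `dilution_factor` is the
#' dilution of the plated sample: 1e-6 means the original culture is a
#' million-fold more concentrated than the spot.
#'
#' @param colony_count Non-negative colony count (vectorised).
#' @param spot_volume_ml Plated volume in ml (default 0.01).
#' @param dilution_factor Positive dilution of the plated sample.
#' @return CFU/ml of the original sample.
#' @export
cfu_per_ml <- function(colony_count, spot_volume_ml = 0.01,
                       dilution_factor = 1) {
  if (!is.numeric(colony_count) || any(colony_count < 0) ||
      any(colony_count != round(colony_count)))
    stop("'colony_count' must be non-negative integer(s)", call. = FALSE)
  check_positive(spot_volume_ml, "spot_volume_ml")
  check_positive(dilution_factor, "dilution_factor")
  colony_count / spot_volume_ml / dilution_factor
}

#' Doubling time under linear growth kinetics
#'
#' For cultures whose post-treatment growth approximates linear, not
#' exponential, kinetics, the doubling time at the point of compound
#' addition is the time for the OD to double at the observed constant
#' slope: `od_at_addition / slope_od_per_h` hours.
#'
#' @param od_at_addition Positive OD at the moment of addition.
#' @param slope_od_per_h Positive OD increase per hour.
#' @return Doubling time in hours.
#' @seealso [od_slope()] to estimate the slope from an OD series.
#' @export
doubling_time_linear <- function(od_at_addition, slope_od_per_h) {
  check_positive(od_at_addition, "od_at_addition")
  if (!is.numeric(slope_od_per_h) || length(slope_od_per_h) != 1L ||
      !is.finite(slope_od_per_h) || slope_od_per_h <= 0)
    stop("'slope_od_per_h' must be positive: no growth, doubling time ",
         "undefined", call. = FALSE)
  od_at_addition / slope_od_per_h
}

#' Least-squares growth slope from an OD time series
#'
#' Ordinary least-squares slope of OD against time over a user-selected
#' window, for feeding [doubling_time_linear()].
#'
#' @param time_h Times in hours.
#' @param od Optical densities (same length).
#' @param window Optional `c(from, to)` time window in hours.
#' @return Slope in OD per hour.
#' @export
od_slope <- function(time_h, od, window = NULL) {
  stopifnot(is.numeric(time_h), is.numeric(od),
            length(time_h) == length(od))
  if (!is.null(window)) {
    keep <- time_h >= window[1L] & time_h <= window[2L]
    time_h <- time_h[keep]
    od <- od[keep]
  }
  if (length(time_h) < 2L)
    stop("need >= 2 points to estimate a slope", call. = FALSE)
  unname(stats::coef(stats::lm(od ~ time_h))[2L])
}
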