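#' Optical model of one sensing film
#'
#' Captures the thickness-dependent optics of a hybrid-gel film: thicker
#' films have a larger optically active (birefringent) area, so more light is
#' blocked from the photodiode at rest and the baseline signal is lower,
#' while their larger active area also transduces a larger response.
#'
#' @param predefined_um nominal deposition thickness, micrometres.
#' @param measured_um microscope-measured thickness, micrometres (> 0).
#' @param baseline_level resting photodiode signal, arbitrary units (> 0).
#' @param active_area_fraction birefringent fraction of the sensing window,
#'   in \[0, 1\]; scales the response amplitude.
#'
#' @return An object of class `film_model`.
#' @export
film_model <- function(predefined_um, measured_um, baseline_level,
                       active_area_fraction) {
  stopifnot_scalar(predefined_um, "predefined_um", positive = TRUE)
  stopifnot_scalar(measured_um, "measured_um", positive = TRUE)
  stopifnot_scalar(baseline_level, "baseline_level", positive = TRUE)
  stopifnot_scalar(active_area_fraction, "active_area_fraction")
  if (active_area_fraction < 0 || active_area_fraction > 1)
    stop("`active_area_fraction` must be in [0, 1]", call. = FALSE)
  structure(list(predefined_um = predefined_um, measured_um = measured_um,
                 baseline_level = baseline_level,
                 active_area_fraction = active_area_fraction),
            class = "film_model")
}

#' @export
print.film_model <- function(x, ...) {
  cat(sprintf(
    "film_model: nominal %g um (measured %g um), baseline %g, active area %.0f%%\n",
    x$predefined_um, x$measured_um, x$baseline_level,
    100 * x$active_area_fraction))
  invisible(x)
}

#' Default set of four sensing films
#'
#' The four nominal thicknesses are 15, 30, 60 and 90 um.  Measured
#' thicknesses follow the reported deposition behaviour (thin films come out
#' 1.2-1.8x thicker than nominal, thick films thinner: 27, 36, 44 and 62 um).
#' Baseline levels decrease and active-area fractions increase strictly with
#' measured thickness; the numeric values are simulator inventions that
#' respect those monotone trends, not measurements.
#'
#' @return Named list of four [film_model] objects; names are the nominal
#'   thicknesses in micrometres ("15", "30", "60", "90").
#' @examples
#' films <- default_film_set()
#' sapply(films, function(f) f$baseline_level)
#' @export
default_film_set <- function() {
  films <- list(
    film_model(15, 27, baseline_level = 820, active_area_fraction = 0.35),
    film_model(30, 36, baseline_level = 760, active_area_fraction = 0.50),
    film_model(60, 44, baseline_level = 690, active_area_fraction = 0.62),
    film_model(90, 62, baseline_level = 580, active_area_fraction = 0.78)
  )
  names(films) <- vapply(films, function(f) format(f$predefined_um), "")
  films
}
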