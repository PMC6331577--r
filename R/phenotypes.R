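#' Proportional (Lea-Dahl) back-calculation of body length
#'
#' Estimates body length at an earlier age from scale growth, assuming body
#' length proportional to scale radius: `L_i = (S_i / S_total) * L_capture`.
#' Smolt length is the value at the smolt annulus.
#'
#' @param radius scale radius at the annulus of interest (same arbitrary units
#'   as `total_radius`); vectorized.
#' @param total_radius total scale radius at capture (> 0).
#' @param capture_length body length at capture, mm (> 0).
#' @return back-calculated length in mm.
#' @export
back_calculate_length <- function(radius, total_radius, capture_length) {
  stop_if(any(total_radius <= 0, na.rm = TRUE), "total scale radius must be > 0")
  stop_if(any(capture_length <= 0, na.rm = TRUE), "capture length must be > 0")
  stop_if(any(radius < 0 | radius > total_radius, na.rm = TRUE),
          "annulus radius must lie in [0, total_radius]")
  radius / total_radius * capture_length
}

#' Egg size and number from a volumetric count
#'
#' The mean egg diameter is obtained from the number of eggs spanning 25 cm
#' (`diameter = 250 mm / eggs_per_25cm`); per-egg volume uses the sphere model
#' `(pi/6) d^3` converted to ml, and egg number is the total volume divided by
#' the per-egg volume, rounded to the nearest integer. Only relative effects
#' enter the downstream log-scale models, so the conversion constant cancels
#' there.
#'
#' @param eggs_per_25cm count of eggs needed to span 25 cm (> 0); vectorized.
#' @param total_volume total egg volume per dam, ml (> 0).
#' @param dam_id optional dam identifier.
#' @return data frame with `dam_id`, `eggs_per_25cm`, `total_volume`,
#'   `egg_diameter_mm`, `egg_size_ml` and `egg_number`.
#' @export
egg_size_from_count <- function(eggs_per_25cm, total_volume, dam_id = NA) {
  stop_if(any(eggs_per_25cm <= 0, na.rm = TRUE), "'eggs_per_25cm' must be > 0")
  stop_if(any(total_volume <= 0, na.rm = TRUE), "'total_volume' must be > 0")
  diameter <- 250 / eggs_per_25cm                 # mm
  size_ml <- pi / 6 * diameter^3 / 1000           # mm^3 -> ml
  data.frame(dam_id = dam_id, eggs_per_25cm = eggs_per_25cm,
             total_volume = total_volume, egg_diameter_mm = diameter,
             egg_size_ml = size_ml,
             egg_number = round(total_volume / size_ml),
             stringsAsFactors = FALSE)
}

#' Back-calculate smolt lengths for an adult table
#'
#' Convenience wrapper applying [back_calculate_length()] to the smolt-annulus
#' radius of each fish.
#'
#' @param adults data frame with `smolt_radius`, `total_radius`,
#'   `capture_length`.
#' @return the input with a `bc_smolt_length` column appended.
#' @export
add_back_calculated_smolt <- function(adults) {
  adults$bc_smolt_length <- back_calculate_length(adults$smolt_radius,
                                                  adults$total_radius,
                                                  adults$capture_length)
  adults
}
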