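#' Total solids content from a gravimetric moisture measurement
#'
#' Thermogravimetric bookkeeping: the solids fraction is the mass remaining
#' after driving off moisture, as a percentage of the initial sample mass.
#'
#' @param initial_mass Initial sample mass, g; must be positive.
#' @param moisture_mass Mass lost as moisture, g; between 0 and
#'   `initial_mass`.
#' @return Total solids, percent (0--100).
#' @examples
#' total_solids_percent(10, 8.4) # 16% w/w
#' @export
total_solids_percent <- function(initial_mass, moisture_mass) {
  check_positive(initial_mass, "initial_mass", "g")
  check_nonnegative(moisture_mass, "moisture_mass", "g")
  if (moisture_mass > initial_mass) {
    stop("`moisture_mass` cannot exceed `initial_mass`", call. = FALSE)
  }
  100 * (initial_mass - moisture_mass) / initial_mass
}

#' Derive linear vessel dimensions from the working height and aspect ratios
#'
#' Given the actual working-volume height Z0 and the dimensionless ratios of a
#' geometrically specified tank, returns the tank diameter `T = Z0 / (Z/T)`,
#' the total height `H = (H/T) * T` and the impeller diameter
#' `D = (D/T) * T`.
#'
#' @param working_height Actual working-volume height Z0, m.
#' @param Z_over_T Actual liquid height ratio Z0/T.
#' @param H_over_T Total height ratio H/T.
#' @param D_over_T Impeller diameter ratio D/T.
#' @return A list with `tank_diameter`, `total_height` and
#'   `impeller_diameter`, all in metres.
#' @examples
#' derive_geometry(11.47, 2.55, 3, 0.45)
#' @export
derive_geometry <- function(working_height, Z_over_T, H_over_T, D_over_T) {
  check_positive(working_height, "working_height", "m")
  check_positive(Z_over_T, "Z_over_T")
  check_positive(H_over_T, "H_over_T")
  check_positive(D_over_T, "D_over_T")
  tank <- working_height / Z_over_T
  list(tank_diameter = tank,
       total_height = H_over_T * tank,
       impeller_diameter = D_over_T * tank)
}

#' Working-volume height implied by a target liquid height ratio
#'
#' `Z_calc = (Z/T)_target * T`: the liquid height a vessel of diameter `T`
#' would need in order to match the aspect ratio of a geometrically similar
#' reference vessel.
#'
#' @param tank_diameter Tank diameter T, m.
#' @param target_Z_over_T Target liquid height ratio, anchored at the
#'   reference scale.
#' @return Calculated working height, m.
#' @export
calculated_working_height <- function(tank_diameter, target_Z_over_T) {
  check_positive(tank_diameter, "tank_diameter", "m")
  check_positive(target_Z_over_T, "target_Z_over_T")
  target_Z_over_T * tank_diameter
}

#' Geometric similarity ratio of a vessel
#'
#' The ratio of the similarity-calculated working height to the actual
#' working height, `Z_calc / Z0`. A value of 1 means the vessel already has
#' the reference aspect ratio; smaller values mean the liquid must sit lower
#' than the vessel was built for.
#'
#' @param Z_calc Calculated (similarity) working height, m.
#' @param Z0 Actual working height, m.
#' @return Dimensionless ratio.
#' @export
similarity_ratio <- function(Z_calc, Z0) {
  check_nonnegative(Z_calc, "Z_calc", "m")
  check_positive(Z0, "Z0", "m")
  Z_calc / Z0
}

#' Apply a similarity ratio to an actual working height
#'
#' Inverse bookkeeping of [similarity_ratio()]: transfers the ratio observed
#' at one scale onto the actual height of another, `Z = ratio * Z0`.
#'
#' @param ratio Similarity ratio, in (0, 1.05].
#' @param Z0 Actual working height, m.
#' @return Working height, m.
#' @examples
#' apply_similarity_ratio(0.81, 11.47) # 9.29 m
#' @export
apply_similarity_ratio <- function(ratio, Z0) {
  check_positive(ratio, "ratio")
  if (ratio > 1.05) {
    stop("`ratio` must be at most 1.05 (liquid above the design height)",
         call. = FALSE)
  }
  check_positive(Z0, "Z0", "m")
  ratio * Z0
}

#' Vessel height occupancy
#'
#' Percentage of the actual working height occupied by the calculated liquid
#' height. Large industrial fermenters conventionally keep the working volume
#' at or above 80% of the design height; a warning (not an error) is emitted
#' below the threshold.
#'
#' @param Z_calc Calculated working height, m.
#' @param Z0 Actual working height, m.
#' @param warn_below Warning threshold, percent; default 80.
#' @return Occupancy, percent.
#' @export
occupancy_percent <- function(Z_calc, Z0, warn_below = 80) {
  check_nonnegative(Z_calc, "Z_calc", "m")
  check_positive(Z0, "Z0", "m")
  occ <- 100 * Z_calc / Z0
  if (occ < warn_below) {
    warning(sprintf(
      "occupancy %.1f%% is below the customary %g%% working-volume floor",
      occ, warn_below), call. = FALSE)
  }
  occ
}

#' Linear scale factor between geometrically similar vessels
#'
#' The cube root of the volume ratio, `(V2/V1)^(1/3)`, which scales every
#' linear dimension (T, D, Z) between two geometrically similar vessels.
#'
#' @param V1,V2 Volumes of the two vessels, m^3 (same basis for both).
#' @return Dimensionless linear scale factor.
#' @examples
#' geometric_scale_factor(0.003, 0.1) # 3.218
#' @export
geometric_scale_factor <- function(V1, V2) {
  check_positive(V1, "V1", "m^3")
  check_positive(V2, "V2", "m^3")
  (V2 / V1)^(1 / 3)
}

#' Similarity bookkeeping record for one scale
#'
#' Collects, for one vessel, the similarity quantities tabulated during
#' scale-up screening: the calculated working height at a target aspect
#' ratio, its ratio to the actual height, and the height occupancy.
#'
#' @param label Scale label.
#' @param tank_diameter Tank diameter T, m.
#' @param Z0 Actual working height, m.
#' @param target_Z_over_T Target liquid height ratio anchored at the
#'   reference scale.
#' @param warn_below Occupancy warning threshold passed to
#'   [occupancy_percent()].
#' @return A one-row `data.frame` with columns `label`, `Z_calc`,
#'   `Z_calc_over_T`, `similarity_ratio` and `occupancy_fraction`.
#' @export
similarity_record <- function(label, tank_diameter, Z0, target_Z_over_T,
                              warn_below = 80) {
  Z_calc <- calculated_working_height(tank_diameter, target_Z_over_T)
  ratio <- similarity_ratio(Z_calc, Z0)
  if (ratio > 1.05) {
    stop("similarity ratio exceeds 1.05; target aspect ratio is ",
         "incompatible with this vessel", call. = FALSE)
  }
  occ <- occupancy_percent(Z_calc, Z0, warn_below = warn_below)
  data.frame(label = label,
             Z_calc = Z_calc,
             Z_calc_over_T = Z_calc / tank_diameter,
             similarity_ratio = ratio,
             occupancy_fraction = occ / 100,
             stringsAsFactors = FALSE)
}
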