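#' Fermentation broth properties
#'
#' Bundles the fluid properties the hydrodynamic calculations need: density,
#' dynamic viscosity, kinematic viscosity and (optionally) the size range of
#' the microbial cells suspended in the broth, used by the shear screen.
#'
#' When `kinematic_viscosity` is omitted it is derived as
#' `dynamic_viscosity / density`. When it is supplied it must agree with that
#' ratio within 2% — measured viscosities are often reported rounded
#' independently of the density, so a small slack is allowed, but a larger
#' disagreement indicates a unit error and is rejected.
#'
#' @param density Broth density, kg m^-3.
#' @param dynamic_viscosity Dynamic viscosity, Pa s (kg m^-1 s^-1).
#' @param kinematic_viscosity Kinematic viscosity, m^2 s^-1; derived from the
#'   other two when `NULL`.
#' @param cell_size_range_um Optional length-2 numeric, min and max microbial
#'   cell size in micrometres.
#' @return An object of class `fermenter_fluid`.
#' @examples
#' fluid(1060, 0.0057)
#' @export
fluid <- function(density, dynamic_viscosity, kinematic_viscosity = NULL,
                  cell_size_range_um = NULL) {
  check_positive(density, "density", "kg m^-3")
  check_positive(dynamic_viscosity, "dynamic_viscosity", "Pa s")
  derived <- dynamic_viscosity / density
  if (is.null(kinematic_viscosity)) {
    kinematic_viscosity <- derived
  } else {
    check_positive(kinematic_viscosity, "kinematic_viscosity", "m^2 s^-1")
    if (rel_diff(derived, kinematic_viscosity) > 0.02) {
      stop("`kinematic_viscosity` disagrees with dynamic_viscosity / density ",
           sprintf("by more than 2%% (%.4g vs %.4g m^2 s^-1)",
                   kinematic_viscosity, derived),
           call. = FALSE)
    }
  }
  if (!is.null(cell_size_range_um)) {
    if (!is.numeric(cell_size_range_um) || length(cell_size_range_um) != 2L ||
        any(cell_size_range_um <= 0) ||
        cell_size_range_um[1] > cell_size_range_um[2]) {
      stop("`cell_size_range_um` must be two positive numbers, min <= max",
           call. = FALSE)
    }
  }
  structure(
    list(density = density,
         dynamic_viscosity = dynamic_viscosity,
         kinematic_viscosity = kinematic_viscosity,
         cell_size_range_um = cell_size_range_um),
    class = "fermenter_fluid")
}

#' Stirred-tank vessel geometry
#'
#' Describes one vessel: volumes, tank diameter, heights and the dimensionless
#' aspect ratios used for geometric similarity. The tank diameter may be given
#' directly or derived from the working height and the liquid height ratio
#' `Z_over_T`; when both routes are available they must agree within 0.5%.
#'
#' Volumes are independent inputs, never derived from cylinder geometry:
#' vessel heads and freeboard make `pi/4 T^2 Z` a poor predictor of the real
#' working volume, so no cross-check is enforced between volumes and heights.
#'
#' @param total_volume Total vessel volume V_t, m^3.
#' @param working_volume Working (liquid) volume V_w, m^3; must not exceed
#'   `total_volume`.
#' @param working_height Actual working-volume height Z0, m.
#' @param tank_diameter Tank diameter T, m; derived from
#'   `working_height / Z_over_T` when `NULL`.
#' @param total_height Total vessel height H, m; derived from
#'   `H_over_T * tank_diameter` when `NULL` and `H_over_T` is given.
#' @param Z_over_T Actual liquid height ratio Z0/T.
#' @param H_over_T Total height ratio H/T.
#' @param D_over_T Impeller diameter ratio D/T (bookkeeping only; the
#'   impeller itself carries its diameter).
#' @return An object of class `vessel_geometry`.
#' @examples
#' vessel_geometry(300, 207, working_height = 11.47, Z_over_T = 2.55,
#'                 H_over_T = 3, D_over_T = 0.45)
#' @export
vessel_geometry <- function(total_volume, working_volume, working_height,
                            tank_diameter = NULL, total_height = NULL,
                            Z_over_T = NULL, H_over_T = NULL,
                            D_over_T = NULL) {
  check_positive(total_volume, "total_volume", "m^3")
  check_positive(working_volume, "working_volume", "m^3")
  if (working_volume > total_volume) {
    stop("`working_volume` must not exceed `total_volume`", call. = FALSE)
  }
  check_positive(working_height, "working_height", "m")
  if (is.null(tank_diameter)) {
    if (is.null(Z_over_T)) {
      stop("supply `tank_diameter` or `Z_over_T` to fix the tank diameter",
           call. = FALSE)
    }
    check_positive(Z_over_T, "Z_over_T")
    tank_diameter <- working_height / Z_over_T
  } else {
    check_positive(tank_diameter, "tank_diameter", "m")
    if (!is.null(Z_over_T)) {
      check_positive(Z_over_T, "Z_over_T")
      if (rel_diff(working_height / Z_over_T, tank_diameter) > 0.005) {
        stop("`tank_diameter` disagrees with working_height / Z_over_T ",
             "by more than 0.5%", call. = FALSE)
      }
    }
  }
  if (is.null(total_height) && !is.null(H_over_T)) {
    check_positive(H_over_T, "H_over_T")
    total_height <- H_over_T * tank_diameter
  }
  if (!is.null(total_height)) check_positive(total_height, "total_height", "m")
  if (!is.null(D_over_T)) check_positive(D_over_T, "D_over_T")
  structure(
    list(total_volume = total_volume,
         working_volume = working_volume,
         working_height = working_height,
         tank_diameter = tank_diameter,
         total_height = total_height,
         Z_over_T = working_height / tank_diameter,
         H_over_T = if (is.null(total_height)) NULL else
           total_height / tank_diameter,
         D_over_T = D_over_T),
    class = "vessel_geometry")
}

#' Impeller description
#'
#' @param type Impeller type id, one of `"RTB"` (Rushton turbine blade),
#'   `"CBT"` (concave blade turbine), `"PBT"` (pitched blade turbine),
#'   `"LA310"`, `"LA315"` (Lightnin hydrofoils) or `"MP"` (marine propeller).
#'   Other ids are accepted for custom impellers.
#' @param power_number Turbulent power number Po (dimensionless drag
#'   coefficient, constant for Re > 1e4).
#' @param diameter Impeller diameter D, m.
#' @param count Number of identical impellers on the shaft (stages).
#' @return An object of class `impeller`.
#' @examples
#' impeller("RTB", 5, diameter = 2.03, count = 2)
#' @export
impeller <- function(type, power_number, diameter, count = 1L) {
  if (!is.character(type) || length(type) != 1L || !nzchar(type)) {
    stop("`type` must be a non-empty string", call. = FALSE)
  }
  check_positive(power_number, "power_number")
  check_positive(diameter, "diameter", "m")
  count <- check_count(count, "count")
  structure(
    list(type = type, power_number = power_number,
         diameter = diameter, count = count),
    class = "impeller")
}

#' One fermenter scale: fluid + vessel + impeller + nominal speed
#'
#' @param label Short identifier, e.g. `"pilot"`.
#' @param fluid A [fluid()] object.
#' @param vessel A [vessel_geometry()] object.
#' @param impeller An [impeller()] object.
#' @param speed Nominal agitation speed N, s^-1.
#' @return An object of class `fermenter_case`.
#' @seealso [whey_scaleup_cases()] for the bundled three-scale case study.
#' @export
fermenter_case <- function(label, fluid, vessel, impeller, speed) {
  if (!is.character(label) || length(label) != 1L) {
    stop("`label` must be a single string", call. = FALSE)
  }
  if (!inherits(fluid, "fermenter_fluid")) {
    stop("`fluid` must be a fermenter_fluid object", call. = FALSE)
  }
  if (!inherits(vessel, "vessel_geometry")) {
    stop("`vessel` must be a vessel_geometry object", call. = FALSE)
  }
  if (!inherits(impeller, "impeller")) {
    stop("`impeller` must be an impeller object", call. = FALSE)
  }
  check_positive(speed, "speed", "s^-1")
  structure(
    list(label = label, fluid = fluid, vessel = vessel,
         impeller = impeller, speed = speed),
    class = "fermenter_case")
}

#' @export
print.fermenter_case <- function(x, ...) {
  cat(sprintf("<fermenter_case> %s\n", x$label))
  cat(sprintf("  vessel : V_t %.4g m^3, V_w %.4g m^3, T %.4g m, Z0 %.4g m\n",
              x$vessel$total_volume, x$vessel$working_volume,
              x$vessel$tank_diameter, x$vessel$working_height))
  cat(sprintf("  fluid  : rho %.4g kg m^-3, mu %.4g Pa s\n",
              x$fluid$density, x$fluid$dynamic_viscosity))
  cat(sprintf("  mixing : %d x %s (Po %.3g), D %.4g m, N %.4g s^-1 (%.0f rpm)\n",
              x$impeller$count, x$impeller$type, x$impeller$power_number,
              x$impeller$diameter, x$speed, 60 * x$speed))
  invisible(x)
}
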