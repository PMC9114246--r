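#' Impeller Reynolds number
#'
#' `Re = rho * N * D^2 / mu`, the agitated-vessel Reynolds number that
#' classifies the mixing regime.
#'
#' @param density Fluid density rho, kg m^-3.
#' @param speed Impeller speed N, s^-1.
#' @param diameter Impeller diameter D, m.
#' @param viscosity Dynamic viscosity mu, Pa s.
#' @return Dimensionless Reynolds number.
#' @examples
#' reynolds_number(1060, 3.333, 0.1814, 0.0057) # ~2.04e4
#' @export
reynolds_number <- function(density, speed, diameter, viscosity) {
  check_positive(density, "density", "kg m^-3")
  check_positive(speed, "speed", "s^-1")
  check_positive(diameter, "diameter", "m")
  check_positive(viscosity, "viscosity", "Pa s")
  density * speed * diameter^2 / viscosity
}

#' Impeller diameter implied by a Reynolds number
#'
#' Closed-form inversion of [reynolds_number()]:
#' `D = sqrt(Re * mu / (rho * N))`. Used to anchor impeller diameters to
#' reported Reynolds numbers when no diameter is published.
#'
#' @param reynolds Target Reynolds number.
#' @inheritParams reynolds_number
#' @return Impeller diameter, m.
#' @export
diameter_from_reynolds <- function(reynolds, density, speed, viscosity) {
  check_positive(reynolds, "reynolds")
  check_positive(density, "density", "kg m^-3")
  check_positive(speed, "speed", "s^-1")
  check_positive(viscosity, "viscosity", "Pa s")
  sqrt(reynolds * viscosity / (density * speed))
}

#' Classify the mixing flow regime
#'
#' Standard agitated-vessel convention: turbulent above `turbulent_limit`
#' (default 1e4, where power numbers become constant), laminar below
#' `laminar_limit` (default 10), transition in between.
#'
#' @param reynolds Reynolds number, >= 0.
#' @param laminar_limit Upper Re bound of the laminar regime (inclusive).
#' @param turbulent_limit Lower Re bound of the turbulent regime (exclusive:
#'   the flow is turbulent for Re strictly greater).
#' @return One of `"laminar"`, `"transition"`, `"turbulent"`.
#' @export
classify_regime <- function(reynolds, laminar_limit = 10,
                            turbulent_limit = 1e4) {
  check_nonnegative(reynolds, "reynolds")
  if (reynolds > turbulent_limit) "turbulent"
  else if (reynolds <= laminar_limit) "laminar"
  else "transition"
}

#' Power-number correlation table
#'
#' Per impeller type: the constant turbulent power number Po, the laminar
#' drag constant K_L (laminar regime: `Po = K_L / Re`) and an optional
#' transition-regime power number. When `transition_po` is `NA` the
#' turbulent constant is used in the transition regime, with a warning —
#' published Po--Re charts dip below the turbulent plateau there, so a
#' chart-read value should be supplied when transition operation matters.
#'
#' The turbulent constants are the conventional values for the six stock
#' types: Rushton turbine 5, concave blade turbine 4.4, pitched blade
#' turbine 1.64, Lightnin A310 0.3, Lightnin A315 0.75, marine propeller
#' 0.34. The laminar K_L defaults are approximate chart-order magnitudes and
#' fully overridable.
#'
#' @param types Character vector of type ids.
#' @param turbulent_po Turbulent power numbers, same length.
#' @param laminar_kl Laminar drag constants, same length.
#' @param transition_po Transition-regime power numbers (`NA` = fall back to
#'   turbulent constant with a warning).
#' @return A `data.frame` of class `power_correlation`.
#' @export
power_correlation <- function(types, turbulent_po, laminar_kl,
                              transition_po = rep(NA_real_, length(types))) {
  stopifnot(length(types) == length(turbulent_po),
            length(types) == length(laminar_kl),
            length(types) == length(transition_po))
  if (any(turbulent_po <= 0) || any(laminar_kl <= 0)) {
    stop("power-number constants must be strictly positive", call. = FALSE)
  }
  structure(
    data.frame(type = as.character(types),
               turbulent_po = as.numeric(turbulent_po),
               laminar_kl = as.numeric(laminar_kl),
               transition_po = as.numeric(transition_po),
               stringsAsFactors = FALSE),
    class = c("power_correlation", "data.frame"))
}

#' @rdname power_correlation
#' @export
default_power_correlation <- function() {
  power_correlation(
    types        = c("RTB", "CBT", "PBT", "LA310", "LA315", "MP"),
    turbulent_po = c(5,     4.4,   1.64,  0.3,     0.75,    0.34),
    laminar_kl   = c(64,    64,    44.5,  40,      43,      41))
}

#' Power number of an impeller at a given Reynolds number
#'
#' @param type Impeller type id present in `correlation`.
#' @param reynolds Reynolds number, > 0.
#' @param correlation A [power_correlation()] table.
#' @inheritParams classify_regime
#' @return Dimensionless power number Po.
#' @examples
#' power_number("RTB", 2.55e6) # 5, turbulent plateau
#' @export
power_number <- function(type, reynolds,
                         correlation = default_power_correlation(),
                         laminar_limit = 10, turbulent_limit = 1e4) {
  check_positive(reynolds, "reynolds")
  row <- correlation[correlation$type == type, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("impeller type '%s' not found in the power correlation",
                 type), call. = FALSE)
  }
  regime <- classify_regime(reynolds, laminar_limit, turbulent_limit)
  switch(regime,
         turbulent = row$turbulent_po,
         laminar = row$laminar_kl / reynolds,
         transition = {
           if (is.na(row$transition_po)) {
             warning(sprintf(
               "Re = %.3g is in the transition regime for '%s'; using the turbulent Po = %.3g",
               reynolds, type, row$turbulent_po), call. = FALSE)
             row$turbulent_po
           } else {
             row$transition_po
           }
         })
}

#' Impeller mixing power draw
#'
#' `P = n * Po * N^3 * D^5 * rho / Gc`, the power drawn by `n_impellers`
#' identical impellers on one shaft (power of an optimally spaced multi-stage
#' system is the sum of the single-impeller draws).
#'
#' @param po Power number at the operating regime.
#' @param speed Impeller speed N, s^-1.
#' @param diameter Impeller diameter D, m.
#' @param density Fluid density, kg m^-3.
#' @param n_impellers Number of stages, integer >= 1.
#' @param gc Newton-law proportionality factor, 1 in SI units.
#' @return Power, W.
#' @examples
#' mixing_power(5, 3.333, 0.1814, 1060, n_impellers = 2) # ~77 W
#' @export
mixing_power <- function(po, speed, diameter, density, n_impellers = 1L,
                         gc = 1) {
  check_positive(po, "po")
  check_positive(speed, "speed", "s^-1")
  check_positive(diameter, "diameter", "m")
  check_positive(density, "density", "kg m^-3")
  n_impellers <- check_count(n_impellers, "n_impellers")
  check_positive(gc, "gc")
  n_impellers * po * speed^3 * diameter^5 * density / gc
}

#' Specific power (power per unit volume)
#'
#' `P/V`, tagged with its volume basis. The working-volume basis divides by
#' the liquid volume; the total-volume basis divides by the vessel capacity.
#' The two appear side by side in scale-up practice, so the basis is explicit
#' and carried on the result as an attribute -- there is no silent default
#' volume.
#'
#' @param power Power, W (or kW; the result inherits the power unit).
#' @param volume Volume, m^3.
#' @param basis `"working"` or `"total"`; which volume was supplied.
#' @return Specific power, power-unit per m^3, with attribute
#'   `volume_basis`.
#' @export
specific_power <- function(power, volume, basis = c("working", "total")) {
  check_nonnegative(power, "power", "W")
  check_positive(volume, "volume", "m^3")
  basis <- match.arg(basis)
  structure(power / volume, volume_basis = basis)
}

#' Specific energy dissipation rate
#'
#' `epsilon_t = P / (rho * V_w)`: at steady state the impeller power is
#' dissipated into the liquid mass, so the mean dissipation per unit mass is
#' the power divided by the broth mass (density times working volume).
#'
#' @param power Power transmitted to the liquid, W.
#' @param density Fluid density, kg m^-3.
#' @param working_volume Liquid (working) volume, m^3.
#' @return epsilon_t, W kg^-1.
#' @examples
#' energy_dissipation_rate(77.006, 1060, 0.1) # 0.7265 W/kg
#' @export
energy_dissipation_rate <- function(power, density, working_volume) {
  check_positive(power, "power", "W")
  check_positive(density, "density", "kg m^-3")
  check_positive(working_volume, "working_volume", "m^3")
  power / (density * working_volume)
}

#' Kolmogorov microscale of turbulence
#'
#' `lambda_k = (nu^3 / epsilon_t)^(1/4)`: the smallest turbulent eddy size.
#' Cells smaller than `lambda_k` are screened from the damaging eddies and
#' are considered shear-safe.
#'
#' @param epsilon_t Specific energy dissipation rate, W kg^-1; must be > 0
#'   (zero dissipation has no finite microscale).
#' @param kinematic_viscosity Kinematic viscosity nu, m^2 s^-1.
#' @return Microscale length, m.
#' @examples
#' kolmogorov_length(0.7265, 5.37e-6) * 1e6 # ~120.9 um
#' @export
kolmogorov_length <- function(epsilon_t, kinematic_viscosity) {
  check_positive(epsilon_t, "epsilon_t", "W kg^-1")
  check_positive(kinematic_viscosity, "kinematic_viscosity", "m^2 s^-1")
  (kinematic_viscosity^3 / epsilon_t)^(1 / 4)
}

#' Shear-damage screen against the Kolmogorov microscale
#'
#' Compares the turbulence microscale with the largest microbial cell
#' dimension. The margin is `lambda_k / cell_size`; cells are flagged safe
#' when the margin exceeds 1 (cell strictly smaller than the smallest eddy).
#'
#' @param lambda_k Kolmogorov microscale, m.
#' @param cell_size_um Largest cell dimension, micrometres.
#' @return List with `margin` (dimensionless) and `safe` (logical).
#' @export
shear_safety <- function(lambda_k, cell_size_um) {
  check_positive(lambda_k, "lambda_k", "m")
  check_positive(cell_size_um, "cell_size_um", "um")
  margin <- (lambda_k * 1e6) / cell_size_um
  list(margin = margin, safe = margin > 1)
}

#' Agitator shaft torque
#'
#' Physical mode (default) is the definition `T = P / (2 pi N)` with P in
#' watts and N in s^-1. The `"hp_formula"` mode is the horsepower/rpm sizing
#' chain `T = (P_kW * 63025 / rpm) * 0.112985` -- the lb-in horsepower
#' formula fed with kilowatts and converted to N m, as found on some
#' industrial sizing sheets. Because the kilowatt feed skips the hp
#' conversion, the hp-formula value is a fixed factor 0.74571 of the physical
#' torque; both are exposed so either convention can be reported.
#'
#' @param power Power, W.
#' @param speed Impeller speed N, s^-1 (> 0).
#' @param mode `"physical"` or `"hp_formula"`.
#' @return Torque, N m.
#' @examples
#' impeller_torque(2 * pi, 1)                    # 1 N m
#' impeller_torque(862540, 80 / 60, "hp_formula") # ~76,800 N m
#' @export
impeller_torque <- function(power, speed, mode = c("physical", "hp_formula")) {
  check_nonnegative(power, "power", "W")
  check_positive(speed, "speed", "s^-1")
  mode <- match.arg(mode)
  if (mode == "physical") {
    power / (2 * pi * speed)
  } else {
    (power / 1000) * 63025 / (speed * 60) * 0.112985
  }
}

#' Full hydrodynamic state of a fermenter case at a given speed
#'
#' Evaluates the whole derived chain for one operating speed: Reynolds
#' number, regime, power number, power draw of all stages, specific power on
#' both volume bases, specific energy dissipation rate, Kolmogorov
#' microscale, shear margin (when the fluid carries a cell size range) and
#' shaft torque in both conventions.
#'
#' @param case A [fermenter_case()].
#' @param speed Operating speed, s^-1; defaults to the case's nominal speed.
#' @param correlation A [power_correlation()] table used for the power
#'   number lookup.
#' @param n_impellers Stage count; defaults to the case impeller's count.
#' @return An object of class `operating_point`.
#' @examples
#' op <- operating_point(whey_scaleup_cases()$pilot)
#' op$reynolds
#' @export
operating_point <- function(case, speed = NULL,
                            correlation = default_power_correlation(),
                            n_impellers = NULL) {
  stopifnot(inherits(case, "fermenter_case"))
  speed <- speed %||% case$speed
  n_impellers <- n_impellers %||% case$impeller$count
  fl <- case$fluid
  D <- case$impeller$diameter
  re <- reynolds_number(fl$density, speed, D, fl$dynamic_viscosity)
  regime <- classify_regime(re)
  po <- power_number(case$impeller$type, re, correlation)
  p <- mixing_power(po, speed, D, fl$density, n_impellers)
  eps <- energy_dissipation_rate(p, fl$density, case$vessel$working_volume)
  lam <- kolmogorov_length(eps, fl$kinematic_viscosity)
  shear <- if (is.null(fl$cell_size_range_um)) NULL else
    shear_safety(lam, max(fl$cell_size_range_um))
  structure(
    list(label = case$label,
         speed = speed,
         rpm = 60 * speed,
         n_impellers = n_impellers,
         reynolds = re,
         regime = regime,
         power_number = po,
         power = p,
         specific_power_working = specific_power(
           p, case$vessel$working_volume, "working"),
         specific_power_total = specific_power(
           p, case$vessel$total_volume, "total"),
         epsilon_t = eps,
         kolmogorov = lam,
         shear = shear,
         torque_physical = impeller_torque(p, speed, "physical"),
         torque_hp = impeller_torque(p, speed, "hp_formula")),
    class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf("<operating_point> %s @ %.4g s^-1 (%.0f rpm)\n",
              x$label %||% "", x$speed, x$rpm))
  cat(sprintf("  Re %.4g (%s), Po %.3g, %d stage(s)\n",
              x$reynolds, x$regime, x$power_number, x$n_impellers))
  cat(sprintf("  P %.6g W | P/V_w %.4g W m^-3 | P/V_t %.4g W m^-3\n",
              x$power, as.numeric(x$specific_power_working),
              as.numeric(x$specific_power_total)))
  cat(sprintf("  eps_t %.4g W kg^-1 | lambda_k %.4g um\n",
              x$epsilon_t, 1e6 * x$kolmogorov))
  cat(sprintf("  torque %.6g N m (physical), %.6g N m (hp formula)\n",
              x$torque_physical, x$torque_hp))
  if (!is.null(x$shear)) {
    cat(sprintf("  shear margin %.3g (%s)\n", x$shear$margin,
                if (x$shear$safe) "safe" else "NOT safe"))
  }
  invisible(x)
}

#' Serialize operating points to a tidy data frame
#'
#' @param ... `operating_point` objects.
#' @return A `data.frame` with one row per operating point.
#' @export
operating_point_table <- function(...) {
  ops <- list(...)
  stopifnot(all(vapply(ops, inherits, logical(1), "operating_point")))
  do.call(rbind, lapply(ops, function(x) {
    data.frame(label = x$label %||% NA_character_,
               speed = x$speed, rpm = x$rpm,
               n_impellers = x$n_impellers,
               reynolds = x$reynolds, regime = x$regime,
               power_number = x$power_number, power_W = x$power,
               pv_working = as.numeric(x$specific_power_working),
               pv_total = as.numeric(x$specific_power_total),
               epsilon_t = x$epsilon_t,
               kolmogorov_um = 1e6 * x$kolmogorov,
               torque_physical = x$torque_physical,
               torque_hp = x$torque_hp,
               stringsAsFactors = FALSE)
  }))
}
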