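#' Bundled whey-permeate lactic acid case study (three scales)
#'
#' The worked case study shipped with the package: anaerobic lactic acid
#' fermentation of dairy cheese whey permeate in geometrically similar
#' stirred tanks at laboratory (0.003 m^3 working volume), pilot (0.1 m^3)
#' and industrial (300 m^3 total / 207 m^3 working) scale, all agitated by
#' two-stage Rushton turbines at a nominal 3.333 s^-1.
#'
#' Measured quantities (density 1060 kg m^-3; dynamic viscosities 0.0068 /
#' 0.0057 / 0.0057 Pa s; kinematic viscosities 6.36e-6 / 5.37e-6 / 5.37e-6
#' m^2 s^-1; vessel volumes and heights; cell size range 0.9--1.9 um) enter
#' as stated. Impeller diameters are not reported for this campaign and are
#' anchored by inverting the reported Reynolds numbers at the nominal speed
#' (1.81e3 / 2.040e4 / 2.55319e6), giving 0.0590, 0.1814 and 2.0296 m; the
#' derivation is recorded in the `provenance` attribute and re-derived in
#' the package tests rather than trusted as constants.
#'
#' The accompanying power correlation ([whey_power_correlation()]) carries a
#' transition-regime power number of 4.58 for the Rushton turbine, the
#' chart-read value at the laboratory Reynolds number (~1.8e3) where the
#' Rushton Po--Re curve sits below its turbulent plateau.
#'
#' @return A named list with elements `lab`, `pilot` and `industrial`
#'   ([fermenter_case()] objects), carrying attributes `correlation` (a
#'   [power_correlation()]) and `provenance` (character notes per derived
#'   field).
#' @export
whey_scaleup_cases <- function() {
  nominal_speed <- 3.333
  cells <- c(0.9, 1.9)

  lab_fluid <- fluid(1060, 0.0068, 6.36e-6, cell_size_range_um = cells)
  big_fluid <- fluid(1060, 0.0057, 5.37e-6, cell_size_range_um = cells)

  lab_D <- diameter_from_reynolds(0.181e4, 1060, nominal_speed, 0.0068)
  pilot_D <- diameter_from_reynolds(2.040e4, 1060, nominal_speed, 0.0057)
  ind_D <- diameter_from_reynolds(255.319e4, 1060, nominal_speed, 0.0057)

  lab <- fermenter_case(
    "lab", lab_fluid,
    vessel_geometry(total_volume = 0.03, working_volume = 0.003,
                    working_height = 0.18, Z_over_T = 1.37, H_over_T = 3,
                    D_over_T = 0.45),
    impeller("RTB", 5, diameter = lab_D, count = 2L),
    speed = nominal_speed)

  pilot <- fermenter_case(
    "pilot", big_fluid,
    vessel_geometry(total_volume = 0.1, working_volume = 0.1,
                    working_height = 0.65, Z_over_T = 1.61, H_over_T = 3,
                    D_over_T = 0.45),
    impeller("RTB", 5, diameter = pilot_D, count = 2L),
    speed = nominal_speed)

  industrial <- fermenter_case(
    "industrial", big_fluid,
    vessel_geometry(total_volume = 300, working_volume = 207,
                    working_height = 11.47, Z_over_T = 2.55, H_over_T = 3,
                    D_over_T = 0.45),
    impeller("RTB", 5, diameter = ind_D, count = 2L),
    speed = nominal_speed)

  structure(
    list(lab = lab, pilot = pilot, industrial = industrial),
    correlation = whey_power_correlation(),
    provenance = c(
      lab_diameter = "derived: Reynolds inversion, Re = 1.81e3 at N = 3.333 s^-1",
      pilot_diameter = "derived: Reynolds inversion, Re = 2.040e4 at N = 3.333 s^-1",
      industrial_diameter = "derived: Reynolds inversion, Re = 2.55319e6 at N = 3.333 s^-1",
      lab_kinematic_viscosity = "stated 6.36e-6; mu/rho = 6.415e-6 (independent rounding, within 2%)",
      pilot_total_volume = "assumed equal to working volume (not reported)",
      rtb_transition_po = "chart-read 4.58 at Re ~ 1.8e3 (transition regime)"))
}

#' @rdname whey_scaleup_cases
#' @export
whey_power_correlation <- function() {
  corr <- default_power_correlation()
  corr$transition_po[corr$type == "RTB"] <- 4.58
  corr
}

#' Sampling ranges for the random scenario generator
#'
#' Defines physically plausible ranges bracketing real fermentation duty:
#' density 950--1200 kg m^-3, dynamic viscosity 0.001--0.02 Pa s, working
#' volume 1e-3--1e3 m^3 (log-uniform), D/T 0.3--0.5, Z/T 1--3, H/T
#' 1.5--3.5, speed 0.2--5 s^-1, impeller type uniform over the library,
#' working fraction (V_w/V_t) 0.7--0.85.
#'
#' @param density,viscosity,working_volume,D_over_T,Z_over_T,H_over_T,speed,working_fraction
#'   Length-2 numeric ranges (min, max).
#' @param library Impeller library to sample types from.
#' @return List of class `scenario_distribution`.
#' @export
scenario_distribution <- function(density = c(950, 1200),
                                  viscosity = c(0.001, 0.02),
                                  working_volume = c(1e-3, 1e3),
                                  D_over_T = c(0.3, 0.5),
                                  Z_over_T = c(1, 3),
                                  H_over_T = c(1.5, 3.5),
                                  speed = c(0.2, 5),
                                  working_fraction = c(0.7, 0.85),
                                  library = impeller_library()) {
  rng <- list(density = density, viscosity = viscosity,
              working_volume = working_volume, D_over_T = D_over_T,
              Z_over_T = Z_over_T, H_over_T = H_over_T, speed = speed,
              working_fraction = working_fraction)
  for (nm in names(rng)) {
    r <- rng[[nm]]
    if (length(r) != 2L || !is.numeric(r) || any(r <= 0) || r[1] > r[2]) {
      stop(sprintf("`%s` must be a positive (min, max) pair", nm),
           call. = FALSE)
    }
  }
  structure(c(rng, list(library = library)),
            class = "scenario_distribution")
}

runif1 <- function(range) stats::runif(1, range[1], range[2])

#' Sample one random, physically consistent fermenter case
#'
#' Draws fluid, vessel and impeller parameters from a
#' [scenario_distribution()] using the current RNG state (call
#' `set.seed()` for reproducibility). The vessel is built as a cylinder of
#' the drawn aspect ratios (heads and freeboard ignored -- this generator
#' feeds property tests, not equipment design), so all type invariants hold
#' by construction and at least one impeller stage always fits.
#'
#' @param distribution A [scenario_distribution()].
#' @param label Case label.
#' @return A [fermenter_case()].
#' @examples
#' set.seed(1)
#' random_fermenter_case()
#' @export
random_fermenter_case <- function(distribution = scenario_distribution(),
                                  label = "random") {
  stopifnot(inherits(distribution, "scenario_distribution"))
  d <- distribution
  density <- runif1(d$density)
  viscosity <- runif1(d$viscosity)
  vw <- exp(stats::runif(1, log(d$working_volume[1]),
                         log(d$working_volume[2])))
  frac <- runif1(d$working_fraction)
  zt <- runif1(d$Z_over_T)
  ht <- runif1(d$H_over_T)
  dt <- runif1(d$D_over_T)
  tank <- (4 * vw / (pi * zt))^(1 / 3)
  Z0 <- zt * tank
  imp_row <- d$library[sample.int(nrow(d$library), 1L), ]
  D <- dt * tank
  counts <- feasible_impeller_counts(Z0, D)
  fermenter_case(
    label,
    fluid(density, viscosity),
    vessel_geometry(total_volume = vw / frac, working_volume = vw,
                    working_height = Z0, tank_diameter = tank,
                    total_height = ht * tank, D_over_T = dt),
    impeller(imp_row$type, imp_row$turbulent_po, diameter = D,
             count = attr(counts, "selected")),
    speed = runif1(d$speed))
}

#' Random electricity characterization factors
#'
#' Draws the eight CML factors log-uniformly over 1e-6--1 kg-eq per kWh
#' using the current RNG state. Intended for property tests (linearity and
#' rank preservation hold for any non-negative table), not for reporting
#' real impacts.
#'
#' @return An [impact_factor_table()].
#' @examples
#' set.seed(7)
#' random_impact_factors()
#' @export
random_impact_factors <- function() {
  cats <- cml_categories()
  f <- 10^stats::runif(length(cats), -6, 0)
  names(f) <- cats
  impact_factor_table(f)
}
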