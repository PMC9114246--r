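#' Scale specific power between volumes at constant mixing performance
#'
#' Empirical constant-performance rule for ungassed stirred tanks:
#' `(P/Vw)_2 = (P/Vw)_1 * (Vw1/Vw2)^alpha` with the industrial-survey
#' exponent `alpha = 0.37` by default, i.e. the specific power a larger
#' vessel needs falls off as a weak power of the volume ratio.
#'
#' @param pv1 Specific power at the source scale, W m^-3 (working basis).
#' @param Vw1,Vw2 Source and target working volumes, m^3.
#' @param alpha Volume exponent; default 0.37.
#' @return Predicted specific power at the target scale, W m^-3.
#' @export
scale_specific_power <- function(pv1, Vw1, Vw2, alpha = 0.37) {
  check_positive(pv1, "pv1", "W m^-3")
  check_positive(Vw1, "Vw1", "m^3")
  check_positive(Vw2, "Vw2", "m^3")
  check_positive(alpha, "alpha")
  pv1 * (Vw1 / Vw2)^alpha
}

#' Scale the impeller speed between geometrically similar vessels
#'
#' Constant-P/Vw speed rule:
#' `N2 = N1 * (Vw2/Vw1)^beta * (D1/D2)^gamma` with `beta = 0.21` and
#' `gamma = 5/3`. Derived by combining the turbulent power expression
#' `P = Po N^3 D^5 rho` with the specific-power rule: the speed drops
#' steeply with impeller diameter and rises weakly with volume.
#'
#' @param N1 Source impeller speed, s^-1.
#' @param Vw1,Vw2 Source and target working volumes, m^3.
#' @param D1,D2 Source and target impeller diameters, m.
#' @param beta Volume exponent; default 0.21.
#' @param gamma Diameter exponent; default 5/3.
#' @return Target impeller speed N2, s^-1.
#' @examples
#' scale_impeller_speed(3.333, 0.1, 207, 0.1814, 2.0295) # ~0.296 s^-1
#' @export
scale_impeller_speed <- function(N1, Vw1, Vw2, D1, D2,
                                 beta = 0.21, gamma = 5 / 3) {
  check_positive(N1, "N1", "s^-1")
  check_positive(Vw1, "Vw1", "m^3")
  check_positive(Vw2, "Vw2", "m^3")
  check_positive(D1, "D1", "m")
  check_positive(D2, "D2", "m")
  check_positive(beta, "beta")
  check_positive(gamma, "gamma")
  N1 * (Vw2 / Vw1)^beta * (D1 / D2)^gamma
}

#' Bounds on the number of impeller stages from shaft clearance
#'
#' Spacing rule for stacked impellers in a liquid column of height `Z`:
#' `(Z - 2D) / (2D) < n < (Z - D) / D`. The lower bound keeps stages at
#' least two diameters apart (no starved impellers), the upper bound keeps
#' every stage at least one diameter below the surface and above the base.
#'
#' @param Z Working-volume (liquid) height, m; must exceed `D`.
#' @param D Impeller diameter, m.
#' @return List with `lower` and `upper` (dimensionless bounds on n).
#' @export
impeller_count_bounds <- function(Z, D) {
  check_positive(Z, "Z", "m")
  check_positive(D, "D", "m")
  if (Z <= D) {
    stop("`Z` must exceed the impeller diameter `D`: no impeller fits",
         call. = FALSE)
  }
  list(lower = (Z - 2 * D) / (2 * D), upper = (Z - D) / D)
}

#' Feasible integer impeller counts
#'
#' Integer stage counts satisfying the clearance bounds of
#' [impeller_count_bounds()], with a small tolerance `tol` added to the
#' upper bound: published selections routinely accept a count sitting a few
#' percent above the strict open interval (e.g. two stages in a column of
#' 1.95 diameters of clearance), and `tol = 0.1` reproduces that practice.
#' The conventional selection is the maximum feasible count (attribute
#' `selected`).
#'
#' @inheritParams impeller_count_bounds
#' @param tol Tolerance added to the upper bound; default 0.1.
#' @return Integer vector of feasible counts, with attribute `selected`
#'   (the maximum). Errors if no count is feasible.
#' @examples
#' feasible_impeller_counts(9.29, 2.0296) # 2 3, selected 3
#' @export
feasible_impeller_counts <- function(Z, D, tol = 0.1) {
  check_nonnegative(tol, "tol")
  b <- impeller_count_bounds(Z, D)
  hi <- floor(b$upper + tol)
  lo <- floor(b$lower) + 1L  # smallest integer strictly above the lower bound
  if (lo <= b$lower) lo <- lo + 1L
  lo <- max(1L, lo)
  if (hi < lo) {
    stop(sprintf(
      "no integer impeller count fits Z = %.3g m, D = %.3g m (bounds %.3g-%.3g)",
      Z, D, b$lower, b$upper), call. = FALSE)
  }
  counts <- seq.int(lo, hi)
  structure(counts, selected = max(counts))
}

#' Scale up a fermenter case at constant specific power
#'
#' End-to-end constant-P/Vw scale-up from a characterized source case to a
#' target vessel: the target speed comes from [scale_impeller_speed()], the
#' stage count from the clearance rule at the target working height, the
#' power from the turbulent power draw at the scaled speed, and the derived
#' hydrodynamic state (specific power on both bases, energy dissipation,
#' Kolmogorov microscale, torque in both conventions) is evaluated at that
#' point.
#'
#' The scaled operating point always uses the *turbulent* power number: the
#' constant-P/Vw rule is derived under turbulent similarity. If the target
#' Reynolds number falls below 1e4 the regime is still reported and a
#' warning is emitted. The source operating point, by contrast, is
#' characterized with the supplied correlation at its own regime.
#'
#' Alongside the power actually drawn at the scaled speed, the result
#' carries the specific power *predicted* directly by the volume-exponent
#' rule ([scale_specific_power()]). The two disagree by construction --
#' the speed rule rounds through discrete geometry -- and both are reported
#' so the discrepancy is visible; they are never averaged.
#'
#' @param source Characterized [fermenter_case()] (speed known).
#' @param target Target [fermenter_case()]; its impeller diameter is used as
#'   the target diameter and its impeller count as the stage count when
#'   `target_Z` is not given.
#' @param target_Z Optional liquid height, m, from which the stage count is
#'   derived via [feasible_impeller_counts()] (maximum feasible count).
#' @param alpha,beta,gamma Scale-rule exponents, see
#'   [scale_specific_power()] and [scale_impeller_speed()].
#' @param count_tol Tolerance for the impeller-count rule.
#' @param correlation [power_correlation()] used to characterize the source.
#' @return An object of class `scaleup_result`.
#' @examples
#' cases <- whey_scaleup_cases()
#' scaleup(cases$pilot, cases$industrial, target_Z = 9.29)
#' @export
scaleup <- function(source, target, target_Z = NULL,
                    alpha = 0.37, beta = 0.21, gamma = 5 / 3,
                    count_tol = 0.1,
                    correlation = default_power_correlation()) {
  stopifnot(inherits(source, "fermenter_case"),
            inherits(target, "fermenter_case"))
  Vw1 <- source$vessel$working_volume
  Vw2 <- target$vessel$working_volume
  D1 <- source$impeller$diameter
  D2 <- target$impeller$diameter
  fl <- target$fluid

  N2 <- scale_impeller_speed(source$speed, Vw1, Vw2, D1, D2, beta, gamma)

  if (is.null(target_Z)) {
    n <- target$impeller$count
    counts <- n
  } else {
    counts <- feasible_impeller_counts(target_Z, D2, tol = count_tol)
    n <- attr(counts, "selected")
  }

  re2 <- reynolds_number(fl$density, N2, D2, fl$dynamic_viscosity)
  regime2 <- classify_regime(re2)
  if (regime2 != "turbulent") {
    warning(sprintf(
      "scaled operating point has Re = %.3g (%s); the constant-P/Vw rule presumes turbulence",
      re2, regime2), call. = FALSE)
  }
  po <- correlation$turbulent_po[correlation$type == target$impeller$type]
  if (length(po) != 1L) {
    stop(sprintf("impeller type '%s' not found in the power correlation",
                 target$impeller$type), call. = FALSE)
  }

  single_power <- mixing_power(po, N2, D2, fl$density, 1L)
  p <- n * single_power
  eps <- energy_dissipation_rate(p, fl$density, Vw2)
  lam <- kolmogorov_length(eps, fl$kinematic_viscosity)
  shear <- if (is.null(fl$cell_size_range_um)) NULL else
    shear_safety(lam, max(fl$cell_size_range_um))

  source_op <- operating_point(source, correlation = correlation)
  pv_actual <- specific_power(p, Vw2, "working")
  pv_predicted <- scale_specific_power(
    as.numeric(source_op$specific_power_working), Vw1, Vw2, alpha)

  structure(
    list(source_label = source$label,
         target_label = target$label,
         exponents = c(alpha = alpha, beta = beta, gamma = gamma),
         target_speed = N2,
         target_rpm = 60 * N2,
         reynolds = re2,
         regime = regime2,
         n_impellers = n,
         feasible_counts = as.integer(counts),
         target_Z = target_Z,
         single_power = single_power,
         power = p,
         pv_working = pv_actual,
         pv_total = specific_power(p, target$vessel$total_volume, "total"),
         pv_predicted = pv_predicted,
         pv_discrepancy = as.numeric(pv_actual) - pv_predicted,
         epsilon_t = eps,
         kolmogorov = lam,
         shear = shear,
         torque_physical = impeller_torque(p, N2, "physical"),
         torque_hp = impeller_torque(p, N2, "hp_formula"),
         source_op = source_op),
    class = "scaleup_result")
}

#' @export
print.scaleup_result <- function(x, ...) {
  cat(sprintf("<scaleup_result> %s -> %s\n", x$source_label, x$target_label))
  cat(sprintf("  scaled speed N2 = %.4g s^-1 (%.1f rpm), Re %.4g (%s)\n",
              x$target_speed, x$target_rpm, x$reynolds, x$regime))
  cat(sprintf("  stages n = %d (feasible: %s%s)\n", x$n_impellers,
              paste(x$feasible_counts, collapse = ", "),
              if (is.null(x$target_Z)) ""
              else sprintf(" at Z = %.3g m", x$target_Z)))
  cat(sprintf("  power %.6g W (%.6g W per stage)\n", x$power, x$single_power))
  cat(sprintf("  P/V_w %.4g W m^-3 (rule predicts %.4g; gap %.3g)\n",
              as.numeric(x$pv_working), x$pv_predicted, x$pv_discrepancy))
  cat(sprintf("  eps_t %.4g W kg^-1 | lambda_k %.4g um\n",
              x$epsilon_t, 1e6 * x$kolmogorov))
  cat(sprintf("  torque %.6g N m (physical) / %.6g N m (hp formula)\n",
              x$torque_physical, x$torque_hp))
  invisible(x)
}

#' @export
summary.scaleup_result <- function(object, ...) {
  data.frame(source = object$source_label,
             target = object$target_label,
             N2 = object$target_speed,
             reynolds = object$reynolds,
             regime = object$regime,
             n_impellers = object$n_impellers,
             power_W = object$power,
             pv_working = as.numeric(object$pv_working),
             pv_total = as.numeric(object$pv_total),
             pv_predicted = object$pv_predicted,
             epsilon_t = object$epsilon_t,
             kolmogorov_um = 1e6 * object$kolmogorov,
             torque_physical = object$torque_physical,
             torque_hp = object$torque_hp,
             stringsAsFactors = FALSE)
}
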