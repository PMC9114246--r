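#' Stock impeller library
#'
#' The six commercial impeller types routinely screened for fermentation
#' duty, with their turbulent power numbers: Rushton turbine blade (RTB, 5),
#' concave blade turbine (CBT, 4.4), pitched blade turbine (PBT, 1.64),
#' Lightnin A310 three-blade hydrofoil (0.3), Lightnin A315 four-blade
#' hydrofoil (0.75) and marine propeller (MP, 0.34).
#'
#' @return A `data.frame` with columns `type` and `turbulent_po`.
#' @export
impeller_library <- function() {
  data.frame(
    type = c("RTB", "CBT", "PBT", "LA310", "LA315", "MP"),
    turbulent_po = c(5, 4.4, 1.64, 0.3, 0.75, 0.34),
    stringsAsFactors = FALSE)
}

#' Impeller-type by agitation-speed design matrix
#'
#' Evaluates every combination of impeller type, agitation speed and stage
#' count for one vessel: power draw, shaft torque (horsepower-formula
#' convention, the one used on sizing sheets) and specific power on the
#' total-volume basis. All cells share the case's impeller diameter (the
#' candidates are drop-in alternatives on the same shaft) and assume the
#' turbulent power number; a warning is emitted for any cell whose Reynolds
#' number is not turbulent.
#'
#' @param case A [fermenter_case()] supplying vessel, fluid and impeller
#'   diameter.
#' @param library Impeller library, a `data.frame` with `type` and
#'   `turbulent_po` columns; default [impeller_library()].
#' @param speeds_rpm Agitation speeds in rpm; converted internally to s^-1
#'   (`N = rpm / 60`).
#' @param counts Stage counts to tabulate; default `c(2, 3)`.
#' @return A `data.frame` of class `design_matrix` with one row per
#'   (type, speed, count) cell: `type`, `po`, `speed`, `rpm`, `count`,
#'   `power_kw`, `torque_hp`, `pv_total` (kW m^-3). The case is attached as
#'   attribute `case`.
#' @examples
#' dm <- build_design_matrix(whey_scaleup_cases()$industrial)
#' subset(dm, type == "RTB" & rpm == 80 & count == 2)
#' @export
build_design_matrix <- function(case, library = impeller_library(),
                                speeds_rpm = c(17, 50, 80, 110, 150),
                                counts = c(2L, 3L)) {
  stopifnot(inherits(case, "fermenter_case"))
  if (!is.data.frame(library) || nrow(library) == 0L ||
      !all(c("type", "turbulent_po") %in% names(library))) {
    stop("`library` must be a non-empty data.frame with columns ",
         "`type` and `turbulent_po`", call. = FALSE)
  }
  if (length(speeds_rpm) == 0L || any(speeds_rpm <= 0)) {
    stop("`speeds_rpm` must be a non-empty vector of positive speeds",
         call. = FALSE)
  }
  counts <- vapply(counts, check_count, integer(1), name = "counts")
  fl <- case$fluid
  D <- case$impeller$diameter
  grid <- expand.grid(i = seq_len(nrow(library)),
                      rpm = as.numeric(speeds_rpm),
                      count = counts)
  speed <- grid$rpm / 60
  po <- library$turbulent_po[grid$i]
  re <- fl$density * speed * D^2 / fl$dynamic_viscosity
  not_turb <- re <= 1e4
  if (any(not_turb)) {
    warning(sprintf(
      "%d design cell(s) fall outside the turbulent regime (min Re = %.3g); turbulent Po still applied",
      sum(not_turb), min(re)), call. = FALSE)
  }
  power_w <- grid$count * po * speed^3 * D^5 * fl$density
  out <- data.frame(
    type = library$type[grid$i],
    po = po,
    speed = speed,
    rpm = grid$rpm,
    count = grid$count,
    reynolds = re,
    power_kw = power_w / 1000,
    torque_hp = impeller_torque_vec(power_w, speed),
    pv_total = (power_w / 1000) / case$vessel$total_volume,
    stringsAsFactors = FALSE)
  structure(out, case = case, class = c("design_matrix", "data.frame"))
}

# vectorised hp-formula torque used by the matrix builder
impeller_torque_vec <- function(power_w, speed) {
  (power_w / 1000) * 63025 / (speed * 60) * 0.112985
}

#' Filter design-matrix cells by a specific-power window
#'
#' Keeps the cells whose total-volume specific power lies inside the closed
#' window. The conventional industrial window for scaled-up fermentations is
#' 2--4 kW m^-3.
#'
#' @param matrix A [build_design_matrix()] result.
#' @param window Length-2 numeric, kW m^-3, min < max; cells are retained
#'   when `window[1] <= pv_total <= window[2]`.
#' @return The retained rows (possibly zero rows), same class.
#' @export
filter_by_pv_window <- function(matrix, window = c(2, 4)) {
  stopifnot(inherits(matrix, "design_matrix") || is.data.frame(matrix))
  if (length(window) != 2L || !is.numeric(window) || window[1] >= window[2]) {
    stop("`window` must be two numbers, min < max (kW m^-3)", call. = FALSE)
  }
  matrix[matrix$pv_total >= window[1] & matrix$pv_total <= window[2], ,
         drop = FALSE]
}

#' Select an impeller type and speed from a design matrix
#'
#' Applies the selection criteria in sequence: (1) restrict to the given
#' stage count, (2) keep cells inside the specific-power window, (3) keep
#' cells whose Kolmogorov microscale at the cell's own dissipation rate
#' clears the largest cell size (shear-safe), then (4) pick the
#' maximum-torque cell, breaking ties toward lower power. High torque at low
#' speed is what slow-growing suspended cultures want: momentum transfer
#' without tip-speed damage.
#'
#' @param matrix A [build_design_matrix()] result (carries its case).
#' @param window Specific-power window, kW m^-3 (total-volume basis).
#' @param count Stage count the selection operates on; default 2.
#' @param cell_size_um Largest cell size for the shear screen; defaults to
#'   the case fluid's `cell_size_range_um` maximum, and the screen is
#'   skipped when neither is available.
#' @return An object of class `impeller_selection`: the selected cell, the
#'   ranked candidate table with torque ratios relative to the selection,
#'   and the runner-up (the other candidate with the nearest specific
#'   power). If no candidate survives, a structured result with
#'   `feasible = FALSE`.
#' @examples
#' dm <- build_design_matrix(whey_scaleup_cases()$industrial)
#' select_impeller(dm)
#' @export
select_impeller <- function(matrix, window = c(2, 4), count = 2L,
                            cell_size_um = NULL) {
  stopifnot(inherits(matrix, "design_matrix"))
  case <- attr(matrix, "case")
  count <- check_count(count, "count")
  cand <- filter_by_pv_window(matrix[matrix$count == count, , drop = FALSE],
                              window)
  if (is.null(cell_size_um) && !is.null(case$fluid$cell_size_range_um)) {
    cell_size_um <- max(case$fluid$cell_size_range_um)
  }
  if (nrow(cand) > 0L) {
    eps <- (cand$power_kw * 1000) /
      (case$fluid$density * case$vessel$working_volume)
    lam <- (case$fluid$kinematic_viscosity^3 / eps)^(1 / 4)
    cand$kolmogorov_um <- 1e6 * lam
    if (!is.null(cell_size_um)) {
      cand$shear_margin <- cand$kolmogorov_um / cell_size_um
      cand <- cand[cand$shear_margin > 1, , drop = FALSE]
    } else {
      cand$shear_margin <- NA_real_
    }
  }
  if (nrow(cand) == 0L) {
    return(structure(list(feasible = FALSE, selected = NULL,
                          candidates = cand, window = window, count = count),
                     class = "impeller_selection"))
  }
  ord <- order(-cand$torque_hp, cand$power_kw)
  cand <- cand[ord, , drop = FALSE]
  sel <- cand[1L, , drop = FALSE]
  cand$torque_ratio <- sel$torque_hp / cand$torque_hp
  runner <- NULL
  if (nrow(cand) > 1L) {
    others <- cand[-1L, , drop = FALSE]
    runner <- others[which.min(abs(others$pv_total - sel$pv_total)), ,
                     drop = FALSE]
  }
  structure(
    list(feasible = TRUE,
         selected = sel,
         candidates = cand,
         runner_up = runner,
         torque_ratio_vs_runner_up = if (is.null(runner)) NA_real_ else
           sel$torque_hp / runner$torque_hp,
         window = window, count = count,
         cell_size_um = cell_size_um),
    class = "impeller_selection")
}

#' @export
print.impeller_selection <- function(x, ...) {
  if (!x$feasible) {
    cat("<impeller_selection> no feasible design inside the window ",
        sprintf("[%g, %g] kW m^-3\n", x$window[1], x$window[2]), sep = "")
    return(invisible(x))
  }
  s <- x$selected
  cat(sprintf("<impeller_selection> %s @ %.4g s^-1 (%.0f rpm), %d stage(s)\n",
              s$type, s$speed, s$rpm, s$count))
  cat(sprintf("  P %.6g kW | P/V_t %.3g kW m^-3 | torque %.6g N m (hp formula)\n",
              s$power_kw, s$pv_total, s$torque_hp))
  if (!is.null(x$runner_up)) {
    cat(sprintf("  torque %.3g x runner-up (%s @ %.0f rpm)\n",
                x$torque_ratio_vs_runner_up, x$runner_up$type,
                x$runner_up$rpm))
  }
  cat(sprintf("  %d candidate cell(s) in window [%g, %g] kW m^-3\n",
              nrow(x$candidates), x$window[1], x$window[2]))
  invisible(x)
}

#' Default ladder of standard motor sizes
#'
#' An IEC-flavoured ladder of market motor ratings, kW. Purely a default:
#' real procurement lists should be supplied to [size_motor()].
#'
#' @return Sorted numeric vector of kW ratings.
#' @export
default_motor_sizes <- function() {
  c(90, 110, 132, 160, 200, 250, 315, 400, 500, 630, 800, 900,
    1000, 1200, 1400)
}

#' Size the installed motor for a shaft power requirement
#'
#' Multiplies the required shaft power by a service correction factor
#' (default 1.5, covering motor, bearing and gearbox losses) and picks the
#' smallest standard rating at or above that figure.
#'
#' @param shaft_power_kw Required shaft power, kW.
#' @param correction Service factor applied before rounding up; default 1.5.
#' @param sizes Ascending ladder of standard ratings, kW.
#' @return List of class `motor_spec`: `shaft_power_kw`, `correction`,
#'   `required_kw` (corrected), `installed_kw`.
#' @examples
#' size_motor(596.2) # 1.5 x 596.2 = 894.3 -> 900 kW
#' @export
size_motor <- function(shaft_power_kw, correction = 1.5,
                       sizes = default_motor_sizes()) {
  check_positive(shaft_power_kw, "shaft_power_kw", "kW")
  check_positive(correction, "correction")
  if (length(sizes) == 0L || any(diff(sizes) <= 0)) {
    stop("`sizes` must be a non-empty ascending ladder of ratings (kW)",
         call. = FALSE)
  }
  required <- correction * shaft_power_kw
  idx <- which(sizes >= required)
  if (length(idx) == 0L) {
    stop(sprintf(
      "no standard size covers %.4g kW (largest available: %.4g kW)",
      required, max(sizes)), call. = FALSE)
  }
  structure(list(shaft_power_kw = shaft_power_kw,
                 correction = correction,
                 required_kw = required,
                 installed_kw = sizes[min(idx)]),
            class = "motor_spec")
}

#' @export
print.motor_spec <- function(x, ...) {
  cat(sprintf("<motor_spec> shaft %.4g kW x %.2g -> install %.4g kW\n",
              x$shaft_power_kw, x$correction, x$installed_kw))
  invisible(x)
}
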