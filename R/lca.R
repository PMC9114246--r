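#' CML impact category ids
#'
#' The eight CML 2001 midpoint categories used for the electricity-only
#' gate-to-gate assessment: acidification (AP), eutrophication (EP),
#' freshwater aquatic ecotoxicity (FAETP), global warming over 100 years
#' (GWP), human toxicity (HTP), ozone layer depletion (ODP), photochemical
#' ozone creation (POCP) and terrestrial ecotoxicity (TETP).
#'
#' @return Character vector of category ids.
#' @export
cml_categories <- function() {
  c("AP", "EP", "FAETP", "GWP", "HTP", "ODP", "POCP", "TETP")
}

#' Electricity characterization factor table
#'
#' Per-category characterization factors for grid electricity, in kg of
#' category-equivalent per kWh. Factors are user configuration: they depend
#' on the grid mix and database vintage and are not bundled as constants.
#'
#' @param factors Named numeric vector covering every [cml_categories()]
#'   id; all values must be non-negative.
#' @return Named numeric vector of class `impact_factor_table`.
#' @examples
#' impact_factor_table(c(AP = 1e-3, EP = 5e-4, FAETP = 2e-2, GWP = 0.4,
#'                       HTP = 3e-2, ODP = 1e-8, POCP = 1e-4, TETP = 1e-3))
#' @export
impact_factor_table <- function(factors) {
  cats <- cml_categories()
  if (!is.numeric(factors) || is.null(names(factors))) {
    stop("`factors` must be a named numeric vector", call. = FALSE)
  }
  missing <- setdiff(cats, names(factors))
  if (length(missing) > 0L) {
    stop("missing impact categor", if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  factors <- factors[cats]
  if (any(!is.finite(factors)) || any(factors < 0)) {
    stop("characterization factors must be finite and non-negative",
         call. = FALSE)
  }
  structure(factors, class = "impact_factor_table")
}

#' Electricity use per functional unit
#'
#' Gate-to-gate inventory of fermenter operation: the agitator runs at power
#' `P` for `batch_hours` to process one batch of `substrate_volume`, so the
#' energy attributable to 1 m^3 of substrate (the functional unit) is
#' `E = P * batch_hours / substrate_volume`.
#'
#' @param power_kw Agitator electrical power, kW.
#' @param batch_hours Operating hours per batch; default 20 (one day of a
#'   20 h d^-1 campaign).
#' @param substrate_volume Substrate processed per batch, m^3; default 207
#'   (an industrial working volume).
#' @return Energy intensity, kWh per m^3 substrate.
#' @examples
#' energy_per_functional_unit(862.54, 20, 207) # ~83.3 kWh/m^3
#' @export
energy_per_functional_unit <- function(power_kw, batch_hours = 20,
                                       substrate_volume = 207) {
  check_positive(power_kw, "power_kw", "kW")
  check_positive(batch_hours, "batch_hours", "h")
  check_positive(substrate_volume, "substrate_volume", "m^3")
  power_kw * batch_hours / substrate_volume
}

#' Characterize an energy intensity into CML impacts
#'
#' Single-flow model: every impact is exactly
#' `impact_c = E * factor_c`. Linearity in `E` is therefore a structural
#' property, and impact rankings across options are identical in every
#' category.
#'
#' @param energy Energy intensity, kWh per m^3 substrate (>= 0).
#' @param factors An [impact_factor_table()].
#' @return A `data.frame` of class `lca_result` with columns `category`,
#'   `factor` and `impact` (kg-equivalent per m^3 substrate); the energy is
#'   attached as attribute `energy`.
#' @export
characterize_impacts <- function(energy, factors) {
  check_nonnegative(energy, "energy", "kWh m^-3")
  factors <- impact_factor_table(unclass(factors))
  out <- data.frame(category = cml_categories(),
                    factor = as.numeric(factors),
                    impact = energy * as.numeric(factors),
                    stringsAsFactors = FALSE)
  structure(out, energy = energy, class = c("lca_result", "data.frame"))
}

#' Compare turbine candidates on energy and impacts
#'
#' Computes the per-functional-unit energy and CML impacts of each candidate
#' operating cell and the pairwise percentage differences in energy.
#' Because the model is single-flow, the impact ranking in every category
#' equals the energy ranking; the result records the ranking so callers can
#' assert it.
#'
#' @param candidates A `data.frame` with columns `label` and `power_kw`
#'   (design-matrix rows work after adding a label), one row per candidate.
#' @param factors An [impact_factor_table()].
#' @param batch_hours,substrate_volume Passed to
#'   [energy_per_functional_unit()].
#' @return List of class `turbine_comparison`: `table` (label, power_kw,
#'   energy, one column per category, rank), `pairwise_percent` (matrix of
#'   100 * (E_i / E_j - 1)).
#' @export
compare_turbines <- function(candidates, factors, batch_hours = 20,
                             substrate_volume = 207) {
  if (!is.data.frame(candidates) || nrow(candidates) < 2L ||
      !all(c("label", "power_kw") %in% names(candidates))) {
    stop("`candidates` must be a data.frame with >= 2 rows and columns ",
         "`label` and `power_kw`", call. = FALSE)
  }
  factors <- impact_factor_table(unclass(factors))
  energy <- vapply(candidates$power_kw, energy_per_functional_unit,
                   numeric(1), batch_hours = batch_hours,
                   substrate_volume = substrate_volume)
  impacts <- outer(energy, as.numeric(factors))
  colnames(impacts) <- cml_categories()
  tab <- cbind(
    data.frame(label = candidates$label, power_kw = candidates$power_kw,
               energy_kwh_m3 = energy, stringsAsFactors = FALSE),
    as.data.frame(impacts))
  tab$rank <- rank(energy, ties.method = "min")
  pair <- 100 * (outer(energy, energy, `/`) - 1)
  dimnames(pair) <- list(candidates$label, candidates$label)
  structure(list(table = tab, pairwise_percent = pair),
            class = "turbine_comparison")
}

#' @export
print.turbine_comparison <- function(x, ...) {
  cat("<turbine_comparison>\n")
  print(x$table[order(x$table$rank),
                c("label", "power_kw", "energy_kwh_m3", "GWP", "rank")],
        row.names = FALSE)
  invisible(x)
}

#' Geometry scenario sweep: working height and aspect ratio
#'
#' Sweeps the working-volume height `Z` (and optionally the `H/T` ratio)
#' of a vessel and records, at each grid point, the feasible impeller
#' counts under the clearance rule, the specific power on the total-volume
#' basis averaged over those counts, and (when factors are supplied) the
#' correspondingly averaged energy intensity and GWP.
#'
#' Varying `H/T` at a fixed total height rescales the tank diameter
#' (`T = H / (H/T)`) and with it the impeller diameter at fixed `D/T`, so
#' larger `H/T` means a slimmer tank, a smaller impeller and less power.
#' The averaged specific power is piecewise constant in `Z`: it changes only
#' when the feasible count set changes.
#'
#' @param case A [fermenter_case()]; supplies fluid, volumes, total height
#'   and the baseline impeller.
#' @param speed Agitation speed, s^-1.
#' @param po Turbulent power number of the swept impeller; defaults to the
#'   case impeller's.
#' @param Z_grid Working-height grid, m.
#' @param HT_grid Optional `H/T` grid; `NULL` keeps the case geometry.
#' @param factors Optional [impact_factor_table()] for GWP.
#' @param batch_hours,substrate_volume Passed to
#'   [energy_per_functional_unit()].
#' @param count_tol Tolerance of the impeller-count rule.
#' @param average One of `"mean"`, `"min"`, `"max"`: how the per-count
#'   results are pooled.
#' @return A `data.frame` of class `scenario_sweep`: `Z`, `H_over_T`,
#'   `tank_diameter`, `impeller_diameter`, `counts` (comma string),
#'   `n_counts`, `avg_pv_total` (kW m^-3), `avg_energy` (kWh m^-3),
#'   `avg_gwp`, `feasible`. Infeasible grid points are recorded with `NA`
#'   values, not dropped.
#' @examples
#' scenario_sweep(whey_scaleup_cases()$industrial, speed = 80 / 60,
#'                Z_grid = c(8.6, 9.1))
#' @export
scenario_sweep <- function(case, speed, po = NULL, Z_grid, HT_grid = NULL,
                           factors = NULL, batch_hours = 20,
                           substrate_volume = NULL, count_tol = 0.1,
                           average = c("mean", "min", "max")) {
  stopifnot(inherits(case, "fermenter_case"))
  check_positive(speed, "speed", "s^-1")
  if (length(Z_grid) == 0L || any(Z_grid <= 0)) {
    stop("`Z_grid` must be a non-empty vector of positive heights (m)",
         call. = FALSE)
  }
  average <- match.arg(average)
  pool <- switch(average, mean = mean, min = min, max = max)
  po <- po %||% case$impeller$power_number
  substrate_volume <- substrate_volume %||% case$vessel$working_volume
  gwp_factor <- if (is.null(factors)) NA_real_ else
    as.numeric(impact_factor_table(unclass(factors))["GWP"])

  D0 <- case$impeller$diameter
  T0 <- case$vessel$tank_diameter
  H0 <- case$vessel$total_height
  d_over_t <- D0 / T0

  ht_values <- if (is.null(HT_grid)) NA_real_ else as.numeric(HT_grid)
  grid <- expand.grid(Z = as.numeric(Z_grid), H_over_T = ht_values)

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    Z <- grid$Z[i]
    ht <- grid$H_over_T[i]
    if (is.na(ht)) {
      tank <- T0; D <- D0
    } else {
      if (is.null(H0)) {
        stop("case vessel has no total_height; cannot sweep H/T",
             call. = FALSE)
      }
      tank <- H0 / ht
      D <- d_over_t * tank
    }
    counts <- tryCatch(feasible_impeller_counts(Z, D, tol = count_tol),
                       error = function(e) NULL)
    if (is.null(counts)) {
      return(data.frame(Z = Z, H_over_T = ht, tank_diameter = tank,
                        impeller_diameter = D, counts = "",
                        n_counts = 0L, avg_pv_total = NA_real_,
                        avg_energy = NA_real_, avg_gwp = NA_real_,
                        feasible = FALSE, stringsAsFactors = FALSE))
    }
    single_kw <- mixing_power(po, speed, D, case$fluid$density, 1L) / 1000
    pv <- vapply(counts, function(n)
      n * single_kw / case$vessel$total_volume, numeric(1))
    energy <- vapply(counts, function(n)
      energy_per_functional_unit(n * single_kw, batch_hours,
                                 substrate_volume), numeric(1))
    data.frame(Z = Z, H_over_T = ht, tank_diameter = tank,
               impeller_diameter = D,
               counts = paste(counts, collapse = ","),
               n_counts = length(counts),
               avg_pv_total = pool(pv),
               avg_energy = pool(energy),
               avg_gwp = if (is.na(gwp_factor)) NA_real_ else
                 gwp_factor * pool(energy),
               feasible = TRUE, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            case_label = case$label, speed = speed, po = po,
            average = average,
            class = c("scenario_sweep", "data.frame"))
}
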