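# configuration loading and report writing

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0L) {
    stop(sprintf("unknown key(s) in %s: %s (allowed: %s)", where,
                 paste(unknown, collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

num_field <- function(x, name, where) {
  if (is.null(x[[name]])) return(NULL)
  v <- unlist(x[[name]], use.names = FALSE)
  if (!is.numeric(v)) {
    stop(sprintf("field `%s` in %s must be numeric", name, where),
         call. = FALSE)
  }
  v
}

parse_case <- function(cfg, label) {
  where <- sprintf("case '%s'", label)
  check_keys(cfg, c("fluid", "vessel", "impeller", "speed"), where)
  for (part in c("fluid", "vessel", "impeller", "speed")) {
    if (is.null(cfg[[part]])) {
      stop(sprintf("%s is missing section `%s`", where, part), call. = FALSE)
    }
  }
  fl_cfg <- cfg$fluid
  check_keys(fl_cfg, c("density", "dynamic_viscosity", "kinematic_viscosity",
                       "cell_size_range_um"), paste0(where, " fluid"))
  fl <- fluid(num_field(fl_cfg, "density", where),
              num_field(fl_cfg, "dynamic_viscosity", where),
              num_field(fl_cfg, "kinematic_viscosity", where),
              num_field(fl_cfg, "cell_size_range_um", where))
  vs_cfg <- cfg$vessel
  check_keys(vs_cfg, c("total_volume", "working_volume", "working_height",
                       "tank_diameter", "total_height", "Z_over_T",
                       "H_over_T", "D_over_T"), paste0(where, " vessel"))
  vs <- vessel_geometry(num_field(vs_cfg, "total_volume", where),
                        num_field(vs_cfg, "working_volume", where),
                        num_field(vs_cfg, "working_height", where),
                        num_field(vs_cfg, "tank_diameter", where),
                        num_field(vs_cfg, "total_height", where),
                        num_field(vs_cfg, "Z_over_T", where),
                        num_field(vs_cfg, "H_over_T", where),
                        num_field(vs_cfg, "D_over_T", where))
  im_cfg <- cfg$impeller
  check_keys(im_cfg, c("type", "power_number", "diameter", "count",
                       "reynolds_anchor"), paste0(where, " impeller"))
  speed <- num_field(cfg, "speed", where)
  diam <- num_field(im_cfg, "diameter", where)
  if (is.null(diam)) {
    anchor <- im_cfg$reynolds_anchor
    if (is.null(anchor)) {
      stop(sprintf("%s impeller needs `diameter` or `reynolds_anchor`",
                   where), call. = FALSE)
    }
    check_keys(anchor, c("reynolds", "speed"),
               paste0(where, " reynolds_anchor"))
    diam <- diameter_from_reynolds(
      num_field(anchor, "reynolds", where), fl$density,
      num_field(anchor, "speed", where) %||% speed, fl$dynamic_viscosity)
  }
  fermenter_case(label, fl, vs,
                 impeller(as.character(im_cfg$type),
                          num_field(im_cfg, "power_number", where),
                          diam, num_field(im_cfg, "count", where) %||% 1L),
                 speed)
}

#' Load fermenter cases from a YAML or JSON configuration file
#'
#' The file holds a `cases` mapping (label -> fluid/vessel/impeller/speed,
#' SI units throughout) and an optional `correlation` list overriding the
#' default power-number table. Impeller diameters may be given directly or
#' as a `reynolds_anchor` (`reynolds` and optionally `speed`), in which case
#' the diameter is derived by [diameter_from_reynolds()]. Unknown keys are
#' rejected and validation failures name the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of [fermenter_case()] objects with attribute
#'   `correlation` (a [power_correlation()] table; the default one when the
#'   file does not override it).
#' @examples
#' cfg <- system.file("extdata", "whey_cases.yaml", package = "fermscale")
#' names(load_cases(cfg))
#' @export
load_cases <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    stop("config must be .yaml, .yml or .json", call. = FALSE)
  }
  check_keys(cfg, c("cases", "correlation"), "config")
  if (is.null(cfg$cases) || length(cfg$cases) == 0L ||
      is.null(names(cfg$cases))) {
    stop("config must contain a named `cases` mapping", call. = FALSE)
  }
  cases <- lapply(names(cfg$cases), function(lbl)
    parse_case(cfg$cases[[lbl]], lbl))
  names(cases) <- names(cfg$cases)
  corr <- default_power_correlation()
  if (!is.null(cfg$correlation)) {
    for (row in cfg$correlation) {
      check_keys(row, c("type", "turbulent_po", "laminar_kl",
                        "transition_po"), "correlation entry")
      ty <- as.character(row$type)
      i <- match(ty, corr$type)
      if (is.na(i)) {
        corr <- rbind(corr, data.frame(
          type = ty,
          turbulent_po = row$turbulent_po %||% NA_real_,
          laminar_kl = row$laminar_kl %||% 64,
          transition_po = row$transition_po %||% NA_real_))
      } else {
        if (!is.null(row$turbulent_po)) corr$turbulent_po[i] <- row$turbulent_po
        if (!is.null(row$laminar_kl)) corr$laminar_kl[i] <- row$laminar_kl
        if (!is.null(row$transition_po)) corr$transition_po[i] <- row$transition_po
      }
    }
  }
  structure(cases, correlation = corr)
}

#' Write a tabular result to CSV or JSON
#'
#' CSV keeps the data frame's column layout; JSON is a lossless row-wise
#' serialization (full double precision, no rounding) that reloads to the
#' same values.
#'
#' @param x A `data.frame` (design matrices, sweep results, summaries...).
#' @param path Output path; the format is taken from `format`, not the
#'   extension.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x)
  attr(x, "case") <- NULL
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Recompute the bundled case study and diff against reference values
#'
#' Runs the full analysis chain on [whey_scaleup_cases()] -- operating
#' points, the two scale-up steps, the industrial design matrix, the
#' impeller selection and the working-height sweep -- and compares each
#' derived quantity against the reference values shipped in
#' `extdata/reference_values.csv`, at the per-cell tolerance stored there.
#'
#' @param reference Path to the reference CSV; defaults to the bundled one.
#' @return A `data.frame` with `quantity`, `unit`, `expected`, `computed`,
#'   `rel_err`, `tolerance`, `pass`.
#' @export
replicate_case_study <- function(reference = system.file(
  "extdata", "reference_values.csv", package = "fermscale")) {
  ref <- utils::read.csv(reference, stringsAsFactors = FALSE)
  cases <- whey_scaleup_cases()
  corr <- attr(cases, "correlation")

  lab_op <- operating_point(cases$lab, correlation = corr)
  pilot_op <- operating_point(cases$pilot, correlation = corr)
  su_pilot <- suppressWarnings(scaleup(cases$lab, cases$pilot,
                                       correlation = corr))
  su_ind2 <- scaleup(cases$pilot, cases$industrial, target_Z = 5.99,
                     correlation = corr)
  su_ind3 <- scaleup(cases$pilot, cases$industrial, target_Z = 9.29,
                     correlation = corr)
  dm <- build_design_matrix(cases$industrial)
  sel <- select_impeller(dm)
  sweep <- scenario_sweep(cases$industrial, speed = 80 / 60,
                          Z_grid = 8.6)
  cell <- function(type, rpm, count, col) {
    dm[dm$type == type & dm$rpm == rpm & dm$count == count, ][[col]]
  }

  computed <- c(
    lab_power_W = lab_op$power,
    lab_pv_working = as.numeric(lab_op$specific_power_working),
    lab_lambda_um = 1e6 * lab_op$kolmogorov,
    pilot_power_W = pilot_op$power,
    pilot_pv_working = as.numeric(pilot_op$specific_power_working),
    pilot_lambda_um = 1e6 * pilot_op$kolmogorov,
    pilot_scaled_speed = su_pilot$target_speed,
    pilot_scaled_power_W = su_pilot$power,
    industrial_scaled_speed = su_ind2$target_speed,
    industrial_power_2stage_W = su_ind2$power,
    industrial_power_3stage_W = su_ind3$power,
    industrial_pv_2stage = as.numeric(su_ind2$pv_working),
    industrial_pv_3stage = as.numeric(su_ind3$pv_working),
    industrial_lambda_2stage_um = 1e6 * su_ind2$kolmogorov,
    industrial_lambda_3stage_um = 1e6 * su_ind3$kolmogorov,
    rtb_80_power_kW = cell("RTB", 80, 2, "power_kw"),
    rtb_80_torque_Nm = cell("RTB", 80, 2, "torque_hp"),
    rtb_80_pv_total = cell("RTB", 80, 2, "pv_total"),
    la315_150_power_kW = cell("LA315", 150, 2, "power_kw"),
    la315_150_torque_Nm = cell("LA315", 150, 2, "torque_hp"),
    la315_150_pv_total = cell("LA315", 150, 2, "pv_total"),
    cbt_80_power_kW = cell("CBT", 80, 2, "power_kw"),
    pbt_110_power_kW = cell("PBT", 110, 2, "power_kw"),
    selection_torque_ratio = sel$torque_ratio_vs_runner_up,
    sweep_avg_pv_z86 = sweep$avg_pv_total[1])

  idx <- match(ref$quantity, names(computed))
  if (anyNA(idx)) {
    stop("reference quantities not computed: ",
         paste(ref$quantity[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  ref$computed <- as.numeric(computed[idx])
  ref$rel_err <- abs(ref$computed - ref$expected) / abs(ref$expected)
  ref$pass <- ref$rel_err <= ref$tolerance
  ref
}
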