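# Reporting layer: the only place numbers are rounded. Per-patient values
# print to cents, hospital-year totals to whole dollars, national totals to
# the nearest $0.1M, relative savings to the nearest whole percent. Every
# displayed number derives from a full-precision value by one of these
# rules; re-deriving a scaled total from an already-rounded per-patient
# value does NOT reproduce the report, by design.

#' Round a value to a display unit
#'
#' @param x Numeric value(s).
#' @param unit Display unit: `0.01` for cents, `1` for whole dollars,
#'   `1e5` for $0.1M.
#' @return `round(x / unit) * unit`.
#' @export
round_display <- function(x, unit) {
  stopifnot(is.numeric(unit), unit > 0)
  round(x / unit) * unit
}

#' Run configuration
#'
#' Bundles the evaluation settings a reporting run needs: the parameter
#' source, the diversion convention, the output directory, and the display
#' rounding units.
#'
#' @param parameters_path Path to a JSON parameter file, or `NULL` to use
#'   [default_parameters()].
#' @param convention Diversion convention, see [cost_protocol_B()].
#' @param output_dir Directory for [write_report()] artifacts.
#' @param rounding Named list of display units; defaults: `perPatient` cents,
#'   `hospital` whole dollars, `national` $0.1M.
#' @return A `cvc_run_config` list.
#' @export
run_config <- function(parameters_path = NULL, convention = "sequential",
                       output_dir = "results",
                       rounding = list(perPatient = 0.01, hospital = 1,
                                       national = 1e5)) {
  stopifnot(all(c("perPatient", "hospital", "national") %in% names(rounding)),
            all(unlist(rounding) > 0))
  structure(list(parametersPath = parameters_path,
                 convention = .match_convention(convention),
                 outputDir = output_dir, rounding = rounding),
            class = "cvc_run_config")
}

#' Load parameters and run configuration from a JSON file
#'
#' The file is either a bare parameter file (top-level keys `wages`, `times`,
#' `probabilities`, `population`) or a wrapper with a `parameters` key
#' (inline object or path relative to the config file) plus optional
#' `convention` and `outputDir`.
#'
#' @param path Path to the JSON file.
#' @return List with elements `parameters` (`cvc_parameters`) and `config`
#'   (`cvc_run_config`).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(raw$parameters)) {
    params <- if (is.character(raw$parameters[[1]] %||% raw$parameters)) {
      ppath <- as.character(raw$parameters)
      if (!file.exists(ppath)) {
        ppath <- file.path(dirname(path), ppath)
      }
      load_parameters(ppath)
    } else {
      tmp <- tempfile(fileext = ".json")
      on.exit(unlink(tmp), add = TRUE)
      jsonlite::write_json(raw$parameters, tmp, auto_unbox = TRUE,
                           digits = NA)
      load_parameters(tmp)
    }
    cfg <- run_config(
      parameters_path = path,
      convention = as.character(raw$convention %||% "sequential"),
      output_dir = as.character(raw$outputDir %||% "results")
    )
  } else {
    params <- load_parameters(path)
    cfg <- run_config(parameters_path = path)
  }
  list(parameters = params, config = cfg)
}

#' Render the cost-comparison report
#'
#' Builds the machine-readable mirror of the published cost-comparison
#' table plus the population-scaling rows, with display rounding applied
#' (full-precision values are carried alongside in `*_full` columns).
#'
#' @param params A `cvc_parameters` object.
#' @param convention Diversion convention, see [cost_protocol_B()].
#' @param rounding Display units as in [run_config()].
#' @return A `cvc_report` list:
#'   \describe{
#'     \item{perPatient}{line items of both protocols with cents-rounded
#'       costs, including the two diversion rows and per-protocol totals.}
#'     \item{incremental}{costs, absolute savings (cents), relative savings
#'       (whole percent).}
#'     \item{scaling}{hospital-year (whole dollars), per-million and
#'       national-scale ($0.1M) totals and differences.}
#'     \item{metadata}{package version, convention, timestamp.}
#'   }
#' @export
render_cost_report <- function(params, convention = "sequential",
                               rounding = list(perPatient = 0.01,
                                               hospital = 1, national = 1e5)) {
  validate_parameters(params)
  convention <- .match_convention(convention)
  a <- cost_protocol_A(params)
  b <- cost_protocol_B(params, convention)
  inc <- incremental_result(params, convention)
  ru <- rounding

  line_rows <- function(bd) {
    rows <- bd$lines
    rows$protocol <- bd$protocol
    if (bd$protocol == "B") {
      rows <- rbind(rows, data.frame(
        description = c("Diversion to CXR protocol (malposition)",
                        "Diversion to CXR protocol (pneumothorax)"),
        role = NA_character_, minutes = NA_real_, wagePerMinute = NA_real_,
        cost = c(bd$diversionMalposition, bd$diversionPneumothorax),
        protocol = "B", stringsAsFactors = FALSE))
    }
    rows <- rbind(rows, data.frame(
      description = "Total cost per patient", role = NA_character_,
      minutes = NA_real_, wagePerMinute = NA_real_, cost = bd$total,
      protocol = bd$protocol, stringsAsFactors = FALSE))
    rows
  }
  per_patient <- rbind(line_rows(a), line_rows(b))
  per_patient$cost_full <- per_patient$cost
  per_patient$cost <- round_display(per_patient$cost, ru$perPatient)
  per_patient <- per_patient[, c("protocol", "description", "role", "minutes",
                                 "wagePerMinute", "cost", "cost_full")]

  pop <- params$population
  scale_row <- function(scale, n, unit) {
    totalA <- scale_to_population(inc$costA, n)
    totalB <- scale_to_population(inc$costB, n)
    data.frame(scale = scale, n = n,
               costA = round_display(totalA, unit),
               costB = round_display(totalB, unit),
               difference = round_display(totalA - totalB, unit),
               costA_full = totalA, costB_full = totalB,
               stringsAsFactors = FALSE)
  }
  scaling <- rbind(
    scale_row("hospital-year", pop$hospitalCxrConfirmed, ru$hospital),
    scale_row("per-million-CVCs", 1e6, ru$national),
    scale_row("national-eligible", pop$nationalEligible, ru$national)
  )

  incremental <- data.frame(
    costA = round_display(inc$costA, ru$perPatient),
    costB = round_display(inc$costB, ru$perPatient),
    absoluteSavings = round_display(inc$absoluteSavings, ru$perPatient),
    relativeSavingsPct = round(100 * inc$relativeSavings),
    costA_full = inc$costA, costB_full = inc$costB,
    absoluteSavings_full = inc$absoluteSavings
  )

  structure(list(
    perPatient = per_patient,
    incremental = incremental,
    scaling = scaling,
    metadata = list(
      package = "cvccost",
      version = as.character(utils::packageVersion("cvccost")),
      convention = convention,
      generated = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    )
  ), class = "cvc_report")
}

#' Write a report bundle to CSV and JSON
#'
#' Writes `per_patient_costs.csv`, `population_scaling.csv`,
#' `incremental.csv`, and `report.json` into `dir` (created if missing).
#' CSV is UTF-8, comma-separated, header row, period decimal mark.
#'
#' @param report A `cvc_report` from [render_cost_report()].
#' @param dir Output directory.
#' @return Character vector of the written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cvc_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    per_patient = file.path(dir, "per_patient_costs.csv"),
    scaling = file.path(dir, "population_scaling.csv"),
    incremental = file.path(dir, "incremental.csv"),
    json = file.path(dir, "report.json")
  )
  utils::write.csv(report$perPatient, paths[["per_patient"]],
                   row.names = FALSE)
  utils::write.csv(report$scaling, paths[["scaling"]], row.names = FALSE)
  utils::write.csv(report$incremental, paths[["incremental"]],
                   row.names = FALSE)
  jsonlite::write_json(unclass(report), paths[["json"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(paths)
}

#' @export
print.cvc_report <- function(x, ...) {
  inc <- x$incremental
  cat("CVC confirmation labor-cost report (", x$metadata$convention,
      " diversion convention)\n", sep = "")
  cat(sprintf("  per patient: A $%.2f vs B $%.2f; savings $%.2f (%d%%)\n",
              inc$costA, inc$costB, inc$absoluteSavings,
              inc$relativeSavingsPct))
  h <- x$scaling[x$scaling$scale == "hospital-year", ]
  cat(sprintf("  hospital-year (n = %s): $%s vs $%s (difference $%s)\n",
              format(h$n, big.mark = ","),
              format(h$costA, big.mark = ","),
              format(h$costB, big.mark = ","),
              format(h$difference, big.mark = ",")))
  nat <- x$scaling[x$scaling$scale == "national-eligible", ]
  cat(sprintf("  national (%s eligible): $%.1fM vs $%.1fM (difference $%.1fM)\n",
              format(nat$n, big.mark = ",", scientific = FALSE),
              nat$costA / 1e6, nat$costB / 1e6, nat$difference / 1e6))
  invisible(x)
}
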