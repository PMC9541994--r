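#' @keywords internal
"_PACKAGE"

# Canonical labels. Roles index the wage table; tasks index the time table.
.role_labels <- c("bedside-physician", "radiologist", "registered-nurse",
                  "radiology-technician")
.task_labels <- c("mdTimeA", "mdTimeB", "radiologistRead", "rnTimeB",
                  "techTimeA")
# Which role performs each task (wage lookup for cost lines).
.task_role <- c(
  mdTimeA         = "bedside-physician",
  mdTimeB         = "bedside-physician",
  radiologistRead = "radiologist",
  rnTimeB         = "registered-nurse",
  techTimeA       = "radiology-technician"
)

.range3 <- function(central, low, high) {
  list(central = central, low = low, high = high)
}

#' Default model parameters
#'
#' Central estimates and sensitivity ranges for all model inputs: $/minute
#' wage rates for the four personnel roles (ranges are 25th-75th salary
#' percentiles), task durations in minutes for the five labor segments,
#' complication probabilities (malposition and pneumothorax on ultrasound,
#' which divert a protocol-B patient to the full radiograph pathway), and the
#' population counts used for hospital- and national-scale projections.
#'
#' Probability ranges span the three published sources available as scenarios
#' (see [load_scenario()]): malposition 0.026-0.176, pneumothorax 0.011-0.032,
#' with the Smit 2018 meta-analysis values as the central estimates.
#'
#' @return A `cvc_parameters` object: a validated list with components
#'   `wages`, `times`, `probabilities`, and `population`.
#' @seealso [load_parameters()] to read the same structure from JSON,
#'   [set_parameter()] to perturb a single quantity.
#' @export
#' @examples
#' p <- default_parameters()
#' cost_protocol_A(p)$total
default_parameters <- function() {
  params <- structure(list(
    wages = list(
      "bedside-physician"    = .range3(1.72, 1.41, 1.99),
      "radiologist"          = .range3(1.89, 1.66, 2.06),
      "registered-nurse"     = .range3(0.64, 0.52, 0.79),
      "radiology-technician" = .range3(0.51, 0.42, 0.63)
    ),
    times = list(
      mdTimeA         = .range3(3.0, 2.0, 4.0),
      mdTimeB         = .range3(5.6, 3.1, 8.1),
      radiologistRead = .range3(3.0, 2.0, 4.0),
      rnTimeB         = .range3(5.6, 3.1, 8.1),
      techTimeA       = .range3(15.0, 10.0, 20.0)
    ),
    probabilities = list(
      pMalposition  = .range3(0.068, 0.026, 0.176),
      pPneumothorax = .range3(0.011, 0.011, 0.032),
      source        = "smit2018"
    ),
    population = list(
      hospitalCvcTotal          = 3069,
      hospitalCxrConfirmed      = 2045,
      nationalCvcTotal          = 5e6,
      supradiaphragmaticFraction = 0.66,
      nationalEligible          = 3.3e6
    )
  ), class = "cvc_parameters")
  validate_parameters(params)
  params
}

.check <- function(ok, field, msg) {
  if (!isTRUE(ok)) {
    stop(sprintf("invalid parameters: %s: %s", field, msg), call. = FALSE)
  }
}

.check_range3 <- function(x, field, positive_low = FALSE, zero_ok = TRUE,
                          unit_interval = FALSE) {
  .check(is.list(x) && all(c("central", "low", "high") %in% names(x)),
         field, "must have central, low and high")
  for (nm in c("central", "low", "high")) {
    v <- x[[nm]]
    .check(is.numeric(v) && length(v) == 1L && is.finite(v),
           paste(field, nm, sep = "."), "must be a finite number")
  }
  lo <- if (positive_low) x$low > 0 else if (zero_ok) x$low >= 0 else x$low > 0
  .check(lo, paste0(field, ".low"),
         if (positive_low) "must be > 0" else "must be >= 0")
  .check(x$low <= x$central && x$central <= x$high, field,
         "requires low <= central <= high")
  if (unit_interval) {
    .check(x$high <= 1, paste0(field, ".high"), "must be <= 1")
  }
}

#' Validate a parameter set
#'
#' Checks the structural and numeric invariants of a `cvc_parameters` object:
#' exactly one wage entry per role and one duration entry per task; wages
#' strictly positive with `low <= central <= high`; task times nonnegative
#' (zero-duration tasks are allowed as degenerate limits); probabilities in
#' \[0, 1\] (their sum must additionally stay at or below 1 whenever the
#' additive convention is evaluated, checked at evaluation time); population
#' counts consistent (`hospitalCxrConfirmed <= hospitalCvcTotal`, and the
#' national eligible count within 1% of `nationalCvcTotal *
#' supradiaphragmaticFraction`).
#'
#' @param params A `cvc_parameters` object.
#' @return `params`, invisibly. Errors name the offending field path, e.g.
#'   `wages.registered-nurse`.
#' @export
validate_parameters <- function(params) {
  .check(is.list(params), "parameters", "must be a list")
  .check(all(c("wages", "times", "probabilities", "population") %in%
               names(params)),
         "parameters", "must have wages, times, probabilities, population")

  for (role in .role_labels) {
    .check(role %in% names(params$wages), paste0("wages.", role), "missing")
    .check_range3(params$wages[[role]], paste0("wages.", role),
                  positive_low = TRUE)
  }
  .check(length(params$wages) == length(.role_labels),
         "wages", "must contain exactly one entry per role")

  for (task in .task_labels) {
    .check(task %in% names(params$times), paste0("times.", task), "missing")
    .check_range3(params$times[[task]], paste0("times.", task))
  }
  .check(length(params$times) == length(.task_labels),
         "times", "must contain exactly one entry per task")

  for (pr in c("pMalposition", "pPneumothorax")) {
    .check(pr %in% names(params$probabilities),
           paste0("probabilities.", pr), "missing")
    .check_range3(params$probabilities[[pr]], paste0("probabilities.", pr),
                  unit_interval = TRUE)
  }
  pop <- params$population
  for (nm in c("hospitalCvcTotal", "hospitalCxrConfirmed", "nationalCvcTotal",
               "supradiaphragmaticFraction", "nationalEligible")) {
    .check(nm %in% names(pop) && is.numeric(pop[[nm]]) && pop[[nm]] >= 0,
           paste0("population.", nm), "must be a nonnegative number")
  }
  .check(pop$hospitalCxrConfirmed <= pop$hospitalCvcTotal,
         "population.hospitalCxrConfirmed",
         "cannot exceed hospitalCvcTotal")
  implied <- pop$nationalCvcTotal * pop$supradiaphragmaticFraction
  .check(abs(pop$nationalEligible - implied) <= 0.01 * implied,
         "population.nationalEligible",
         "must be within 1% of nationalCvcTotal * supradiaphragmaticFraction")
  invisible(params)
}

# --- sensitivity parameter labels ------------------------------------------

.wage_param <- c(
  wageBedsideMD   = "bedside-physician",
  wageRadiologist = "radiologist",
  wageRN          = "registered-nurse",
  wageTech        = "radiology-technician"
)
.prob_param <- c("pMalposition", "pPneumothorax")

#' Labels of the quantities that can be varied in sensitivity analyses
#'
#' Five task durations, two complication probabilities, and (optionally) the
#' four wage rates. Wage sensitivity is exposed but excluded from the default
#' tornado: salaries scale both protocols proportionally, so their
#' sensitivity is reported separately from the time/probability drivers.
#'
#' @param include_wages Include the four wage-rate labels?
#' @return Character vector of parameter labels.
#' @export
parameter_labels <- function(include_wages = TRUE) {
  out <- c(.task_labels, .prob_param)
  if (include_wages) out <- c(out, names(.wage_param))
  out
}

.locate_parameter <- function(params, label) {
  if (label %in% .task_labels) {
    list(group = "times", key = label)
  } else if (label %in% names(.wage_param)) {
    list(group = "wages", key = .wage_param[[label]])
  } else if (label %in% .prob_param) {
    list(group = "probabilities", key = label)
  } else {
    stop(sprintf("unknown parameter '%s'; valid labels: %s", label,
                 paste(parameter_labels(), collapse = ", ")), call. = FALSE)
  }
}

#' Low/central/high range of a model parameter
#'
#' @param params A `cvc_parameters` object.
#' @param label One of [parameter_labels()].
#' @return Named numeric vector `c(low, central, high)`.
#' @export
parameter_range <- function(params, label) {
  loc <- .locate_parameter(params, label)
  r <- params[[loc$group]][[loc$key]]
  c(low = r$low, central = r$central, high = r$high)
}

#' Set the working (central) value of one model parameter
#'
#' Used by the sensitivity and Monte-Carlo machinery: replaces the central
#' value and, if needed, widens the stored range so `low <= central <= high`
#' keeps holding. Model evaluation reads only central values.
#'
#' @inheritParams parameter_range
#' @param value New value (minutes, $/minute, or probability as appropriate).
#' @return Updated `cvc_parameters` object.
#' @export
set_parameter <- function(params, label, value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  loc <- .locate_parameter(params, label)
  # Targeted checks: the rest of the object is untouched, so a full
  # validate_parameters() pass here would only repeat work (this function
  # sits in the sensitivity/Monte-Carlo hot path).
  if (loc$group == "wages" && value <= 0) {
    .check(FALSE, paste0("wages.", loc$key), "must be > 0")
  }
  if (loc$group == "times" && value < 0) {
    .check(FALSE, paste0("times.", loc$key), "must be >= 0")
  }
  if (loc$group == "probabilities" && (value < 0 || value > 1)) {
    .check(FALSE, paste0("probabilities.", loc$key), "must lie in [0, 1]")
  }
  r <- params[[loc$group]][[loc$key]]
  r$central <- value
  r$low <- min(r$low, value)
  r$high <- max(r$high, value)
  params[[loc$group]][[loc$key]] <- r
  params
}

# Central-value accessors used throughout the cost equations.
.wage <- function(params, role) params$wages[[role]]$central
.time <- function(params, task) params$times[[task]]$central
.prob <- function(params, which) params$probabilities[[which]]$central

# --- JSON I/O ---------------------------------------------------------------

#' Read model parameters from a JSON file
#'
#' The file holds top-level keys `wages`, `times`, `probabilities`, and
#' `population`; each wage/time/probability entry is an object with `central`,
#' `low`, `high`. The packaged default (`system.file("extdata",
#' "default_parameters.json", package = "cvccost")`) reproduces
#' [default_parameters()] exactly.
#'
#' @param path Path to a JSON parameter file.
#' @return Validated `cvc_parameters` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  }
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("could not parse '%s' as JSON: %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  # Flatten length-1 lists left by simplifyVector = FALSE into scalars and
  # keep all numbers double (JSON integers would otherwise break identity
  # round trips).
  unwrap <- function(x) {
    if (is.list(x)) return(lapply(x, unwrap))
    if (length(x) == 1L) x <- x[[1L]]
    if (is.numeric(x)) x <- as.numeric(x)
    x
  }
  params <- structure(unwrap(raw), class = "cvc_parameters")
  validate_parameters(params)
  params
}

#' Write model parameters to JSON
#'
#' Inverse of [load_parameters()]: full precision (no digit truncation), so a
#' write/load round trip reproduces the in-memory parameters exactly.
#'
#' @param params A `cvc_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.cvc_parameters <- function(x, ...) {
  cat("CVC confirmation labor-cost model parameters\n")
  cat("  wages ($/min):",
      paste(sprintf("%s=%.2f", names(x$wages),
                    vapply(x$wages, `[[`, 0, "central")), collapse = ", "),
      "\n")
  cat("  times (min):  ",
      paste(sprintf("%s=%.1f", names(x$times),
                    vapply(x$times, `[[`, 0, "central")), collapse = ", "),
      "\n")
  cat(sprintf("  probabilities: malposition=%.3f, pneumothorax=%.3f (%s)\n",
              x$probabilities$pMalposition$central,
              x$probabilities$pPneumothorax$central,
              x$probabilities$source %||% "unspecified"))
  cat(sprintf("  population: hospital %d CXR-confirmed / %d CVCs; national %s eligible\n",
              as.integer(x$population$hospitalCxrConfirmed),
              as.integer(x$population$hospitalCvcTotal),
              format(x$population$nationalEligible, big.mark = ",",
                     scientific = FALSE)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
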