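# Published alternative inputs for the complication probabilities, packaged
# as named scenarios: two meta-analyses and one internal chart review. Each
# scenario also carries the corresponding published confirmation-time
# intervals as annotation; those intervals describe elapsed wall-clock time
# (order-to-completion), not hands-on labor minutes, so they are metadata
# only and never enter the cost equations.

.scenarios <- list(
  smit2018 = list(
    label = "Smit 2018 meta-analysis",
    probabilities = list(pMalposition = 0.068, pPneumothorax = 0.011),
    times = data.frame(
      interval = c("CXR ordered to CXR performed",
                   "CXR ordered to radiology read complete",
                   "POCUS confirmation initiated to complete"),
      central = c(34.7, 46.3, 2.83),
      low = c(32.6, 44.4, 2.77),
      high = c(36.7, 48.2, 2.89),
      dispersion = "95% CI",
      stringsAsFactors = FALSE
    )
  ),
  ablordeppey2017 = list(
    label = "Ablordeppey 2017 meta-analysis",
    probabilities = list(pMalposition = 0.176, pPneumothorax = 0.011),
    times = data.frame(
      interval = c("CXR ordered to CXR performed",
                   "CXR ordered to radiology read complete",
                   "POCUS confirmation initiated to complete"),
      central = c(63.9, 143.4, 5.6),
      low = c(63.9 - 57.1, 143.4 - 123.7, 5.6 - 2.5),
      high = c(63.9 + 57.1, 143.4 + 123.7, 5.6 + 2.5),
      dispersion = "mean +/- SD",
      stringsAsFactors = FALSE
    )
  ),
  internal2019 = list(
    label = "Internal chart review, 2019",
    probabilities = list(pMalposition = 0.026, pPneumothorax = 0.032),
    times = data.frame(
      interval = c("CXR ordered to CXR performed",
                   "POCUS confirmation initiated to complete"),
      central = c(29, 9),
      low = c(1, 8.5),
      high = c(269, 9.5),
      dispersion = "range",
      stringsAsFactors = FALSE
    )
  )
)

#' Names of the packaged probability scenarios
#'
#' @return Character vector of scenario names accepted by [load_scenario()].
#' @export
scenario_names <- function() names(.scenarios)

#' Load a published complication-probability scenario
#'
#' Each scenario holds the malposition and pneumothorax detection
#' probabilities from one published source, plus that source's confirmation
#' time intervals as annotation (elapsed order-to-completion times, not the
#' hands-on labor minutes the cost model uses).
#'
#' @param name One of [scenario_names()].
#' @return A `cvc_scenario` list: `name`, `label`, `probabilities`
#'   (`pMalposition`, `pPneumothorax`), and the annotated `times` data frame.
#' @seealso [apply_scenario()]
#' @export
#' @examples
#' load_scenario("internal2019")$probabilities
load_scenario <- function(name) {
  if (!name %in% names(.scenarios)) {
    stop(sprintf("unknown scenario '%s'; valid names: %s", name,
                 paste(scenario_names(), collapse = ", ")), call. = FALSE)
  }
  structure(c(list(name = name), .scenarios[[name]]), class = "cvc_scenario")
}

#' Overlay a scenario's probabilities on a parameter set
#'
#' Replaces the central complication probabilities (and the probability
#' source label) with the scenario's values; wage, time, and population
#' inputs are untouched. Ranges widen if the scenario value falls outside
#' the declared range.
#'
#' @param params A `cvc_parameters` object.
#' @param scenario A `cvc_scenario` from [load_scenario()], or its name.
#' @return Updated `cvc_parameters` object.
#' @export
#' @examples
#' p <- apply_scenario(default_parameters(), "ablordeppey2017")
#' round(cost_protocol_B(p)$total, 2)
apply_scenario <- function(params, scenario) {
  if (is.character(scenario)) scenario <- load_scenario(scenario)
  stopifnot(inherits(scenario, "cvc_scenario"))
  params <- set_parameter(params, "pMalposition",
                          scenario$probabilities$pMalposition)
  params <- set_parameter(params, "pPneumothorax",
                          scenario$probabilities$pPneumothorax)
  params$probabilities$source <- scenario$name
  params
}

#' @export
print.cvc_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s' (%s)\n", x$name, x$label))
  cat(sprintf("  P(malposition) = %.3f, P(pneumothorax) = %.3f\n",
              x$probabilities$pMalposition, x$probabilities$pPneumothorax))
  cat(sprintf("  %d annotated time interval(s), dispersion: %s\n",
              nrow(x$times), x$times$dispersion[1]))
  invisible(x)
}
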