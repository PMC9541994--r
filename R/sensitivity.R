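# Deterministic sensitivity analysis: one-way and two-way evaluation over the
# declared parameter ranges, tornado ordering, and break-even roots on the
# cost difference A - B. Every evaluation re-runs the full model, so effects
# propagate consistently (e.g. varying a protocol-A time also moves protocol
# B's diversion cost, because diverted patients incur the perturbed A cost).

.diff_at <- function(params, convention, label = NULL, value = NULL) {
  if (!is.null(label)) params <- set_parameter(params, label, value)
  .totals_unchecked(params, .match_convention(convention))
}

#' One-way sensitivity of the cost difference to a single parameter
#'
#' Evaluates the full model with the chosen parameter at its low and its high
#' bound, all other parameters held at central values.
#'
#' @param params A `cvc_parameters` object.
#' @param parameter One of [parameter_labels()].
#' @param convention Diversion convention, see [cost_protocol_B()].
#' @return One-row data frame with the inputs used and `costA`, `costB`, and
#'   `diff` (savings, `A - B`) at each extreme.
#' @export
#' @examples
#' one_way(default_parameters(), "mdTimeB")  # diff_high < 0: savings flip
one_way <- function(params, parameter, convention = "sequential") {
  validate_parameters(params)
  rng <- parameter_range(params, parameter)
  lo <- .diff_at(params, convention, parameter, rng[["low"]])
  hi <- .diff_at(params, convention, parameter, rng[["high"]])
  data.frame(
    parameter = parameter,
    lowInput = rng[["low"]], highInput = rng[["high"]],
    costA_low = lo[["costA"]], costA_high = hi[["costA"]],
    costB_low = lo[["costB"]], costB_high = hi[["costB"]],
    diff_low = lo[["diff"]], diff_high = hi[["diff"]],
    stringsAsFactors = FALSE
  )
}

#' One-way sensitivity over every varying parameter
#'
#' @inheritParams one_way
#' @param include_wages Also vary the four wage rates? Wages move both
#'   protocols proportionally, so they are reported but excluded from the
#'   default tornado.
#' @return Data frame with one [one_way()] row per parameter.
#' @export
one_way_all <- function(params, convention = "sequential",
                        include_wages = TRUE) {
  labels <- parameter_labels(include_wages)
  do.call(rbind, lapply(labels, one_way, params = params,
                        convention = convention))
}

#' Tornado-diagram data: parameters ordered by their swing on the savings
#'
#' Swing is `|diff_high - diff_low|`, the full excursion of the cost
#' difference `A - B` as the parameter traverses its range. Entries are
#' sorted by swing, descending; ties break lexicographically by parameter
#' label so the ordering is reproducible. `direction` names the extreme
#' (`"low"` or `"high"`) at which the savings are smallest, i.e. which end of
#' the range favors the radiograph protocol.
#'
#' @inheritParams one_way_all
#' @param include_wages Include wage rates? Defaults to `FALSE`: salary
#'   sensitivity is exposed but kept out of the default tornado because
#'   salaries shift both protocols proportionally.
#' @param metric `"dollars"` reports swings in dollars of savings;
#'   `"percent"` rescales swings to percent of the base-case protocol-A cost.
#' @return Data frame: `parameter`, `diff_low`, `diff_high`, `swing`,
#'   `direction`, sorted by descending swing.
#' @export
tornado <- function(params, convention = "sequential", include_wages = FALSE,
                    metric = c("dollars", "percent")) {
  metric <- match.arg(metric)
  ow <- one_way_all(params, convention, include_wages)
  swing <- abs(ow$diff_high - ow$diff_low)
  if (metric == "percent") {
    base_a <- cost_protocol_A(params)$total
    swing <- 100 * swing / base_a
  }
  out <- data.frame(
    parameter = ow$parameter,
    diff_low = ow$diff_low, diff_high = ow$diff_high,
    swing = swing,
    direction = ifelse(ow$diff_low <= ow$diff_high, "low", "high"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$swing, out$parameter), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-way sensitivity grid
#'
#' Evaluates the cost difference `A - B` on an evenly spaced grid spanning
#' the ranges of two distinct parameters, all others at central values.
#'
#' @inheritParams one_way
#' @param parameterX,parameterY Distinct labels from [parameter_labels()].
#' @param gridPoints Points per axis (`>= 2`; default 11).
#' @return A `cvc_two_way` list: `parameterX`, `parameterY`, `xValues`,
#'   `yValues`, and the `diff` matrix (rows index x, columns index y).
#' @export
two_way <- function(params, parameterX, parameterY, gridPoints = 11,
                    convention = "sequential") {
  if (identical(parameterX, parameterY)) {
    stop("parameterX and parameterY must be distinct", call. = FALSE)
  }
  stopifnot(gridPoints >= 2)
  validate_parameters(params)
  rx <- parameter_range(params, parameterX)
  ry <- parameter_range(params, parameterY)
  xv <- seq(rx[["low"]], rx[["high"]], length.out = gridPoints)
  yv <- seq(ry[["low"]], ry[["high"]], length.out = gridPoints)
  diff <- matrix(NA_real_, nrow = gridPoints, ncol = gridPoints)
  for (i in seq_along(xv)) {
    pi <- set_parameter(params, parameterX, xv[i])
    for (j in seq_along(yv)) {
      pij <- set_parameter(pi, parameterY, yv[j])
      diff[i, j] <- .diff_at(pij, convention)[["diff"]]
    }
  }
  structure(list(parameterX = parameterX, parameterY = parameterY,
                 xValues = xv, yValues = yv, diff = diff),
            class = "cvc_two_way")
}

#' Long-format view of a two-way grid (for CSV export / plotting)
#'
#' @param grid A `cvc_two_way` object.
#' @return Data frame with columns `x`, `y`, `diff`.
#' @export
two_way_long <- function(grid) {
  stopifnot(inherits(grid, "cvc_two_way"))
  data.frame(
    x = rep(grid$xValues, times = length(grid$yValues)),
    y = rep(grid$yValues, each = length(grid$xValues)),
    diff = as.vector(grid$diff)
  )
}

#' Break-even (threshold) value of a parameter
#'
#' Finds the parameter value at which the two protocols cost the same
#' (`costA = costB`). The cost difference is linear in every individual model
#' parameter, so the root is solved in closed form from two evaluations and
#' then verified against [stats::uniroot()] when a sign change brackets it.
#' The search window is the declared range extended tenfold about the central
#' value (clamped to valid supports: nonnegative times, positive wages,
#' probabilities in \[0, 1\]); a root outside that window is reported as
#' `NA` (no break-even in any plausible neighborhood).
#'
#' @inheritParams one_way
#' @return The break-even value in the parameter's own units, or `NA_real_`
#'   if no root lies in the extended window. If the cost difference does not
#'   depend on the parameter at all, the central value is returned when the
#'   difference is identically zero and `NA_real_` otherwise.
#' @export
#' @examples
#' break_even(default_parameters(), "mdTimeB")  # approx 7.82 minutes
break_even <- function(params, parameter, convention = "sequential") {
  validate_parameters(params)
  rng <- parameter_range(params, parameter)
  lo <- rng[["low"]]; ctr <- rng[["central"]]; hi <- rng[["high"]]

  ext_lo <- ctr - 10 * (ctr - lo)
  ext_hi <- ctr + 10 * (hi - ctr)
  if (parameter %in% .prob_param) {
    ext_lo <- max(ext_lo, 0); ext_hi <- min(ext_hi, 1)
  } else if (parameter %in% names(.wage_param)) {
    ext_lo <- max(ext_lo, 1e-9)
  } else {
    ext_lo <- max(ext_lo, 0)
  }

  f <- function(t) .diff_at(params, convention, parameter, t)[["diff"]]
  f_lo <- f(ext_lo)
  f_hi <- f(ext_hi)

  if (isTRUE(all.equal(f_lo, f_hi, tolerance = 1e-12)) ||
      ext_hi - ext_lo < 1e-12) {
    # Flat difference: a break-even exists everywhere or nowhere.
    if (abs(f_lo) < 1e-9) return(ctr)
    return(NA_real_)
  }

  slope <- (f_hi - f_lo) / (ext_hi - ext_lo)
  root <- ext_lo - f_lo / slope
  if (root < ext_lo || root > ext_hi) {
    return(NA_real_)
  }
  if (f_lo * f_hi < 0) {
    numeric_root <- stats::uniroot(f, c(ext_lo, ext_hi), tol = 1e-10)$root
    if (abs(numeric_root - root) > 1e-6) {
      stop(sprintf(
        "break_even: analytic root %.8f disagrees with numeric root %.8f",
        root, numeric_root), call. = FALSE)
    }
  }
  root
}

#' Convenience tornado plot
#'
#' Horizontal bar chart of the one-way excursions of the savings `A - B`
#' about the base case, in tornado order. Purely presentational; the data
#' surface is [tornado()].
#'
#' @param params A `cvc_parameters` object.
#' @param ... Passed to [tornado()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(params, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_tornado() requires the ggplot2 package", call. = FALSE)
  }
  tor <- tornado(params, ...)
  base <- incremental_result(params)$absoluteSavings
  tor$parameter <- factor(tor$parameter, levels = rev(tor$parameter))
  ggplot2::ggplot(tor) +
    ggplot2::geom_segment(ggplot2::aes(
      x = .data$diff_low, xend = .data$diff_high,
      y = .data$parameter, yend = .data$parameter), linewidth = 4) +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "red") +
    ggplot2::labs(x = "savings per patient, A - B ($)", y = NULL,
                  title = "One-way sensitivity of labor-cost savings")
}

# ggplot2 non-standard evaluation helper; only used when ggplot2 is present.
utils::globalVariables(".data")
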