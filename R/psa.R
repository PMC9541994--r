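# Probabilistic sensitivity analysis. The deterministic inputs carry ranges,
# not distributions, so the Monte-Carlo layer assigns each parameter a
# sampling family: triangular(low, central, high) for task times and
# complication probabilities (mode at the central estimate, bounded support),
# uniform(low, high) for wage rates (the range endpoints are salary
# percentiles, carrying no mode information). All families are overridable.

#' Sampling distribution for one model parameter
#'
#' @param parameter One of [parameter_labels()].
#' @param family `"triangular"` (needs `low <= mode <= high`), `"uniform"`
#'   (needs `low <= high`), or `"fixed"` (degenerate at `mode`).
#' @param low,mode,high Support, in the parameter's own units. `mode` doubles
#'   as the point value for `"fixed"`; bounds are ignored there.
#' @return A `cvc_dist_spec` object.
#' @export
dist_spec <- function(parameter, family = c("triangular", "uniform", "fixed"),
                      low = NA_real_, mode = NA_real_, high = NA_real_) {
  family <- match.arg(family)
  if (family == "fixed") {
    if (!is.finite(mode)) {
      stop(sprintf("dist_spec '%s': fixed family needs a finite mode",
                   parameter), call. = FALSE)
    }
  } else {
    if (!is.finite(low) || !is.finite(high) || low > high) {
      stop(sprintf("dist_spec '%s': support must satisfy low <= high",
                   parameter), call. = FALSE)
    }
    if (family == "triangular" &&
        (!is.finite(mode) || mode < low || mode > high)) {
      stop(sprintf("dist_spec '%s': triangular mode must lie in [low, high]",
                   parameter), call. = FALSE)
    }
  }
  structure(list(parameter = parameter, family = family,
                 low = low, mode = mode, high = high),
            class = "cvc_dist_spec")
}

#' Default sampling specification for every varying parameter
#'
#' Triangular over (low, central, high) for the five task times and the two
#' complication probabilities; uniform over (low, high) for the four wage
#' rates.
#'
#' @param params A `cvc_parameters` object supplying the supports.
#' @return Named list of `cvc_dist_spec`, one per [parameter_labels()] entry.
#' @export
default_psa_specs <- function(params = default_parameters()) {
  specs <- lapply(parameter_labels(), function(label) {
    rng <- parameter_range(params, label)
    fam <- if (label %in% names(.wage_param)) "uniform" else "triangular"
    dist_spec(label, fam, low = rng[["low"]], mode = rng[["central"]],
              high = rng[["high"]])
  })
  names(specs) <- parameter_labels()
  specs
}

# Inverse-CDF triangular quantile; no installed package provides one.
.qtriangular <- function(p, low, mode, high) {
  if (high == low) return(rep(low, length(p)))
  fc <- (mode - low) / (high - low)
  ifelse(p < fc,
         low + sqrt(p * (high - low) * (mode - low)),
         high - sqrt((1 - p) * (high - low) * (high - mode)))
}

.draw_spec <- function(spec, n) {
  switch(spec$family,
    fixed      = rep(spec$mode, n),
    uniform    = stats::runif(n, spec$low, spec$high),
    triangular = .qtriangular(stats::runif(n), spec$low, spec$mode, spec$high)
  )
}

#' Sample parameter sets for probabilistic sensitivity analysis
#'
#' Draws are independent across parameters and across replicates, and
#' reproducible for a given `(specs, n, seed)`: parameters are sampled
#' one at a time in the order of `specs`, each as a block of `n` values.
#' Probability draws are truncated to \[0, 1\].
#'
#' @param specs Named list of [dist_spec()] objects (default:
#'   [default_psa_specs()]).
#' @param n Number of draws (`>= 1`).
#' @param seed Integer seed.
#' @param base Base `cvc_parameters` supplying everything the specs do not
#'   vary.
#' @return A `cvc_psa_draws` object: list of `n` `cvc_parameters`, with the
#'   draw matrix (`attr(, "draws")`, a data frame with one column per
#'   sampled parameter) and the seed attached as attributes.
#' @export
sample_parameters <- function(specs = default_psa_specs(), n = 10000,
                              seed = 20220915, base = default_parameters()) {
  stopifnot(n >= 1)
  validate_parameters(base)
  if (is.null(names(specs)) || any(!nzchar(names(specs)))) {
    names(specs) <- vapply(specs, `[[`, "", "parameter")
  }
  set.seed(seed)
  draws <- lapply(specs, function(spec) {
    x <- .draw_spec(spec, n)
    if (spec$parameter %in% .prob_param) x <- pmin(pmax(x, 0), 1)
    x
  })
  draws <- as.data.frame(draws, optional = TRUE)
  param_sets <- lapply(seq_len(n), function(i) {
    p <- base
    for (label in names(draws)) {
      p <- set_parameter(p, label, draws[[label]][i])
    }
    p
  })
  structure(param_sets, class = "cvc_psa_draws",
            draws = draws, seed = seed)
}

#' Run a Monte-Carlo probabilistic sensitivity analysis
#'
#' Evaluates the full cost model on every sampled parameter set and
#' summarizes the distribution of the incremental cost `A - B`.
#'
#' @param draws A `cvc_psa_draws` object from [sample_parameters()], or a
#'   plain list of `cvc_parameters`.
#' @inheritParams cost_protocol_B
#' @return A `cvc_psa_summary`: `nDraws`, `seed` (if known), `meanDiff`,
#'   `intervalDiff` (2.5th and 97.5th percentiles of `A - B`),
#'   `probBcheaper` (fraction of draws with `A - B > 0`), and the per-draw
#'   `results` data frame (`index`, sampled parameter values, `costA`,
#'   `costB`, `diff`).
#' @export
run_psa <- function(draws, convention = "sequential") {
  stopifnot(length(draws) >= 1)
  convention <- .match_convention(convention)
  per_draw <- vapply(draws, .totals_unchecked, numeric(3),
                     convention = convention)
  results <- data.frame(index = seq_along(draws),
                        costA = per_draw[1, ], costB = per_draw[2, ],
                        diff = per_draw[3, ])
  draw_values <- attr(draws, "draws")
  if (!is.null(draw_values)) {
    results <- cbind(results[, "index", drop = FALSE], draw_values,
                     results[, c("costA", "costB", "diff")])
  }
  q <- stats::quantile(results$diff, c(0.025, 0.975), names = FALSE)
  structure(list(
    nDraws = nrow(results),
    seed = attr(draws, "seed"),
    meanDiff = mean(results$diff),
    intervalDiff = c(lower = q[1], upper = q[2]),
    probBcheaper = mean(results$diff > 0),
    results = results
  ), class = "cvc_psa_summary")
}

#' @export
print.cvc_psa_summary <- function(x, ...) {
  cat(sprintf("PSA over %d draws%s\n", x$nDraws,
              if (!is.null(x$seed)) sprintf(" (seed %d)", x$seed) else ""))
  cat(sprintf("  mean savings A - B: $%.2f  [95%% interval $%.2f, $%.2f]\n",
              x$meanDiff, x$intervalDiff[["lower"]],
              x$intervalDiff[["upper"]]))
  cat(sprintf("  P(ultrasound protocol cheaper): %.3f\n", x$probBcheaper))
  invisible(x)
}
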