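# Closed-form per-patient cost equations.
#
# Protocol A (radiograph): technician acquires a portable CXR, the bedside
# physician reviews it, a radiologist interprets it. Three labor lines.
# Protocol B (ultrasound): the bedside physician performs the three-step
# ultrasound confirmation assisted by a nurse; a suspected malposition or
# pneumothorax diverts the patient to the full protocol-A pathway, so the
# expected cost adds probability-weighted protocol-A cost on top of the base
# lines. All arithmetic is carried at full floating precision; rounding to
# cents/dollars happens only in the reporting layer.

#' Labor cost of a single task
#'
#' @param minutes Task duration in minutes (`>= 0`).
#' @param wage Wage rate in dollars per minute (`> 0`).
#' @return `minutes * wage` in dollars, full precision.
#' @export
#' @examples
#' line_cost(15, 0.51)  # technician acquiring a portable radiograph: $7.65
line_cost <- function(minutes, wage) {
  if (!is.numeric(minutes) || any(minutes < 0)) {
    stop("invalid 'minutes': must be nonnegative", call. = FALSE)
  }
  if (!is.numeric(wage) || any(wage <= 0)) {
    stop("invalid 'wage': must be positive", call. = FALSE)
  }
  minutes * wage
}

.cost_line <- function(description, role, minutes, wage) {
  data.frame(description = description, role = role, minutes = minutes,
             wagePerMinute = wage, cost = line_cost(minutes, wage),
             stringsAsFactors = FALSE)
}

.new_breakdown <- function(protocol, lines, div_mal = 0, div_ptx = 0) {
  structure(list(
    protocol = protocol,
    lines = lines,
    diversionMalposition = div_mal,
    diversionPneumothorax = div_ptx,
    total = sum(lines$cost) + div_mal + div_ptx
  ), class = "cvc_cost_breakdown")
}

#' Per-patient labor cost of protocol A (radiograph confirmation)
#'
#' Three labor lines: radiograph acquisition by the radiology technician,
#' image review by the bedside physician, and interpretation by the
#' radiologist. No diversion terms.
#'
#' @param params A `cvc_parameters` object.
#' @return A `cvc_cost_breakdown`: line items, zero diversion fields, and the
#'   full-precision total.
#' @export
#' @examples
#' cost_protocol_A(default_parameters())$total  # 18.48 at central inputs
cost_protocol_A <- function(params) {
  validate_parameters(params)
  .cost_A_unchecked(params)
}

.cost_A_unchecked <- function(params) {
  lines <- rbind(
    .cost_line("CXR by radiology technician", "radiology-technician",
               .time(params, "techTimeA"),
               .wage(params, "radiology-technician")),
    .cost_line("CXR review by bedside MD", "bedside-physician",
               .time(params, "mdTimeA"), .wage(params, "bedside-physician")),
    .cost_line("CXR review by radiologist", "radiologist",
               .time(params, "radiologistRead"), .wage(params, "radiologist"))
  )
  .new_breakdown("A", lines)
}

.match_convention <- function(convention) {
  match.arg(convention, c("sequential", "additive"))
}

#' Per-patient expected labor cost of protocol B (ultrasound confirmation)
#'
#' Two base labor lines (bedside physician performing the three-step
#' ultrasound protocol, nurse assisting) plus expected diversion costs: a
#' patient with a suspected complication on ultrasound goes on to the full
#' protocol-A pathway, incurring its entire cost in addition to the
#' already-spent ultrasound time.
#'
#' Two conventions govern how the two complication probabilities combine.
#' Under `"sequential"` (the default) pneumothorax is only reached when no
#' malposition was seen, so its weight is `(1 - pMal) * pPtx`; under
#' `"additive"` the two probabilities are simply summed. The sequential
#' diversion cost is never larger than the additive one.
#'
#' @param params A `cvc_parameters` object.
#' @param convention `"sequential"` or `"additive"`.
#' @return A `cvc_cost_breakdown` with two line items and the two diversion
#'   dollar terms.
#' @export
#' @examples
#' cost_protocol_B(default_parameters())$total  # 14.6621 -> $14.66
cost_protocol_B <- function(params, convention = "sequential") {
  validate_parameters(params)
  .cost_B_unchecked(params, .match_convention(convention))
}

.cost_B_unchecked <- function(params, convention) {
  a_total <- .cost_A_unchecked(params)$total
  p_mal <- .prob(params, "pMalposition")
  p_ptx <- .prob(params, "pPneumothorax")
  if (convention == "additive" && p_mal + p_ptx > 1) {
    stop("additive convention needs pMalposition + pPneumothorax <= 1",
         call. = FALSE)
  }
  lines <- rbind(
    .cost_line("POCUS confirmation by bedside MD", "bedside-physician",
               .time(params, "mdTimeB"), .wage(params, "bedside-physician")),
    .cost_line("POCUS confirmation assisted by bedside RN", "registered-nurse",
               .time(params, "rnTimeB"), .wage(params, "registered-nurse"))
  )
  div_mal <- p_mal * a_total
  div_ptx <- switch(convention,
    sequential = (1 - p_mal) * p_ptx * a_total,
    additive   = p_ptx * a_total
  )
  .new_breakdown("B", lines, div_mal, div_ptx)
}

#' Incremental cost of switching from radiograph to ultrasound confirmation
#'
#' @inheritParams cost_protocol_B
#' @return A `cvc_incremental` list: `costA`, `costB`, `absoluteSavings`
#'   (`costA - costB`), and `relativeSavings` (`absoluteSavings / costA`), all
#'   at full precision. Display rounding is the reporting layer's job.
#' @export
#' @examples
#' r <- incremental_result(default_parameters())
#' round(r$absoluteSavings, 2)        # 3.82
#' round(100 * r$relativeSavings)     # 21
incremental_result <- function(params, convention = "sequential") {
  validate_parameters(params)
  .incremental_unchecked(params, .match_convention(convention))
}

.incremental_unchecked <- function(params, convention) {
  costA <- .cost_A_unchecked(params)$total
  costB <- .cost_B_unchecked(params, convention)$total
  structure(list(
    costA = costA,
    costB = costB,
    absoluteSavings = costA - costB,
    relativeSavings = (costA - costB) / costA
  ), class = "cvc_incremental")
}

# Totals-only evaluator for the sensitivity/Monte-Carlo hot paths: same
# arithmetic as the breakdown builders, without itemized data frames. The
# suite pins its agreement with the breakdown route and the tree rollback.
.totals_unchecked <- function(params, convention) {
  costA <- .time(params, "techTimeA") * .wage(params, "radiology-technician") +
    .time(params, "mdTimeA") * .wage(params, "bedside-physician") +
    .time(params, "radiologistRead") * .wage(params, "radiologist")
  base_b <- .time(params, "mdTimeB") * .wage(params, "bedside-physician") +
    .time(params, "rnTimeB") * .wage(params, "registered-nurse")
  p_mal <- .prob(params, "pMalposition")
  p_ptx <- .prob(params, "pPneumothorax")
  if (convention == "additive" && p_mal + p_ptx > 1) {
    stop("additive convention needs pMalposition + pPneumothorax <= 1",
         call. = FALSE)
  }
  p_div <- switch(convention,
    sequential = p_mal + (1 - p_mal) * p_ptx,
    additive   = p_mal + p_ptx
  )
  costB <- base_b + p_div * costA
  c(costA = costA, costB = costB, diff = costA - costB)
}

#' Probability that a protocol-B patient is diverted to radiograph
#'
#' @param params A `cvc_parameters` object (central probabilities are used).
#' @inheritParams cost_protocol_B
#' @return The diversion probability: `pMal + pPtx` under the additive
#'   convention, `pMal + (1 - pMal) * pPtx` under the sequential one.
#' @export
#' @examples
#' diversion_probability(default_parameters(), "additive")    # 0.079
#' diversion_probability(default_parameters(), "sequential")  # 0.078252
diversion_probability <- function(params, convention = "sequential") {
  convention <- .match_convention(convention)
  p_mal <- .prob(params, "pMalposition")
  p_ptx <- .prob(params, "pPneumothorax")
  switch(convention,
    additive   = p_mal + p_ptx,
    sequential = p_mal + (1 - p_mal) * p_ptx
  )
}

#' Scale a per-patient cost to a patient population
#'
#' The per-patient cost must be the full-precision value, not a cent-rounded
#' display value: hospital- and national-scale figures only reconcile when
#' rounding happens after multiplication.
#'
#' @param per_patient Per-patient cost in dollars (full precision).
#' @param n Number of patients (`>= 0`).
#' @return `per_patient * n`, full precision.
#' @export
#' @examples
#' scale_to_population(cost_protocol_A(default_parameters())$total, 2045)
scale_to_population <- function(per_patient, n) {
  if (!is.numeric(n) || any(n < 0)) {
    stop("invalid 'n': must be a nonnegative count", call. = FALSE)
  }
  per_patient * n
}

#' @export
print.cvc_cost_breakdown <- function(x, ...) {
  cat(sprintf("Protocol %s labor cost per patient\n", x$protocol))
  for (i in seq_len(nrow(x$lines))) {
    ln <- x$lines[i, ]
    cat(sprintf("  %-42s %4.1f min x $%.2f/min = $%.2f\n",
                ln$description, ln$minutes, ln$wagePerMinute,
                round(ln$cost, 2)))
  }
  if (x$protocol == "B") {
    cat(sprintf("  %-42s $%.2f\n", "Diversion to CXR (malposition)",
                round(x$diversionMalposition, 2)))
    cat(sprintf("  %-42s $%.2f\n", "Diversion to CXR (pneumothorax)",
                round(x$diversionPneumothorax, 2)))
  }
  cat(sprintf("  Total: $%.2f\n", round(x$total, 2)))
  invisible(x)
}

#' @export
print.cvc_incremental <- function(x, ...) {
  cat(sprintf("Protocol A $%.2f vs protocol B $%.2f per patient\n",
              round(x$costA, 2), round(x$costB, 2)))
  cat(sprintf("Savings from switching to ultrasound: $%.2f (%d%%)\n",
              round(x$absoluteSavings, 2), round(100 * x$relativeSavings)))
  invisible(x)
}
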