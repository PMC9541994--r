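# Explicit decision-tree representation of the two confirmation strategies,
# evaluated by standard expected-value rollback. The tree route must agree
# with the closed-form cost equations to numerical precision; the test suite
# enforces this over randomized parameter sets.

#' Terminal (payoff) node of a decision tree
#'
#' @param name Node label.
#' @param payoff Payoff in dollars.
#' @return A `cvc_tree_node` of kind `"terminal"`.
#' @export
terminal_node <- function(name, payoff) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(payoff), length(payoff) == 1L, is.finite(payoff))
  structure(list(kind = "terminal", name = name, payoff = payoff),
            class = "cvc_tree_node")
}

#' Chance node of a decision tree
#'
#' @param name Node label.
#' @param probs Branch probabilities; must lie in \[0, 1\] and sum to 1
#'   within `1e-9` (checked again at rollback).
#' @param children List of child `cvc_tree_node`s, one per probability.
#' @return A `cvc_tree_node` of kind `"chance"`.
#' @export
chance_node <- function(name, probs, children) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(probs), length(probs) == length(children))
  if (any(probs < 0 | probs > 1)) {
    stop(sprintf("chance node '%s': branch probabilities must lie in [0, 1]",
                 name), call. = FALSE)
  }
  structure(list(kind = "chance", name = name, probs = probs,
                 children = children),
            class = "cvc_tree_node")
}

#' Build the two-strategy decision tree
#'
#' Protocol A is a terminal payoff (its cost has no chance structure in this
#' model). Protocol B is a chance node with three paths: no complication
#' suspected (base ultrasound cost), suspected malposition, and suspected
#' pneumothorax (each: base cost plus the full protocol-A cost for the
#' diverted confirmation). Path probabilities follow the chosen diversion
#' convention and sum to 1.
#'
#' @inheritParams cost_protocol_B
#' @return A `cvc_decision_tree`: list with `cvc_tree_node` elements
#'   `protocolA` and `protocolB` and a `convention` attribute.
#' @seealso [rollback()]
#' @export
build_decision_tree <- function(params, convention = "sequential") {
  validate_parameters(params)
  convention <- .match_convention(convention)
  a_total <- cost_protocol_A(params)$total
  b_base <- line_cost(.time(params, "mdTimeB"),
                      .wage(params, "bedside-physician")) +
            line_cost(.time(params, "rnTimeB"),
                      .wage(params, "registered-nurse"))
  p_mal <- .prob(params, "pMalposition")
  p_ptx <- .prob(params, "pPneumothorax")
  p_path_mal <- p_mal
  p_path_ptx <- switch(convention,
    sequential = (1 - p_mal) * p_ptx,
    additive   = p_ptx
  )
  p_none <- 1 - p_path_mal - p_path_ptx
  if (p_none < 0) {
    stop("complication probabilities leave a negative no-complication path",
         call. = FALSE)
  }
  tree <- list(
    protocolA = terminal_node("CXR confirmation", a_total),
    protocolB = chance_node(
      "POCUS confirmation", c(p_none, p_path_mal, p_path_ptx),
      list(
        terminal_node("no complication suspected", b_base),
        terminal_node("malposition suspected, diverted to CXR",
                      b_base + a_total),
        terminal_node("pneumothorax suspected, diverted to CXR",
                      b_base + a_total)
      )
    )
  )
  structure(tree, class = "cvc_decision_tree", convention = convention)
}

#' Expected-value rollback of a decision tree
#'
#' Terminal nodes return their payoff; chance nodes return the
#' probability-weighted sum of their children's rollback values. Applied to a
#' whole `cvc_decision_tree` it returns the expected cost of each strategy.
#'
#' @param tree A `cvc_tree_node` or `cvc_decision_tree`.
#' @return Dollars: a scalar for a node, or a named vector
#'   `c(protocolA, protocolB)` for a full tree.
#' @export
#' @examples
#' tr <- build_decision_tree(default_parameters())
#' rollback(tr)               # expected costs of both strategies
#' rollback(tr$protocolB)     # just the ultrasound arm
rollback <- function(tree) {
  UseMethod("rollback")
}

#' @export
rollback.cvc_decision_tree <- function(tree) {
  c(protocolA = rollback(tree$protocolA),
    protocolB = rollback(tree$protocolB))
}

#' @export
rollback.cvc_tree_node <- function(tree) {
  if (tree$kind == "terminal") {
    return(tree$payoff)
  }
  if (abs(sum(tree$probs) - 1) > 1e-9) {
    stop(sprintf("chance node '%s': branch probabilities sum to %.12f, not 1",
                 tree$name, sum(tree$probs)), call. = FALSE)
  }
  sum(tree$probs * vapply(tree$children, rollback, numeric(1)))
}

#' @export
print.cvc_decision_tree <- function(x, ...) {
  cat(sprintf("CVC confirmation decision tree (%s diversion convention)\n",
              attr(x, "convention")))
  ev <- rollback(x)
  cat(sprintf("  protocol A (CXR):   expected cost $%.4f\n", ev[["protocolA"]]))
  cat(sprintf("  protocol B (POCUS): expected cost $%.4f, %d chance paths\n",
              ev[["protocolB"]], length(x$protocolB$children)))
  invisible(x)
}
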