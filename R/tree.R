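# Generic decision-tree machinery: chance and terminal nodes, structural
# validation, expected-value rollback over (cost, QALY) payoff pairs.

PROB_TOL <- 1e-9

#' Decision-tree nodes
#'
#' A tree is built from two node kinds. A chance node carries at least two
#' branches whose probabilities must each lie in \[0, 1\] and sum to 1 within
#' `1e-9` (no silent renormalization: an off-by-rounding config is an error,
#' not something to paper over). A terminal node carries a `(cost, qaly)`
#' payoff pair and optional metadata used by the microsimulation.
#'
#' @param label Node label; terminal labels key the audit of expected patient
#'   counts in [rollback()].
#' @param probs Numeric vector of branch probabilities.
#' @param children List of child nodes, same length as `probs`.
#' @param cost,qaly Terminal payoff pair.
#' @param info Optional named list of metadata attached to a terminal (the
#'   arm builders store route descriptors here).
#' @return An object of class `tree_node`.
#' @export
#' @examples
#' tree <- chance_node("toss", c(0.5, 0.5), list(
#'   terminal_node("heads", cost = 0, qaly = 0),
#'   terminal_node("tails", cost = 200, qaly = 2)))
#' rollback(tree, cohort_size = 1)
chance_node <- function(label, probs, children) {
  structure(list(kind = "chance", label = label, probs = probs,
                 children = children),
            class = "tree_node")
}

#' @rdname chance_node
#' @export
terminal_node <- function(label, cost, qaly, info = list()) {
  structure(list(kind = "terminal", label = label,
                 payoff = c(cost = cost, qaly = qaly), info = info),
            class = "tree_node")
}

#' Structural validation of a decision tree
#'
#' Returns findings as data rather than raising: one entry per violated
#' invariant, prefixed with the slash-separated node path.
#'
#' @param root A [chance_node()] or [terminal_node()].
#' @return Character vector of findings; empty iff the tree is well formed.
#' @export
validate_tree <- function(root) {
  walk <- function(node, path) {
    f <- character(0)
    here <- paste(c(path, node$label), collapse = "/")
    if (!inherits(node, "tree_node") ||
        !node$kind %in% c("chance", "terminal"))
      return(sprintf("%s: not a tree node", here))
    if (node$kind == "terminal") {
      if (!is.null(node$children) && length(node$children) > 0)
        f <- c(f, sprintf("%s: terminal node has children", here))
      if (!is.numeric(node$payoff) || length(node$payoff) != 2L ||
          any(!is.finite(node$payoff)))
        f <- c(f, sprintf("%s: terminal payoff must be finite (cost, qaly)", here))
      return(f)
    }
    if (length(node$children) < 2L)
      f <- c(f, sprintf("%s: chance node needs >= 2 branches", here))
    if (length(node$probs) != length(node$children))
      f <- c(f, sprintf("%s: %d probabilities for %d branches", here,
                        length(node$probs), length(node$children)))
    if (any(node$probs < -PROB_TOL) || any(node$probs > 1 + PROB_TOL))
      f <- c(f, sprintf("%s: branch probability outside [0, 1]", here))
    if (abs(sum(node$probs) - 1) > PROB_TOL)
      f <- c(f, sprintf("%s: probabilities sum to %.10g", here,
                        sum(node$probs)))
    for (ch in node$children) f <- c(f, walk(ch, c(path, node$label)))
    f
  }
  walk(root, character(0))
}

#' Expected-value rollback of a decision tree
#'
#' Standard backward induction: the expected (cost, QALY) of a chance node is
#' the probability-weighted sum over its branches. Expected terminal patient
#' counts ("terminal masses") are recorded for auditing; they sum to the
#' cohort size by construction.
#'
#' @param root A validated tree (structural findings raise an error).
#' @param cohort_size Number of patients entering at the root.
#' @return An object of class `arm_outcome` with elements `expected_cost`,
#'   `expected_qaly` (cohort totals), `per_patient_cost`, `per_patient_qaly`,
#'   `terminal_masses` (named expected counts) and `cohort_size`.
#' @export
rollback <- function(root, cohort_size) {
  f <- validate_tree(root)
  if (length(f) > 0)
    stop("invalid tree:\n  ", paste(f, collapse = "\n  "), call. = FALSE)
  masses <- new.env(parent = emptyenv())
  ev <- function(node, w) {
    if (node$kind == "terminal") {
      prev <- get0(node$label, envir = masses, ifnotfound = 0)
      assign(node$label, prev + w, envir = masses)
      return(node$payoff)
    }
    acc <- c(cost = 0, qaly = 0)
    for (i in seq_along(node$children))
      acc <- acc + node$probs[i] * ev(node$children[[i]], w * node$probs[i])
    acc
  }
  pp <- ev(root, 1)
  tm <- unlist(as.list(masses)) * cohort_size
  arm_outcome(expected_cost = unname(pp["cost"]) * cohort_size,
              expected_qaly = unname(pp["qaly"]) * cohort_size,
              per_patient_cost = unname(pp["cost"]),
              per_patient_qaly = unname(pp["qaly"]),
              terminal_masses = tm, cohort_size = cohort_size)
}

arm_outcome <- function(expected_cost, expected_qaly, per_patient_cost,
                        per_patient_qaly, terminal_masses, cohort_size) {
  structure(list(expected_cost = expected_cost, expected_qaly = expected_qaly,
                 per_patient_cost = per_patient_cost,
                 per_patient_qaly = per_patient_qaly,
                 terminal_masses = terminal_masses,
                 cohort_size = cohort_size),
            class = "arm_outcome")
}

#' Enumerate the terminal leaves of a tree
#'
#' Each leaf is returned with its total root-to-leaf probability, payoff and
#' metadata. This is the distribution the microsimulation samples from.
#'
#' @param root A tree node.
#' @return A list of lists with elements `label`, `prob`, `cost`, `qaly`,
#'   `info`.
#' @export
tree_leaves <- function(root) {
  out <- list()
  walk <- function(node, p) {
    if (node$kind == "terminal") {
      out[[length(out) + 1L]] <<- list(
        label = node$label, prob = p,
        cost = unname(node$payoff["cost"]),
        qaly = unname(node$payoff["qaly"]), info = node$info)
      return(invisible())
    }
    for (i in seq_along(node$children))
      walk(node$children[[i]], p * node$probs[i])
  }
  walk(root, 1)
  out
}

#' Serialize a tree to plain nested lists
#'
#' For inspection and golden-file tests; the output survives YAML/JSON
#' round-trips.
#'
#' @param node A tree node.
#' @return A nested plain list.
#' @export
tree_to_list <- function(node) {
  if (node$kind == "terminal")
    return(list(kind = "terminal", label = node$label,
                cost = unname(node$payoff["cost"]),
                qaly = unname(node$payoff["qaly"])))
  list(kind = "chance", label = node$label,
       branches = lapply(seq_along(node$children), function(i)
         list(prob = node$probs[i],
              node = tree_to_list(node$children[[i]]))))
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome> N = %g\n", x$cohort_size))
  cat(sprintf("  expected cost: %.2f (%.4f per patient)\n",
              x$expected_cost, x$per_patient_cost))
  cat(sprintf("  expected QALY: %.4f (%.6f per patient)\n",
              x$expected_qaly, x$per_patient_qaly))
  cat("  terminal masses:\n")
  for (nm in sort(names(x$terminal_masses)))
    cat(sprintf("    %-28s %12.3f\n", nm, x$terminal_masses[[nm]]))
  invisible(x)
}

#' @export
print.tree_node <- function(x, ...) {
  show <- function(node, indent, p) {
    pre <- strrep("  ", indent)
    if (node$kind == "terminal") {
      cat(sprintf("%s- %s [p=%.6g] cost=%.2f qaly=%.4f\n", pre, node$label, p,
                  node$payoff["cost"], node$payoff["qaly"]))
    } else {
      cat(sprintf("%s+ %s\n", pre, node$label))
      for (i in seq_along(node$children))
        show(node$children[[i]], indent + 1L, node$probs[i])
    }
  }
  show(x, 0L, 1)
  invisible(x)
}
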