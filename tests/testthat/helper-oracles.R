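# Independent oracles used across the suite. These deliberately do not share
# code paths with the package internals they check.

# Brute-force expected value by exhaustive root-to-leaf path enumeration.
enumerate_expectation <- function(root) {
  paths <- list()
  stack <- list(list(node = root, prob = 1))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    if (node$kind == "terminal") {
      paths[[length(paths) + 1L]] <- c(prob = top$prob,
                                       cost = unname(node$payoff["cost"]),
                                       qaly = unname(node$payoff["qaly"]))
    } else {
      for (i in seq_along(node$children))
        stack[[length(stack) + 1L]] <- list(node = node$children[[i]],
                                            prob = top$prob * node$probs[i])
    }
  }
  m <- do.call(rbind, paths)
  c(cost = sum(m[, "prob"] * m[, "cost"]),
    qaly = sum(m[, "prob"] * m[, "qaly"]),
    mass = sum(m[, "prob"]))
}

# Random well-formed tree of depth <= max_depth.
random_tree <- function(max_depth, p_chance = 0.7, id = new.env()) {
  if (is.null(id$n)) id$n <- 0L
  id$n <- id$n + 1L
  lbl <- paste0("n", id$n)
  if (max_depth == 0 || stats::runif(1) > p_chance)
    return(terminal_node(lbl, cost = stats::runif(1, 0, 1000),
                         qaly = stats::runif(1, 0, 2)))
  k <- sample(2:4, 1)
  w <- stats::runif(k)
  chance_node(lbl, w / sum(w),
              lapply(seq_len(k), function(i)
                random_tree(max_depth - 1, p_chance, id)))
}

# Random valid parameter set spanning both care settings and countries.
random_params <- function() {
  scenario <- sample(c("primary", "secondary"), 1)
  country <- sample(c("UK", "USA"), 1)
  p <- default_parameters(scenario, country,
                          test_cost = stats::runif(1, 20, 200))
  p$test$sensitivity <- stats::runif(1, 0.6, 0.99)
  p$test$specificity <- stats::runif(1, 0.6, 0.99)
  p$cohort$prevalence <- stats::runif(1, 0.002, 0.1)
  p$pathway$p_image_after_negative <-
    if (scenario == "primary") stats::runif(1, 0.2, 1) else 1
  p$outcomes$qaly_gain_per_true_positive <- stats::runif(1, 0, 0.5)
  p$outcomes$avoided_cost_per_skipped_workup <- stats::runif(1, 0, 150)
  p$outcomes$monitoring_cost_per_true_positive <-
    if (stats::runif(1) < 0.5) stats::runif(1, 0, 200) else NULL
  validate_parameters(p)
  p
}

# Independently coded patient sampler: a direct Bernoulli chain
# (disease -> test result -> imaging decision), not the tree's leaf
# distribution. Payoffs are looked up from terminal_payoff().
flat_simulate <- function(params, with_test, seed) {
  set.seed(seed)
  n <- params$cohort$size
  diseased <- stats::runif(n) < params$cohort$prevalence
  if (!with_test) {
    routes <- ifelse(diseased, "diseased_standard", "well_standard")
  } else {
    positive <- logical(n)
    positive[diseased] <- stats::runif(sum(diseased)) < params$test$sensitivity
    positive[!diseased] <- stats::runif(sum(!diseased)) >
      params$test$specificity
    imaged <- stats::runif(n) < params$pathway$p_image_after_negative
    routes <- character(n)
    routes[diseased & positive] <- "tp_fast_track"
    routes[diseased & !positive & imaged] <- "fn_imaging"
    routes[diseased & !positive & !imaged] <- "fn_no_imaging"
    routes[!diseased & positive] <- "fp_fast_track"
    routes[!diseased & !positive & imaged] <- "tn_imaging"
    routes[!diseased & !positive & !imaged] <- "tn_no_imaging"
  }
  payoff_for <- function(label) {
    rs <- switch(label,
      diseased_standard = route_spec("diseased_standard", "D2", 1, TRUE, FALSE),
      well_standard = route_spec("well_standard", "D2", 1, FALSE, FALSE),
      tp_fast_track = route_spec("tp_fast_track", "D1", 1, TRUE, TRUE,
                                 "positive", fast_track = TRUE,
                                 extra_monitoring = TRUE),
      fn_imaging = route_spec("fn_imaging", "D2", 1, TRUE, TRUE, "negative"),
      fn_no_imaging = route_spec("fn_no_imaging", "none", 0, TRUE, TRUE,
                                 "negative", skipped_workup = TRUE),
      fp_fast_track = route_spec("fp_fast_track", "D1", 1, FALSE, TRUE,
                                 "positive", fast_track = TRUE),
      tn_imaging = route_spec("tn_imaging", "D2", 1, FALSE, TRUE, "negative"),
      tn_no_imaging = route_spec("tn_no_imaging", "none", 0, FALSE, TRUE,
                                 "negative", skipped_workup = TRUE))
    terminal_payoff(rs, params)
  }
  pays <- lapply(setNames(nm = unique(routes)), payoff_for)
  data.frame(
    diseased = diseased, route = routes,
    cost = vapply(routes, function(r) pays[[r]]$cost, numeric(1)),
    qaly = vapply(routes, function(r) pays[[r]]$qaly, numeric(1)),
    row.names = NULL)
}
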