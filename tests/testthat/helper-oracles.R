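# Independent oracles used across the suite.

# Exhaustive path-enumeration oracle for the tree engine: recursively
# enumerates every outcome path (drop-out before a stage, diagnosed at a
# stage, continue undiagnosed) and probability-weights the discounted
# cost and yield along each path. Structured deliberately differently
# from the sequential reach-probability walk it checks.
oracle_evaluate <- function(strat, tests, rate) {
  rec <- function(i, prob, cost_so_far) {
    if (i > length(strat$stages)) {
      return(c(cost = prob * cost_so_far, yield = 0))
    }
    sg <- strat$stages[[i]]
    y <- tests[[sg$test]]$yields[[sg$context]]$mean
    cst <- tests[[sg$test]]$cost$mean + (sg$extra_cost %||% 0)
    df <- (1 + rate)^-(sg$year - 1)
    p <- sg$proceed_prob %||% 1
    drop_out <- c(prob * (1 - p) * cost_so_far, 0)
    cost_here <- cost_so_far + cst * df
    diagnosed <- c(prob * p * y * cost_here, prob * p * y * df)
    continued <- rec(i + 1, prob * p * (1 - y), cost_here)
    drop_out + diagnosed + continued
  }
  out <- rec(1, 1, 0)
  list(cost = out[[1]], yield = out[[2]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact frontier oracle: strategy i lies on the efficiency frontier iff
# there is a WTP lambda >= 0 at which it is the strict NMB maximiser.
# The feasible lambda set is an interval obtained from pairwise
# comparisons; the frontier is exactly the set with a non-empty open
# interval (equivalently, i is not dominated by any convex combination
# of the others).
oracle_frontier <- function(cost, yield) {
  n <- length(cost)
  vapply(seq_len(n), function(i) {
    lo <- 0
    hi <- Inf
    for (j in setdiff(seq_len(n), i)) {
      dy <- yield[i] - yield[j]
      dc <- cost[i] - cost[j]
      if (dy > 0) {
        lo <- max(lo, dc / dy)
      } else if (dy < 0) {
        hi <- min(hi, dc / dy)
      } else if (dc >= 0) {
        return(FALSE) # same yield, not strictly cheaper
      }
    }
    lo < hi
  }, TRUE)
}

# Random strategy-level (cost, yield) sets for frontier properties.
random_results <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    strategy = sprintf("S%02d", seq_len(n)),
    cost = round(stats::runif(n, 100, 8000), 2),
    yield = round(stats::runif(n, 0.01, 0.95), 4)
  )
}

# Random small models with non-trivial proceed probabilities and extra
# stage costs, for engine equivalence checks.
random_model <- function(seed) {
  set.seed(seed)
  n_tests <- sample(2:4, 1)
  tests <- lapply(seq_len(n_tests), function(i) {
    cost <- stats::runif(1, 100, 5000)
    test_definition(
      id = sprintf("t%d", i), cost_mean = cost,
      cost_ci = cost * c(0.9, 1.1),
      yields = list(unconditional = list(
        mean = stats::runif(1, 0, 0.6),
        ci = c(0, 1)
      ))
    )
  })
  k <- sample(1:4, 1)
  horizon <- max(4L, k)
  strategies <- list(list(
    name = "S1",
    stages = lapply(seq_len(k), function(j) {
      stage(test = sprintf("t%d", sample(n_tests, 1)),
            context = "unconditional", year = j,
            proceed_prob = stats::runif(1, 0.5, 1),
            extra_cost = stats::runif(1, 0, 300))
    })
  ))
  cea_model(tests, strategies,
            settings = list(discount_rate = stats::runif(1, 0, 0.1),
                            horizon_years = horizon))
}
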