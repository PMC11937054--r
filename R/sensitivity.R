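## Deterministic sensitivity analysis: scenario tables and one-way
## threshold analysis at a stated willingness to pay.

#' Scenario re-analysis
#'
#' Applies a scenario's overrides, re-evaluates every strategy and
#' returns the incremental dominance table.
#'
#' @param model A `cea_model`.
#' @param scenario Scenario name or override list as in
#'   [apply_scenario()]; an empty list reproduces the base-case table.
#' @return A `cea_table` (see [dominance_table()]).
#' @export
run_scenario_table <- function(model, scenario = list()) {
  dominance_table(evaluate_model(apply_scenario(model, scenario)))
}

#' One-way threshold analysis at a willingness to pay
#'
#' Finds the value of a single numeric model input at which
#' `target_strategy` becomes (or ceases to be) the NMB-optimal strategy
#' at the stated WTP, holding everything else fixed. The gap
#' `NMB(target) - max(NMB(others))` is scanned across the search
#' bounds; a single sign change is refined by bisection. If the gap
#' never changes sign within the bounds the target is reported as
#' never optimal over that range.
#'
#' @param model A `cea_model`.
#' @param parameter_path Dot-path of the input to vary (a test cost
#'   mean or a context yield mean), see [get_parameter()].
#' @param target_strategy Strategy that should become optimal.
#' @param wtp Willingness to pay per additional diagnosis.
#' @param bounds Length-2 search interval in the parameter's units.
#'   Defaults to (0.01x, 100x) the current value for costs and (0, 1)
#'   for yields/probabilities.
#' @param tol Absolute bisection tolerance; defaults to 0.01 (costs)
#'   or 1e-6 (yields/probabilities).
#' @param n_scan Number of scan points used to locate sign changes and
#'   reject non-single-crossing gaps.
#' @param max_iter Maximum bisection iterations.
#' @return A `threshold_result` list: `parameter_path`, `wtp`,
#'   `threshold` (parameter value, or `NA` when never), `never`,
#'   `optimal_before`, `optimal_after`, `current` (the input's
#'   base value).
#' @examples
#' m <- canonical_model()
#' solve_threshold(m, "tests.gs.cost.mean", "1st-line GS", wtp = 8613)
#' @export
solve_threshold <- function(model, parameter_path, target_strategy, wtp,
                            bounds = NULL, tol = NULL, n_scan = 41L,
                            max_iter = 200L) {
  if (is.null(model$strategies[[target_strategy]])) {
    stop(sprintf("unknown strategy '%s'", target_strategy), call. = FALSE)
  }
  current <- get_parameter(model, parameter_path)
  if (length(current) != 1) {
    stop("threshold analysis requires a scalar parameter", call. = FALSE)
  }
  is_prob <- any(split_path(parameter_path) %in% c("yields", "proceed_prob"))
  if (is.null(bounds)) {
    bounds <- if (is_prob) c(0, 1) else c(0.01, 100) * current
  }
  if (length(bounds) != 2 || bounds[1] >= bounds[2]) {
    stop("`bounds` must be an increasing length-2 interval", call. = FALSE)
  }
  if (is.null(tol)) tol <- if (is_prob) 1e-6 else 0.01

  gap <- function(v) {
    res <- evaluate_model(set_parameter(model, parameter_path, v))
    b <- nmb(res$cost, res$yield, wtp)
    tgt <- res$strategy == target_strategy
    b[tgt] - max(b[!tgt])
  }

  optimal_before <- optimal_strategy(model, wtp)
  if (optimal_before == target_strategy) {
    return(structure(
      list(parameter_path = parameter_path, wtp = wtp, threshold = current,
           never = FALSE, optimal_before = optimal_before,
           optimal_after = optimal_before, current = current),
      class = "threshold_result"
    ))
  }

  grid <- seq(bounds[1], bounds[2], length.out = n_scan)
  # probabilities of exactly 0/1 are valid inputs; costs must stay > 0
  if (!is_prob) grid <- pmax(grid, tol)
  g <- vapply(grid, gap, 0)
  sgn <- sign(g)
  crossings <- which(sgn[-1] * sgn[-n_scan] < 0 |
                       (sgn[-n_scan] != 0 & sgn[-1] == 0))
  if (length(crossings) == 0) {
    if (all(g < 0)) {
      return(structure(
        list(parameter_path = parameter_path, wtp = wtp,
             threshold = NA_real_, never = TRUE,
             optimal_before = optimal_before,
             optimal_after = optimal_before, current = current),
        class = "threshold_result"
      ))
    }
    stop("NMB gap does not cross zero cleanly within `bounds`; ",
         "narrow the bounds", call. = FALSE)
  }
  if (length(crossings) > 1) {
    stop("NMB gap is not single-crossing over `bounds`; narrow the bounds",
         call. = FALSE)
  }

  lo <- grid[crossings]
  hi <- grid[crossings + 1L]
  g_lo <- g[crossings]
  it <- 0L
  while (hi - lo > tol) {
    it <- it + 1L
    if (it > max_iter) {
      stop("bisection failed to converge within `max_iter` iterations",
           call. = FALSE)
    }
    mid <- (lo + hi) / 2
    g_mid <- gap(mid)
    if (sign(g_mid) == sign(g_lo) && g_mid != 0) {
      lo <- mid
      g_lo <- g_mid
    } else {
      hi <- mid
    }
  }
  threshold <- (lo + hi) / 2
  # optimum just on the target's side of the root
  side <- if (gap(lo) > gap(hi)) lo else hi
  optimal_after <- optimal_strategy(
    set_parameter(model, parameter_path, side), wtp)

  structure(
    list(parameter_path = parameter_path, wtp = wtp, threshold = threshold,
         never = FALSE, optimal_before = optimal_before,
         optimal_after = optimal_after, current = current),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  if (x$never) {
    cat(sprintf("<threshold> %s: target never NMB-optimal over bounds (WTP %s)\n",
                x$parameter_path, format(x$wtp)))
  } else {
    cat(sprintf("<threshold> %s: %.6g (current %.6g, WTP %s); optimal %s -> %s\n",
                x$parameter_path, x$threshold, x$current, format(x$wtp),
                x$optimal_before, x$optimal_after))
  }
  invisible(x)
}
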