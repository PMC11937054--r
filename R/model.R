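#' gencea: cost-effectiveness analysis of sequential diagnostic testing
#'
#' A decision-tree cohort model for comparing ordered sequences of
#' diagnostic tests ("strategies"). Each strategy is walked stage by
#' stage: undiagnosed patients may proceed to the next test, incur its
#' cost, and are diagnosed with the test's context-specific diagnostic
#' yield; diagnosed patients exit the pathway. Costs and diagnoses
#' delivered after year 1 are discounted. On top of the tree engine the
#' package provides incremental cost-per-additional-diagnosis analysis
#' with dominance and efficiency-frontier construction
#' ([dominance_table()]), net-monetary-benefit threshold analysis
#' ([solve_threshold()]), and probabilistic sensitivity analysis with
#' cost-effectiveness acceptability curves ([run_psa()], [ceac()]).
#'
#' @keywords internal
#' @aliases gencea-package
"_PACKAGE"

YIELD_CONTEXTS <- c("first_line", "second_line", "last_resort", "unconditional")

#' Discount factor for a model year
#'
#' Costs and diagnoses delivered in year 1 are undiscounted; later years
#' are discounted at `rate` per annum, i.e. year `t` receives weight
#' `(1 + rate)^-(t - 1)`.
#'
#' @param year Integer model year, starting at 1.
#' @param rate Annual discount rate as a proportion (e.g. 0.035).
#' @return Discount weight in (0, 1].
#' @examples
#' discount_factor(1, 0.035) # 1
#' discount_factor(2, 0.035) # 1 / 1.035
#' @export
discount_factor <- function(year, rate) {
  if (any(year < 1) || any(year != round(year))) {
    stop("`year` must be a whole number >= 1", call. = FALSE)
  }
  if (any(rate < 0)) stop("`rate` must be >= 0", call. = FALSE)
  (1 + rate)^-(year - 1)
}

## ---- constructors -------------------------------------------------------

#' Define a diagnostic test
#'
#' @param id Short identifier used by strategy stages.
#' @param cost_mean Mean cost per patient (GBP).
#' @param cost_ci Length-2 numeric, 95% CI for the cost.
#' @param yields Named list mapping context labels (`first_line`,
#'   `second_line`, `last_resort`, `unconditional`) to
#'   `list(mean =, ci = c(low, high))` diagnostic-yield entries.
#' @param label Optional human-readable name.
#' @param cost_family PSA distribution family for the cost (default
#'   gamma).
#' @return A `test_definition` list.
#' @export
test_definition <- function(id, cost_mean, cost_ci = c(cost_mean, cost_mean),
                            yields, label = id, cost_family = "gamma") {
  out <- structure(
    list(id = id, label = label,
         cost = list(mean = cost_mean, ci = as.numeric(cost_ci),
                     family = cost_family),
         yields = yields),
    class = "test_definition"
  )
  out
}

#' Define a strategy stage
#'
#' @param test Test id.
#' @param context Yield-context label under which the test is delivered.
#' @param year Model year of delivery (1-based).
#' @param proceed_prob Probability that an undiagnosed patient continues
#'   to this stage from the previous one.
#' @param extra_cost Additional per-patient cost incurred at this stage
#'   (e.g. associated clinic visits), discounted with the stage.
#' @return A `stage` list.
#' @export
stage <- function(test, context, year, proceed_prob = 1, extra_cost = 0) {
  structure(list(test = test, context = context, year = as.integer(year),
                 proceed_prob = proceed_prob, extra_cost = extra_cost),
            class = "stage")
}

#' Assemble a cost-effectiveness model
#'
#' @param tests List of [test_definition()] objects.
#' @param strategies List of `list(name =, stages = list(...))` entries;
#'   file/argument order is preserved in all outputs.
#' @param settings `list(discount_rate =, horizon_years =)`.
#' @param name Model label.
#' @param scenarios Named list of scenario override maps
#'   (parameter path -> value), see [apply_scenario()].
#' @param currency,cost_year Reporting metadata.
#' @return A validated `cea_model`.
#' @export
cea_model <- function(tests, strategies, settings, name = "model",
                      scenarios = list(), currency = "GBP",
                      cost_year = 2022L) {
  names(tests) <- vapply(tests, `[[`, "", "id")
  names(strategies) <- vapply(strategies, `[[`, "", "name")
  model <- structure(
    list(name = name, currency = currency, cost_year = cost_year,
         settings = settings, tests = tests, strategies = strategies,
         scenarios = scenarios),
    class = "cea_model"
  )
  validate_model(model)
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf("<cea_model> %s: %d tests, %d strategies, rate %.3f, horizon %d y\n",
              x$name, length(x$tests), length(x$strategies),
              x$settings$discount_rate, x$settings$horizon_years))
  invisible(x)
}

## ---- validation ---------------------------------------------------------

#' Validate a model configuration
#'
#' Checks every structural invariant (positive costs, CI bounds
#' bracketing means, yields and proceed-probabilities in \[0, 1\],
#' stage years within the horizon and non-decreasing, resolvable test
#' and context references) and reports *all* violations at once.
#'
#' @param model A `cea_model`.
#' @param check_ci Also require CI bounds to bracket means (relaxed
#'   after scenario overrides of a mean alone).
#' @return The model, invisibly-validated (returned unchanged).
#' @export
validate_model <- function(model, check_ci = TRUE) {
  errs <- character()
  add <- function(msg) errs[[length(errs) + 1L]] <<- msg

  s <- model$settings
  if (is.null(s$discount_rate) || s$discount_rate < 0) {
    add("settings.discount_rate must be >= 0")
  }
  if (is.null(s$horizon_years) || s$horizon_years < 1 ||
      s$horizon_years != round(s$horizon_years)) {
    add("settings.horizon_years must be a whole number >= 1")
  }

  if (length(model$tests) == 0) add("at least one test is required")
  if (anyDuplicated(names(model$tests))) add("test ids must be unique")
  for (t in model$tests) {
    pre <- sprintf("tests.%s", t$id)
    if (!is.numeric(t$cost$mean) || t$cost$mean <= 0) {
      add(sprintf("%s.cost.mean must be > 0", pre))
    }
    ci <- t$cost$ci
    if (check_ci &&
        (length(ci) != 2 || ci[1] > t$cost$mean || ci[2] < t$cost$mean)) {
      add(sprintf("%s.cost.ci must bracket the mean", pre))
    }
    if (length(t$yields) == 0) add(sprintf("%s has no yields", pre))
    if (!all(names(t$yields) %in% YIELD_CONTEXTS)) {
      add(sprintf("%s.yields has unknown context label(s): %s", pre,
                  paste(setdiff(names(t$yields), YIELD_CONTEXTS),
                        collapse = ", ")))
    }
    for (ctx in names(t$yields)) {
      y <- t$yields[[ctx]]
      if (!is.numeric(y$mean) || y$mean < 0 || y$mean > 1) {
        add(sprintf("%s.yields.%s.mean must be in [0, 1]", pre, ctx))
      }
      if (check_ci &&
          (length(y$ci) != 2 || y$ci[1] > y$mean || y$ci[2] < y$mean ||
           y$ci[1] < 0 || y$ci[2] > 1)) {
        add(sprintf("%s.yields.%s.ci must lie in [0, 1] and bracket the mean",
                    pre, ctx))
      }
    }
  }

  if (length(model$strategies) == 0) add("at least one strategy is required")
  if (anyDuplicated(names(model$strategies))) {
    add("strategy names must be unique")
  }
  for (st in model$strategies) {
    pre <- sprintf("strategies.%s", st$name)
    if (length(st$stages) == 0) {
      add(sprintf("%s must have at least one stage", pre))
      next
    }
    prev_year <- 0L
    for (i in seq_along(st$stages)) {
      sg <- st$stages[[i]]
      spre <- sprintf("%s.stages[%d]", pre, i)
      tst <- model$tests[[sg$test]]
      if (is.null(tst)) {
        add(sprintf("%s references unknown test '%s'", spre, sg$test))
      } else if (is.null(tst$yields[[sg$context]])) {
        add(sprintf("%s: test '%s' has no yield for context '%s'",
                    spre, sg$test, sg$context))
      }
      if (sg$year < 1 || (!is.null(s$horizon_years) &&
                          sg$year > s$horizon_years)) {
        add(sprintf("%s.year must be within 1..horizon_years", spre))
      }
      if (sg$year < prev_year) add(sprintf("%s.year decreases", spre))
      prev_year <- sg$year
      if (sg$proceed_prob < 0 || sg$proceed_prob > 1) {
        add(sprintf("%s.proceed_prob must be in [0, 1]", spre))
      }
      if (sg$extra_cost < 0) add(sprintf("%s.extra_cost must be >= 0", spre))
    }
  }

  if (length(errs)) {
    stop("invalid model configuration:\n  - ",
         paste(errs, collapse = "\n  - "), call. = FALSE)
  }
  model
}

## ---- evaluation ---------------------------------------------------------

# Vectorised tree walk shared by deterministic evaluation and the PSA.
# cost_of(stage) / yield_of(stage) return scalars or length-n vectors.
walk_strategy <- function(strat, rate, cost_of, yield_of, n = 1L) {
  reach <- rep(1, n)
  cost <- rep(0, n)
  yield <- rep(0, n)
  per_stage <- vector("list", length(strat$stages))
  for (i in seq_along(strat$stages)) {
    sg <- strat$stages[[i]]
    reach <- reach * sg$proceed_prob
    df <- discount_factor(sg$year, rate)
    c_i <- reach * (cost_of(sg) + sg$extra_cost) * df
    y_i <- reach * yield_of(sg) * df
    cost <- cost + c_i
    yield <- yield + y_i
    per_stage[[i]] <- list(reach = reach, cost = c_i, yield = y_i)
    reach <- reach * (1 - yield_of(sg))
  }
  list(cost = cost, yield = yield, per_stage = per_stage)
}

#' Evaluate one strategy
#'
#' Walks the strategy's stages in order, maintaining the probability of
#' reaching each stage: undiagnosed patients continue with the stage's
#' `proceed_prob`, incur the test's (discounted) cost, are diagnosed
#' with the test's context-specific yield, and diagnosed patients exit
#' all later stages.
#'
#' @param model A `cea_model`.
#' @param strategy Strategy name (or a strategy list from the model).
#' @return A `cea_eval` list with `strategy`, `expected_cost`,
#'   `expected_yield`, and a `per_stage` tibble (stage, test, context,
#'   year, reach probability, discounted cost and yield contributions).
#' @examples
#' m <- canonical_model()
#' evaluate_strategy(m, "1st-line GS")
#' @export
evaluate_strategy <- function(model, strategy) {
  if (is.character(strategy)) {
    strat <- model$strategies[[strategy]]
    if (is.null(strat)) {
      stop(sprintf("unknown strategy '%s'", strategy), call. = FALSE)
    }
  } else {
    strat <- strategy
  }
  rate <- model$settings$discount_rate
  res <- walk_strategy(
    strat, rate,
    cost_of = function(sg) model$tests[[sg$test]]$cost$mean,
    yield_of = function(sg) model$tests[[sg$test]]$yields[[sg$context]]$mean
  )
  per_stage <- tibble::tibble(
    stage = seq_along(strat$stages),
    test = vapply(strat$stages, `[[`, "", "test"),
    context = vapply(strat$stages, `[[`, "", "context"),
    year = vapply(strat$stages, `[[`, 1L, "year"),
    reach_prob = vapply(res$per_stage, `[[`, 0, "reach"),
    cost_contrib = vapply(res$per_stage, `[[`, 0, "cost"),
    yield_contrib = vapply(res$per_stage, `[[`, 0, "yield")
  )
  structure(
    list(strategy = strat$name, expected_cost = res$cost,
         expected_yield = res$yield, per_stage = per_stage),
    class = "cea_eval"
  )
}

#' @export
print.cea_eval <- function(x, ...) {
  cat(sprintf("<cea_eval> %s: cost %s%.2f, diagnostic yield %.1f%%\n",
              x$strategy, "£", x$expected_cost,
              100 * x$expected_yield))
  print(x$per_stage)
  invisible(x)
}

#' Evaluate every strategy in a model
#'
#' @param model A `cea_model`.
#' @return A tibble with columns `strategy`, `cost`, `yield` in the
#'   model's strategy order; per-stage breakdowns are attached as the
#'   `"evals"` attribute (a list of [evaluate_strategy()] results).
#' @export
evaluate_model <- function(model) {
  evals <- lapply(names(model$strategies),
                  function(nm) evaluate_strategy(model, nm))
  out <- tibble::tibble(
    strategy = vapply(evals, `[[`, "", "strategy"),
    cost = vapply(evals, `[[`, 0, "expected_cost"),
    yield = vapply(evals, `[[`, 0, "expected_yield")
  )
  attr(out, "evals") <- evals
  out
}
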