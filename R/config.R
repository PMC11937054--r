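## Configuration I/O: YAML/JSON model files, scenario overrides,
## packaged canonical fixtures.

model_from_list <- function(x, name = NULL) {
  stopifnot(is.list(x))
  if (is.null(x$tests) || length(x$tests) == 0) {
    stop("invalid model configuration:\n  - no tests defined", call. = FALSE)
  }
  if (is.null(x$strategies) || length(x$strategies) == 0) {
    stop("invalid model configuration:\n  - no strategies defined",
         call. = FALSE)
  }
  tests <- lapply(x$tests, function(t) {
    yields <- lapply(t$yields, function(y) {
      list(mean = as.numeric(y$mean), ci = as.numeric(unlist(y$ci)),
           family = y$family %||% "beta")
    })
    test_definition(
      id = t$id, label = t$label %||% t$id,
      cost_mean = as.numeric(t$cost$mean),
      cost_ci = as.numeric(unlist(t$cost$ci %||% rep(t$cost$mean, 2))),
      yields = yields,
      cost_family = t$cost$family %||% "gamma"
    )
  })
  strategies <- lapply(x$strategies, function(st) {
    list(
      name = st$name,
      stages = lapply(st$stages, function(sg) {
        stage(test = sg$test, context = sg$context, year = sg$year,
              proceed_prob = sg$proceed_prob %||% 1,
              extra_cost = sg$extra_cost %||% 0)
      })
    )
  })
  cea_model(
    tests = tests, strategies = strategies,
    settings = list(
      discount_rate = as.numeric(x$settings$discount_rate),
      horizon_years = as.integer(x$settings$horizon_years)
    ),
    name = name %||% x$name %||% "model",
    scenarios = x$scenarios %||% list(),
    currency = x$currency %||% "GBP",
    cost_year = x$cost_year %||% 2022L
  )
}

model_to_list <- function(model) {
  list(
    name = model$name,
    currency = model$currency,
    cost_year = model$cost_year,
    settings = model$settings,
    tests = lapply(unname(model$tests), function(t) {
      list(id = t$id, label = t$label,
           cost = list(mean = t$cost$mean, ci = t$cost$ci,
                       family = t$cost$family),
           yields = lapply(t$yields, function(y) {
             list(mean = y$mean, ci = y$ci, family = y$family %||% "beta")
           }))
    }),
    strategies = lapply(unname(model$strategies), function(st) {
      list(name = st$name, stages = lapply(st$stages, unclass))
    }),
    scenarios = model$scenarios
  )
}

#' Load a model configuration file
#'
#' Reads a YAML (or JSON, which YAML parses) model configuration and
#' validates it. The schema has four blocks: `settings` (discount_rate,
#' horizon_years), `tests` (id, cost mean + 95% CI, context-specific
#' yields with mean + 95% CI), `strategies` (ordered stages with test,
#' context, year, and optional proceed_prob / extra_cost calibration
#' slots), and optional named `scenarios` override maps. Strategy order
#' in the file is preserved in all outputs.
#'
#' @param path Path to the configuration file.
#' @return A validated `cea_model`.
#' @seealso [canonical_model()] for the packaged configuration,
#'   [write_model()] for the inverse.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  }
  model_from_list(yaml::read_yaml(path))
}

#' Write a model configuration to YAML
#'
#' Inverse of [load_model()]: `load_model(write_model(m, f))` reproduces
#' `m`, and write -> load -> write is byte-idempotent.
#'
#' @param model A `cea_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  yaml::write_yaml(model_to_list(model), path, precision = 15L)
  invisible(path)
}

## ---- parameter paths ----------------------------------------------------

split_path <- function(path) strsplit(path, ".", fixed = TRUE)[[1]]

#' Read a numeric model parameter by path
#'
#' Parameter paths are dot-separated, e.g. `"tests.gs.cost.mean"`,
#' `"tests.es.yields.second_line.mean"`, `"settings.discount_rate"`.
#'
#' @param model A `cea_model`.
#' @param path Parameter path string.
#' @return The numeric value at the path.
#' @export
get_parameter <- function(model, path) {
  node <- unclass(model)
  for (key in split_path(path)) {
    if (is.null(node[[key]])) {
      stop(sprintf("parameter path '%s' does not resolve ('%s' missing)",
                   path, key), call. = FALSE)
    }
    node <- node[[key]]
  }
  if (!is.numeric(node)) {
    stop(sprintf("parameter path '%s' is not numeric", path), call. = FALSE)
  }
  node
}

#' Set a numeric model parameter by path
#'
#' Domain checks only (costs must stay positive, yields and
#' probabilities in \[0, 1\]); CI-bracketing is not re-imposed, so a
#' mean can be moved through its interval during threshold searches.
#'
#' @inheritParams get_parameter
#' @param value Replacement numeric value (same length as the current
#'   value, so a CI path takes a length-2 vector).
#' @return A new `cea_model`; the input model is unchanged.
#' @export
set_parameter <- function(model, path, value) {
  old <- get_parameter(model, path) # errors if unresolvable / non-numeric
  if (length(value) != length(old)) {
    stop(sprintf("parameter '%s' has length %d, replacement has length %d",
                 path, length(old), length(value)), call. = FALSE)
  }
  keys <- split_path(path)
  bad <- if (any(keys == "yields") || any(keys == "proceed_prob")) {
    any(value < 0) || any(value > 1)
  } else if (any(keys == "cost")) {
    any(value <= 0)
  } else if (any(keys == "extra_cost") || any(keys == "discount_rate")) {
    any(value < 0)
  } else FALSE
  if (bad) {
    stop(sprintf("override of '%s' is outside the parameter's domain", path),
         call. = FALSE)
  }
  rec <- function(node, keys, value) {
    if (length(keys) == 0) return(value)
    node[[keys[1]]] <- rec(node[[keys[1]]], keys[-1], value)
    node
  }
  out <- rec(unclass(model), keys, value)
  structure(out, class = "cea_model")
}

#' Apply a scenario (set of parameter overrides) to a model
#'
#' @param model A `cea_model`.
#' @param overrides Either the name of a scenario declared in the
#'   model's `scenarios` block (e.g. `"low_gs"`), or a named list
#'   mapping parameter paths to replacement values. An empty list is
#'   the identity.
#' @return A new `cea_model` with the overrides applied; the original
#'   model is unchanged.
#' @examples
#' m <- canonical_model()
#' low <- apply_scenario(m, "low_gs")
#' evaluate_strategy(low, "1st-line GS")$expected_cost # 3781
#' @export
apply_scenario <- function(model, overrides) {
  if (is.character(overrides) && length(overrides) == 1) {
    sc <- model$scenarios[[overrides]]
    if (is.null(sc)) {
      stop(sprintf("unknown scenario '%s' (available: %s)", overrides,
                   paste(names(model$scenarios), collapse = ", ")),
           call. = FALSE)
    }
    overrides <- sc
  }
  for (path in names(overrides)) {
    model <- set_parameter(model, path, as.numeric(unlist(overrides[[path]])))
  }
  validate_model(model, check_ci = FALSE)
}

## ---- packaged fixtures --------------------------------------------------

#' The canonical Scottish testing-strategy model
#'
#' Loads the packaged configuration of six genetic/genomic testing
#' strategies for rare developmental disorders (standard genetic
#' testing; 1st-line, 2nd-line and last-resort trio genome sequencing;
#' 2nd-line and last-resort trio exome sequencing), with 2022 GBP costs,
#' a 3-year horizon and 3.5% annual discounting. The `"low_gs"`
#' scenario swaps the trio-GS cost from £5576 to £3781 per trio
#' (outsourced sequencing pipeline).
#'
#' @param scenario Optional scenario name to apply (e.g. `"low_gs"`).
#' @return A validated `cea_model`.
#' @export
canonical_model <- function(scenario = NULL) {
  path <- system.file("extdata", "scotland_base.yaml", package = "gencea",
                      mustWork = TRUE)
  model <- load_model(path)
  if (!is.null(scenario)) model <- apply_scenario(model, scenario)
  model
}

#' Published strategy-level reference results
#'
#' Strategy-level discounted cost and diagnostic yield for the Scottish
#' evaluation as originally published (computed from the full
#' supplementary decision tree, which includes clinic-visit costs and
#' pathway branch detail beyond the simplified tree shipped here).
#' These are the inputs to the incremental (footnote) arithmetic that
#' [dominance_table()] reproduces, and the reference against which the
#' simplified reconstruction is compared.
#'
#' @param scenario `"base"` (GS £5576 per trio) or `"low_gs"` (£3781).
#' @return A tibble with columns `strategy`, `cost`, `yield`, ordered
#'   by ascending cost.
#' @export
reference_results <- function(scenario = c("base", "low_gs")) {
  scenario <- match.arg(scenario)
  path <- system.file("extdata", "scotland_reference_results.csv",
                      package = "gencea", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- df[df$scenario == scenario, c("strategy", "cost", "yield")]
  tibble::as_tibble(df[order(df$cost), ])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
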