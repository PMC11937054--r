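## Report writers and plots: CEA tables as CSV, efficiency-frontier and
## CEAC figures, run manifests.

#' Truncate money to the whole pound
#'
#' Display convention for incremental cost-effectiveness ratios:
#' truncation toward zero after clearing floating-point noise at the
#' sixth decimal, so a ratio of exactly 536/0.001 prints as 536000.
#'
#' @param x Numeric money values.
#' @return Whole-pound values.
#' @export
trunc_pound <- function(x) trunc(round(x, 6))

utils::globalVariables(c("yield_pct", "cost", "status", "strategy", "wtp",
                         "probability"))

#' Format a CEA table for presentation
#'
#' Rounds costs to the nearest pound, yields to 0.1 percentage point,
#' and ICADs truncated to the pound (the convention used in published
#' incremental tables); dominance status becomes a "Dominated by ..."
#' label. Machine-readable outputs keep full precision — use the raw
#' [dominance_table()] for those.
#'
#' @param tab A `cea_table`.
#' @return A tibble of display strings/rounded values.
#' @export
format_cea_table <- function(tab) {
  icad_lab <- ifelse(
    tab$status == "frontier",
    ifelse(is.na(tab$icad), "–", sprintf("%d", trunc_pound(tab$icad))),
    paste("Dominated by", tab$dominated_by)
  )
  tibble::tibble(
    strategy = tab$strategy,
    cost_gbp = round(tab$cost),
    yield_pct = round(100 * tab$yield, 1),
    incremental_cost_gbp = round(tab$incremental_cost),
    incremental_yield_pct = round(100 * tab$incremental_yield, 1),
    icad = icad_lab
  )
}

#' Write evaluation and CEA tables to CSV
#'
#' @param tab A `cea_table` from [dominance_table()].
#' @param path Output CSV path.
#' @param currency,cost_year Labels recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_cea_csv <- function(tab, path, currency = "GBP", cost_year = 2022) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# costs in %s (%s); yields are proportions",
                     currency, cost_year), con)
  utils::write.csv(as.data.frame(tab), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Write per-strategy evaluation results to CSV
#'
#' One row per strategy with expected discounted cost and yield, plus
#' per-stage breakdown rows keyed by strategy and stage.
#'
#' @param model A `cea_model`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_evaluation_csv <- function(model, path) {
  res <- evaluate_model(model)
  evals <- attr(res, "evals")
  per_stage <- do.call(rbind, lapply(evals, function(e) {
    cbind(strategy = e$strategy, as.data.frame(e$per_stage))
  }))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# costs in %s (%s); yields are proportions",
                     model$currency, model$cost_year), con)
  utils::write.csv(
    merge(as.data.frame(res), per_stage, by = "strategy", sort = FALSE),
    con, row.names = FALSE, na = ""
  )
  invisible(path)
}

#' Efficiency-frontier plot
#'
#' Plots each strategy's expected diagnostic yield against expected
#' cost; frontier members are connected in cost order.
#'
#' @param tab A `cea_table`.
#' @return A ggplot object.
#' @export
plot_frontier <- function(tab) {
  tab <- tibble::as_tibble(tab)
  tab$yield_pct <- 100 * tab$yield
  front <- tab[tab$status == "frontier", ]
  ggplot2::ggplot(tab, ggplot2::aes(x = yield_pct, y = cost)) +
    ggplot2::geom_line(data = front, colour = "darkorange", linewidth = 0.8) +
    ggplot2::geom_point(ggplot2::aes(shape = status), size = 2.5) +
    ggplot2::geom_text(ggplot2::aes(label = strategy),
                       vjust = -0.9, size = 3) +
    ggplot2::labs(x = "Diagnostic yield (%)", y = "Expected cost (GBP)",
                  shape = NULL, title = "Efficiency frontier") +
    ggplot2::theme_minimal()
}

#' CEAC plot
#'
#' @param cc A `ceac_result` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(cc) {
  ggplot2::ggplot(cc$curves,
                  ggplot2::aes(x = wtp, y = probability,
                               colour = strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Willingness to pay per additional diagnosis (GBP)",
                  y = "Probability cost effective", colour = NULL,
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}

#' Write a run manifest
#'
#' Records the run's provenance: timestamp, configuration path and MD5
#' hash, scenario, seed, package version, and the invoking subcommand
#' and flags, one per line as `key: value`.
#'
#' @param outdir Output directory (created if needed).
#' @param config_path Path of the configuration used.
#' @param scenario Scenario name or `NA`.
#' @param seed Seed or `NA` for deterministic subcommands.
#' @param subcommand,flags Invocation details.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(outdir, config_path, scenario = NA, seed = NA,
                           subcommand = NA, flags = "") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(outdir, "manifest.txt")
  lines <- c(
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    sprintf("config: %s", config_path),
    sprintf("config_md5: %s", unname(tools::md5sum(config_path))),
    sprintf("scenario: %s", scenario),
    sprintf("seed: %s", seed),
    sprintf("tool_version: gencea %s",
            as.character(utils::packageVersion("gencea"))),
    sprintf("subcommand: %s", subcommand),
    sprintf("flags: %s", flags)
  )
  writeLines(lines, path)
  invisible(path)
}
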