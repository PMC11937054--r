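## Incremental cost-effectiveness analysis: ICAD, strict and extended
## dominance, efficiency frontier, net monetary benefit.

#' Incremental cost per additional diagnosis (ICAD)
#'
#' `(c1 - c0) / (dy1 - dy0)` between a strategy and the next-best
#' alternative.
#'
#' @param c1,c0 Strategy and comparator expected costs.
#' @param dy1,dy0 Strategy and comparator expected diagnostic yields
#'   (proportions).
#' @return Cost per additional diagnosis (unrounded).
#' @examples
#' icad(3168, 1402, 0.448, 0.421) # ~65407
#' @export
icad <- function(c1, c0, dy1, dy0) {
  if (any(dy1 == dy0)) {
    stop("ICAD undefined: equal diagnostic yields (handle via dominance)",
         call. = FALSE)
  }
  (c1 - c0) / (dy1 - dy0)
}

#' Net monetary benefit
#'
#' `wtp * yield - cost`: the strategy maximising NMB at a given
#' willingness to pay per additional diagnosis is "cost effective" at
#' that WTP.
#'
#' @param cost Expected cost (or a `cea_eval` object).
#' @param yield Expected diagnostic yield (ignored when `cost` is a
#'   `cea_eval`).
#' @param wtp Willingness to pay per additional diagnosis (>= 0).
#' @return Net monetary benefit (money).
#' @export
nmb <- function(cost, yield = NULL, wtp) {
  if (inherits(cost, "cea_eval")) {
    yield <- cost$expected_yield
    cost <- cost$expected_cost
  }
  if (any(wtp < 0)) stop("`wtp` must be >= 0", call. = FALSE)
  wtp * yield - cost
}

#' Implied willingness to pay per diagnosis
#'
#' Historical spending per diagnosis: cost divided by diagnostic yield.
#' Dividing the average standard genetic testing cost by its yield
#' gives the WTP implicitly revealed by past testing policy.
#'
#' @param cost Money spent per patient.
#' @param yield Diagnostic yield achieved (proportion, > 0).
#' @return Money per diagnosis.
#' @examples
#' implied_wtp(2429, 0.282) # ~8613
#' @export
implied_wtp <- function(cost, yield) {
  if (any(yield <= 0)) stop("`yield` must be > 0", call. = FALSE)
  cost / yield
}

#' Incremental analysis with dominance and efficiency frontier
#'
#' Sorts strategies by ascending cost, marks strict dominance (another
#' strategy costs no more and diagnoses strictly more, or costs
#' strictly less and diagnoses no fewer), then iteratively removes
#' extended-dominated strategies (whose ICAD against the previous
#' surviving strategy exceeds the next survivor's) until frontier
#' ICADs are strictly increasing. Each row's incremental cost and
#' yield are taken against the most recent frontier member of lower
#' cost; ICADs are reported for frontier rows only.
#'
#' @param results A data frame with columns `strategy`, `cost`,
#'   `yield` — e.g. the output of [evaluate_model()] or
#'   [reference_results()].
#' @return A `cea_table` tibble with columns `strategy`, `cost`,
#'   `yield`, `incremental_cost`, `incremental_yield`, `icad`,
#'   `status` (`"frontier"`, `"dominated"`, `"extended_dominated"`),
#'   `dominated_by` and `tied`, sorted by ascending cost.
#' @examples
#' dominance_table(reference_results("base"))
#' @export
dominance_table <- function(results) {
  df <- tibble::as_tibble(results[, c("strategy", "cost", "yield")])
  if (nrow(df) < 1) stop("at least one strategy is required", call. = FALSE)
  if (anyDuplicated(df$strategy)) {
    stop("strategy names must be unique", call. = FALSE)
  }
  df <- df[order(df$cost, -df$yield), ]
  n <- nrow(df)

  status <- rep("frontier", n)
  dominated_by <- rep(NA_character_, n)
  tied <- rep(FALSE, n)

  # strict dominance
  for (i in seq_len(n)) {
    dom <- which((df$cost < df$cost[i] & df$yield >= df$yield[i]) |
                   (df$cost <= df$cost[i] & df$yield > df$yield[i]))
    dom <- setdiff(dom, i)
    if (length(dom)) {
      status[i] <- "dominated"
      # name the dominator with the highest yield (cheapest on ties)
      best <- dom[order(-df$yield[dom], df$cost[dom])][1]
      dominated_by[i] <- df$strategy[best]
    }
    tied[i] <- any(df$cost[-i] == df$cost[i] & df$yield[-i] == df$yield[i])
  }

  # extended dominance among survivors: enforce strictly increasing ICADs.
  # Exact (cost, yield) ties are kept on the frontier but enter the ICAD
  # chain once.
  surv <- which(status == "frontier")
  dup <- tied & duplicated(paste(df$cost, df$yield))
  surv <- setdiff(surv, which(dup))
  repeat {
    if (length(surv) < 3) break
    ic <- icad(df$cost[surv[-1]], df$cost[surv[-length(surv)]],
               df$yield[surv[-1]], df$yield[surv[-length(surv)]])
    viol <- which(diff(ic) <= 0)
    if (!length(viol)) break
    k <- surv[viol[1] + 1L] # middle strategy of the first violation
    status[k] <- "extended_dominated"
    dominated_by[k] <- df$strategy[surv[viol[1] + 2L]]
    surv <- setdiff(surv, k)
  }

  # increments against the most recent lower-cost frontier member
  inc_cost <- rep(NA_real_, n)
  inc_yield <- rep(NA_real_, n)
  icad_col <- rep(NA_real_, n)
  frontier_idx <- which(status == "frontier")
  for (i in seq_len(n)) {
    prev <- frontier_idx[frontier_idx < i]
    if (!length(prev)) next
    p <- max(prev)
    inc_cost[i] <- df$cost[i] - df$cost[p]
    inc_yield[i] <- df$yield[i] - df$yield[p]
    if (status[i] == "frontier" && inc_yield[i] != 0) {
      icad_col[i] <- inc_cost[i] / inc_yield[i]
    }
  }

  out <- tibble::tibble(
    strategy = df$strategy, cost = df$cost, yield = df$yield,
    incremental_cost = inc_cost, incremental_yield = inc_yield,
    icad = icad_col, status = status, dominated_by = dominated_by,
    tied = tied
  )
  class(out) <- c("cea_table", class(out))
  out
}

#' Frontier member names of a CEA table
#' @param tab A `cea_table` from [dominance_table()].
#' @return Character vector of frontier strategies in cost order.
#' @export
frontier_strategies <- function(tab) {
  tab$strategy[tab$status == "frontier"]
}

#' NMB-optimal strategy at a willingness to pay
#'
#' Evaluates every strategy in the model and returns the one with the
#' highest net monetary benefit at `wtp`. Exact NMB ties are broken in
#' favour of the lexicographically first strategy name (with a
#' warning).
#'
#' @param model A `cea_model`.
#' @param wtp Willingness to pay per additional diagnosis.
#' @param results Optional pre-computed [evaluate_model()] table.
#' @return A strategy name.
#' @export
optimal_strategy <- function(model, wtp, results = NULL) {
  if (is.null(results)) results <- evaluate_model(model)
  b <- nmb(results$cost, results$yield, wtp)
  best <- which(b == max(b))
  if (length(best) > 1) {
    best <- best[order(results$strategy[best])]
    warning(sprintf("NMB tie at wtp %s between: %s; reporting '%s'",
                    format(wtp), paste(results$strategy[best], collapse = ", "),
                    results$strategy[best[1]]), call. = FALSE)
  }
  results$strategy[best[1]]
}
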