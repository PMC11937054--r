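## Probabilistic sensitivity analysis: distributions fitted from
## published means and 95% CIs, Monte-Carlo propagation through the
## tree engine, cost-effectiveness acceptability curves.

#' Fit a sampling distribution from a mean and 95% CI
#'
#' The standard error is taken as `(high - low) / 3.92` (normal-theory
#' 95% interval width) and the family's parameters are matched to the
#' mean and that variance: beta via `alpha = m (m (1 - m) / v - 1)`,
#' `beta = alpha (1 - m) / m`; gamma via `shape = m^2 / v`,
#' `scale = v / m`; normal as `(m, se)`; lognormal moment-matched on
#' the log scale. A zero-width CI yields a point mass for any family.
#'
#' @param mean Published mean.
#' @param ci Length-2 numeric 95% CI, `low <= mean <= high`.
#' @param family One of `"beta"`, `"gamma"`, `"normal"`, `"lognormal"`.
#' @param parameter_path Optional model path this spec samples.
#' @return A `dist_spec` list: `parameter_path`, `family`, `par`
#'   (named family parameters) and `provenance` (`mean`, `ci`).
#' @examples
#' fit_distribution(0.10, c(0.09, 0.12), "beta")
#' fit_distribution(1153, c(1060, 1245), "gamma")
#' @export
fit_distribution <- function(mean, ci, family = c("beta", "gamma", "normal",
                                                  "lognormal"),
                             parameter_path = NULL) {
  family <- match.arg(family)
  ci <- as.numeric(ci)
  if (length(ci) != 2 || ci[1] > mean || ci[2] < mean) {
    stop("`ci` must be (low, high) with low <= mean <= high", call. = FALSE)
  }
  se <- (ci[2] - ci[1]) / 3.92
  v <- se^2
  m <- mean
  if (v == 0) {
    par <- c(value = m)
    family <- "point"
  } else {
    par <- switch(
      family,
      beta = {
        if (m <= 0 || m >= 1) {
          stop("beta family requires mean in (0, 1)", call. = FALSE)
        }
        if (v >= m * (1 - m)) {
          stop("beta family infeasible: variance >= m(1-m)", call. = FALSE)
        }
        a <- m * (m * (1 - m) / v - 1)
        c(shape1 = a, shape2 = a * (1 - m) / m)
      },
      gamma = {
        if (m <= 0) stop("gamma family requires mean > 0", call. = FALSE)
        c(shape = m^2 / v, scale = v / m)
      },
      normal = c(mean = m, sd = se),
      lognormal = {
        if (m <= 0) stop("lognormal family requires mean > 0", call. = FALSE)
        sdlog <- sqrt(log(1 + v / m^2))
        c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
      }
    )
  }
  structure(
    list(parameter_path = parameter_path, family = family, par = par,
         provenance = list(mean = m, ci = ci)),
    class = "dist_spec"
  )
}

#' Sample from a fitted distribution
#' @param spec A `dist_spec` from [fit_distribution()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_distribution <- function(spec, n) {
  p <- spec$par
  switch(
    spec$family,
    point = rep(p[["value"]], n),
    beta = stats::rbeta(n, p[["shape1"]], p[["shape2"]]),
    gamma = stats::rgamma(n, shape = p[["shape"]], scale = p[["scale"]]),
    normal = stats::rnorm(n, p[["mean"]], p[["sd"]]),
    lognormal = stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]),
    stop(sprintf("unknown family '%s'", spec$family), call. = FALSE)
  )
}

#' Distribution specifications for every model parameter
#'
#' Builds one `dist_spec` per uncertain input from its published mean
#' and 95% CI: beta for diagnostic yields, gamma for costs (families
#' can be overridden per parameter in the configuration file). All
#' parameters are treated as independent.
#'
#' @param model A `cea_model`.
#' @return Named list of `dist_spec` objects keyed by parameter path.
#' @export
model_distributions <- function(model) {
  specs <- list()
  for (t in model$tests) {
    path <- sprintf("tests.%s.cost.mean", t$id)
    specs[[path]] <- fit_distribution(t$cost$mean, t$cost$ci,
                                      t$cost$family %||% "gamma",
                                      parameter_path = path)
    for (ctx in names(t$yields)) {
      y <- t$yields[[ctx]]
      path <- sprintf("tests.%s.yields.%s.mean", t$id, ctx)
      specs[[path]] <- fit_distribution(y$mean, y$ci, y$family %||% "beta",
                                        parameter_path = path)
    }
  }
  specs
}

#' Run a probabilistic sensitivity analysis
#'
#' Draws every uncertain parameter independently from its fitted
#' distribution, re-evaluates all strategies per iteration through the
#' tree engine, and stores the per-iteration (cost, yield) matrices.
#' Fully reproducible from `seed`.
#'
#' @param model A `cea_model`.
#' @param n_iter Number of Monte-Carlo iterations.
#' @param seed Integer RNG seed (required, for reproducibility).
#' @param specs Distribution specs; defaults to
#'   [model_distributions()] of the model.
#' @return A `psa_result` list: `n_iter`, `seed`, `strategies`, `cost`
#'   and `yield` matrices (`n_iter` x strategies), and `param_draws`
#'   (`n_iter` x parameters).
#' @export
run_psa <- function(model, n_iter = 10000L, seed, specs = NULL) {
  if (missing(seed)) stop("`seed` is required for a reproducible PSA",
                          call. = FALSE)
  if (n_iter < 1) stop("`n_iter` must be >= 1", call. = FALSE)
  if (is.null(specs)) specs <- model_distributions(model)

  set.seed(seed)
  draws <- vapply(specs, sample_distribution, numeric(n_iter), n = n_iter)
  if (n_iter == 1L) draws <- matrix(draws, nrow = 1,
                                    dimnames = list(NULL, names(specs)))
  bad <- colnames(draws)[apply(draws, 2, function(x) any(!is.finite(x)))]
  if (length(bad)) {
    stop("non-finite parameter draws for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  # look-up closures: sampled column if the path has a spec, else the mean
  col_or <- function(path, fallback) {
    if (path %in% colnames(draws)) draws[, path] else rep(fallback, n_iter)
  }
  cost_of <- function(sg) {
    col_or(sprintf("tests.%s.cost.mean", sg$test),
           model$tests[[sg$test]]$cost$mean)
  }
  yield_of <- function(sg) {
    y <- col_or(sprintf("tests.%s.yields.%s.mean", sg$test, sg$context),
                model$tests[[sg$test]]$yields[[sg$context]]$mean)
    if (any(y < 0 | y > 1)) {
      stop(sprintf("sampled yield outside [0, 1] for %s/%s",
                   sg$test, sg$context), call. = FALSE)
    }
    y
  }

  rate <- model$settings$discount_rate
  snames <- names(model$strategies)
  cost <- matrix(NA_real_, n_iter, length(snames),
                 dimnames = list(NULL, snames))
  yield <- cost
  for (nm in snames) {
    res <- walk_strategy(model$strategies[[nm]], rate, cost_of, yield_of,
                         n = n_iter)
    cost[, nm] <- res$cost
    yield[, nm] <- res$yield
  }

  structure(
    list(n_iter = as.integer(n_iter), seed = as.integer(seed),
         strategies = snames, cost = cost, yield = yield,
         param_draws = draws, specs = specs),
    class = "psa_result"
  )
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d), %d strategies, %d parameters\n",
              x$n_iter, x$seed, length(x$strategies), ncol(x$param_draws)))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability a strategy is
#' cost effective is the fraction of PSA iterations in which it attains
#' the maximal net monetary benefit (ties broken deterministically in
#' favour of the lexicographically first strategy name, so the
#' probabilities sum to exactly 1 at every grid point).
#'
#' @param psa A `psa_result` from [run_psa()].
#' @param wtp_grid Ascending WTP grid; default £0–£100,000 in £500
#'   steps.
#' @return A `ceac_result` list: `curves` (long tibble: `wtp`,
#'   `strategy`, `probability`), `most_likely` (tibble: `wtp`,
#'   `strategy`), `crossover_wtp` (smallest grid WTP at which the
#'   most-likely strategy differs from the one at the low-WTP end; `NA`
#'   if it never changes) and `last_stable_wtp` (largest grid WTP
#'   before that switch).
#' @export
ceac <- function(psa, wtp_grid = seq(0, 100000, by = 500)) {
  if (is.unsorted(wtp_grid, strictly = TRUE)) {
    stop("`wtp_grid` must be strictly increasing", call. = FALSE)
  }
  if (is.null(psa$cost) || nrow(psa$cost) == 0) {
    stop("PSA result contains no draws", call. = FALSE)
  }
  snames <- psa$strategies
  # alphabetical column order makes max.col(ties = "first") the
  # lexicographic tie-break
  ord <- order(snames)
  cost <- psa$cost[, ord, drop = FALSE]
  yield <- psa$yield[, ord, drop = FALSE]
  sorted_names <- snames[ord]

  prob <- matrix(0, length(wtp_grid), length(snames),
                 dimnames = list(NULL, sorted_names))
  for (k in seq_along(wtp_grid)) {
    b <- wtp_grid[k] * yield - cost
    win <- max.col(b, ties.method = "first")
    tab <- tabulate(win, nbins = length(snames))
    prob[k, ] <- tab / nrow(b)
  }
  prob <- prob[, snames, drop = FALSE] # back to model order

  most_likely <- vapply(seq_along(wtp_grid), function(k) {
    p <- prob[k, ]
    nm <- names(p)[p == max(p)]
    sort(nm)[1]
  }, "")

  leader0 <- most_likely[1]
  switch_at <- which(most_likely != leader0)
  crossover <- if (length(switch_at)) wtp_grid[switch_at[1]] else NA_real_
  last_stable <- if (length(switch_at)) {
    wtp_grid[switch_at[1] - 1L]
  } else {
    wtp_grid[length(wtp_grid)]
  }

  curves <- tibble::tibble(
    wtp = rep(wtp_grid, times = length(snames)),
    strategy = rep(snames, each = length(wtp_grid)),
    probability = as.vector(prob)
  )
  structure(
    list(curves = curves, prob = prob, wtp_grid = wtp_grid,
         most_likely = tibble::tibble(wtp = wtp_grid,
                                      strategy = most_likely),
         leader_low_wtp = leader0,
         crossover_wtp = crossover, last_stable_wtp = last_stable),
    class = "ceac_result"
  )
}

#' @export
print.ceac_result <- function(x, ...) {
  cat(sprintf("<ceac_result> %d strategies over WTP %s..%s\n",
              ncol(x$prob), format(min(x$wtp_grid)), format(max(x$wtp_grid))))
  if (is.na(x$crossover_wtp)) {
    cat(sprintf("  '%s' most likely cost effective across the whole grid\n",
                x$leader_low_wtp))
  } else {
    cat(sprintf("  '%s' most likely cost effective up to WTP %s (switch at %s)\n",
                x$leader_low_wtp, format(x$last_stable_wtp),
                format(x$crossover_wtp)))
  }
  invisible(x)
}

#' Probability each strategy is cost effective at one WTP
#'
#' @param psa A `psa_result`.
#' @param wtp Single willingness-to-pay value.
#' @return Named numeric vector of probabilities (sums to 1).
#' @export
p_cost_effective <- function(psa, wtp) {
  ceac(psa, wtp_grid = wtp)$prob[1, ]
}
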