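## Synthetic model configurations: random but structurally faithful
## test/strategy sets, so every analysis is exercisable without any
## external data.

#' Generator settings for synthetic model configurations
#'
#' @param seed Integer RNG seed.
#' @param n_tests Number of diagnostic tests to invent.
#' @param n_strategies Number of strategies to assemble.
#' @param max_stages Maximum stages per strategy (<= `horizon_years`).
#' @param cost_range Uniform sampling range for mean test costs (GBP).
#' @param yield_range Uniform sampling range for mean yields.
#' @param ci_relative_width Total 95%-CI width relative to the mean
#'   (0 gives point-mass inputs); CIs are symmetric on the natural
#'   scale, clipped to the parameter domain.
#' @param horizon_years Model horizon; stage `k` is delivered in year
#'   `k`.
#' @return A `generator_settings` list.
#' @export
generator_settings <- function(seed, n_tests = 4L, n_strategies = 6L,
                               max_stages = 3L, cost_range = c(300, 6000),
                               yield_range = c(0.05, 0.5),
                               ci_relative_width = 0.2,
                               horizon_years = 3L) {
  s <- structure(
    list(seed = as.integer(seed), n_tests = as.integer(n_tests),
         n_strategies = as.integer(n_strategies),
         max_stages = as.integer(max_stages),
         cost_range = as.numeric(cost_range),
         yield_range = as.numeric(yield_range),
         ci_relative_width = as.numeric(ci_relative_width),
         horizon_years = as.integer(horizon_years)),
    class = "generator_settings"
  )
  if (s$n_tests < 1 || s$n_strategies < 1 || s$max_stages < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (s$max_stages > s$horizon_years) {
    stop("`max_stages` must not exceed `horizon_years`", call. = FALSE)
  }
  if (s$max_stages > s$n_tests) {
    stop("`max_stages` must not exceed `n_tests` (stages sample tests ",
         "without replacement)", call. = FALSE)
  }
  if (diff(s$cost_range) < 0 || s$cost_range[1] <= 0) {
    stop("`cost_range` must be positive and ordered", call. = FALSE)
  }
  if (diff(s$yield_range) < 0 || s$yield_range[1] < 0 ||
      s$yield_range[2] > 1) {
    stop("`yield_range` must be ordered and within [0, 1]", call. = FALSE)
  }
  if (s$ci_relative_width < 0) {
    stop("`ci_relative_width` must be >= 0", call. = FALSE)
  }
  s
}

sym_ci <- function(mean, rel_width, lo = 0, hi = Inf) {
  half <- rel_width * mean / 2
  c(max(mean - half, lo), min(mean + half, hi))
}

#' Generate a random model configuration
#'
#' Draws test costs and yields uniformly within the configured ranges,
#' builds symmetric 95% CIs of the stated relative width, and
#' assembles strategies as ordered stages in years `1..k` with
#' proceed probability 1. Deterministic in the seed; the result always
#' passes [validate_model()].
#'
#' @param settings A [generator_settings()] object (or a seed, with
#'   defaults for everything else).
#' @return A validated `cea_model`.
#' @examples
#' m <- generate_model(generator_settings(seed = 42))
#' evaluate_model(m)
#' @export
generate_model <- function(settings) {
  if (is.numeric(settings)) settings <- generator_settings(seed = settings)
  s <- settings
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(s$seed)

  tests <- lapply(seq_len(s$n_tests), function(i) {
    cost <- stats::runif(1, s$cost_range[1], s$cost_range[2])
    yield <- stats::runif(1, s$yield_range[1], s$yield_range[2])
    test_definition(
      id = sprintf("test_%02d", i),
      label = sprintf("Synthetic test %d", i),
      cost_mean = cost,
      cost_ci = sym_ci(cost, s$ci_relative_width, lo = .Machine$double.eps),
      yields = list(unconditional = list(
        mean = yield,
        ci = sym_ci(yield, s$ci_relative_width, lo = 0, hi = 1),
        family = "beta"
      ))
    )
  })

  strategies <- lapply(seq_len(s$n_strategies), function(m) {
    k <- sample.int(s$max_stages, 1)
    picks <- sample.int(s$n_tests, k)
    list(
      name = sprintf("strategy_%02d", m),
      stages = lapply(seq_len(k), function(j) {
        stage(test = sprintf("test_%02d", picks[j]),
              context = "unconditional", year = j)
      })
    )
  })

  cea_model(
    tests = tests, strategies = strategies,
    settings = list(discount_rate = 0.035,
                    horizon_years = s$horizon_years),
    name = sprintf("synthetic_seed%d", s$seed)
  )
}
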