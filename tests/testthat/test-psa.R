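test_that("moment matching reproduces hand-computed family parameters", {
  # independent arithmetic: se = ci width / 3.92, then the matching
  # formulae applied by hand
  se_y <- (0.12 - 0.09) / 3.92
  a <- 0.10 * (0.10 * 0.90 / se_y^2 - 1)
  spec <- fit_distribution(0.10, c(0.09, 0.12), "beta")
  expect_equal(unname(spec$par["shape1"]), a) # ~153.5
  expect_equal(unname(spec$par["shape2"]), a * 0.9 / 0.1) # ~1381.9
  expect_equal(round(unname(spec$par["shape1"]), 1), 153.6)

  se_c <- (1245 - 1060) / 3.92
  spec <- fit_distribution(1153, c(1060, 1245), "gamma")
  expect_equal(unname(spec$par["shape"]), 1153^2 / se_c^2) # ~596
  expect_equal(unname(spec$par["scale"]), se_c^2 / 1153) # ~1.93
  expect_equal(round(unname(spec$par["shape"])), 597)

  # degenerate CI collapses to a point mass regardless of family
  pm <- fit_distribution(0.3, c(0.3, 0.3), "normal")
  expect_equal(pm$family, "point")
  expect_equal(sample_distribution(pm, 5), rep(0.3, 5))

  expect_error(fit_distribution(0.5, c(0.6, 0.7), "beta"), "low <= mean")
  # a CI wide enough that the matched variance exceeds m(1 - m)
  expect_error(fit_distribution(0.01, c(0, 0.4), "beta"), "infeasible")
})

test_that("fitted distributions recover the published means and CIs", {
  m <- canonical_model()
  for (spec in model_distributions(m)) {
    p <- spec$par
    fitted_mean <- switch(spec$family,
                          beta = p[["shape1"]] / (p[["shape1"]] + p[["shape2"]]),
                          gamma = p[["shape"]] * p[["scale"]])
    expect_equal(fitted_mean, spec$provenance$mean,
                 tolerance = 0.01, label = spec$parameter_path)
    q <- switch(spec$family,
                beta = stats::qbeta(c(0.025, 0.975), p[["shape1"]],
                                    p[["shape2"]]),
                gamma = stats::qgamma(c(0.025, 0.975), shape = p[["shape"]],
                                      scale = p[["scale"]]))
    expect_lt(max(abs(q - spec$provenance$ci) / spec$provenance$ci), 0.05,
              label = spec$parameter_path)
  }
})

test_that("re-fitting from large samples recovers the family parameters", {
  set.seed(99)
  for (spec in list(fit_distribution(0.37, c(0.27, 0.49), "beta"),
                    fit_distribution(2275, c(1836, 2948), "gamma"))) {
    x <- sample_distribution(spec, 50000)
    ci <- unname(stats::quantile(x, c(0.025, 0.975)))
    refit <- fit_distribution(mean(x), ci, spec$family)
    expect_equal(unname(refit$par), unname(spec$par), tolerance = 0.02)
  }
})

test_that("the PSA is reproducible and unbiased for the deterministic model", {
  m <- canonical_model()
  p1 <- run_psa(m, n_iter = 300, seed = 7)
  p2 <- run_psa(m, n_iter = 300, seed = 7)
  expect_identical(p1$cost, p2$cost)
  expect_identical(p1$yield, p2$yield)
  expect_identical(p1$param_draws, p2$param_draws)
  expect_false(identical(p1$cost, run_psa(m, n_iter = 300, seed = 8)$cost))

  # with independent inputs the Monte-Carlo mean of every strategy's
  # cost and yield is the deterministic evaluation; check at 4 SE
  psa <- run_psa(m, n_iter = 4000, seed = 11)
  det <- evaluate_model(m)
  for (j in seq_along(psa$strategies)) {
    mc_se <- stats::sd(psa$cost[, j]) / sqrt(psa$n_iter)
    expect_lt(abs(mean(psa$cost[, j]) - det$cost[j]), 4 * mc_se)
    mc_se <- stats::sd(psa$yield[, j]) / sqrt(psa$n_iter)
    expect_lt(abs(mean(psa$yield[, j]) - det$yield[j]), 4 * mc_se)
  }

  expect_error(run_psa(m, n_iter = 10), "seed")
  expect_error(run_psa(m, n_iter = 0, seed = 1), "n_iter")
})

test_that("point-mass inputs make the PSA collapse to the deterministic model", {
  m <- canonical_model()
  specs <- model_distributions(m)
  point_specs <- lapply(specs, function(s) {
    fit_distribution(s$provenance$mean,
                     rep(s$provenance$mean, 2), "normal",
                     parameter_path = s$parameter_path)
  })
  psa <- run_psa(m, n_iter = 1, seed = 1, specs = point_specs)
  det <- evaluate_model(m)
  expect_equal(unname(psa$cost[1, ]), det$cost)
  expect_equal(unname(psa$yield[1, ]), det$yield)

  # CEACs become 0/1 curves matching the deterministic optimum
  grid <- seq(0, 100000, by = 5000)
  cc <- ceac(run_psa(m, n_iter = 10, seed = 2, specs = point_specs), grid)
  expect_true(all(cc$prob %in% c(0, 1)))
  det_opt <- vapply(grid, function(l) optimal_strategy(m, l, results = det),
                    "")
  expect_equal(cc$most_likely$strategy, det_opt)
})

test_that("CEAC probabilities normalise and reduce to cost ranks at WTP 0", {
  m <- canonical_model()
  psa <- run_psa(m, n_iter = 2000, seed = 5)
  grid <- seq(0, 100000, by = 2500)
  cc <- ceac(psa, grid)
  expect_equal(unname(rowSums(cc$prob)), rep(1, length(grid)))
  expect_true(all(cc$prob >= 0 & cc$prob <= 1))

  # at WTP 0 the "optimal" strategy is simply the cheapest draw
  cheapest <- psa$strategies[max.col(-psa$cost, ties.method = "first")]
  expect_equal(unname(cc$prob[1, ]),
               as.vector(table(factor(cheapest, psa$strategies))) /
                 psa$n_iter)

  expect_error(ceac(psa, c(5, 1)), "increasing")
})
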