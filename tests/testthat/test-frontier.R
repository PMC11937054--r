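test_that("ICAD reproduces the published footnote arithmetic", {
  expect_equal(icad(3168, 1402, 0.448, 0.421), 1766 / 0.027)
  expect_equal(trunc_pound(icad(3168, 1402, 0.448, 0.421)), 65407)
  expect_equal(trunc_pound(icad(6112, 5576, 0.461, 0.460)), 536000)
  expect_equal(icad(500, 500, 0.5, 0.4), 0)
  expect_error(icad(100, 50, 0.3, 0.3), "undefined")
})

test_that("net monetary benefit and implied WTP follow their definitions", {
  expect_equal(nmb(1402, 0.421, wtp = 8613), 8613 * 0.421 - 1402)
  expect_equal(round(nmb(1402, 0.421, wtp = 8613), 2), 2224.07)
  expect_equal(nmb(1402, 0.421, wtp = 0), -1402)
  expect_error(nmb(100, 0.5, wtp = -1), "wtp")

  expect_equal(round(implied_wtp(2429, 0.282)), 8613)
  expect_equal(round(implied_wtp(1027, 0.139)), 7388)
  expect_equal(implied_wtp(500, 1), 500)
  expect_error(implied_wtp(500, 0), "yield")
})

test_that("base-case incremental table reproduces the published analysis", {
  tab <- dominance_table(reference_results("base"))
  expect_equal(frontier_strategies(tab),
               c("2nd-line ES", "Last-resort ES", "1st-line GS",
                 "Last-resort GS"))
  expect_equal(tab$dominated_by[tab$strategy == "Standard genetic testing"],
               "2nd-line ES")
  expect_equal(tab$dominated_by[tab$strategy == "2nd-line GS"],
               "Last-resort ES")
  # increments against the most recent frontier member
  expect_equal(tab$incremental_cost,
               c(NA, 1027, 1766, 2026, 2408, 536))
  expect_equal(round(100 * tab$incremental_yield, 1),
               c(NA, -13.9, 2.7, -0.1, 1.2, 0.1))
  expect_equal(trunc_pound(tab$icad[tab$status == "frontier"][-1]),
               c(65407, 200666, 536000))
  # frontier ICADs strictly increase (concavity)
  expect_true(all(diff(tab$icad[tab$status == "frontier"][-1]) > 0))
})

test_that("low-GS incremental table shows extended dominance of last-resort ES", {
  tab <- dominance_table(reference_results("low_gs"))
  expect_equal(frontier_strategies(tab),
               c("2nd-line ES", "1st-line GS", "Last-resort GS"))
  expect_equal(tab$status[tab$strategy == "Last-resort ES"],
               "extended_dominated")
  expect_equal(tab$dominated_by[tab$strategy == "Last-resort ES"],
               "1st-line GS")
  expect_equal(tab$dominated_by[tab$strategy == "2nd-line GS"],
               "Last-resort ES")
  expect_equal(tab$incremental_cost, c(NA, 1027, 1766, 2255, 2379, 1152))
  expect_equal(trunc_pound(tab$icad[tab$status == "frontier"][-1]),
               c(61000, 1152000))
})

test_that("degenerate and synthetic dominance cases behave", {
  one <- dominance_table(tibble::tibble(strategy = "only", cost = 100,
                                        yield = 0.2))
  expect_equal(one$status, "frontier")
  expect_true(is.na(one$incremental_cost))

  # middle strategy excluded by extended dominance
  tri <- dominance_table(tibble::tibble(
    strategy = c("A", "B", "C"),
    cost = c(100, 200, 210),
    yield = c(0.10, 0.15, 0.30)
  ))
  expect_equal(tri$status[tri$strategy == "B"], "extended_dominated")
  expect_equal(frontier_strategies(tri), c("A", "C"))

  expect_error(dominance_table(tibble::tibble(
    strategy = c("A", "A"), cost = c(1, 2), yield = c(0.1, 0.2))), "unique")
})

test_that("frontier matches the exact lambda-feasibility oracle", {
  for (seed in 1:100) {
    res <- random_results(n = sample(3:8, 1), seed = seed)
    tab <- dominance_table(res)
    want <- res$strategy[oracle_frontier(res$cost, res$yield)]
    expect_setequal(frontier_strategies(tab), want)
  }
})

test_that("adding a strictly dominated strategy never changes the frontier", {
  for (seed in 101:130) {
    res <- random_results(n = 6, seed = seed)
    tab <- dominance_table(res)
    # a strategy worse than an existing one on both axes
    k <- sample(nrow(res), 1)
    worse <- tibble::tibble(strategy = "worse", cost = res$cost[k] + 1,
                            yield = max(res$yield[k] - 0.001, 0))
    tab2 <- dominance_table(rbind(res, worse))
    expect_equal(frontier_strategies(tab2), frontier_strategies(tab))
    expect_equal(tab2$icad[tab2$status == "frontier"],
                 tab$icad[tab$status == "frontier"])
  }
})

test_that("sweeping WTP visits frontier members in cost order", {
  m <- canonical_model()
  res <- evaluate_model(m)
  tab <- dominance_table(res)
  lambdas <- c(0, 10^seq(2, 8, by = 0.1))
  seen <- unique(vapply(lambdas, function(l) {
    suppressWarnings(optimal_strategy(m, l, results = res))
  }, ""))
  front <- frontier_strategies(tab)
  # every NMB optimum is a frontier member, visited in cost order
  expect_true(all(seen %in% front))
  expect_equal(seen, front[match(seen, front)])
  expect_false(is.unsorted(match(seen, front)))
})
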