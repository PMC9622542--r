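# Weight scenarios, value and distance aggregation, rank assignment,
# scenario aggregation and top-k selection.

test_that("weight apportionment matches the two-objective scheme", {
  scenarios <- make_weight_scenarios()
  wq60 <- Filter(function(s) s$objective == "water_quality" &&
                   s$emphasis == 0.60, scenarios)[[1]]
  expect_equal(unname(wq60$weights[c("TN", "TP", "AG", "EHA", "FP")]),
               rep(0.12, 5))
  expect_equal(unname(wq60$weights[c("WS", "CF")]), rep(0.2, 2))
  for (s in scenarios) expect_equal(sum(s$weights), 1)
})

test_that("the default schedule yields seven iterations per objective", {
  scenarios <- make_weight_scenarios()
  obj <- vapply(scenarios, `[[`, character(1), "objective")
  expect_equal(unname(table(obj)["water_quality"]), 7L)
  expect_equal(unname(table(obj)["climate_resilience"]), 7L)
  emph <- vapply(scenarios, `[[`, numeric(1), "emphasis")
  expect_setequal(round(unique(emph), 2), seq(0.60, 0.90, 0.05))
})

test_that("degenerate objective groupings are rejected", {
  specs <- default_criterion_specs()
  specs$group <- "water_quality"
  expect_error(make_weight_scenarios(specs), "two non-empty")
})

test_that("value scores are the weighted sums of scaled criteria", {
  x <- matrix(c(0.5, 1, 1, 0), 2, 2, dimnames = list(1:2, c("A", "B")))
  sm <- structure(list(values = x, orientation = "value",
                       worst = c(A = 0, B = 0), best = c(A = 1, B = 1)),
                  class = "scaled_matrix")
  v <- value_score(sm, c(A = 0.3, B = 0.7))
  expect_equal(unname(v[1]), 0.85)     # 0.3 * 0.5 + 0.7 * 1
  expect_equal(unname(v[2]), 0.3)
  expect_error(value_score(sm, c(A = 0.3, B = 0.3)), "sum to 1")
  sm$orientation <- "distance"
  expect_error(value_score(sm, c(A = 0.3, B = 0.7)), "value-oriented")
})

test_that("distance scores follow the printed power-sum form", {
  x <- matrix(c(0.5, 0, 1, 0), 2, 2, dimnames = list(1:2, c("A", "B")))
  sm <- structure(list(values = x, orientation = "distance",
                       worst = c(A = 0, B = 0), best = c(A = 1, B = 1)),
                  class = "scaled_matrix")
  d <- distance_score(sm, c(A = 0.3, B = 0.7), p = 2)
  expect_equal(unname(d[1]), 0.3^2 * 0.5^2 + 0.7^2 * 1^2)  # 0.0225 + 0.49
  expect_equal(unname(d[2]), 0)                            # ideal alternative
  dlp <- distance_score(sm, c(A = 0.3, B = 0.7), p = 2, form = "lp")
  expect_equal(unname(dlp), sqrt(unname(d)))
  expect_error(distance_score(sm, c(A = 0.3, B = 0.7), p = 0.5), ">= 1")
})

test_that("with p = 1 the distance score is the value complement", {
  tab <- gen_alternatives(synth_config(n_alternatives = 40, seed = 21))$table
  m <- criteria_matrix(tab)
  sv <- scale_matrix(m, orientation = "value")
  sd_ <- scale_matrix(m, orientation = "distance")
  w <- make_weight_scenarios()[[1]]$weights
  expect_equal(distance_score(sd_, w, p = 1),
               1 - value_score(sv, w))
})

test_that("ranks average ties and match the sort-and-assign oracle", {
  expect_equal(rank_alternatives(c(3, 1, 2), "higher"), c(1, 3, 2))
  expect_equal(rank_alternatives(rep(7, 3), "higher"), rep(2, 2 + 1))
  set.seed(6)
  for (trial in 1:5) {
    s <- sample(rnorm(30), 50, replace = TRUE)  # guarantees some ties
    expect_equal(rank_alternatives(s, "higher"), oracle_rank(s, TRUE))
    expect_equal(rank_alternatives(s, "lower"), oracle_rank(s, FALSE))
    expect_equal(sum(rank_alternatives(s, "higher")), 50 * 51 / 2)
  }
  expect_error(rank_alternatives(c(1, NA)), "finite")
})

test_that("scenario aggregation averages the 14 ranks per alternative", {
  tab <- gen_alternatives(synth_config(n_alternatives = 100, seed = 22))$table
  runs <- run_ranking_sweep(tab)
  expect_length(runs, 28L)
  wq <- Filter(function(r) r$objective == "water_quality", runs)
  mean_rank <- aggregate_scenario(wq)
  manual <- rowMeans(sapply(wq, `[[`, "ranks"))
  expect_equal(mean_rank, manual)
  expect_error(aggregate_scenario(runs), "single objective")
  expect_error(aggregate_scenario(wq[1:5]), "incomplete")
})

test_that("top_k returns the smallest mean ranks with id tie-breaks", {
  mr <- c(`1` = 3, `2` = 1, `3` = 2, `4` = 5, `5` = 4)
  expect_equal(top_k(mr, 100), c("2", "3", "1", "5", "4"))
  expect_equal(top_k(mr, 2), c("2", "3"))
  tied <- c(`10` = 1, `2` = 2, `11` = 2)
  expect_equal(top_k(tied, 2), c("10", "2"))  # lower id admitted at the tie
})

test_that("planted dominants score best under every scenario and method", {
  ga <- gen_alternatives(synth_config(n_alternatives = 150, seed = 23))
  for (p in c(1, 2, 3)) {
    runs <- run_ranking_sweep(ga$table, p = p)
    for (r in runs)
      expect_equal(unname(r$ranks[as.character(ga$truth$dominant_ids)]), 1)
  }
})

test_that("rising water-quality emphasis never demotes a WQ specialist", {
  tab <- gen_alternatives(synth_config(n_alternatives = 80, seed = 24,
                                       n_planted_dominant = 0))$table
  # make alternative 1 best on every water-quality criterion, worst on both
  # climate-resilience criteria
  for (col in c("TN_kg_yr", "TP_kg_yr", "AG_pct", "EHA_pct"))
    tab[[col]][1] <- max(tab[[col]]) * 1.01
  tab$FP[1] <- 1L
  tab$WS_pct[1] <- 0
  tab$CF_pct[1] <- 0
  runs <- run_ranking_sweep(tab)
  wq <- Filter(function(r) r$objective == "water_quality", runs)
  emph <- vapply(wq, `[[`, numeric(1), "emphasis")
  for (method in c("value", "distance")) {
    sel <- vapply(wq, `[[`, character(1), "method") == method
    r1 <- vapply(wq[sel], function(r) unname(r$ranks["1"]), numeric(1))
    expect_true(all(diff(r1[order(emph[sel])]) <= 0))
  }
})

test_that("pipeline scores match a brute-force loop implementation", {
  set.seed(7)
  for (trial in 1:5) {
    x <- matrix(runif(8 * 3), 8, 3, dimnames = list(1:8, c("A", "B", "C")))
    w <- runif(3); w <- w / sum(w); names(w) <- c("A", "B", "C")
    smv <- structure(list(values = x, orientation = "value",
                          worst = rep(0, 3), best = rep(1, 3)),
                     class = "scaled_matrix")
    smd <- structure(list(values = x, orientation = "distance",
                          worst = rep(0, 3), best = rep(1, 3)),
                     class = "scaled_matrix")
    expect_equal(unname(value_score(smv, w)), oracle_value(x, w),
                 tolerance = 1e-12)
    expect_equal(unname(distance_score(smd, w, p = 2)),
                 oracle_distance(x, w, 2), tolerance = 1e-12)
  }
})
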