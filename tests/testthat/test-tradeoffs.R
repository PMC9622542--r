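# Consequence tables, 20/60/20 color coding, irrelevant-criterion
# elimination and dominance screening.

two_region_table <- function() {
  make_table(TN = c(10, 20, 30, 40), TP = c(1, 2, 3, 4),
             AG = c(50, 60, 70, 80), EHA = c(5, 10, 15, 20),
             FP = c(1, 1, 0, 0), WS = c(10, 20, 30, 40),
             CF = c(2, 4, 6, 8),
             region = c("R1", "R1", "R2", "R2"))
}

test_that("consequence cells are category means per region", {
  tab <- two_region_table()
  sets <- build_priority_sets(top_wq = c("1", "3"), top_cr = c("2", "3"))
  # overall members: wq {1}, cr {2}, both {3}
  ct <- consequence_table(tab, sets, "overall")
  expect_equal(ct$means["R1", "TN"], mean(c(10, 20)))
  expect_equal(ct$means["R2", "TN"], 30)      # single member = raw measure
  expect_equal(ct$means["R1", "FP"], 1)       # binary mean is a proportion
  # water-quality category covers wq + both only
  ctwq <- consequence_table(tab, sets, "water_quality")
  expect_equal(ctwq$means["R1", "TN"], 10)
  # a region with no category members is omitted, not zero-filled
  ctcr <- consequence_table(tab, sets, "climate_resilience")
  expect_equal(rownames(ctcr$means), c("R1", "R2"))
  sets2 <- build_priority_sets(top_wq = "1", top_cr = "1")
  ct2 <- consequence_table(tab, sets2, "overall")
  expect_equal(rownames(ct2$means), "R1")
  expect_error(consequence_table(tab, sets, "bogus"))
})

test_that("20/60/20 placement codes follow the percentile cuts", {
  codes5 <- function(v) {
    ct <- structure(list(means = matrix(v, 5, 1,
                                        dimnames = list(paste0("R", 1:5),
                                                        "WS")),
                         category = "overall",
                         n_members = rep(1, 5)),
                    class = "consequence_table")
    color_code(ct, coding = "raw")$codes[, 1]
  }
  # strictly increasing column: exactly one favorable, one unfavorable
  cc <- codes5(c(10, 20, 30, 40, 50))
  expect_equal(unname(cc), c("unfavorable", "middle", "middle", "middle",
                             "favorable"))
  # equal cells: no spread, all middle
  expect_true(all(codes5(rep(7, 5)) == "middle"))
})

test_that("a single-region table codes all cells middle", {
  ct <- structure(list(means = matrix(1:3, 1, 3,
                                      dimnames = list("R1",
                                                      c("TN", "TP", "AG"))),
                       category = "overall", n_members = 1),
                  class = "consequence_table")
  expect_message(cc <- color_code(ct, coding = "raw"), "single-region")
  expect_true(all(cc$codes == "middle"))
})

test_that("scaled coding transforms nonlinear criteria monotonically", {
  tab <- gen_alternatives(synth_config(n_alternatives = 200, seed = 29))$table
  sets <- prioritize_alternatives(tab, k = 60)
  ct <- consequence_table(tab, sets, "overall")
  raw <- color_code(ct, coding = "raw")
  scl <- color_code(ct, reference = tab, coding = "scaled")
  # linear criteria are untouched by the ECDF transform
  for (j in c("AG", "EHA", "FP", "WS"))
    expect_equal(raw$codes[, j], scl$codes[, j])
  # ECDF transform is monotone: favorable cells still hold the largest means
  for (j in c("TN", "TP", "CF")) {
    fav <- scl$codes[, j] == "favorable"
    if (any(fav) && any(!fav))
      expect_gt(min(ct$means[fav, j]), max(ct$means[!fav, j]))
  }
})

test_that("uniform criteria are dropped and recorded", {
  codes <- matrix(c("middle", "middle", "favorable", "unfavorable"), 2, 2,
                  dimnames = list(c("R1", "R2"), c("EHA", "WS")))
  coded <- structure(list(codes = codes, dropped = character(0),
                          category = "overall"),
                     class = "coded_table")
  out <- drop_irrelevant(coded)
  expect_equal(out$dropped, "EHA")
  expect_equal(colnames(out$codes), "WS")
  allsame <- coded
  allsame$codes[] <- "middle"
  expect_warning(empty <- drop_irrelevant(allsame), "none retained")
  expect_equal(ncol(empty$codes), 0L)
})

test_that("dominance follows the coded ordering", {
  # X equal to Y on four criteria and better on two -> X dominates Y
  codes <- rbind(X = c("middle", "middle", "favorable", "middle",
                       "favorable", "favorable"),
                 Y = c("middle", "middle", "favorable", "middle",
                       "middle", "middle"))
  colnames(codes) <- c("TN", "TP", "AG", "EHA", "WS", "CF")
  coded <- structure(list(codes = codes, dropped = character(0),
                          category = "overall"),
                     class = "coded_table")
  d <- dominance(coded)
  expect_equal(d$pairs, data.frame(dominator = "X", dominated = "Y",
                                   stringsAsFactors = FALSE))
  expect_equal(d$non_dominated, "X")
  expect_equal(d$dominator_of_all, "X")
  # identical rows dominate neither way
  codes2 <- codes; codes2["X", ] <- codes2["Y", ]
  coded2 <- structure(list(codes = codes2, dropped = character(0),
                           category = "overall"),
                      class = "coded_table")
  d2 <- dominance(coded2)
  expect_equal(nrow(d2$pairs), 0L)
  expect_setequal(d2$non_dominated, c("X", "Y"))
  expect_true(is.na(d2$dominator_of_all))
})

test_that("dominance matches the all-pairs oracle on random tables", {
  set.seed(10)
  lvl <- c(unfavorable = 1, middle = 2, favorable = 3)
  for (trial in 1:20) {
    coded <- random_coded_table(4, 5)
    d <- dominance(coded)
    lv <- matrix(lvl[coded$codes], 4, 5, dimnames = dimnames(coded$codes))
    oracle <- oracle_dominance_pairs(lv)
    expect_equal(d$pairs[order(d$pairs$dominator, d$pairs$dominated), ],
                 oracle[order(oracle$dominator, oracle$dominated), ],
                 ignore_attr = TRUE)
  }
})

test_that("an all-favorable region dominates any imperfect region", {
  codes <- rbind(A = rep("favorable", 4),
                 B = c("favorable", "favorable", "middle", "favorable"),
                 C = rep("favorable", 4))
  colnames(codes) <- paste0("C", 1:4)
  coded <- structure(list(codes = codes, dropped = character(0),
                          category = "overall"),
                     class = "coded_table")
  d <- dominance(coded)
  expect_true(all(c("A", "C") %in% d$non_dominated))
  expect_true("B" %in% d$pairs$dominated)
})

test_that("dropping uniform criteria never changes the dominance relation", {
  set.seed(11)
  for (trial in 1:20) {
    coded <- random_coded_table(4, 4)
    coded$codes <- cbind(coded$codes,
                         U1 = rep("middle", 4), U2 = rep("favorable", 4))
    before <- dominance(coded)
    after <- dominance(drop_irrelevant(coded))
    expect_equal(before$pairs, after$pairs)
    expect_equal(before$non_dominated, after$non_dominated)
  }
})
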