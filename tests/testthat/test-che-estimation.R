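random_hh_fixture <- function(n, seed, integer_weights = FALSE) {
  set.seed(seed)
  data.frame(
    household_id = sprintf("H%04d", seq_len(n)),
    country = "A",
    stratum = sprintf("S%d", sample(1:4, n, replace = TRUE)),
    psu = sprintf("P%d", sample(1:12, n, replace = TRUE)),
    weight = if (integer_weights) sample(1:9, n, replace = TRUE)
             else rexp(n) + 0.1,
    size = sample(1:7, n, replace = TRUE),
    expenditure = rlnorm(n, 8, 0.6),
    food_expenditure = NA, wealth_quintile = sample(1:5, n, replace = TRUE),
    stringsAsFactors = FALSE) -> d
  d$food_expenditure <- d$expenditure * rbeta(n, 5, 6)
  d
}

test_that("food poverty line matches the textbook band on simple fixtures", {
  hh <- data.frame(household_id = sprintf("H%03d", 1:100),
                   food_expenditure = 1:100, size = 1, weight = 1)
  expect_equal(food_poverty_line(hh), mean(46:55))  # = 50.5
  hh$food_expenditure <- 42
  expect_equal(food_poverty_line(hh), 42)
  expect_error(food_poverty_line(hh[0, ]), "empty")
})

test_that("food poverty line agrees with the brute-force weighted-band oracle", {
  for (seed in 1:8) {
    hh <- random_hh_fixture(60, seed = 200 + seed)
    for (beta in c(1, 0.56)) {
      expect_equal(
        food_poverty_line(hh, equivalence_beta = beta),
        oracle_food_line(hh$food_expenditure, hh$size, hh$weight, beta),
        tolerance = 1e-12)
    }
    # beta changes the ranking and hence the line
    expect_false(isTRUE(all.equal(food_poverty_line(hh, equivalence_beta = 1),
                                  food_poverty_line(hh, equivalence_beta = 0.56))))
  }
})

test_that("capacity-to-pay follows the subsistence arithmetic and conventions", {
  hh <- data.frame(household_id = c("H1", "H2", "H3", "H4"),
                   expenditure = c(1200, 1200, 200, -5),
                   food_expenditure = c(300, 150, 220, 100),
                   size = c(4, 4, 4, 2), stringsAsFactors = FALSE)
  res <- suppressMessages(capacity_to_pay(hh, line = 50, equivalence_beta = 1))
  expect_equal(res$subsistence[1], 200)
  expect_equal(res$capacity_to_pay[1], 1000)          # 1200 - 200
  # food below subsistence: actual food spending is the subsistence proxy
  expect_equal(res$capacity_to_pay[2], 1050)          # 1200 - 150
  # expenditure at/below subsistence: floored at epsilon
  expect_true(res$floored[3])
  expect_equal(res$capacity_to_pay[3], 0.01)
  expect_true(res$excluded[4])
  expect_true(all(res$capacity_to_pay <= pmax(res$expenditure, 0.01)))
})

test_that("CHE flag uses a strict 40% inequality", {
  ctp <- suppressMessages(capacity_to_pay(
    data.frame(household_id = c("H1", "H2", "H3"),
               expenditure = c(1100, 1100, 1100),
               food_expenditure = c(100, 100, 100), size = 1), line = 100))
  expect_equal(ctp$capacity_to_pay, rep(1000, 3))
  oop <- data.frame(household_id = c("H1", "H2", "H3"),
                    total = c(450, 400, 0))
  fl <- flag_che(oop, ctp, threshold = 0.40)
  expect_identical(fl$che, c(TRUE, FALSE, FALSE))
  expect_error(flag_che(oop, ctp, threshold = 0), "threshold")
})

test_that("attribution matches the exhaustive share-grid oracle including the 0.75 boundary", {
  grid <- expand.grid(ncd = seq(0, 1, 0.05), cd = seq(0, 1, 0.05))
  grid <- grid[grid$ncd + grid$cd <= 1, ]
  grid$inj <- 1 - grid$ncd - grid$cd
  scale <- 173.3  # attribution is scale-free
  case_oop <- data.frame(NCD = grid$ncd * scale, CD = grid$cd * scale,
                         INJURY = grid$inj * scale)
  got <- attribute_che(case_oop)
  want <- vapply(seq_len(nrow(grid)),
                 function(i) oracle_attribution(c(grid$ncd[i], grid$cd[i],
                                                  grid$inj[i])),
                 character(1))
  expect_identical(got, want)
  # explicit boundary and stated examples
  expect_identical(attribute_che(data.frame(NCD = 75, CD = 25, INJURY = 0)),
                   "UNALLOCABLE")   # exactly 75% is not "more than 75%"
  expect_identical(attribute_che(data.frame(NCD = 80, CD = 20, INJURY = 0)), "NCD")
  expect_identical(attribute_che(data.frame(NCD = 60, CD = 40, INJURY = 0)),
                   "UNALLOCABLE")
  expect_identical(attribute_che(data.frame(NCD = 1, CD = 0, INJURY = 0)), "NCD")
  expect_identical(attribute_che(data.frame(NCD = 0, CD = 0, INJURY = 0)),
                   "UNALLOCABLE")
  # non-disease spending is excluded from the denominator by construction:
  # only the three disease columns enter
  expect_identical(attribute_che(data.frame(NCD = 10, CD = 1, INJURY = 0,
                                            PAIN = 500)), "NCD")
})

test_that("weighted CHE shares reproduce hand-computed tallies and sum to 100", {
  cases <- data.frame(
    household_id = sprintf("H%d", 1:6), country = "A",
    weight = c(1, 1, 2, 3, 1, 1),
    che = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    category = c("NCD", "CD", "NCD", "CD", NA, NA),
    stringsAsFactors = FALSE)
  s <- che_share_by_disease(cases)
  expect_equal(s$share_cases[s$category == "NCD"], 100 * 3 / 7)
  expect_equal(s$share_cases[s$category == "CD"], 100 * 4 / 7)
  expect_equal(s$share_households[s$category == "NCD"], 100 * 3 / 9)
  expect_equal(sum(s$share_cases), 100, tolerance = 1e-9)

  eq <- cases
  eq$weight <- 1
  se <- che_share_by_disease(eq)
  expect_equal(se$share_cases[se$category %in% c("NCD", "CD")], c(50, 50))

  none <- cases
  none$che <- FALSE
  none$category <- NA
  expect_message(sn <- che_share_by_disease(none), "no CHE cases")
  expect_true(all(is.na(sn$share_cases)))
  expect_equal(sum(sn$share_households), 0)
})

test_that("wealth-quintile breakdown recovers planted patterns", {
  set.seed(301)
  n <- 1500
  q <- sample(1:5, n, replace = TRUE)
  # planted gradient: CHE probability decreases with wealth
  p <- 0.25 - 0.04 * q
  che <- rbinom(n, 1, p) == 1
  cases <- data.frame(household_id = sprintf("H%d", 1:n), country = "A",
                      weight = 1, che = che,
                      category = ifelse(che, "NCD", NA),
                      wealth_quintile = q, stringsAsFactors = FALSE)
  bq <- che_by_wealth_quintile(cases)
  rates <- unique(bq[, c("wealth_quintile", "che_rate")])$che_rate
  expect_true(all(diff(rates) < 0.06 * 100))  # weakly decreasing up to noise
  expect_gt(rates[1], rates[5])

  only1 <- cases
  only1$che <- only1$che & q == 1
  only1$category <- ifelse(only1$che, "NCD", NA)
  b1 <- che_by_wealth_quintile(only1)
  expect_true(all(b1$che_rate[b1$wealth_quintile > 1] == 0))
  expect_gt(b1$che_rate[b1$wealth_quintile == 1][1], 0)
})

test_that("bootstrap is seeded, respects degeneracy and resamples PSUs within strata", {
  hh <- random_hh_fixture(200, seed = 302)
  hh$y <- rnorm(200)
  est <- function(d) weighted.mean(d$y, d$weight)
  b1 <- suppressMessages(bootstrap_ui(est, hh, B = 50, seed = 5))
  b2 <- suppressMessages(bootstrap_ui(est, hh, B = 50, seed = 5))
  expect_identical(b1, b2)
  expect_lte(b1$lower, b1$estimate)
  expect_gte(b1$upper, b1$estimate)

  # degenerate: estimator constant -> zero-width interval
  bc <- suppressMessages(bootstrap_ui(function(d) 3.14, hh, B = 20, seed = 1))
  expect_equal(bc$lower, 3.14)
  expect_equal(bc$upper, 3.14)

  # single-PSU strata are merged, not dropped
  hh2 <- hh
  hh2$stratum[1] <- "S9"
  hh2$psu[1] <- "Plone"
  expect_message(bootstrap_ui(est, hh2, B = 10, seed = 1), "merging")
})

test_that("pairing NCD CHE shares with DALY shares is a validated join", {
  che <- data.frame(country = "China", ncd_share_che = 0.38)
  daly <- data.frame(country = c("China", "Ghana"),
                     ncd_daly_share_adults_20plus = c(0.84, 0.48))
  out <- ncd_share_vs_dalys(che, daly)
  expect_identical(out$ncd_share_che, 0.38)
  expect_identical(out$ncd_daly_share, 0.84)

  expect_identical(nrow(ncd_share_vs_dalys(che[0, ], daly)), 0L)
  expect_error(ncd_share_vs_dalys(che, rbind(daly, daly[1, ])), "duplicate")
  expect_error(ncd_share_vs_dalys(data.frame(country = "India",
                                             ncd_share_che = 0.25), daly),
               "India")
  daly$ncd_daly_share_adults_20plus[1] <- 1.5
  expect_error(ncd_share_vs_dalys(che, daly), "0,1")
})

test_that("CHE flags agree with a brute-force row-by-row recomputation", {
  sim <- small_sim(seed = 303)
  tru <- truth_che(sim)
  hh <- sim$households
  line <- food_poverty_line(hh)
  oop <- tru$household_oop
  for (i in seq_len(nrow(hh))) {
    sub <- min(line * hh$size[i], hh$food_expenditure[i])
    ctp_i <- max(hh$expenditure[i] - sub, 0.01)
    want <- if (hh$expenditure[i] <= 0) NA else
      oop$total[oop$household_id == hh$household_id[i]] > 0.4 * ctp_i
    got <- tru$cases$che[tru$cases$household_id == hh$household_id[i]]
    expect_identical(got, want)
  }
})
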