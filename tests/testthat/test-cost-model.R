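# Direct two-part data generator for parameter-recovery checks: binary NCD
# indicator, P(positive) = p, positive cost ~ lognormal(a + b*ncd, sdlog).
two_part_fixture <- function(n, seed, p = 0.7, b = log(1.6), a = log(30),
                             sdlog = 0.8) {
  set.seed(seed)
  ncd <- rbinom(n, 1, 0.5)
  age <- runif(n, 20, 80)
  pos <- rbinom(n, 1, p) == 1
  cost <- ifelse(pos, rlnorm(n, a + b * ncd, sdlog), 0)
  data.frame(respondent_id = sprintf("R%06d", seq_len(n)),
             oop_cost = cost,
             cause = factor(ifelse(ncd == 1, "NCD", "CD"), levels = c("CD", "NCD")),
             age = age, stringsAsFactors = FALSE)
}

test_that("part-2 recovers the planted NCD-vs-CD log cost ratio", {
  d <- two_part_fixture(30000, seed = 101)
  m <- fit_two_part(d, c("cause", "age"))
  est <- coef(m$part2)["causeNCD"]
  se <- sqrt(diag(vcov(m$part2)))["causeNCD"]
  expect_lt(abs(est - log(1.6)), 3 * se)
  expect_lt(abs(est - log(1.6)) / log(1.6), 0.05)
  # part 1 recovers the participation probability
  p_hat <- mean(predict_cost(m, d) / predict(m$part2, newdata = d,
                                             type = "response"))
  expect_lt(abs(p_hat - 0.7), 0.02)
})

test_that("lognormal part-2 with smearing matches the gamma fit on the mean scale", {
  d <- two_part_fixture(8000, seed = 102)
  mg <- fit_two_part(d, "cause", family = "gamma")
  ml <- fit_two_part(d, "cause", family = "lognormal")
  pg <- predict_cost(mg, d)
  pl <- predict_cost(ml, d)
  expect_lt(max(abs(pg - pl) / pg), 0.05)
})

test_that("degenerate cost patterns are handled explicitly", {
  d <- two_part_fixture(500, seed = 103)
  dp <- d[d$oop_cost > 0, ]
  mp <- fit_two_part(dp, "cause")
  expect_identical(mp$p_const, 1)
  expect_true(all(predict_cost(mp, dp) > 0))

  dz <- d
  dz$oop_cost <- 0
  mz <- fit_two_part(dz, "cause")
  expect_identical(mz$p_const, 0)
  expect_true(all(predict_cost(mz, dz) == 0))
})

test_that("expected cost is p times the conditional mean", {
  # half zeros, all positive costs exactly 100: p-hat = 0.5, mean = 100
  d <- data.frame(oop_cost = rep(c(0, 100), each = 50), x = 1,
                  respondent_id = sprintf("R%03d", 1:100))
  m <- fit_two_part(d, character(0))
  pred <- predict_cost(m, d)
  expect_equal(pred, rep(50, 100), tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(pred >= 0))
  expect_length(predict_cost(m, d[0, ]), 0)
})

test_that("out-of-support covariates are predicted but flagged", {
  d <- two_part_fixture(1000, seed = 104)
  m <- fit_two_part(d, c("cause", "age"))
  new <- d[1:3, ]
  new$age[1] <- 200
  expect_warning(pred <- predict_cost(m, new), "support")
  expect_identical(attr(pred, "extrapolated"), c(TRUE, FALSE, FALSE))
  expect_true(all(is.finite(pred)))
})

test_that("separation in part 1 falls back to a penalized fit", {
  set.seed(105)
  d <- data.frame(oop_cost = c(rep(0, 40), rlnorm(40, 3, 0.5)),
                  z = rep(c(0, 1), each = 40),
                  respondent_id = sprintf("R%03d", 1:80))
  expect_warning(m <- fit_two_part(d, "z"), "separation|ridge")
  pred <- suppressWarnings(predict_cost(m, d))
  expect_true(all(is.finite(pred)))
  expect_true(all(pred >= 0))
})

test_that("covariate selection by grouped-CV RMSE never picks intercept-only under signal", {
  d <- two_part_fixture(3000, seed = 106, b = log(3), sdlog = 0.5)
  d$noise1 <- rnorm(nrow(d))
  d$noise2 <- rnorm(nrow(d))
  sets <- list(truth = c("cause"),
               truth_plus_noise = c("cause", "noise1", "noise2"),
               intercept_only = character(0))
  sel <- select_covariates(sets, d, k_folds = 5)
  expect_false(sel$chosen_name == "intercept_only")
  expect_identical(names(which.min(sel$rmse)), sel$chosen_name)
  # one candidate -> returned unchanged, no CV run
  one <- select_covariates(sets["truth"], d)
  expect_identical(one$chosen, c("cause"))
  # identical candidates -> first in listed order
  tie <- select_covariates(list(a = "cause", b = "cause"), d, k_folds = 3)
  expect_identical(tie$chosen_name, "a")
})

test_that("currency conversion is linear, positive and order-preserving", {
  expect_identical(convert_currency(c(10, 0), 1), c(10, 0))
  expect_identical(convert_currency(c(10, 0), 2), c(20, 0))
  conv <- currency_conversion("A", 2009, 0.35)
  x <- c(5, 7.5, NA, 0)
  expect_equal(convert_currency(x, conv), x * 0.35)
  a <- runif(50); b <- a + runif(50)
  expect_true(all(convert_currency(a, conv) < convert_currency(b, conv)))
  expect_error(convert_currency(1, -1), "positive")
  expect_error(currency_conversion("A", 2009, 0), "positive")
})

test_that("annual OOP combines observed and predicted values by the stated rule", {
  resp <- data.frame(respondent_id = c("R1", "R2"),
                     household_id = c("H1", "H2"), stringsAsFactors = FALSE)
  # R1: 4 visits, causes NCD,NCD,CD observed + CD imputed;
  # costs: observed 100, predicted 80,80,80
  visits <- data.frame(
    respondent_id = rep("R1", 4),
    cause = c("NCD", "NCD", "CD", "CD"),
    cost = c(100, 80, 80, 80), stringsAsFactors = FALSE)
  out <- annual_oop_by_disease(resp, visits)
  r1 <- out[out$respondent_id == "R1", ]
  expect_equal(r1$NCD, 180)
  expect_equal(r1$CD, 160)
  expect_equal(r1$total, 340)
  # zero-visit respondent gets an all-zero row
  r2 <- out[out$respondent_id == "R2", ]
  expect_equal(r2$total, 0)
  expect_true(all(r2[, cause_groups()] == 0))

  single <- annual_oop_by_disease(
    resp[1, ], data.frame(respondent_id = "R1", cause = "NCD", cost = 120))
  expect_equal(single$NCD, 120)
  expect_equal(single$total, 120)

  expect_error(annual_oop_by_disease(
    resp, data.frame(respondent_id = "R1", cause = NA, cost = 5)),
    "pipeline-order")
})

test_that("group totals conserve the grand total on random fixtures", {
  sim <- small_sim(seed = 107)
  tv <- sim$truth$visits
  annual <- annual_oop_by_disease(
    sim$respondents, data.frame(respondent_id = tv$respondent_id,
                                cause = tv$true_cause, cost = tv$true_oop))
  expect_true(all(abs(rowSums(annual[, cause_groups()]) - annual$total) < 1e-6))
  hh <- household_oop_by_disease(annual, sim$households)
  expect_true(all(abs(rowSums(hh[, cause_groups()]) - hh$total) < 1e-6))
  expect_equal(sum(hh$total), sum(tv$true_oop), tolerance = 1e-9)
})
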