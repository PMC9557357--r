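test_that("visits-to-CHE matches hand-worked and brute-force cases", {
  expect_identical(visits_to_che(500, 400), 1L)
  expect_identical(visits_to_che(c(50, 30, 20), 60), 2L)
  expect_identical(visits_to_che(rep(10, 9), 85), 9L)
  expect_error(visits_to_che(c(10, 10), 25), "cannot be a CHE case")
  expect_error(visits_to_che(c(10, 10), 20), "cannot be a CHE case")  # strict
})

test_that("greedy k equals the exhaustive minimum crossing-subset size", {
  set.seed(401)
  for (i in 1:40) {
    n <- sample(1:12, 1)
    costs <- round(rexp(n, 1 / 50), 2)
    threshold <- runif(1, 0, sum(costs) * 0.95)
    if (sum(costs) <= threshold) next
    expect_identical(visits_to_che(costs, threshold),
                     as.integer(oracle_min_visits(costs, threshold)))
  }
})

test_that("k is invariant to permutations of equal-cost visits", {
  costs <- c(40, 40, 40, 10, 10)
  for (i in 1:10) {
    expect_identical(visits_to_che(sample(costs), 75), 2L)
  }
})

test_that("the case table builds one_visit / five_plus exclusively", {
  cases <- data.frame(household_id = c("H1", "H2", "H3"),
                      che = c(TRUE, TRUE, FALSE),
                      capacity_to_pay = c(1000, 1000, 500),
                      stringsAsFactors = FALSE)
  vc <- data.frame(household_id = c("H1", rep("H2", 6), "H3"),
                   cost = c(500, rep(85, 6), 10))
  k <- visits_to_che_table(cases, vc, threshold = 0.40)
  expect_identical(nrow(k), 2L)   # CHE households only
  expect_identical(k$k, c(1L, 5L))
  expect_identical(k$one_visit, c(TRUE, FALSE))
  expect_identical(k$five_plus, c(FALSE, TRUE))
  expect_false(any(k$one_visit & k$five_plus))
})

test_that("OLS with a single binary covariate returns the difference in group means", {
  set.seed(402)
  d <- data.frame(one_visit = c(rnorm(30, 1), rnorm(30, 3)),
                  category = rep(c("CD", "NCD"), each = 30),
                  psu = rep(sprintf("P%d", 1:12), 5),
                  stringsAsFactors = FALSE)
  res <- suppressMessages(regress_che_shape(d, "one_visit", covariates = character(0)))
  diff_means <- mean(d$one_visit[d$category == "NCD"]) -
    mean(d$one_visit[d$category == "CD"])
  expect_equal(res$estimate[res$term == "categoryNCD"], diff_means,
               tolerance = 1e-10)
})

test_that("cluster-robust SEs match the hand-computed sandwich on a small fixture", {
  set.seed(403)
  d <- data.frame(oop_cost = rnorm(12, 50, 10),
                  category = rep(c("CD", "NCD"), 6),
                  age = runif(12, 20, 70),
                  psu = rep(c("P1", "P2", "P3", "P4"), each = 3),
                  stringsAsFactors = FALSE)
  res <- suppressMessages(
    regress_visit_outcome(d, "oop_cost", covariates = "age"))
  X <- cbind(1, as.numeric(d$category == "NCD"), d$age)
  V <- oracle_cluster_vcov(X, d$oop_cost, d$psu)
  expect_equal(res$se, sqrt(diag(V)), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(res$estimate, as.numeric(qr.solve(X, d$oop_cost)),
               tolerance = 1e-10)
  expect_identical(res$n_clusters, rep(4L, 3))
})

test_that("planted cost contrast yields a positive significant NCD coefficient", {
  cfg <- flat_cost_config(n_households = 2500, seed = 404,
                          visit_rate_outpatient = 2)
  sim <- simulate_sage(cfg)
  v <- sim$visits[sim$visits$rank == 1 & sim$visits$care_level == "outpatient", ]
  ridx <- match(v$respondent_id, sim$respondents$respondent_id)
  hidx <- match(v$household_id, sim$households$household_id)
  d <- data.frame(oop_cost = v$oop_cost,
                  category = ifelse(v$cause %in% c("NCD", "CD", "INJURY"),
                                    v$cause, "OTHER"),
                  age = sim$respondents$age[ridx],
                  sex = sim$respondents$sex[ridx],
                  urban = sim$respondents$urban[ridx],
                  education = sim$respondents$education[ridx],
                  wealth_quintile = sim$respondents$wealth_quintile[ridx],
                  psu = sim$households$psu[hidx], stringsAsFactors = FALSE)
  res <- suppressMessages(regress_visit_outcome(d, "oop_cost"))
  ncd <- res[res$term == "categoryNCD", ]
  expect_gt(ncd$estimate, 0)
  expect_lt(ncd$p_value, 0.05)
})

test_that("degenerate and error paths of the shape regression", {
  d <- data.frame(one_visit = rep(TRUE, 20),
                  category = rep(c("CD", "NCD"), 10),
                  psu = rep(c("P1", "P2"), 10), stringsAsFactors = FALSE)
  expect_warning(res <- regress_che_shape(d, "one_visit",
                                          covariates = character(0)),
                 "constant")
  expect_true(is.na(res$se))
  d$one_visit <- rep(c(TRUE, FALSE), 10)
  d$psu <- "P1"
  expect_error(suppressMessages(
    regress_che_shape(d, "one_visit", covariates = character(0))),
    "clusters")
})

test_that("covariate-free shape regression intercept equals the outcome share", {
  set.seed(405)
  d <- data.frame(five_plus = rbinom(60, 1, 0.3) == 1,
                  psu = rep(sprintf("P%d", 1:10), 6))
  res <- suppressMessages(
    regress_che_shape(d, "five_plus", covariates = character(0),
                      include_category = FALSE))
  expect_equal(res$estimate[res$term == "(Intercept)"], mean(d$five_plus),
               tolerance = 1e-12)
})

test_that("collinear covariates are dropped with a warning, not an error", {
  set.seed(406)
  d <- data.frame(oop_cost = rnorm(40, 10), category = rep(c("CD", "NCD"), 20),
                  age = rep(1:10, 4), psu = rep(sprintf("P%d", 1:8), 5))
  d$age2 <- 2 * d$age   # exactly collinear
  expect_warning(res <- suppressMessages(
    regress_visit_outcome(d, "oop_cost", covariates = c("age", "age2"))),
    "collinear")
  expect_false("age2" %in% res$term)
  expect_true(all(res$se > 0))
})
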