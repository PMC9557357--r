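test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_households = -1), "n_households")
  expect_error(sim_config(share_50plus_households = 1.2), "share_50plus_households")
  expect_error(sim_config(cause_mix = c(NCD = 0.5, CD = 0.6, INJURY = 0,
                                        PAIN = 0, SURGERY = 0, OTHER = 0,
                                        UNIDENTIFIED = 0)), "cause_mix")
  expect_error(sim_config(ncd_cost_ratio = 0), "ncd_cost_ratio")
  expect_error(sim_config(visit_rate_outpatient = -0.1), "visit_rate_outpatient")
})

test_that("generation is deterministic under a fixed seed", {
  a <- simulate_sage(sim_config(n_households = 150, seed = 7))
  b <- simulate_sage(sim_config(n_households = 150, seed = 7))
  expect_identical(a$households, b$households)
  expect_identical(a$respondents, b$respondents)
  expect_identical(a$visits, b$visits)
  expect_identical(a$truth$visits, b$truth$visits)
})

test_that("degenerate configurations behave as documented", {
  empty <- simulate_sage(sim_config(n_households = 0))
  expect_identical(nrow(empty$households), 0L)
  expect_identical(nrow(empty$respondents), 0L)
  expect_identical(nrow(empty$visits), 0L)

  all50 <- simulate_sage(sim_config(n_households = 120, seed = 2,
                                    share_50plus_households = 1))
  expect_true(all(all50$respondents$age >= 50))
  expect_true(all(all50$households$hh_type == "50plus"))

  novisit <- simulate_sage(sim_config(n_households = 100, seed = 3,
                                      visit_rate_outpatient = 0,
                                      visit_rate_inpatient = 0))
  expect_identical(nrow(novisit$visits), 0L)
})

test_that("population respects the household-selection design", {
  sim <- small_sim(seed = 21, n = 600)
  hh <- sim$households
  resp <- sim$respondents
  expect_true(all(hh$weight > 0))
  expect_true(all(resp$weight > 0))
  n_per_hh <- table(resp$household_id)
  young <- hh$household_id[hh$hh_type == "18-49"]
  expect_true(all(n_per_hh[young] == 1))
  ages_young <- resp$age[resp$household_id %in% young]
  expect_true(all(ages_young >= 18 & ages_young < 50))
  old <- hh$household_id[hh$hh_type == "50plus"]
  expect_true(all(n_per_hh[old] >= 1))
  expect_true(all(resp$age[resp$household_id %in% old] >= 50))
  expect_true(all(hh$wealth_quintile %in% 1:5))
  # weighted quintiles hold roughly 20% of total weight each
  wq <- tapply(hh$weight, hh$wealth_quintile, sum) / sum(hh$weight)
  expect_true(all(abs(wq - 0.2) < 0.05))
})

test_that("planted NCD-vs-CD cost ratio is recovered from generated visits", {
  cfg <- flat_cost_config(n_households = 4000, seed = 31,
                          visit_rate_outpatient = 8)
  sim <- simulate_sage(cfg)
  tv <- sim$truth$visits
  pos <- tv$true_oop > 0 & tv$care_level == "outpatient"
  m_ncd <- mean(tv$true_oop[pos & tv$true_cause == "NCD"])
  m_cd <- mean(tv$true_oop[pos & tv$true_cause == "CD"])
  n_min <- min(sum(pos & tv$true_cause == "NCD"), sum(pos & tv$true_cause == "CD"))
  expect_gt(n_min, 5000)
  # Monte-Carlo band: lognormal(sdlog=1) mean has relative SE ~ sqrt(e-1)/sqrt(n)
  se_rel <- sqrt(exp(1) - 1) * sqrt(1 / n_min) * sqrt(2)
  expect_lt(abs(m_ncd / m_cd - 1.6), 4 * se_rel * 1.6)

  cfg0 <- flat_cost_config(n_households = 4000, seed = 32,
                           visit_rate_outpatient = 8, ncd_cost_ratio = 1)
  tv0 <- simulate_sage(cfg0)$truth$visits
  pos0 <- tv0$true_oop > 0 & tv0$care_level == "outpatient"
  r0 <- mean(tv0$true_oop[pos0 & tv0$true_cause == "NCD"]) /
    mean(tv0$true_oop[pos0 & tv0$true_cause == "CD"])
  expect_lt(abs(r0 - 1), 4 * se_rel)
})

test_that("cause frequencies converge to the configured mix", {
  cfg <- sim_config(n_households = 7000, seed = 41, visit_rate_outpatient = 8,
                    cause_covariate_strength = 0, cause_concentration = 0)
  tv <- simulate_sage(cfg)$truth$visits
  expect_gt(nrow(tv), 50000)
  obs <- table(factor(tv$true_cause, levels = cause_groups()))
  pval <- suppressWarnings(chisq.test(obs, p = cfg$cause_mix)$p.value)
  expect_gt(pval, 0.001)
})

test_that("zero-cost fraction matches 1 - p_positive", {
  cfg <- flat_cost_config(n_households = 3000, seed = 51,
                          visit_rate_outpatient = 6)
  tv <- simulate_sage(cfg)$truth$visits
  out <- tv[tv$care_level == "outpatient", ]
  frac0 <- mean(out$true_oop == 0)
  expect_lt(abs(frac0 - (1 - cfg$cost_params$p_positive[["outpatient"]])), 0.01)
})

test_that("censoring implements the three-cause / one-cost recall pattern", {
  visits <- data.frame(
    visit_id = paste0("V", 1:8), respondent_id = rep("R1", 8),
    household_id = rep("H1", 8), country = "A",
    care_level = c(rep("outpatient", 6), rep("inpatient", 2)),
    rank = c(1:6, 1:2), true_cause = rep("NCD", 8),
    reason_code = rep(1L, 8), facility = rep("public", 8),
    true_oop = 10 * (1:8), stringsAsFactors = FALSE)
  obs <- censor_to_sage(visits)
  outp <- obs[obs$care_level == "outpatient", ]
  expect_identical(sum(!is.na(outp$cause)), 3L)
  expect_identical(sum(!is.na(outp$oop_cost)), 1L)
  expect_identical(nrow(outp), 6L)   # counts retained: every visit keeps a row
  inp <- obs[obs$care_level == "inpatient", ]
  expect_identical(sum(!is.na(inp$cause)), 2L)
  expect_identical(sum(!is.na(inp$oop_cost)), 1L)

  expect_identical(nrow(censor_to_sage(visits[0, ])), 0L)
  expect_error(censor_to_sage(transform(visits, rank = NA)), "rank")
})

test_that("censoring is a pure sub-selection of the truth", {
  sim <- small_sim(seed = 61)
  tv <- sim$truth$visits
  obs <- sim$visits
  idx <- match(obs$visit_id, tv$visit_id)
  expect_false(anyNA(idx))
  keep <- !is.na(obs$cause)
  expect_identical(obs$cause[keep], tv$true_cause[idx][keep])
  keep <- !is.na(obs$oop_cost)
  expect_identical(obs$oop_cost[keep], tv$true_oop[idx][keep])
  keep <- !is.na(obs$facility)
  expect_identical(obs$facility[keep], tv$facility[idx][keep])
  expect_true(all(obs$rank[!is.na(obs$cause)] <= 3))
  expect_true(all(obs$rank[!is.na(obs$oop_cost)] == 1))
})
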