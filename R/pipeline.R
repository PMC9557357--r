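# End-to-end orchestration: reason mapping -> cause imputation -> two-part
# cost prediction -> currency conversion -> annual OOP by disease ->
# capacity-to-pay / CHE / attribution -> shares, quintiles, bootstrap ->
# drivers.

#' Pipeline configuration
#'
#' Every analysis constant is a named field with its conventional default:
#' the 40% capacity-to-pay threshold, the 75% attribution cutoff, the
#' 45th–55th weighted percentile food band, and 1000 bootstrap draws.
#'
#' @param threshold CHE threshold fraction of capacity-to-pay, in (0,1).
#' @param attribution_cutoff disease-attribution cutoff, in (0,1).
#' @param band food poverty line weighted-percentile band.
#' @param equivalence_beta household-size equivalence exponent (1 =
#'   per-capita).
#' @param B bootstrap replicates (>= 2); `0` disables bootstrap intervals.
#' @param seed seed for the bootstrap and any stochastic stage.
#' @param classifier [cause_settings()] for cause imputation.
#' @param cost_family positive-part family for [fit_two_part()].
#' @param cost_covariates covariates of the cost model (must include
#'   `"cause"`).
#' @param candidate_covariate_sets optional named list of candidate
#'   covariate sets; when given, [select_covariates()] picks the set per
#'   country and care level by grouped-CV RMSE.
#' @param ppp purchasing-power-parity factor(s) to 2017 international
#'   dollars: a scalar, or a named vector by country. Applied to OOP costs
#'   and to household expenditure and food expenditure alike.
#' @param weighted_regressions use survey weights in the drivers
#'   regressions (default FALSE: unweighted with cluster-robust errors).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(threshold = 0.40, attribution_cutoff = 0.75,
                            band = c(0.45, 0.55), equivalence_beta = 1,
                            B = 1000, seed = 1L,
                            classifier = cause_settings(),
                            cost_family = "gamma",
                            cost_covariates = c("cause", "age", "sex", "urban",
                                                "education", "wealth_quintile"),
                            candidate_covariate_sets = NULL,
                            ppp = 1,
                            weighted_regressions = FALSE) {
  for (f in c("threshold", "attribution_cutoff")) {
    v <- get(f)
    if (!is_prob(v) || v == 0 || v == 1) stop_config(f, "must lie in (0,1)")
  }
  if (length(band) != 2 || band[1] >= band[2] || band[1] < 0 || band[2] > 1)
    stop_config("band", "must be an increasing pair in [0,1]")
  if (!(is_count(B) && (B == 0 || B >= 2))) stop_config("B", "must be 0 or >= 2")
  if (!"cause" %in% cost_covariates)
    stop_config("cost_covariates", "must include 'cause'")
  if (any(ppp <= 0)) stop_config("ppp", "must be positive")
  structure(list(threshold = threshold, attribution_cutoff = attribution_cutoff,
                 band = band, equivalence_beta = equivalence_beta,
                 B = as.integer(B), seed = as.integer(seed),
                 classifier = classifier, cost_family = cost_family,
                 cost_covariates = cost_covariates,
                 candidate_covariate_sets = candidate_covariate_sets,
                 ppp = ppp, weighted_regressions = weighted_regressions),
            class = "pipeline_config")
}

ppp_for <- function(ppp, country) {
  if (length(ppp) == 1L && is.null(names(ppp))) return(rep(ppp, length(country)))
  missing <- setdiff(unique(country), names(ppp))
  if (length(missing))
    stop(sprintf("ppp: no factor for countries: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  unname(ppp[country])
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

cost_feature_frame <- function(visits, respondents) {
  ridx <- match(visits$respondent_id, respondents$respondent_id)
  data.frame(
    cause = factor(visits$cause_final,
                   levels = c("CD", setdiff(cause_groups(), "CD"))),
    age = respondents$age[ridx],
    sex = factor(respondents$sex[ridx]),
    urban = respondents$urban[ridx],
    education = respondents$education[ridx],
    wealth_quintile = respondents$wealth_quintile[ridx])
}

#' Run the full CHE decomposition pipeline
#'
#' Executes the stages in order on validated survey tables: (1) map raw
#' reason codes to cause groups; (2) fit the cause classifier on visits with
#' observed causes and impute the rest; (3) fit two-part cost models per
#' country and care level on the most recent (observed-cost) visits,
#' predict the expected cost of all other visits, and convert to 2017
#' international dollars; (4) aggregate annual OOP by disease per
#' respondent and household; (5) compute the food poverty line,
#' capacity-to-pay, CHE flags, disease attribution, weighted shares and
#' wealth-quintile breakdowns, with strata-resampled bootstrap intervals;
#' (6) run the drivers analysis (visits-to-CHE and PSU-clustered
#' regressions). Observed causes and costs always override model
#' predictions.
#'
#' @param data a `sage_sim` object, a list with `households`, `respondents`,
#'   `visits`, or a directory path readable by [read_survey()].
#' @param codebook reason codebook (default [default_codebook()]).
#' @param config a [pipeline_config()].
#' @param quiet suppress per-stage messages.
#' @return list of class `che_pipeline_result`: resolved `visits`,
#'   `cause_model`, `cause_accuracy`, `cost_models`, `annual_oop`,
#'   `household_oop`, `ctp` (per country), `cases`, `shares`,
#'   `shares_ui` (bootstrap), `by_quintile`, `drivers`, `manifest`.
#' @export
run_pipeline <- function(data, codebook = default_codebook(),
                         config = pipeline_config(), quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(data)) data <- read_survey(data, codebook, quiet = quiet)
  households <- data$households
  respondents <- data$respondents
  visits <- data$visits
  run_stage("validate", validate_survey(households, respondents, visits,
                                        codebook, quiet = TRUE))
  run_stage("validate", ppp_for(config$ppp, unique(households$country)))
  manifest <- list(seed = config$seed, threshold = config$threshold,
                   attribution_cutoff = config$attribution_cutoff,
                   n_households = nrow(households),
                   n_respondents = nrow(respondents),
                   n_visits = nrow(visits), warnings = character())

  # 1. reason codes -> cause groups (codebook is authoritative)
  visits$cause <- run_stage("map_reasons",
                            map_reason_to_group(visits$reason_code, codebook))

  # 2. cause imputation for visits beyond the three most recent
  model <- run_stage("cause_imputation", fit_cause_classifier(
    visits, respondents, households, settings = config$classifier))
  needs_cause <- is.na(visits$cause)
  visits$cause_final <- visits$cause
  cause_pred <- NULL
  if (any(needs_cause)) {
    cause_pred <- run_stage("cause_imputation", predict_cause(
      model, visits[needs_cause, , drop = FALSE], respondents, households,
      context = visits))
    visits$cause_final[needs_cause] <- cause_pred$cause_pred
  }

  # 3. two-part cost models per country x care level, then PPP conversion
  feats <- cost_feature_frame(visits, respondents)
  costd <- cbind(visits[, c("visit_id", "respondent_id", "country",
                            "care_level", "rank", "oop_cost")], feats)
  cost_models <- list()
  visits$cost_pred <- NA_real_
  for (cty in unique(costd$country)) {
    for (lvl in unique(costd$care_level[costd$country == cty])) {
      sel <- costd$country == cty & costd$care_level == lvl
      train <- costd[sel & !is.na(costd$oop_cost), , drop = FALSE]
      covs <- config$cost_covariates
      if (!is.null(config$candidate_covariate_sets)) {
        covs <- run_stage("covariate_selection", select_covariates(
          config$candidate_covariate_sets, train,
          family = config$cost_family, seed = config$seed))$chosen
      }
      m <- run_stage("cost_model", fit_two_part(train, covs,
                                                family = config$cost_family))
      key <- paste(cty, lvl, sep = "|")
      cost_models[[key]] <- m
      pred_rows <- sel & is.na(costd$oop_cost)
      if (any(pred_rows)) {
        visits$cost_pred[pred_rows] <- suppressWarnings(
          predict_cost(m, costd[pred_rows, , drop = FALSE]))
      }
    }
  }
  visits$cost_final <- ifelse(is.na(visits$oop_cost), visits$cost_pred,
                              visits$oop_cost)
  fac <- ppp_for(config$ppp, visits$country)
  visits$cost_final <- visits$cost_final * fac
  hfac <- ppp_for(config$ppp, households$country)
  households$expenditure <- households$expenditure * hfac
  households$food_expenditure <- households$food_expenditure * hfac

  # 4. annual OOP by disease, respondent then household
  annual <- run_stage("annual_oop", annual_oop_by_disease(
    respondents, data.frame(respondent_id = visits$respondent_id,
                            cause = visits$cause_final,
                            cost = visits$cost_final,
                            stringsAsFactors = FALSE)))
  hh_oop <- household_oop_by_disease(annual, households)

  # 5. CHE estimation per country
  cases_list <- list()
  ctp_list <- list()
  for (cty in unique(households$country)) {
    hh <- households[households$country == cty, , drop = FALSE]
    line <- run_stage("che", food_poverty_line(
      hh, equivalence_beta = config$equivalence_beta, band = config$band))
    ctp <- run_stage("che", suppressMessages(capacity_to_pay(
      hh, line, equivalence_beta = config$equivalence_beta)))
    ctp_list[[cty]] <- list(line = line, ctp = ctp)
    cases_list[[cty]] <- build_che_cases(
      hh_oop[hh_oop$household_id %in% hh$household_id, , drop = FALSE],
      ctp, hh, threshold = config$threshold,
      cutoff = config$attribution_cutoff)
  }
  cases <- do.call(rbind, cases_list)
  rownames(cases) <- NULL
  shares <- run_stage("che", suppressMessages(che_share_by_disease(cases)))
  by_quintile <- run_stage("che", suppressMessages(che_by_wealth_quintile(cases)))

  shares_ui <- NULL
  if (config$B >= 2) {
    shares_ui <- lapply(setNames(nm = unique(cases$country)), function(cty) {
      d <- cases[cases$country == cty, , drop = FALSE]
      est <- function(dd) {
        s <- suppressMessages(che_share_by_disease(dd))
        ok <- !is.na(dd$che)
        c(che_rate = 100 * sum(dd$weight[ok & dd$che]) / sum(dd$weight[ok]),
          setNames(s$share_cases, paste0("share_cases_", s$category)))
      }
      suppressMessages(bootstrap_ui(est, d, B = config$B, seed = config$seed))
    })
  }

  # 6. drivers
  drivers <- run_stage("drivers", run_drivers(visits, respondents, cases,
                                              config))
  manifest$n_imputed_causes <- sum(needs_cause)
  manifest$n_predicted_costs <- sum(!is.na(visits$cost_pred))
  manifest$n_che_cases <- sum(cases$che, na.rm = TRUE)
  structure(list(visits = visits, cause_model = model,
                 cause_predictions = cause_pred, cost_models = cost_models,
                 annual_oop = annual, household_oop = hh_oop, ctp = ctp_list,
                 cases = cases, shares = shares, shares_ui = shares_ui,
                 by_quintile = by_quintile, drivers = drivers,
                 manifest = manifest, config = config),
            class = "che_pipeline_result")
}

# Drivers stage: rank-1 visit regressions and CHE-shape regressions.
run_drivers <- function(visits, respondents, cases, config) {
  ridx <- match(visits$respondent_id, respondents$respondent_id)
  hidx <- match(visits$household_id, cases$household_id)
  v1 <- data.frame(
    country = visits$country, care_level = visits$care_level,
    oop_cost = visits$oop_cost, facility = visits$facility,
    category = collapse_category(visits$cause),
    age = respondents$age[ridx], sex = respondents$sex[ridx],
    urban = respondents$urban[ridx], education = respondents$education[ridx],
    wealth_quintile = respondents$wealth_quintile[ridx],
    psu = cases$psu[hidx], weight = respondents$weight[ridx],
    stringsAsFactors = FALSE)[visits$rank == 1, , drop = FALSE]

  k_tab <- visits_to_che_table(
    cases, data.frame(household_id = visits$household_id,
                      cost = visits$cost_final, stringsAsFactors = FALSE),
    threshold = config$threshold)
  case_rows <- cases[!is.na(cases$che) & cases$che, , drop = FALSE]
  shape <- merge(case_rows, k_tab, by = "household_id")
  # head-of-case covariates: the household's first surveyed respondent
  rfirst <- respondents[!duplicated(respondents$household_id), , drop = FALSE]
  sidx <- match(shape$household_id, rfirst$household_id)
  shape$age <- rfirst$age[sidx]
  shape$sex <- rfirst$sex[sidx]
  shape$urban <- rfirst$urban[sidx]
  shape$education <- rfirst$education[sidx]

  wts <- config$weighted_regressions
  visit_reg <- list()
  shape_reg <- list()
  for (cty in unique(cases$country)) {
    for (lvl in c("outpatient", "inpatient")) {
      d <- v1[v1$country == cty & v1$care_level == lvl &
                !is.na(v1$category), , drop = FALSE]
      for (oc in c("oop_cost", "private_facility")) {
        key <- paste(cty, lvl, oc, sep = "|")
        visit_reg[[key]] <- try_regression(function() suppressMessages(
          regress_visit_outcome(d, oc,
                                weights = if (wts) d$weight else NULL)))
      }
    }
    s <- shape[shape$country == cty & shape$category != "UNALLOCABLE", ,
               drop = FALSE]
    for (oc in c("one_visit", "five_plus")) {
      key <- paste(cty, oc, sep = "|")
      shape_reg[[key]] <- try_regression(function() suppressMessages(
        regress_che_shape(s, oc, weights = if (wts) s$weight else NULL)))
    }
  }
  list(visit_regressions = visit_reg, shape_regressions = shape_reg,
       visits_to_che = k_tab)
}

try_regression <- function(fn) {
  tryCatch(suppressWarnings(fn()), error = function(e) {
    data.frame(outcome = NA_character_, term = NA_character_,
               estimate = NA_real_, se = NA_real_, statistic = NA_real_,
               p_value = NA_real_, n = 0L, n_clusters = 0L,
               note = conditionMessage(e), stringsAsFactors = FALSE)
  })
}

# NCD / CD / INJURY kept; remaining groups collapsed to OTHER; NA stays NA.
collapse_category <- function(cause) {
  out <- ifelse(cause %in% disease_categories(), cause,
                ifelse(is.na(cause), NA_character_, "OTHER"))
  out
}

#' CHE shares computed from the ground truth
#'
#' Applies the CHE definitions directly to the uncensored truth table of a
#' synthetic survey (true causes and true costs for every visit), bypassing
#' imputation and cost modelling. Used as the recovery target in
#' simulation tests; never available for real data.
#'
#' @param sim a `sage_sim` object.
#' @param config a [pipeline_config()] (threshold, cutoff, band, beta and
#'   ppp are honoured).
#' @return list with `cases` and `shares` as in [run_pipeline()].
#' @export
truth_che <- function(sim, config = pipeline_config()) {
  stopifnot(inherits(sim, "sage_sim"))
  tv <- sim$truth$visits
  households <- sim$households
  fac <- ppp_for(config$ppp, tv$country)
  hfac <- ppp_for(config$ppp, households$country)
  households$expenditure <- households$expenditure * hfac
  households$food_expenditure <- households$food_expenditure * hfac
  annual <- annual_oop_by_disease(
    sim$respondents, data.frame(respondent_id = tv$respondent_id,
                                cause = tv$true_cause,
                                cost = tv$true_oop * fac,
                                stringsAsFactors = FALSE))
  hh_oop <- household_oop_by_disease(annual, households)
  cases_list <- list()
  for (cty in unique(households$country)) {
    hh <- households[households$country == cty, , drop = FALSE]
    line <- food_poverty_line(hh, equivalence_beta = config$equivalence_beta,
                              band = config$band)
    ctp <- suppressMessages(capacity_to_pay(hh, line,
                                            equivalence_beta = config$equivalence_beta))
    cases_list[[cty]] <- build_che_cases(
      hh_oop[hh_oop$household_id %in% hh$household_id, , drop = FALSE],
      ctp, hh, threshold = config$threshold,
      cutoff = config$attribution_cutoff)
  }
  cases <- do.call(rbind, cases_list)
  rownames(cases) <- NULL
  list(cases = cases,
       shares = suppressMessages(che_share_by_disease(cases)),
       household_oop = hh_oop)
}

#' Repeated simulate-estimate recovery study
#'
#' Runs `n_reps` generate -> censor -> estimate cycles and reports, per
#' replicate, the pipeline's CHE category shares against the truth-sidecar
#' shares, the estimated part-2 NCD-vs-CD log cost ratio against the planted
#' `log(ncd_cost_ratio)`, and the NCD-vs-CD contrasts of the CHE-shape
#' regressions.
#'
#' @param sim_cfg a [sim_config()] (its seed is advanced per replicate).
#' @param pipe_cfg a [pipeline_config()]; bootstrap is disabled inside the
#'   replicates.
#' @param n_reps number of replicates (>= 1).
#' @return list with `replicates` (one data frame row per rep) and
#'   `summary` (bias of each estimand).
#' @export
simulate_and_recover <- function(sim_cfg, pipe_cfg = pipeline_config(B = 0),
                                 n_reps = 10) {
  if (!is_count(n_reps) || n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  pipe_cfg$B <- 0L
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- sim_cfg
    cfg$seed <- sim_cfg$seed + 97L * r
    sim <- simulate_sage(cfg)
    res <- run_pipeline(sim, config = pipe_cfg)
    tru <- truth_che(sim, pipe_cfg)
    est_s <- res$shares
    tru_s <- tru$shares
    getshare <- function(s, cat) {
      v <- s$share_cases[s$category == cat]
      if (length(v)) mean(v, na.rm = TRUE) else NA_real_
    }
    m2 <- res$cost_models[[1]]$part2
    beta_ncd <- if (!is.null(m2)) unname(coef(m2)["causeNCD"]) else NA_real_
    sh <- res$drivers$shape_regressions
    getco <- function(tab) {
      if (is.null(tab) || !"term" %in% names(tab)) return(NA_real_)
      v <- tab$estimate[tab$term == "categoryNCD"]
      if (length(v)) v[1] else NA_real_
    }
    rows[[r]] <- data.frame(
      rep = r,
      ncd_share_est = getshare(est_s, "NCD"), ncd_share_true = getshare(tru_s, "NCD"),
      cd_share_est = getshare(est_s, "CD"), cd_share_true = getshare(tru_s, "CD"),
      injury_share_est = getshare(est_s, "INJURY"),
      injury_share_true = getshare(tru_s, "INJURY"),
      beta_ncd = beta_ncd, beta_ncd_true = log(sim_cfg$ncd_cost_ratio),
      five_plus_ncd = getco(sh[[grep("five_plus", names(sh))[1]]]),
      one_visit_ncd = getco(sh[[grep("one_visit", names(sh))[1]]]))
  }
  reps <- do.call(rbind, rows)
  list(replicates = reps,
       summary = c(bias_ncd_share = mean(reps$ncd_share_est - reps$ncd_share_true,
                                         na.rm = TRUE),
                   bias_cd_share = mean(reps$cd_share_est - reps$cd_share_true,
                                        na.rm = TRUE),
                   bias_beta_ncd = mean(reps$beta_ncd - reps$beta_ncd_true,
                                        na.rm = TRUE),
                   mean_five_plus_ncd = mean(reps$five_plus_ncd, na.rm = TRUE),
                   mean_one_visit_ncd = mean(reps$one_visit_ncd, na.rm = TRUE)))
}

#' @export
print.che_pipeline_result <- function(x, ...) {
  cat("CHE decomposition pipeline result\n")
  cat(sprintf("  %d households, %d CHE case(s), %d imputed cause(s), %d predicted cost(s)\n",
              x$manifest$n_households, x$manifest$n_che_cases,
              x$manifest$n_imputed_causes, x$manifest$n_predicted_costs))
  print(x$shares)
  invisible(x)
}
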