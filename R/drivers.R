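# Drivers of CHE: the visits-to-CHE statistic and comparative regressions
# on per-visit costs, private-facility attendance, and the shape of CHE
# (single shock vs accumulation over many visits).

#' Number of visits to reach the CHE threshold
#'
#' Ranks a household's per-visit OOP costs from the most to the least
#' expensive and accumulates them until the CHE threshold amount (0.40 x
#' capacity-to-pay) is strictly exceeded; `k` is the number of visits
#' accumulated. The descending-sort prefix is provably the minimum
#' cardinality over all subsets of visits whose sum crosses the threshold,
#' and `k` is invariant to the ordering of equal-cost visits.
#'
#' @param costs numeric vector of the household's per-visit OOP costs
#'   (observed and predicted).
#' @param threshold threshold amount in currency (not the 0.40 fraction).
#' @return integer `k >= 1`.
#' @export
visits_to_che <- function(costs, threshold) {
  stopifnot(is.numeric(costs), length(costs) >= 1, all(costs >= 0),
            length(threshold) == 1, threshold >= 0)
  if (sum(costs) <= threshold)
    stop("total OOP does not exceed the threshold: household cannot be a CHE case",
         call. = FALSE)
  cum <- cumsum(sort(costs, decreasing = TRUE))
  which(cum > threshold)[1]
}

#' Visits-to-CHE table for all CHE cases
#'
#' @param cases case table from [build_che_cases()] (CHE rows are used).
#' @param visit_costs data frame with `household_id` and `cost` (one row per
#'   visit, final observed-or-predicted cost).
#' @param threshold capacity-to-pay fraction (default 0.40).
#' @return data frame: `household_id`, `k`, `one_visit`, `five_plus`,
#'   `threshold_amount` — one row per CHE household.
#' @export
visits_to_che_table <- function(cases, visit_costs, threshold = 0.40) {
  require_columns(cases, c("household_id", "che", "capacity_to_pay"), "cases")
  require_columns(visit_costs, c("household_id", "cost"), "visit_costs")
  case_rows <- cases[!is.na(cases$che) & cases$che, , drop = FALSE]
  costs_by_hh <- split(visit_costs$cost, visit_costs$household_id)
  k <- vapply(seq_len(nrow(case_rows)), function(i) {
    hh <- case_rows$household_id[i]
    visits_to_che(costs_by_hh[[hh]], threshold * case_rows$capacity_to_pay[i])
  }, integer(1))
  data.frame(household_id = case_rows$household_id, k = k,
             one_visit = k == 1L, five_plus = k >= 5L,
             threshold_amount = threshold * case_rows$capacity_to_pay,
             stringsAsFactors = FALSE)
}

# One-way cluster-robust OLS with listwise deletion and collinear-term
# dropping. p-values use t with (G - 1) degrees of freedom.
cluster_ols <- function(formula, data, cluster_col, weights = NULL,
                        outcome_name) {
  vars <- all.vars(formula)
  keep <- complete.cases(data[, c(vars, cluster_col), drop = FALSE])
  if (sum(!keep))
    message(sprintf("%s: %d row(s) dropped by listwise deletion", outcome_name,
                    sum(!keep)))
  d <- data[keep, , drop = FALSE]
  cl <- d[[cluster_col]]
  if (length(unique(cl)) < 2)
    stop("fewer than 2 clusters: cluster-robust inference impossible", call. = FALSE)
  fit <- if (is.null(weights)) lm(formula, data = d)
         else lm(formula, data = d, weights = weights[keep])
  aliased <- is.na(coef(fit))
  if (any(aliased)) {
    warning(sprintf("%s: dropping collinear term(s): %s", outcome_name,
                    paste(names(coef(fit))[aliased], collapse = ", ")),
            call. = FALSE)
    keep_terms <- setdiff(attr(terms(fit), "term.labels"),
                          find_aliased_terms(fit))
    rhs <- if (length(keep_terms)) paste(keep_terms, collapse = " + ") else "1"
    formula <- as.formula(paste(vars[1], "~", rhs))
    fit <- if (is.null(weights)) lm(formula, data = d)
           else lm(formula, data = d, weights = weights[keep])
  }
  V <- sandwich::vcovCL(fit, cluster = cl)
  est <- coef(fit)
  se <- sqrt(diag(V))
  df <- length(unique(cl)) - 1
  tval <- est / se
  data.frame(outcome = outcome_name, term = names(est),
             estimate = as.numeric(est), se = as.numeric(se),
             statistic = as.numeric(tval),
             p_value = 2 * pt(abs(tval), df = df, lower.tail = FALSE),
             n = nrow(d), n_clusters = length(unique(cl)),
             stringsAsFactors = FALSE, row.names = NULL)
}

find_aliased_terms <- function(fit) {
  aliased <- names(coef(fit))[is.na(coef(fit))]
  labs <- attr(terms(fit), "term.labels")
  asgn <- attr(model.matrix(fit), "assign")
  cols <- colnames(model.matrix(fit))
  unique(labs[asgn[match(aliased, cols)]])
}

#' Regress most-recent-visit outcomes on disease category and covariates
#'
#' OLS of per-visit OOP cost or private-facility attendance on a disease
#' category indicator plus socio-demographic covariates, using only the
#' most recent visit per care level (the non-modelled survey information).
#' Standard errors are clustered by primary sampling unit. Run separately by
#' country and care level by subsetting the input.
#'
#' @param visits_most_recent data frame of rank-1 visits with observed
#'   `oop_cost`, `facility`, a `category` column (typically NCD / CD /
#'   INJURY / OTHER with CD as reference), covariate columns and a `psu`
#'   column.
#' @param outcome `"oop_cost"` or `"private_facility"`.
#' @param covariates additional covariate column names.
#' @param weights optional survey weights (default unweighted).
#' @return tidy data frame: `outcome`, `term`, `estimate`, `se`,
#'   `statistic`, `p_value`, `n`, `n_clusters`.
#' @export
regress_visit_outcome <- function(visits_most_recent,
                                  outcome = c("oop_cost", "private_facility"),
                                  covariates = c("age", "urban", "education",
                                                 "sex", "wealth_quintile"),
                                  weights = NULL) {
  outcome <- match.arg(outcome)
  d <- visits_most_recent
  require_columns(d, c("category", "psu"), "visits_most_recent")
  if (outcome == "private_facility") {
    require_columns(d, "facility", "visits_most_recent")
    d$private_facility <- as.numeric(d$facility == "private")
  } else {
    require_columns(d, "oop_cost", "visits_most_recent")
  }
  d$category <- stats::relevel(factor(d$category), ref = "CD")
  rhs <- paste(c("category", covariates), collapse = " + ")
  f <- as.formula(paste(outcome, "~", rhs))
  cluster_ols(f, d, "psu", weights = weights, outcome_name = outcome)
}

#' Regress the shape of CHE on the disease causing it
#'
#' Linear probability models (OLS) for whether CHE arose from a single visit
#' (`one_visit`, k = 1) or from five or more visits (`five_plus`, k >= 5),
#' on an indicator for the disease area causing CHE plus covariates,
#' restricted to CHE cases, with PSU-clustered standard errors. A constant
#' outcome yields a degenerate-model warning and estimates without
#' inference.
#'
#' @param che_cases CHE-case rows joined with their [visits_to_che_table()]
#'   indicators, a `category` column, covariates and `psu`.
#' @param outcome `"one_visit"` or `"five_plus"`.
#' @param covariates additional covariate column names (may be empty).
#' @param weights optional survey weights.
#' @param include_category include the disease-category indicator (default
#'   TRUE; FALSE gives, e.g., the covariate-free model whose intercept is
#'   the sample share of the outcome).
#' @return tidy regression data frame as in [regress_visit_outcome()].
#' @export
regress_che_shape <- function(che_cases,
                              outcome = c("one_visit", "five_plus"),
                              covariates = c("age", "urban", "education",
                                             "sex", "wealth_quintile"),
                              weights = NULL, include_category = TRUE) {
  outcome <- match.arg(outcome)
  d <- che_cases
  require_columns(d, c(outcome, if (include_category) "category", "psu"),
                  "che_cases")
  d[[outcome]] <- as.numeric(d[[outcome]])
  if (length(unique(d[[outcome]])) < 2) {
    warning(sprintf("outcome '%s' is constant among CHE cases: no inference possible",
                    outcome), call. = FALSE)
    return(data.frame(outcome = outcome, term = "(Intercept)",
                      estimate = unique(d[[outcome]]), se = NA_real_,
                      statistic = NA_real_, p_value = NA_real_,
                      n = nrow(d), n_clusters = length(unique(d$psu)),
                      stringsAsFactors = FALSE))
  }
  terms_rhs <- covariates
  if (include_category) {
    d$category <- stats::relevel(factor(d$category), ref = "CD")
    terms_rhs <- c("category", covariates)
  }
  rhs <- if (length(terms_rhs)) paste(terms_rhs, collapse = " + ") else "1"
  f <- as.formula(paste(outcome, "~", rhs))
  cluster_ols(f, d, "psu", weights = weights, outcome_name = outcome)
}
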