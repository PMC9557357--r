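# Two-part out-of-pocket cost model: a logistic model for P(OOP > 0) and a
# log-link GLM for the positive part. Expected cost per visit is
# p-hat x conditional mean; covariates are selected by grouped
# cross-validated RMSE on the expected-cost scale (zeros included).

#' Fit a two-part cost model
#'
#' Part 1 is a logistic regression for the probability of any spending,
#' fitted on all observed-cost visits. Part 2 models the positive costs with
#' a log link: a Gamma GLM by default, or a Gaussian regression on log cost
#' with Duan's smearing retransformation (`family = "lognormal"`).
#' Degenerate inputs are handled explicitly: with no positive costs, part 2
#' is skipped and the conditional mean is 0; with no zeros, part 1 is the
#' constant 1. Complete separation in part 1 falls back to a ridge-penalized
#' logistic fit (via glmnet) with a warning.
#'
#' @param visits_observed data frame of visits with an observed `oop_cost`
#'   plus all covariate columns.
#' @param covariates character vector of covariate column names (may be
#'   empty for an intercept-only model).
#' @param family positive-part family: `"gamma"` (default) or
#'   `"lognormal"`.
#' @return object of class `two_part_model`.
#' @export
fit_two_part <- function(visits_observed, covariates,
                         family = c("gamma", "lognormal")) {
  family <- match.arg(family)
  require_columns(visits_observed, c("oop_cost", covariates), "visits_observed")
  y <- visits_observed$oop_cost
  if (anyNA(y)) stop("visits_observed: oop_cost must be observed (non-NA)", call. = FALSE)
  if (any(y < 0)) stop("visits_observed: negative oop_cost", call. = FALSE)
  dat <- prepare_covariates(visits_observed, covariates)
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  pos <- y > 0

  model <- list(covariates = covariates, family = family,
                p_const = NULL, part1 = NULL, part2 = NULL, smear = NULL,
                train_levels = lapply(dat[covariates], function(v)
                  if (is.factor(v)) list(levels = levels(v),
                                         seen = levels(droplevels(v)))
                  else range(v)),
                n = length(y), n_positive = sum(pos), rmse = NA_real_)

  if (all(pos)) {
    model$p_const <- 1
  } else if (!any(pos)) {
    model$p_const <- 0
  } else {
    f1 <- as.formula(paste("pos ~", rhs))
    d1 <- cbind(pos = pos, dat)
    fit1 <- suppressWarnings(glm(f1, data = d1, family = binomial()))
    if (!fit1$converged || any(abs(coef(fit1)) > 15, na.rm = TRUE)) {
      if (requireNamespace("glmnet", quietly = TRUE) && length(covariates)) {
        warning("part 1: separation detected; using ridge-penalized logistic fallback",
                call. = FALSE)
        X <- model.matrix(as.formula(paste("~", rhs)), data = dat)[, -1, drop = FALSE]
        if (ncol(X) < 2) X <- cbind(X, .pad = 0)  # glmnet needs >= 2 columns
        fit1 <- glmnet::glmnet(X, as.numeric(pos), family = "binomial",
                               alpha = 0, lambda = 1e-3)
        attr(fit1, "design_rhs") <- rhs
      } else {
        warning("part 1: possible separation; keeping unpenalized fit", call. = FALSE)
      }
    }
    model$part1 <- fit1
  }

  if (any(pos)) {
    f2 <- as.formula(paste("oop_cost ~", rhs))
    d2 <- cbind(oop_cost = y[pos], dat[pos, , drop = FALSE])
    if (family == "gamma") {
      model$part2 <- glm(f2, data = d2, family = Gamma(link = "log"))
    } else {
      d2$oop_cost <- log(d2$oop_cost)
      model$part2 <- lm(f2, data = d2)
      model$smear <- mean(exp(residuals(model$part2)))
    }
    if (any(!is.finite(coef(model$part2)[!is.na(coef(model$part2))])))
      stop("part 2: non-finite coefficients", call. = FALSE)
  }
  class(model) <- "two_part_model"
  model
}

# character covariates -> factors; leaves numerics alone
prepare_covariates <- function(df, covariates) {
  out <- df[, covariates, drop = FALSE]
  for (col in covariates) {
    if (is.character(out[[col]]) || is.logical(out[[col]]))
      out[[col]] <- factor(out[[col]])
  }
  out
}

predict_part1 <- function(model, dat) {
  if (!is.null(model$p_const)) return(rep(model$p_const, nrow(dat)))
  fit1 <- model$part1
  if (inherits(fit1, "glmnet")) {
    X <- model.matrix(as.formula(paste("~", attr(fit1, "design_rhs"))),
                      data = dat)[, -1, drop = FALSE]
    if (ncol(X) < 2) X <- cbind(X, .pad = 0)
    as.numeric(predict(fit1, newx = X, type = "response"))
  } else {
    as.numeric(predict(fit1, newdata = dat, type = "response"))
  }
}

#' Predict expected OOP cost per visit
#'
#' Expected cost is `P(positive) x conditional mean`, the deterministic
#' plug-in used downstream (no stochastic draw, so visit-level noise is
#' smoothed away while the mean is preserved). Rows with covariates outside
#' the training support (numerics beyond the training range, or unseen
#' factor levels) are still predicted but flagged.
#'
#' @param model a `two_part_model`.
#' @param visits data frame with the model's covariate columns.
#' @return numeric vector of expected costs, with a logical attribute
#'   `extrapolated` marking out-of-support rows.
#' @export
predict_cost <- function(model, visits) {
  stopifnot(inherits(model, "two_part_model"))
  if (nrow(visits) == 0) {
    out <- numeric(0)
    attr(out, "extrapolated") <- logical(0)
    return(out)
  }
  require_columns(visits, model$covariates, "visits")
  dat <- prepare_covariates(visits, model$covariates)
  extrap <- rep(FALSE, nrow(dat))
  for (col in model$covariates) {
    tl <- model$train_levels[[col]]
    v <- dat[[col]]
    if (is.factor(v)) {
      extrap <- extrap | !(as.character(v) %in% tl$seen)
      dat[[col]] <- factor(as.character(v), levels = tl$levels)
      if (anyNA(dat[[col]])) dat[[col]][is.na(dat[[col]])] <- tl$seen[1]
    } else {
      extrap <- extrap | v < tl[1] | v > tl[2]
    }
  }
  if (any(extrap))
    warning(sprintf("%d row(s) outside training support; predictions flagged",
                    sum(extrap)), call. = FALSE)
  p <- predict_part1(model, dat)
  mu <- if (is.null(model$part2)) {
    rep(0, nrow(dat))
  } else if (model$family == "gamma") {
    as.numeric(predict(model$part2, newdata = dat, type = "response"))
  } else {
    exp(as.numeric(predict(model$part2, newdata = dat))) * model$smear
  }
  out <- p * mu
  attr(out, "extrapolated") <- extrap
  out
}

grouped_folds <- function(groups, k, seed = 1L) {
  u <- unique(groups)
  if (length(u) < k)
    stop(sprintf("degenerate folds: %d groups < %d folds", length(u), k),
         call. = FALSE)
  set.seed(seed)
  fold_of <- setNames(sample(rep_len(seq_len(k), length(u))), u)
  unname(fold_of[as.character(groups)])
}

#' Select covariates by out-of-sample RMSE
#'
#' Fits each candidate covariate set with grouped k-fold cross-validation
#' (grouping by respondent, mirroring how predictions are consumed) and
#' returns the set minimizing held-out RMSE of the expected cost against the
#' observed cost, zeros included. Ties go to the first candidate in listed
#' order.
#'
#' @param candidate_sets named list of character vectors of covariate names.
#' @param visits_observed observed-cost visit table with covariate columns
#'   and a `respondent_id` grouping column.
#' @param k_folds number of folds (default 5).
#' @param family passed to [fit_two_part()].
#' @param seed fold-assignment seed.
#' @return list with `chosen` (covariate vector), `chosen_name`, and `rmse`
#'   (named numeric, one entry per candidate).
#' @export
select_covariates <- function(candidate_sets, visits_observed, k_folds = 5,
                              family = "gamma", seed = 1L) {
  stopifnot(is.list(candidate_sets), length(candidate_sets) >= 1)
  if (is.null(names(candidate_sets)))
    names(candidate_sets) <- paste0("set", seq_along(candidate_sets))
  if (length(candidate_sets) == 1L)
    return(list(chosen = candidate_sets[[1]],
                chosen_name = names(candidate_sets)[1],
                rmse = setNames(NA_real_, names(candidate_sets)[1])))
  fold <- grouped_folds(visits_observed$respondent_id, k_folds, seed)
  rmse <- vapply(candidate_sets, function(covs) {
    err2 <- numeric(0)
    for (f in seq_len(k_folds)) {
      test <- fold == f
      fit <- fit_two_part(visits_observed[!test, , drop = FALSE], covs,
                          family = family)
      pred <- suppressWarnings(
        predict_cost(fit, visits_observed[test, , drop = FALSE]))
      err2 <- c(err2, (pred - visits_observed$oop_cost[test])^2)
    }
    sqrt(mean(err2))
  }, numeric(1))
  best <- which.min(rmse)  # which.min takes the first minimum: listed-order tie-break
  list(chosen = candidate_sets[[best]], chosen_name = names(candidate_sets)[best],
       rmse = rmse)
}

#' Currency conversion to 2017 international dollars
#'
#' @param country country label.
#' @param source_year currency-year of the source amounts.
#' @param factor positive purchasing-power-parity factor; converted amount =
#'   amount x factor.
#' @return object of class `currency_conversion`.
#' @export
currency_conversion <- function(country, source_year, factor) {
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("currency conversion factor must be a positive real", call. = FALSE)
  structure(list(country = country, source_year = source_year,
                 factor = factor), class = "currency_conversion")
}

#' Convert amounts to 2017 international dollars
#'
#' Linear, elementwise and order-preserving.
#'
#' @param amounts numeric vector (NA passed through).
#' @param conversion a [currency_conversion()] object, or a bare positive
#'   factor.
#' @return converted amounts.
#' @export
convert_currency <- function(amounts, conversion) {
  factor <- if (inherits(conversion, "currency_conversion")) conversion$factor
            else conversion
  if (length(factor) != 1L || !is.finite(factor) || factor <= 0)
    stop("currency conversion factor must be a positive real", call. = FALSE)
  amounts * factor
}

#' Annual OOP spending by disease area per respondent
#'
#' Sums per-visit costs by cause group within respondent. Callers must
#' resolve each visit to a single cause (observed for the three most recent
#' visits, imputed otherwise) and a single cost (the observed most-recent
#' cost, predicted otherwise) before aggregation; observed values always
#' override predictions.
#'
#' @param respondents respondent table (every respondent gets a row, zero
#'   visits giving an all-zero row).
#' @param visits visit table with non-missing `cause` and `cost` columns.
#' @return data frame: `respondent_id`, `household_id`, one column per cause
#'   group, and `total` (equal to the row sum within 1e-6).
#' @export
annual_oop_by_disease <- function(respondents, visits) {
  require_columns(respondents, c("respondent_id", "household_id"), "respondents")
  groups <- cause_groups()
  out <- data.frame(respondent_id = respondents$respondent_id,
                    household_id = respondents$household_id,
                    stringsAsFactors = FALSE)
  for (g in groups) out[[g]] <- 0
  if (nrow(visits)) {
    require_columns(visits, c("respondent_id", "cause", "cost"), "visits")
    if (anyNA(visits$cause) || anyNA(visits$cost))
      stop("pipeline-order error: every visit needs a resolved cause and cost before aggregation",
           call. = FALSE)
    if (any(visits$cost < 0)) stop("visits: negative cost", call. = FALSE)
    tab <- tapply(visits$cost,
                  list(factor(visits$respondent_id, levels = respondents$respondent_id),
                       factor(visits$cause, levels = groups)),
                  sum, default = 0)
    out[, groups] <- tab[match(out$respondent_id, rownames(tab)), groups]
  }
  out$total <- rowSums(out[, groups, drop = FALSE])
  out
}

#' Household OOP totals by disease area
#'
#' Aggregates [annual_oop_by_disease()] output over each household's
#' surveyed respondents.
#'
#' @param annual_oop respondent-level table from [annual_oop_by_disease()].
#' @param households household table (every household gets a row).
#' @return data frame: `household_id`, per-group totals, `total`.
#' @export
household_oop_by_disease <- function(annual_oop, households) {
  groups <- cause_groups()
  out <- data.frame(household_id = households$household_id,
                    stringsAsFactors = FALSE)
  idx <- factor(annual_oop$household_id, levels = households$household_id)
  for (g in groups) {
    s <- tapply(annual_oop[[g]], idx, sum, default = 0)
    out[[g]] <- as.numeric(s[match(out$household_id, names(s))])
    out[[g]][is.na(out[[g]])] <- 0
  }
  out$total <- rowSums(out[, groups, drop = FALSE])
  out
}

#' @export
print.two_part_model <- function(x, ...) {
  cat(sprintf("Two-part cost model (%s positive part): n=%d, %d positive\n",
              x$family, x$n, x$n_positive))
  cat("Covariates:", if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(intercept only)", "\n")
  if (!is.null(x$p_const)) cat("Part 1: constant p =", x$p_const, "\n")
  invisible(x)
}
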