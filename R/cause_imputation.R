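# Random-forest imputation of the cause group for visits beyond the three
# most recent. Models are fit per country and care level on visits with an
# observed cause; features combine respondent covariates, utilization
# counts, and the causes of the respondent's other observed visits.

#' Classifier settings for cause imputation
#'
#' @param num_trees number of trees (default 500).
#' @param min_node_size minimum terminal node size (default 5).
#' @param mtry features per split; `NULL` = square root of the feature count.
#' @param seed RNG seed pinning forest construction.
#' @param min_rows minimum training rows per country x care-level model.
#' @param min_class_rows minimum rows for a class to count as present.
#' @return list of class `cause_settings`.
#' @export
cause_settings <- function(num_trees = 500, min_node_size = 5, mtry = NULL,
                           seed = 1L, min_rows = 30, min_class_rows = 5) {
  stopifnot(num_trees >= 1, min_node_size >= 1, min_rows >= 1)
  structure(list(num_trees = num_trees, min_node_size = min_node_size,
                 mtry = mtry, seed = as.integer(seed), min_rows = min_rows,
                 min_class_rows = min_class_rows), class = "cause_settings")
}

# Feature frame, one row per visit. Utilization counts and co-visit cause
# counts are computed from `context` (typically the respondent's full
# observed visit table); each visit's own observed label is subtracted from
# its co-visit counts so it never leaks into its own features.
build_cause_features <- function(visits, respondents, context = visits) {
  require_columns(visits, c("respondent_id", "care_level"), "visits")
  require_columns(respondents, c("respondent_id", "age", "sex", "urban",
                                 "education", "wealth_quintile"), "respondents")
  ridx <- match(visits$respondent_id, respondents$respondent_id)
  if (anyNA(ridx))
    stop("imputation-input error: visits reference respondents absent from the respondent table",
         call. = FALSE)
  groups <- cause_groups()
  rid_ctx <- factor(context$respondent_id, levels = respondents$respondent_id)
  lvl <- table(rid_ctx, factor(context$care_level,
                               levels = c("outpatient", "inpatient")))
  has_cause <- !is.na(context$cause)
  co <- table(rid_ctx[has_cause], factor(context$cause[has_cause], levels = groups))
  co_mat <- matrix(0, nrow(respondents), length(groups),
                   dimnames = list(respondents$respondent_id, groups))
  co_mat[rownames(co), colnames(co)] <- co
  co_rows <- co_mat[ridx, , drop = FALSE]
  # subtract each visit's own observed cause (if the row sits in the context)
  own_cause <- visits$cause %||% rep(NA_character_, nrow(visits))
  if (!is.null(visits$visit_id) && !is.null(context$visit_id))
    own_cause[!(visits$visit_id %in% context$visit_id)] <- NA
  own <- cbind(seq_len(nrow(visits)), match(own_cause, groups))
  own <- own[!is.na(own[, 2]), , drop = FALSE]
  if (nrow(own)) co_rows[own] <- co_rows[own] - 1
  colnames(co_rows) <- paste0("co_", tolower(groups))

  out <- data.frame(
    care_level = factor(visits$care_level, levels = c("outpatient", "inpatient")),
    age = respondents$age[ridx],
    male = as.numeric(respondents$sex[ridx] == "male"),
    urban = respondents$urban[ridx],
    education = respondents$education[ridx],
    wealth_quintile = respondents$wealth_quintile[ridx],
    n_outpatient = as.numeric(lvl[cbind(ridx, 1L)]),
    n_inpatient = as.numeric(lvl[cbind(ridx, 2L)]))
  out <- cbind(out, as.data.frame(co_rows))
  for (col in names(out)) {
    if (anyNA(out[[col]]))
      stop(sprintf("imputation-input error: feature '%s' is missing for %d visit(s)",
                   col, sum(is.na(out[[col]]))), call. = FALSE)
  }
  out
}

fit_one_forest <- function(x, y, settings) {
  dat <- cbind(.cause = droplevels(y), x)
  ranger::ranger(
    dependent.variable.name = ".cause", data = dat, probability = TRUE,
    num.trees = settings$num_trees, min.node.size = settings$min_node_size,
    mtry = settings$mtry %||% floor(sqrt(ncol(x))),
    seed = settings$seed, num.threads = 1, verbose = FALSE)
}

#' Fit the cause-imputation classifier
#'
#' Trains one probability random forest per country and care level on visits
#' with an observed cause group. A stratum whose training data contain fewer
#' than two classes with at least `min_class_rows` rows each degenerates to
#' a constant (majority-class) predictor, with a warning.
#'
#' @param visits_observed visit table (only rows with non-missing `cause`
#'   are used for training, but all rows contribute utilization and co-visit
#'   features).
#' @param respondents respondent covariate table.
#' @param households optional household table (used only to backfill
#'   `wealth_quintile` if absent from `respondents`).
#' @param settings a [cause_settings()] object.
#' @return object of class `cause_model`.
#' @export
fit_cause_classifier <- function(visits_observed, respondents,
                                 households = NULL,
                                 settings = cause_settings()) {
  stopifnot(inherits(settings, "cause_settings"))
  if (!"wealth_quintile" %in% names(respondents) && !is.null(households)) {
    respondents$wealth_quintile <-
      households$wealth_quintile[match(respondents$household_id,
                                       households$household_id)]
  }
  feats <- build_cause_features(visits_observed, respondents)
  groups <- cause_groups()
  key <- interaction(visits_observed$country, visits_observed$care_level,
                     sep = "|", drop = TRUE)
  models <- list()
  train <- list()
  for (k in levels(key)) {
    in_stratum <- key == k
    obs <- in_stratum & !is.na(visits_observed$cause)
    y <- factor(visits_observed$cause[obs], levels = groups)
    x <- feats[obs, , drop = FALSE]
    if (length(y) < settings$min_rows)
      stop(sprintf("too few training rows (%d < %d) for stratum %s",
                   length(y), settings$min_rows, k), call. = FALSE)
    tab <- table(y)
    usable <- sum(tab >= settings$min_class_rows)
    if (usable < 2) {
      maj <- names(tab)[which.max(tab)]
      warning(sprintf("stratum %s: fewer than two usable classes; returning constant '%s' predictor",
                      k, maj), call. = FALSE)
      models[[k]] <- list(type = "constant", class = maj, n = length(y))
    } else {
      models[[k]] <- list(type = "ranger",
                          fit = fit_one_forest(x, y, settings),
                          n = length(y))
    }
    train[[k]] <- list(x = x, y = y,
                       group = visits_observed$respondent_id[obs])
  }
  structure(list(models = models, features = names(feats),
                 settings = settings, train = train, accuracy = NULL),
            class = "cause_model")
}

predict_prob_matrix <- function(m, x) {
  groups <- cause_groups()
  out <- matrix(0, nrow(x), length(groups), dimnames = list(NULL, groups))
  if (m$type == "constant") {
    out[, m$class] <- 1
  } else {
    p <- predict(m$fit, data = x, num.threads = 1)$predictions
    out[, colnames(p)] <- p
  }
  out
}

#' Predict the cause group of unobserved visits
#'
#' Hard labels are the modal class; ties are broken deterministically in the
#' canonical group order (NCD, CD, INJURY, PAIN, SURGERY, OTHER,
#' UNIDENTIFIED). The full probability vector is retained for sensitivity
#' analysis. Predictions are deterministic given the fitted model and
#' invariant to the row order of the input.
#'
#' @param model a `cause_model` from [fit_cause_classifier()].
#' @param visits_unobserved visit rows needing a cause (their `country` and
#'   `care_level` select the stratum model).
#' @param respondents respondent covariate table (must cover all rows).
#' @param households optional household table, as in
#'   [fit_cause_classifier()].
#' @param context visit table supplying the utilization and co-visit cause
#'   features (typically the respondent's full observed visit table,
#'   including the rows with observed causes).
#' @return data frame: `visit_id`, `cause_pred`, and one `p_<group>` column
#'   per cause group (each row sums to 1).
#' @export
predict_cause <- function(model, visits_unobserved, respondents,
                          households = NULL, context = visits_unobserved) {
  stopifnot(inherits(model, "cause_model"))
  groups <- cause_groups()
  if (nrow(visits_unobserved) == 0) {
    out <- data.frame(visit_id = character(), cause_pred = character(),
                      stringsAsFactors = FALSE)
    for (g in groups) out[[paste0("p_", tolower(g))]] <- numeric()
    return(out)
  }
  if (!"wealth_quintile" %in% names(respondents) && !is.null(households)) {
    respondents$wealth_quintile <-
      households$wealth_quintile[match(respondents$household_id,
                                       households$household_id)]
  }
  feats <- build_cause_features(visits_unobserved, respondents, context = context)
  key <- paste(visits_unobserved$country, visits_unobserved$care_level, sep = "|")
  prob <- matrix(NA_real_, nrow(feats), length(groups),
                 dimnames = list(NULL, groups))
  for (k in unique(key)) {
    m <- model$models[[k]]
    if (is.null(m))
      stop(sprintf("no fitted model for stratum %s", k), call. = FALSE)
    idx <- key == k
    prob[idx, ] <- predict_prob_matrix(m, feats[idx, , drop = FALSE])
  }
  label <- groups[max.col(prob, ties.method = "first")]
  out <- data.frame(visit_id = visits_unobserved$visit_id,
                    cause_pred = label, stringsAsFactors = FALSE)
  colnames(prob) <- paste0("p_", tolower(groups))
  cbind(out, as.data.frame(prob))
}

#' Grouped cross-validated accuracy of the cause classifier
#'
#' Refits each stratum model on `k_folds` grouped folds (grouping by
#' respondent, so a respondent's visits never straddle train and test) and
#' reports held-out overall and per-class accuracy.
#'
#' @param model a `cause_model` (must retain its training data, as produced
#'   by [fit_cause_classifier()]).
#' @param k_folds number of folds (>= 2; must not exceed the number of
#'   distinct respondents in any stratum).
#' @return list with `overall` accuracy, `per_class` data frame, and
#'   `per_stratum` data frame.
#' @export
holdout_accuracy <- function(model, k_folds = 5) {
  stopifnot(inherits(model, "cause_model"), k_folds >= 2)
  groups <- cause_groups()
  truth_all <- character()
  pred_all <- character()
  per_stratum <- data.frame(stratum = character(), accuracy = numeric(),
                            n = integer(), stringsAsFactors = FALSE)
  for (k in names(model$models)) {
    tr <- model$train[[k]]
    m <- model$models[[k]]
    if (m$type == "constant") {
      pred <- rep(m$class, length(tr$y))
    } else {
      resp <- unique(tr$group)
      if (length(resp) < k_folds)
        stop(sprintf("stratum %s: %d respondent groups < %d folds",
                     k, length(resp), k_folds), call. = FALSE)
      set.seed(model$settings$seed)
      fold_of <- setNames(sample(rep_len(seq_len(k_folds), length(resp))), resp)
      fold <- fold_of[tr$group]
      pred <- character(length(tr$y))
      for (f in seq_len(k_folds)) {
        test <- fold == f
        fit <- fit_one_forest(tr$x[!test, , drop = FALSE],
                              droplevels(tr$y[!test]), model$settings)
        p <- predict_prob_matrix(list(type = "ranger", fit = fit),
                                 tr$x[test, , drop = FALSE])
        pred[test] <- groups[max.col(p, ties.method = "first")]
      }
    }
    acc <- mean(pred == as.character(tr$y))
    per_stratum <- rbind(per_stratum,
                         data.frame(stratum = k, accuracy = acc,
                                    n = length(tr$y), stringsAsFactors = FALSE))
    truth_all <- c(truth_all, as.character(tr$y))
    pred_all <- c(pred_all, pred)
  }
  per_class <- do.call(rbind, lapply(groups, function(g) {
    n <- sum(truth_all == g)
    data.frame(class = g, accuracy = if (n) mean(pred_all[truth_all == g] == g) else NA_real_,
               n = n, stringsAsFactors = FALSE)
  }))
  list(overall = mean(pred_all == truth_all), per_class = per_class,
       per_stratum = per_stratum)
}

#' @export
print.cause_model <- function(x, ...) {
  cat("Cause-imputation model:", length(x$models), "country x care-level stratum model(s)\n")
  for (k in names(x$models)) {
    m <- x$models[[k]]
    cat(sprintf("  %s: %s (n=%d)\n", k,
                if (m$type == "constant") paste0("constant '", m$class, "'")
                else sprintf("random forest, %d trees", x$settings$num_trees),
                m$n))
  }
  invisible(x)
}
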