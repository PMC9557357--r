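# Capacity-to-pay, CHE flagging, disease attribution, survey-weighted
# shares, wealth-quintile breakdowns, and the strata-resampled cluster
# bootstrap.

#' Food-based subsistence (poverty) line
#'
#' Ranks households by food consumption expenditure per equivalent adult
#' (household size raised to `equivalence_beta`) using survey weights, and
#' returns the weighted mean of per-equivalent food spending among the
#' households lying between the 45th and 55th weighted percentiles
#' (inclusive): the food spending of households around the median food
#' share, taken as the subsistence requirement per equivalent adult.
#'
#' @param households table with `food_expenditure`, `size` and `weight` (a
#'   `design` can supply the weights instead).
#' @param design optional design table (`household_id`, `weight`) overriding
#'   household weights.
#' @param equivalence_beta household-size equivalence exponent: 1 is strict
#'   per-capita scaling (the default), 0.56 a common equivalence-scale
#'   convention.
#' @param band lower/upper weighted-percentile bounds of the averaging band.
#' @param weighted use survey weights for both ranking and averaging
#'   (default TRUE; FALSE gives the unweighted band).
#' @return subsistence line per equivalent adult (currency).
#' @export
food_poverty_line <- function(households, design = NULL, equivalence_beta = 1,
                              band = c(0.45, 0.55), weighted = TRUE) {
  require_columns(households, c("food_expenditure", "size"), "households")
  if (nrow(households) == 0) stop("food_poverty_line: empty input", call. = FALSE)
  w <- if (!is.null(design)) {
    design$weight[match(households$household_id, design$household_id)]
  } else households$weight
  if (is.null(w) || anyNA(w) || any(w <= 0))
    stop("food_poverty_line: positive weights required for every household",
         call. = FALSE)
  if (!weighted) w <- rep(1, nrow(households))
  per_eq <- households$food_expenditure / households$size^equivalence_beta
  weighted_band_mean(per_eq, w, band[1], band[2])
}

#' Capacity to pay
#'
#' Capacity-to-pay is annual household expenditure minus subsistence
#' spending, where subsistence is the food poverty line scaled by household
#' size (`line x size^beta`). Households whose actual food spending falls
#' below their subsistence requirement use their actual food spending
#' instead (the convention of the 40%-threshold CHE methodology, preventing
#' negative-capacity artifacts). Capacity is floored at a small positive
#' epsilon; households with nonpositive total expenditure are flagged
#' `excluded` and dropped from CHE denominators downstream.
#'
#' @param households table with `household_id`, `expenditure`,
#'   `food_expenditure`, `size`.
#' @param line subsistence line per equivalent adult (from
#'   [food_poverty_line()]; must be >= 0).
#' @param equivalence_beta same exponent used for the line.
#' @param epsilon positive floor for capacity-to-pay.
#' @return data frame of class `capacity_to_pay`: `household_id`,
#'   `expenditure`, `food_expenditure`, `size`, `eq_size`, `subsistence`,
#'   `capacity_to_pay`, `floored`, `excluded`; the number of floored rows is
#'   reported via a message.
#' @export
capacity_to_pay <- function(households, line, equivalence_beta = 1,
                            epsilon = 0.01) {
  require_columns(households, c("household_id", "expenditure",
                                "food_expenditure", "size"), "households")
  if (length(line) != 1L || !is.finite(line) || line < 0)
    stop("capacity_to_pay: line must be a single nonnegative number", call. = FALSE)
  stopifnot(epsilon > 0)
  eq_size <- households$size^equivalence_beta
  subsistence <- line * eq_size
  spend_sub <- ifelse(households$food_expenditure < subsistence,
                      households$food_expenditure, subsistence)
  ctp <- households$expenditure - spend_sub
  excluded <- households$expenditure <= 0
  floored <- !excluded & ctp < epsilon
  ctp[floored] <- epsilon
  if (any(floored))
    message(sprintf("capacity_to_pay: %d household(s) floored at epsilon=%g",
                    sum(floored), epsilon))
  if (any(excluded))
    message(sprintf("capacity_to_pay: %d household(s) with nonpositive expenditure excluded",
                    sum(excluded)))
  out <- data.frame(household_id = households$household_id,
                    expenditure = households$expenditure,
                    food_expenditure = households$food_expenditure,
                    size = households$size, eq_size = eq_size,
                    subsistence = subsistence, capacity_to_pay = ctp,
                    floored = floored, excluded = excluded,
                    stringsAsFactors = FALSE)
  class(out) <- c("capacity_to_pay", class(out))
  out
}

#' Flag catastrophic health expenditure
#'
#' A household incurs CHE when its annual OOP health spending strictly
#' exceeds `threshold` times its capacity-to-pay.
#'
#' @param household_oop data frame with `household_id` and `total` (annual
#'   household OOP; typically from [household_oop_by_disease()]).
#' @param ctp [capacity_to_pay()] output.
#' @param threshold capacity-to-pay fraction (default 0.40).
#' @return data frame: `household_id`, `oop`, `capacity_to_pay`, `che`
#'   (logical; `NA` for excluded households).
#' @export
flag_che <- function(household_oop, ctp, threshold = 0.40) {
  require_columns(household_oop, c("household_id", "total"), "household_oop")
  if (!is_prob(threshold) || threshold == 0)
    stop("threshold must lie in (0,1]", call. = FALSE)
  idx <- match(household_oop$household_id, ctp$household_id)
  if (anyNA(idx))
    stop("flag_che: capacity-to-pay missing for some households", call. = FALSE)
  che <- household_oop$total > threshold * ctp$capacity_to_pay[idx]
  che[ctp$excluded[idx]] <- NA
  data.frame(household_id = household_oop$household_id,
             oop = household_oop$total,
             capacity_to_pay = ctp$capacity_to_pay[idx],
             che = che, stringsAsFactors = FALSE)
}

#' Attribute CHE cases to a disease area
#'
#' A CHE case is assigned to NCD, CD or INJURY if OOP spending on that
#' disease area strictly exceeds `cutoff` (default 75%) of the household's
#' disease-specific OOP spending (the NCD + CD + INJURY total; spending in
#' the PAIN/SURGERY/OTHER/UNIDENTIFIED groups is excluded from the
#' attribution denominator). Cases with all spending in one disease area are
#' assigned to it (their share is 1). All other cases — including those with
#' zero disease-specific spending — are `UNALLOCABLE`.
#'
#' @param case_oop data frame with columns `NCD`, `CD`, `INJURY` (household
#'   OOP by disease area for flagged cases).
#' @param cutoff attribution cutoff in (0,1); strict inequality.
#' @return character vector: `"NCD"`, `"CD"`, `"INJURY"` or
#'   `"UNALLOCABLE"`.
#' @export
attribute_che <- function(case_oop, cutoff = 0.75) {
  require_columns(case_oop, disease_categories(), "case_oop")
  if (!is_prob(cutoff) || cutoff == 0) stop("cutoff must lie in (0,1]", call. = FALSE)
  m <- as.matrix(case_oop[, disease_categories(), drop = FALSE])
  denom <- rowSums(m)
  out <- rep("UNALLOCABLE", nrow(m))
  ok <- denom > 0
  if (any(ok)) {
    share <- m[ok, , drop = FALSE] / denom[ok]
    top <- max.col(share, ties.method = "first")
    top_share <- share[cbind(seq_len(nrow(share)), top)]
    # strict ">" with a 1e-9 guard so a share exactly at the cutoff is never
    # pushed over it by floating-point round-off in the division
    over <- top_share > cutoff + 1e-9
    out[ok][over] <- disease_categories()[top][over]
  }
  out
}

# Household-level CHE case table: flags + attribution in one pass.
# Returns one row per household with weight, quintile, category.
build_che_cases <- function(hh_oop, ctp, households, threshold = 0.40,
                            cutoff = 0.75) {
  flags <- flag_che(hh_oop, ctp, threshold)
  category <- rep(NA_character_, nrow(flags))
  is_case <- !is.na(flags$che) & flags$che
  if (any(is_case)) {
    category[is_case] <- attribute_che(hh_oop[is_case, , drop = FALSE], cutoff)
  }
  idx <- match(flags$household_id, households$household_id)
  data.frame(household_id = flags$household_id,
             country = households$country[idx],
             stratum = households$stratum[idx],
             psu = households$psu[idx],
             weight = households$weight[idx],
             wealth_quintile = households$wealth_quintile[idx],
             oop = flags$oop, capacity_to_pay = flags$capacity_to_pay,
             che = flags$che, category = category,
             stringsAsFactors = FALSE)
}

che_categories <- function() c(disease_categories(), "UNALLOCABLE")

#' Survey-weighted CHE shares by disease area
#'
#' Two normalizations, per country: (a) the weighted share of all households
#' incurring CHE attributed to each category (denominator: all non-excluded
#' households) and (b) each category's weighted share of CHE cases
#' (denominator: CHE cases; sums to 100% across categories). Both are
#' reported in percent.
#'
#' @param cases case table from [build_che_cases()] (columns `weight`,
#'   `che`, `category`, `country`).
#' @return data frame: `country`, `category`, `share_households`,
#'   `share_cases` (percent; `share_cases` is `NA` with a message if a
#'   country has no CHE cases).
#' @export
che_share_by_disease <- function(cases) {
  require_columns(cases, c("country", "weight", "che", "category"), "cases")
  cats <- che_categories()
  res <- list()
  for (cty in unique(cases$country)) {
    d <- cases[cases$country == cty & !is.na(cases$che), , drop = FALSE]
    w_all <- sum(d$weight)
    case_rows <- d$che
    w_case <- sum(d$weight[case_rows])
    if (w_case == 0)
      message(sprintf("che_share_by_disease: no CHE cases in %s; case shares undefined", cty))
    for (cat in cats) {
      w_cat <- sum(d$weight[case_rows & !is.na(d$category) & d$category == cat])
      res[[length(res) + 1L]] <- data.frame(
        country = cty, category = cat,
        share_households = 100 * w_cat / w_all,
        share_cases = if (w_case > 0) 100 * w_cat / w_case else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' CHE rates and composition by wealth quintile
#'
#' Per country and wealth quintile: the weighted share of households with
#' CHE by category (percent of the quintile's households) and each
#' category's share of the quintile's CHE cases.
#'
#' @param cases case table from [build_che_cases()] (must carry
#'   `wealth_quintile`).
#' @return data frame: `country`, `wealth_quintile`, `category`,
#'   `share_households`, `share_cases`, plus the quintile-level overall
#'   `che_rate` (percent). Empty quintiles are reported as `NA` with a
#'   message.
#' @export
che_by_wealth_quintile <- function(cases) {
  require_columns(cases, c("country", "weight", "che", "category",
                           "wealth_quintile"), "cases")
  res <- list()
  for (cty in unique(cases$country)) {
    for (q in 1:5) {
      d <- cases[cases$country == cty & !is.na(cases$che) &
                   cases$wealth_quintile == q, , drop = FALSE]
      if (nrow(d) == 0) {
        message(sprintf("che_by_wealth_quintile: no households in %s quintile %d", cty, q))
        res[[length(res) + 1L]] <- data.frame(
          country = cty, wealth_quintile = q, category = che_categories(),
          share_households = NA_real_, share_cases = NA_real_,
          che_rate = NA_real_, stringsAsFactors = FALSE)
        next
      }
      w_all <- sum(d$weight)
      w_case <- sum(d$weight[d$che])
      rate <- 100 * w_case / w_all
      for (cat in che_categories()) {
        w_cat <- sum(d$weight[d$che & !is.na(d$category) & d$category == cat])
        res[[length(res) + 1L]] <- data.frame(
          country = cty, wealth_quintile = q, category = cat,
          share_households = 100 * w_cat / w_all,
          share_cases = if (w_case > 0) 100 * w_cat / w_case else NA_real_,
          che_rate = rate, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, res)
}

#' Strata-resampled cluster bootstrap
#'
#' Non-parametric bootstrap respecting the complex survey design: within
#' each stratum of `n_h` primary sampling units (PSUs), `n_h - 1` PSUs are
#' resampled with replacement (a sampled PSU contributes all of its member
#' rows) and, when a `weight` column is present, the replicate weights of
#' the stratum are rescaled by `n_h / (n_h - 1)` — the Rao–Wu rescaling
#' bootstrap, which removes the `(n_h - 1) / n_h` variance bias of naive
#' with-replacement cluster resampling. The estimator is recomputed on each
#' replicate and percentile intervals are returned. Strata containing a
#' single PSU are merged with the next stratum (in sorted stratum order),
#' with a message.
#'
#' @param estimator function taking a data frame and returning a (possibly
#'   named) numeric vector.
#' @param data data frame with `stratum` and `psu` columns (plus whatever
#'   the estimator needs).
#' @param B number of replicates (>= 2; 1000 for production intervals).
#' @param seed RNG seed.
#' @param conf interval coverage (default 0.95, giving 2.5/97.5 percentile
#'   bounds).
#' @param rescale use the Rao–Wu `n_h - 1` rescaling scheme (default TRUE);
#'   FALSE resamples `n_h` PSUs per stratum without weight rescaling.
#' @return data frame of class `bootstrap_estimate`: `stat`, `estimate`,
#'   `lower`, `upper`, `B`. A warning is raised if a point estimate falls
#'   outside its percentile interval.
#' @export
bootstrap_ui <- function(estimator, data, B = 1000, seed = 1L, conf = 0.95,
                         rescale = TRUE) {
  stopifnot(is.function(estimator), B >= 2)
  require_columns(data, c("stratum", "psu"), "data")
  point <- estimator(data)
  if (is.null(names(point)))
    names(point) <- if (length(point) == 1) "estimate"
                    else paste0("stat", seq_along(point))
  stratum <- as.character(data$stratum)
  # merge single-PSU strata with the adjacent stratum
  repeat {
    npsu <- tapply(data$psu, stratum, function(p) length(unique(p)))
    singles <- names(npsu)[npsu < 2]
    if (!length(singles) || length(npsu) == 1) break
    s <- singles[1]
    others <- sort(names(npsu))
    pos <- match(s, others)
    target <- if (pos < length(others)) others[pos + 1] else others[pos - 1]
    message(sprintf("bootstrap_ui: merging single-PSU stratum %s into %s", s, target))
    stratum[stratum == s] <- target
  }
  psu_rows <- split(seq_len(nrow(data)), paste(stratum, data$psu, sep = "\r"))
  psu_stratum <- vapply(strsplit(names(psu_rows), "\r", fixed = TRUE), `[`, "", 1)
  psus_by_stratum <- split(seq_along(psu_rows), psu_stratum)
  has_weight <- "weight" %in% names(data)

  set.seed(seed)
  reps <- matrix(NA_real_, B, length(point))
  for (b in seq_len(B)) {
    take <- unlist(lapply(psus_by_stratum, function(ps) {
      k <- length(ps)
      m <- if (rescale) max(1L, k - 1L) else k
      ps[sample.int(k, m, replace = TRUE)]
    }), use.names = FALSE)
    rows <- unlist(psu_rows[take], use.names = FALSE)
    rep_data <- data[rows, , drop = FALSE]
    if (rescale && has_weight) {
      st <- stratum[rows]
      k_h <- lengths(psus_by_stratum)
      m_h <- setNames(pmax(1L, k_h - 1L), names(k_h))
      rep_data$weight <- rep_data$weight * (k_h[st] / m_h[st])
    }
    reps[b, ] <- estimator(rep_data)
  }
  alpha <- (1 - conf) / 2
  lower <- apply(reps, 2, quantile, probs = alpha, na.rm = TRUE)
  upper <- apply(reps, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
  out <- data.frame(stat = names(point), estimate = as.numeric(point),
                    lower = as.numeric(lower), upper = as.numeric(upper),
                    B = B, stringsAsFactors = FALSE)
  bad <- !is.na(out$estimate) & (out$estimate < out$lower | out$estimate > out$upper)
  if (any(bad))
    warning(sprintf("bootstrap_ui: point estimate outside percentile interval for %s",
                    paste(out$stat[bad], collapse = ", ")), call. = FALSE)
  class(out) <- c("bootstrap_estimate", class(out))
  out
}

#' Pair NCD CHE shares with NCD DALY shares
#'
#' Joins the estimated NCD share of CHE cases with an externally supplied
#' reference table of the NCD share of adult (20+) disability-adjusted life
#' years per country. The DALY shares are inputs, not computed.
#'
#' @param che_shares data frame with `country` and `ncd_share_che` (0-1 or
#'   percent, passed through unchanged).
#' @param daly_table data frame with `country` and
#'   `ncd_daly_share_adults_20plus` in `[0,1]`.
#' @return joined data frame: `country`, `ncd_share_che`, `ncd_daly_share`.
#' @export
ncd_share_vs_dalys <- function(che_shares, daly_table) {
  require_columns(che_shares, c("country", "ncd_share_che"), "che_shares")
  require_columns(daly_table, c("country", "ncd_daly_share_adults_20plus"),
                  "daly_table")
  if (anyDuplicated(daly_table$country))
    stop("daly_table: duplicate country entries", call. = FALSE)
  if (any(daly_table$ncd_daly_share_adults_20plus < 0 |
          daly_table$ncd_daly_share_adults_20plus > 1))
    stop("daly_table: NCD DALY shares must lie in [0,1]", call. = FALSE)
  missing <- setdiff(che_shares$country, daly_table$country)
  if (length(missing))
    stop(sprintf("daly_table: missing countries: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  idx <- match(che_shares$country, daly_table$country)
  data.frame(country = che_shares$country,
             ncd_share_che = che_shares$ncd_share_che,
             ncd_daly_share = daly_table$ncd_daly_share_adults_20plus[idx],
             stringsAsFactors = FALSE)
}
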