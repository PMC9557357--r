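# Synthetic multi-country ageing-and-adult-health survey generator.
#
# Emulates the design features the downstream analysis relies on: stratified
# multistage cluster sampling with oversampling of households containing
# adults aged 50+, survey weights that invert the stage-wise selection
# probabilities, per-respondent visit counts with cause structure, and a
# two-part out-of-pocket cost law whose parameters are retained as ground
# truth for parameter-recovery tests.

#' Simulation configuration for the synthetic survey generator
#'
#' Builds and validates the full set of data-generating parameters. Defaults
#' are calibrated to resemble adult household surveys in middle-income
#' settings: 1.4–1.8 outpatient visits per person-year, roughly 0.1
#' hospitalizations per person-year, oversampling of 50+ households, and a
#' heavy-tailed out-of-pocket (OOP) cost distribution in which
#' non-communicable disease (NCD) visits cost `ncd_cost_ratio` times as much
#' as communicable disease (CD) visits on the positive part.
#'
#' @param n_households number of households to generate (split evenly across
#'   `countries`).
#' @param countries character vector of country labels.
#' @param seed integer seed; the same seed yields byte-identical output.
#' @param share_50plus_households sampled share of households of the 50+
#'   type (all members aged 50+ interviewed); the remainder are 18–49
#'   households with a single interviewed adult.
#' @param pop_share_50plus population share of 50+ households; the gap to
#'   `share_50plus_households` is the oversampling the weights undo.
#' @param n_strata,psus_per_stratum sampling design dimensions per country.
#' @param visit_rate_outpatient,visit_rate_inpatient mean visits per person
#'   per year.
#' @param visit_dispersion negative-binomial size parameter for visit counts
#'   (`Inf` gives Poisson).
#' @param visit_cap optional cap on visit counts per care level (default
#'   none).
#' @param cause_mix named probability vector over the seven cause groups
#'   (must sum to 1 within 1e-12).
#' @param cause_covariate_strength scale of the covariate signal in the
#'   cause mix (age pushes NCD up / CD down; male sex pushes injuries up).
#'   0 removes all signal; large values make cause a near-deterministic
#'   function of covariates.
#' @param cause_concentration probability that a visit repeats the
#'   respondent's latent primary cause rather than a fresh draw from the
#'   covariate-adjusted mix (chronic conditions generate repeat visits).
#' @param cause_visit_rate_mult named multiplier on both visit rates by the
#'   respondent's primary cause (lets, e.g., NCD respondents accumulate many
#'   visits).
#' @param ncd_cost_ratio true multiplicative NCD-vs-CD effect on the
#'   positive-cost mean (log-scale offset `log(ncd_cost_ratio)`).
#' @param cost_params list of two-part cost-law parameters; see Details.
#' @param expenditure_params list with `meanlog`, `sdlog` of log-normal
#'   annual household expenditure and `food_share_shape1/2` of the Beta food
#'   share.
#' @param private_sector_prob named per-cause probability of attending a
#'   private facility.
#' @param ppp_factor purchasing-power-parity factor from the generator's
#'   nominal currency to 2017 international dollars (exercises the
#'   conversion path; 1 = already international dollars).
#'
#' @details `cost_params` holds, per care level, `p_positive` (probability
#'   of nonzero OOP), `meanlog` (log-scale intercept of the positive cost),
#'   and `sdlog`; plus `cause_offsets` (log-scale additive effects by cause
#'   group, CD = 0 reference; the NCD entry defaults to
#'   `log(ncd_cost_ratio)`) and covariate slopes `beta_age` (per decade from
#'   45), `beta_urban`, `beta_educ` (per level from 1.5), `beta_female`,
#'   `beta_wealth` (per quintile from 3).
#'
#' @return a validated list of class `sim_config`.
#' @seealso [simulate_sage()], [generate_population()], [generate_visits()]
#' @export
sim_config <- function(n_households = 2000,
                       countries = "A",
                       seed = 1L,
                       share_50plus_households = 0.55,
                       pop_share_50plus = 0.35,
                       n_strata = 8L,
                       psus_per_stratum = 8L,
                       visit_rate_outpatient = 1.6,
                       visit_rate_inpatient = 0.10,
                       visit_dispersion = 1.2,
                       visit_cap = NULL,
                       cause_mix = c(NCD = 0.34, CD = 0.30, INJURY = 0.08,
                                     PAIN = 0.11, SURGERY = 0.05,
                                     OTHER = 0.07, UNIDENTIFIED = 0.05),
                       cause_covariate_strength = 1,
                       cause_concentration = 0.6,
                       cause_visit_rate_mult = NULL,
                       ncd_cost_ratio = 1.6,
                       cost_params = NULL,
                       expenditure_params = NULL,
                       private_sector_prob = NULL,
                       ppp_factor = 1) {
  if (!is_count(n_households)) stop_config("n_households", "must be a nonnegative integer")
  if (!length(countries) || anyNA(countries)) stop_config("countries", "must be a nonempty character vector")
  if (length(seed) != 1L || !is.finite(seed)) stop_config("seed", "must be a single integer")
  if (!is_prob(share_50plus_households)) stop_config("share_50plus_households", "must lie in [0,1]")
  if (!is_prob(pop_share_50plus)) stop_config("pop_share_50plus", "must lie in [0,1]")
  if (!is_count(n_strata) || n_strata < 1) stop_config("n_strata", "must be a positive integer")
  if (!is_count(psus_per_stratum) || psus_per_stratum < 1) stop_config("psus_per_stratum", "must be a positive integer")
  for (f in c("visit_rate_outpatient", "visit_rate_inpatient")) {
    v <- get(f)
    if (length(v) != 1L || !is.finite(v) || v < 0) stop_config(f, "must be a nonnegative real")
  }
  if (length(visit_dispersion) != 1L || is.na(visit_dispersion) || visit_dispersion <= 0)
    stop_config("visit_dispersion", "must be positive (Inf for Poisson)")
  if (!is.null(visit_cap) && (!is_count(visit_cap) || visit_cap < 1))
    stop_config("visit_cap", "must be NULL or a positive integer")

  groups <- cause_groups()
  if (!all(sort(names(cause_mix)) == sort(groups)))
    stop_config("cause_mix", "must be named by the seven cause groups")
  cause_mix <- cause_mix[groups]
  if (any(cause_mix < 0) || abs(sum(cause_mix) - 1) > 1e-12)
    stop_config("cause_mix", "must be a probability vector summing to 1 (tolerance 1e-12)")
  if (length(cause_covariate_strength) != 1L || cause_covariate_strength < 0)
    stop_config("cause_covariate_strength", "must be a nonnegative real")
  if (!is_prob(cause_concentration)) stop_config("cause_concentration", "must lie in [0,1]")

  if (is.null(cause_visit_rate_mult))
    cause_visit_rate_mult <- setNames(rep(1, 7), groups)
  if (!all(groups %in% names(cause_visit_rate_mult)) || any(cause_visit_rate_mult < 0))
    stop_config("cause_visit_rate_mult", "must be nonnegative and named by cause group")
  cause_visit_rate_mult <- cause_visit_rate_mult[groups]

  if (length(ncd_cost_ratio) != 1L || !is.finite(ncd_cost_ratio) || ncd_cost_ratio <= 0)
    stop_config("ncd_cost_ratio", "must be a positive real")

  default_cost <- list(
    p_positive = c(outpatient = 0.80, inpatient = 0.85),
    meanlog = c(outpatient = log(25), inpatient = log(250)),
    sdlog = c(outpatient = 1.3, inpatient = 1.3),
    cause_offsets = c(NCD = log(ncd_cost_ratio), CD = 0, INJURY = 0.20,
                      PAIN = -0.30, SURGERY = 0.50, OTHER = -0.20,
                      UNIDENTIFIED = -0.10),
    beta_age = 0.10, beta_urban = 0.15, beta_educ = 0.05,
    beta_female = -0.05, beta_wealth = 0.05)
  cost_params <- utils::modifyList(default_cost, cost_params %||% list())
  if (!all(cost_params$p_positive >= 0 & cost_params$p_positive <= 1))
    stop_config("cost_params$p_positive", "must lie in [0,1]")
  if (any(cost_params$sdlog <= 0)) stop_config("cost_params$sdlog", "must be positive")
  cost_params$cause_offsets <- cost_params$cause_offsets[groups]
  if (anyNA(cost_params$cause_offsets))
    stop_config("cost_params$cause_offsets", "must be named by the seven cause groups")

  expenditure_params <- utils::modifyList(
    list(meanlog = log(4000), sdlog = 0.7,
         food_share_shape1 = 5, food_share_shape2 = 6),
    expenditure_params %||% list())
  if (expenditure_params$sdlog <= 0) stop_config("expenditure_params$sdlog", "must be positive")

  if (is.null(private_sector_prob))
    private_sector_prob <- c(NCD = 0.45, CD = 0.35, INJURY = 0.40, PAIN = 0.40,
                             SURGERY = 0.45, OTHER = 0.40, UNIDENTIFIED = 0.35)
  if (!all(groups %in% names(private_sector_prob)) ||
      any(private_sector_prob < 0 | private_sector_prob > 1))
    stop_config("private_sector_prob", "must be probabilities named by cause group")
  private_sector_prob <- private_sector_prob[groups]

  if (length(ppp_factor) != 1L || !is.finite(ppp_factor) || ppp_factor <= 0)
    stop_config("ppp_factor", "must be a positive real")

  structure(list(
    n_households = as.integer(n_households), countries = as.character(countries),
    seed = as.integer(seed),
    share_50plus_households = share_50plus_households,
    pop_share_50plus = pop_share_50plus,
    n_strata = as.integer(n_strata), psus_per_stratum = as.integer(psus_per_stratum),
    visit_rate_outpatient = visit_rate_outpatient,
    visit_rate_inpatient = visit_rate_inpatient,
    visit_dispersion = visit_dispersion, visit_cap = visit_cap,
    cause_mix = cause_mix,
    cause_covariate_strength = cause_covariate_strength,
    cause_concentration = cause_concentration,
    cause_visit_rate_mult = cause_visit_rate_mult,
    ncd_cost_ratio = ncd_cost_ratio, cost_params = cost_params,
    expenditure_params = expenditure_params,
    private_sector_prob = private_sector_prob,
    ppp_factor = ppp_factor), class = "sim_config")
}

# Covariate-adjusted cause weights, one row per respondent.
# Age pushes NCD up and CD down; male sex pushes INJURY up and age pushes it
# slightly down. At large strength the mix degenerates to a deterministic
# function of (age, sex), which is what high-signal recovery tests exploit.
cause_weights_matrix <- function(age, male, config) {
  s <- config$cause_covariate_strength
  lw <- matrix(log(pmax(config$cause_mix, 1e-12)), nrow = length(age),
               ncol = 7, byrow = TRUE, dimnames = list(NULL, cause_groups()))
  z <- (age - 45) / 15
  lw[, "NCD"] <- lw[, "NCD"] + s * z
  lw[, "CD"] <- lw[, "CD"] - s * z
  lw[, "INJURY"] <- lw[, "INJURY"] + s * (0.4 * male - z / 3)
  w <- exp(lw - apply(lw, 1, max))
  w / rowSums(w)
}

sample_rows <- function(prob_matrix) {
  # one categorical draw per row of a probability matrix
  u <- runif(nrow(prob_matrix))
  cum <- t(apply(prob_matrix, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  colnames(prob_matrix)[pmin(idx, ncol(prob_matrix))]
}

#' Generate the household and respondent frames
#'
#' Draws households into a stratified two-stage design (strata containing
#' primary sampling units, PSUs) with oversampling of 50+ households, then
#' selects respondents the way the emulated surveys do: one adult aged 18–49
#' from each 18–49 household, and all adults aged 50+ from 50+ households.
#' Survey weights invert the type- and stratum-specific selection
#' probabilities and, for 18–49 households, the within-household selection
#' among eligible adults; household weights are normalized to mean 1000.
#' Wealth quintiles are weighted quintiles of a simulated asset index that is
#' correlated with, but distinct from, expenditure.
#'
#' @param config a [sim_config()] object.
#' @return list with `households` and `respondents` data frames.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- cause_groups()
  ncty <- length(config$countries)
  n_by_country <- diff(round(seq(0, config$n_households, length.out = ncty + 1)))

  hh_list <- vector("list", ncty)
  resp_list <- vector("list", ncty)
  for (ci in seq_len(ncty)) {
    cty <- config$countries[ci]
    n <- n_by_country[ci]
    if (n == 0) next
    stratum <- sample(seq_len(config$n_strata), n, replace = TRUE)
    psu_within <- sample(seq_len(config$psus_per_stratum), n, replace = TRUE)
    # PSU-level urbanicity: a fixed 40% of PSUs are urban
    urban_psu <- matrix(rbinom(config$n_strata * config$psus_per_stratum, 1, 0.4),
                        config$n_strata, config$psus_per_stratum)
    # stratum sampling fractions vary, making the design informative
    stratum_factor <- exp(runif(config$n_strata, -0.2, 0.2))

    type50 <- rbinom(n, 1, config$share_50plus_households) == 1
    size <- 1L + rpois(n, 2.2)
    expenditure <- rlnorm(n, config$expenditure_params$meanlog,
                          config$expenditure_params$sdlog)
    food_share <- rbeta(n, config$expenditure_params$food_share_shape1,
                        config$expenditure_params$food_share_shape2)
    food <- food_share * expenditure

    # base design weight: undo 50+ oversampling and stratum sampling fractions
    p_samp <- ifelse(type50, config$share_50plus_households,
                     1 - config$share_50plus_households)
    p_pop <- ifelse(type50, config$pop_share_50plus, 1 - config$pop_share_50plus)
    w <- (p_pop / pmax(p_samp, 1e-9)) * stratum_factor[stratum]
    w <- w / mean(w) * 1000

    asset <- 0.8 * scale(log(expenditure))[, 1] + rnorm(n, 0, 0.6)
    quintile <- weighted_quintile(asset, w)

    hh <- data.frame(
      household_id = sprintf("%s-H%05d", cty, seq_len(n)),
      country = cty,
      stratum = sprintf("%s-S%02d", cty, stratum),
      psu = sprintf("%s-S%02d-P%02d", cty, stratum, psu_within),
      weight = w, hh_type = ifelse(type50, "50plus", "18-49"),
      size = size, expenditure = expenditure, food_expenditure = food,
      asset_index = asset, wealth_quintile = quintile,
      urban = urban_psu[cbind(stratum, psu_within)],
      stringsAsFactors = FALSE)

    n50 <- ifelse(type50, pmin(1L + rbinom(n, 2, 0.4), size), 1L)
    eligible_1849 <- pmin(1L + rpois(n, 0.8), size)
    ridx <- rep(seq_len(n), n50)
    is50 <- type50[ridx]
    age <- ifelse(is50, pmin(50 + rexp(length(ridx), 1 / 12), 95),
                  runif(length(ridx), 18, 49.999))
    resp <- data.frame(
      respondent_id = sprintf("%s-R%06d", cty, seq_along(ridx)),
      household_id = hh$household_id[ridx],
      country = cty,
      age = age,
      sex = ifelse(rbinom(length(ridx), 1, 0.52) == 1, "female", "male"),
      urban = hh$urban[ridx],
      education = sample(0:3, length(ridx), replace = TRUE,
                         prob = c(0.25, 0.35, 0.25, 0.15)),
      wealth_quintile = hh$wealth_quintile[ridx],
      weight = hh$weight[ridx] * ifelse(is50, 1, eligible_1849[ridx]),
      stringsAsFactors = FALSE)
    hh_list[[ci]] <- hh
    resp_list[[ci]] <- resp
  }
  households <- do.call(rbind, hh_list) %||% empty_households()
  respondents <- do.call(rbind, resp_list) %||% empty_respondents()
  if (is.null(households)) households <- empty_households()
  if (is.null(respondents)) respondents <- empty_respondents()
  rownames(households) <- rownames(respondents) <- NULL
  list(households = households, respondents = respondents)
}

empty_households <- function() {
  data.frame(household_id = character(), country = character(),
             stratum = character(), psu = character(), weight = numeric(),
             hh_type = character(), size = integer(), expenditure = numeric(),
             food_expenditure = numeric(), asset_index = numeric(),
             wealth_quintile = integer(), urban = integer(),
             stringsAsFactors = FALSE)
}

empty_respondents <- function() {
  data.frame(respondent_id = character(), household_id = character(),
             country = character(), age = numeric(), sex = character(),
             urban = integer(), education = integer(),
             wealth_quintile = integer(), weight = numeric(),
             stringsAsFactors = FALSE)
}

empty_visits <- function() {
  data.frame(visit_id = character(), respondent_id = character(),
             household_id = character(), country = character(),
             care_level = character(), rank = integer(),
             true_cause = character(), reason_code = integer(),
             facility = character(), true_oop = numeric(),
             stringsAsFactors = FALSE)
}

#' Generate the full (uncensored) visit history
#'
#' For each respondent, draws inpatient and outpatient visit counts from a
#' negative-binomial rate model, assigns each visit a true cause group (a
#' respondent-level latent primary cause repeated with probability
#' `cause_concentration`, otherwise a fresh draw from the covariate-adjusted
#' mix), a raw reason code consistent with that group, a facility sector,
#' and a true OOP cost from the two-part law: zero with probability
#' `1 - p_positive`, else log-normal with a cause/care-level/covariate
#' specific log-scale mean in which the NCD offset equals
#' `log(ncd_cost_ratio)` relative to CD.
#'
#' Recency rank 1 is the most recent visit (within respondent and care
#' level). All visits are emitted with their true cause and cost; apply
#' [censor_to_sage()] to obtain what a survey would actually observe.
#'
#' @param respondents respondent frame from [generate_population()].
#' @param config the same [sim_config()].
#' @return data frame of visits carrying ground truth.
#' @export
generate_visits <- function(respondents, config) {
  stopifnot(inherits(config, "sim_config"))
  require_columns(respondents, c("respondent_id", "household_id", "age", "sex",
                                 "urban", "education", "wealth_quintile"),
                  "respondents")
  set.seed(config$seed + 1L)
  n <- nrow(respondents)
  if (n == 0) return(empty_visits())
  groups <- cause_groups()
  male <- as.numeric(respondents$sex == "male")
  pw <- cause_weights_matrix(respondents$age, male, config)
  primary <- sample_rows(pw)
  mult <- config$cause_visit_rate_mult[primary]

  draw_counts <- function(rate) {
    mu <- rate * mult
    if (is.infinite(config$visit_dispersion)) k <- rpois(n, mu)
    else k <- rnbinom(n, size = config$visit_dispersion, mu = mu)
    if (!is.null(config$visit_cap)) k <- pmin(k, config$visit_cap)
    k
  }
  n_out <- draw_counts(config$visit_rate_outpatient)
  n_in <- draw_counts(config$visit_rate_inpatient)

  build_level <- function(counts, level) {
    ridx <- rep(seq_len(n), counts)
    if (!length(ridx)) return(NULL)
    rank <- sequence(counts[counts > 0])
    keep_primary <- runif(length(ridx)) < config$cause_concentration
    fresh <- sample_rows(pw[ridx, , drop = FALSE])
    cause <- ifelse(keep_primary, primary[ridx], fresh)
    cp <- config$cost_params
    meanlog <- cp$meanlog[[level]] + cp$cause_offsets[cause] +
      cp$beta_age * (respondents$age[ridx] - 45) / 10 +
      cp$beta_urban * respondents$urban[ridx] +
      cp$beta_educ * (respondents$education[ridx] - 1.5) +
      cp$beta_female * (respondents$sex[ridx] == "female") +
      cp$beta_wealth * (respondents$wealth_quintile[ridx] - 3)
    positive <- runif(length(ridx)) < cp$p_positive[[level]]
    cost <- ifelse(positive, rlnorm(length(ridx), meanlog, cp$sdlog[[level]]), 0)
    data.frame(
      respondent_id = respondents$respondent_id[ridx],
      household_id = respondents$household_id[ridx],
      country = respondents$country[ridx],
      care_level = level, rank = rank,
      true_cause = cause,
      reason_code = draw_reason_codes(cause),
      facility = ifelse(runif(length(ridx)) < config$private_sector_prob[cause],
                        "private", "public"),
      true_oop = cost, stringsAsFactors = FALSE)
  }
  out <- rbind(build_level(n_out, "outpatient"), build_level(n_in, "inpatient"))
  if (is.null(out)) return(empty_visits())
  out <- out[order(out$respondent_id, out$care_level, out$rank), , drop = FALSE]
  out$visit_id <- sprintf("V%07d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("visit_id", setdiff(names(out), "visit_id"))]
}

# uniform draw of a raw reason code consistent with the true cause group
draw_reason_codes <- function(cause) {
  cb <- default_codebook()
  by_group <- split(cb$code, cb$group)
  out <- integer(length(cause))
  for (g in unique(cause)) {
    idx <- which(cause == g)
    codes <- by_group[[g]]
    out[idx] <- codes[sample.int(length(codes), length(idx), replace = TRUE)]
  }
  out
}

#' Censor a full visit table to the survey observation pattern
#'
#' Applies the recall structure of the emulated questionnaire: the reason
#' for seeking care (and hence the cause group and facility sector) is
#' observed only for the three most recent visits per care level, and the
#' OOP cost only for the single most recent visit per care level. Total
#' visit counts are retained because every visit keeps its row; unobserved
#' cells become `NA`. The observed table is a pure sub-selection of the
#' truth: no retained value is altered.
#'
#' @param visits full visit table from [generate_visits()] (must carry
#'   recency `rank` within respondent and care level).
#' @return observed visit table with columns `visit_id, respondent_id,
#'   household_id, country, care_level, rank, reason_code, cause, facility,
#'   oop_cost`.
#' @export
censor_to_sage <- function(visits) {
  require_columns(visits, c("respondent_id", "care_level", "rank"), "visits")
  if (nrow(visits) && anyNA(visits$rank))
    stop("visits: recency rank missing; cannot censor", call. = FALSE)
  obs <- data.frame(
    visit_id = visits$visit_id, respondent_id = visits$respondent_id,
    household_id = visits$household_id, country = visits$country,
    care_level = visits$care_level, rank = visits$rank,
    reason_code = ifelse(visits$rank <= 3, visits$reason_code, NA_integer_),
    cause = ifelse(visits$rank <= 3, visits$true_cause, NA_character_),
    facility = ifelse(visits$rank <= 3, visits$facility, NA_character_),
    oop_cost = ifelse(visits$rank == 1, visits$true_oop, NA_real_),
    stringsAsFactors = FALSE)
  rownames(obs) <- NULL
  obs
}

#' Generate, censor and bundle a complete synthetic survey
#'
#' Convenience wrapper running [generate_population()], [generate_visits()]
#' and [censor_to_sage()] and bundling the results with the ground truth.
#'
#' @param config a [sim_config()].
#' @return object of class `sage_sim`: list with `households`,
#'   `respondents`, `visits` (observed/censored), `design`, `truth` (full
#'   visit table plus the generating parameters; for testing only, never an
#'   input to estimation), and `config`.
#' @export
simulate_sage <- function(config = sim_config()) {
  pop <- generate_population(config)
  full <- generate_visits(pop$respondents, config)
  obs <- censor_to_sage(full)
  design <- pop$households[, c("household_id", "stratum", "psu", "weight")]
  structure(list(
    households = pop$households, respondents = pop$respondents,
    visits = obs, design = design,
    truth = list(visits = full,
                 cause_mix = config$cause_mix,
                 ncd_cost_ratio = config$ncd_cost_ratio,
                 cost_params = config$cost_params,
                 ppp_factor = config$ppp_factor),
    config = config), class = "sage_sim")
}

#' @export
print.sage_sim <- function(x, ...) {
  cat("Synthetic survey:", nrow(x$households), "households,",
      nrow(x$respondents), "respondents,", nrow(x$visits), "visits\n")
  cat("Countries:", paste(unique(x$households$country), collapse = ", "), "\n")
  invisible(x)
}
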