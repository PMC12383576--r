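#' Feature specification for the synthetic generator
#'
#' One simulated column: a distribution family, its base parameters, the
#' class-conditional effect applied to positive rows, and whether the column
#' participates in supervised discretization.
#'
#' Families and effects: `lognormal(meanlog, sdlog)` and `gamma(shape, rate)`
#' with a multiplicative positive-class effect; `normal(mean, sd)` and
#' `poisson_like(lambda)` with an additive effect (for `poisson_like` the
#' effect shifts lambda); `bernoulli(prob)` where the effect replaces the
#' positive-class probability.
#'
#' @param name column name.
#' @param family one of `"lognormal"`, `"gamma"`, `"normal"`,
#'   `"poisson_like"`, `"bernoulli"`.
#' @param params named list of base parameters for the family.
#' @param class_effect the positive-class effect (see above); 0 or 1 for "no
#'   effect" depending on family (1 for multiplicative, 0 for additive,
#'   `params$prob` for bernoulli).
#' @param flag whether the column is flagged for discretization (must be
#'   `FALSE` for bernoulli, which is categorical).
#' @return list of class `feature_spec`.
#' @export
feature_spec <- function(name, family, params, class_effect, flag = TRUE) {
  families <- c("lognormal", "gamma", "normal", "poisson_like", "bernoulli")
  if (!family %in% families)
    validation_error(sprintf("unknown family '%s'", family))
  needed <- switch(family,
    lognormal = c("meanlog", "sdlog"), gamma = c("shape", "rate"),
    normal = c("mean", "sd"), poisson_like = "lambda", bernoulli = "prob")
  if (!all(needed %in% names(params)))
    validation_error(sprintf("family '%s' needs parameter(s): %s", family,
                             paste(needed, collapse = ", ")))
  if (family == "bernoulli" && flag)
    validation_error("bernoulli features are categorical; flag must be FALSE")
  structure(list(name = name, family = family, params = params,
                 class_effect = class_effect, flag = flag),
            class = "feature_spec")
}

#' Scenario configuration for the synthetic generator
#'
#' Named scenarios emulate the statistical structure of severely imbalanced
#' clinical tabular data: `"clinical_like"` is the default desk-scale panel
#' (three heavily right-skewed lognormal "lab" features with multiplicative
#' positive-class shifts, four near-normal "hematology" features with small
#' additive shifts, one binary "urine flag" with an elevated positive-class
#' rate and one pure-noise feature); `"separable"` has effects large enough
#' that the classes barely overlap; `"null"` is the same panel as
#' `clinical_like` with every class effect removed; `"threshold_step"` is the
#' single-feature step-probability design of [known_threshold_dataset()].
#'
#' @param scenario scenario name.
#' @param n number of rows (>= 20).
#' @param prevalence positive fraction in (0, 0.5]; the positive count is
#'   `round(n * prevalence)` exactly, by construction.
#' @param seed integer master seed.
#' @param features optional list of [feature_spec()]s overriding the
#'   scenario panel.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("clinical_like", "separable",
                                         "null", "threshold_step"),
                            n = 5000L, prevalence = 0.02, seed = 1L,
                            features = NULL) {
  scenario <- match.arg(scenario)
  if (!(prevalence > 0 && prevalence <= 0.5))
    validation_error("prevalence must be in (0, 0.5]")
  if (n < 20L) validation_error("n must be >= 20")
  if (is.null(features)) features <- scenario_panel(scenario)
  structure(list(scenario = scenario, n = as.integer(n),
                 prevalence = prevalence, seed = as.integer(seed),
                 features = features),
            class = "scenario_config")
}

# Default feature panels. The clinical_like magnitudes follow the structure
# of published pediatric febrile-illness laboratory panels: inflammatory
# markers (CRP-like, transaminase-like) are lognormal with multiplicative
# positive-class shifts of roughly 1.5-3.7x, hematology counts are
# near-normal with shifts of about half a standard deviation, and a binary
# urine flag rises from ~7% to ~43% in positives.
scenario_panel <- function(scenario) {
  clinical <- list(
    feature_spec("crp_like", "lognormal",
                 list(meanlog = log(20), sdlog = 1.2), class_effect = 20),
    feature_spec("alt_like", "lognormal",
                 list(meanlog = log(30), sdlog = 1.5), class_effect = 10),
    feature_spec("ast_like", "lognormal",
                 list(meanlog = log(45), sdlog = 1.5), class_effect = 6),
    feature_spec("wbc_like", "normal",
                 list(mean = 10.8, sd = 5.9), class_effect = 9),
    feature_spec("hgb_like", "normal",
                 list(mean = 12, sd = 1.8), class_effect = -3.2),
    feature_spec("plt_like", "normal",
                 list(mean = 294, sd = 125), class_effect = 220),
    feature_spec("rdw_like", "normal",
                 list(mean = 14.1, sd = 2.1), class_effect = -3),
    feature_spec("urine_flag", "bernoulli",
                 list(prob = 0.05), class_effect = 0.8, flag = FALSE),
    feature_spec("noise", "normal",
                 list(mean = 0, sd = 1), class_effect = 0)
  )
  switch(scenario,
    clinical_like = clinical,
    null = lapply(clinical, function(fs) {
      fs$class_effect <- switch(fs$family,
        lognormal = 1, gamma = 1, bernoulli = fs$params$prob, 0)
      fs
    }),
    separable = list(
      feature_spec("marker_a", "normal",
                   list(mean = 0, sd = 1), class_effect = 8),
      feature_spec("marker_b", "lognormal",
                   list(meanlog = log(10), sdlog = 0.5), class_effect = 20)
    ),
    threshold_step = list(
      feature_spec("x", "normal", list(mean = 0.5, sd = 0.3),
                   class_effect = 0)
    )
  )
}

draw_feature <- function(fs, y, seed) {
  n <- length(y)
  pos <- y == 1L
  set.seed(seed)
  switch(fs$family,
    lognormal = {
      ml <- rep(fs$params$meanlog, n)
      ml[pos] <- ml[pos] + log(fs$class_effect)
      rlnorm(n, meanlog = ml, sdlog = fs$params$sdlog)
    },
    gamma = {
      rate <- rep(fs$params$rate, n)
      rate[pos] <- rate[pos] / fs$class_effect
      rgamma(n, shape = fs$params$shape, rate = rate)
    },
    normal = {
      mu <- rep(fs$params$mean, n)
      mu[pos] <- mu[pos] + fs$class_effect
      rnorm(n, mean = mu, sd = fs$params$sd)
    },
    poisson_like = {
      lam <- rep(fs$params$lambda, n)
      lam[pos] <- pmax(lam[pos] + fs$class_effect, 1e-9)
      rpois(n, lambda = lam)
    },
    bernoulli = {
      pr <- rep(fs$params$prob, n)
      pr[pos] <- fs$class_effect
      rbinom(n, size = 1L, prob = pr)
    }
  )
}

#' Generate a synthetic imbalanced dataset
#'
#' Draws a seeded class-conditional sample for each feature of the scenario.
#' Exactly `round(n * prevalence)` rows are positive (assigned by exact count
#' rather than per-row coin flips, so prevalence carries no sampling noise);
#' the final row order is a seeded shuffle. One master seed governs label
#' assignment and every feature through derived sub-streams, so adding a
#' feature to a panel never perturbs the labels or the other columns.
#'
#' @param config a [scenario_config()].
#' @return a [tabular_dataset()] with the scenario's schema.
#' @export
generate <- function(config) {
  if (!inherits(config, "scenario_config"))
    validation_error("config must be a scenario_config")
  n <- config$n
  n_pos <- round(n * config$prevalence)
  y0 <- c(rep(1L, n_pos), rep(0L, n - n_pos))
  cols <- lapply(config$features, function(fs)
    draw_feature(fs, y0, derive_seed(config$seed, paste0("feat:", fs$name))))
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(config$features, function(fs) fs$name, character(1))
  set.seed(derive_seed(config$seed, "shuffle"))
  ord <- sample.int(n)
  schema <- data.frame(
    name = colnames(X),
    kind = vapply(config$features, function(fs)
      if (fs$family == "bernoulli") "categorical" else "continuous",
      character(1)),
    discretize = vapply(config$features, function(fs) isTRUE(fs$flag),
                        logical(1)),
    stringsAsFactors = FALSE
  )
  tabular_dataset(X[ord, , drop = FALSE], y0[ord], schema)
}

#' Single-feature dataset with a known probability step
#'
#' A uniform feature `x` on `[0, 1]` whose positive probability jumps from
#' `p_low` (for `x <= c`) to `p_high` (for `x > c`); labels are per-row
#' Bernoulli draws under the seed. Used to verify that the supervised
#' discretizer recovers a known cut point (reliable for `n >= 500`; small `n`
#' is out of contract).
#'
#' @param c cut point strictly inside (0, 1).
#' @param n number of rows.
#' @param p_low,p_high positive probabilities below/above the cut,
#'   `p_low < p_high`.
#' @param seed integer seed.
#' @return a [tabular_dataset()] with a single flagged feature `x`.
#' @export
known_threshold_dataset <- function(c = 0.5, n = 1000L, p_low = 0.01,
                                    p_high = 0.9, seed = 1L) {
  if (!(c > 0 && c < 1)) validation_error("c must lie strictly inside (0,1)")
  if (p_low > p_high) validation_error("p_low must be <= p_high")
  set.seed(derive_seed(seed, "step_x"))
  x <- runif(n)
  set.seed(derive_seed(seed, "step_y"))
  y <- rbinom(n, 1L, ifelse(x <= c, p_low, p_high))
  tabular_dataset(matrix(x, ncol = 1, dimnames = list(NULL, "x")), y)
}
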