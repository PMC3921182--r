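#' Fit a repeated-measures mixed model for selection ratios
#'
#' Fits `ln_rf` panels by maximum likelihood with a random intercept per
#' bird and a within-bird serial correlation structure over months: AR(1)
#' (`rho^|t - t'|` on integer month lags, gaps allowed) or compound
#' symmetry. The AR(1) structure reflects that a bird's selection in
#' adjacent months is more alike than in distant months; compound symmetry
#' assumes a constant within-bird correlation.
#'
#' @param data data frame with the response and covariates plus `bird_id`
#'   and either `month_index` (integer time) or `year` + `month` from which
#'   it is built.
#' @param fixed fixed-effects formula, e.g.
#'   `ln_rf ~ sex + factor(month) + thermal_height`.
#' @param covariance `"ar1"` or `"compound_symmetry"`.
#' @return An object of class `soar_fit`: the underlying [nlme::lme] model
#'   plus `loglik`, `k` (parameter count), `n`, `coefficients` (tibble of
#'   term, estimate, se, df, statistic, p.value), `tests` (marginal F-tests
#'   per term), `rho`, `sigma_u`, `sigma`, `covariance`, `data`.
#' @export
fit_rsf_model <- function(data, fixed,
                          covariance = c("ar1", "compound_symmetry")) {
  covariance <- match.arg(covariance)
  data <- as.data.frame(prepare_panel_data(data))
  corr <- switch(covariance,
    ar1 = nlme::corAR1(form = ~ month_index | bird_id),
    compound_symmetry = nlme::corCompSymm(form = ~ month_index | bird_id)
  )
  fit <- tryCatch(
    nlme::lme(fixed, data = data, random = ~ 1 | bird_id, correlation = corr,
              method = "ML",
              control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                         msMaxIter = 200, niterEM = 50)),
    error = function(e) {
      stop("mixed-model fit (", covariance, ") failed: ",
           conditionMessage(e), call. = FALSE)
    }
  )
  ll <- stats::logLik(fit)
  tt <- summary(fit)$tTable
  coefs <- tibble::tibble(
    term = rownames(tt),
    estimate = tt[, "Value"],
    se = tt[, "Std.Error"],
    df = tt[, "DF"],
    statistic = tt[, "t-value"],
    p.value = tt[, "p-value"]
  )
  an <- stats::anova(fit, type = "marginal")
  tests <- tibble::tibble(
    term = rownames(an),
    num_df = an[, "numDF"],
    den_df = an[, "denDF"],
    statistic = an[, "F-value"],
    p.value = an[, "p-value"]
  )
  cs <- fit$modelStruct$corStruct
  rho <- if (!is.null(cs)) unname(stats::coef(cs, unconstrained = FALSE)[1]) else NA_real_
  vc <- nlme::VarCorr(fit)
  structure(list(
    model = fit, loglik = as.numeric(ll), k = attr(ll, "df"),
    n = stats::nobs(fit), coefficients = coefs, tests = tests,
    rho = rho, sigma_u = as.numeric(vc["(Intercept)", "StdDev"]),
    sigma = fit$sigma, covariance = covariance, fixed = fixed, data = data
  ), class = "soar_fit")
}

prepare_panel_data <- function(data) {
  if (!"bird_id" %in% names(data)) stop("data needs a bird_id column", call. = FALSE)
  if (!"month_index" %in% names(data)) {
    if (!all(c("year", "month") %in% names(data))) {
      stop("data needs month_index, or year and month", call. = FALSE)
    }
    data$month_index <- as.integer((data$year - min(data$year)) * 12L + data$month)
  }
  data
}

#' @export
print.soar_fit <- function(x, ...) {
  cat(sprintf(
    "<soar_fit> %s covariance, n = %d, k = %d, logLik = %.2f, AICc = %.2f, rho = %.3f\n",
    x$covariance, x$n, x$k, x$loglik, aicc(x$loglik, x$k, x$n), x$rho
  ))
  invisible(x)
}

#' @method tidy soar_fit
#' @export
tidy.soar_fit <- function(x, ...) x$coefficients

#' @method glance soar_fit
#' @export
glance.soar_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, k = x$k, nobs = x$n,
    AICc = aicc(x$loglik, x$k, x$n),
    rho = x$rho, sigma_u = x$sigma_u, sigma = x$sigma,
    covariance = x$covariance
  )
}

#' Choose between AR(1) and compound-symmetry covariance
#'
#' Fits both serial-correlation structures and retains the one with lower
#' AICc; exact ties go to compound symmetry (the simpler interpretation).
#' If one structure fails to converge the other is returned with a note.
#'
#' @inheritParams fit_rsf_model
#' @return List of class `soar_cov_choice`: `winner` (`"ar1"` or
#'   `"compound_symmetry"`), `aicc` (named vector), `fits` (named list of
#'   [fit_rsf_model()] results), `note`.
#' @export
compare_covariance <- function(data, fixed) {
  fits <- list(
    ar1 = tryCatch(fit_rsf_model(data, fixed, "ar1"), error = identity),
    compound_symmetry = tryCatch(fit_rsf_model(data, fixed, "compound_symmetry"),
                                 error = identity)
  )
  failed <- vapply(fits, inherits, logical(1), "condition")
  if (all(failed)) {
    stop("both covariance structures failed to fit: ",
         conditionMessage(fits$ar1), call. = FALSE)
  }
  note <- NULL
  if (any(failed)) {
    note <- paste(names(fits)[failed], "failed to converge; other retained")
    winner <- names(fits)[!failed]
    av <- stats::setNames(aicc(fits[[winner]]$loglik, fits[[winner]]$k,
                               fits[[winner]]$n), winner)
  } else {
    av <- vapply(fits, function(f) aicc(f$loglik, f$k, f$n), numeric(1))
    winner <- if (av["compound_symmetry"] <= av["ar1"]) "compound_symmetry" else "ar1"
  }
  structure(list(winner = winner, aicc = av,
                 fits = fits[!failed], note = note),
            class = "soar_cov_choice")
}

#' @export
print.soar_cov_choice <- function(x, ...) {
  cat("<soar_cov_choice>", x$winner, "retained; AICc:",
      paste(sprintf("%s = %.2f", names(x$aicc), x$aicc), collapse = ", "), "\n")
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Least-squares marginal means for a model factor
#'
#' Model-predicted factor-level means averaged over a balanced grid of the
#' other categorical terms with continuous covariates at their means
#' (LSMEANS), appropriate for unbalanced panels.
#'
#' @param fit a [fit_rsf_model()] result.
#' @param factor name of a categorical term in the model.
#' @param contrasts if `TRUE` also return pairwise contrasts.
#' @param adjust p-adjustment for contrasts (default `"bonferroni"`).
#' @return Tibble `level`, `mean`, `se`, `df`, `lower`, `upper`; with
#'   `contrasts = TRUE`, a list with `means` and `contrasts`.
#' @export
marginal_means <- function(fit, factor, contrasts = FALSE,
                           adjust = "bonferroni") {
  terms_in <- all.vars(fit$fixed[[3]])
  if (!factor %in% terms_in) {
    stop("factor '", factor, "' is not in the model", call. = FALSE)
  }
  em <- emmeans::emmeans(fit$model, specs = factor, data = fit$data)
  s <- as.data.frame(em)
  means <- tibble::tibble(
    level = as.character(s[[1]]), mean = s$emmean, se = s$SE, df = s$df,
    lower = s$lower.CL, upper = s$upper.CL
  )
  if (!contrasts) return(means)
  ct <- as.data.frame(emmeans::contrast(em, method = "pairwise", adjust = adjust))
  list(means = means,
       contrasts = tibble::tibble(
         contrast = as.character(ct$contrast), estimate = ct$estimate,
         se = ct$SE, df = ct$df, statistic = ct$t.ratio, p.value = ct$p.value
       ))
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1)`; requires `n > k + 1`.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @param n number of observations.
#' @return AICc value (vectorized).
#' @export
aicc <- function(loglik, k, n) {
  if (any(n <= k + 1)) {
    stop("AICc undefined: need n > k + 1", call. = FALSE)
  }
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike model weights
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min(AICc)`; the weights are invariant to adding a
#' constant to every AICc and sum to 1.
#'
#' @param aicc_values numeric vector of AICc values.
#' @return Numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(aicc_values) {
  if (length(aicc_values) == 0) stop("need at least one model", call. = FALSE)
  d <- aicc_values - min(aicc_values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit the candidate model set over meteorological covariates
#'
#' Fits one model per subset of the meteorological parameters (all 2^p
#' subsets, default the 8 subsets of thermal height, thermal velocity and
#' wind speed), holding any bird-characteristic base terms in every model,
#' and ranks the set by AICc.
#'
#' @param data panel data (see [fit_rsf_model()]).
#' @param base_terms character vector of terms present in every model (may
#'   be empty for an intercept-plus-met set).
#' @param met_terms character vector of met covariates to combine.
#' @param response response column name (default `"ln_rf"`).
#' @param covariance serial-correlation structure for all fits.
#' @return Object of class `soar_candidates`: tibble with `model_id`,
#'   `met_terms` (list), `fit` (list of `soar_fit`), `loglik`, `k`, `n`,
#'   `aicc`, `delta`, `weight`, sorted by AICc.
#' @export
fit_candidates <- function(data, base_terms = character(),
                           met_terms = c("thermal_height", "thermal_velocity",
                                         "wind_speed"),
                           response = "ln_rf",
                           covariance = "ar1") {
  subsets <- purrr::map(0:(2^length(met_terms) - 1), function(mask) {
    met_terms[bitwAnd(mask, 2^(seq_along(met_terms) - 1)) > 0]
  })
  fits <- purrr::map(subsets, function(ms) {
    rhs <- c(base_terms, ms)
    f <- stats::reformulate(if (length(rhs)) rhs else "1", response = response)
    fit_rsf_model(data, f, covariance = covariance)
  })
  tbl <- tibble::tibble(
    model_id = purrr::map_chr(subsets, ~ if (length(.x)) paste(.x, collapse = "+") else "(null)"),
    met_terms = subsets,
    fit = fits,
    loglik = purrr::map_dbl(fits, "loglik"),
    k = purrr::map_dbl(fits, "k"),
    n = purrr::map_dbl(fits, "n")
  )
  tbl$aicc <- aicc(tbl$loglik, tbl$k, tbl$n)
  tbl$delta <- tbl$aicc - min(tbl$aicc)
  tbl$weight <- akaike_weights(tbl$aicc)
  tbl <- dplyr::arrange(tbl, .data$aicc)
  class(tbl) <- c("soar_candidates", class(tbl))
  tbl
}

#' @method tidy soar_candidates
#' @export
tidy.soar_candidates <- function(x, ...) {
  tibble::as_tibble(x)[, c("model_id", "loglik", "k", "n", "aicc", "delta", "weight")]
}

#' Model-averaged coefficient with unconditional standard error
#'
#' Shrinkage (full-set) model averaging: each parameter's estimate is the
#' Akaike-weight-weighted mean of its per-model estimates, with estimate 0
#' (and variance 0) in models that exclude it, so rarely supported
#' parameters shrink toward zero. The unconditional SE,
#' `sqrt(sum_i w_i (var_i + (b_i - b_bar)^2))`, folds model-selection
#' uncertainty into the interval. The importance weight of a parameter is
#' the summed weight of the models containing it. Conditional averaging
#' (over containing models only) is available via `conditional = TRUE`.
#'
#' @param candidates a [fit_candidates()] result (or a tibble with columns
#'   `weight`, `met_terms`, `fit`).
#' @param parameters parameter names to average (default: all met terms in
#'   the candidate set).
#' @param conditional average over containing models only.
#' @param conf_level normal-theory interval level (default 0.95).
#' @return Object of class `soar_modelavg`: tibble `parameter`, `estimate`,
#'   `se`, `lower`, `upper`, `importance`.
#' @export
model_average <- function(candidates, parameters = NULL, conditional = FALSE,
                          conf_level = 0.95) {
  parameters <- parameters %||% unique(unlist(candidates$met_terms))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- purrr::map_dfr(parameters, function(p) {
    beta <- var <- has <- numeric(nrow(candidates))
    for (i in seq_len(nrow(candidates))) {
      cf <- candidates$fit[[i]]$coefficients
      j <- match(p, cf$term)
      if (!is.na(j)) {
        beta[i] <- cf$estimate[j]; var[i] <- cf$se[j]^2; has[i] <- 1
      }
    }
    w <- candidates$weight
    importance <- sum(w[has == 1])
    if (conditional) {
      if (importance == 0) {
        return(tibble::tibble(parameter = p, estimate = 0, se = 0,
                              lower = 0, upper = 0, importance = 0))
      }
      w <- w * has / importance
    }
    est <- sum(w * beta)
    se <- sqrt(sum(w * (var + (beta - est)^2)))
    tibble::tibble(parameter = p, estimate = est, se = se,
                   lower = est - z * se, upper = est + z * se,
                   importance = importance)
  })
  class(rows) <- c("soar_modelavg", class(rows))
  rows
}

#' @method tidy soar_modelavg
#' @export
tidy.soar_modelavg <- function(x, ...) tibble::as_tibble(x)

#' Multiplicative effect of a covariate change on the selection ratio
#'
#' Because the response is `ln(rf)`, a slope `beta` means a change of
#' `delta_x` in the covariate multiplies the selection ratio rf by
#' `exp(beta * delta_x)`.
#'
#' @param beta model (or model-averaged) coefficient.
#' @param delta_x covariate change in its native units (default 1).
#' @param digits optional rounding for reporting.
#' @return The multiplicative change in rf.
#' @export
effect_multiplier <- function(beta, delta_x = 1, digits = NULL) {
  out <- exp(beta * delta_x)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Screen effect tests at a strict alpha
#'
#' Flags effects with `p < alpha` (strict inequality; default 0.01, a
#' conservative threshold chosen to limit Type I errors across many
#' habitat- and ecoregion-level tests).
#'
#' @param test_table data frame with a `p.value` column.
#' @param alpha significance threshold.
#' @return The table with a logical `flagged` column added.
#' @export
screen_effects <- function(test_table, alpha = 0.01) {
  stopifnot("p.value" %in% names(test_table))
  p <- test_table$p.value
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]", call. = FALSE)
  dplyr::mutate(tibble::as_tibble(test_table),
                flagged = !is.na(p) & p < alpha)
}

#' Simulate ln(rf) panels from the repeated-measures model family
#'
#' Generates multi-bird monthly panels directly from the model the fitting
#' code assumes: `ln_rf = b0 + X beta + u_bird + e`, with `u_bird ~ N(0,
#' sigma_u^2)` and `e` a stationary AR(1) process over months (lag-1
#' correlation `rho`, marginal SD `sigma`). Meteorological covariates follow
#' a seasonal sinusoid plus bird-month noise so slopes are identifiable.
#'
#' @param seed RNG seed.
#' @param n_birds,months panel dimensions (months as integer vector).
#' @param beta named vector of covariate slopes (names become columns).
#' @param intercept fixed intercept.
#' @param rho AR(1) lag-1 correlation in (-1, 1).
#' @param sigma_u random-intercept SD.
#' @param sigma residual (marginal) SD.
#' @param x_amplitude,x_noise_sd seasonal amplitude and bird-month noise SD
#'   of the simulated covariates.
#' @return Tibble `bird_id`, `year`, `month`, `month_index`, one column per
#'   covariate, `ln_rf`.
#' @export
simulate_lnrf_panels <- function(seed, n_birds = 40, months = 1:12,
                                 beta = c(thermal_height = 1),
                                 intercept = 0, rho = 0.6, sigma_u = 0.3,
                                 sigma = 0.5, x_amplitude = 0.5,
                                 x_noise_sd = 0.3) {
  stopifnot(abs(rho) < 1)
  seed_rng(seed)
  nm <- length(months)
  grid <- tidyr::expand_grid(
    bird_id = sprintf("bird_%02d", seq_len(n_birds)),
    month = as.integer(months)
  )
  grid$year <- 2008L
  grid$month_index <- grid$month
  for (p in names(beta)) {
    grid[[p]] <- 1 + x_amplitude * cos(2 * pi * (grid$month - 6) / 12) +
      stats::rnorm(nrow(grid), 0, x_noise_sd)
  }
  u <- stats::rnorm(n_birds, 0, sigma_u)
  e <- as.vector(vapply(seq_len(n_birds), function(b) {
    z <- stats::rnorm(nm)
    out <- numeric(nm)
    out[1] <- sigma * z[1]
    for (t in seq_len(nm)[-1]) {
      out[t] <- rho * out[t - 1] + sigma * sqrt(1 - rho^2) * z[t]
    }
    out
  }, numeric(nm)))
  X <- as.matrix(grid[, names(beta), drop = FALSE])
  grid$ln_rf <- intercept + as.vector(X %*% beta) +
    rep(u, each = nm) + e
  grid[, c("bird_id", "year", "month", "month_index", names(beta), "ln_rf")]
}
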