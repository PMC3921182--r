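test_that("AICc and Akaike weights match direct arithmetic", {
  expect_equal(aicc(0, 1, 100), 2 + 4 / 98)
  # large-n limit recovers AIC
  expect_equal(aicc(-10, 3, 1e9), 20 + 6, tolerance = 1e-6)
  expect_error(aicc(0, 10, 11), "n > k")
  # random tuples against the formula written out independently
  set.seed(61)
  for (i in 1:5) {
    ll <- stats::rnorm(1, -50, 10); k <- sample(2:6, 1); n <- sample(30:100, 1)
    expect_equal(aicc(ll, k, n),
                 -2 * ll + 2 * k + (2 * k * (k + 1)) / (n - k - 1))
  }

  expect_equal(akaike_weights(rep(123.4, 4)), rep(0.25, 4))
  w <- akaike_weights(c(100, 102))
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  # normalization and shift invariance
  set.seed(62)
  a <- stats::runif(6, 200, 240)
  expect_equal(sum(akaike_weights(a)), 1, tolerance = 1e-12)
  expect_equal(akaike_weights(a + 57.3), akaike_weights(a), tolerance = 1e-12)
  expect_equal(akaike_weights(150), 1)
})

test_that("effect multiplier converts ln(rf) slopes to rf ratios", {
  # the model-averaged thermal-height slope of 1.080 corresponds to a
  # ~2.9-fold change in the selection ratio per km
  expect_equal(effect_multiplier(1.080, 1), exp(1.080))
  expect_lt(abs(effect_multiplier(1.080, 1) - 2.95), 0.006)
  expect_equal(effect_multiplier(0), 1)
  expect_equal(effect_multiplier(-0.218, 1), exp(-0.218))
  expect_equal(effect_multiplier(0.5, 2, digits = 2), round(exp(1), 2))
})

test_that("screening uses a strict inequality at alpha", {
  tt <- tibble::tibble(term = c("a", "b", "c", "d"),
                       p.value = c(0.01, 0.0099, 0.5, NA))
  out <- screen_effects(tt, alpha = 0.01)
  expect_equal(out$flagged, c(FALSE, TRUE, FALSE, FALSE))
  expect_error(screen_effects(tibble::tibble(p.value = 1.2)), "0, 1")
})

test_that("null screening flags about one percent of effects", {
  # type-I simulation: p-values from genuine null t-tests
  set.seed(63)
  p <- replicate(1000, stats::t.test(stats::rnorm(20))$p.value)
  rate <- mean(screen_effects(tibble::tibble(p.value = p))$flagged)
  expect_gt(rate, 0.001)
  expect_lt(rate, 0.025)
})

test_that("model averaging reproduces hand arithmetic and its edge cases", {
  mkfit <- function(terms, est, se) {
    structure(list(coefficients = tibble::tibble(
      term = terms, estimate = est, se = se
    )), class = "soar_fit")
  }
  cand <- tibble::tibble(
    weight = c(0.6, 0.4),
    met_terms = list("x", character()),
    fit = list(mkfit(c("(Intercept)", "x"), c(0, 2), c(0.1, 0.5)),
               mkfit("(Intercept)", 0, 0.1))
  )
  ma <- model_average(cand, parameters = "x")
  # shrinkage: beta_bar = 0.6*2, SE folds model spread around the average
  expect_equal(ma$estimate, 1.2)
  expect_equal(ma$se, sqrt(0.6 * (0.25 + 0.64) + 0.4 * (0 + 1.44)))
  expect_equal(ma$importance, 0.6)
  expect_equal(ma$lower, 1.2 - 1.96 * ma$se, tolerance = 1e-4)

  # identical estimate in all models: averaging is a no-op
  cand2 <- tibble::tibble(
    weight = c(0.5, 0.5),
    met_terms = list("x", "x"),
    fit = list(mkfit("x", 1.5, 0.3), mkfit("x", 1.5, 0.3))
  )
  ma2 <- model_average(cand2, parameters = "x")
  expect_equal(ma2$estimate, 1.5)
  expect_equal(ma2$se, 0.3)
  expect_equal(ma2$importance, 1)

  # absent everywhere: zero estimate, zero SE, zero importance
  ma0 <- model_average(cand2, parameters = "z")
  expect_equal(unlist(ma0[, c("estimate", "se", "importance")]),
               c(estimate = 0, se = 0, importance = 0))

  # conditional averaging over containing models only
  mac <- model_average(cand, parameters = "x", conditional = TRUE)
  expect_equal(mac$estimate, 2)
  expect_equal(mac$importance, 0.6)

  # a single model reduces to that model exactly
  one <- tibble::tibble(weight = 1, met_terms = list("x"),
                        fit = list(mkfit("x", -0.7, 0.21)))
  ma1 <- model_average(one, parameters = "x")
  expect_equal(ma1$estimate, -0.7)
  expect_equal(ma1$se, 0.21)
})

test_that("the AR(1) mixed model recovers known parameters", {
  d <- simulate_lnrf_panels(seed = 71, n_birds = 40, months = 1:12,
                            beta = c(thermal_height = 1), rho = 0,
                            sigma_u = 0.3, sigma = 0.5)
  fit <- fit_rsf_model(d, ln_rf ~ thermal_height, covariance = "ar1")
  expect_lt(abs(fit$rho), 0.08)
  b <- fit$coefficients
  expect_lt(abs(b$estimate[b$term == "thermal_height"] - 1), 0.15)
  expect_equal(fit$n, 480)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$AICc, aicc(fit$loglik, fit$k, fit$n))

  d6 <- simulate_lnrf_panels(seed = 72, n_birds = 40, months = 1:12,
                             beta = c(thermal_height = 1), rho = 0.6,
                             sigma_u = 0.3, sigma = 0.5)
  fit6 <- fit_rsf_model(d6, ln_rf ~ thermal_height, covariance = "ar1")
  expect_lt(abs(fit6$rho - 0.6), 0.15)
})

test_that("AR(1)-generated data prefers the AR(1) covariance and nests cleanly", {
  d <- simulate_lnrf_panels(seed = 73, n_birds = 40, months = 1:12,
                            beta = c(thermal_height = 1), rho = 0.6)
  cc <- compare_covariance(d, ln_rf ~ thermal_height)
  expect_equal(cc$winner, "ar1")
  expect_lt(cc$aicc["ar1"], cc$aicc["compound_symmetry"])
  # likelihood sanity: AR(1) cannot do worse than independent errors
  ind <- nlme::lme(ln_rf ~ thermal_height, data = as.data.frame(d),
                   random = ~ 1 | bird_id, method = "ML")
  expect_gte(cc$fits$ar1$loglik, as.numeric(stats::logLik(ind)))
})

test_that("marginal means match group means in balanced designs", {
  d <- simulate_lnrf_panels(seed = 74, n_birds = 20, months = 1:6,
                            beta = c(thermal_height = 0.5), rho = 0.3)
  d$sex <- rep(rep(c("F", "M"), each = 6), times = 10)  # 10 birds per sex
  # under exchangeable (compound-symmetry) months the GLS weights are
  # uniform, so balanced LSMEANS equal raw group means exactly
  fit <- fit_rsf_model(d, ln_rf ~ sex, covariance = "compound_symmetry")
  mm <- marginal_means(fit, "sex")
  expect_equal(mm$level, c("F", "M"))
  raw <- tapply(d$ln_rf, d$sex, mean)
  expect_equal(mm$mean, unname(as.vector(raw)), tolerance = 1e-6)
  expect_error(marginal_means(fit, "breeder"), "not in the model")
  cm <- marginal_means(fit, "sex", contrasts = TRUE)
  expect_equal(nrow(cm$contrasts), 1)
})

test_that("candidate set spans all met subsets and ranks by AICc", {
  d <- simulate_lnrf_panels(seed = 75, n_birds = 25, months = 1:8,
                            beta = c(thermal_height = 1, wind_speed = 0),
                            rho = 0.4)
  d$thermal_velocity <- stats::rnorm(nrow(d), 2, 0.5)
  cand <- fit_candidates(d)
  expect_equal(nrow(cand), 8)
  expect_equal(sum(cand$weight), 1, tolerance = 1e-12)
  expect_true(!is.unsorted(cand$aicc))
  expect_equal(cand$delta[1], 0)
  # the supported covariate should carry most of the importance
  ma <- model_average(cand)
  imp <- ma$importance[ma$parameter == "thermal_height"]
  expect_gt(imp, 0.9)
  expect_true(ma$lower[ma$parameter == "thermal_height"] <= 1 &&
                ma$upper[ma$parameter == "thermal_height"] >= 1)
})

test_that("degenerate model inputs fail informatively", {
  d <- simulate_lnrf_panels(seed = 76, n_birds = 6, months = 1:4,
                            beta = c(thermal_height = 1))
  expect_error(fit_rsf_model(d[, -1], ln_rf ~ thermal_height), "bird_id")
  d2 <- d; d2$month_index <- NULL; d2$month <- NULL
  expect_error(fit_rsf_model(d2, ln_rf ~ thermal_height), "month")
})
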