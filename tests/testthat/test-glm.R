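test_that("the null model recovers the closed-form logit of the mean", {
  tab <- data.frame(presence = rep(c(1L, 0L), c(40, 60)))
  fit <- fit_logistic(tab, model_spec(character(0)))
  expect_equal(unname(fit$beta), log(40 / 60), tolerance = 1e-6)
  expect_true(fit$converged)
})

test_that("IRLS matches a brute-force likelihood-grid oracle on a 4-point toy", {
  # non-separated toy: the grid search can bracket the optimum
  tab <- data.frame(presence = c(0L, 1L, 0L, 1L), elevation = c(1, 2, 3, 4))
  fit <- fit_logistic(tab, model_spec("elevation"))
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * tab$elevation
    sum(tab$presence * eta - log(1 + exp(eta)))
  }
  # coarse-to-fine grid search
  b0g <- seq(-10, 10, length.out = 81); b1g <- seq(-5, 5, length.out = 81)
  for (pass in 1:6) {
    ll <- outer(b0g, b1g, Vectorize(loglik))
    best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    span0 <- diff(range(b0g)) / 8; span1 <- diff(range(b1g)) / 8
    b0c <- b0g[best[1]]; b1c <- b1g[best[2]]
    b0g <- seq(b0c - span0, b0c + span0, length.out = 81)
    b1g <- seq(b1c - span1, b1c + span1, length.out = 81)
  }
  expect_equal(unname(fit$beta), c(b0c, b1c), tolerance = 1e-3)

  # the separated toy is flagged
  sep <- data.frame(presence = c(0L, 0L, 1L, 1L), elevation = c(1, 2, 3, 4))
  expect_warning(fsep <- fit_logistic(sep, model_spec("elevation")),
                 "separation")
  expect_true(fsep$separation)
})

test_that("IRLS agrees with the reference GLM on 50 random datasets", {
  set.seed(20)
  for (k in 1:50) {
    n <- sample(40:120, 1)
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    eta <- -0.3 + 0.8 * x1 - 0.5 * x2
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    if (length(unique(y)) < 2) next
    tab <- data.frame(presence = y, elevation = x1, slope = x2)
    fit <- fit_logistic(tab, model_spec(c("elevation", "slope")))
    ref <- stats::glm(y ~ x1 + x2, family = stats::binomial())
    expect_equal(unname(fit$beta), unname(stats::coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(summary(ref)$coefficients[, "Std. Error"]),
                 tolerance = 1e-4)
    expect_equal(fit$loglik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  }
})

test_that("deviance is non-increasing across IRLS iterations", {
  set.seed(21)
  n <- 200
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(0.5 + 1.5 * x))
  fit <- fit_logistic(data.frame(presence = y, elevation = x),
                      model_spec("elevation"))
  expect_true(all(diff(fit$deviance_trace) <= 1e-8))
})

test_that("a null effect stays within 3 standard errors of zero", {
  set.seed(22)
  n <- 400
  x <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, 0.5)   # independent of x
  fit <- fit_logistic(data.frame(presence = y, elevation = x),
                      model_spec("elevation"))
  expect_lt(abs(fit$beta[["elevation"]] / fit$se[["elevation"]]), 3)
})

test_that("AICc follows the small-sample formula and its limits", {
  expect_equal(aicc(list(loglik = -10, k = 2, n_obs = 20)), 24 + 12 / 17)
  expect_equal(aicc(list(loglik = -5, k = 1, n_obs = 10)), 12.5)
  # AICc -> AIC as n grows
  big <- aicc(list(loglik = -100, k = 3, n_obs = 1e6))
  expect_equal(big, 206, tolerance = 1e-4)
  expect_error(aicc(list(loglik = -5, k = 5, n_obs = 6)), "n_obs")
})

test_that("McFadden pseudo-R2 is the log-likelihood ratio complement", {
  f <- list(loglik = -50); n <- list(loglik = -100)
  expect_equal(mcfadden_r2(f, n), 0.5)
  expect_equal(mcfadden_r2(n, n), 0)
  expect_error(mcfadden_r2(f, list(loglik = 0)), "zero")

  # adding a predictor never decreases pseudo-R2 (nested likelihoods)
  set.seed(23)
  nobs <- 150
  x1 <- stats::rnorm(nobs); x2 <- stats::rnorm(nobs)
  y <- stats::rbinom(nobs, 1, stats::plogis(0.4 * x1))
  tab <- data.frame(presence = y, elevation = x1, slope = x2)
  f0 <- fit_logistic(tab, model_spec(character(0)))
  f1 <- fit_logistic(tab, model_spec("elevation"))
  f2 <- fit_logistic(tab, model_spec(c("elevation", "slope")))
  expect_gte(mcfadden_r2(f1, f0), 0)
  expect_gte(mcfadden_r2(f2, f0), mcfadden_r2(f1, f0) - 1e-12)
})

test_that("ROC AUC equals the all-pairs Mann-Whitney statistic", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)

  set.seed(24)
  labels <- stats::rbinom(200, 1, 0.4)
  scores <- round(stats::rnorm(200), 1)   # coarse scores force ties
  got <- roc_auc(labels, scores)
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  pairs <- outer(s1, s0, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(got, mean(pairs))
  expect_error(roc_auc(rep(1, 5), stats::runif(5)), "both classes")
})

test_that("predicted probabilities invert the logit", {
  tab <- data.frame(presence = rep(c(1L, 0L), c(30, 70)))
  null_fit <- fit_logistic(tab, model_spec(character(0)))
  expect_equal(unique(round(predict_prob(null_fit, tab), 10)), 0.3,
               tolerance = 1e-6)

  set.seed(25)
  n <- 120
  tab2 <- data.frame(presence = stats::rbinom(n, 1, 0.5),
                     elevation = stats::rnorm(n), slope = stats::rnorm(n))
  fit <- fit_logistic(tab2, model_spec(c("elevation", "slope")))
  new <- data.frame(elevation = stats::rnorm(20), slope = stats::rnorm(20))
  eta <- fit$beta[["(Intercept)"]] +
    fit$beta[["elevation"]] * new$elevation + fit$beta[["slope"]] * new$slope
  expect_equal(predict_prob(fit, new), 1 / (1 + exp(-eta)), tolerance = 1e-12)
})

test_that("LULC enters as treatment dummies by default with integer as an option", {
  set.seed(26)
  n <- 300
  f <- factor(sample(lulc_levels()[1:4], n, TRUE), levels = lulc_levels())
  y <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.4 * (as.integer(f) - 1)))
  tab <- data.frame(presence = y, lulc = f)
  fd <- fit_logistic(tab, model_spec("lulc", "dummy"))
  expect_equal(fd$k, 4)   # intercept + 3 non-reference classes present
  ref <- stats::glm(y ~ f2, family = stats::binomial(),
                    data = data.frame(y = y, f2 = droplevels(f)))
  expect_equal(unname(fd$beta), unname(stats::coef(ref)), tolerance = 1e-6)

  fi <- fit_logistic(tab, model_spec("lulc", "integer"))
  expect_equal(fi$k, 2)

  # predicting an unseen category is an error
  new <- data.frame(lulc = factor("water_bodies", levels = lulc_levels()))
  expect_error(predict_prob(fd, new), "unseen")
})

test_that("collinear predictors raise an error naming the columns", {
  set.seed(27)
  n <- 80
  x <- stats::rnorm(n)
  tab <- data.frame(presence = stats::rbinom(n, 1, 0.5),
                    elevation = x, slope = 2 * x)
  expect_error(fit_logistic(tab, model_spec(c("elevation", "slope"))),
               "collinear")
  # constant column dropped with a warning rather than failing
  tab2 <- data.frame(presence = stats::rbinom(n, 1, 0.5),
                     elevation = x, slope = rep(1.5, n))
  expect_warning(fit <- fit_logistic(tab2, model_spec(c("elevation", "slope"))),
                 "constant")
  expect_equal(fit$k, 2)
})

test_that("model comparison orders by AICc with deterministic tie-breaking", {
  set.seed(28)
  n <- 250
  x1 <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(1.2 * x1))
  tab <- data.frame(presence = y, elevation = x1,
                    slope = stats::rnorm(n))
  specs <- list(null = model_spec(character(0)),
                elev = model_spec("elevation"),
                noise = model_spec("slope"))
  cm <- compare_models(tab, specs)
  expect_equal(cm$table$spec[1], "elev")
  expect_true(cm$table$best[1])
  expect_equal(cm$table$delta_aicc[1], 0)
  expect_error(compare_models(tab, specs["null"]), "at least 2")

  # identical specs -> identical AICc, name breaks the tie
  cm2 <- compare_models(tab, list(b_copy = model_spec("elevation"),
                                  a_copy = model_spec("elevation")))
  expect_equal(cm2$table$aicc[1], cm2$table$aicc[2])
  expect_equal(cm2$table$spec[1], "a_copy")

  # a failing candidate annotates its row instead of aborting
  tab3 <- tab; tab3$slope <- 2 * tab3$elevation
  cm3 <- compare_models(tab3, list(
    ok = model_spec("elevation"),
    broken = model_spec(c("elevation", "slope"))
  ))
  expect_true(any(!is.na(cm3$table$error)))
  expect_equal(cm3$table$spec[1], "ok")
})
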