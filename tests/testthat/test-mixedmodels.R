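make_gamma_data <- function(seed, G = 15, npg = 8, effect = 0.5, sd_b = 0.3,
                            shape = 6) {
  set.seed(seed)
  d <- data.frame(g = factor(rep(seq_len(G), each = npg)),
                  x = factor(rep(c("a", "b"), length.out = G * npg)))
  b <- rnorm(G, 0, sd_b)
  eta <- ifelse(d$x == "b", effect, 0) + b[as.integer(d$g)]
  d$y <- rgamma(nrow(d), shape = shape, rate = shape / exp(eta))
  d
}

make_binom_data <- function(seed, G = 20, npg = 10, effect = 0.8, sd_b = 0.5) {
  set.seed(seed)
  d <- data.frame(g = factor(rep(seq_len(G), each = npg)),
                  x = factor(rep(c("a", "b"), length.out = G * npg)))
  b <- rnorm(G, 0, sd_b)
  d$y <- rbinom(nrow(d), 1, plogis(ifelse(d$x == "b", effect, 0) + b[as.integer(d$g)]))
  d
}

test_that("without a random term the engine matches the IRLS GLM oracle", {
  d <- make_gamma_data(1, sd_b = 0)
  f <- fit_glmm(d, glmm_spec("y", "gamma_log", ~x))
  g <- glm(y ~ x, data = d, family = Gamma(link = "log"),
           control = glm.control(epsilon = 1e-14))
  expect_lt(max(abs(f$coefficients - coef(g))), 1e-6)

  db <- make_binom_data(2, sd_b = 0)
  fb <- fit_glmm(db, glmm_spec("y", "binomial_logit", ~x))
  gb <- glm(y ~ x, data = db, family = binomial(),
            control = glm.control(epsilon = 1e-14))
  expect_lt(max(abs(fb$coefficients - coef(gb))), 1e-6)
  expect_lt(max(abs(sqrt(diag(fb$covariance)) - sqrt(diag(vcov(gb))))), 1e-4)
})

test_that("random-intercept fits agree with an independent mixed-model fitter", {
  d <- make_gamma_data(7)
  f <- fit_glmm(d, glmm_spec("y", "gamma_log", ~x, random_group = "g"))
  tmb <- glmmTMB::glmmTMB(y ~ x + (1 | g), data = d,
                          family = Gamma(link = "log"))
  expect_equal(unname(f$coefficients), unname(glmmTMB::fixef(tmb)$cond),
               tolerance = 1e-4)
  expect_equal(f$random_sd,
               unname(attr(glmmTMB::VarCorr(tmb)$cond$g, "stddev")),
               tolerance = 1e-3)
  expect_equal(sqrt(diag(f$covariance)),
               sqrt(diag(as.matrix(vcov(tmb)$cond))),
               tolerance = 1e-3, ignore_attr = TRUE)

  db <- make_binom_data(8)
  fb <- fit_glmm(db, glmm_spec("y", "binomial_logit", ~x, random_group = "g"))
  tb <- glmmTMB::glmmTMB(y ~ x + (1 | g), data = db, family = binomial())
  expect_equal(unname(fb$coefficients), unname(glmmTMB::fixef(tb)$cond),
               tolerance = 5e-3)
  expect_equal(fb$random_sd,
               unname(attr(glmmTMB::VarCorr(tb)$cond$g, "stddev")),
               tolerance = 0.05)
})

test_that("response validation and factor checks reject invalid inputs", {
  d <- make_gamma_data(3)
  d$y[1] <- -1
  expect_error(fit_glmm(d, glmm_spec("y", "gamma_log", ~x)), "positive")
  d2 <- make_binom_data(3); d2$y[1] <- 2
  expect_error(fit_glmm(d2, glmm_spec("y", "binomial_logit", ~x)), "0/1")
  d3 <- make_gamma_data(3); d3$x <- factor("a", levels = c("a", "b"))
  expect_error(fit_glmm(d3, glmm_spec("y", "gamma_log", ~x)), "levels")
  expect_error(fit_glmm(d, glmm_spec("z", "gamma_log", ~x)), "not found")
})

test_that("posterior draws are reproducible and honour the covariance", {
  d <- make_gamma_data(4)
  f <- fit_glmm(d, glmm_spec("y", "gamma_log", ~x, random_group = "g"))
  d1 <- posterior_draws(f, n = 500, seed = 99)
  d2 <- posterior_draws(f, n = 500, seed = 99)
  expect_identical(d1, d2)
  expect_false(identical(d1, posterior_draws(f, n = 500, seed = 100)))

  f0 <- f
  f0$covariance[] <- 0
  dz <- posterior_draws(f0, n = 50, seed = 1)
  expect_true(all(apply(dz, 1, function(r) all(r == f$coefficients))))
})

test_that("level predictions invert the link and collapse under zero covariance", {
  d <- make_binom_data(5)
  f <- fit_glmm(d, glmm_spec("y", "binomial_logit", ~x, random_group = "g"))
  f0 <- f
  f0$coefficients[] <- c(0, 0)
  f0$covariance[] <- 0
  draws <- posterior_draws(f0, n = 200, seed = 1)
  pr <- predict_levels(f0, draws, data.frame(x = c("a", "b")))
  expect_equal(pr$median, c(0.5, 0.5))
  expect_equal(pr$ci_low, pr$ci_high)

  dg <- make_gamma_data(5)
  fg <- fit_glmm(dg, glmm_spec("y", "gamma_log", ~x, random_group = "g"))
  fg$coefficients[] <- c(log(2), 0)
  fg$covariance[] <- 0
  drg <- posterior_draws(fg, n = 100, seed = 1)
  prg <- predict_levels(fg, drg, data.frame(x = "a"))
  expect_equal(prg$median, 2)
  expect_true(all(predict_levels(fg, drg, data.frame(x = c("a", "b")))$median > 0))
  expect_error(predict_levels(fg, drg, data.frame(x = "c")), "level")
})

test_that("response ratios recover simulated effects and flag CI exclusion", {
  d <- make_gamma_data(6, G = 20, npg = 20, effect = log(0.8))
  f <- fit_glmm(d, glmm_spec("y", "gamma_log", ~x, random_group = "g"))
  draws <- posterior_draws(f, n = 4000, seed = 2)
  rr <- response_ratio(f, draws, data.frame(x = "b"), data.frame(x = "a"))
  expect_gt(rr$ratio_median, 0.7)
  expect_lt(rr$ratio_median, 0.9)
  expect_equal(rr$excludes_one, rr$ci_low > 1 || rr$ci_high < 1)

  f0 <- f
  f0$covariance[] <- 0
  dr0 <- posterior_draws(f0, n = 100, seed = 1)
  same <- response_ratio(f0, dr0, data.frame(x = "a"), data.frame(x = "a"))
  expect_equal(same$ratio_median, 1)
  expect_equal(same$ci_low, 1)
  expect_equal(same$ci_high, 1)
})

test_that("R2 decomposition behaves across random-effect and effect sizes", {
  d <- make_gamma_data(9, sd_b = 0)
  f <- fit_glmm(d, glmm_spec("y", "gamma_log", ~x))
  r2 <- r_squared(f)
  expect_equal(r2[["marginal"]], r2[["conditional"]])

  fnull <- fit_glmm(d, glmm_spec("y", "gamma_log", ~1))
  expect_equal(r_squared(fnull)[["marginal"]], 0)

  marg <- vapply(c(0.3, 1, 2.5), function(eff) {
    db <- make_binom_data(11, G = 30, npg = 10, effect = eff, sd_b = 0.3)
    r_squared(fit_glmm(db, glmm_spec("y", "binomial_logit", ~x,
                                     random_group = "g")))[["marginal"]]
  }, numeric(1))
  expect_true(all(diff(marg) > 0))
})

test_that("quantile residuals are uniform under the fitted model", {
  d <- make_gamma_data(12, G = 20, npg = 10)
  f <- fit_glmm(d, glmm_spec("y", "gamma_log", ~x, random_group = "g"))
  r1 <- quantile_residuals(f, n_sim = 100, seed = 5)
  expect_identical(r1, quantile_residuals(f, n_sim = 100, seed = 5))
  expect_true(all(r1 > 0 & r1 < 1))
  expect_error(quantile_residuals(f, n_sim = 10), "20")

  # an observation far above anything the model simulates lands at ~1
  f2 <- f
  f2$y[1] <- max(d$y) * 100
  expect_gt(quantile_residuals(f2, n_sim = 100, seed = 5)[1], 0.98)

  # residuals from data simulated under the fitted model pass a KS check
  crit <- 1.63 / sqrt(200)   # alpha = 0.01 asymptotic KS critical value
  pass <- 0
  nrep <- 30
  for (k in seq_len(nrep)) {
    set.seed(1000 + k)
    b <- rnorm(20, 0, f$random_sd)
    eta <- drop(f$X %*% f$coefficients) + b[as.integer(d$g)]
    ysim <- rgamma(length(eta), shape = f$dispersion_or_shape,
                   rate = f$dispersion_or_shape / exp(eta))
    fsim <- f
    fsim$y <- ysim
    r <- quantile_residuals(fsim, n_sim = 200, seed = k)
    D <- suppressWarnings(ks.test(r, "punif")$statistic)
    if (D < crit) pass <- pass + 1
  }
  expect_gte(pass / nrep, 0.9)
})

test_that("complete separation is detected and stabilised by the ridge", {
  set.seed(13)
  d <- data.frame(g = factor(rep(1:10, each = 4)),
                  x = factor(rep(c("a", "b"), each = 20)))
  d$y <- ifelse(d$x == "b", 1L, rbinom(40, 1, 0.5))
  f <- fit_glmm(d, glmm_spec("y", "binomial_logit", ~x, random_group = "g"))
  expect_true(detect_separation(f))
  fr <- fit_glmm(d, glmm_spec("y", "binomial_logit", ~x, random_group = "g"),
                 ridge_var = 25)
  expect_false(detect_separation(fr))
  expect_true(all(is.finite(fr$coefficients)))
  expect_true(all(is.finite(sqrt(diag(fr$covariance)))))
})
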