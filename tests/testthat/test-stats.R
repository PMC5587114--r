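# Agreement and regression statistics.

# independent one-way ANOVA oracle via stats::aov on long-format data
icc_oracle <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subj = factor(rep(seq_len(nrow(m)), ncol(m))))
  a <- anova(stats::aov(y ~ subj, d))
  bms <- a["subj", "Mean Sq"]; wms <- a["Residuals", "Mean Sq"]
  (bms - wms) / bms
}

test_that("ICC(1,k) matches the one-way ANOVA decomposition exactly", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:10, 1); k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, sd = sample(1:3, 1)), n, k) +
      rnorm(n, sd = 2)  # subject effects
    expect_equal(icc_1k(m)$icc, icc_oracle(m), tolerance = 1e-12)
  }
})

test_that("ICC edge cases: duplicated columns, pure noise, degenerate input", {
  set.seed(2)
  x <- rnorm(8)
  expect_equal(icc_1k(cbind(x, x, x))$icc, 1)
  noise <- matrix(rnorm(4000 * 2), 4000, 2)
  expect_lt(abs(icc_1k(noise)$icc), 0.1)
  expect_error(icc_1k(matrix(1:2, 1, 2)), "n >= 2")
  expect_error(icc_1k(matrix(1:4, 4, 1)), "k >= 2")
  z <- icc_1k(matrix(5, 4, 2))
  expect_true(is.na(z$icc))
  # two-way absolute-agreement variant stays in range on random input
  m <- matrix(rnorm(20), 5, 4)
  expect_lte(icc_1k(m, type = "ICCAk")$icc, 1)
})

test_that("Bland-Altman bias and limits of agreement", {
  x <- c(1, 2, 3, 4)
  b <- bland_altman(x, x)
  expect_equal(b$bias, 0); expect_equal(b$loa_low, 0)
  b2 <- bland_altman(x, x + 2)
  expect_equal(b2$bias, -2); expect_equal(b2$sd_diff, 0)
  b3 <- bland_altman(c(0, 1, 2), c(1, 1, 1))  # d = -1, 0, 1
  expect_equal(b3$bias, 0)
  expect_equal(b3$loa_high, 1.96)
  expect_equal(b3$loa_low, -1.96)
  expect_error(bland_altman(1, 1), "n >= 2")
  # LoA contain ~95% of normally distributed differences
  set.seed(5)
  xx <- rnorm(10000); yy <- xx + rnorm(10000)
  bb <- bland_altman(xx, yy)
  inside <- mean(xx - yy >= bb$loa_low & xx - yy <= bb$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.01)
})

test_that("OLS matches the normal equations and flags aliased terms", {
  set.seed(3)
  d <- data.frame(shielded = factor(sample(c("no", "yes"), 50, TRUE)),
                  height = runif(50, 4, 13),
                  tag_id = factor(sample(letters[1:4], 50, TRUE)),
                  baseplate = factor(sample(c("p1", "p2", "p3"), 50, TRUE)))
  d$readrate <- 0.5 + 0.1 * (d$shielded == "yes") - 0.02 * d$height +
    rnorm(50, sd = 0.05)
  fit <- fit_ols(readrate ~ shielded + height + tag_id + baseplate, d)
  mm <- model.matrix(~ shielded + height + tag_id + baseplate, d)
  beta <- solve(t(mm) %*% mm, t(mm) %*% d$readrate)
  expect_equal(fit$coefficients$estimate, as.vector(beta), tolerance = 1e-8)
  # noise-free data from known coefficients is recovered exactly
  d$clean <- 1 + 2 * d$height
  f2 <- suppressWarnings(fit_ols(clean ~ height, d))  # perfect-fit warning
  expect_equal(f2$coefficients$estimate, c(1, 2), tolerance = 1e-10)
  # intercept-only fit is the sample mean
  f3 <- fit_ols(clean ~ 1, d)
  expect_equal(f3$coefficients$estimate, mean(d$clean))
  # aliased term named in the error
  d$dup <- d$height
  expect_error(fit_ols(clean ~ height + dup, d), "dup")
})

test_that("OLS is invariant to column order and response shifts", {
  set.seed(8)
  d <- data.frame(a = rnorm(30), b = factor(sample(1:3, 30, TRUE)))
  d$y <- 1 + d$a + as.numeric(d$b) + rnorm(30)
  f1 <- fit_ols(y ~ a + b, d)
  f2 <- fit_ols(y ~ b + a, d)
  expect_equal(sort(f1$coefficients$estimate), sort(f2$coefficients$estimate))
  d$y2 <- d$y + 100
  f3 <- fit_ols(y2 ~ a + b, d)
  slope <- f1$coefficients$term != "(Intercept)"
  expect_equal(f1$coefficients$estimate[slope],
               f3$coefficients$estimate[slope], tolerance = 1e-8)
})

test_that("random-intercept REML: limits, fallback and recovery", {
  set.seed(21)
  # tau2 = 0 limiting case: fixed effects match OLS closely
  d0 <- data.frame(rat = factor(rep(1:6, each = 20)),
                   phase = factor(rep(c("dark", "light"), 60)))
  d0$y <- 10 - 3 * (d0$phase == "light") + rnorm(120)
  fm <- fit_random_intercept(y ~ phase + (1 | rat), d0)
  fo <- fit_ols(y ~ phase, d0)
  expect_equal(fm$coefficients$estimate, fo$coefficients$estimate,
               tolerance = 1e-4)
  expect_gte(fm$tau2, 0)
  # known phase effect with real rat effects: recovered within 3 SE
  d1 <- d0
  d1$y <- 10 - 3 * (d1$phase == "light") +
    rep(rnorm(6, sd = 2), each = 20) + rnorm(120)
  f1 <- fit_random_intercept(y ~ phase + (1 | rat), d1)
  ph <- f1$coefficients[f1$coefficients$term == "phaselight", ]
  expect_lt(abs(ph$estimate - (-3)), 3 * ph$se)
  expect_gt(f1$tau2, 0)
  # one group falls back to OLS with a flag
  d2 <- d0[d0$rat == "1", ]
  expect_warning(f2 <- fit_random_intercept(y ~ phase + (1 | rat), d2),
                 "one grouping level")
  expect_equal(f2$label, "eq_mixed_ols_fallback")
  expect_error(fit_random_intercept(y ~ phase, d0), "exactly one")
})

test_that("negative binomial fit: validation, trivial and limiting cases", {
  d <- data.frame(y = c(2, 2, 2, 2), g = factor(c(1, 1, 2, 2)))
  f <- suppressWarnings(fit_negbin(y ~ 1, d))
  expect_equal(exp(f$coefficients$estimate[1]), 2, tolerance = 1e-6)
  expect_error(fit_negbin(y ~ 1, data.frame(y = c(-1, 2))), "non-negative")
  expect_error(fit_negbin(y ~ 1, data.frame(y = c(1.5, 2))), "integer")
  # near-Poisson data: coefficients match the Poisson ML fit
  set.seed(31)
  dd <- data.frame(g = factor(rep(c("a", "b"), each = 100)))
  dd$y <- rpois(200, lambda = ifelse(dd$g == "a", 5, 10))
  fn <- suppressWarnings(fit_negbin(y ~ g, dd))
  fp <- glm(y ~ g, dd, family = poisson())
  expect_equal(fn$coefficients$estimate, unname(coef(fp)), tolerance = 1e-3)
  # two-group rate ratio recovered within 3 SE on over-dispersed data
  set.seed(32)
  dd2 <- data.frame(g = factor(rep(c("a", "b"), each = 150)))
  mu <- ifelse(dd2$g == "a", 5, 10)
  dd2$y <- MASS::rnegbin(300, mu = mu, theta = 3)
  f2 <- suppressWarnings(fit_negbin(y ~ g, dd2))
  est <- f2$coefficients[f2$coefficients$term == "gb", ]
  expect_lt(abs(est$estimate - log(2)), 3 * est$se)
})

test_that("paired t-test: closed formula, symmetry, degenerate input", {
  r <- paired_t(c(2, 4, 6), c(1, 2, 3))  # d = 1, 2, 3
  expect_equal(r$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_equal(r$p, 2 * pt(-2 * sqrt(3), df = 2), tolerance = 1e-12)
  r2 <- paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(paired_t(c(1, 2), c(1, 2)), "zero-variance")
})

test_that("rubric bands score the validation metrics", {
  s <- rubric_scores(read_freq_hz = 0.74, icc_tracking = 0.83,
                     r2_sideview = 0.92, implant_issues = 1)
  expect_equal(s$score, c(4L, 4L, 5L, 4L))
  expect_equal(rubric_scores(read_freq_hz = 0.80)$score, 5L)
  expect_equal(rubric_scores(read_freq_hz = 0.25)$score, 1L)
  expect_equal(rubric_scores(icc_tracking = -0.2)$score, 1L)
  # total and monotone: a larger metric never scores lower
  grid <- seq(0, 1.2, by = 0.01)
  sc <- vapply(grid, function(x) rubric_scores(read_freq_hz = x)$score,
               integer(1))
  expect_true(all(diff(sc) >= 0))
  sc2 <- vapply(seq(-0.5, 1, by = 0.01),
                function(x) rubric_scores(icc_tracking = x)$score, integer(1))
  expect_true(all(diff(sc2) >= 0))
})

test_that("light/dark summary computes phase means, ratio and difference", {
  bins <- data.table::data.table(
    window_start = (0:7) * 900, window_end = (1:8) * 900,
    animal_id = "r1", n_transitions = c(10, 10, 10, 10, 14, 14, 14, 14),
    distance_cm = 0, phase = rep(c("light", "dark"), each = 4))
  s <- light_dark_summary(bins)
  expect_equal(s$cage$ratio, 1.4)
  expect_equal(s$cage$difference, 4)
  uniform <- data.table::copy(bins)
  uniform$n_transitions <- 5L
  expect_equal(light_dark_summary(uniform)$cage$ratio, 1)
  zero <- data.table::copy(bins)
  zero$n_transitions[zero$phase == "light"] <- 0L
  expect_true(is.na(light_dark_summary(zero)$cage$ratio))
})
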