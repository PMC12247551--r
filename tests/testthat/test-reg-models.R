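test_that("WMH transform logs positives and flags zeros", {
  tw <- transform_wmh(c(1.0, 0, 2.37))
  expect_equal(tw$log_wmh, c(0, 0, 0.86289), tolerance = 1e-5)
  expect_equal(tw$wmh_zero, c(0L, 1L, 0L))
  expect_error(transform_wmh(c(1, -0.1)), "negative")
})

test_that("beta regression recovers mean and precision on simulated data", {
  set.seed(103)
  y <- rbeta(1e4, 0.25 * 40, 0.75 * 40)
  fit <- beta_reg(y ~ 1, data.frame(y = y))
  expect_lt(abs(plogis(coef(fit)[[1]]) - 0.25), 0.01)
  expect_lt(abs(fit$phi - 40), 2)
  expect_equal(nobs(fit), 10000L)
})

test_that("beta regression equals an independent generic optimizer", {
  set.seed(107)
  worst <- 0
  for (i in 1:20) {
    d <- data.frame(x = rnorm(80))
    mu <- plogis(-1 + 0.5 * d$x)
    d$y <- rbeta(80, mu * 30, (1 - mu) * 30)
    fit <- beta_reg(y ~ x, d)
    nll <- function(th) {
      m <- plogis(th[1] + th[2] * d$x)
      p <- exp(th[3])
      -sum(dbeta(d$y, m * p, (1 - m) * p, log = TRUE))
    }
    o <- optim(c(0, 0, log(10)), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-15))
    worst <- max(worst, max(abs(coef(fit) - o$par[1:2])))
    expect_lt(abs(logLik(fit) + o$value), 1e-6)
  }
  expect_lt(worst, 1e-6)
})

test_that("beta regression Wald test has uniform p under the null", {
  set.seed(109)
  rej <- logical(2000)
  for (i in seq_along(rej)) {
    d <- data.frame(x = rnorm(150))
    d$y <- rbeta(150, 0.25 * 50, 0.75 * 50)  # no dependence on x
    fit <- beta_reg(y ~ x, d)
    rej[i] <- fit$p["x"] < 0.05
  }
  expect_lt(abs(mean(rej) - 0.05), 0.01)
})

test_that("beta regression boundary handling is explicit", {
  d <- data.frame(y = c(0.2, 0.4, 1.0, 0.3, 0.5, 0.25, 0.35, 0.45))
  expect_error(beta_reg(y ~ 1, d), "boundary")
  fit <- beta_reg(y ~ 1, d, shrink_boundary = TRUE)
  expect_true(is.finite(coef(fit)[[1]]))
  dd <- data.frame(y = rbeta(30, 2, 5))
  dd$x <- 1  # constant column -> rank deficient with intercept
  expect_error(beta_reg(y ~ x, dd), "rank")
})

test_that("Gamma GLM recovers a planted occupancy multiplier", {
  set.seed(113)
  n <- 5000
  d <- data.frame(fo_high = rbeta(n, 0.25 * 60, 0.75 * 60))
  mu <- exp(log(80) + 20 * log(0.98) * d$fo_high)
  d$y <- rgamma(n, shape = 8, rate = 8 / mu)
  fit <- gamma_reg(y ~ fo_high, d)
  eff <- effect_per_k_pp(fit, 5)
  expect_lt(abs(coef(fit)["fo_high"] - 20 * log(0.98)), 2 * fit$se["fo_high"])
  expect_true(eff$conf.low <= 0.98 && 0.98 <= eff$conf.high)
  expect_error(gamma_reg(y ~ fo_high, transform(d, y = y - min(y) - 1)),
               "positive")
})

test_that("Gamma and binomial fits match independent ML optimization", {
  set.seed(127)
  for (i in 1:25) {
    n <- 60
    d <- data.frame(x = rnorm(n))
    mu <- exp(0.5 + 0.3 * d$x)
    d$y <- rgamma(n, shape = 5, rate = 5 / mu)
    fit <- gamma_reg(y ~ x, d)
    nll <- function(th) {
      m <- exp(th[1] + th[2] * d$x)
      sh <- exp(th[3])
      -sum(dgamma(d$y, shape = sh, rate = sh / m, log = TRUE))
    }
    o <- optim(c(0, 0, 1), nll, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
    o <- optim(o$par, nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
    expect_lt(max(abs(coef(fit) - o$par[1:2])), 1e-6)
  }
  for (i in 1:25) {
    n <- 80
    d <- data.frame(x = rnorm(n), size = 20L)
    p <- plogis(-0.5 + 0.4 * d$x)
    d$s <- rbinom(n, 20, p)
    fit <- binom_reg(cbind(s, size - s) ~ x, d)
    nll <- function(th) {
      pp <- plogis(th[1] + th[2] * d$x)
      -sum(dbinom(d$s, 20, pp, log = TRUE))
    }
    o <- optim(c(0, 0), nll, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
    expect_lt(max(abs(coef(fit) - o$par)), 1e-6)
  }
})

test_that("binomial GLM recovers an odds ratio per 20 pp and scales exactly", {
  set.seed(131)
  n <- 5000
  d <- data.frame(fo = rbeta(n, 0.25 * 40, 0.75 * 40), size = 30L)
  p <- plogis(1 + log(1.19) / 0.20 * (d$fo - 0.25))
  d$s <- rbinom(n, 30, p)
  fit <- binom_reg(cbind(s, size - s) ~ fo, d)
  e20 <- effect_per_k_pp(fit, 20, coef_name = "fo")
  e5 <- effect_per_k_pp(fit, 5, coef_name = "fo")
  expect_lt(abs(coef(fit)["fo"] - log(1.19) / 0.20), 2 * fit$se["fo"])
  expect_equal(e20$estimate, e5$estimate^4, tolerance = 1e-12)

  half <- data.frame(s = rep(10L, 40), size = 20L)
  fit0 <- binom_reg(cbind(s, size - s) ~ 1, half)
  expect_equal(unname(coef(fit0)[1]), 0, tolerance = 1e-10)

  sep <- data.frame(s = c(rep(0L, 20), rep(20L, 20)), size = 20L,
                    x = rep(c(0, 1), each = 20))
  expect_error(binom_reg(cbind(s, size - s) ~ x, sep), "separation")
})

test_that("effect transforms follow their closed forms and keep p-values", {
  set.seed(137)
  d <- data.frame(log_wmh = rnorm(400))
  mu <- plogis(-1.1 - 0.05 * d$log_wmh)
  d$y <- rbeta(400, mu * 60, (1 - mu) * 60)
  fit <- beta_reg(y ~ log_wmh, d)

  eff <- effect_per_iqr(fit, q1 = 0.468, q3 = 2.37)
  s <- log(2.37 / 0.468)
  expect_equal(log(5.06), s, tolerance = 1e-3)         # IQR-ratio scaling
  expect_equal(eff$estimate, exp(coef(fit)["log_wmh"] * s), ignore_attr = TRUE)
  expect_equal(eff$p, unname(fit$p["log_wmh"]))
  ci <- confint(fit)["log_wmh", ]
  expect_equal(c(eff$conf.low, eff$conf.high), unname(exp(ci * s)),
               tolerance = 1e-12)
  expect_error(effect_per_iqr(fit, 2.37, 0.468), "q3 > q1")
  expect_error(effect_per_iqr(fit, 0.5, 2, coef_name = "nope"), "not in")

  # a null coefficient maps to an effect of exactly 1 for any quartiles
  fit0 <- fit
  fit0$coefficients["log_wmh"] <- 0
  expect_equal(effect_per_iqr(fit0, 0.1, 7)$estimate, 1, ignore_attr = TRUE)
  expect_equal(effect_per_k_pp(fit0, 0, coef_name = "log_wmh")$estimate, 1,
               ignore_attr = TRUE)

  # per-5-pp decrease is the reciprocal of the per-5-pp increase
  e5 <- effect_per_k_pp(fit, 5, coef_name = "log_wmh")
  e5d <- effect_per_k_pp(fit, -5, coef_name = "log_wmh")
  expect_equal(e5d$estimate, 1 / e5$estimate, tolerance = 1e-12)
})

test_that("the zero indicator is included exactly when zeros are present", {
  co <- simulate_cohort(generator_config(n_participants = 400, seed = 139),
                        include_sequences = FALSE)
  ph <- co$phenotype
  with_zeros <- run_primary(ph)
  expect_true(any(ph$wmh_total_ml == 0))
  expect_true("wmh_zero" %in% names(coef(with_zeros$fit)))

  ph_pos <- ph[ph$wmh_total_ml > 0, ]
  no_zeros <- run_primary(ph_pos)
  expect_false("wmh_zero" %in% names(coef(no_zeros$fit)))

  # dropping the indicator when no zeros exist leaves estimates identical to
  # a fit that never saw the column
  manual <- beta_reg(fo_high ~ log_wmh + age + sex,
                     cbind(ph_pos, transform_wmh(ph_pos$wmh_total_ml)))
  expect_equal(coef(no_zeros$fit), coef(manual), tolerance = 1e-10)
})
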