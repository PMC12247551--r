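#' Log-transform WMH volumes with a zero indicator
#'
#' Non-zero volumes are natural-log transformed; exact zeros keep the value 0
#' and raise a binary indicator instead, so the regression models can absorb
#' the zero-inflation with one coefficient.
#'
#' @param volumes Non-negative WMH volumes (mL).
#' @return `data.frame` with columns `log_wmh` and `wmh_zero` (0/1).
#' @export
transform_wmh <- function(volumes) {
  stop_if(any(!is.finite(volumes) & !is.na(volumes)), "volumes must be finite")
  stop_if(any(volumes < 0, na.rm = TRUE), "negative WMH volume")
  data.frame(log_wmh = ifelse(is.na(volumes), NA_real_,
                              ifelse(volumes > 0, log(volumes), 0)),
             wmh_zero = ifelse(is.na(volumes), NA_integer_,
                               as.integer(volumes == 0)))
}

# Shared constructor for fitted-model objects.
new_cap_fit <- function(subclass, coefficients, vcov, dispersion, loglik, n,
                        fitted, y, formula, terms, extra = list()) {
  se <- sqrt(diag(vcov))
  z <- coefficients / se
  p <- 2 * stats::pnorm(-abs(z))
  ci <- cbind(coefficients - stats::qnorm(0.975) * se,
              coefficients + stats::qnorm(0.975) * se)
  colnames(ci) <- c("2.5 %", "97.5 %")
  structure(c(list(coefficients = coefficients, vcov = vcov, se = se,
                   z = z, p = p, ci = ci, dispersion = dispersion,
                   loglik = loglik, n = n, fitted = fitted, y = y,
                   formula = formula, terms = terms),
              extra),
            class = c(subclass, "cap_fit"))
}

#' Fixed-dispersion beta regression with logit link
#'
#' Maximum-likelihood fit of the beta regression model
#' \deqn{y_i \sim \mathrm{Beta}(\mu_i \phi, (1 - \mu_i)\phi), \qquad
#'   \mathrm{logit}(\mu_i) = x_i^\top \beta,}
#' with a single (fixed) precision \eqn{\phi} shared by all observations.
#' Optimization is over \eqn{(\beta, \log\phi)} (the log keeps \eqn{\phi}
#' positive) by BFGS with analytic gradients followed by Newton polishing;
#' starting values come from a least-squares fit on the logit scale. Wald
#' standard errors are taken from the inverse observed information.
#'
#' @param formula Model formula; the response must lie strictly in (0, 1).
#' @param data Data frame.
#' @param shrink_boundary If `TRUE`, responses are shrunk away from the
#'   boundary as `(y * (n - 1) + 0.5) / n` before fitting. Never applied
#'   silently: boundary values with the default `FALSE` are an error.
#' @param max_iter Maximum optimizer iterations.
#' @param tol Convergence tolerance on the score (max absolute gradient).
#' @return Object of classes `beta_fit`, `cap_fit` with components
#'   `coefficients` (logit scale), `phi`, `vcov` (for `beta`), `vcov_full`
#'   (incl. `log(phi)`), `loglik`, Wald `z`/`p`/`ci`, `fitted`.
#' @seealso [gamma_reg()], [binom_reg()], [effect_per_iqr()],
#'   [effect_per_k_pp()]
#' @export
beta_reg <- function(formula, data, shrink_boundary = FALSE,
                     max_iter = 500, tol = 1e-8) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  stop_if(n < ncol(X) + 2L, "too few observations")
  if (any(y <= 0 | y >= 1)) {
    if (shrink_boundary) {
      y <- (y * (n - 1) + 0.5) / n
    } else {
      stop("response values at or beyond the (0, 1) boundary; drop them or ",
           "use `shrink_boundary = TRUE` (shrinkage (y*(n-1)+0.5)/n)",
           call. = FALSE)
    }
  }
  stop_if(qr(X)$rank < ncol(X), "design matrix is rank deficient")

  negll <- function(theta) {
    beta <- theta[-length(theta)]
    phi <- exp(theta[length(theta)])
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(lgamma(phi) - lgamma(mu * phi) - lgamma((1 - mu) * phi) +
           (mu * phi - 1) * log(y) + ((1 - mu) * phi - 1) * log1p(-y))
  }
  neggr <- function(theta) {
    beta <- theta[-length(theta)]
    phi <- exp(theta[length(theta)])
    mu <- stats::plogis(drop(X %*% beta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ystar <- stats::qlogis(y)
    mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
    g_beta <- phi * drop(crossprod(X, (ystar - mustar) * mu * (1 - mu)))
    g_phi <- sum(digamma(phi) - mu * digamma(mu * phi) -
                   (1 - mu) * digamma((1 - mu) * phi) +
                   mu * log(y) + (1 - mu) * log1p(-y))
    -c(g_beta, phi * g_phi)
  }

  # logit-scale least-squares start; moment start for phi
  b0 <- qr.solve(X, stats::qlogis(y))
  mu0 <- stats::plogis(drop(X %*% b0))
  v0 <- stats::var(y - mu0)
  phi0 <- max(mean(mu0 * (1 - mu0)) / max(v0, 1e-10) - 1, 1)
  theta <- c(b0, log(phi0))

  opt <- stats::optim(theta, negll, neggr, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-14))
  theta <- opt$par
  # Newton polish to drive the score toward zero. The score tolerance is
  # scaled by the log-likelihood magnitude: below that level the objective
  # itself is flat to machine precision.
  gtol <- max(tol, 1e-7 * (1 + abs(negll(theta))))
  trace_g <- numeric(0)
  for (it in seq_len(50L)) {
    g <- neggr(theta)
    trace_g <- c(trace_g, max(abs(g)))
    if (max(abs(g)) < gtol) break
    H <- stats::optimHess(theta, negll, neggr)
    step <- tryCatch(solve(H, g), error = function(e) g / max(abs(g)))
    f0 <- negll(theta)
    lambda <- 1
    accepted <- FALSE
    repeat {
      cand <- theta - lambda * step
      fc <- negll(cand)
      if (is.finite(fc) && fc <= f0 + 1e-9 * (1 + abs(f0))) {
        accepted <- TRUE
        break
      }
      lambda <- lambda / 2
      if (lambda < 1e-8) break
    }
    if (!accepted || max(abs(lambda * step)) < 1e-12) break
    theta <- cand
  }
  g <- neggr(theta)
  if (max(abs(g)) >= max(gtol, sqrt(tol))) {
    stop("beta regression did not converge; score trace: ",
         paste(utils::head(signif(trace_g, 3), 10), collapse = " -> "),
         call. = FALSE)
  }
  H <- stats::optimHess(theta, negll, neggr)
  vcov_full <- solve(H)
  vcov_full <- (vcov_full + t(vcov_full)) / 2

  p <- ncol(X)
  beta <- theta[1:p]
  names(beta) <- colnames(X)
  phi <- exp(theta[p + 1])
  vc <- vcov_full[1:p, 1:p, drop = FALSE]
  dimnames(vc) <- list(colnames(X), colnames(X))
  mu <- stats::plogis(drop(X %*% beta))
  new_cap_fit("beta_fit", beta, vc, phi, -negll(theta), n, mu, y,
              formula, attr(mf, "terms"),
              extra = list(phi = phi, vcov_full = vcov_full,
                           phi_se = sqrt(vcov_full[p + 1, p + 1]) * phi))
}

#' Gamma GLM with log link
#'
#' Thin wrapper around [stats::glm()] with `Gamma(link = "log")`: IRLS
#' maximum likelihood for the coefficients, Pearson-based dispersion, and
#' Wald (normal) inference on the log scale, matching the study's reporting.
#'
#' @param formula Model formula; the response must be strictly positive.
#' @param data Data frame.
#' @return Object of classes `gamma_fit`, `cap_fit`; the underlying `glm`
#'   fit is kept in `$glm_fit`.
#' @export
gamma_reg <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  stop_if(any(y <= 0), "Gamma regression requires a strictly positive response")
  fit <- stats::glm(formula, family = stats::Gamma(link = "log"), data = data,
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  stop_if(!fit$converged, "Gamma GLM did not converge")
  sm <- summary(fit)
  new_cap_fit("gamma_fit", stats::coef(fit), sm$cov.scaled, sm$dispersion,
              as.numeric(stats::logLik(fit)), stats::nobs(fit),
              stats::fitted(fit), y, formula, stats::terms(fit),
              extra = list(glm_fit = fit))
}

#' Binomial GLM with logit link
#'
#' Logit-link binomial regression for bounded scores (successes out of a
#' fixed number of items), via [stats::glm()]. Complete or quasi-complete
#' separation is detected (non-convergence or runaway coefficients) and
#' raised as an error naming the offending covariate.
#'
#' @param formula Formula whose left-hand side is `cbind(successes,
#'   failures)`.
#' @param data Data frame.
#' @return Object of classes `binom_fit`, `cap_fit`.
#' @export
binom_reg <- function(formula, data) {
  fit <- suppressWarnings(
    stats::glm(formula, family = stats::binomial(), data = data,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  cf <- stats::coef(fit)
  if (!fit$converged || any(abs(cf) > 15)) {
    worst <- names(cf)[which.max(abs(cf))]
    stop("possible separation in binomial GLM (covariate `", worst,
         "`); fit did not stabilize", call. = FALSE)
  }
  sm <- summary(fit)
  new_cap_fit("binom_fit", cf, sm$cov.scaled, 1,
              as.numeric(stats::logLik(fit)), stats::nobs(fit),
              stats::fitted(fit), stats::model.response(stats::model.frame(fit)),
              formula, stats::terms(fit),
              extra = list(glm_fit = fit))
}

# ---- methods -----------------------------------------------------------

#' @export
coef.cap_fit <- function(object, ...) object$coefficients

#' @export
vcov.cap_fit <- function(object, ...) object$vcov

#' @export
logLik.cap_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) +
              as.integer(inherits(object, "beta_fit")), class = "logLik")
}

#' @export
nobs.cap_fit <- function(object, ...) object$n

#' @export
confint.cap_fit <- function(object, parm, level = 0.95, ...) {
  q <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - q * object$se,
              object$coefficients + q * object$se)
  colnames(ci) <- paste(format(100 * c((1 - level) / 2, 1 - (1 - level) / 2),
                               trim = TRUE), "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.cap_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$z, `Pr(>|z|)` = object$p)
  structure(list(coefficients = tab, ci = object$ci,
                 dispersion = object$dispersion, loglik = object$loglik,
                 n = object$n, formula = object$formula,
                 type = class(object)[1]),
            class = "summary.cap_fit")
}

#' @export
print.summary.cap_fit <- function(x, ...) {
  label <- switch(x$type,
                  beta_fit = "Fixed-dispersion beta regression (logit link)",
                  gamma_fit = "Gamma GLM (log link)",
                  binom_fit = "Binomial GLM (logit link)", x$type)
  cat(label, "\n")
  cat("Formula:", deparse(x$formula), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\n%s %.4f   log-likelihood %.2f   n = %d\n",
              if (x$type == "beta_fit") "phi" else "dispersion",
              x$dispersion, x$loglik, x$n))
  invisible(x)
}

#' @export
print.cap_fit <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' @export
fitted.cap_fit <- function(object, ...) object$fitted

#' @export
predict.beta_fit <- function(object, newdata = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- stats::qlogis(object$fitted)
  } else {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
predict.gamma_fit <- function(object, newdata = NULL,
                              type = c("response", "link"), ...) {
  stats::predict(object$glm_fit, newdata = newdata, type = match.arg(type))
}

#' @export
residuals.beta_fit <- function(object, type = c("response", "pearson"), ...) {
  type <- match.arg(type)
  r <- object$y - object$fitted
  if (type == "pearson") {
    r <- r / sqrt(object$fitted * (1 - object$fitted) / (1 + object$phi))
  }
  r
}

#' @export
simulate.beta_fit <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    out <- as.data.frame(replicate(nsim, stats::rbeta(
      object$n, object$fitted * object$phi, (1 - object$fitted) * object$phi)))
    names(out) <- paste0("sim_", seq_len(nsim))
    out
  })
}

# ---- effect-size transforms -------------------------------------------

cap_effect <- function(estimate, conf.low, conf.high, p, scale) {
  structure(list(estimate = unname(estimate), conf.low = unname(conf.low),
                 conf.high = unname(conf.high), p = unname(p), scale = scale),
            class = "cap_effect")
}

#' @export
print.cap_effect <- function(x, ...) {
  cat(sprintf("%s: %.2f (95%% CI %.2f-%.2f), P = %s\n",
              x$scale, x$estimate, x$conf.low, x$conf.high, fmt_p(x$p)))
  invisible(x)
}

#' Odds ratio (or multiplier) per interquartile ratio of WMH volume
#'
#' Rescales the log-WMH coefficient to the study's reporting scale:
#' `exp(beta * log(q3 / q1))`, the multiplicative effect of moving from the
#' first to the third quartile of the WMH volume distribution. Confidence
#' limits are transformed the same way; the p-value is unchanged by the
#' monotone rescaling.
#'
#' @param fit A `cap_fit`.
#' @param q1,q3 First and third quartile of the non-zero WMH volumes (mL).
#' @param coef_name Name of the log-WMH coefficient (default `"log_wmh"`).
#' @return A `cap_effect` (estimate, 95% CI, p).
#' @export
effect_per_iqr <- function(fit, q1, q3, coef_name = "log_wmh") {
  stopifnot(inherits(fit, "cap_fit"))
  stop_if(!(q3 > q1 && q1 > 0), "need q3 > q1 > 0")
  stop_if(!coef_name %in% names(fit$coefficients),
          "coefficient `", coef_name, "` not in the fit")
  s <- log(q3 / q1)
  b <- fit$coefficients[coef_name]
  se <- fit$se[coef_name]
  q <- stats::qnorm(0.975)
  cap_effect(exp(b * s), exp((b - q * se) * s), exp((b + q * se) * s),
             unname(fit$p[coef_name]),
             sprintf("per %.2f-fold WMH increase", q3 / q1))
}

#' Multiplier per k percentage points of fractional occupancy
#'
#' Rescales a coefficient of a proportion-scale covariate to "per `k_pp`
#' percentage points": `exp(beta * k_pp / 100)`. Used to report the
#' occupancy effect per 5 pp (study tables) or per 20 pp.
#'
#' @param fit A `cap_fit`.
#' @param k_pp Percentage-point step (default 5).
#' @param coef_name Name of the occupancy coefficient (default `"fo_high"`).
#' @return A `cap_effect`.
#' @export
effect_per_k_pp <- function(fit, k_pp = 5, coef_name = "fo_high") {
  stopifnot(inherits(fit, "cap_fit"))
  stop_if(!coef_name %in% names(fit$coefficients),
          "coefficient `", coef_name, "` not in the fit")
  s <- k_pp / 100
  b <- fit$coefficients[coef_name]
  se <- fit$se[coef_name]
  q <- stats::qnorm(0.975)
  lo <- exp((b - q * se) * s)
  hi <- exp((b + q * se) * s)
  cap_effect(exp(b * s), min(lo, hi), max(lo, hi),
             unname(fit$p[coef_name]),
             sprintf("per %g pp occupancy", k_pp))
}
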