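# Gaussian linear mixed models for turbine proximity.
#
# Fits are maximum likelihood (not REML) so AIC/BIC are comparable across
# fixed-effect structures, with independent crossed random intercepts for
# wind farm, turbine and bird identity. Estimation delegates to
# lme4/lmerTest; model enumeration, selection, the Nakagawa R-squared
# decomposition, variance shares and effect grids are computed here.

#' Fit one candidate proximity mixed model
#'
#' Response is the 3-D distance to the paired turbine hub (`d3d`, metres).
#' Random factors present in the data with at least two levels enter as
#' independent crossed random intercepts; degenerate factors (fewer than two
#' levels, inevitable in small fixtures) are dropped with a warning rather
#' than fitted at the boundary. If no random factor survives, an ordinary
#' least-squares fit is returned (flagged).
#'
#' @param fixed Right-hand-side fixed-effects formula string (e.g.
#'   `"get_turbine * postop"`), or a one-row candidate tibble from the
#'   `enumerate_*_candidates()` functions.
#' @param data Proximity records. A `phase` column is converted to the
#'   `postop` factor (levels BEFORE, AFTER); `blade_status` to a factor
#'   (levels STILL, MOVING). Rows incomplete for the model's terms are
#'   dropped (complete-case).
#' @param label Optional model label; taken from the candidate row if given.
#' @param random Character vector of random-intercept factors.
#' @return An object of class `ta_fit`: see [tidy()] and [glance()] methods.
#' @export
fit_lmm <- function(fixed, data, label = NULL,
                    random = c("farm_id", "turbine_id", "bird_id")) {
  if (is.data.frame(fixed)) {
    label <- label %||% fixed$label[1]
    fixed <- fixed$fixed[1]
  }
  label <- label %||% fixed
  data <- as_tibble(data)
  if ("phase" %in% names(data) && !("postop" %in% names(data))) {
    data$postop <- factor(data$phase, levels = c("BEFORE", "AFTER"))
  }
  if ("blade_status" %in% names(data) && !is.factor(data$blade_status)) {
    data$blade_status <- factor(data$blade_status,
                                levels = c("STILL", "MOVING"))
  }
  if (!"d3d" %in% names(data)) abort("data must contain a d3d response column")

  fixed_vars <- all.vars(as.formula(paste("~", fixed)))
  used <- c("d3d", fixed_vars, intersect(random, names(data)))
  data <- data[stats::complete.cases(data[, used, drop = FALSE]), , drop = FALSE]

  keep_random <- character(0)
  for (rf in random) {
    if (!rf %in% names(data)) next
    nlev <- length(unique(data[[rf]]))
    if (nlev >= 2) keep_random <- c(keep_random, rf)
    else warn(sprintf("random factor `%s` has %d level(s); dropped", rf, nlev))
  }

  if (length(keep_random) == 0) {
    fml <- as.formula(paste("d3d ~", fixed))
    fit <- stats::lm(fml, data = data)
    ll <- logLik(fit)
    sm <- coef(summary(fit))
    coefs <- tibble(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
      ci_lo = sm[, 1] - qnorm(0.975) * sm[, 2],
      ci_hi = sm[, 1] + qnorm(0.975) * sm[, 2],
      df = fit$df.residual, p = sm[, 4]
    )
    res <- list(label = label, fixed = fixed, fit = fit, engine = "lm",
                n_obs = nrow(data), df = attr(ll, "df"),
                logLik = as.numeric(ll), AIC = AIC(fit), BIC = BIC(fit),
                sigma2 = sum(fit$residuals^2) / nrow(data),  # ML estimate
                tau = setNames(numeric(0), character(0)),
                n_groups = integer(0), coefficients = coefs,
                singular = FALSE, converged = TRUE, data = data)
    class(res) <- "ta_fit"
    return(res)
  }

  rterms <- paste(sprintf("(1 | %s)", keep_random), collapse = " + ")
  fml <- as.formula(paste("d3d ~", fixed, "+", rterms))
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            optCtrl = list(maxfun = 1e5))
  fit <- lmerTest::lmer(fml, data = data, REML = FALSE, control = ctrl)

  ll <- logLik(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau <- setNames(vc$vcov[vc$grp != "Residual"], vc$grp[vc$grp != "Residual"])
  sigma2 <- vc$vcov[vc$grp == "Residual"]

  sm <- coef(summary(fit))   # lmerTest: Estimate, SE, df, t, Pr(>|t|)
  coefs <- tibble(
    term = rownames(sm), estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    ci_lo = sm[, "Estimate"] - qnorm(0.975) * sm[, "Std. Error"],
    ci_hi = sm[, "Estimate"] + qnorm(0.975) * sm[, "Std. Error"],
    df = sm[, "df"], p = sm[, "Pr(>|t|)"]
  )
  msgs <- fit@optinfo$conv$lme4$messages
  res <- list(
    label = label, fixed = fixed, fit = fit, engine = "lmer",
    n_obs = stats::nobs(fit), df = attr(ll, "df"),
    logLik = as.numeric(ll), AIC = AIC(fit), BIC = BIC(fit),
    sigma2 = sigma2, tau = tau,
    n_groups = setNames(as.integer(lme4::ngrps(fit)),
                        names(lme4::ngrps(fit))),
    coefficients = coefs,
    singular = lme4::isSingular(fit),
    converged = is.null(msgs) || length(msgs) == 0,
    data = data
  )
  class(res) <- "ta_fit"
  res
}

#' @export
print.ta_fit <- function(x, ...) {
  cat(sprintf("<ta_fit %s> d3d ~ %s (%s, ML), n = %d, df = %d\n",
              x$label, x$fixed, x$engine, x$n_obs, x$df))
  cat(sprintf("  AIC %.1f  BIC %.1f  logLik %.1f%s\n", x$AIC, x$BIC, x$logLik,
              if (x$singular) "  [singular]" else ""))
  if (length(x$tau) > 0) {
    cat("  sigma2", format(x$sigma2, digits = 6), " tau:",
        paste(sprintf("%s=%.1f", names(x$tau), x$tau), collapse = " "), "\n")
  }
  invisible(x)
}

#' Tidy the fixed-effect coefficients of a proximity model fit
#' @param x A `ta_fit`.
#' @param ... Unused.
#' @return A tibble: `term`, `estimate`, `se`, `ci_lo`, `ci_hi`, `df`
#'   (Satterthwaite for mixed fits), `p`.
#' @method tidy ta_fit
#' @export
tidy.ta_fit <- function(x, ...) x$coefficients

#' One-row summary of a proximity model fit
#' @param x A `ta_fit`.
#' @param ... Unused.
#' @return A tibble: `label`, `df`, `logLik`, `AIC`, `BIC`, `sigma2`,
#'   `n_obs`, `singular`, `converged`, `marginal_r2`, `conditional_r2`.
#' @method glance ta_fit
#' @export
glance.ta_fit <- function(x, ...) {
  r2 <- r2_nakagawa(x)
  tibble(label = x$label, df = x$df, logLik = x$logLik, AIC = x$AIC,
         BIC = x$BIC, sigma2 = x$sigma2, n_obs = x$n_obs,
         singular = x$singular, converged = x$converged,
         marginal_r2 = r2$marginal, conditional_r2 = r2$conditional)
}

# fixed-effects linear predictor and design matrix on (new)data; columns
# are aligned to the estimated coefficients (aliased columns dropped by the
# fitting engine on rank-deficient data contribute zero)
fixed_predictor <- function(x, newdata = NULL) {
  data <- newdata %||% x$data
  X <- model.matrix(as.formula(paste("~", x$fixed)), data = data)
  beta <- if (x$engine == "lm") coef(x$fit) else lme4::fixef(x$fit)
  beta <- beta[!is.na(beta)]
  keep <- intersect(colnames(X), names(beta))
  X <- X[, keep, drop = FALSE]
  beta <- beta[keep]
  list(X = X, eta = as.numeric(X %*% beta))
}

#' Nakagawa marginal and conditional R-squared
#'
#' The fixed-effects variance is the variance of the fixed-effects linear
#' predictor over the model data; marginal R2 relates it to the total
#' (fixed + random-intercept + residual) variance, conditional R2 adds the
#' random-intercept variances to the numerator.
#'
#' @param fit A `ta_fit`.
#' @return A tibble with `marginal` and `conditional` (both in `[0, 1]`,
#'   `conditional >= marginal`).
#' @export
r2_nakagawa <- function(fit) {
  eta <- fixed_predictor(fit)$eta
  sigma_f2 <- if (length(eta) > 1) var(eta) else 0
  r2_from_components(sigma_f2, fit$tau, fit$sigma2)
}

#' Nakagawa R-squared from variance components
#'
#' The same decomposition as [r2_nakagawa()], computed directly from a
#' fixed-effects variance, random-intercept variances and a residual
#' variance — e.g. components reported in a published model table.
#'
#' @param sigma_f2 Fixed-effects (linear predictor) variance.
#' @param tau Numeric vector of random-intercept variances.
#' @param sigma2 Residual variance.
#' @return A tibble with `marginal` and `conditional`.
#' @export
r2_from_components <- function(sigma_f2, tau, sigma2) {
  if (sigma_f2 < 0 || any(tau < 0) || sigma2 < 0) {
    abort("variance components must be non-negative")
  }
  total <- sigma_f2 + sum(tau) + sigma2
  if (total == 0) return(tibble(marginal = 0, conditional = 0))
  tibble(marginal = sigma_f2 / total,
         conditional = (sigma_f2 + sum(tau)) / total)
}

#' Recover the fixed-effects variance from reported R-squared values
#'
#' Algebraic inversion of the Nakagawa identities: given marginal and
#' conditional R2 and the sum of random-intercept variances,
#' `sigma_f2 = marginal * sum_tau / (conditional - marginal)`.
#'
#' @param marginal,conditional Reported R2 values (`conditional > marginal`).
#' @param sum_tau Sum of the random-intercept variances.
#' @return The implied fixed-effects variance.
#' @export
fixed_variance_from_r2 <- function(marginal, conditional, sum_tau) {
  if (marginal < 0) abort("marginal R2 must be >= 0")
  if (marginal == 0) return(0)
  if (conditional <= marginal) abort("conditional R2 must exceed marginal R2")
  if (sum_tau <= 0) abort("sum_tau must be > 0")
  marginal * sum_tau / (conditional - marginal)
}

#' Shares of the explained variance
#'
#' Partitions the explained variance (fixed-effects variance plus
#' random-intercept variances) into the share attributable to the fixed
#' effects and to each random factor. Shares sum to 1.
#'
#' @param sigma_f2 Fixed-effects variance (>= 0).
#' @param tau Named numeric vector of random-intercept variances.
#' @return A tibble with `component`, `variance`, `share`.
#' @export
variance_shares <- function(sigma_f2, tau) {
  if (sigma_f2 < 0 || any(tau < 0)) abort("variances must be non-negative")
  denom <- sigma_f2 + sum(tau)
  if (denom == 0) abort("all variance components are zero")
  tibble(
    component = c("fixed", names(tau) %||% paste0("tau", seq_along(tau))),
    variance = c(sigma_f2, unname(tau)),
    share = c(sigma_f2, unname(tau)) / denom
  )
}

#' Fitted-effect grid for a focal predictor
#'
#' Evaluates the fixed-effects linear predictor over a grid of the focal
#' predictor, holding other numeric predictors at their observed means and
#' factors at their reference level (or at values supplied in
#' `conditions`, which may be vectors to produce panels). Random effects are
#' set to zero; confidence intervals are delta-method Wald intervals from
#' the fixed-effects coefficient covariance.
#'
#' @param fit A `ta_fit`.
#' @param focal Name of the focal predictor (must appear in the model).
#' @param grid Values of the focal predictor; defaults to an even grid over
#'   the observed range (numeric) or all levels (factor).
#' @param conditions Named list of values for non-focal predictors.
#' @param level Confidence level (default 0.95).
#' @return A tibble: the focal column, any conditioning columns, `fitted`,
#'   `lo`, `hi`.
#' @export
effect_grid <- function(fit, focal, grid = NULL, conditions = list(),
                        level = 0.95) {
  vars <- all.vars(as.formula(paste("~", fit$fixed)))
  if (!focal %in% vars) {
    abort(sprintf("focal predictor `%s` is not in the model (%s)",
                  focal, fit$fixed))
  }
  data <- fit$data
  if (is.null(grid)) {
    v <- data[[focal]]
    grid <- if (is.numeric(v)) {
      seq(min(v), max(v), length.out = 25)
    } else {
      factor(levels(factor(v)), levels = levels(factor(v)))
    }
  }
  others <- setdiff(vars, focal)
  base <- purrr::map(setNames(others, others), function(nm) {
    if (!is.null(conditions[[nm]])) return(conditions[[nm]])
    v <- data[[nm]]
    if (is.numeric(v)) mean(v) else factor(levels(factor(v))[1],
                                           levels = levels(factor(v)))
  })
  nd <- tidyr::expand_grid(!!focal := grid, !!!base)
  # preserve factor levels so model.matrix contrasts match the fit
  for (nm in vars) {
    if (is.factor(data[[nm]]) && !is.factor(nd[[nm]])) {
      nd[[nm]] <- factor(nd[[nm]], levels = levels(data[[nm]]))
    }
  }
  fp <- fixed_predictor(fit, newdata = nd)
  V <- as.matrix(vcov(fit$fit))   # fixed-effects covariance
  V <- V[colnames(fp$X), colnames(fp$X), drop = FALSE]
  se <- sqrt(rowSums((fp$X %*% V) * fp$X))
  z <- qnorm(1 - (1 - level) / 2)
  dplyr::bind_cols(nd, tibble(fitted = fp$eta,
                              lo = fp$eta - z * se, hi = fp$eta + z * se))
}
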