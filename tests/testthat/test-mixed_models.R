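# Candidate enumeration, mixed-model fitting, selection and variance
# decomposition.

term_labels <- function(fixed) {
  attr(stats::terms(stats::as.formula(paste("~", fixed))), "term.labels")
}

test_that("the before/after candidate set is the full 12-model enumeration", {
  cand <- enumerate_before_after_candidates()
  expect_equal(nrow(cand), 12)
  expect_equal(cand$fixed[1], "1")                       # null model
  expect_setequal(
    term_labels(cand$fixed[12]),                         # saturated model
    c("get_turbine", "postop", "get_location",
      "get_turbine:postop", "get_turbine:get_location",
      "postop:get_location", "get_turbine:postop:get_location")
  )
  # interactions only among included main effects
  for (f in cand$fixed[-1]) {
    labs <- term_labels(f)
    mains <- labs[!grepl(":", labs)]
    for (int in labs[grepl(":", labs)]) {
      expect_true(all(strsplit(int, ":")[[1]] %in% mains))
    }
  }
})

test_that("the after-operation candidate set is the full 27-model enumeration", {
  cand <- enumerate_after_candidates()
  expect_equal(nrow(cand), 27)
  expect_setequal(
    term_labels(cand$fixed[25]),                         # wind x GETturb x turn
    c("wind_speed", "get_turbine", "blade_status",
      "wind_speed:get_turbine", "wind_speed:blade_status",
      "get_turbine:blade_status", "wind_speed:get_turbine:blade_status")
  )
  expect_length(term_labels(cand$fixed[27]), 15)         # four-way saturated
  expect_setequal(term_labels(cand$fixed[26]),
                  c("wind_speed", "get_location", "get_turbine",
                    "blade_status"))
  for (f in cand$fixed[-1]) {
    labs <- term_labels(f)
    mains <- labs[!grepl(":", labs)]
    for (int in labs[grepl(":", labs)]) {
      expect_true(all(strsplit(int, ":")[[1]] %in% mains))
    }
  }
})

sim_lmm_data <- function(n_per = 40, n_turb = 12, n_bird = 6, beta = 75,
                         tau_turb = 120^2, tau_bird = 60^2, sigma = 150,
                         seed = 1) {
  set.seed(seed)
  g <- tidyr::expand_grid(turbine_id = sprintf("T%02d", seq_len(n_turb)),
                          bird_id = sprintf("B%02d", seq_len(n_bird)),
                          rep = seq_len(n_per))
  u_t <- stats::setNames(rnorm(n_turb, 0, sqrt(tau_turb)),
                         sprintf("T%02d", seq_len(n_turb)))
  u_b <- stats::setNames(rnorm(n_bird, 0, sqrt(tau_bird)),
                         sprintf("B%02d", seq_len(n_bird)))
  g$phase <- sample(c("BEFORE", "AFTER"), nrow(g), replace = TRUE)
  g$farm_id <- ifelse(g$turbine_id <= sprintf("T%02d", n_turb %/% 2),
                      "F1", "F2")
  g$d3d <- 600 + beta * (g$phase == "AFTER") + u_t[g$turbine_id] +
    u_b[g$bird_id] + rnorm(nrow(g), 0, sigma)
  g
}

test_that("fit_lmm matches OLS when random-effect variances are zero", {
  dat <- sim_lmm_data(tau_turb = 0, tau_bird = 0, seed = 2)
  fit <- fit_lmm("postop", dat)
  ols <- stats::lm(d3d ~ factor(phase, levels = c("BEFORE", "AFTER")),
                   data = dat)
  co <- tidy(fit)
  expect_lt(abs(co$estimate[2] - coef(ols)[2]), 2 * co$se[2])
  expect_lt(sum(fit$tau), 200)   # variances pinned near the boundary
  expect_true(fit$singular)      # ...and flagged
})

test_that("ML variance components match the closed-form one-way estimator", {
  # balanced one-way layout: ML gives sigma2 = SSW/(N-a),
  # tau = SSB/(a n) - sigma2/n with SSB about the grand mean
  set.seed(3)
  a <- 30; n <- 25
  grp <- rep(sprintf("G%02d", 1:a), each = n)
  y <- 500 + rep(rnorm(a, 0, 80), each = n) + rnorm(a * n, 0, 120)
  dat <- tibble::tibble(d3d = y, turbine_id = grp)
  fit <- fit_lmm("1", dat, random = "turbine_id")

  gm <- mean(y); gmean <- tapply(y, grp, mean)
  ssw <- sum((y - gmean[grp])^2)
  ssb <- n * sum((gmean - gm)^2)
  sigma2_ml <- ssw / (a * n - a)
  tau_ml <- ssb / (a * n) - sigma2_ml / n
  expect_equal(unname(fit$sigma2), sigma2_ml, tolerance = 1e-4)
  expect_equal(unname(fit$tau[["turbine_id"]]), tau_ml, tolerance = 1e-4)
})

test_that("fit_lmm recovers a known displacement effect", {
  dat <- sim_lmm_data(beta = 75, seed = 4)
  fit <- fit_lmm("postop", dat)
  co <- dplyr::filter(tidy(fit), term == "postopAFTER")
  expect_gt(co$estimate, 0)
  expect_true(co$ci_lo <= 75 && 75 <= co$ci_hi)
  # refitting permuted rows yields identical estimates
  perm <- dat[sample(nrow(dat)), ]
  fit2 <- fit_lmm("postop", perm)
  expect_equal(tidy(fit2)$estimate, tidy(fit)$estimate, tolerance = 1e-6)
})

test_that("AIC and BIC satisfy their identities on every fit", {
  dat <- sim_lmm_data(seed = 5)
  for (fixed in c("1", "postop", "get_turbine + postop")) {
    d <- dat
    if (grepl("get_turbine", fixed)) d$get_turbine <- sample(1:10, nrow(d),
                                                             replace = TRUE)
    fit <- fit_lmm(fixed, d)
    expect_equal(fit$AIC, -2 * fit$logLik + 2 * fit$df, tolerance = 1e-8)
    expect_equal(fit$BIC, -2 * fit$logLik + fit$df * log(fit$n_obs),
                 tolerance = 1e-8)
  }
})

test_that("delta_table and select_best implement the selection rules", {
  gl <- tibble::tibble(label = c("A", "B"), df = c(5, 6),
                       AIC = c(100, 110), BIC = c(105, 118))
  dt <- delta_table(gl)
  expect_equal(dt$dAIC, c(0, 10))
  expect_equal(dt$dBIC, c(0, 13))
  expect_equal(min(dt$dAIC), 0)
  expect_equal(select_best(gl), "A")                  # both criteria agree

  # disagreement: BIC wins by default, AIC behind the flag
  gl2 <- tibble::tibble(label = c("A", "B"), df = c(12, 20),
                        AIC = c(41, 0), BIC = c(0, 3))
  expect_equal(select_best(gl2), "A")
  expect_equal(select_best(gl2, prefer = "AIC"), "B")

  # all-equal criteria: fewest df
  gl3 <- tibble::tibble(label = c("A", "B"), df = c(8, 5),
                        AIC = c(50, 50), BIC = c(60, 60))
  expect_equal(select_best(gl3), "B")
})

test_that("Nakagawa R2 reproduces published variance-component analytics", {
  # null-model components from the fix-based analysis table
  r2 <- r2_from_components(0, c(28645.2, 5796.5, 2554.0), 30626.0)
  expect_equal(r2$marginal, 0)
  expect_equal(r2$conditional, 0.547, tolerance = 0.001 / 0.547)
  # null-model components from the flight-line analysis table
  r2b <- r2_from_components(0, c(5141.9, 809.7, 234.4), 6843.1)
  expect_equal(r2b$conditional, 0.475, tolerance = 0.001 / 0.475)
  # degenerate: nothing explained
  expect_equal(unlist(r2_from_components(0, c(0, 0), 100)),
               c(marginal = 0, conditional = 0))
})

test_that("r2_nakagawa is consistent with a by-hand computation on a fit", {
  dat <- sim_lmm_data(seed = 6)
  fit <- fit_lmm("postop", dat)
  r2 <- r2_nakagawa(fit)
  # independent route: variance of X beta from the lme4 object directly
  X <- stats::model.matrix(fit$fit)
  sf2 <- stats::var(as.numeric(X %*% lme4::fixef(fit$fit)))
  vc <- as.data.frame(lme4::VarCorr(fit$fit))
  tot <- sf2 + sum(vc$vcov)
  expect_equal(r2$marginal, sf2 / tot, tolerance = 1e-8)
  expect_equal(r2$conditional, (tot - vc$vcov[vc$grp == "Residual"]) / tot,
               tolerance = 1e-8)
  expect_true(r2$conditional >= r2$marginal)
  expect_true(r2$conditional <= 1 && r2$marginal >= 0)
})

test_that("fixed_variance_from_r2 inverts the Nakagawa identities", {
  sf2 <- fixed_variance_from_r2(0.063, 0.613, 38625.6)
  expect_equal(sf2, 0.063 * 38625.6 / 0.55, tolerance = 1e-12)
  expect_equal(fixed_variance_from_r2(0, 0.5, 1000), 0)
  expect_error(fixed_variance_from_r2(0.6, 0.5, 1000), "exceed")

  # round trip through r2_from_components
  tau <- c(30898.9, 5244.8, 2481.9)
  r2 <- r2_from_components(sf2, tau, 27247.2)
  back <- fixed_variance_from_r2(r2$marginal, r2$conditional, sum(tau))
  expect_equal(back, sf2, tolerance = 1e-9)
})

test_that("variance_shares recovers the published turbine-identity shares", {
  # fix-based full model: tau (turbine, bird, farm) + printed R2 0.063/0.613
  tau <- c(turbine_id = 30898.9, bird_id = 5244.8, farm_id = 2481.9)
  sf2 <- fixed_variance_from_r2(0.063, 0.613, sum(tau))
  sh <- variance_shares(sf2, tau)
  expect_equal(sum(sh$share), 1, tolerance = 1e-9)
  turb <- sh$share[sh$component == "turbine_id"]
  expect_gt(turb, 0.712); expect_lt(turb, 0.722)       # printed: 71.7%

  # flight-line full model: printed R2 0.086/0.559
  tau2 <- c(turbine_id = 6145.4, bird_id = 503.0, farm_id = 260.1)
  sf22 <- fixed_variance_from_r2(0.086, 0.559, sum(tau2))
  sh2 <- variance_shares(sf22, tau2)
  turb2 <- sh2$share[sh2$component == "turbine_id"]
  expect_gt(turb2, 0.747); expect_lt(turb2, 0.757)     # printed: 75.2%

  expect_equal(variance_shares(0, c(g = 42))$share, c(0, 1))
  expect_error(variance_shares(0, c(0, 0)), "zero")
})

test_that("effect_grid evaluates the fixed-effects linear predictor", {
  set.seed(7)
  dat <- tibble::tibble(
    d3d = 300 + 12 * (1:200) / 10 + rnorm(200, 0, 5),
    get_turbine = (1:200) / 10,
    turbine_id = rep(sprintf("T%d", 1:10), 20),
    bird_id = rep(sprintf("B%d", 1:4), 50)
  )
  fit <- fit_lmm("get_turbine", dat, random = c("turbine_id", "bird_id"))
  b <- lme4::fixef(fit$fit)
  grid <- effect_grid(fit, "get_turbine", grid = c(2, 5, 9))
  expect_equal(grid$fitted, unname(b[1] + b[2] * c(2, 5, 9)), tolerance = 1e-10)
  expect_true(all(grid$lo < grid$fitted & grid$fitted < grid$hi))
  expect_error(effect_grid(fit, "wind_speed"), "not in the model")

  # interaction model against a hand-computed linear predictor
  fit2 <- fit_lmm(enumerate_after_candidates()[25, ], shared_after_records)
  g2 <- effect_grid(fit2, "wind_speed", grid = c(4, 10),
                    conditions = list(blade_status = factor(
                      c("STILL", "MOVING"), levels = c("STILL", "MOVING"))))
  b2 <- lme4::fixef(fit2$fit)
  gt <- mean(fit2$data$get_turbine)
  hand <- function(w, moving) {
    unname(b2["(Intercept)"] + b2["wind_speed"] * w + b2["get_turbine"] * gt +
      moving * (b2["blade_statusMOVING"] +
                  b2["wind_speed:blade_statusMOVING"] * w +
                  b2["get_turbine:blade_statusMOVING"] * gt) +
      b2["wind_speed:get_turbine"] * w * gt +
      moving * b2["wind_speed:get_turbine:blade_statusMOVING"] * w * gt)
  }
  for (i in seq_len(nrow(g2))) {
    expect_equal(g2$fitted[i],
                 hand(g2$wind_speed[i], g2$blade_status[i] == "MOVING"),
                 tolerance = 1e-8)
  }
})

test_that("confidence bands narrow as the sample grows", {
  width <- vapply(c(200, 2000), function(n) {
    set.seed(8)
    dat <- tibble::tibble(
      d3d = 300 + 10 * runif(n, 1, 10) + rnorm(n, 0, 50),
      get_turbine = runif(n, 1, 10),
      turbine_id = rep_len(sprintf("T%d", 1:10), n)
    )
    fit <- fit_lmm("get_turbine", dat, random = "turbine_id")
    g <- effect_grid(fit, "get_turbine", grid = 5)
    g$hi - g$lo
  }, numeric(1))
  expect_lt(width[2], width[1])
})
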