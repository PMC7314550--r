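test_that("Cox fit matches a grid-search partial-likelihood oracle", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 0, 1)
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- fit_cox(time, event, cbind(x = x))
  oracle <- grid_search_cox(time, event, x)
  expect_lt(abs(unname(fit$coefficients) - oracle), 1e-3)
  # and the fitter's optimum scores at least as well under the oracle's
  # own likelihood evaluator
  expect_gte(naive_cox_loglik(fit$coefficients, time, event, x) + 1e-10,
             naive_cox_loglik(oracle, time, event, x))
})

test_that("Cox fit handles ties like the Efron reference implementation", {
  skip_if_not_installed("survival")
  set.seed(8)
  n <- 120
  x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
  time <- ceiling(rexp(n, exp(0.8 * x1 - 0.3 * x2) / 10))  # many ties
  event <- rbinom(n, 1, 0.7)
  event[1] <- 1
  fit <- fit_cox(time, event, cbind(x1 = x1, x2 = x2))
  ref <- survival::coxph(survival::Surv(time, event) ~ x1 + x2,
                         ties = "efron")
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(ref$var))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("partial likelihood is invariant to covariate shifts", {
  set.seed(21)
  time <- rexp(40); event <- rbinom(40, 1, 0.6); event[1] <- 1
  x <- rnorm(40)
  f1 <- fit_cox(time, event, cbind(x = x))
  f2 <- fit_cox(time, event, cbind(x = x + 100))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("Cox fit recovers the generating burden effect with nominal coverage", {
  set.seed(1234)
  cfg <- sim_config(n_individuals = 20000, seed = NULL)
  hits <- positive <- logical(50)
  for (r in 1:50) {
    co <- simulate_cohort(cfg, variants = FALSE)
    ph <- co$phenotypes
    f <- fit_cox(ph$time, ph$death,
                 cbind(burden = co$burden[, 1], sex = ph$sex,
                       age = ph$age_at_assessment))
    hits[r] <- f$ci["burden", "lower"] <= 0.046 &&
      0.046 <= f$ci["burden", "upper"]
    positive[r] <- f$coefficients["burden"] > 0
  }
  expect_gte(mean(hits), 0.90)
  expect_gte(mean(positive), 0.90)
})

test_that("degenerate Cox inputs raise informative errors", {
  time <- 1:6; event <- c(1, 0, 1, 1, 0, 1); x <- c(1, 0, 1, 0, 1, 0)
  expect_error(fit_cox(time, rep(0, 6), cbind(x)), "no events")
  expect_error(fit_cox(time, event, cbind(x, x)), "rank-deficient")
  expect_error(fit_cox(time, event, cbind(rep(2, 6))), "constant")
  expect_error(fit_cox(time, c(1, 1, 1, 0, 0, 0), cbind(x = c(5, 5, 5, 0, 0, 0))),
               "separation|monotone")
})

test_that("Gompertz-PH optimum beats a parameter grid on a small fixture", {
  time <- c(55, 62, 70, 48, 81)
  event <- c(1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 1, 0)
  fit <- fit_gompertz_ph(time, event, cbind(x = x))
  ll_hat <- naive_gompertz_loglik(fit$h0, fit$gamma, fit$coefficients,
                                  time, event, x)
  grid_h0 <- exp(seq(log(1e-7), log(1e-1), length.out = 50))
  grid_g <- seq(0.001, 0.3, length.out = 50)
  grid_b <- seq(-2, 2, length.out = 50)
  best <- -Inf
  for (h0 in grid_h0) for (g in grid_g) {
    lls <- vapply(grid_b, function(b)
      naive_gompertz_loglik(h0, g, b, time, event, x), numeric(1))
    best <- max(best, max(lls))
  }
  expect_gte(ll_hat + 1e-8, best)
})

test_that("exponential limit reduces to the closed-form hazard MLE", {
  set.seed(5)
  time <- rexp(300, 0.05)
  event <- rep(1L, 300)
  fit <- fit_gompertz_ph(time, event, distribution = "exponential")
  expect_equal(fit$h0, sum(event) / sum(time), tolerance = 1e-6)
  # near-exponential data: the full Gompertz fit drives Gamma toward 0
  # and its h0 toward the same closed form
  cens <- as.integer(time < 15)
  t2 <- pmin(time, 15)
  fitg <- fit_gompertz_ph(t2, cens)
  expect_equal(fitg$h0 * exp(fitg$gamma * mean(t2)),
               sum(cens) / sum(t2), tolerance = 0.15)
})

test_that("Gompertz-PH agrees with the flexsurv reference on simulated data", {
  skip_if_not_installed("flexsurv")
  cfg <- sim_config(n_individuals = 4000, seed = 86)
  set.seed(86)
  d <- morbidity_cohort(cfg)
  fit <- fit_gompertz_ph(d$time, d$event,
                         cbind(burden = d$burden, sex = d$sex))
  ref <- flexsurv::flexsurvreg(
    survival::Surv(time, event) ~ burden + sex, data = d,
    dist = "gompertz")
  rc <- ref$res[, "est"]
  expect_equal(fit$gamma, unname(rc["shape"]), tolerance = 1e-4)
  expect_equal(fit$h0, unname(rc["rate"]), tolerance = 1e-3)
  expect_equal(unname(fit$coefficients),
               unname(rc[c("burden", "sex")]), tolerance = 1e-4)
})

test_that("Gompertz-PH rejects degenerate designs", {
  time <- c(50, 60, 70); event <- c(1, 1, 0)
  expect_error(fit_gompertz_ph(time, c(0, 0, 0)), "censored")
  x <- c(1, 0, 1)
  expect_error(fit_gompertz_ph(time, event, cbind(x, x)), "rank-deficient")
  # covariate collinear with age aliases the Gompertz slope
  expect_error(fit_gompertz_ph(time, event, cbind(age = time)),
               "rank-deficient")
})

test_that("Kaplan-Meier matches hand-computed product-limit values", {
  time <- c(1, 2, 3, 4, 4, 5, 6, 7)
  event <- c(1, 0, 1, 1, 1, 0, 1, 1)
  km <- km_estimate(time, event)[["all"]]
  expect_equal(km$time, c(1, 3, 4, 6, 7))
  expect_equal(km$n_risk, c(8L, 6L, 5L, 2L, 1L))
  expect_equal(km$survival, c(7 / 8, 35 / 48, 7 / 16, 7 / 32, 0))
  expect_true(all(diff(km$survival) <= 0))
})

test_that("Kaplan-Meier limits: empirical survival, flat curve, mean identity", {
  # no censoring: KM equals the empirical survival fraction
  set.seed(3)
  t_ <- sample(1:20, 30, replace = TRUE)
  km <- km_estimate(t_, rep(1, 30))[["all"]]
  emp <- vapply(km$time, function(u) mean(t_ > u), numeric(1))
  expect_equal(km$survival, emp)
  # discrete identity: sum of S * interval widths = mean lifetime
  mean_t <- sum(c(1, head(km$survival, -1)) * diff(c(0, km$time)))
  expect_equal(mean_t, mean(t_))
  # all censored: flat at 1 (no event rows)
  km0 <- km_estimate(c(2, 4, 6), c(0, 0, 0))[["all"]]
  expect_equal(nrow(km0), 0)
})

test_that("log-rank matches the hand-computed O/E/V table", {
  time <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  event <- c(1, 1, 1, 0, 1, 1, 1, 1, 0, 1)
  group <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(time, event, group)
  # hand calculation: E_a = 1/2+4/9+1/2+3/7+1/2+2/5+1/2, O_a = 4,
  # V = 1/4 + 20/81 + 1/4 + 12/49 + 1/4 + 6/25 + 1/4
  E_a <- 1 / 2 + 4 / 9 + 1 / 2 + 3 / 7 + 1 / 2 + 2 / 5 + 1 / 2
  V <- 1 / 4 + 20 / 81 + 1 / 4 + 12 / 49 + 1 / 4 + 6 / 25 + 1 / 4
  expect_equal(unname(lr$observed["a"]), 4)
  expect_equal(unname(lr$expected["a"]), E_a, tolerance = 1e-12)
  expect_equal(lr$statistic, (4 - E_a)^2 / V, tolerance = 1e-12)
  expect_equal(lr$p, pchisq((4 - E_a)^2 / V, 1, lower.tail = FALSE))
})

test_that("log-rank is symmetric, null on identical groups, and powered", {
  set.seed(12)
  t_ <- rexp(60); e_ <- rbinom(60, 1, 0.7); e_[1] <- 1
  g <- rep(c("x", "y"), 30)
  a <- logrank_test(t_, e_, g)
  b <- logrank_test(t_, e_, ifelse(g == "x", "y", "x"))
  expect_equal(a$statistic, b$statistic)
  # label split of the same data duplicated: statistic 0, p 1
  lr0 <- logrank_test(rep(t_, 2), rep(e_, 2),
                      rep(c("u", "v"), each = 60))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  expect_error(logrank_test(t_, e_, rep("x", 60)), "two")
  # power at the study's effect size: burden groups 0-3 vs 10+,
  # hazard ratio exp(0.046 * (11 - 2)) ~ 1.5, 5000 deaths
  cfg <- sim_config(seed = NULL)
  set.seed(77)
  reject <- replicate(20, {
    ages_lo <- simulate_event_ages(cfg, rep(2, 2500), rep(0, 2500),
                                   "lifespan", seed = NA)
    ages_hi <- simulate_event_ages(cfg, rep(11, 2500), rep(0, 2500),
                                   "lifespan", seed = NA)
    lr <- logrank_test(c(ages_lo, ages_hi), rep(1, 5000),
                       rep(c("low", "high"), each = 2500))
    lr$p < 0.05
  })
  expect_gte(mean(reject), 0.80)
})

test_that("KS balance check accepts matched ages and rejects shifted ones", {
  same <- c(rnorm(200, 57.5, 8))
  res <- ks_age_balance(c(same, same), rep(c("g1", "g2"), each = 200))
  expect_equal(res$statistic, 0)
  expect_equal(attr(res, "min_p"), 1)
  set.seed(9)
  shifted <- ks_age_balance(c(rnorm(200), rnorm(200, 3)),
                            rep(c("g1", "g2"), each = 200))
  expect_lt(attr(shifted, "min_p"), 0.01)
  # five burden groups drawn from one age distribution pass at 1%
  set.seed(10)
  ages <- rnorm(1122, 57.5, 7.9)
  grp <- stratify_by_burden(rnbinom(1122, size = 47.4, mu = 6))
  bal <- ks_age_balance(ages, grp)
  expect_gt(attr(bal, "min_p"), 0.01)
  expect_error(ks_age_balance(c(1, 2), c("a", "b")), "at least 2")
})

test_that("sex-stratified fits isolate sex-specific burden effects", {
  cfg_f <- sim_config(n_individuals = 6000, beta_burden_healthspan = 0.08,
                      beta_sex_healthspan = 0, seed = NULL)
  cfg_m <- sim_config(n_individuals = 6000, beta_burden_healthspan = 0,
                      beta_sex_healthspan = 0, seed = NULL)
  set.seed(42)
  df <- morbidity_cohort(cfg_f); df$sex <- 0
  dm <- morbidity_cohort(cfg_m); dm$sex <- 1
  d <- rbind(df, dm)
  out <- fit_sex_stratified(d$time, d$event, cbind(burden = d$burden),
                            d$sex, model = "gompertz")
  bf <- out$fits$female$coefficients["burden"]
  bm <- out$fits$male$coefficients["burden"]
  expect_gt(bf, 0.05)
  expect_lt(abs(bm), 0.03)
  # identical strata give identical fits
  same <- fit_sex_stratified(rep(df$time, 2), rep(df$event, 2),
                             cbind(burden = rep(df$burden, 2)),
                             rep(c(0, 1), each = nrow(df)),
                             model = "gompertz")
  expect_equal(same$fits$female$coefficients,
               same$fits$male$coefficients, tolerance = 1e-6)
  # reporting schema mirrors the published per-sex layout
  expect_named(out$table, c("sex", "term", "coef", "ci_lower", "ci_upper",
                            "p", "n", "events"))
  expect_error(fit_sex_stratified(d$time, rep(0, nrow(d)),
                                  cbind(burden = d$burden), d$sex),
               "zero events")
})

test_that("Cox and Gompertz-PH agree under proportional hazards at scale", {
  cfg <- sim_config(n_individuals = 20000, beta_burden_healthspan = 0.046,
                    seed = NULL)
  set.seed(2718)
  d <- morbidity_cohort(cfg)
  gz <- fit_gompertz_ph(d$time, d$event,
                        cbind(burden = d$burden, sex = d$sex))
  cx <- fit_cox(d$time, d$event, cbind(burden = d$burden, sex = d$sex))
  joint_se <- sqrt(gz$se["burden"]^2 + cx$se["burden"]^2)
  expect_lt(abs(gz$coefficients["burden"] - cx$coefficients["burden"]),
            2 * joint_se)
})
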