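test_that("km_estimate equals the hand product-limit computation", {
  rec <- data.frame(time = 1:5, event = c(1, 1, 0, 1, 0))
  km <- km_estimate(rec)
  oracle <- oracle_km(rec$time, rec$event)
  est_at <- function(t) km$survfn(t)
  expect_equal(vapply(oracle$time, est_at, 0), oracle$surv,
               tolerance = 1e-12)
  expect_equal(oracle$surv, c(0.8, 0.6, 0.3), tolerance = 1e-12)
  expect_equal(est_at(3), 0.6)   # censoring does not drop the curve
  expect_equal(est_at(0), 1)

  # no events: S(t) identically 1
  km0 <- km_estimate(data.frame(time = c(2, 5, 7), event = 0))
  expect_true(all(km0$surv == 1))

  # duplicating every record leaves the curve unchanged
  km2 <- km_estimate(rbind(rec, rec))
  expect_equal(vapply(oracle$time, km2$survfn, 0), oracle$surv,
               tolerance = 1e-12)

  expect_error(km_estimate(data.frame(time = c(-1, 2), event = c(1, 0))),
               "negative")
  expect_error(km_estimate(data.frame(time = 1:2, event = c(1, 2))), "0/1")
})

test_that("logrank_test matches brute-force hypergeometric accumulation", {
  # 6-subject two-group toy, no ties
  time <- c(1, 3, 4, 2, 6, 8)
  event <- c(1, 1, 0, 1, 1, 1)
  group <- rep(c("a", "b"), each = 3)
  lt <- logrank_test(data.frame(time = time, event = event, group = group))
  oracle <- oracle_logrank2(time, event, group)
  expect_equal(lt$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(lt$p, oracle$p, tolerance = 1e-10)

  # a second randomized toy, with ties
  set.seed(14)
  time2 <- sample(1:5, 12, replace = TRUE)
  event2 <- rbinom(12, 1, 0.7)
  group2 <- rep(c("a", "b"), 6)
  lt2 <- logrank_test(data.frame(time = time2, event = event2,
                                 group = group2))
  o2 <- oracle_logrank2(time2, event2, group2)
  expect_equal(lt2$statistic, o2$statistic, tolerance = 1e-10)

  # identical groups: statistic 0, p 1
  same <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(c(1, 1, 0), 2),
                     group = rep(c("a", "b"), each = 3))
  lt0 <- logrank_test(same)
  expect_equal(lt0$statistic, 0, tolerance = 1e-12)
  expect_equal(lt0$p, 1, tolerance = 1e-12)

  expect_error(
    logrank_test(data.frame(time = 1:4, event = 0,
                            group = rep(c("a", "b"), 2))),
    "zero events")
  mixed <- data.frame(time = 1:4, event = 1, group = rep(c("a", "b"), 2),
                      endpoint = c("OS", "OS", "RFS", "RFS"))
  expect_error(logrank_test(mixed), "mix endpoints")
})

test_that("log-rank is invariant to strictly increasing time transforms", {
  set.seed(2)
  d <- data.frame(time = rexp(30), event = rbinom(30, 1, 0.8),
                  group = rep(c("a", "b"), 15))
  a <- logrank_test(d)
  d2 <- d; d2$time <- log1p(d$time) * 3
  b <- logrank_test(d2)
  expect_equal(a$statistic, b$statistic, tolerance = 1e-12)
})

test_that("cox_fit matches a brute-force partial-likelihood grid search", {
  # binary covariate, 6 subjects, no ties
  rec <- data.frame(time = c(1.1, 2.3, 3.7, 4.2, 5.9, 7.4),
                    event = c(1, 1, 1, 1, 1, 0))
  x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(rec, data.frame(x = x))
  beta_oracle <- oracle_cox_beta(rec$time, rec$event, x)
  expect_equal(fit$coef, beta_oracle, tolerance = 1e-4)
  expect_equal(fit$hr, exp(beta_oracle), tolerance = 1e-3)
  expect_true(fit$ci_low <= fit$hr && fit$hr <= fit$ci_high)
  expect_identical(attr(fit, "ties"), "efron")
})

test_that("cox_fit: centering invariance, scaling equivariance, errors", {
  set.seed(8)
  rec <- data.frame(time = rexp(80), event = rbinom(80, 1, 0.8))
  x <- rnorm(80)
  f1 <- cox_fit(rec, data.frame(x = x))
  f2 <- cox_fit(rec, data.frame(x = x - mean(x) + 5))
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
  f3 <- cox_fit(rec, data.frame(x = 2 * x))
  expect_equal(f3$coef, f1$coef / 2, tolerance = 1e-8)

  expect_error(cox_fit(rec, data.frame(x = rep(1, 80))), "constant")
  # categorical covariate expands against a reference level
  g <- factor(sample(c("lo", "mid", "hi"), 80, replace = TRUE),
              levels = c("lo", "mid", "hi"))
  fc <- cox_fit(rec, data.frame(g = g))
  expect_equal(nrow(fc), 2L)
  expect_true(all(grepl("^g", fc$term)))
})

test_that("two-group log-rank agrees with the Cox score test on untied data", {
  set.seed(21)
  d <- data.frame(time = rexp(60), event = rbinom(60, 1, 0.9),
                  group = rep(c(0, 1), 30))
  lr <- logrank_test(data.frame(time = d$time, event = d$event,
                                group = d$group))
  sc <- survival::coxph(survival::Surv(time, event) ~ group, data = d)
  p_score <- pchisq(sc$score, 1, lower.tail = FALSE)
  expect_equal(lr$p, p_score, tolerance = 1e-6)
})

test_that("five_year_survival_test classifies and tests as specified", {
  # all event-free with follow-up >= 5
  a <- data.frame(time = rep(6, 10), event = 0)
  b <- data.frame(time = rep(7, 8), event = 0)
  r0 <- five_year_survival_test(a, b)
  expect_equal(unname(r0$proportions), c(1, 1))
  expect_equal(r0$p, 1)

  # counts [[40,10],[20,30]] -> chi-square ~ 16.67
  ga <- data.frame(time = c(rep(6, 40), rep(2, 10)),
                   event = c(rep(0, 40), rep(1, 10)))
  gb <- data.frame(time = c(rep(6, 20), rep(2, 30)),
                   event = c(rep(0, 20), rep(1, 30)))
  r1 <- five_year_survival_test(ga, gb)
  expect_equal(unname(r1$counts), matrix(c(40, 20, 10, 30), 2),
               tolerance = 0)
  expect_equal(r1$statistic, 50 / 3, tolerance = 1e-10)
  expect_lt(r1$p, 0.001)

  # censored before 5: excluded and counted
  gc <- data.frame(time = c(rep(6, 5), rep(3, 10)),
                   event = 0)
  r2 <- five_year_survival_test(gc, ga)
  expect_equal(unname(r2$excluded["A"]), 10)

  expect_error(
    five_year_survival_test(data.frame(time = 2, event = 0), ga),
    "zero classifiable")
})

test_that("stratified_treatment_analysis drops sub-floor rows with a note", {
  set.seed(6)
  n <- 40
  coh <- data.frame(sample_id = paste0("s", 1:n), time = rexp(n),
                    event = rbinom(n, 1, 0.8),
                    treated = c(rep(0, 30), rep(1, 10)))
  st <- setNames(factor(rep(c("low", "high"), each = n / 2),
                        levels = c("low", "high")), coh$sample_id)
  # high & treated cell nearly empty; every subcohort is < 30 except none
  expect_error(stratified_treatment_analysis(coh, st, min_n = 50),
               "floor")
  res <- stratified_treatment_analysis(coh, st, min_n = 10)
  expect_true(all(c("hr", "ci_low", "ci_high", "p_wald", "p_logrank") %in%
                  names(res)))
  expect_true(nrow(res) >= 1)
  dropped <- attr(res, "dropped")
  expect_true(is.character(dropped))
})

test_that("stratified analysis recovers a planted treatment interaction", {
  cfg <- sim_config(seed = 3, hazard_beta = 0.7, treat_beta = -0.9)
  set.seed(33)
  ces <- setNames(rnorm(600, 110, 4), paste0("p", 1:600))
  coh <- simulate_cohort(cfg, ces)
  st <- stratify(ces, "top_tertile_vs_rest")
  res <- stratified_treatment_analysis(coh, st)
  expect_equal(nrow(res), 4L)
  hi <- res[res$analysis == "treatment_within_high", ]
  lo <- res[res$analysis == "treatment_within_low", ]
  expect_lt(hi$hr, 1)
  expect_lt(hi$p_wald, 0.05)
  # no planted treatment effect in the low stratum
  expect_true(lo$ci_low <= 1 && 1 <= lo$ci_high)
})
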