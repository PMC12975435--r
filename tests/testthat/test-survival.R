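test_that("KM equals the empirical survival function on fully observed data", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$table$survival, c(2 / 3, 1 / 3, 0))
  set.seed(1)
  t2 <- sort(runif(40, 0, 10))
  km2 <- km_estimate(t2, rep(1, 40))
  emp <- vapply(km2$table$time, function(u) mean(t2 > u), numeric(1))
  expect_equal(km2$table$survival, emp)
})

test_that("fully censored data keep survival at one", {
  km <- km_estimate(c(2, 5, 9), c(0, 0, 0))
  expect_equal(nrow(km$table), 0)
  expect_true(all(km$fit$surv == 1))
})

test_that("KM matches hand product-limit bookkeeping under censoring", {
  times <- c(1, 2, 2, 3, 4, 5, 6, 6, 7)
  events <- c(1, 0, 1, 1, 0, 1, 0, 1, 0)
  km <- km_estimate(times, events)
  oracle <- oracle_km(times, events)
  expect_equal(km$table$time, oracle$time)
  expect_equal(km$table$survival, oracle$survival)
  expect_true(all(diff(km$table$survival) <= 0))
  expect_true(all(km$table$lower <= km$table$survival + 1e-12 &
                    km$table$survival <= km$table$upper + 1e-12))
})

test_that("log-rank is null on identical groups and symmetric in labels", {
  times <- rep(c(1, 3, 5, 7, 9), 2)
  events <- rep(c(1, 1, 0, 1, 0), 2)
  g <- rep(c("a", "b"), each = 5)
  lr <- logrank_test(times, events, g)
  expect_lt(lr$chisq, 1e-10)
  expect_gt(lr$p, 0.999)
  set.seed(2)
  t2 <- rexp(40); e2 <- rbinom(40, 1, 0.7); g2 <- rep(0:1, 20)
  expect_equal(logrank_test(t2, e2, g2)$chisq,
               logrank_test(t2, e2, 1 - g2)$chisq)
})

test_that("log-rank detects a rate ratio of 4 almost always", {
  sig <- vapply(1:10, function(s) {
    set.seed(s)
    t1 <- rexp(50, 1); t2 <- rexp(50, 4)
    logrank_test(c(t1, t2), rep(1, 100), rep(0:1, each = 50))$p < 0.01
  }, logical(1))
  expect_gte(mean(sig), 0.9)
})

test_that("log-rank chi-square p agrees with a permutation p on small samples", {
  set.seed(7)
  n <- 30
  g <- rep(0:1, each = n / 2)
  times <- rexp(n, ifelse(g == 1, 1.8, 1))
  events <- rep(1, n)
  p_chi <- logrank_test(times, events, g)$p
  B <- 4000
  obs <- logrank_test(times, events, g)$chisq
  perm <- vapply(1:B, function(b) {
    logrank_test(times, events, sample(g))$chisq
  }, numeric(1))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(p_chi - p_perm), 0.05)
})

test_that("Cox coefficients match brute-force partial-likelihood maximization", {
  set.seed(3)
  for (rep_i in 1:3) {
    n <- 25
    x <- rbinom(n, 1, 0.5)
    times <- rexp(n, exp(0.8 * x))
    times <- times + seq_len(n) * 1e-6  # break ties so Efron = Breslow = exact
    events <- rbinom(n, 1, 0.8)
    if (length(unique(x)) < 2 || sum(events) < 3) next
    fit <- cox_fit(data.frame(x = x), times, events)
    oracle <- oracle_cox_coef(x, times, events)
    expect_lt(abs(fit$table$coef - oracle), 1e-6)
    expect_equal(fit$table$hr, exp(fit$table$coef))
    expect_lte(fit$table$lower, fit$table$hr)
    expect_gte(fit$table$upper, fit$table$hr)
  }
})

test_that("rescaling a covariate rescales the coefficient inversely", {
  set.seed(4)
  n <- 60
  x <- rnorm(n)
  times <- rexp(n, exp(0.5 * x)) + seq_len(n) * 1e-8
  events <- rep(1, n)
  f1 <- cox_fit(data.frame(x = x), times, events)
  f2 <- cox_fit(data.frame(x = 10 * x), times, events)
  expect_equal(f2$table$coef, f1$table$coef / 10, tolerance = 1e-6)
})

test_that("a simulated hazard ratio of 2.7 is recovered within 15% on average", {
  hrs <- vapply(1:50, function(s) {
    set.seed(s)
    n <- 95
    x <- rbinom(n, 1, 0.5)
    t_event <- rexp(n, 0.05 * 2.7^x)
    cens <- runif(n, 5, 40)
    times <- pmin(t_event, cens)
    events <- as.integer(t_event <= cens)
    cox_fit(data.frame(x = x), times, events)$table$hr
  }, numeric(1))
  expect_lt(abs(mean(hrs) - 2.7) / 2.7, 0.15)
})

test_that("the p < 0.20 univariable screen gates the multivariable model", {
  set.seed(5)
  n <- 120
  noise <- rbinom(n, 1, 0.5)
  times0 <- rexp(n, 0.1)
  scr0 <- multivariable_screen(data.frame(noise = noise), times0, rep(1, n))
  if (scr0$univariable$p[1] >= 0.20) expect_null(scr0$multivariable)
  # two independent strong covariates both enter and keep their sign
  a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5)
  times <- rexp(n, 0.05 * exp(1.0 * a + 1.0 * b))
  scr <- multivariable_screen(data.frame(a = a, b = b), times, rep(1, n))
  expect_setequal(scr$entered, c("a", "b"))
  expect_true(all(scr$multivariable$table$coef > 0))
  # the screening decision is reproducible from the univariable p-values
  expect_identical(scr$entered,
                   scr$univariable$covariate[scr$univariable$p < 0.20])
})

test_that("constant covariates are rejected", {
  expect_error(cox_fit(data.frame(x = rep(1, 10)), rexp(10), rep(1, 10)),
               "constant")
})

test_that("stratified survival reports KM, log-rank and Cox per endpoint", {
  dat <- generate_cohort(cohort_spec(seed = 41))
  out <- dat$outcomes[dat$outcomes$batch == "center1", ]
  # grouping by 1-year status nearly separates the PFS times, so the Cox
  # stage may warn about a monotone likelihood; the estimate stays bounded
  ss <- suppressWarnings(
    stratified_survival(out$pfs_time, out$pfs_event, out$status_1y))
  expect_true(is.finite(ss$cox$table$hr))
  expect_s3_class(ss$km_positive, "km_curve")
  expect_s3_class(ss$cox, "cox_fit")
  expect_true(ss$logrank$p >= 0 && ss$logrank$p <= 1)
  # 1-year progressors must have worse PFS by construction
  expect_gt(ss$cox$table$hr, 1)
})
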