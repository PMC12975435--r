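sep_gaussians <- function(n, seed, gap = 3) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- cbind(f1 = rnorm(n) + gap * y, f2 = rnorm(n))
  list(x = x, y = y)
}

test_that("the development split is stratified, sized and deterministic", {
  status <- rep(c(1L, 0L), c(48, 47))
  sp <- split_development(status, 0.6, seed = 2)
  expect_length(sp$train, 57)
  expect_length(sp$validation, 38)
  expect_identical(sp, split_development(status, 0.6, seed = 2))
  f_all <- mean(status)
  expect_lte(abs(sum(status[sp$train]) - f_all * 57), 1)
  expect_lte(abs(sum(status[sp$validation]) - f_all * 38), 1)
  expect_error(split_development(c(rep(0L, 20), 1L)), "fewer than 2")
})

test_that("MLP softmax probabilities normalize and training is seeded", {
  d <- sep_gaussians(60, 1)
  m <- train_mlp(d$x, d$y, mlp_hyperparams(seed = 3))
  raw <- predict(m$net, sweep(sweep(d$x, 2, m$center), 2, m$scale, "/"))
  expect_lt(max(abs(rowSums(raw) - 1)), 1e-12)
  m2 <- train_mlp(d$x, d$y, mlp_hyperparams(seed = 3))
  expect_identical(predict(m, d$x), predict(m2, d$x))
})

test_that("a 4-unit MLP separates the XOR pattern", {
  set.seed(8)
  base <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  x <- base[rep(1:4, each = 10), ] + matrix(rnorm(80, 0, 0.03), 40, 2)
  colnames(x) <- c("a", "b")
  y <- as.integer(xor(base[rep(1:4, each = 10), 1] > 0.5,
                      base[rep(1:4, each = 10), 2] > 0.5))
  m <- train_mlp(x, y, mlp_hyperparams(hidden = 4, restarts = 5,
                                       max_epochs = 1000, seed = 4))
  expect_equal(mean((predict(m, x) > 0.5) == y), 1.0)
})

test_that("well-separated Gaussians give near-perfect validation AUC", {
  tr <- sep_gaussians(80, 11)
  va <- sep_gaussians(60, 12)
  m <- train_mlp(tr$x, tr$y, mlp_hyperparams(seed = 5))
  expect_gt(auc_mw(predict(m, va$x), va$y), 0.95)
})

test_that("cross-validation partitions correctly and ranks are deterministic", {
  d <- sep_gaussians(100, 21, gap = 4)
  cv <- cross_validate(d$x, d$y, mlp_hyperparams(seed = 6), k = 10, seed = 9)
  sizes <- table(cv$folds)
  expect_lte(max(sizes) - min(sizes), 1)
  expect_true(all(!is.na(cv$oof_prob)))   # each patient out-of-fold once
  expect_gt(cv$auc, 0.95)
  cv2 <- cross_validate(d$x, d$y, mlp_hyperparams(seed = 6), k = 10, seed = 9)
  expect_identical(cv$mean_rank, cv2$mean_rank)
  expect_identical(cv$oof_prob, cv2$oof_prob)
})

test_that("permutation importance ranks a pure-noise feature last", {
  last <- vapply(1:10, function(s) {
    set.seed(s * 13)
    y <- rep(c(0L, 1L), 30)
    x <- cbind(signal = rnorm(60) + 2.5 * y, noise = rnorm(60))
    m <- train_mlp(x, y, mlp_hyperparams(seed = s))
    fi <- feature_importance(m, x, y, seed = s)
    unname(fi$rank["noise"]) == 2L
  }, logical(1))
  expect_gte(mean(last), 0.9)
})

test_that("backward elimination keeps planted signal and is deterministic", {
  seq1 <- NULL
  hits <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    n <- 60
    y <- rep(c(0L, 1L), n / 2)
    x <- cbind(s1 = rnorm(n) + 1.4 * y, s2 = rnorm(n) + 1.4 * y,
               s3 = rnorm(n) + 1.4 * y, n1 = rnorm(n), n2 = rnorm(n),
               n3 = rnorm(n))
    va <- 1:20; tr <- 21:n
    be <- backward_eliminate(x[tr, ], y[tr], x[va, ], y[va],
                             mlp_hyperparams(seed = s), k = 5, seed = s)
    sizes <- vapply(be$steps, function(st) length(st$features), integer(1))
    step3 <- be$steps[[which(sizes == 3)]]
    if (s == 1) seq1 <<- vapply(be$steps, function(st)
      paste(sort(st$features), collapse = ","), character(1))
    all(c("s1", "s2", "s3") %in% step3$features)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  # determinism of the elimination order
  set.seed(1001)
  n <- 60
  y <- rep(c(0L, 1L), n / 2)
  x <- cbind(s1 = rnorm(n) + 1.4 * y, s2 = rnorm(n) + 1.4 * y,
             s3 = rnorm(n) + 1.4 * y, n1 = rnorm(n), n2 = rnorm(n),
             n3 = rnorm(n))
  be_a <- backward_eliminate(x[21:n, ], y[21:n], x[1:20, ], y[1:20],
                             mlp_hyperparams(seed = 1), k = 5, seed = 1)
  be_b <- backward_eliminate(x[21:n, ], y[21:n], x[1:20, ], y[1:20],
                             mlp_hyperparams(seed = 1), k = 5, seed = 1)
  expect_identical(
    lapply(be_a$steps, `[[`, "features"),
    lapply(be_b$steps, `[[`, "features"))
  # single-feature start gives a length-1 sequence
  be1 <- backward_eliminate(x[21:n, "s1", drop = FALSE], y[21:n],
                            x[1:20, "s1", drop = FALSE], y[1:20],
                            mlp_hyperparams(seed = 1), k = 5, seed = 1)
  expect_length(be1$steps, 1)
})

test_that("efficiency follows the prevalence-weighted formula", {
  expect_equal(efficiency(1, 1, 0.3), 1)
  expect_equal(efficiency(0.938, 0.319, 0.484), 0.618596)
  expect_error(efficiency(1.2, 0.5, 0.5), "\\[0, 1\\]")
  set.seed(2)
  for (i in 1:25) {
    se <- runif(1); sp <- runif(1); p <- runif(1)
    e <- efficiency(se, sp, p)
    expect_gte(e, min(se, sp) - 1e-12)
    expect_lte(e, max(se, sp) + 1e-12)
  }
})

test_that("threshold selection maximizes EFF on the grid, smallest tie first", {
  out <- select_threshold(c(0.2, 0.8), c(0, 1))
  expect_equal(out$eff, 1)
  expect_equal(out$threshold, 0.2)  # smallest grid point reaching EFF = 1
  # uninformative classifier: max EFF ~ max(P, 1 - P)
  set.seed(10)
  n <- 4000
  y <- rbinom(n, 1, 0.3)
  p <- runif(n)
  out2 <- select_threshold(p, y)
  expect_lt(abs(out2$eff - 0.7), 0.03)
})

test_that("evaluate reproduces confusion counts, AUC identities and Bayes identities", {
  # probabilities realizing TP=22 FN=1 FP=26 TN=10 at threshold 0.55
  prob <- c(rep(0.9, 22), rep(0.1, 1), rep(0.9, 26), rep(0.1, 10))
  labels <- c(rep(1, 23), rep(0, 36))
  r <- evaluate(prob, labels, 0.55)
  expect_equal(c(r$tp, r$fn, r$fp, r$tn), c(22, 1, 26, 10))
  expect_equal(round(100 * r$sensitivity, 1), 95.7)
  expect_equal(round(100 * r$specificity, 1), 27.8)
  expect_equal(round(100 * r$ppv, 1), 45.8)
  expect_equal(round(100 * r$npv, 1), 90.9)
  # Bayes identities from Se/Sp/prevalence
  pr <- r$prevalence
  expect_equal(r$ppv, pr * r$sensitivity /
                 (pr * r$sensitivity + (1 - pr) * (1 - r$specificity)))
  expect_equal(r$npv, (1 - pr) * r$specificity /
                 ((1 - pr) * r$specificity + pr * (1 - r$sensitivity)))
  # AUC identities
  expect_equal(evaluate(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5)$auc, 1)
  set.seed(3)
  p2 <- runif(40); y2 <- rbinom(40, 1, 0.5)
  expect_equal(auc_mw(p2, y2), 1 - auc_mw(p2, 1 - y2))
  # pair-enumeration oracle
  pos <- p2[y2 == 1]; neg <- p2[y2 == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(auc_mw(p2, y2), mean(pairs))
})

test_that("melrad_fit returns a working classifier with S3 methods", {
  dat <- generate_cohort(cohort_spec(seed = 31))
  c1 <- dat$features$batch == "center1"
  sel <- select_features(dat$features[c1, ], dat$outcomes$status_1y[c1])
  fit <- melrad_fit(dat$features[c1, sel$step2, drop = FALSE],
                    dat$outcomes$status_1y[c1], seed = 31)
  expect_s3_class(fit, "melrad")
  expect_true(fit$threshold >= 0 && fit$threshold <= 1)
  p_test <- predict(fit, dat$features[!c1, fit$features, drop = FALSE])
  expect_true(all(p_test >= 0 & p_test <= 1))
  cls <- predict(fit, dat$features[!c1, fit$features, drop = FALSE],
                 type = "class")
  expect_identical(cls, as.integer(p_test > fit$threshold))
  expect_output(print(fit), "MEL-RAD")
  expect_output(summary(fit), "elimination trace")
  # refitting with the same seed is bit-identical in its predictions
  fit2 <- melrad_fit(dat$features[c1, sel$step2, drop = FALSE],
                     dat$outcomes$status_1y[c1], seed = 31)
  expect_identical(p_test,
                   predict(fit2, dat$features[!c1, fit$features, drop = FALSE]))
})
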