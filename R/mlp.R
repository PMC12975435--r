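#' Multilayer-perceptron hyperparameters
#'
#' One hidden layer, softmax output over the two classes, weights
#' initialized uniformly on `[-offset, +offset]` around 0. The hidden-layer
#' width is configurable (default 4, sized for the small 3-feature final
#' models). `lambda` is the regularization constant (used as the weight
#' decay of the optimizer); training restarts keep the best of several
#' seeded initializations to smooth out local optima.
#'
#' @param hidden hidden units (>= 1).
#' @param offset weight-initialization half-range (> 0).
#' @param lambda regularization constant (>= 0), default 5e-7.
#' @param max_epochs optimizer iteration cap.
#' @param restarts random restarts per fit (>= 1).
#' @param seed integer seed.
#' @return list of class `mlp_hyperparams`.
#' @export
mlp_hyperparams <- function(hidden = 4L, offset = 0.5, lambda = 5e-7,
                            max_epochs = 500L, restarts = 3L, seed = 1L) {
  stop_if_not(hidden >= 1, "need at least one hidden unit")
  stop_if_not(offset > 0, "offset must be > 0")
  stop_if_not(lambda >= 0, "lambda must be >= 0")
  structure(list(hidden = as.integer(hidden), offset = offset,
                 lambda = lambda, max_epochs = as.integer(max_epochs),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "mlp_hyperparams")
}

#' Train a single-hidden-layer softmax MLP
#'
#' Standardizes the features to the training mean/SD, then fits a
#' two-output softmax network (via \pkg{nnet}) minimizing cross-entropy,
#' keeping the best of `hp$restarts` seeded initializations. Deterministic
#' under `hp$seed`.
#'
#' @param x numeric matrix (rows = patients), >= 2 examples per class.
#' @param y binary 0/1 labels.
#' @param hp a [mlp_hyperparams()].
#' @return object of class `melrad_mlp`.
#' @export
train_mlp <- function(x, y, hp = mlp_hyperparams()) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stop_if_not(sum(y == 1L) >= 2 && sum(y == 0L) >= 2,
              "need >= 2 examples per class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  targets <- cbind(neg = 1 - y, pos = y)
  best <- NULL
  for (r in seq_len(hp$restarts)) {
    fit <- with_seed(hp$seed + 1000L * (r - 1L),
                     nnet::nnet(xs, targets, size = hp$hidden,
                                softmax = TRUE, rang = hp$offset,
                                decay = hp$lambda, maxit = hp$max_epochs,
                                trace = FALSE))
    if (!is.finite(fit$value))
      stop("MLP training produced a non-finite loss", call. = FALSE)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(list(net = best, center = ctr, scale = scl,
                 features = colnames(x), hp = hp),
            class = "melrad_mlp")
}

#' @export
predict.melrad_mlp <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (!is.null(object$features)) {
    stop_if_not(all(object$features %in% colnames(x)),
                "newdata is missing model features")
    x <- x[, object$features, drop = FALSE]
  }
  xs <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  p <- stats::predict(object$net, xs)
  as.numeric(p[, "pos"])
}

# stratified fold assignment, deterministic under seed; per-class
# remainders go to the currently smallest folds so overall fold sizes
# differ by at most one
stratified_folds <- function(y, k, seed) {
  y <- as.integer(y)
  folds <- integer(length(y))
  with_seed(seed, {
    totals <- integer(k)
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      n_c <- length(idx)
      sizes <- rep(n_c %/% k, k)
      rem <- n_c %% k
      if (rem > 0) {
        ord <- order(totals, stats::runif(k))
        sizes[ord[seq_len(rem)]] <- sizes[ord[seq_len(rem)]] + 1L
      }
      folds[idx] <- rep(seq_len(k), times = sizes)
      totals <- totals + sizes
    }
  })
  folds
}

log_loss <- function(prob, y) {
  eps <- 1e-12
  p <- pmin(pmax(prob, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Permutation feature importance
#'
#' Mean increase in log-loss over `n_shuffles` random permutations of each
#' feature column, evaluated on held-out data, converted to ranks
#' (1 = most important). Ties in the raw importances are broken
#' lexicographically by feature name.
#'
#' @param model a `melrad_mlp`.
#' @param x,y evaluation data (ideally out-of-fold).
#' @param n_shuffles permutations per feature (default 20).
#' @param seed integer seed.
#' @return list with `importance` (named raw values) and `rank` (named).
#' @export
feature_importance <- function(model, x, y, n_shuffles = 20L, seed = 1L) {
  x <- as.matrix(x)[, model$features, drop = FALSE]
  y <- as.integer(y)
  base <- log_loss(predict(model, x), y)
  imp <- with_seed(seed, {
    vapply(model$features, function(f) {
      inc <- numeric(n_shuffles)
      for (s in seq_len(n_shuffles)) {
        xp <- x
        xp[, f] <- xp[sample(nrow(xp)), f]
        inc[s] <- log_loss(predict(model, xp), y) - base
      }
      mean(inc)
    }, numeric(1))
  })
  ord <- order(-imp, names(imp))
  rk <- integer(length(imp))
  rk[ord] <- seq_along(imp)
  names(rk) <- names(imp)
  list(importance = imp, rank = rk)
}

#' Stratified k-fold cross-validation of the MLP
#'
#' Trains one model per fold, records each patient's out-of-fold predicted
#' probability, and averages per-feature permutation-importance ranks over
#' folds.
#'
#' @param x feature matrix; @param y binary labels; @param hp
#'   [mlp_hyperparams()]; @param k folds (default 10); @param seed seed for
#'   fold assignment and importance shuffles.
#' @return list of class `cv_ensemble`: `models`, `folds`, `oof_prob`,
#'   `mean_rank` (named), `features`, `auc` (out-of-fold).
#' @export
cross_validate <- function(x, y, hp = mlp_hyperparams(), k = 10L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stop_if_not(nrow(x) >= k, "need at least k patients")
  folds <- stratified_folds(y, k, seed)
  for (f in seq_len(k))
    if (length(unique(y[folds != f])) < 2)
      stop("a training fold contains a single class; reduce k", call. = FALSE)
  oof <- rep(NA_real_, length(y))
  models <- vector("list", k)
  ranks <- matrix(0, nrow = k, ncol = ncol(x),
                  dimnames = list(NULL, colnames(x)))
  for (f in seq_len(k)) {
    tr <- folds != f
    hp_f <- hp
    hp_f$seed <- hp$seed + f
    m <- train_mlp(x[tr, , drop = FALSE], y[tr], hp_f)
    models[[f]] <- m
    oof[!tr] <- predict(m, x[!tr, , drop = FALSE])
    fi <- feature_importance(m, x[!tr, , drop = FALSE], y[!tr],
                             seed = seed + 100L * f)
    ranks[f, ] <- fi$rank[colnames(x)]
  }
  structure(list(models = models, folds = folds, oof_prob = oof,
                 mean_rank = colMeans(ranks), features = colnames(x),
                 auc = if (length(unique(y)) == 2) auc_mw(oof, y) else NA),
            class = "cv_ensemble")
}

#' @export
print.cv_ensemble <- function(x, ...) {
  cat(sprintf("%d-fold CV ensemble on %d feature(s); out-of-fold AUC %.3f\n",
              length(x$models), length(x$features), x$auc))
  invisible(x)
}
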