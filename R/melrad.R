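#' Stratified development split
#'
#' Randomly divides the development cohort into training and validation
#' parts (default 60%/40%), stratified on the 1-year status so the event
#' fraction of each part is within one patient of the overall fraction.
#'
#' @param status binary 0/1 vector; each stratum needs >= 2 members.
#' @param ratio training fraction (default 0.6).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `validation`.
#' @export
split_development <- function(status, ratio = 0.6, seed = 1L) {
  status <- as.integer(status)
  stop_if_not(length(status) >= 10, "need at least 10 patients")
  stop_if_not(ratio > 0 && ratio < 1, "ratio must be in (0, 1)")
  for (cl in c(0L, 1L))
    stop_if_not(sum(status == cl) >= 2,
                sprintf("stratum %d has fewer than 2 members", cl))
  train <- integer(0)
  with_seed(seed, {
    for (cl in c(0L, 1L)) {
      idx <- which(status == cl)
      n_tr <- round(ratio * length(idx))
      train <- c(train, sample(idx, n_tr))
    }
  })
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(status), train))
}

#' Importance-ranked backward elimination with EFF threshold selection
#'
#' Starting from the initial feature set: run stratified k-fold CV on the
#' training data, average permutation-importance ranks over folds, train a
#' model on the whole training split, pick the EFF-maximizing threshold on
#' the validation split, then drop the feature with the worst mean rank and
#' repeat until one feature remains. The returned selection is the set size
#' (and its threshold) with the highest validation EFF; ties go to the
#' smaller feature set.
#'
#' @param x_train,y_train training-split data (matrix with named columns).
#' @param x_val,y_val validation-split data for EFF-based selection.
#' @param hp [mlp_hyperparams()]; @param k CV folds; @param seed seed.
#' @return list of class `backward_elimination`: `steps` (one entry per set
#'   size with `features`, `cv` ensemble, `model`, `threshold`, `eff`,
#'   `val_report`), `best` (index into steps), `selected_features`,
#'   `threshold`.
#' @export
backward_eliminate <- function(x_train, y_train, x_val, y_val,
                               hp = mlp_hyperparams(), k = 10L, seed = 1L) {
  x_train <- as.matrix(x_train)
  x_val <- as.matrix(x_val)
  feats <- colnames(x_train)
  stop_if_not(length(feats) >= 1, "initial feature set is empty")
  steps <- list()
  current <- feats
  step_i <- 0L
  while (length(current) >= 1) {
    step_i <- step_i + 1L
    xs <- x_train[, current, drop = FALSE]
    cv <- cross_validate(xs, y_train, hp, k = k, seed = seed + step_i)
    hp_m <- hp
    hp_m$seed <- hp$seed + 7000L + step_i
    model <- train_mlp(xs, y_train, hp_m)
    val_prob <- predict(model, x_val[, current, drop = FALSE])
    thr <- select_threshold(val_prob, y_val)
    steps[[step_i]] <- list(features = current, cv = cv, model = model,
                            threshold = thr$threshold, eff = thr$eff,
                            val_report = thr$report)
    if (length(current) == 1) break
    worst <- names(which.max(cv$mean_rank))  # ties: first name in column order
    current <- setdiff(current, worst)
  }
  effs <- vapply(steps, `[[`, numeric(1), "eff")
  sizes <- vapply(steps, function(s) length(s$features), integer(1))
  best <- which(effs == max(effs))
  best <- best[which.min(sizes[best])]
  structure(list(steps = steps, best = best,
                 selected_features = steps[[best]]$features,
                 threshold = steps[[best]]$threshold),
            class = "backward_elimination")
}

#' Fit the MEL-RAD radiomic classifier
#'
#' The full model-building procedure on a development cohort: stratified
#' 60/40 training/validation split; stratified 10-fold cross-validated MLP
#' with permutation-importance ranking; backward elimination of the least
#' important feature; selection of the feature-set size and probability
#' threshold maximizing the prevalence-weighted efficiency (EFF) on the
#' validation split; and a final MLP refit on the training split with the
#' selected features.
#'
#' @param features data.frame or matrix of candidate features (patients x
#'   features; `patient_id`/`batch` columns ignored). Typically the output
#'   of [select_features()] applied to harmonized features.
#' @param status binary 0/1 one-year progression status.
#' @param hp [mlp_hyperparams()].
#' @param split_ratio training fraction of the development cohort.
#' @param k CV folds.
#' @param seed integer seed driving the split, folds and restarts.
#' @return object of class `melrad`: the final `model`, `features`
#'   (selected identifiers), `threshold`, `elimination` trace, `split`,
#'   `val_report` (validation performance at the selected threshold),
#'   `val_auc`, `cv_auc` (out-of-fold AUC of the selected set).
#' @export
melrad_fit <- function(features, status, hp = mlp_hyperparams(),
                       split_ratio = 0.6, k = 10L, seed = 1L) {
  x <- if (is.data.frame(features))
    as.matrix(features[, setdiff(names(features), c("patient_id", "batch")),
                       drop = FALSE])
  else as.matrix(features)
  stop_if_not(!is.null(colnames(x)), "features must have column names")
  status <- as.integer(status)
  split <- split_development(status, split_ratio, seed)
  elim <- backward_eliminate(x[split$train, , drop = FALSE],
                             status[split$train],
                             x[split$validation, , drop = FALSE],
                             status[split$validation],
                             hp = hp, k = k, seed = seed)
  best <- elim$steps[[elim$best]]
  structure(list(model = best$model, features = elim$selected_features,
                 threshold = elim$threshold, elimination = elim,
                 split = split, val_report = best$val_report,
                 val_auc = best$val_report$auc, cv_auc = best$cv$auc,
                 hp = hp, seed = seed, n = length(status),
                 prevalence = mean(status)),
            class = "melrad")
}

#' @export
predict.melrad <- function(object, newdata,
                           type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- if (is.data.frame(newdata))
    as.matrix(newdata[, setdiff(names(newdata), c("patient_id", "batch")),
                      drop = FALSE])
  else as.matrix(newdata)
  p <- predict(object$model, x)
  if (type == "prob") p else as.integer(p > object$threshold)
}

#' @export
print.melrad <- function(x, ...) {
  cat("MEL-RAD classifier\n")
  cat(sprintf("  features (%d): %s\n", length(x$features),
              paste(x$features, collapse = ", ")))
  cat(sprintf("  probability threshold: %.1f%%\n", 100 * x$threshold))
  cat(sprintf("  validation AUC %.3f, out-of-fold CV AUC %.3f\n",
              x$val_auc, x$cv_auc))
  invisible(x)
}

#' @export
summary.melrad <- function(object, ...) {
  cat("MEL-RAD classifier fit\n")
  cat(sprintf("  development cohort: n = %d, prevalence %.1f%%\n",
              object$n, 100 * object$prevalence))
  cat(sprintf("  split: %d training / %d validation\n",
              length(object$split$train), length(object$split$validation)))
  sizes <- vapply(object$elimination$steps,
                  function(s) length(s$features), integer(1))
  effs <- vapply(object$elimination$steps, `[[`, numeric(1), "eff")
  cat("  elimination trace (set size: validation EFF):\n")
  for (i in order(-sizes))
    cat(sprintf("    %d: %.3f%s\n", sizes[i], effs[i],
                if (i == object$elimination$best) "  <- selected" else ""))
  cat("  validation performance at the selected threshold:\n")
  print(object$val_report)
  invisible(object)
}

#' @export
plot.melrad <- function(x, newdata = NULL, labels = NULL, ...) {
  if (is.null(newdata) || is.null(labels))
    stop("plot.melrad needs `newdata` features and `labels` to draw a ROC curve",
         call. = FALSE)
  prob <- predict(x, newdata)
  labels <- as.integer(labels)
  ths <- sort(unique(c(0, prob, 1)), decreasing = TRUE)
  se <- vapply(ths, function(t) sum(prob > t & labels == 1) / sum(labels == 1),
               numeric(1))
  fpr <- vapply(ths, function(t) sum(prob > t & labels == 0) / sum(labels == 0),
                numeric(1))
  graphics::plot(fpr, se, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("MEL-RAD ROC (AUC %.2f)", auc_mw(prob, labels)),
                 ...)
  graphics::abline(0, 1, lty = 3)
  invisible(list(fpr = fpr, sensitivity = se))
}
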