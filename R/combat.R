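# Reference-batch location/scale harmonization with parametric
# empirical-Bayes shrinkage (the "a posteriori" ComBat variant: the
# reference centre defines the standardization and is itself left
# untouched).

ft_matrix <- function(table) {
  stop_if_not(is.data.frame(table) && "batch" %in% names(table),
              "feature table needs a `batch` column")
  meta_cols <- intersect(c("patient_id", "batch"), names(table))
  x <- as.matrix(table[, setdiff(names(table), meta_cols), drop = FALSE])
  stop_if_not(is.numeric(x) && !anyNA(x), "feature values must be numeric, no NAs")
  list(x = x, batch = as.character(table$batch),
       ids = table$patient_id %||% seq_len(nrow(x)))
}

# moment-matched inverse-gamma hyperparameters for the scale prior
ig_aprior <- function(d2) {
  m <- mean(d2); s2 <- stats::var(d2)
  if (!is.finite(s2) || s2 <= 0) return(2.001)
  (2 * s2 + m^2) / s2
}
ig_bprior <- function(d2) {
  m <- mean(d2); s2 <- stats::var(d2)
  if (!is.finite(s2) || s2 <= 0) return(m)
  (m * s2 + m^3) / s2
}

# iterative conditional means for (gamma*, delta2*) of one batch
eb_iterate <- function(z_b, g_hat, d2_hat, g_bar, tau2, a_pr, b_pr,
                       tol = 1e-6, max_iter = 100L) {
  n_b <- nrow(z_b)
  g_new <- g_hat
  d2_new <- d2_hat
  for (it in seq_len(max_iter)) {
    g_old <- g_new; d2_old <- d2_new
    g_new <- (n_b * tau2 * g_hat + d2_new * g_bar) / (n_b * tau2 + d2_new)
    sum2 <- colSums(sweep(z_b, 2, g_new)^2)
    d2_new <- (b_pr + 0.5 * sum2) / (n_b / 2 + a_pr - 1)
    chg <- max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
               abs(d2_new - d2_old) / (abs(d2_old) + 1e-12))
    if (chg < tol) break
  }
  list(gamma = g_new, delta2 = d2_new)
}

#' Fit a reference-batch ComBat harmonization model
#'
#' Standardizes every feature against the reference batch (its mean and SD),
#' estimates per-batch location (`gamma`) and scale (`delta^2`) on the
#' standardized scale, and shrinks them with the standard parametric
#' empirical-Bayes iteration (normal prior on gamma, inverse-gamma on
#' delta^2; `method = "ls"` skips the shrinkage). The reference batch is a
#' fixed point of the resulting transform. Features with zero variance in
#' the reference batch are flagged and passed through unharmonized, and are
#' excluded from the shrinkage pooling.
#'
#' @param table feature data.frame with `patient_id`, `batch` and feature
#'   columns; at least 2 patients per batch.
#' @param reference reference batch label (must occur in `table`).
#' @param method `"eb"` (default) or `"ls"` (plain location/scale).
#' @param tol,max_iter empirical-Bayes iteration controls.
#' @return object of class `combat_model`.
#' @export
combat_fit <- function(table, reference, method = c("eb", "ls"),
                       tol = 1e-6, max_iter = 100L) {
  method <- match.arg(method)
  ft <- ft_matrix(table)
  stop_if_not(reference %in% ft$batch, "reference batch not present")
  tb <- table(ft$batch)
  stop_if_not(all(tb >= 2), "every batch needs >= 2 patients")
  xr <- ft$x[ft$batch == reference, , drop = FALSE]
  ref_mean <- colMeans(xr)
  # population variance of the reference batch (standard ComBat convention)
  ref_var <- colMeans(sweep(xr, 2, ref_mean)^2)
  degenerate <- ref_var <= 0
  if (any(degenerate))
    warning(sum(degenerate),
            " feature(s) have zero variance in the reference batch; passed through unharmonized")
  ref_sd <- sqrt(ifelse(degenerate, 1, ref_var))
  z <- sweep(sweep(ft$x, 2, ref_mean), 2, ref_sd, "/")
  batches <- setdiff(unique(ft$batch), reference)
  par <- list()
  for (b in batches) {
    zb <- z[ft$batch == b, !degenerate, drop = FALSE]
    g_hat <- colMeans(zb)
    d2_hat <- apply(zb, 2, stats::var)
    d2_hat[d2_hat <= 0] <- 1e-8
    if (method == "eb" && ncol(zb) >= 2) {
      g_bar <- mean(g_hat)
      tau2 <- stats::var(g_hat)
      if (!is.finite(tau2) || tau2 <= 0) tau2 <- 1e-8
      sol <- eb_iterate(zb, g_hat, d2_hat, g_bar, tau2,
                        ig_aprior(d2_hat), ig_bprior(d2_hat), tol, max_iter)
    } else sol <- list(gamma = g_hat, delta2 = d2_hat)
    gamma <- numeric(ncol(ft$x)); delta2 <- rep(1, ncol(ft$x))
    gamma[!degenerate] <- sol$gamma
    delta2[!degenerate] <- sol$delta2
    par[[b]] <- list(gamma = gamma, delta2 = delta2)
  }
  structure(list(reference = reference, features = colnames(ft$x),
                 ref_mean = ref_mean, ref_sd = ref_sd,
                 degenerate = degenerate, batch_par = par, method = method),
            class = "combat_model")
}

#' Apply a fitted ComBat model to a feature table
#'
#' Reference-batch rows are returned bit-identical; rows from other batches
#' are adjusted to the reference location/scale using the stored parameters.
#'
#' @param model a [combat_fit()] model.
#' @param table feature data.frame whose feature columns match the model.
#' @return the harmonized feature table (same shape).
#' @export
combat_apply <- function(model, table) {
  stopifnot(inherits(model, "combat_model"))
  ft <- ft_matrix(table)
  stop_if_not(identical(colnames(ft$x), model$features),
              "feature columns do not match the fitted model")
  unknown <- setdiff(unique(ft$batch),
                     c(model$reference, names(model$batch_par)))
  if (length(unknown))
    stop("unknown batch label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- ft$x
  for (b in names(model$batch_par)) {
    rows <- ft$batch == b
    if (!any(rows)) next
    p <- model$batch_par[[b]]
    z <- sweep(sweep(ft$x[rows, , drop = FALSE], 2, model$ref_mean),
               2, model$ref_sd, "/")
    zadj <- sweep(sweep(z, 2, p$gamma), 2, sqrt(p$delta2), "/")
    xadj <- sweep(sweep(zadj, 2, model$ref_sd, "*"), 2, model$ref_mean, "+")
    keep <- model$degenerate
    if (any(keep)) xadj[, keep] <- ft$x[rows, keep]
    out[rows, ] <- xadj
  }
  res <- table
  res[, model$features] <- out
  res
}

#' Serialize / restore a ComBat model as JSON
#' @param model a `combat_model`; @param path file path.
#' @export
write_combat_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_combat_model
#' @export
read_combat_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$ref_mean <- stats::setNames(as.numeric(m$ref_mean), m$features)
  m$ref_sd <- stats::setNames(as.numeric(m$ref_sd), m$features)
  m$degenerate <- as.logical(m$degenerate)
  m$batch_par <- lapply(m$batch_par, function(p)
    list(gamma = as.numeric(p$gamma), delta2 = as.numeric(p$delta2)))
  structure(m, class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf("ComBat model (%s): reference '%s', %d feature(s), %d other batch(es)\n",
              x$method, x$reference, length(x$features), length(x$batch_par)))
  invisible(x)
}
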