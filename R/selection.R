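#' Mann-Whitney association screen (selection step 1)
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of every feature against
#' the binary 1-year progression status. Features with `p < alpha` are
#' retained; no multiplicity adjustment is applied at this exploratory
#' stage (redundancy is controlled downstream). Small samples (both groups
#' <= 20 and no ties) use the exact null distribution, larger ones the
#' normal approximation with tie and continuity correction. Constant
#' features get p = 1 and are never retained.
#'
#' @param features numeric matrix or data.frame (patients x features;
#'   non-feature columns `patient_id`/`batch` are ignored).
#' @param status binary 0/1 outcome vector, both groups non-empty.
#' @param alpha retention level (default 0.05).
#' @return list of class `selection_result`: `p_values` (named), `step1`
#'   (retained identifiers, ascending p), `alpha`.
#' @export
mann_whitney_screen <- function(features, status, alpha = 0.05) {
  x <- if (is.data.frame(features))
    as.matrix(features[, setdiff(names(features), c("patient_id", "batch")),
                       drop = FALSE])
  else as.matrix(features)
  status <- as.integer(status)
  stop_if_not(all(status %in% c(0L, 1L)), "status must be 0/1")
  stop_if_not(length(status) == nrow(x), "status length must match rows")
  stop_if_not(any(status == 0L) && any(status == 1L),
              "both outcome groups must be non-empty")
  g1 <- status == 1L
  n1 <- sum(g1); n0 <- sum(!g1)
  p <- vapply(seq_len(ncol(x)), function(j) {
    v <- x[, j]
    if (max(v) == min(v)) return(1)
    use_exact <- n1 <= 20 && n0 <= 20 && !any(duplicated(v))
    suppressWarnings(
      stats::wilcox.test(v[g1], v[!g1], exact = use_exact,
                         correct = !use_exact)$p.value)
  }, numeric(1))
  names(p) <- colnames(x)
  ord <- order(p, names(p))
  kept <- names(p)[ord][p[ord] < alpha]
  structure(list(p_values = p, step1 = kept, alpha = alpha,
                 step2 = NULL, decisions = NULL),
            class = "selection_result")
}

#' Spearman redundancy pruning (selection step 2)
#'
#' Greedy pass over the step-1 features in ascending-p order (ties broken
#' lexicographically by identifier): a feature is kept iff its absolute
#' Spearman correlation with every already-kept feature is <= `rho_max`.
#' Discarded pairs are logged.
#'
#' @param features the feature table used for the screen (development
#'   cohort only).
#' @param selection a `selection_result` from [mann_whitney_screen()].
#' @param rho_max correlation bound (default 0.7).
#' @return the `selection_result` with `step2` and a `decisions` data.frame
#'   (`feature`, `discarded_against`, `rho`).
#' @export
spearman_dedupe <- function(features, selection, rho_max = 0.7) {
  stopifnot(inherits(selection, "selection_result"))
  x <- if (is.data.frame(features))
    as.matrix(features[, setdiff(names(features), c("patient_id", "batch")),
                       drop = FALSE])
  else as.matrix(features)
  cand <- selection$step1
  if (length(cand) == 0) {
    selection$step2 <- character(0)
    selection$decisions <- data.frame(feature = character(0),
                                      discarded_against = character(0),
                                      rho = numeric(0))
    return(selection)
  }
  kept <- character(0)
  dec <- list()
  for (f in cand) {
    drop_against <- NA_character_
    rho_hit <- NA_real_
    for (k in kept) {
      rho <- stats::cor(x[, f], x[, k], method = "spearman")
      if (is.finite(rho) && abs(rho) > rho_max) {
        drop_against <- k; rho_hit <- rho; break
      }
    }
    if (is.na(drop_against)) kept <- c(kept, f)
    else dec[[length(dec) + 1L]] <- data.frame(feature = f,
                                               discarded_against = drop_against,
                                               rho = rho_hit)
  }
  selection$step2 <- kept
  selection$decisions <- if (length(dec)) do.call(rbind, dec)
  else data.frame(feature = character(0), discarded_against = character(0),
                  rho = numeric(0))
  selection$rho_max <- rho_max
  selection
}

#' Two-step feature selection
#'
#' Convenience wrapper: [mann_whitney_screen()] then [spearman_dedupe()].
#'
#' @inheritParams mann_whitney_screen
#' @inheritParams spearman_dedupe
#' @return a complete `selection_result`.
#' @export
select_features <- function(features, status, alpha = 0.05, rho_max = 0.7) {
  sel <- mann_whitney_screen(features, status, alpha)
  spearman_dedupe(features, sel, rho_max)
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Feature selection: %d tested, %d retained at p < %g",
              length(x$p_values), length(x$step1), x$alpha))
  if (!is.null(x$step2))
    cat(sprintf(", %d after |rho| <= %g pruning", length(x$step2),
                x$rho_max %||% 0.7))
  cat("\n")
  invisible(x)
}
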