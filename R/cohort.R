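#' Specify a synthetic two-centre radiomic cohort
#'
#' Emulates the statistical structure the analysis assumes: per-patient
#' feature vectors drawn as standard normals, a small set of planted
#' outcome-associated features (standardized mean shift between 1-year
#' progressors and non-progressors), centre-specific additive (`gamma`) and
#' multiplicative (`delta`) batch effects, and proportional-hazards survival
#' times with administrative plus random-dropout censoring.
#'
#' Defaults mirror the study design: a development centre of 95 patients
#' with a 1-year progression (including death) probability of 0.484 and a
#' testing centre of 59 patients with probability 0.407.
#'
#' @param n integer vector, patients per centre.
#' @param p_event 1-year progression probability per centre, each in (0,1).
#' @param n_features number of radiomic features.
#' @param signal_idx indices of the planted outcome-associated features.
#' @param effect standardized mean shift added to signal features for
#'   1-year progressors (before batch effects).
#' @param gamma additive batch shift per centre: numeric vector (one value
#'   per centre, recycled over features) or a list of per-feature vectors.
#' @param delta multiplicative batch scale per centre, same shapes; all > 0.
#' @param baseline_hazard exponential baseline hazard (events/month) for the
#'   progression process of latent-low-risk patients.
#' @param log_hr log hazard ratio linking the latent 1-year-risk indicator
#'   to the progression hazard.
#' @param post_prog_rate rate (1/months) of the exponential post-progression
#'   survival increment (OS = progression time + increment).
#' @param horizon administrative censoring time (months).
#' @param dropout probability of random dropout, censored uniformly on
#'   (12, horizon).
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = c(95, 59), p_event = c(0.484, 0.407),
                        n_features = 100, signal_idx = 1:3, effect = 1.0,
                        gamma = c(0, 0.5), delta = c(1, 1.5),
                        baseline_hazard = 0.03, log_hr = 1.5,
                        post_prog_rate = 1 / 8, horizon = 36, dropout = 0.2,
                        seed = 1L) {
  n <- as.integer(n)
  k <- length(n)
  stop_if_not(k >= 1L && all(n >= 2L), "`n` must give >= 2 patients per centre")
  stop_if_not(length(p_event) == k && all(p_event > 0 & p_event < 1),
              "event probabilities must lie in (0, 1)")
  stop_if_not(n_features >= 1, "need at least one feature")
  stop_if_not(all(signal_idx >= 1 & signal_idx <= n_features),
              "planted signal indices must lie within the feature count")
  expand <- function(x, what) {
    if (is.list(x)) {
      stop_if_not(length(x) == k, sprintf("`%s` list must have one entry per centre", what))
      lapply(x, function(v) rep_len(as.numeric(v), n_features))
    } else {
      stop_if_not(length(x) == k, sprintf("`%s` must have one value per centre", what))
      lapply(as.numeric(x), function(v) rep(v, n_features))
    }
  }
  gamma <- expand(gamma, "gamma")
  delta <- expand(delta, "delta")
  stop_if_not(all(unlist(delta) > 0), "multiplicative batch scales `delta` must be > 0")
  stop_if_not(baseline_hazard > 0 && post_prog_rate > 0 && horizon > 12,
              "hazards must be positive and horizon > 12 months")
  stop_if_not(dropout >= 0 && dropout < 1, "`dropout` must be in [0, 1)")
  structure(list(n = n, p_event = p_event, n_features = as.integer(n_features),
                 signal_idx = as.integer(signal_idx), effect = effect,
                 gamma = gamma, delta = delta,
                 baseline_hazard = baseline_hazard, log_hr = log_hr,
                 post_prog_rate = post_prog_rate, horizon = horizon,
                 dropout = dropout, seed = as.integer(seed)),
            class = "cohort_spec")
}

# inverse-CDF draw from Exp(rate) truncated to (0, upper]
rtrunc_exp <- function(n, rate, upper) {
  u <- runif(n)
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}

#' Generate a synthetic two-centre cohort
#'
#' Draws, per centre: a Bernoulli 1-year progression status; standard-normal
#' features with the planted effect added to signal features of progressors;
#' batch effects applied as `x -> delta * x + gamma`; progression times from
#' an exponential proportional-hazards model on the latent risk indicator
#' (truncated to 12 months for 1-year progressors and shifted beyond 12
#' months otherwise, so status and times are consistent by construction);
#' overall survival as progression time plus an exponential increment; and
#' dropout/administrative censoring never earlier than 12 months, so every
#' 1-year event is observed. Binary clinical covariates are drawn at fixed
#' prevalences, independent of outcome.
#'
#' @param spec a [cohort_spec()].
#' @return list with `features` (data.frame: `patient_id`, `batch`, feature
#'   columns `f...`) and `outcomes` (data.frame: `patient_id`, `batch`,
#'   `status_1y`, `pfs_time`, `pfs_event`, `os_time`, `os_event` and binary
#'   covariates).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  fnames <- sprintf("f%03d", seq_len(spec$n_features))
  covar <- c(brain_mets = 0.16, hepatic_mets = 0.25, corticosteroids = 0.26,
             elevated_ldh = 0.30, ecog_1 = 0.45, age_gt65 = 0.52,
             sex_male = 0.56, combo_regimen = 0.35)
  with_seed(spec$seed, {
    feats <- vector("list", length(spec$n))
    outs <- vector("list", length(spec$n))
    id0 <- 0L
    for (c_i in seq_along(spec$n)) {
      n <- spec$n[c_i]
      s <- rbinom(n, 1L, spec$p_event[c_i])
      x <- matrix(rnorm(n * spec$n_features), nrow = n,
                  dimnames = list(NULL, fnames))
      if (spec$effect != 0 && any(s == 1L))
        x[s == 1L, spec$signal_idx] <- x[s == 1L, spec$signal_idx] + spec$effect
      x <- sweep(sweep(x, 2, spec$delta[[c_i]], "*"), 2, spec$gamma[[c_i]], "+")

      lam0 <- spec$baseline_hazard
      lam1 <- lam0 * exp(spec$log_hr)
      t_prog <- numeric(n)
      t_prog[s == 1L] <- rtrunc_exp(sum(s == 1L), lam1, 12)
      t_prog[s == 0L] <- 12 + rexp(sum(s == 0L), lam0)
      cens <- rep(spec$horizon, n)
      drop_i <- runif(n) < spec$dropout
      cens[drop_i] <- runif(sum(drop_i), 12, spec$horizon)
      pfs_time <- pmin(t_prog, cens)
      pfs_event <- as.integer(t_prog <= cens)
      t_death <- t_prog + rexp(n, spec$post_prog_rate)
      os_time <- pmin(t_death, cens)
      os_event <- as.integer(t_death <= cens)

      ids <- sprintf("P%03d", id0 + seq_len(n))
      id0 <- id0 + n
      batch <- sprintf("center%d", c_i)
      cv <- vapply(covar, function(p) rbinom(n, 1L, p), integer(n))
      feats[[c_i]] <- data.frame(patient_id = ids, batch = batch, x,
                                 stringsAsFactors = FALSE)
      outs[[c_i]] <- data.frame(patient_id = ids, batch = batch,
                                status_1y = s, pfs_time = pfs_time,
                                pfs_event = pfs_event, os_time = os_time,
                                os_event = os_event, cv,
                                stringsAsFactors = FALSE)
    }
    list(features = do.call(rbind, feats), outcomes = do.call(rbind, outs))
  })
}

#' One-year progression rate of an outcome table
#'
#' The fraction of patients whose progression (including death) event
#' occurred within the first 12 months, computed from the event counts.
#'
#' @param outcomes outcome data.frame with `pfs_time` and `pfs_event` (or a
#'   precomputed `status_1y` column, used as a consistency cross-check).
#' @param cutoff months defining the one-year window (events at exactly the
#'   cutoff count, default 12).
#' @return fraction in [0, 1].
#' @export
one_year_dp_rate <- function(outcomes, cutoff = 12) {
  status <- derive_one_year_status(outcomes$pfs_time, outcomes$pfs_event, cutoff)
  mean(status)
}

#' Derive one-year progression status from PFS time and event flag
#'
#' @param time PFS time in months; @param event 0/1 event flag;
#' @param cutoff window in months (inclusive).
#' @return integer 0/1 vector.
#' @export
derive_one_year_status <- function(time, event, cutoff = 12) {
  stop_if_not(all(time >= 0), "times must be >= 0")
  as.integer(event == 1 & time <= cutoff)
}
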