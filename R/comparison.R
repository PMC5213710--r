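#' Bayesian Information Criterion
#'
#' `k * log(n) - 2 * loglik`; lower values indicate better fit.
#'
#' @param loglik maximized log-likelihood.
#' @param k number of free parameters (>= 0).
#' @param n number of observations (choice trials, >= 1).
#' @return the BIC value.
#' @examples
#' bic(-100, 4, 240)
#' @export
bic <- function(loglik, k, n) {
  if (any(n < 1) || any(k < 0)) stopf("need n >= 1 and k >= 0")
  k * log(n) - 2 * loglik
}

#' Compare models by summed BIC of per-participant ML fits
#'
#' Fits each model to each participant by maximum likelihood and sums
#' per-participant BIC values (using each participant's own trial count in
#' the `log(n)` penalty).
#'
#' @param datasets list of `choice_data` data frames.
#' @param model_ids models to compare.
#' @param config a [fit_config()].
#' @return a `comparison_table` data frame: one row per model with
#'   `summed_bic`, `summed_loglik`, `k`; per-participant BICs in
#'   attribute `per_participant`.
#' @export
compare_models_bic <- function(datasets, model_ids = paste0("M", 1:6),
                               config = fit_config()) {
  rows <- lapply(model_ids, function(m) {
    fits <- lapply(seq_along(datasets), function(i)
      fit_ml(datasets[[i]], m,
             fit_config(n_restarts = config$n_restarts,
                        seed = derive_seed(config$seed, i),
                        beta_max = config$beta_max,
                        init_pred = config$init_pred)))
    bics <- vapply(fits, function(f) bic(f$loglik, f$k, f$n), numeric(1))
    lls <- vapply(fits, `[[`, numeric(1), "loglik")
    list(row = data.frame(model_id = m, k = fits[[1]]$k,
                          summed_loglik = sum(lls), summed_bic = sum(bics)),
         per = bics)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  attr(out, "per_participant") <- do.call(cbind, lapply(rows, `[[`, "per"))
  colnames(attr(out, "per_participant")) <- model_ids
  class(out) <- c("comparison_table", "data.frame")
  out
}

# split one participant's dataset by session
split_sessions <- function(dataset) {
  lapply(split(as.data.frame(dataset), dataset$session), function(d)
    structure(d, config = attr(dataset, "config"),
              class = c("choice_data", "data.frame")))
}

#' Half-split cross-validation across sessions
#'
#' Fits each model on one session's data from all participants and scores
#' the summed predictive log-likelihood on the held-out session, in both
#' directions (fit session 1, test session 2, and vice versa); reported as
#' summed `-2 * loglik` across directions and participants (lower is
#' better).  Participants missing a session are excluded with a warning.
#'
#' @param datasets list of `choice_data` with a `session` column covering
#'   two sessions.
#' @param model_id model to evaluate.
#' @param config a [fit_config()].
#' @param method `"hierarchical"` (fit with group shrinkage, evaluate at
#'   per-participant posterior means) or `"ml"`.
#' @return a list with `cv_deviance` (summed -2 loglik over held-out
#'   data), `by_direction`, and the two fits.
#' @export
half_split_cv <- function(datasets, model_id, config = fit_config(),
                          method = c("hierarchical", "ml")) {
  method <- match.arg(method)
  ok <- vapply(datasets, function(d) length(unique(d$session)) >= 2, logical(1))
  if (any(!ok)) {
    warning(sprintf("excluding %d participant(s) missing a session", sum(!ok)))
    datasets <- datasets[ok]
  }
  if (!length(datasets)) stopf("no participant has both sessions")
  halves <- lapply(datasets, split_sessions)
  s1 <- lapply(halves, `[[`, 1)
  s2 <- lapply(halves, `[[`, 2)
  info <- model_info(model_id)
  fit_on <- function(sets, off) {
    cfg <- fit_config(n_chains = config$n_chains, n_warmup = config$n_warmup,
                      n_samples = config$n_samples,
                      seed = derive_seed(config$seed, off),
                      rhat_threshold = config$rhat_threshold,
                      n_restarts = config$n_restarts,
                      beta_max = config$beta_max,
                      init_pred = config$init_pred)
    if (method == "hierarchical") fit_hierarchical(sets, model_id, cfg)
    else {
      ests <- lapply(seq_along(sets), function(i)
        fit_ml(sets[[i]], model_id,
               fit_config(n_restarts = config$n_restarts,
                          seed = derive_seed(config$seed, off + i),
                          beta_max = config$beta_max,
                          init_pred = config$init_pred)))
      est <- do.call(rbind, lapply(ests, `[[`, "estimates"))
      list(estimates = est, model_id = model_id)
    }
  }
  eval_on <- function(fit, sets) {
    sum(vapply(seq_along(sets), function(i) {
      p <- do.call(model_params,
                   c(list(model_id = model_id),
                     as.list(fit$estimates[i, info$free, drop = FALSE])))
      sequence_log_likelihood(sets[[i]], p, init_pred = config$init_pred)
    }, numeric(1)))
  }
  fit1 <- fit_on(s1, 31); fit2 <- fit_on(s2, 32)
  d12 <- -2 * eval_on(fit1, s2)
  d21 <- -2 * eval_on(fit2, s1)
  list(model_id = model_id, cv_deviance = d12 + d21,
       by_direction = c(train1_test2 = d12, train2_test1 = d21),
       fit_session1 = fit1, fit_session2 = fit2)
}

#' Test-retest stability of parameter estimates
#'
#' Pearson correlation, per free parameter, of per-participant estimates
#' from two independent fits of the same participants (e.g. the two task
#' sessions).
#'
#' @param fit_session1,fit_session2 `fit_result` objects (or anything with
#'   an `estimates` data frame) over the same participants, matched by
#'   `participant_id`.
#' @return data frame with `parameter`, `r`, `p`, `n`.
#' @export
parameter_stability <- function(fit_session1, fit_session2) {
  e1 <- fit_session1$estimates; e2 <- fit_session2$estimates
  common <- intersect(e1$participant_id, e2$participant_id)
  if (length(common) < 3) stopf("need at least 3 matched participants")
  e1 <- e1[match(common, e1$participant_id), ]
  e2 <- e2[match(common, e2$participant_id), ]
  pars <- setdiff(intersect(names(e1), names(e2)), c("participant_id", "group"))
  out <- do.call(rbind, lapply(pars, function(p) {
    ct <- cor.test(e1[[p]], e2[[p]])
    data.frame(parameter = p, r = unname(ct$estimate), p = ct$p.value,
               n = length(common))
  }))
  rownames(out) <- NULL
  out
}

#' Parameter-recovery study: simulate, refit, correlate
#'
#' Simulates `n_sets` cohorts of `n_per_set` agents from group-level
#' parameter distributions, refits each cohort hierarchically, and
#' correlates recovered (posterior-mean) with true per-participant
#' parameters, pooled across sets.  The stay/switch regression is also run
#' on the simulated data and its group-mean weight pattern reported, so
#' the simulation can be checked against the model-free signature of real
#' behavior.  Non-converged fits are reported, not dropped.
#'
#' @param spec a [cohort_spec()] giving group means/SDs and model.
#' @param n_sets number of simulated cohorts.
#' @param n_per_set participants per cohort.
#' @param schedule_cfg a [schedule_config()].
#' @param config a [fit_config()].
#' @param seed master seed.
#' @return a `recovery_report` list: `correlations` (per parameter, pooled
#'   r), `pairs` (true/recovered values), `weights` (group-mean
#'   stay/switch weights), `non_converged` count.
#' @export
run_recovery_study <- function(spec = cohort_spec(), n_sets = 10,
                               n_per_set = 27,
                               schedule_cfg = schedule_config(),
                               config = fit_config(), seed = 1) {
  info <- model_info(spec$model_id)
  pairs <- list(); weights <- list(); nonconv <- 0
  for (s in seq_len(n_sets)) {
    sp <- cohort_spec(n_participants = n_per_set, model_id = spec$model_id,
                      mu = spec$mu, sigma = spec$sigma,
                      beta_max = spec$beta_max,
                      seed = derive_seed(seed, 200 + s))
    sim <- simulate_cohort(sp, schedule_cfg = schedule_cfg)
    cfg <- fit_config(n_chains = config$n_chains, n_warmup = config$n_warmup,
                      n_samples = config$n_samples,
                      seed = derive_seed(seed, 300 + s),
                      rhat_threshold = config$rhat_threshold,
                      n_restarts = config$n_restarts,
                      beta_max = config$beta_max,
                      init_pred = config$init_pred)
    fit <- fit_hierarchical(sim$datasets, spec$model_id, cfg)
    if (!fit$converged) nonconv <- nonconv + 1
    m <- merge(sim$params, fit$estimates, by = "participant_id",
               suffixes = c("_true", "_fit"))
    m$set <- s
    pairs[[s]] <- m
    des <- lapply(sim$datasets, build_stay_switch_design)
    w <- do.call(rbind, lapply(des, fit_stay_switch))
    weights[[s]] <- colMeans(w[, -1, drop = FALSE])
  }
  pairs <- do.call(rbind, pairs)
  cors <- do.call(rbind, lapply(info$free, function(p) {
    ct <- cor.test(pairs[[paste0(p, "_true")]], pairs[[paste0(p, "_fit")]])
    data.frame(parameter = p, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(pairs))
  }))
  structure(list(model_id = spec$model_id, correlations = cors,
                 pairs = pairs,
                 weights = colMeans(do.call(rbind, weights)),
                 non_converged = nonconv, n_sets = n_sets,
                 n_per_set = n_per_set),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report %s> %d sets x %d participants (%d non-converged fits)\n",
              x$model_id, x$n_sets, x$n_per_set, x$non_converged))
  print(x$correlations, row.names = FALSE)
  invisible(x)
}
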