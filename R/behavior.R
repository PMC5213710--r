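#' Build the lagged stay/switch regression design
#'
#' For every analyzable learning trial, the response is whether the
#' participant repeated the previous choice (stay = 1) or switched
#' (switch = 0).  Regressors are the current displayed reward probability
#' and the reward (`RM`) and effort (`EM`) magnitude outcomes from the
#' previous `n_lags` trials, each coded in the frame of reference of the
#' stay choice relative to the switch choice (stay option's value minus
#' the alternative's), then z-scored within participant.  Lags never cross
#' session boundaries, so the first `n_lags` learning trials of each
#' session (plus each session's first trial, which has no stay reference)
#' are excluded; attention trials are removed before lag counting because
#' they carry no feedback.
#'
#' @param data one participant's `choice_data`.
#' @param n_lags number of outcome lags (default 4).
#' @return a `stay_switch_design` data frame: `stay`, `prob`, `RM_1` ..
#'   `RM_n`, `EM_1` .. `EM_n` (z-scored), with attribute `participant_id`.
#' @export
build_stay_switch_design <- function(data, n_lags = 4) {
  df <- as.data.frame(data)
  df <- df[df$trial_type != "attention", , drop = FALSE]
  df <- df[order(df$session, df$trial), , drop = FALSE]
  if (anyNA(df$choice)) stopf("missing choices on learning trials")
  rows <- list()
  for (s in unique(df$session)) {
    d <- df[df$session == s, , drop = FALSE]
    n <- nrow(d)
    if (n < n_lags + 1) next
    t <- (n_lags + 1):n                      # first trial with all lags
    sign_a <- ifelse(d$choice[t - 1] == "A", 1, -1)  # stay option = last choice
    val <- function(col_a, col_b, tt) sign_a * (d[[col_a]][tt] - d[[col_b]][tt])
    r <- data.frame(stay = as.integer(d$choice[t] == d$choice[t - 1]),
                    prob = val("prob_A", "prob_B", t))
    for (l in seq_len(n_lags)) {
      r[[paste0("RM_", l)]] <- val("rm_A", "rm_B", t - l)
      r[[paste0("EM_", l)]] <- val("em_A", "em_B", t - l)
    }
    rows[[length(rows) + 1L]] <- r
  }
  if (!length(rows))
    stopf("fewer than n_lags + 1 usable trials in every session")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  for (v in setdiff(names(out), "stay")) {
    s <- sd(out[[v]])
    if (!is.finite(s) || s < 1e-12)
      stopf("regressor `%s` has zero variance and cannot be z-scored", v)
    out[[v]] <- (out[[v]] - mean(out[[v]])) / s
  }
  structure(out, participant_id = data$participant_id[1] %||% "p1",
            n_lags = n_lags,
            class = c("stay_switch_design", "data.frame"))
}

# ridge-penalised IRLS logistic fit, used as a flagged fallback when the
# unpenalised likelihood is separated (weights diverge)
ridge_logistic <- function(X, y, lambda = 0.01, maxit = 100) {
  b <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    H <- crossprod(X, X * w) + diag(lambda, ncol(X))
    b_new <- solve(H, crossprod(X, w * z))
    if (max(abs(b_new - b)) < 1e-10) { b <- b_new; break }
    b <- b_new
  }
  drop(b)
}

#' Fit the stay/switch logistic regression for one participant
#'
#' Maximum-likelihood logistic regression of the stay response on the
#' coded regressors (intercept `b0` plus probability and lagged magnitude
#' weights).  If the fit is separated (non-convergence or absurd weight
#' magnitudes), a ridge-penalised fit is substituted and flagged via the
#' `penalized` attribute.
#'
#' @param design a [build_stay_switch_design()] result.
#' @return a named numeric vector `b0`, `prob`, `RM_1` .. `EM_n`.
#' @export
fit_stay_switch <- function(design) {
  separated <- FALSE
  f <- withCallingHandlers(
    glm(stay ~ ., data = design, family = binomial(),
        control = list(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- coef(f)
  penalized <- FALSE
  if (separated || !f$converged || any(!is.finite(co)) || any(abs(co) > 15)) {
    X <- cbind(1, as.matrix(design[setdiff(names(design), "stay")]))
    co <- ridge_logistic(X, design$stay)
    penalized <- TRUE
  }
  names(co)[1] <- "b0"
  structure(co, penalized = penalized,
            participant_id = attr(design, "participant_id"))
}

#' Group-level tests on stay/switch regression weights
#'
#' The probability weight is tested across participants with a one-sample
#' t-test (df = n - 1).  For each lag family (reward magnitudes, effort
#' magnitudes), the per-participant mean across the lag weights is tested
#' against zero while controlling for the binary group assignment as a
#' between-participant confound (centred covariate in a linear model),
#' which yields the F(1, n - 2) main-effect structure of a
#' repeated-measures ANOVA with one between factor.
#'
#' @param weights matrix/data frame of per-participant weight vectors
#'   (rows = participants, columns as from [fit_stay_switch()]).
#' @param group binary group labels, one per participant.
#' @return a `group_test_result` list: `t_prob` (statistic, df, p),
#'   `F_rm`, `F_em` (statistic, df1, df2, p), and per-regressor means.
#' @export
group_tests <- function(weights, group) {
  w <- as.data.frame(weights)
  if (anyNA(w)) stopf("missing regression weights")
  n <- nrow(w)
  if (length(unique(group)) != 2 || min(table(group)) < 3)
    stopf("need two groups with >= 3 participants per group")
  tt <- t.test(w$prob)
  fam_test <- function(cols) {
    mw <- rowMeans(w[, cols, drop = FALSE])
    g <- as.numeric(group) - mean(as.numeric(group))
    if (all(abs(mw) < 1e-12))
      return(list(F = 0, df1 = 1, df2 = n - 2, p = 1))
    fit <- lm(mw ~ g)
    s <- summary(fit)$coefficients
    list(F = unname(s[1, "t value"]^2), df1 = 1, df2 = n - 2,
         p = unname(s[1, "Pr(>|t|)"]))
  }
  rm_cols <- grep("^RM_", names(w), value = TRUE)
  em_cols <- grep("^EM_", names(w), value = TRUE)
  structure(list(
    t_prob = list(t = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value),
    F_rm = fam_test(rm_cols), F_em = fam_test(em_cols),
    means = colMeans(w), n = n), class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("probability weight: t(%d) = %.2f, p = %.3g\n",
              x$t_prob$df, x$t_prob$t, x$t_prob$p))
  cat(sprintf("reward-magnitude lags: F(%d,%d) = %.2f, p = %.3g\n",
              x$F_rm$df1, x$F_rm$df2, x$F_rm$F, x$F_rm$p))
  cat(sprintf("effort-magnitude lags: F(%d,%d) = %.2f, p = %.3g\n",
              x$F_em$df1, x$F_em$df2, x$F_em$F, x$F_em$p))
  invisible(x)
}

#' Binned choice curves over learnt-value and probability differences
#'
#' Pools trials across datasets, bins them by the difference (option A
#' minus option B) in learnt value (`lambda * rew_pred - (1 - lambda) *
#' eff_pred`, from the Bayesian observer stand-in by default) and,
#' separately, by the difference in displayed probability, and reports the
#' proportion of A choices per bin.  Also returns the logistic slope of
#' choice on each difference, which is the quantitative handle on "which
#' curve is steeper".  Empty bins are reported as `NA`, not zero.
#'
#' @param datasets list of `choice_data`.
#' @param lambda reward-versus-effort weight used to collapse reward and
#'   effort predictions into one learnt value.
#' @param n_bins number of equal-width bins.
#' @param predictions function(data) returning a prediction matrix as
#'   [bayes_observer_predictions()]; defaults to the observer.
#' @return a list with `curves` (data frame: `measure`, `bin_mid`,
#'   `p_choose_a`, `n`) and `slopes` (named: `learnt_value`,
#'   `probability`).
#' @export
binned_choice_curves <- function(datasets, lambda = 0.5, n_bins = 7,
                                 predictions = bayes_observer_predictions) {
  acc <- lapply(datasets, function(d) {
    arr <- choice_arrays(d, require_choice = TRUE)
    pr <- predictions(d)
    data.frame(
      choice_a = as.integer(arr$choice == 1L),
      dv = (lambda * pr[, "rew_A"] - (1 - lambda) * pr[, "eff_A"]) -
           (lambda * pr[, "rew_B"] - (1 - lambda) * pr[, "eff_B"]),
      dp = arr$prob_a - arr$prob_b)
  })
  df <- do.call(rbind, acc)
  one <- function(x, label) {
    br <- seq(min(x), max(x), length.out = n_bins + 1)
    idx <- findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
    mids <- (br[-1] + br[-length(br)]) / 2
    p <- vapply(seq_len(n_bins), function(b)
      if (any(idx == b)) mean(df$choice_a[idx == b]) else NA_real_,
      numeric(1))
    nb <- vapply(seq_len(n_bins), function(b) sum(idx == b), numeric(1))
    data.frame(measure = label, bin_mid = mids, p_choose_a = p, n = nb)
  }
  slope <- function(x) unname(coef(glm(df$choice_a ~ x,
                                       family = binomial()))[2])
  list(curves = rbind(one(df$dv, "learnt_value"), one(df$dp, "probability")),
       slopes = c(learnt_value = slope(df$dv), probability = slope(df$dp)))
}
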