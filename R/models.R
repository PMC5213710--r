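#' Rescorla-Wagner prediction update
#'
#' Moves a magnitude prediction toward an observed outcome by a fraction
#' `alpha` of the prediction error: `prediction + alpha * (outcome -
#' prediction)`.
#'
#' @param prediction current prediction (any magnitude scale).
#' @param outcome observed outcome on the same scale.
#' @param alpha learning rate in \[0, 1\].
#' @return the updated prediction.
#' @examples
#' rw_update(5, 10, 0.5)  # 7.5
#' @export
rw_update <- function(prediction, outcome, alpha) {
  check_range(alpha, "alpha", 0, 1)
  if (!is.numeric(prediction) || !is.numeric(outcome))
    stopf("`prediction` and `outcome` must be numeric")
  prediction + alpha * (outcome - prediction)
}

#' Option utility under linear integration (models M1-M3)
#'
#' `(1 - gamma) * prob + gamma * (lambda * rew_pred - (1 - lambda) *
#' eff_pred)`.  `gamma` weighs learnt magnitude information against the
#' displayed reward probability; `lambda` weighs reward against effort.
#' Magnitude predictions are expected on the normalised \[0, 1\] scale.
#'
#' @param prob displayed reward probability in \[0, 1\].
#' @param rew_pred,eff_pred normalised reward/effort magnitude predictions.
#' @param gamma,lambda weights in \[0, 1\].
#' @return the scalar utility.
#' @examples
#' utility_linear(0.7, 0.5, 0.4, gamma = 0.4, lambda = 0.6)  # 0.476
#' @export
utility_linear <- function(prob, rew_pred, eff_pred, gamma, lambda) {
  check_range(gamma, "gamma", 0, 1)
  check_range(lambda, "lambda", 0, 1)
  (1 - gamma) * prob + gamma * (lambda * rew_pred - (1 - lambda) * eff_pred)
}

#' Option utility under multiplicative integration (models M4-M6)
#'
#' `(1 - lambda) * prob * rew_pred - lambda * eff_pred`: probability and
#' reward prediction multiply into an expected value, traded off against
#' the effort prediction by `lambda`.
#'
#' @inheritParams utility_linear
#' @return the scalar utility.
#' @examples
#' utility_multiplicative(0.5, 0.8, 0.2, lambda = 0.25)  # 0.25
#' @export
utility_multiplicative <- function(prob, rew_pred, eff_pred, lambda) {
  check_range(lambda, "lambda", 0, 1)
  (1 - lambda) * prob * rew_pred - lambda * eff_pred
}

#' Softmax probability of choosing option A
#'
#' `exp(beta * U_A) / (exp(beta * U_A) + exp(beta * U_B))`, computed in a
#' numerically stable form so large `beta * |U_A - U_B|` never overflows.
#'
#' @param utility_a,utility_b finite option utilities.
#' @param beta inverse temperature, >= 0.
#' @return probability of choosing A, in (0, 1).
#' @examples
#' softmax_prob(0.5, 0, beta = 1)  # 1 / (1 + exp(-0.5))
#' @export
softmax_prob <- function(utility_a, utility_b, beta) {
  if (any(!is.finite(c(utility_a, utility_b))))
    stopf("utilities must be finite")
  if (!is.numeric(beta) || any(beta < 0)) stopf("`beta` must be >= 0")
  plogis(beta * (utility_a - utility_b))
}

# ---------------------------------------------------------------------------
# internal: flatten a choice dataset (or bare schedule) into the ordered
# arrays the C++ core consumes.  Learning trials only; attention trials
# carry no feedback and are dropped.  `new_block` marks session starts so
# predictions reset between sessions.
choice_arrays <- function(data, require_choice = TRUE) {
  df <- as.data.frame(data)
  need <- c("session", "trial", "trial_type", "prob_A", "prob_B",
            "rm_A", "rm_B", "em_A", "em_B")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("data is missing column(s): %s", paste(miss, collapse = ", "))
  df <- df[order(df$session, df$trial), , drop = FALSE]
  df <- df[df$trial_type != "attention", , drop = FALSE]
  if (require_choice) {
    if (!"choice" %in% names(df)) stopf("data is missing column(s): choice")
    if (anyNA(df$choice))
      stopf("missing choice/feedback on a standard or special trial")
    if (anyNA(df[, c("rm_A", "rm_B", "em_A", "em_B")]))
      stopf("missing choice/feedback on a standard or special trial")
  }
  fixed <- rep(0L, nrow(df))
  if ("fixed_option" %in% names(df)) {
    fixed[!is.na(df$fixed_option) & df$fixed_option == "A"] <- 1L
    fixed[!is.na(df$fixed_option) & df$fixed_option == "B"] <- 2L
  }
  list(
    prob_a = as.numeric(df$prob_A), prob_b = as.numeric(df$prob_B),
    rm_a = as.numeric(df$rm_A), rm_b = as.numeric(df$rm_B),
    em_a = as.numeric(df$em_A), em_b = as.numeric(df$em_B),
    fixed_opt = fixed,
    new_block = as.integer(c(1L, diff(as.integer(factor(df$session))) != 0)),
    choice = if (require_choice) ifelse(df$choice == "A", 1L, 2L)
             else rep(1L, nrow(df)),
    n = nrow(df), df = df
  )
}

scale_opts <- function(data, max_rm = NULL, max_em = NULL, init_pred = 0.5) {
  cfg <- attr(data, "config")
  list(
    max_rm = max_rm %||% (if (!is.null(cfg)) cfg$rm_range[2] else 20),
    max_em = max_em %||% (if (!is.null(cfg)) cfg$em_range[2] else 15),
    init_pred = init_pred
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# external (observer) prediction matrix for M3/M6, else a 0-row dummy
ext_pred_matrix <- function(info, arr, sc, observer = NULL) {
  if (info$learning != "observer") return(matrix(0, 0, 4))
  if (is.null(observer))
    observer <- kalman_predictions_arrays(arr, sc)
  observer
}

#' Total choice log-likelihood of a dataset under one model
#'
#' Walks the trials in task order: computes both options' utilities from
#' the current predictions, adds the log softmax probability of the choice
#' actually made, then updates the predictions for both options from the
#' displayed feedback (both outcomes are shown on every learning trial).
#' Attention trials contribute nothing and trigger no update.  On
#' special-option trials the fixed option's prediction is pinned to its
#' known (pre-trained) value and only the drifting option is updated.
#' Predictions reset at session boundaries.
#'
#' @param data a choice dataset (see [simulate_agent()] /
#'   [read_choice_table()]).
#' @param params a [model_params()] object.
#' @param max_rm,max_em magnitude normalisation constants (defaults taken
#'   from the schedule configuration attached to `data`, else 20 pence and
#'   15 circles).
#' @param init_pred initial prediction on the normalised scale.
#' @param observer optional pre-computed observer prediction matrix for
#'   M3/M6 (as returned by [bayes_observer_predictions()]).
#' @return the summed log-likelihood (a scalar).
#' @export
sequence_log_likelihood <- function(data, params, max_rm = NULL,
                                    max_em = NULL, init_pred = 0.5,
                                    observer = NULL) {
  info <- model_info(params$model_id)
  arr <- choice_arrays(data, require_choice = TRUE)
  sc <- scale_opts(data, max_rm, max_em, init_pred)
  ep <- ext_pred_matrix(info, arr, sc, observer)
  cpp_loglik(par5(params), as.integer(info$utility == "multiplicative"),
             as.integer(info$learning == "observer"),
             arr$prob_a, arr$prob_b, arr$rm_a, arr$rm_b, arr$em_a, arr$em_b,
             arr$fixed_opt, arr$new_block, arr$choice,
             sc$max_rm, sc$max_em, sc$init_pred, ep)
}

# ---------------------------------------------------------------------------
# Bayesian observer stand-in: an independent Gaussian random-walk filter
# (Kalman mean-tracker) per option and attribute.  The underlying means
# drift between levels; the filter's drift variance q and observation
# variance r are set from the schedule generator defaults on the
# normalised scale.  Returns prior (pre-update) predictions per trial.
kalman_predictions_arrays <- function(arr, sc, q = 0.005, r = 0.01,
                                      prior_mean = 0.5, prior_var = 0.25) {
  n <- arr$n
  out <- matrix(NA_real_, n, 4)
  m <- rep(prior_mean, 4); v <- rep(prior_var, 4)
  obs <- cbind(arr$rm_a / sc$max_rm, arr$rm_b / sc$max_rm,
               arr$em_a / sc$max_em, arr$em_b / sc$max_em)
  upd <- cbind(arr$fixed_opt != 1L, arr$fixed_opt != 2L,
               arr$fixed_opt != 1L, arr$fixed_opt != 2L)
  for (t in seq_len(n)) {
    if (arr$new_block[t] == 1L) { m <- rep(prior_mean, 4); v <- rep(prior_var, 4) }
    out[t, ] <- m
    vp <- v + q
    k <- vp / (vp + r)
    for (j in 1:4) {
      if (upd[t, j]) {
        m[j] <- m[j] + k[j] * (obs[t, j] - m[j])
        v[j] <- (1 - k[j]) * vp[j]
      } else v[j] <- vp[j]
    }
  }
  colnames(out) <- c("rew_A", "rew_B", "eff_A", "eff_B")
  out
}

#' Bayesian observer predictions for reward and effort magnitudes
#'
#' A Gaussian random-walk filter (Kalman mean-tracker) per option and
#' attribute, used by models M3/M6 in place of a fitted learning rate and
#' for regressor construction.  Each filter assumes the latent magnitude
#' mean performs a random walk with drift variance `q` and that drawn
#' magnitudes are noisy observations with variance `r` (both on the
#' normalised \[0, 1\] scale, matched to the schedule generator defaults).
#' The returned predictions are the filter means *before* seeing the
#' trial's outcome; the first trial of each session equals `prior_mean`.
#'
#' @inheritParams sequence_log_likelihood
#' @param q drift (process) variance per trial.
#' @param r observation variance of a single magnitude draw.
#' @param prior_mean,prior_var initial filter mean and variance.
#' @return a matrix with one row per learning trial and columns `rew_A`,
#'   `rew_B`, `eff_A`, `eff_B`.
#' @export
bayes_observer_predictions <- function(data, q = 0.005, r = 0.01,
                                       prior_mean = 0.5, prior_var = 0.25,
                                       max_rm = NULL, max_em = NULL) {
  arr <- choice_arrays(data, require_choice = FALSE)
  sc <- scale_opts(data, max_rm, max_em)
  kalman_predictions_arrays(arr, sc, q = q, r = r, prior_mean = prior_mean,
                            prior_var = prior_var)
}

#' Per-trial Rescorla-Wagner predictions at given parameters
#'
#' Convenience wrapper returning the prior (pre-update) normalised
#' predictions for both options' reward and effort magnitudes under a
#' fitted learning rate; used for binned choice curves and regressors.
#'
#' @inheritParams sequence_log_likelihood
#' @param alpha_rew,alpha_eff learning rates (set both to a shared alpha
#'   for M1/M4-style predictions).
#' @return matrix as in [bayes_observer_predictions()].
#' @export
rw_predictions <- function(data, alpha_rew, alpha_eff = alpha_rew,
                           max_rm = NULL, max_em = NULL, init_pred = 0.5) {
  check_range(alpha_rew, "alpha_rew", 0, 1)
  check_range(alpha_eff, "alpha_eff", 0, 1)
  arr <- choice_arrays(data, require_choice = FALSE)
  sc <- scale_opts(data, max_rm, max_em, init_pred)
  out <- cpp_rw_predictions(c(alpha_rew, alpha_eff), arr$rm_a, arr$rm_b,
                            arr$em_a, arr$em_b, arr$fixed_opt,
                            arr$new_block, sc$max_rm, sc$max_em,
                            sc$init_pred)
  colnames(out) <- c("rew_A", "rew_B", "eff_A", "eff_B")
  out
}
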