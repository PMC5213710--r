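#' Model registry for the learning-model family M1-M6
#'
#' The six candidate models differ along two axes: how probability and
#' learnt magnitudes are integrated into a utility (linear weighted sum for
#' M1-M3 versus multiplicative for M4-M6), and how magnitude predictions
#' are formed (shared Rescorla-Wagner learning rate for M1/M4, separate
#' reward and effort learning rates for M2/M5, or predictions from a
#' Bayesian mean-tracking observer with no fitted learning rate for M3/M6).
#'
#' @param model_id one of `"M1"` .. `"M6"`.
#' @return a list with elements `utility` (`"linear"` or
#'   `"multiplicative"`), `learning` (`"shared"`, `"separate"` or
#'   `"observer"`), `free` (names of free parameters) and `k` (their count).
#' @examples
#' model_info("M1")$free
#' @export
model_info <- function(model_id) {
  info <- switch(model_id,
    M1 = list(utility = "linear", learning = "shared",
              free = c("alpha", "gamma", "lambda", "beta")),
    M2 = list(utility = "linear", learning = "separate",
              free = c("alpha_rew", "alpha_eff", "gamma", "lambda", "beta")),
    M3 = list(utility = "linear", learning = "observer",
              free = c("gamma", "lambda", "beta")),
    M4 = list(utility = "multiplicative", learning = "shared",
              free = c("alpha", "lambda", "beta")),
    M5 = list(utility = "multiplicative", learning = "separate",
              free = c("alpha_rew", "alpha_eff", "lambda", "beta")),
    M6 = list(utility = "multiplicative", learning = "observer",
              free = c("lambda", "beta")),
    stopf("unknown model_id `%s` (expected one of M1..M6)", model_id)
  )
  info$model_id <- model_id
  info$k <- length(info$free)
  info
}

#' Construct a validated parameter set for one model
#'
#' Bounded parameters (learning rates, the use-of-learnt-information weight
#' `gamma`, the reward-versus-effort weight `lambda`) live in \[0, 1\]; the
#' softmax inverse temperature `beta` is positive.  Only the fields a model
#' uses may be supplied.
#'
#' @param model_id one of `"M1"` .. `"M6"`.
#' @param alpha shared learning rate (M1, M4).
#' @param alpha_rew,alpha_eff separate reward/effort learning rates (M2, M5).
#' @param gamma weight on learnt magnitude information versus displayed
#'   probability (linear models M1-M3).
#' @param lambda reward-versus-effort weight.
#' @param beta softmax inverse temperature (> 0).
#' @return an object of class `model_params`.
#' @examples
#' model_params("M1", alpha = 0.3, gamma = 0.6, lambda = 0.5, beta = 5)
#' @export
model_params <- function(model_id, alpha = NULL, alpha_rew = NULL,
                         alpha_eff = NULL, gamma = NULL, lambda = NULL,
                         beta = NULL) {
  info <- model_info(model_id)
  supplied <- list(alpha = alpha, alpha_rew = alpha_rew,
                   alpha_eff = alpha_eff, gamma = gamma, lambda = lambda,
                   beta = beta)
  supplied <- supplied[!vapply(supplied, is.null, logical(1))]
  missing <- setdiff(info$free, names(supplied))
  if (length(missing))
    stopf("model %s needs parameter(s): %s", model_id,
          paste(missing, collapse = ", "))
  extra <- setdiff(names(supplied), info$free)
  if (length(extra))
    stopf("model %s does not use parameter(s): %s", model_id,
          paste(extra, collapse = ", "))
  for (nm in setdiff(info$free, "beta"))
    check_range(supplied[[nm]], nm, 0, 1)
  if (!is.numeric(supplied$beta) || supplied$beta < 0)
    stopf("`beta` must be a non-negative number")
  structure(c(supplied, list(model_id = model_id)), class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params ", x$model_id, "> ", sep = "")
  vals <- x[setdiff(names(x), "model_id")]
  cat(paste(names(vals), signif(unlist(vals), 4), sep = "="), sep = "  ")
  cat("\n")
  invisible(x)
}

# expand a model_params object (or named natural-scale vector) to the
# 5-slot parameter vector the C++ core expects:
# (alpha_rew, alpha_eff, gamma, lambda, beta)
par5 <- function(params) {
  if (inherits(params, "model_params")) {
    info <- model_info(params$model_id)
    p <- params
  } else stopf("`params` must be a model_params object")
  a_r <- a_e <- 0
  if (info$learning == "shared") a_r <- a_e <- p$alpha
  if (info$learning == "separate") { a_r <- p$alpha_rew; a_e <- p$alpha_eff }
  g <- if (info$utility == "linear") p$gamma else 0
  c(a_r, a_e, g, p$lambda, p$beta)
}

# free natural-scale named vector -> 5-slot row (used by fitting code)
free_to_par5 <- function(theta, info) {
  a_r <- a_e <- 0
  if (info$learning == "shared") a_r <- a_e <- theta[["alpha"]]
  if (info$learning == "separate") {
    a_r <- theta[["alpha_rew"]]; a_e <- theta[["alpha_eff"]]
  }
  g <- if (info$utility == "linear") theta[["gamma"]] else 0
  c(a_r, a_e, g, theta[["lambda"]], theta[["beta"]])
}

#' Map parameters between the unconstrained and natural scales
#'
#' Fitting is performed on an unconstrained scale: learning rates, `gamma`
#' and `lambda` are logit-transformed from (0, 1), and `beta` is a scaled
#' logit from (0, `beta_max`).  These helpers apply the transform and its
#' inverse for a named vector of free parameters.
#'
#' @param theta named numeric vector of free parameters.
#' @param info a [model_info()] list naming the free parameters.
#' @param beta_max upper bound of the inverse-temperature scale.
#' @return named numeric vector on the other scale.
#' @export
to_natural <- function(theta, info, beta_max = 20) {
  out <- plogis(theta)
  if ("beta" %in% names(out)) out[["beta"]] <- beta_max * out[["beta"]]
  out[info$free]
}

#' @rdname to_natural
#' @export
to_unconstrained <- function(theta, info, beta_max = 20) {
  th <- theta
  if ("beta" %in% names(th)) th[["beta"]] <- th[["beta"]] / beta_max
  out <- qlogis(th)
  out[info$free]
}
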