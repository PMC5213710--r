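#' Fitting configuration
#'
#' Defaults follow the study's sampling scheme: three chains of 1000 kept
#' samples after 1000 warm-up samples each, with convergence judged by
#' split-R-hat below 1.1.
#'
#' @param n_chains number of MCMC chains.
#' @param n_warmup warm-up (adaptation) iterations per chain, discarded.
#' @param n_samples kept iterations per chain.
#' @param seed integer seed.
#' @param rhat_threshold convergence bound on split-R-hat (> 1).
#' @param n_restarts random restarts for maximum-likelihood fitting.
#' @param beta_max upper bound of the inverse-temperature scale.
#' @param init_pred initial magnitude prediction (normalised scale).
#' @return a `fit_config` list.
#' @export
fit_config <- function(n_chains = 3, n_warmup = 1000, n_samples = 1000,
                       seed = 1, rhat_threshold = 1.1, n_restarts = 10,
                       beta_max = 20, init_pred = 0.5) {
  if (n_chains < 1 || n_warmup < 1 || n_samples < 1 || n_restarts < 1)
    stopf("counts in fit_config must be positive")
  if (rhat_threshold <= 1) stopf("rhat_threshold must exceed 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples), seed = as.integer(seed),
                 rhat_threshold = rhat_threshold,
                 n_restarts = as.integer(n_restarts), beta_max = beta_max,
                 init_pred = init_pred),
            class = "fit_config")
}

# stack a list of choice datasets into one set of arrays with participant
# index, plus per-participant trial counts and external predictions
stack_cohort <- function(datasets, info, config) {
  arrs <- lapply(datasets, choice_arrays, require_choice = TRUE)
  scs <- lapply(datasets, scale_opts, init_pred = config$init_pred)
  sc <- scs[[1]]
  part <- rep(seq_along(arrs) - 1L, vapply(arrs, `[[`, 0L, "n"))
  cat_f <- function(f) do.call(c, lapply(arrs, `[[`, f))
  ep <- if (info$learning == "observer")
    do.call(rbind, lapply(seq_along(arrs), function(i)
      kalman_predictions_arrays(arrs[[i]], scs[[i]])))
  else matrix(0, 0, 4)
  list(part = part, prob_a = cat_f("prob_a"), prob_b = cat_f("prob_b"),
       rm_a = cat_f("rm_a"), rm_b = cat_f("rm_b"),
       em_a = cat_f("em_a"), em_b = cat_f("em_b"),
       fixed_opt = cat_f("fixed_opt"),
       new_block = do.call(c, lapply(arrs, `[[`, "new_block")),
       choice = cat_f("choice"), sc = sc, ep = ep,
       n_trials = vapply(arrs, `[[`, 0L, "n"))
}

# log-likelihood for an n_part x k matrix of unconstrained free params
cohort_loglik <- function(theta_unc, info, st, config) {
  nat <- plogis(theta_unc)
  if ("beta" %in% info$free)
    nat[, "beta"] <- config$beta_max * nat[, "beta"]
  n <- nrow(nat)
  zero <- numeric(n)
  p5 <- switch(info$learning,
    shared = cbind(nat[, "alpha"], nat[, "alpha"]),
    separate = cbind(nat[, "alpha_rew"], nat[, "alpha_eff"]),
    observer = cbind(zero, zero))
  p5 <- cbind(p5, if (info$utility == "linear") nat[, "gamma"] else zero,
              nat[, "lambda"], nat[, "beta"])
  cpp_loglik_matrix(p5, as.integer(info$utility == "multiplicative"),
                    as.integer(info$learning == "observer"), st$part,
                    st$prob_a, st$prob_b, st$rm_a, st$rm_b, st$em_a,
                    st$em_b, st$fixed_opt, st$new_block, st$choice,
                    st$sc$max_rm, st$sc$max_em, st$sc$init_pred, st$ep)
}

# likelihood of one participant's data (stacked as `st`, single
# participant) under each row of an unconstrained free-parameter matrix
grid_loglik <- function(theta_unc, info, st, config) {
  nat <- plogis(theta_unc)
  if ("beta" %in% info$free)
    nat[, "beta"] <- config$beta_max * nat[, "beta"]
  n <- nrow(nat)
  zero <- numeric(n)
  p5 <- switch(info$learning,
    shared = cbind(nat[, "alpha"], nat[, "alpha"]),
    separate = cbind(nat[, "alpha_rew"], nat[, "alpha_eff"]),
    observer = cbind(zero, zero))
  p5 <- cbind(p5, if (info$utility == "linear") nat[, "gamma"] else zero,
              nat[, "lambda"], nat[, "beta"])
  cpp_loglik_grid(p5, as.integer(info$utility == "multiplicative"),
                  as.integer(info$learning == "observer"),
                  st$prob_a, st$prob_b, st$rm_a, st$rm_b, st$em_a,
                  st$em_b, st$fixed_opt, st$new_block, st$choice,
                  st$sc$max_rm, st$sc$max_em, st$sc$init_pred, st$ep)
}

#' Maximum-likelihood fit of one participant's choices
#'
#' Maximises [sequence_log_likelihood()] over the model's free parameters
#' on the unconstrained scale with Nelder-Mead from multiple random
#' starts.  Ties are broken by the highest likelihood, then the smallest
#' unconstrained parameter norm.  A fit whose maximised likelihood is not
#' significantly better than random choice (likelihood-ratio test against
#' `n * log(0.5)` at the 5% level) is flagged `unidentifiable`: with an
#' effectively random chooser the remaining parameters carry no
#' information.
#'
#' @param dataset a `choice_data` data frame.
#' @param model_id one of `"M1"` .. `"M6"`.
#' @param config a [fit_config()].
#' @return a `fit_result` list: `estimates` (one-row data frame of
#'   natural-scale parameters), `loglik`, `k`, `n`, `unidentifiable`,
#'   `method = "ml"`.
#' @export
fit_ml <- function(dataset, model_id, config = fit_config()) {
  info <- model_info(model_id)
  st <- stack_cohort(list(dataset), info, config)
  negll <- function(th) {
    m <- matrix(th, nrow = 1, dimnames = list(NULL, info$free))
    -cohort_loglik(m, info, st, config)
  }
  starts <- with_seed(config$seed, matrix(rnorm(config$n_restarts * info$k,
                                                0, 1.5),
                                          ncol = info$k))
  best <- NULL
  for (i in seq_len(config$n_restarts)) {
    o <- tryCatch(optim(starts[i, ], negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-10)),
                  error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value - 1e-9 ||
        (abs(o$value - best$value) <= 1e-9 &&
         sum(o$par^2) < sum(best$par^2)))
      best <- o
  }
  if (is.null(best))
    stopf("all restarts failed for participant %s",
          dataset$participant_id[1] %||% "?")
  theta <- best$par
  names(theta) <- info$free
  nat <- to_natural(theta, info, beta_max = config$beta_max)
  ll <- -best$value
  n <- st$n_trials[1]
  unident <- 2 * (ll - n * log(0.5)) < qchisq(0.95, info$k)
  est <- as.data.frame(as.list(nat))
  est$participant_id <- dataset$participant_id[1] %||% "p1"
  structure(list(model_id = model_id, method = "ml", estimates = est,
                 estimates_unc = theta, loglik = ll, k = info$k, n = n,
                 unidentifiable = unident, config = config),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s, %s> k=%d\n", x$model_id, x$method, x$k))
  if (x$method == "ml")
    cat(sprintf("  loglik %.2f over n=%d trials%s\n", x$loglik, x$n,
                if (isTRUE(x$unidentifiable)) " [flagged unidentifiable]" else ""))
  else
    cat(sprintf("  %d participants, max split-Rhat %.3f (%s)\n",
                nrow(x$estimates), x$max_rhat,
                if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# split-R-hat (potential scale reduction on split chains) for a
# (iterations x chains) draw matrix
split_rhat <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  sub <- cbind(draws[seq_len(half), , drop = FALSE],
               draws[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2, stats::var)
  w <- mean(vars)
  b <- half * stats::var(means)
  if (w < 1e-12) return(1)
  sqrt(((half - 1) / half * w + b / half) / w)
}

#' Hierarchical Bayesian fit of a cohort
#'
#' Per-participant parameters are drawn from group-level normal
#' distributions on the unconstrained scale (logit for bounded
#' parameters, scaled logit for the inverse temperature) and transformed
#' to their natural ranges, so individual estimates are shrunk toward the
#' group.  Group means carry flat priors over the allowed range and group
#' SDs half-normal(0, 10) priors.  Sampling uses a Metropolis-within-Gibbs
#' scheme: a joint random-walk Metropolis update per participant (step
#' sizes adapted during warm-up), conjugate Gibbs draws for the group
#' means and random-walk updates on the log group SDs.  Convergence is
#' assessed by split-R-hat on every sampled quantity; a fit exceeding the
#' threshold is returned flagged, never silently accepted.
#'
#' @param datasets list of `choice_data` data frames (>= 2 participants).
#' @param model_id one of `"M1"` .. `"M6"`.
#' @param config a [fit_config()].
#' @return a `fit_result` list with `estimates` (posterior-mean
#'   natural-scale parameters per participant), `group` (posterior means
#'   of group-level means and SDs, both scales), `rhat`, `max_rhat`,
#'   `converged`, and `draws_group` (group-level posterior draws).
#' @export
fit_hierarchical <- function(datasets, model_id, config = fit_config()) {
  if (length(datasets) < 2) stopf("hierarchical fitting needs >= 2 participants")
  info <- model_info(model_id)
  st <- stack_cohort(datasets, info, config)
  if (any(st$n_trials < 20))
    stopf("each dataset must have at least 20 choice trials")
  npart <- length(datasets)
  k <- info$k
  mu_bound <- 8          # flat prior range on the unconstrained scale

  # shared crude ML initialisation, jittered per chain
  init_cfg <- fit_config(n_restarts = 3, seed = derive_seed(config$seed, 7),
                         beta_max = config$beta_max,
                         init_pred = config$init_pred)
  theta0 <- t(vapply(datasets, function(d)
    pmin(pmax(fit_ml(d, model_id, init_cfg)$estimates_unc, -4), 4),
    numeric(k)))
  colnames(theta0) <- info$free

  n_iter <- config$n_warmup + config$n_samples
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chains[[ch]] <- with_seed(derive_seed(config$seed, 1000 + ch),
      run_chain(theta0, info, st, config, n_iter, mu_bound))
  }

  keep <- (config$n_warmup + 1):n_iter
  # R-hat over participants x params + group mu/sigma
  rh <- c()
  for (j in seq_len(k)) {
    for (i in seq_len(npart)) {
      d <- vapply(chains, function(c) c$theta[keep, i, j], numeric(length(keep)))
      rh[sprintf("theta[%d,%s]", i, info$free[j])] <- split_rhat(d)
    }
    rh[paste0("mu_", info$free[j])] <-
      split_rhat(vapply(chains, function(c) c$mu[keep, j], numeric(length(keep))))
    rh[paste0("sigma_", info$free[j])] <-
      split_rhat(vapply(chains, function(c) c$sigma[keep, j], numeric(length(keep))))
  }
  max_rhat <- max(rh)

  # posterior means on the natural scale
  nat_sum <- matrix(0, npart, k)
  for (ch in chains) {
    for (j in seq_len(k)) {
      v <- plogis(ch$theta[keep, , j])
      if (info$free[j] == "beta") v <- v * config$beta_max
      nat_sum[, j] <- nat_sum[, j] + colMeans(v)
    }
  }
  nat <- nat_sum / length(chains)
  colnames(nat) <- info$free
  ids <- vapply(datasets, function(d) as.character(d$participant_id[1] %||% NA),
                character(1))
  est <- data.frame(participant_id = ids, nat, check.names = FALSE)

  mu_draws <- do.call(rbind, lapply(chains, function(c) c$mu[keep, , drop = FALSE]))
  sg_draws <- do.call(rbind, lapply(chains, function(c) c$sigma[keep, , drop = FALSE]))
  colnames(mu_draws) <- colnames(sg_draws) <- info$free
  group <- data.frame(parameter = info$free,
                      mu_unc = colMeans(mu_draws),
                      sigma_unc = colMeans(sg_draws))
  group$mean_natural <- with_seed(derive_seed(config$seed, 999),
    vapply(seq_len(k), function(j) {
      v <- plogis(rnorm(4000, group$mu_unc[j], group$sigma_unc[j]))
      if (info$free[j] == "beta") v <- v * config$beta_max
      mean(v)
    }, numeric(1)))

  theta_hat <- t(vapply(seq_len(npart), function(i)
    to_unconstrained(unlist(est[i, info$free]), info, config$beta_max),
    numeric(k)))
  colnames(theta_hat) <- info$free
  ll_point <- sum(cohort_loglik(theta_hat, info, st, config))
  structure(list(model_id = model_id, method = "hierarchical",
                 estimates = est, group = group, rhat = rh,
                 max_rhat = max_rhat,
                 converged = max_rhat < config$rhat_threshold,
                 loglik = ll_point, k = k, n = sum(st$n_trials),
                 n_trials = st$n_trials,
                 draws_group = list(mu = mu_draws, sigma = sg_draws),
                 config = config),
            class = "fit_result")
}

# one MCMC chain; returns theta draws (iter x part x k), mu, sigma
run_chain <- function(theta0, info, st, config, n_iter, mu_bound) {
  npart <- nrow(theta0); k <- ncol(theta0)
  theta <- theta0 + matrix(rnorm(npart * k, 0, 0.3), npart, k)
  mu <- colMeans(theta)
  sigma <- pmax(apply(theta, 2, sd), 0.3)
  ll <- cohort_loglik(theta, info, st, config)

  step <- matrix(0.4, npart, k)
  sstep <- rep(0.3, k)
  nstep <- rep(0.15, k); nacc <- rep(0, k)
  acc_w <- matrix(0, npart, k); acc_n <- 0
  out_t <- array(NA_real_, c(n_iter, npart, k))
  out_m <- matrix(NA_real_, n_iter, k)
  out_s <- matrix(NA_real_, n_iter, k)
  warm <- config$n_warmup

  for (it in seq_len(n_iter)) {
    # participant block: coordinate-wise RW Metropolis, all participants'
    # proposals for one coordinate evaluated in a single C++ call
    for (j in seq_len(k)) {
      prop <- theta
      prop[, j] <- theta[, j] + rnorm(npart) * step[, j]
      ll_p <- cohort_loglik(prop, info, st, config)
      dpr <- dnorm(prop[, j], mu[j], sigma[j], log = TRUE) -
        dnorm(theta[, j], mu[j], sigma[j], log = TRUE)
      acc <- log(runif(npart)) < (ll_p + dpr - ll)
      theta[acc, j] <- prop[acc, j]
      ll[acc] <- ll_p[acc]
      acc_w[, j] <- acc_w[, j] + acc
    }
    acc_n <- acc_n + 1

    # group means: conjugate normal (flat prior), kept inside the range
    mu_new <- rnorm(k, colMeans(theta), sigma / sqrt(npart))
    mu <- pmin(pmax(mu_new, -mu_bound), mu_bound)

    # group SDs: RW on log scale, half-normal(0,10) prior (+ Jacobian)
    ls_prop <- log(sigma) + rnorm(k) * sstep
    s_prop <- exp(ls_prop)
    dev <- sweep(theta, 2, mu)
    lt_cur <- -npart * log(sigma) - colSums(dev^2) / (2 * sigma^2) -
      sigma^2 / 200 + log(sigma)
    lt_prop <- -npart * log(s_prop) - colSums(dev^2) / (2 * s_prop^2) -
      s_prop^2 / 200 + ls_prop
    sacc <- log(runif(k)) < (lt_prop - lt_cur)
    sigma[sacc] <- s_prop[sacc]

    # interleaved non-centered update: move (mu_j, sigma_j) jointly while
    # holding the standardised participant deviates fixed, so the chain
    # can traverse the funnel when sigma_j is small
    for (j in seq_len(k)) {
      mu_n <- mu[j] + rnorm(1) * nstep[j]
      ls_n <- log(sigma[j]) + rnorm(1) * nstep[j]
      s_n <- exp(ls_n)
      prop <- theta
      prop[, j] <- mu_n + (s_n / sigma[j]) * (theta[, j] - mu[j])
      if (abs(mu_n) > mu_bound) next
      ll_p <- cohort_loglik(prop, info, st, config)
      lacc <- sum(ll_p - ll) - s_n^2 / 200 + ls_n +
        sigma[j]^2 / 200 - log(sigma[j])
      if (log(runif(1)) < lacc) {
        theta <- prop; ll <- ll_p; mu[j] <- mu_n; sigma[j] <- s_n
        nacc[j] <- nacc[j] + 1
      }
    }

    # warm-up step-size adaptation toward ~40% coordinate acceptance
    if (it <= warm && it %% 25 == 0) {
      rate <- acc_w / acc_n
      step <- step * ifelse(rate < 0.30, 1 / 1.4,
                            ifelse(rate > 0.55, 1.4, 1))
      nrate <- nacc / acc_n
      nstep <- nstep * ifelse(nrate < 0.15, 1 / 1.4,
                              ifelse(nrate > 0.40, 1.4, 1))
      acc_w[] <- 0; nacc[] <- 0; acc_n <- 0
    }
    out_t[it, , ] <- theta
    out_m[it, ] <- mu
    out_s[it, ] <- sigma
  }
  list(theta = out_t, mu = out_m, sigma = out_s, step = step)
}
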