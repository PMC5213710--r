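# Independent oracles, deliberately written as plain explicit loops /
# closed forms so they share no code path with the package internals.

# brute-force trial-by-trial choice log-likelihood
oracle_loglik <- function(data, model_id, pars, max_rm = 20, max_em = 15,
                          init = 0.5, observer_pred = NULL) {
  df <- as.data.frame(data)
  df <- df[df$trial_type != "attention", ]
  df <- df[order(df$session, df$trial), ]
  linear <- model_id %in% c("M1", "M2", "M3")
  uses_obs <- model_id %in% c("M3", "M6")
  a_r <- if (model_id %in% c("M2", "M5")) pars[["alpha_rew"]] else pars[["alpha"]]
  a_e <- if (model_id %in% c("M2", "M5")) pars[["alpha_eff"]] else pars[["alpha"]]
  g <- if (linear) pars[["gamma"]] else NA
  l <- pars[["lambda"]]; b <- pars[["beta"]]
  ll <- 0
  last_session <- NA
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    if (!identical(row$session, last_session)) {
      rA <- rB <- eA <- eB <- init
      last_session <- row$session
    }
    if (uses_obs) {
      pr <- observer_pred[i, ]
      prA <- pr[["rew_A"]]; prB <- pr[["rew_B"]]
      peA <- pr[["eff_A"]]; peB <- pr[["eff_B"]]
    } else { prA <- rA; prB <- rB; peA <- eA; peB <- eB }
    fx <- if (is.na(row$fixed_option)) "" else row$fixed_option
    if (fx == "A") { prA <- row$rm_A / max_rm; peA <- row$em_A / max_em }
    if (fx == "B") { prB <- row$rm_B / max_rm; peB <- row$em_B / max_em }
    if (linear) {
      uA <- (1 - g) * row$prob_A + g * (l * prA - (1 - l) * peA)
      uB <- (1 - g) * row$prob_B + g * (l * prB - (1 - l) * peB)
    } else {
      uA <- (1 - l) * row$prob_A * prA - l * peA
      uB <- (1 - l) * row$prob_B * prB - l * peB
    }
    pA <- exp(b * uA) / (exp(b * uA) + exp(b * uB))
    ll <- ll + log(if (row$choice == "A") pA else 1 - pA)
    if (!uses_obs) {
      if (fx != "A") {
        rA <- rA + a_r * (row$rm_A / max_rm - rA)
        eA <- eA + a_e * (row$em_A / max_em - eA)
      }
      if (fx != "B") {
        rB <- rB + a_r * (row$rm_B / max_rm - rB)
        eB <- eB + a_e * (row$em_B / max_em - eB)
      }
    }
  }
  ll
}

# unpenalised logistic regression by Newton-Raphson (IRLS)
oracle_irls <- function(X, y, maxit = 200) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    p <- 1 / (1 + exp(-drop(X %*% beta)))
    W <- p * (1 - p)
    grad <- t(X) %*% (y - p)
    H <- t(X) %*% (X * W)
    delta <- solve(H, grad)
    beta <- beta + delta
    if (max(abs(delta)) < 1e-12) break
  }
  drop(beta)
}

# partial Spearman by explicit rank residualisation (normal equations)
oracle_partial_spearman <- function(x, y, Z = NULL) {
  rx <- rank(x); ry <- rank(y)
  if (!is.null(Z) && NCOL(Z) > 0) {
    A <- cbind(1, apply(as.matrix(Z), 2, rank))
    proj <- function(v) v - A %*% solve(t(A) %*% A, t(A) %*% v)
    rx <- drop(proj(rx)); ry <- drop(proj(ry))
  }
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# random small hand-style choice table (valid column dictionary)
make_toy_data <- function(n_trials = 12, seed = 1, sessions = 1,
                          p_special = 0.15) {
  set.seed(seed)
  per <- n_trials %/% sessions
  df <- do.call(rbind, lapply(seq_len(sessions), function(s) {
    tt <- ifelse(runif(per) < p_special, "special", "standard")
    fx <- ifelse(tt == "special", sample(c("A", "B"), per, replace = TRUE),
                 NA_character_)
    d <- data.frame(
      participant_id = "toy", group = 0L, session = s, trial = seq_len(per),
      trial_type = tt,
      prob_A = sample(seq(0.1, 0.9, 0.1), per, TRUE),
      prob_B = sample(seq(0.1, 0.9, 0.1), per, TRUE),
      rm_A = round(runif(per, 0, 20), 1), rm_B = round(runif(per, 0, 20), 1),
      em_A = round(runif(per, 0, 15), 1), em_B = round(runif(per, 0, 15), 1),
      fixed_option = fx,
      choice = sample(c("A", "B"), per, TRUE),
      reward_real = rbinom(per, 1, 0.5))
    d$rm_A[!is.na(fx) & fx == "A"] <- 7.5
    d$rm_B[!is.na(fx) & fx == "B"] <- 7.5
    d$em_A[!is.na(fx) & fx == "A"] <- 4
    d$em_B[!is.na(fx) & fx == "B"] <- 12
    d
  }))
  structure(df, class = c("choice_data", "data.frame"))
}

random_model_pars <- function(model_id, seed) {
  set.seed(seed)
  vals <- list(alpha = runif(1, 0.05, 0.95),
               alpha_rew = runif(1, 0.05, 0.95),
               alpha_eff = runif(1, 0.05, 0.95),
               gamma = runif(1, 0.05, 0.95),
               lambda = runif(1, 0.05, 0.95),
               beta = runif(1, 0.5, 10))
  vals[relmrs::model_info(model_id)$free]
}
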