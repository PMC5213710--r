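test_that("the prediction update moves by alpha times the prediction error", {
  expect_equal(rw_update(5, 10, 0.5), 7.5)
  expect_equal(rw_update(3, 12, 0), 3)
  expect_equal(rw_update(3, 12, 1), 12)
  expect_error(rw_update(3, 12, 1.2), "allowed range")
})

test_that("linear utility weighs probability against learnt magnitudes", {
  expect_equal(utility_linear(0.7, 0.5, 0.4, gamma = 0.4, lambda = 0.6),
               0.6 * 0.7 + 0.4 * (0.6 * 0.5 - 0.4 * 0.4))
  # gamma = 0: probability only
  expect_equal(utility_linear(0.3, 0.9, 0.1, gamma = 0, lambda = 0.7), 0.3)
  # gamma = 1, lambda = 1: reward prediction only
  expect_equal(utility_linear(0.3, 0.9, 0.1, gamma = 1, lambda = 1), 0.9)
})

test_that("multiplicative utility multiplies probability into reward", {
  expect_equal(utility_multiplicative(0.5, 0.8, 0.2, lambda = 0.25),
               0.75 * 0.5 * 0.8 - 0.25 * 0.2)
  expect_equal(utility_multiplicative(0.5, 0.8, 0.2, lambda = 1), -0.2)
  expect_equal(utility_multiplicative(0.5, 0.8, 0.2, lambda = 0), 0.4)
})

test_that("softmax is normalised, symmetric and monotone", {
  expect_equal(softmax_prob(0.4, 0.4, 3), 0.5)
  expect_equal(softmax_prob(2, -1, 0), 0.5)
  expect_equal(softmax_prob(0.5, 0, 1), 1 / (1 + exp(-0.5)))
  # normalisation to machine precision for a range of inputs
  for (d in c(-50, -2, 0, 1e-8, 3, 80))
    expect_equal(softmax_prob(d, 0, 2) + softmax_prob(0, d, 2), 1)
  # strictly increasing in the utility difference and in beta
  diffs <- seq(-2, 2, length.out = 9)
  p <- softmax_prob(diffs, 0, 1.5)
  expect_true(all(diff(p) > 0))
  expect_true(all(diff(softmax_prob(1, 0, c(0.5, 1, 2, 8))) > 0))
  # numerically stable for huge beta*delta
  expect_equal(softmax_prob(1, 0, 5000), 1)
  expect_error(softmax_prob(Inf, 0, 1), "finite")
})

test_that("sequence likelihood matches the brute-force trial loop", {
  for (i in 1:25) {
    for (model in c("M1", "M2", "M4", "M5")) {
      d <- make_toy_data(n_trials = sample(8:20, 1),
                         seed = 1000 * i + match(model, paste0("M", 1:6)),
                         sessions = sample(1:2, 1))
      pars <- random_model_pars(model, seed = i + 77)
      p <- do.call(model_params, c(list(model_id = model), pars))
      expect_equal(sequence_log_likelihood(d, p),
                   oracle_loglik(d, model, pars),
                   tolerance = 1e-10,
                   label = sprintf("%s dataset %d", model, i))
    }
  }
})

test_that("observer-based models agree with the oracle given the same predictions", {
  for (i in 1:10) {
    d <- make_toy_data(n_trials = 16, seed = 400 + i)
    obs <- bayes_observer_predictions(d)
    for (model in c("M3", "M6")) {
      pars <- random_model_pars(model, seed = i)
      p <- do.call(model_params, c(list(model_id = model), pars))
      expect_equal(sequence_log_likelihood(d, p),
                   oracle_loglik(d, model, pars, observer_pred = obs),
                   tolerance = 1e-10)
    }
  }
})

test_that("beta = 0 gives the closed-form random-choice likelihood", {
  d <- make_toy_data(n_trials = 18, seed = 5)
  p <- model_params("M1", alpha = 0.3, gamma = 0.7, lambda = 0.4, beta = 0)
  expect_equal(sequence_log_likelihood(d, p), 18 * log(0.5))
})

test_that("likelihood is additive over sessions", {
  d1 <- make_toy_data(n_trials = 15, seed = 6)
  d2 <- d1; d2$session <- 2           # identical second session
  both <- structure(rbind(as.data.frame(d1), as.data.frame(d2)),
                    class = class(d1))
  p <- model_params("M1", alpha = 0.4, gamma = 0.5, lambda = 0.6, beta = 3)
  expect_equal(sequence_log_likelihood(both, p),
               2 * sequence_log_likelihood(d1, p))
})

test_that("with gamma = 0 the likelihood ignores magnitude outcomes", {
  d <- make_toy_data(n_trials = 20, seed = 7)
  p <- model_params("M1", alpha = 0.3, gamma = 0, lambda = 0.6, beta = 4)
  ll <- sequence_log_likelihood(d, p)
  perm <- d
  perm$rm_A <- rev(d$rm_A); perm$rm_B <- sample(d$rm_B)
  perm$em_A <- sample(d$em_A); perm$em_B <- rev(d$em_B)
  expect_equal(sequence_log_likelihood(perm, p), ll)
})

test_that("M2 with equal learning rates reduces exactly to M1", {
  d <- make_toy_data(n_trials = 20, seed = 8)
  p1 <- model_params("M1", alpha = 0.35, gamma = 0.6, lambda = 0.55, beta = 5)
  p2 <- model_params("M2", alpha_rew = 0.35, alpha_eff = 0.35, gamma = 0.6,
                     lambda = 0.55, beta = 5)
  expect_identical(sequence_log_likelihood(d, p1),
                   sequence_log_likelihood(d, p2))
})

test_that("invalid parameters are rejected at construction", {
  expect_error(model_params("M1", alpha = 0.5, gamma = 1.3, lambda = 0.5,
                            beta = 2), "allowed range")
  expect_error(model_params("M1", alpha = 0.5, gamma = 0.5, lambda = 0.5,
                            beta = -1), "beta")
  expect_error(model_params("M4", alpha = 0.5, gamma = 0.5, lambda = 0.5,
                            beta = 2), "does not use")
  expect_error(model_params("M1", alpha = 0.5, lambda = 0.5, beta = 2),
               "needs parameter")
})

test_that("missing feedback on a learning trial is rejected", {
  d <- make_toy_data(n_trials = 10, seed = 9)
  d$rm_A[4] <- NA
  p <- model_params("M1", alpha = 0.3, gamma = 0.5, lambda = 0.5, beta = 2)
  expect_error(sequence_log_likelihood(d, p), "missing")
})

test_that("observer predictions start at the prior and track constants", {
  d <- make_toy_data(n_trials = 30, seed = 10, p_special = 0)
  d$rm_A <- 16; d$rm_B <- 4; d$em_A <- 3; d$em_B <- 12
  obs <- bayes_observer_predictions(d)
  expect_equal(unname(obs[1, ]), rep(0.5, 4))
  expect_equal(unname(obs[30, ]), c(16 / 20, 4 / 20, 3 / 15, 12 / 15),
               tolerance = 0.05)
})

test_that("observer predictions are nearly collinear with fitted RW predictions", {
  sch <- default_schedule()
  p <- model_params("M1", alpha = 0.35, gamma = 0.7, lambda = 0.5, beta = 6)
  d <- simulate_agent(sch, p, seed = 21)
  obs <- bayes_observer_predictions(d)
  rw <- rw_predictions(d, alpha_rew = 0.35)
  # drop the first trials of each session where both sit at the prior
  keep <- -(1:3)
  r <- cor(as.vector(obs[keep, ]), as.vector(rw[keep, ]))
  expect_gt(r, 0.95)
})
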