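# independent coder for the stay/switch frame used in the hand-check below
code_row <- function(d, t, lag, col_a, col_b) {
  stay <- d$choice[t - 1]
  s <- if (stay == "A") 1 else -1
  s * (d[[col_a]][t - lag] - d[[col_b]][t - lag])
}

test_that("the design codes regressors in the stay-minus-switch frame", {
  d <- data.frame(
    participant_id = "h1", group = 0L, session = 1, trial = 1:6,
    trial_type = "standard",
    prob_A = c(0.2, 0.5, 0.8, 0.3, 0.6, 0.9),
    prob_B = c(0.7, 0.4, 0.1, 0.6, 0.2, 0.3),
    rm_A = c(12, 3, 18, 7, 10, 5), rm_B = c(4, 14, 6, 11, 2, 16),
    em_A = c(2, 9, 14, 5, 8, 11), em_B = c(13, 1, 7, 10, 4, 6),
    fixed_option = NA_character_,
    choice = c("A", "B", "B", "A", "B", "B"),
    reward_real = 1)
  d <- structure(d, class = c("choice_data", "data.frame"))
  des <- build_stay_switch_design(d, n_lags = 4)
  expect_equal(nrow(des), 2)                  # trials 5 and 6 analyzable
  expect_equal(des$stay, c(0L, 1L))           # A after A? no: B then B yes
  # hand-coded raw values, z-scored the same way
  raw <- rbind(
    c(prob = code_row(d, 5, 0, "prob_A", "prob_B"),
      RM_1 = code_row(d, 5, 1, "rm_A", "rm_B"),
      RM_2 = code_row(d, 5, 2, "rm_A", "rm_B"),
      RM_3 = code_row(d, 5, 3, "rm_A", "rm_B"),
      RM_4 = code_row(d, 5, 4, "rm_A", "rm_B"),
      EM_1 = code_row(d, 5, 1, "em_A", "em_B"),
      EM_2 = code_row(d, 5, 2, "em_A", "em_B"),
      EM_3 = code_row(d, 5, 3, "em_A", "em_B"),
      EM_4 = code_row(d, 5, 4, "em_A", "em_B")),
    c(code_row(d, 6, 0, "prob_A", "prob_B"),
      code_row(d, 6, 1, "rm_A", "rm_B"), code_row(d, 6, 2, "rm_A", "rm_B"),
      code_row(d, 6, 3, "rm_A", "rm_B"), code_row(d, 6, 4, "rm_A", "rm_B"),
      code_row(d, 6, 1, "em_A", "em_B"), code_row(d, 6, 2, "em_A", "em_B"),
      code_row(d, 6, 3, "em_A", "em_B"), code_row(d, 6, 4, "em_A", "em_B")))
  z <- apply(raw, 2, function(v) (v - mean(v)) / sd(v))
  for (col in colnames(raw))
    expect_equal(des[[col]], unname(z[, col]), label = col)
  # antisymmetry of the frame: coding relative to the switch option
  # negates every regressor
  for (t in 5:6) for (cc in list(c("rm_A", "rm_B"), c("em_A", "em_B"))) {
    stay_frame <- code_row(d, t, 1, cc[1], cc[2])
    sw <- if (d$choice[t - 1] == "A") -1 else 1
    switch_frame <- sw * (d[[cc[1]]][t - 1] - d[[cc[2]]][t - 1])
    expect_equal(switch_frame, -stay_frame)
  }
})

test_that("lags never cross session boundaries", {
  sch <- short_schedule()
  p <- model_params("M1", alpha = 0.3, gamma = 0.6, lambda = 0.5, beta = 5)
  d <- simulate_agent(sch, p, seed = 90)
  des <- build_stay_switch_design(d)
  learn_per_session <- sum(d$session == 1 & d$trial_type != "attention")
  expect_equal(nrow(des), 2 * (learn_per_session - 4))
})

test_that("constant outcomes make z-scoring fail loudly", {
  d <- make_toy_data(n_trials = 12, seed = 91, p_special = 0)
  d$rm_A <- 10; d$rm_B <- 10
  expect_error(build_stay_switch_design(d), "zero variance")
  short <- make_toy_data(n_trials = 4, seed = 92)
  expect_error(build_stay_switch_design(short), "usable trials")
})

test_that("logistic weights match the IRLS oracle", {
  for (i in 1:20) {
    set.seed(130 + i)
    n <- sample(25:30, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    colnames(X) <- c("prob", "RM_1", "EM_1")
    y <- rbinom(n, 1, plogis(0.3 + X %*% c(0.8, 0.5, -0.7)))
    if (length(unique(y)) < 2) next
    des <- structure(data.frame(stay = y, X),
                     class = c("stay_switch_design", "data.frame"))
    w <- fit_stay_switch(des)
    if (isTRUE(attr(w, "penalized"))) next
    expect_equal(as.numeric(w), unname(oracle_irls(cbind(1, X), y)),
                 tolerance = 1e-8)
  }
})

test_that("weights are invariant to duplicating the design rows", {
  set.seed(150)
  X <- matrix(rnorm(40 * 2), 40, 2)
  colnames(X) <- c("prob", "RM_1")
  y <- rbinom(40, 1, plogis(X %*% c(1, -1)))
  d1 <- structure(data.frame(stay = y, X),
                  class = c("stay_switch_design", "data.frame"))
  d2 <- structure(rbind(d1, d1), class = class(d1))
  expect_equal(as.numeric(fit_stay_switch(d1)), as.numeric(fit_stay_switch(d2)),
               tolerance = 1e-6)
})

test_that("null responses give near-zero weights and separation is flagged", {
  set.seed(151)
  X <- matrix(rnorm(2000 * 2), 2000, 2)
  colnames(X) <- c("prob", "RM_1")
  d <- structure(data.frame(stay = rbinom(2000, 1, 0.5), X),
                 class = c("stay_switch_design", "data.frame"))
  w <- fit_stay_switch(d)
  expect_true(all(abs(w) < 0.12))
  # perfectly separated design falls back to the penalised fit
  sep <- structure(data.frame(stay = rep(c(0L, 1L), each = 10),
                              prob = c(rnorm(10, -3), rnorm(10, 3))),
                   class = class(d))
  ws <- fit_stay_switch(sep)
  expect_true(attr(ws, "penalized"))
  expect_true(all(is.finite(ws)))
})

test_that("group tests carry the study's degrees of freedom", {
  set.seed(160)
  n <- 27
  w <- data.frame(b0 = rnorm(n), prob = rnorm(n, 1),
                  RM_1 = rnorm(n, 0.5), RM_2 = rnorm(n, 0.4),
                  RM_3 = rnorm(n, 0.3), RM_4 = rnorm(n, 0.2),
                  EM_1 = rnorm(n, -0.5), EM_2 = rnorm(n, -0.4),
                  EM_3 = rnorm(n, -0.3), EM_4 = rnorm(n, -0.2))
  g <- rep_len(0:1, n)
  gt <- group_tests(w, g)
  expect_equal(gt$t_prob$df, 26)
  expect_equal(gt$F_rm$df1, 1); expect_equal(gt$F_rm$df2, 25)
  expect_equal(gt$F_em$df2, 25)
  # the F equals the squared t of the adjusted intercept
  mw <- rowMeans(w[, paste0("RM_", 1:4)])
  fit <- lm(mw ~ I(g - mean(g)))
  expect_equal(gt$F_rm$F, unname(summary(fit)$coefficients[1, "t value"]^2))
  # all-zero weights give zero statistics
  w0 <- w; w0[] <- 0
  gt0 <- group_tests(w0, g)
  expect_equal(gt0$F_rm$F, 0)
  expect_error(group_tests(w, rep(0, n)), "3 participants per group")
})

test_that("a deterministic agent produces step-like choice curves", {
  sch <- default_schedule()
  p <- model_params("M1", alpha = 0.5, gamma = 1, lambda = 0.5, beta = 500)
  ds <- lapply(1:3, function(i) simulate_agent(sch, p, seed = 170 + i))
  cc <- binned_choice_curves(ds, n_bins = 7)
  cv <- cc$curves[cc$curves$measure == "learnt_value", ]
  expect_lt(cv$p_choose_a[1], 0.15)
  expect_gt(cv$p_choose_a[7], 0.85)
  expect_gt(cc$slopes[["learnt_value"]], 10)
})

test_that("empty bins are reported as missing, not zero", {
  d <- make_toy_data(n_trials = 30, seed = 171, p_special = 0)
  d$prob_A <- 0.9; d$prob_B <- 0.1   # probability difference constant: one bin
  d$prob_A[1] <- 0.1; d$prob_B[1] <- 0.9
  cc <- binned_choice_curves(list(d), n_bins = 5)
  pb <- cc$curves[cc$curves$measure == "probability", ]
  expect_true(any(is.na(pb$p_choose_a)))
  expect_true(all(pb$n[is.na(pb$p_choose_a)] == 0))
})
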