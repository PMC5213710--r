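test_that("agent simulation is deterministic in the seed", {
  sch <- short_schedule()
  p <- model_params("M1", alpha = 0.3, gamma = 0.6, lambda = 0.5, beta = 5)
  a <- simulate_agent(sch, p, seed = 4)
  b <- simulate_agent(sch, p, seed = 4)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_agent(sch, p, seed = 5)
  expect_false(identical(a$choice, c$choice))
  # attention trials carry no choice or feedback
  expect_true(all(is.na(a$choice[a$trial_type == "attention"])))
  expect_true(all(!is.na(a$choice[a$trial_type != "attention"])))
})

test_that("a greedy probability-only agent picks the higher displayed probability", {
  sch <- default_schedule()
  p <- model_params("M1", alpha = 0.3, gamma = 0, lambda = 0.5, beta = 500)
  d <- simulate_agent(sch, p, seed = 6)
  learn <- d[d$trial_type != "attention" & d$prob_A != d$prob_B, ]
  better <- ifelse(learn$prob_A > learn$prob_B, "A", "B")
  expect_gt(mean(learn$choice == better), 0.999)
})

test_that("simulated choice frequencies converge to the softmax probabilities", {
  # outcomes are fixed by the schedule, so the per-trial model probability
  # is identical across replicate agents and the empirical choice rate is
  # binomial around it
  sch <- generate_schedule(schedule_config(n_trials = 24, n_special = 4,
                                           n_attention = 0, n_sessions = 1),
                           seed = 31)
  p <- model_params("M1", alpha = 0.4, gamma = 0.5, lambda = 0.5, beta = 4)
  n_rep <- 10000
  counts <- rep(0, 24)
  arr <- relmrs:::choice_arrays(sch, require_choice = FALSE)
  sc <- relmrs:::scale_opts(sch)
  set.seed(99)
  for (r in seq_len(n_rep)) {
    sim <- relmrs:::cpp_simulate(relmrs:::par5(p), 0L, 0L, arr$prob_a,
                                 arr$prob_b, arr$rm_a, arr$rm_b, arr$em_a,
                                 arr$em_b, arr$fixed_opt, arr$new_block,
                                 sc$max_rm, sc$max_em, sc$init_pred,
                                 matrix(0, 0, 4))
    counts <- counts + (sim$choice == 1L)
  }
  # reference per-trial probabilities by an explicit independent loop
  # (predictions depend only on the schedule because both outcomes are shown)
  rA <- rB <- eA <- eB <- 0.5
  p_a <- numeric(24)
  for (t in seq_len(24)) {
    row <- sch[t, ]
    prA <- rA; prB <- rB; peA <- eA; peB <- eB
    fx <- if (is.na(row$fixed_option)) "" else row$fixed_option
    if (fx == "A") { prA <- row$rm_A / 20; peA <- row$em_A / 15 }
    if (fx == "B") { prB <- row$rm_B / 20; peB <- row$em_B / 15 }
    uA <- 0.5 * row$prob_A + 0.5 * (0.5 * prA - 0.5 * peA)
    uB <- 0.5 * row$prob_B + 0.5 * (0.5 * prB - 0.5 * peB)
    p_a[t] <- 1 / (1 + exp(-4 * (uA - uB)))
    if (fx != "A") {
      rA <- rA + 0.4 * (row$rm_A / 20 - rA); eA <- eA + 0.4 * (row$em_A / 15 - eA)
    }
    if (fx != "B") {
      rB <- rB + 0.4 * (row$rm_B / 20 - rB); eB <- eB + 0.4 * (row$em_B / 15 - eB)
    }
  }
  se <- sqrt(p_a * (1 - p_a) / n_rep)
  expect_true(all(abs(counts / n_rep - p_a) < 3.5 * se))
})

test_that("cohort simulation returns true parameters and honours group SDs", {
  sim <- small_cohort()
  expect_length(sim$datasets, 8)
  expect_equal(nrow(sim$params), 8)
  expect_true(all(c("alpha", "gamma", "lambda", "beta") %in%
                    names(sim$params)))
  expect_true(all(sim$params$gamma >= 0 & sim$params$gamma <= 1))
  # zero group SDs: every participant shares the same parameters
  sp <- cohort_spec(n_participants = 5, sigma = c(alpha = 0, gamma = 0,
                                                  lambda = 0, beta = 0),
                    seed = 3)
  sim0 <- simulate_cohort(sp, schedule = short_schedule())
  expect_equal(max(apply(sim0$params[, c("alpha", "gamma", "lambda", "beta")],
                         2, sd)), 0)
  expect_equal(sim0$params$gamma[1], plogis(0.6), tolerance = 1e-12)
})

test_that("cohort sizing matches the recovery-study design", {
  # 10 sets of 27 participants = 270 simulated agents
  specs <- lapply(1:10, function(s) cohort_spec(n_participants = 27, seed = s))
  expect_equal(sum(vapply(specs, `[[`, 0L, "n_participants")), 270)
})

test_that("the MRS generator hits its correlation targets at large n", {
  g <- plogis(rnorm(1000, 0.6, 0.65))
  rec <- generate_mrs_cohort(mrs_spec(n_participants = 1000, seed = 4), g)
  expect_true(all(abs(rec$grey_frac + rec$white_frac + rec$csf_frac - 1) < 1e-9))
  cm <- correct_measures(rec, "A")
  expect_equal(cor(cm$glutamate, cm$gaba), 0.47, tolerance = 0.08)
  expect_equal(cor(cm$glu_minus_gaba, g), 0.53, tolerance = 0.08)
})

test_that("a null association spec yields a near-zero partial correlation", {
  g <- plogis(rnorm(500, 0.6, 0.65))
  rec <- generate_mrs_cohort(mrs_spec(n_participants = 500, r_assoc = 0,
                                      seed = 5), g)
  cm <- correct_measures(rec, "A")
  ps <- partial_spearman(cm$glu_minus_gaba, g,
                         cm[, c("rel_grey", "rel_white", "total_tissue")])
  expect_lt(abs(ps$rho), 0.1)
})

test_that("high-CRLB records are generated and excluded downstream", {
  g <- plogis(rnorm(20, 0.6, 0.65))
  rec <- generate_mrs_cohort(mrs_spec(n_participants = 20,
                                      frac_high_crlb = 0.25, seed = 6), g)
  kept <- qc_filter(rec)
  expect_equal(nrow(kept), 15)
  expect_equal(nrow(attr(kept, "exclusions")), 5)
  expect_true(all(attr(kept, "exclusions")$crlb > 20))
})

test_that("impossible correlation structures are rejected", {
  expect_error(mrs_spec(r_glu_gaba = 1.2), "allowed range")
  expect_error(mrs_spec(r_assoc = -2), "allowed range")
  expect_error(generate_mrs_cohort(mrs_spec(n_participants = 5, seed = 1),
                                   gammas = rep(0.5, 4)), "length")
  expect_error(generate_mrs_cohort(mrs_spec(n_participants = 5, seed = 1),
                                   gammas = rep(0.5, 5)), "constant")
})
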