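make_records <- function(n = 12, seed = 1) {
  set.seed(seed)
  g <- plogis(rnorm(n, 0.6, 0.65))
  generate_mrs_cohort(mrs_spec(n_participants = n, seed = seed), g)
}

test_that("the CRLB filter excludes strictly above 20%", {
  rec <- make_records(4)
  rec$crlb_gaba <- c(38, 20, 19.99, 0)
  kept <- qc_filter(rec)
  expect_equal(nrow(kept), 3)                  # exactly 20% is retained
  ex <- attr(kept, "exclusions")
  expect_equal(ex$participant_id, rec$participant_id[1])
  expect_match(ex$metabolite, "gaba")
  rec$crlb_gaba <- 0; rec$crlb_glutamate <- 0
  expect_equal(nrow(qc_filter(rec)), 4)
})

test_that("partial-volume corrections follow their printed forms", {
  rec <- data.frame(participant_id = "p1", group = 0, glutamate_raw = 2,
                    gaba_raw = 0.5, creatine_raw = 1, grey_frac = 0.5,
                    white_frac = 0.3, csf_frac = 0.2)
  expect_equal(correct_measures(rec, "A")$glutamate, 2)
  expect_equal(correct_measures(rec, "B")$glutamate, 2 / 0.5)
  expect_equal(correct_measures(rec, "C")$glutamate, 2 / 0.8)   # 2.5
  expect_equal(correct_measures(rec, "D")$glutamate, (2 / 0.5) / (1 / 0.8))
  a <- correct_measures(rec, "A")
  expect_equal(a$rel_grey, 0.5)
  expect_equal(a$total_tissue, 0.8)
  # degenerate volumes: all of B-D are fixed rescalings of the ratio
  rec2 <- rec; rec2$grey_frac <- 1; rec2$white_frac <- 0; rec2$csf_frac <- 0
  for (v in c("B", "C", "D"))
    expect_equal(correct_measures(rec2, v)$glutamate, 2)
  rec3 <- rec; rec3$creatine_raw <- 0
  expect_error(correct_measures(rec3, "A"), "creatine")
  rec4 <- rec; rec4$grey_frac <- 0
  expect_error(correct_measures(rec4, "B"), "tissue")
})

test_that("partial Spearman reduces to ordinary Spearman without covariates", {
  set.seed(20)
  x <- rnorm(30); y <- x + rnorm(30)
  ps <- partial_spearman(x, y)
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(ps$rho, unname(ct$estimate))
  # monotone transform of x gives rho = 1
  expect_equal(partial_spearman(x, exp(x))$rho, 1)
})

test_that("partial Spearman is invariant to monotone transforms", {
  set.seed(21)
  x <- rexp(25); y <- x + rnorm(25); z <- rnorm(25)
  base <- partial_spearman(x, y, data.frame(z = z))
  warped <- partial_spearman(log(x), y^3 + 5, data.frame(z = plogis(z)))
  expect_equal(warped$rho, base$rho, tolerance = 1e-12)
  expect_equal(warped$p, base$p, tolerance = 1e-12)
})

test_that("partial Spearman matches the residualised-rank oracle", {
  for (i in 1:100) {
    set.seed(300 + i)
    n <- sample(8:15, 1)
    q <- sample(0:3, 1)
    x <- rnorm(n); y <- rnorm(n)
    Z <- if (q > 0) matrix(rnorm(n * q), n, q) else NULL
    if (!is.null(Z) && n <= q + 2) next
    ps <- partial_spearman(x, y, Z)
    expect_equal(ps$rho, oracle_partial_spearman(x, y, Z),
                 tolerance = 1e-10, label = sprintf("table %d", i))
  }
})

test_that("rank-deficient covariates are counted by rank in the df", {
  set.seed(22)
  x <- rnorm(20); y <- rnorm(20); z <- rnorm(20)
  ps <- partial_spearman(x, y, data.frame(z1 = z, z2 = z))  # duplicated
  expect_equal(ps$df, 20 - 1 - 2)
  ps2 <- partial_spearman(x, y, data.frame(z1 = z))
  expect_equal(ps$rho, ps2$rho)
})

test_that("permutation p-values agree with the t approximation", {
  set.seed(23)
  x <- rnorm(40); y <- 0.6 * x + rnorm(40)
  pt_ <- partial_spearman(x, y)
  pp <- partial_spearman(x, y, n_perm = 2000, seed = 7)
  expect_equal(pp$rho, pt_$rho)
  expect_lt(abs(pp$p - pt_$p), 0.02)
  expect_error(partial_spearman(rep(1, 10), rnorm(10)), "constant")
})

test_that("the neurochemistry battery reports the full analysis table", {
  set.seed(24)
  n <- 27
  gam <- plogis(rnorm(n, 0.6, 0.65))
  rec <- generate_mrs_cohort(mrs_spec(n_participants = n, seed = 25), gam)
  est <- data.frame(participant_id = rec$participant_id, gamma = gam,
                    beta = runif(n, 2, 12), alpha = runif(n),
                    lambda = runif(n))
  res <- neurochem_behavior_analysis(rec, list(estimates = est), "A")
  expect_setequal(res$correlations$analysis,
                  c("contrast_vs_gamma", "glutamate_vs_gamma",
                    "gaba_vs_gamma", "specificity_gamma",
                    "specificity_beta", "specificity_alpha",
                    "specificity_lambda"))
  expect_equal(res$bonferroni, 0.0125)
  expect_true(all(abs(res$correlations$rho) <= 1))
  # beta screen must not control for beta itself
  expect_equal(res$correlations$df[res$correlations$analysis ==
                                     "specificity_beta"],
               res$correlations$df[res$correlations$analysis ==
                                     "specificity_gamma"] + 1)
  # unmatched participants are rejected by name
  expect_error(neurochem_behavior_analysis(rec,
                 list(estimates = est[-3, ]), "A"), "sim03")
})

test_that("correction variants give similar associations at scale", {
  g <- plogis(rnorm(2000, 0.6, 0.65))
  rec <- generate_mrs_cohort(mrs_spec(n_participants = 2000, seed = 26), g)
  est <- data.frame(participant_id = rec$participant_id, gamma = g,
                    beta = runif(2000, 2, 12), alpha = runif(2000),
                    lambda = runif(2000))
  rhos <- vapply(c("A", "B", "C", "D"), function(v)
    neurochem_behavior_analysis(rec, list(estimates = est),
                                v)$correlations$rho[1], numeric(1))
  expect_true(all(rhos > 0.3))
  expect_lt(max(rhos) - min(rhos), 0.12)
})

test_that("null MRS cohorts are calibrated at the nominal 5% level", {
  n_rej <- 0; n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    set.seed(7000 + s)
    gam <- plogis(rnorm(27, 0.6, 0.65))
    rec <- generate_mrs_cohort(mrs_spec(n_participants = 27, r_assoc = 0,
                                        seed = 90000 + s), gam)
    est <- data.frame(participant_id = rec$participant_id, gamma = gam,
                      beta = runif(27, 2, 12))
    res <- neurochem_behavior_analysis(rec, list(estimates = est), "A")
    p <- res$correlations$p[res$correlations$analysis == "contrast_vs_gamma"]
    if (p < 0.05) n_rej <- n_rej + 1
  }
  # binomial 3 SD band around 0.05 over 200 draws
  expect_gt(n_rej / n_seeds, 0.05 - 3 * sqrt(0.05 * 0.95 / n_seeds))
  expect_lt(n_rej / n_seeds, 0.05 + 3 * sqrt(0.05 * 0.95 / n_seeds))
})

test_that("the generator's association produces the study's sign pattern", {
  pos_glu <- 0; neg_gaba <- 0; n_seeds <- 200
  for (s in seq_len(n_seeds)) {
    set.seed(8000 + s)
    gam <- plogis(rnorm(27, 0.6, 0.65))
    rec <- generate_mrs_cohort(mrs_spec(n_participants = 27,
                                        seed = 95000 + s), gam)
    est <- data.frame(participant_id = rec$participant_id, gamma = gam,
                      beta = runif(27, 2, 12))
    res <- neurochem_behavior_analysis(rec, list(estimates = est), "A")
    co <- res$correlations
    if (co$rho[co$analysis == "glutamate_vs_gamma"] > 0) pos_glu <- pos_glu + 1
    if (co$rho[co$analysis == "gaba_vs_gamma"] < 0) neg_gaba <- neg_gaba + 1
  }
  expect_gt(pos_glu / n_seeds, 0.7)
  expect_gt(neg_gaba / n_seeds, 0.7)
})
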