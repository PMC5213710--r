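#' Simulate one agent's choices on a task schedule
#'
#' The agent carries Rescorla-Wagner (or observer) predictions of both
#' options' reward and effort magnitudes, computes utilities according to
#' its model, samples each choice from the softmax probabilities, observes
#' both options' outcomes (feedback for chosen and unchosen option is
#' displayed every learning trial) and updates its predictions.  Whether a
#' reward was real or hypothetical is sampled from the chosen option's
#' displayed probability.  Attention trials are skipped: no choice, no
#' feedback, no update.
#'
#' @param schedule a [generate_schedule()] result.
#' @param params a [model_params()] object.
#' @param seed integer seed.
#' @param participant_id identifier stored with the dataset.
#' @param group binary confound label (drug/placebo assignment stand-in).
#' @return a `choice_data` data frame: the schedule columns plus `choice`
#'   (`"A"`/`"B"`, `NA` on attention trials), `reward_real` (0/1) and
#'   `participant_id`, `group`.
#' @export
simulate_agent <- function(schedule, params, seed = 1,
                           participant_id = "sim1", group = 0L) {
  if (!inherits(params, "model_params"))
    stopf("`params` must be a model_params object")
  info <- model_info(params$model_id)
  arr <- choice_arrays(schedule, require_choice = FALSE)
  sc <- scale_opts(schedule)
  ep <- ext_pred_matrix(info, arr, sc)
  sim <- with_seed(seed,
    cpp_simulate(par5(params),
                 as.integer(info$utility == "multiplicative"),
                 as.integer(info$learning == "observer"),
                 arr$prob_a, arr$prob_b, arr$rm_a, arr$rm_b,
                 arr$em_a, arr$em_b, arr$fixed_opt, arr$new_block,
                 sc$max_rm, sc$max_em, sc$init_pred, ep))
  df <- as.data.frame(schedule)
  df$choice <- NA_character_
  df$reward_real <- NA_integer_
  learn <- df$trial_type != "attention"
  ord <- order(df$session[learn], df$trial[learn])
  df$choice[learn][ord] <- c("A", "B")[sim$choice]
  df$reward_real[learn][ord] <- sim$reward_real
  df$participant_id <- participant_id
  df$group <- as.integer(group)
  structure(df, config = attr(schedule, "config"), params = params,
            class = c("choice_data", "data.frame"))
}

#' Specification of a simulated cohort
#'
#' Group-level means and SDs are given on the unconstrained (sampling)
#' scale used by the hierarchical fit: logit scale for learning rates,
#' `gamma` and `lambda`, scaled-logit for `beta`.  Per-participant
#' parameters are drawn from these normals and transformed, mirroring the
#' fitting model's generative assumptions.  The defaults emulate a
#' plausible study population: median `gamma` about 0.65 with a 95%
#' population range of roughly 0.33-0.92, learning rate about 0.27,
#' `lambda` about 0.55 and `beta` about 7 on a (0, 20) scale.
#'
#' @param n_participants cohort size.
#' @param model_id generating model.
#' @param mu,sigma named numeric vectors of unconstrained-scale group
#'   means/SDs for the model's free parameters.
#' @param beta_max inverse-temperature scale bound.
#' @param seed integer seed.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 27, model_id = "M1",
                        mu = NULL, sigma = NULL, beta_max = 20, seed = 1) {
  info <- model_info(model_id)
  default_mu <- c(alpha = -1.0, alpha_rew = -1.0, alpha_eff = -1.0,
                  gamma = 0.6, lambda = 0.2, beta = -0.62)
  default_sd <- c(alpha = 1.0, alpha_rew = 1.0, alpha_eff = 1.0,
                  gamma = 0.65, lambda = 0.5, beta = 0.5)
  mu <- c(mu, default_mu[setdiff(info$free, names(mu))])[info$free]
  sigma <- c(sigma, default_sd[setdiff(info$free, names(sigma))])[info$free]
  if (any(sigma < 0)) stopf("group SDs must be non-negative")
  if (n_participants < 1) stopf("n_participants must be >= 1")
  structure(list(n_participants = as.integer(n_participants),
                 model_id = model_id, mu = mu, sigma = sigma,
                 beta_max = beta_max, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of agents with parameters drawn from group normals
#'
#' Draws each participant's unconstrained parameters from the group
#' distributions in `spec`, transforms them to the natural scale, and
#' simulates every participant on the same schedule (all participants in
#' the study performed the same two schedules).  The true parameters are
#' returned alongside the datasets for recovery scoring.
#'
#' @param spec a [cohort_spec()].
#' @param schedule optional pre-built schedule; generated from
#'   `schedule_cfg` and the spec seed otherwise.
#' @param schedule_cfg a [schedule_config()].
#' @return a list with `datasets` (list of `choice_data`), `params`
#'   (data frame of true natural-scale parameters), `params_unc`
#'   (unconstrained scale) and `schedule`.
#' @export
simulate_cohort <- function(spec, schedule = NULL,
                            schedule_cfg = schedule_config()) {
  if (!inherits(spec, "cohort_spec")) stopf("`spec` must be a cohort_spec")
  info <- model_info(spec$model_id)
  if (is.null(schedule))
    schedule <- generate_schedule(schedule_cfg, seed = derive_seed(spec$seed, 1))
  n <- spec$n_participants
  theta_unc <- with_seed(derive_seed(spec$seed, 2), {
    m <- matrix(rnorm(n * info$k, mean = rep(spec$mu, each = n),
                      sd = rep(spec$sigma, each = n)), nrow = n)
    colnames(m) <- info$free
    m
  })
  nat <- t(apply(theta_unc, 1, to_natural, info = info,
                 beta_max = spec$beta_max))
  colnames(nat) <- info$free
  group <- rep_len(c(0L, 1L), n)
  datasets <- lapply(seq_len(n), function(i) {
    p <- do.call(model_params, c(list(model_id = spec$model_id),
                                 as.list(nat[i, ])))
    simulate_agent(schedule, p, seed = derive_seed(spec$seed, 100 + i),
                   participant_id = sprintf("sim%02d", i), group = group[i])
  })
  params <- data.frame(participant_id = sprintf("sim%02d", seq_len(n)),
                       group = group, nat, check.names = FALSE)
  list(datasets = datasets, params = params,
       params_unc = data.frame(participant_id = params$participant_id,
                               theta_unc, check.names = FALSE),
       schedule = schedule)
}

#' Specification of a synthetic MRS cohort
#'
#' Controls the statistical structure the neurochemical analyses assume:
#' the glutamate-GABA correlation, the strength of the association between
#' the glutamate-minus-GABA contrast and the use-of-learnt-information
#' parameter `gamma`, measurement scales, and the fraction of records
#' given a GABA Cramer-Rao lower bound above the 20% quality threshold.
#' Default targets follow the study population: r(Glu, GABA) = 0.47 and a
#' contrast-gamma association of 0.53.
#'
#' @param n_participants cohort size.
#' @param r_glu_gaba target glutamate-GABA correlation, in (-1, 1).
#' @param r_assoc target correlation of (Glu - GABA) with `gamma`.
#' @param mean_glu,mean_gaba mean creatine ratios.
#' @param sd_ratio common SD of the two creatine ratios.
#' @param mean_cr,sd_cr creatine amplitude distribution (arbitrary units).
#' @param frac_high_crlb fraction of records with GABA CRLB above 20%.
#' @param tissue_noise SD of the grey/white tissue-fraction draws.
#' @param seed integer seed.
#' @return an `mrs_spec` list.
#' @export
mrs_spec <- function(n_participants = 27, r_glu_gaba = 0.47,
                     r_assoc = 0.53, mean_glu = 1.2, mean_gaba = 0.25,
                     sd_ratio = 0.08, mean_cr = 8, sd_cr = 0.5,
                     frac_high_crlb = 0, tissue_noise = 0.02, seed = 1) {
  check_range(r_glu_gaba, "r_glu_gaba", -1, 1)
  check_range(r_assoc, "r_assoc", -1, 1)
  if (r_glu_gaba <= -1 + .Machine$double.eps)
    stopf("r_glu_gaba = -1 gives a degenerate (non-positive-definite) structure")
  structure(list(n_participants = as.integer(n_participants),
                 r_glu_gaba = r_glu_gaba, r_assoc = r_assoc,
                 mean_glu = mean_glu, mean_gaba = mean_gaba,
                 sd_ratio = sd_ratio, mean_cr = mean_cr, sd_cr = sd_cr,
                 frac_high_crlb = frac_high_crlb,
                 tissue_noise = tissue_noise, seed = as.integer(seed)),
            class = "mrs_spec")
}

#' Generate a synthetic MRS cohort keyed to behavioral parameters
#'
#' Builds per-participant spectral-fit amplitudes (glutamate, GABA,
#' creatine), tissue fractions and CRLB quality fields such that (i) the
#' glutamate and GABA creatine ratios correlate at the configured level,
#' and (ii) the glutamate-minus-GABA contrast correlates with the supplied
#' `gamma` values at the configured strength.  The construction decomposes
#' the two ratios into a shared component and a half-difference whose
#' variances are solved from the target correlation; the difference mixes
#' standardised `gamma` with independent noise.
#'
#' @param spec an [mrs_spec()].
#' @param gammas numeric vector of per-participant `gamma` values
#'   (length `spec$n_participants`).
#' @param group optional binary group labels (defaults to alternating).
#' @param participant_id optional identifiers.
#' @return a data frame of MRS records (class `mrs_records`): amplitudes,
#'   `crlb_glutamate`, `crlb_gaba`, `grey_frac`, `white_frac`, `csf_frac`,
#'   `group`.
#' @export
generate_mrs_cohort <- function(spec, gammas, group = NULL,
                                participant_id = NULL) {
  if (!inherits(spec, "mrs_spec")) stopf("`spec` must be an mrs_spec")
  n <- spec$n_participants
  if (length(gammas) != n)
    stopf("length(gammas) = %d but spec$n_participants = %d",
          length(gammas), n)
  r_gg <- spec$r_glu_gaba
  # shared/difference decomposition: glu = m + d/2, gaba = m - d/2 with
  # var chosen so cor(glu, gaba) hits the target; total variance 1 each.
  v_d4 <- (1 - r_gg) / 2          # var(d)/4
  v_m <- (1 + r_gg) / 2
  z_g <- as.numeric(scale(gammas))
  if (any(!is.finite(z_g))) stopf("`gammas` must not be constant")
  with_seed(spec$seed, {
    eps <- rnorm(n)
    d <- 2 * sqrt(v_d4) * (spec$r_assoc * z_g + sqrt(1 - spec$r_assoc^2) * eps)
    m <- rnorm(n, 0, sqrt(v_m))
    glu_ratio <- spec$mean_glu + spec$sd_ratio * (m + d / 2)
    gaba_ratio <- spec$mean_gaba + spec$sd_ratio * (m - d / 2)
    creatine <- rnorm(n, spec$mean_cr, spec$sd_cr)
    grey <- pmin(pmax(rnorm(n, 0.55, spec$tissue_noise), 0.35), 0.75)
    white <- pmin(pmax(rnorm(n, 0.30, spec$tissue_noise), 0.10),
                  0.95 - grey)
    csf <- 1 - grey - white
    crlb_glu <- pmax(rnorm(n, 5, 1.5), 0.5)
    crlb_gaba <- pmax(rnorm(n, 12, 3), 1)
    n_hi <- round(spec$frac_high_crlb * n)
    if (n_hi > 0) {
      hi <- sample.int(n, n_hi)
      crlb_gaba[hi] <- runif(n_hi, 25, 45)
    }
  })
  if (is.null(group)) group <- rep_len(c(0L, 1L), n)
  if (is.null(participant_id)) participant_id <- sprintf("sim%02d", seq_len(n))
  structure(data.frame(
    participant_id = participant_id, group = as.integer(group),
    glutamate_raw = glu_ratio * creatine, gaba_raw = gaba_ratio * creatine,
    creatine_raw = creatine, crlb_glutamate = crlb_glu,
    crlb_gaba = crlb_gaba, grey_frac = grey, white_frac = white,
    csf_frac = csf, stringsAsFactors = FALSE),
    class = c("mrs_records", "data.frame"))
}
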