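#' Configuration of a task schedule
#'
#' Describes one session of the reward/effort learning task: 120 learning
#' trials (100 with two drifting options, 20 special-option trials pitting
#' a drifting option against a fixed, pre-trained option) plus 20
#' attention-check trials that carry no feedback and are excluded from all
#' analyses.  Reward magnitudes live on 0-20 pence, effort magnitudes on
#' 0-15 circles; each magnitude's mean drifts pseudorandomly among three
#' levels, only one mean changing at a time, each mean spending an equal
#' number of learning trials at each level.
#'
#' @param n_trials learning trials per session (standard + special).
#' @param n_sessions number of sessions.
#' @param n_special special-option trials per session.
#' @param n_attention attention trials per session (flagged, no feedback).
#' @param rm_levels,em_levels the three magnitude mean levels (pence /
#'   circles).
#' @param rm_range,em_range legal magnitude ranges; draws are clipped here.
#' @param draw_sd_rm,draw_sd_em SD of the per-trial magnitude draws around
#'   the current mean.
#' @param prob_grid values the displayed reward probabilities are drawn
#'   from (independently per option and trial).
#' @param sot_rm fixed special-option reward magnitude (pence).
#' @param sot_em the two fixed special-option effort magnitudes, used
#'   alternately.
#' @return a `schedule_config` list.
#' @export
schedule_config <- function(n_trials = 120, n_sessions = 2, n_special = 20,
                            n_attention = 20,
                            rm_levels = c(5, 10, 15),
                            em_levels = c(3.75, 7.5, 11.25),
                            rm_range = c(0, 20), em_range = c(0, 15),
                            draw_sd_rm = 2, draw_sd_em = 1.5,
                            prob_grid = seq(0.1, 0.9, by = 0.1),
                            sot_rm = 7.5, sot_em = c(4, 12)) {
  if (length(rm_levels) != 3 || length(em_levels) != 3)
    stopf("exactly three magnitude mean levels are required")
  if (n_trials %% 6 != 0)
    stopf(paste("n_trials = %d cannot be divided into equal occupancy of 3",
                "levels visited twice: it must be a multiple of 6"), n_trials)
  block_len <- n_trials / 6
  if (block_len %% 4 != 0)
    stopf(paste("n_trials = %d gives drift blocks of length %g, which cannot",
                "be staggered across 4 magnitudes: n_trials/6 must be a",
                "multiple of 4"), n_trials, block_len)
  if (n_special < 0 || n_special > n_trials)
    stopf("n_special must be between 0 and n_trials")
  structure(list(n_trials = n_trials, n_sessions = n_sessions,
                 n_special = n_special, n_attention = n_attention,
                 rm_levels = sort(rm_levels), em_levels = sort(em_levels),
                 rm_range = rm_range, em_range = em_range,
                 draw_sd_rm = draw_sd_rm, draw_sd_em = draw_sd_em,
                 prob_grid = prob_grid, sot_rm = sot_rm, sot_em = sot_em,
                 block_len = block_len),
            class = "schedule_config")
}

# one magnitude's per-trial level index (1..3) over n learning trials:
# piecewise constant, block boundaries at offset + k*block_len, each level
# occupied exactly n/3 trials, adjacent segments distinct.
level_track <- function(n, block_len, offset) {
  stopifnot(offset >= 0, offset < block_len)
  if (offset == 0) {
    repeat {
      seq6 <- sample(rep(1:3, 2))
      if (all(diff(seq6) != 0)) break
    }
    return(rep(seq6, each = block_len))
  }
  # segments: first (offset), 5 interior full blocks, last (block_len-offset);
  # first and last share a level w so occupancy stays exact.
  repeat {
    w <- sample(1:3, 1)
    interior <- sample(c(w, rep(setdiff(1:3, w), each = 2)))
    segs <- c(w, interior, w)
    if (all(diff(segs) != 0)) break
  }
  rep(segs, times = c(offset, rep(block_len, 5), block_len - offset))
}

#' Generate a pseudorandom task schedule
#'
#' Builds the per-trial generative state of the experiment: displayed
#' reward probabilities, drifting magnitude means for both options, drawn
#' (noisy, clipped) reward and effort magnitudes, special-option trials
#' with a fixed 7.5-pence option of effort 4 or 12 circles, and
#' interspersed attention trials.  The four magnitude means change level
#' only at staggered block boundaries, so at most one mean moves between
#' consecutive trials, and each mean spends exactly one third of the
#' learning trials at each level.  The same `config` and `seed` always
#' reproduce the identical schedule.
#'
#' @param config a [schedule_config()].
#' @param seed integer seed.
#' @return a `task_schedule` data frame (one row per trial, attention rows
#'   included and flagged) with attributes `config` and `seed`.
#' @examples
#' sch <- generate_schedule(schedule_config(), seed = 1)
#' table(sch$trial_type)
#' @export
generate_schedule <- function(config = schedule_config(), seed = 1) {
  if (!inherits(config, "schedule_config"))
    stopf("`config` must be a schedule_config object")
  with_seed(seed, {
    sessions <- lapply(seq_len(config$n_sessions), function(s)
      generate_session(config, s))
    out <- do.call(rbind, sessions)
  })
  rownames(out) <- NULL
  structure(out, config = config, seed = seed,
            class = c("task_schedule", "data.frame"))
}

generate_session <- function(cfg, session) {
  n <- cfg$n_trials
  bl <- cfg$block_len
  offs <- (0:3) * bl / 4            # staggered: boundaries never coincide
  lv <- cbind(level_track(n, bl, offs[1]), level_track(n, bl, offs[2]),
              level_track(n, bl, offs[3]), level_track(n, bl, offs[4]))
  mean_rm_A <- cfg$rm_levels[lv[, 1]]
  mean_rm_B <- cfg$rm_levels[lv[, 2]]
  mean_em_A <- cfg$em_levels[lv[, 3]]
  mean_em_B <- cfg$em_levels[lv[, 4]]

  clip <- function(x, rng) pmin(pmax(x, rng[1]), rng[2])
  rm_A <- clip(rnorm(n, mean_rm_A, cfg$draw_sd_rm), cfg$rm_range)
  rm_B <- clip(rnorm(n, mean_rm_B, cfg$draw_sd_rm), cfg$rm_range)
  em_A <- clip(rnorm(n, mean_em_A, cfg$draw_sd_em), cfg$em_range)
  em_B <- clip(rnorm(n, mean_em_B, cfg$draw_sd_em), cfg$em_range)

  prob_A <- sample(cfg$prob_grid, n, replace = TRUE)
  prob_B <- sample(cfg$prob_grid, n, replace = TRUE)

  trial_type <- rep("standard", n)
  fixed_option <- rep(NA_character_, n)
  if (cfg$n_special > 0) {
    sot <- sort(sample.int(n, cfg$n_special))
    trial_type[sot] <- "special"
    side <- sample(c("A", "B"), cfg$n_special, replace = TRUE)
    fixed_option[sot] <- side
    em_fixed <- rep_len(cfg$sot_em, cfg$n_special)  # alternate 4 / 12
    a <- sot[side == "A"]; b <- sot[side == "B"]
    rm_A[a] <- cfg$sot_rm; em_A[a] <- em_fixed[side == "A"]
    rm_B[b] <- cfg$sot_rm; em_B[b] <- em_fixed[side == "B"]
  }

  df <- data.frame(session = session, trial = NA_integer_,
                   lt_index = seq_len(n), trial_type = trial_type,
                   prob_A = prob_A, prob_B = prob_B,
                   mean_rm_A = mean_rm_A, mean_rm_B = mean_rm_B,
                   mean_em_A = mean_em_A, mean_em_B = mean_em_B,
                   rm_A = rm_A, rm_B = rm_B, em_A = em_A, em_B = em_B,
                   fixed_option = fixed_option,
                   stringsAsFactors = FALSE)

  # intersperse attention trials: they replicate the prevailing means,
  # carry drawn magnitudes but no usable feedback, and are excluded from
  # analysis and from level-occupancy accounting.
  if (cfg$n_attention > 0) {
    pos <- sort(sample.int(n + 1, cfg$n_attention, replace = TRUE))
    att <- df[pmax(pos - 1, 1), , drop = FALSE]
    att$trial_type <- "attention"
    att$fixed_option <- NA_character_
    att$lt_index <- NA_integer_
    ord <- order(c(seq_len(n), pos - 0.5))
    df <- rbind(df, att)[ord, , drop = FALSE]
  }
  df$trial <- seq_len(nrow(df))
  df
}

#' @export
print.task_schedule <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<task_schedule> %d sessions x %d learning trials (+%d attention), seed %d\n",
              cfg$n_sessions, cfg$n_trials, cfg$n_attention, attr(x, "seed")))
  print(utils::head(as.data.frame(x), 4))
  invisible(x)
}
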