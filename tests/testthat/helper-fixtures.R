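# shared fixtures, built once per test run and memoised

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

default_schedule <- function() fixture("schedule",
  function() generate_schedule(schedule_config(), seed = 101))

# a small M1 cohort used by several fitting/comparison tests
small_cohort <- function() fixture("small_cohort", function()
  simulate_cohort(cohort_spec(n_participants = 8, seed = 202)))

# short two-session schedule for fast fitting tests
short_schedule <- function() fixture("short_schedule", function()
  generate_schedule(schedule_config(n_trials = 48, n_special = 8,
                                    n_attention = 4), seed = 303))
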