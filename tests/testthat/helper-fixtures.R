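# Small programmatic fixtures shared across test files.

# Build an event data frame from parallel vectors, filling optional columns.
make_events <- function(pair_id = "p1", test_code = "mFC", day = 1L,
                        animal_id, behavior, t_start, t_stop,
                        outcome = NA_character_, pellets = NA_integer_,
                        trial = NA_integer_) {
  data.frame(pair_id = pair_id, test_code = test_code, day = as.integer(day),
             trial = as.integer(trial), animal_id = animal_id,
             behavior = behavior, outcome = outcome,
             t_start = t_start, t_stop = t_stop,
             pellets = as.integer(pellets), stringsAsFactors = FALSE)
}

# A clean three-bout log used by several reader tests.
tiny_log <- function() {
  make_events(animal_id = c("A", "B", "A"),
              behavior = c("consumption", "explore_feeder", "pushing"),
              t_start = c(62, 25, 70), t_stop = c(70, 30, 72),
              outcome = c(NA, NA, "successful"),
              pellets = c(6L, NA, NA))
}

# Random bouts within [0, span); possibly several animals/behaviors.
random_bouts <- function(n, span = 900, pair_id = "p1", test_code = "mFC",
                         behaviors = c("explore_feeder", "grooming")) {
  # centisecond resolution, as produced by frame-based video annotation
  starts <- round(runif(n, 0, span - 1), 2)
  durs <- round(runif(n, 0.1, 60), 2)
  make_events(pair_id = pair_id, test_code = test_code,
              animal_id = sample(c("A", "B"), n, replace = TRUE),
              behavior = sample(behaviors, n, replace = TRUE),
              t_start = starts, t_stop = pmin(starts + durs, span))
}

# Independent discretized-overlap oracle: total seconds of bout mass inside
# [lo, hi), measured on a 0.01-s grid of cell midpoints.
grid_overlap <- function(t_start, t_stop, lo, hi, dt = 0.01) {
  mids <- seq(lo + dt / 2, hi - dt / 2, by = dt)
  tot <- 0
  for (i in seq_along(t_start)) {
    tot <- tot + sum(mids >= t_start[i] & mids < t_stop[i]) * dt
  }
  tot
}

# Tube-trial table builder.
make_tube <- function(pair_id = "p1", day = 1L, winner, latency = 4,
                      completed = TRUE) {
  n <- length(winner)
  completed <- rep_len(completed, n)
  latency <- rep_len(latency, n)
  data.frame(pair_id = pair_id, day = as.integer(day), trial = seq_len(n),
             winner = winner,
             latency_s = ifelse(completed, latency, NA_real_),
             completed = completed, stringsAsFactors = FALSE)
}
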