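#' Percentage of successful pushing bouts
#'
#' The fraction of an animal's pushing bouts that actually displaced the
#' partner from the resource, on a bout-count (not duration) basis. With no
#' pushing bouts the ratio is undefined and `NA` is returned rather than 0,
#' so bout-less animals are excluded from (not tied at zero in) downstream
#' comparisons.
#'
#' @param events event data frame; only `behavior == "pushing"` rows are
#'   used, and each must carry an outcome label.
#' @return Percentage in `[0, 100]`, or `NA_real_` with zero bouts.
#' @export
pushing_success_pct <- function(events) {
  push <- events[events$behavior == "pushing", , drop = FALSE]
  if (nrow(push) == 0L) return(NA_real_)
  if (any(!push$outcome %in% .PUSH_OUTCOMES)) {
    stop("pushing bouts must be labeled successful/unsuccessful", call. = FALSE)
  }
  100 * mean(push$outcome == "successful")
}

#' Latency to eat all pellets in one food-competition trial
#'
#' Pair-level latency from time 0 (door opening) to the end of the
#' consumption bout at which the cumulative pellet count of both animals
#' first reaches the 10 pellets available. Missing if fewer than 10 pellets
#' were eaten within the window; a cumulative count exceeding 10 is a
#' validation error (more pellets than were available).
#'
#' @param events events of one mFC/mFCD session.
#' @param window one row of [build_windows()] (must include `time0`).
#' @return Seconds, or `NA_real_`.
#' @export
latency_all_pellets <- function(events, window) {
  cons <- clip_events(events[events$behavior == "consumption", , drop = FALSE],
                      window)
  cons <- cons[!is.na(cons$pellets) & cons$pellets > 0L, , drop = FALSE]
  if (nrow(cons) == 0L) return(NA_real_)
  cons <- cons[order(cons$t_stop), , drop = FALSE]
  cum <- cumsum(cons$pellets)
  if (max(cum) > 10L) {
    stop("cumulative pellet count exceeds the 10 pellets available in a trial",
         call. = FALSE)
  }
  if (max(cum) < 10L) return(NA_real_)
  hit <- which(cum >= 10L)[1]
  cons$t_stop[hit] - window$time0
}

#' Split feeder exploration into anticipatory and reward phases
#'
#' For trial-structured tests, exploration of the feeder/bottle holder is
#' split at time 0: the anticipatory phase is the last `pre_window` seconds
#' of the inter-trial interval (`[t_lo, time0)`, reward present but not
#' accessible) and the reward phase is `[time0, t_hi)`. Durations are exact
#' interval overlaps summed over trials, so anticipatory + reward equals the
#' total windowed exploration.
#'
#' @param events events of one session.
#' @param windows [build_windows()] output.
#' @return Data frame with one row per animal: `animal_id`,
#'   `anticipatory_s`, `reward_s`.
#' @export
split_exploration_by_phase <- function(events, windows) {
  exp_ev <- events[events$behavior == "explore_feeder", , drop = FALSE]
  out <- data.frame(animal_id = .ANIMALS, anticipatory_s = 0, reward_s = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_len(2L)) {
    ev <- exp_ev[exp_ev$animal_id == .ANIMALS[i], , drop = FALSE]
    if (nrow(ev) == 0L) next
    for (k in seq_len(nrow(windows))) {
      w <- windows[k, ]
      out$anticipatory_s[i] <- out$anticipatory_s[i] +
        .overlap_total(ev$t_start, ev$t_stop, w$t_lo, w$time0)
      out$reward_s[i] <- out$reward_s[i] +
        .overlap_total(ev$t_start, ev$t_stop, w$time0, w$t_hi)
    }
  }
  out
}

#' Summarize one session into per-animal behavioral quantities
#'
#' Computes, for each animal of the pair, total duration, bout count and
#' latency to first bout for the four ethogram behaviors. For trial tests
#' durations come from bouts clipped to the per-trial analysis windows; for
#' SC/WC the whole session is used. Consumption units are pellets eaten
#' (mFC/mFCD) or drinking duration in seconds (SC/SCI/WC); percent time
#' consuming is normalized by the effective consumption-observation time
#' (400 s for trial tests: 80 s of reward access over 5 trials; 600 s for the
#' continuous tests), so consumption levels are comparable across tests of
#' different duration.
#'
#' @param events validated events for one (pair, test, day).
#' @param spec matching [default_session_spec()].
#' @param windows optional [build_windows()] output (nominal schedule used
#'   when omitted).
#' @return Data frame with one row per animal; per-trial pair-level
#'   latencies to eat all pellets (mFC/mFCD) are attached as attribute
#'   `"latency_all_pellets"`.
#' @export
summarize_session <- function(events, spec, windows = NULL) {
  stopifnot(inherits(spec, "session_spec"))
  key <- unique(events[, c("pair_id", "test_code", "day")])
  if (nrow(key) > 1L) {
    stop("events must belong to a single (pair, test, day) session", call. = FALSE)
  }
  if (nrow(key) == 1L && key$test_code != spec$test_code) {
    stop("session spec is for ", spec$test_code, " but events are ",
         key$test_code, call. = FALSE)
  }
  windows <- windows %||% build_windows(spec)
  trial_test <- spec$test_code %in% .TRIAL_TESTS

  clipped <- do.call(rbind, lapply(seq_len(nrow(windows)), function(k) {
    clip_events(events, windows[k, ])
  }))
  if (is.null(clipped)) clipped <- .empty_events()

  consume_denom <- if (trial_test) spec$post_window * spec$n_trials else
    spec$session_duration
  phases <- if (trial_test) split_exploration_by_phase(events, windows) else NULL

  lat_all <- NULL
  if (spec$test_code %in% c("mFC", "mFCD")) {
    lat_all <- vapply(seq_len(nrow(windows)), function(k) {
      latency_all_pellets(events, windows[k, ])
    }, numeric(1))
  }

  rows <- lapply(seq_len(2L), function(i) {
    an <- .ANIMALS[i]
    ev <- clipped[clipped$animal_id == an, , drop = FALSE]
    one <- function(beh) {
      b <- ev[ev$behavior == beh, , drop = FALSE]
      list(dur = sum(b$t_stop - b$t_start), n = nrow(b),
           lat = if (nrow(b) > 0L) min(b$t_start) else NA_real_)
    }
    cons <- one("consumption"); push <- one("pushing")
    expl <- one("explore_feeder"); groom <- one("grooming")
    units <- if (spec$test_code %in% c("mFC", "mFCD")) {
      sum(ev$pellets[ev$behavior == "consumption"], na.rm = TRUE)
    } else cons$dur
    data.frame(
      pair_id = if (nrow(key) == 1L) key$pair_id else NA_character_,
      test_code = spec$test_code,
      day = if (nrow(key) == 1L) key$day else NA_integer_,
      animal_id = an,
      consumption_s = cons$dur, consumption_bouts = cons$n,
      consumption_latency_s = cons$lat,
      consumption_units = units,
      percent_time_consuming = 100 * cons$dur / consume_denom,
      pushing_s = push$dur, pushing_bouts = push$n,
      pushing_success_pct = pushing_success_pct(ev),
      explore_s = expl$dur, explore_bouts = expl$n,
      explore_anticipatory_s = if (trial_test) phases$anticipatory_s[i] else NA_real_,
      explore_reward_s = if (trial_test) phases$reward_s[i] else NA_real_,
      grooming_s = groom$dur, grooming_bouts = groom$n,
      mean_latency_all_pellets = if (!is.null(lat_all)) {
        if (all(is.na(lat_all))) NA_real_ else mean(lat_all, na.rm = TRUE)
      } else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "latency_all_pellets") <- lat_all
  out
}
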