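#' Canonical session schedule for a competition test
#'
#' Encodes the trial schedule of each test. The trial-structured tests (mFC,
#' mFCD, SCI) run 5 trials in a 15-min (900 s) session: a 1-min inter-trial
#' interval followed by 2 min of reward access, so nominal time-0 values
#' (the moment the sliding door opens / the bottle is placed) fall at 60,
#' 240, 420, 600 and 780 s. The continuous tests (SC, WC) are a single
#' 10-min (600 s) block. All trial-aligned quantification uses a window of
#' `pre_window` = 40 s before to `post_window` = 80 s after time 0.
#'
#' @param test_code one of `"mFC"`, `"SC"`, `"SCI"`, `"mFCD"`, `"WC"`.
#' @param n_trials,access_duration,session_duration,pre_window,post_window
#'   optional overrides of the canonical schedule.
#' @return An object of class `session_spec`.
#' @export
default_session_spec <- function(test_code, n_trials = NULL,
                                 access_duration = NULL,
                                 session_duration = NULL,
                                 pre_window = 40, post_window = 80) {
  if (!test_code %in% .TEST_CODES) {
    stop("unknown test code: ", test_code, call. = FALSE)
  }
  if (test_code %in% .TRIAL_TESTS) {
    n_trials <- n_trials %||% 5L
    access_duration <- access_duration %||% 120
    iti <- 60
    zeros <- iti + (seq_len(n_trials) - 1L) * (iti + access_duration)
    session_duration <- session_duration %||% (n_trials * (iti + access_duration))
  } else {
    n_trials <- n_trials %||% 1L
    session_duration <- session_duration %||% 600
    access_duration <- access_duration %||% session_duration
    zeros <- 0
  }
  spec <- structure(list(test_code = test_code, n_trials = as.integer(n_trials),
                         trial_zero_times = zeros,
                         access_duration = access_duration,
                         session_duration = session_duration,
                         pre_window = pre_window, post_window = post_window),
                    class = "session_spec")
  .check_spec(spec)
  spec
}

.check_spec <- function(spec) {
  z <- spec$trial_zero_times
  if (length(z) != spec$n_trials) {
    stop("trial_zero_times must have length n_trials", call. = FALSE)
  }
  if (length(z) > 1L) {
    if (any(diff(z) <= 0)) stop("trial_zero_times must be strictly increasing",
                                call. = FALSE)
    if (any(z[-length(z)] + spec$access_duration > z[-1] + 1e-9)) {
      stop("access periods overlap the next trial", call. = FALSE)
    }
  }
  invisible(spec)
}

#' @export
print.session_spec <- function(x, ...) {
  cat(sprintf("<session_spec> %s: %d trial(s), session %.0f s, access %.0f s\n",
              x$test_code, x$n_trials, x$session_duration, x$access_duration))
  cat(sprintf("  time0: %s; window [-%.0f, +%.0f) s\n",
              paste(round(x$trial_zero_times, 1), collapse = ", "),
              x$pre_window, x$post_window))
  invisible(x)
}

#' Build per-trial analysis windows
#'
#' Each trial window spans `[time0 - pre_window, time0 + post_window)`;
#' 120 s for the canonical trial tests. Because door opening / bottle
#' placement was under manual control, observed time-0 values may be supplied
#' per trial and take precedence over the nominal schedule. For the
#' continuous tests the single "window" is the whole session and phases are
#' undefined.
#'
#' @param spec a [default_session_spec()].
#' @param observed_zero_times optional numeric vector, length `n_trials`, of
#'   observed time-0 moments (seconds).
#' @return Data frame with columns `trial`, `t_lo`, `time0`, `t_hi`. The
#'   anticipatory phase of a trial window is `[t_lo, time0)` and the reward
#'   phase `[time0, t_hi)`.
#' @export
build_windows <- function(spec, observed_zero_times = NULL) {
  stopifnot(inherits(spec, "session_spec"))
  if (!spec$test_code %in% .TRIAL_TESTS) {
    return(data.frame(trial = 1L, t_lo = 0, time0 = 0,
                      t_hi = spec$session_duration))
  }
  zeros <- spec$trial_zero_times
  if (!is.null(observed_zero_times)) {
    if (length(observed_zero_times) != spec$n_trials) {
      stop("observed_zero_times must have length n_trials = ", spec$n_trials,
           call. = FALSE)
    }
    zeros <- as.numeric(observed_zero_times)
  }
  w <- data.frame(trial = seq_along(zeros),
                  t_lo = zeros - spec$pre_window,
                  time0 = zeros,
                  t_hi = zeros + spec$post_window)
  if (any(w$t_lo < -1e-9)) {
    stop("invalid schedule: a window extends before session start", call. = FALSE)
  }
  if (nrow(w) > 1L && any(w$t_lo[-1] < w$t_hi[-nrow(w)] - 1e-9)) {
    stop("invalid schedule: analysis windows overlap", call. = FALSE)
  }
  w
}

#' Clip bouts to an analysis window
#'
#' Intersects every bout with the half-open interval `[t_lo, t_hi)`; bouts
#' entirely outside are dropped, boundary-spanning bouts are truncated so
#' that clipped durations sum to the exact interval overlap (duration mass is
#' preserved rather than discarded).
#'
#' @param events event data frame for one session.
#' @param window one row of [build_windows()] output (or any list with
#'   `t_lo`, `t_hi`).
#' @return Clipped event data frame.
#' @export
clip_events <- function(events, window) {
  if (nrow(events) == 0L) return(events)
  s <- pmax(events$t_start, window$t_lo)
  e <- pmin(events$t_stop, window$t_hi)
  keep <- e > s + 1e-12
  out <- events[keep, , drop = FALSE]
  out$t_start <- s[keep]
  out$t_stop <- e[keep]
  rownames(out) <- NULL
  out
}

# total overlap (s) of a set of bouts with [lo, hi)
.overlap_total <- function(t_start, t_stop, lo, hi) {
  sum(pmax(0, pmin(t_stop, hi) - pmax(t_start, lo)))
}
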