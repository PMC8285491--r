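#' Latent generative parameters for one simulated dyad
#'
#' The generator encodes the qualitative structure the competition tests
#' exhibit in real pairs of cage mates with an established hierarchy: a
#' single latent dominance strength `delta` drives pellet allocation in the
#' food competitions, drinking-share asymmetry in the sucrose competitions, a
#' small consumption asymmetry but a strong per-bout pushing-success
#' asymmetry in the water competition, and (together with the body-weight
#' difference) the first tube-test encounters.
#'
#' Default effect sizes are calibrated choices, not values measured in any
#' published dataset (real studies report test statistics, not generative
#' parameters); bout-duration distributions (lognormal, exponential) are
#' stand-ins for unpublished empirical distributions.
#'
#' @param pair_id pair identifier.
#' @param delta latent dominance in `[-1, 1]`; positive means animal A is
#'   dominant. Swapping the animal labels and negating `delta` yields a
#'   distributionally identical dyad.
#' @param weight_a,weight_b body weights in grams (within-pair difference in
#'   age-matched pairs stays below 10%).
#' @param ... overrides for any of the rate/effect-size defaults (see the
#'   returned list).
#' @return Object of class `dyad_params`.
#' @export
dyad_params <- function(pair_id = "pair01", delta = 0.6,
                        weight_a = 370, weight_b = 358, ...) {
  stopifnot(delta >= -1, delta <= 1, weight_a > 0, weight_b > 0)
  p <- list(
    pair_id = pair_id, delta = delta,
    weight_a = weight_a, weight_b = weight_b,
    # food competition
    pellet_gain = 0.2,          # P(pellet to A) = 0.5 + gain * delta
    mfc_latency_median = c(20, 14),  # pair latency-to-all-pellets, day 1 / day 2 (s)
    mfcd_latency_median = 8,    # under food deprivation (s)
    latency_sdlog = 0.3,
    mfc_push_rate = 3,          # pushing bouts / trial / animal
    # sucrose competitions
    sc_share_gain = 0.15,       # drinking share = 0.5 + gain * delta
    sc_share_sd = 0.03,
    sc_push_rate = 4,           # bouts / session / animal (continuous access)
    sci_push_rate = 2,          # bouts / trial / animal (intermittent access)
    # water competition: near-equal totals, strong success asymmetry
    wc_share_gain = 0.02,
    wc_share_sd = 0.02,
    wc_push_rate = 24,          # base bouts / session / animal
    wc_push_asym = 0.3,         # subordinate emits more bouts
    wc_success_gain = 4,
    # pushing bouts generally
    success_gain = 2.5,         # per-bout success logit = gain * delta * side
    push_dur = 2,               # mean bout duration (s)
    # grooming: elevated in the subordinate
    groom_total = 25,           # base grooming (s / session / animal)
    groom_asym = 0.5,
    # tube test
    tube_delta_gain = 5,        # contested-trial win logit gain on delta
    tube_weight_gain = 0.25,    # per percentage point of weight difference
    tube_persist = 0.93,        # P(winner of trial t wins t+1)
    tube_resist_p = 0.095,      # day-2 resistant-trial prob for polarized pairs
    tube_lat_first = 8,         # median latency, first encounter (s)
    tube_lat_stable = 3.5,      # median latency after trial 1 (s)
    tube_lat_sdlog = 0.4)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0L) {
    stop("unknown dyad parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p[names(dots)] <- dots
  structure(p, class = "dyad_params")
}

# n non-overlapping bouts inside [lo, hi) with ~exponential durations;
# returns a plain list of start/stop vectors (assembled into a data frame
# once per session for speed)
.place_bouts <- function(n, lo, hi, mean_dur, min_dur = 0.2) {
  if (n <= 0L || hi - lo <= min_dur) return(NULL)
  starts <- sort(runif(n, lo, hi - min_dur))
  durs <- min_dur + rexp(n, 1 / mean_dur)
  nxt <- c(starts[-1], hi)
  stops <- pmin(starts + durs, nxt - 0.01, hi)
  keep <- stops > starts + 1e-6
  if (!any(keep)) return(NULL)
  list(t_start = starts[keep], t_stop = stops[keep])
}

.ev_rows <- function(pair_id, test_code, day, trial, animal_id, behavior,
                     bouts, outcome = NA_character_, pellets = NA_integer_) {
  if (is.null(bouts)) return(NULL)
  n <- length(bouts$t_start)
  if (n == 0L) return(NULL)
  list(pair_id = rep_len(pair_id, n), test_code = rep_len(test_code, n),
       day = rep_len(as.integer(day), n), trial = rep_len(as.integer(trial), n),
       animal_id = rep_len(animal_id, n), behavior = rep_len(behavior, n),
       outcome = rep_len(outcome, n),
       t_start = bouts$t_start, t_stop = bouts$t_stop,
       pellets = rep_len(as.integer(pellets), n))
}

# column-wise assembly of .ev_rows chunks into one data frame
.bind_rows <- function(rows) {
  rows <- rows[!vapply(rows, is.null, logical(1))]
  cols <- names(rows[[1]])
  out <- lapply(cols, function(cl) unlist(lapply(rows, `[[`, cl),
                                          use.names = FALSE))
  names(out) <- cols
  structure(out, class = "data.frame",
            row.names = seq_along(out[[1]]))
}

# per-bout pushing with logistic success labels for one animal
.push_rows <- function(params, pair_id, test, day, trial, animal, n, lo, hi,
                       gain = NULL) {
  b <- .place_bouts(n, lo, hi, params$push_dur)
  if (is.null(b)) return(NULL)
  side <- if (animal == "A") 1 else -1
  gain <- gain %||% params$success_gain
  p_succ <- plogis(gain * params$delta * side)
  succ <- runif(length(b$t_start)) < p_succ
  .ev_rows(pair_id, test, day, trial, animal, "pushing", b,
           outcome = ifelse(succ, "successful", "unsuccessful"))
}

# resolve residual same-animal same-behavior overlaps by truncation
.sanitize_events <- function(df) {
  key <- interaction(df$animal_id, df$behavior, df$day, df$test_code, drop = TRUE)
  for (grp in split(seq_len(nrow(df)), key, drop = TRUE)) {
    if (length(grp) < 2L) next
    o <- grp[order(df$t_start[grp])]
    nxt <- c(df$t_start[o][-1], Inf)
    df$t_stop[o] <- pmin(df$t_stop[o], nxt - 0.005)
  }
  df <- df[df$t_stop > df$t_start + 1e-6, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Simulate one modified food-competition session
#'
#' Per trial, the 10 available pellets are split `Binomial(10, p)` with
#' `p = 0.5 + pellet_gain * delta`; the pair's latency to eat all pellets is
#' lognormal with median about 20 s on day 1, shrinking on day 2 and further
#' under deprivation; consumption bouts fill the interval from door opening
#' to that latency in proportion to pellet counts (the feeder admits one
#' animal at a time). Pushing bouts are Poisson per trial and animal, each
#' successful with logistic probability favoring the dominant; feeder
#' exploration is elevated in the anticipatory phase (higher for the
#' dominant) and grooming is elevated in the subordinate.
#'
#' @param params [dyad_params()].
#' @param day testing day (1 or 2).
#' @param deprived simulate the food-deprived variant (mFCD; single day).
#' @return Event data frame for one session.
#' @export
simulate_mfc_session <- function(params, day = 1L, deprived = FALSE) {
  stopifnot(inherits(params, "dyad_params"))
  test <- if (deprived) "mFCD" else "mFC"
  spec <- default_session_spec(test)
  delta <- params$delta
  p_a <- .clamp(0.5 + params$pellet_gain * delta, 0.02, 0.98)
  med <- if (deprived) params$mfcd_latency_median else
    params$mfc_latency_median[min(day, 2L)]
  rows <- list()
  for (k in seq_len(spec$n_trials)) {
    z <- spec$trial_zero_times[k]
    n_a <- rbinom(1L, 10L, p_a)
    n_b <- 10L - n_a
    lat <- .clamp(rlnorm(1L, log(med), params$latency_sdlog), 3, 75)
    e0 <- runif(1L, 0.5, 2)
    eat_total <- lat - e0
    first <- if (n_a >= n_b) "A" else "B"
    order_an <- if (first == "A") c("A", "B") else c("B", "A")
    npel <- c(A = n_a, B = n_b)
    t <- z + e0
    for (an in order_an) {
      if (npel[[an]] == 0L) next
      d <- eat_total * npel[[an]] / 10
      rows[[length(rows) + 1L]] <- .ev_rows(
        params$pair_id, test, day, k, an, "consumption",
        list(t_start = t, t_stop = t + d), pellets = npel[[an]])
      t <- t + d
    }
    for (an in .ANIMALS) {
      side <- if (an == "A") 1 else -1
      rows[[length(rows) + 1L]] <- .push_rows(
        params, params$pair_id, test, day, k,
        an, rpois(1L, params$mfc_push_rate), z - 38, z + 78)
      # anticipatory feeder exploration, slightly higher for the dominant
      ant_tot <- .clamp(8 * (1 + 0.4 * delta * side) *
                          (if (deprived) 1.5 else 1), 1, 30)
      nb <- 1L + rpois(1L, 1)
      rows[[length(rows) + 1L]] <- .ev_rows(
        params$pair_id, test, day, k, an, "explore_feeder",
        .place_bouts(nb, z - 39, z - 0.5, ant_tot / nb))
      rows[[length(rows) + 1L]] <- .ev_rows(
        params$pair_id, test, day, k, an, "explore_feeder",
        .place_bouts(1L + rpois(1L, 0.5), z + lat + 0.5, z + 78, 4))
    }
  }
  for (an in .ANIMALS) {
    side <- if (an == "A") 1 else -1
    g_tot <- .clamp(params$groom_total * (1 - params$groom_asym * delta * side),
                    2, 70)
    nb <- 2L + rpois(1L, 1)
    for (j in seq_len(nb)) {
      k <- sample.int(spec$n_trials, 1L)
      z <- spec$trial_zero_times[k]
      rows[[length(rows) + 1L]] <- .ev_rows(
        params$pair_id, test, day, k, an, "grooming",
        .place_bouts(1L, z - 39, z + 78, g_tot / nb))
    }
  }
  .sanitize_events(.bind_rows(rows))
}

#' Simulate one sucrose-competition session
#'
#' Drinking share follows `0.5 + sc_share_gain * delta` plus noise. With
#' continuous access (SC) the pair's drinking bouts alternate over the whole
#' 600-s session with low pushing and feeder exploration; with intermittent
#' access (SCI) drinking is confined to the reward phase of each of 5 trials
#' and anticipatory exploration of the bottle holder is elevated.
#'
#' @param params [dyad_params()].
#' @param day testing day.
#' @param intermittent `TRUE` for SCI, `FALSE` for SC.
#' @return Event data frame for one session.
#' @export
simulate_sc_session <- function(params, day = 1L, intermittent = FALSE) {
  stopifnot(inherits(params, "dyad_params"))
  test <- if (intermittent) "SCI" else "SC"
  spec <- default_session_spec(test)
  delta <- params$delta
  pid <- params$pair_id
  rows <- list()
  share <- .clamp(0.5 + params$sc_share_gain * delta +
                    rnorm(1L, 0, params$sc_share_sd), 0.02, 0.98)
  if (intermittent) {
    for (k in seq_len(spec$n_trials)) {
      z <- spec$trial_zero_times[k]
      tot <- runif(1L, 25, 40)
      e0 <- runif(1L, 0.5, 2)
      d <- c(A = tot * share, B = tot * (1 - share))
      first <- if (delta >= 0) "A" else "B"
      t <- z + e0
      for (an in c(first, setdiff(.ANIMALS, first))) {
        if (d[[an]] < 0.3) next
        rows[[length(rows) + 1L]] <- .ev_rows(
          pid, test, day, k, an, "consumption",
          list(t_start = t, t_stop = t + d[[an]]))
        t <- t + d[[an]] + 0.2
      }
      for (an in .ANIMALS) {
        side <- if (an == "A") 1 else -1
        rows[[length(rows) + 1L]] <- .push_rows(
          params, pid, test, day, k, an,
          rpois(1L, params$sci_push_rate), z - 38, z + 78)
        ant_tot <- .clamp(10 * (1 + 0.3 * delta * side), 1, 30)
        rows[[length(rows) + 1L]] <- .ev_rows(
          pid, test, day, k, an, "explore_feeder",
          .place_bouts(1L + rpois(1L, 1), z - 39, z - 0.5, ant_tot / 2))
      }
    }
  } else {
    tot <- runif(1L, 120, 180)
    ab <- .alternating_bouts(tot * share, tot * (1 - share), 0,
                             spec$session_duration, 20)
    rows[[length(rows) + 1L]] <- .ev_rows(pid, test, day, NA, "A",
                                          "consumption", ab$a)
    rows[[length(rows) + 1L]] <- .ev_rows(pid, test, day, NA, "B",
                                          "consumption", ab$b)
    for (an in .ANIMALS) {
      rows[[length(rows) + 1L]] <- .push_rows(
        params, pid, test, day, NA, an, rpois(1L, params$sc_push_rate),
        0, spec$session_duration)
      rows[[length(rows) + 1L]] <- .ev_rows(
        pid, test, day, NA, an, "explore_feeder",
        .place_bouts(2L + rpois(1L, 1), 0, spec$session_duration, 4))
    }
  }
  for (an in .ANIMALS) {
    side <- if (an == "A") 1 else -1
    g_tot <- .clamp(params$groom_total * 0.6 *
                      (1 - params$groom_asym * delta * side), 1, 50)
    lo <- if (intermittent) 21 else 0
    hi <- if (intermittent) 860 else spec$session_duration
    rows[[length(rows) + 1L]] <- .ev_rows(
      pid, test, day, NA, an, "grooming",
      .place_bouts(2L + rpois(1L, 1), lo, hi, g_tot / 3))
  }
  .sanitize_events(.bind_rows(rows))
}

# interleave two animals' drinking bouts with random gaps across [lo, hi)
.alternating_bouts <- function(tot_a, tot_b, lo, hi, mean_bout) {
  n_a <- max(1L, round(tot_a / mean_bout))
  n_b <- max(1L, round(tot_b / mean_bout))
  wa <- rexp(n_a) + 0.2; wb <- rexp(n_b) + 0.2
  dur <- list(A = tot_a * wa / sum(wa), B = tot_b * wb / sum(wb))
  span <- hi - lo
  busy <- tot_a + tot_b
  stopifnot(busy < span)
  n_tot <- n_a + n_b
  gw <- rexp(n_tot + 1L) + 0.1
  gaps <- (span - busy) * gw / sum(gw)
  # alternate A and B while both have bouts left, then append the remainder
  seq_an <- character(0)
  ia <- ib <- 0L
  for (i in seq_len(n_tot)) {
    take_a <- (i %% 2L == 1L && ia < n_a) || ib >= n_b
    if (take_a) { ia <- ia + 1L; seq_an <- c(seq_an, "A") }
    else { ib <- ib + 1L; seq_an <- c(seq_an, "B") }
  }
  # walk the interleaved sequence once, collecting start/stop vectors
  durs_seq <- numeric(n_tot)
  idx <- c(A = 0L, B = 0L)
  for (i in seq_len(n_tot)) {
    an <- seq_an[i]
    idx[[an]] <- idx[[an]] + 1L
    durs_seq[i] <- dur[[an]][idx[[an]]]
  }
  starts <- lo + cumsum(gaps)[seq_len(n_tot)] + c(0, cumsum(durs_seq))[seq_len(n_tot)]
  stops <- starts + durs_seq
  sel_a <- seq_an == "A"
  list(a = list(t_start = starts[sel_a], t_stop = stops[sel_a]),
       b = list(t_start = starts[!sel_a], t_stop = stops[!sel_a]))
}

#' Simulate one water-competition session
#'
#' Long alternating drinking bouts with near-equal totals (whole-session DI
#' mostly inside the +/-10 noise band), while pushing is asymmetric in the
#' opposite sense: the subordinate emits more (and longer-summed) pushing
#' bouts, but per-bout success strongly favors the dominant, so rank is
#' recoverable from pushing efficiency within the peak-conflict epoch even
#' though consumption is uninformative.
#'
#' @param params [dyad_params()].
#' @return Event data frame for one 600-s session.
#' @export
simulate_wc_session <- function(params) {
  stopifnot(inherits(params, "dyad_params"))
  spec <- default_session_spec("WC")
  delta <- params$delta
  pid <- params$pair_id
  rows <- list()
  tot <- runif(1L, 350, 430)
  share <- .clamp(0.5 + params$wc_share_gain * delta +
                    rnorm(1L, 0, params$wc_share_sd), 0.05, 0.95)
  ab <- .alternating_bouts(tot * share, tot * (1 - share), 0,
                           spec$session_duration, 25)
  rows[[1L]] <- .ev_rows(pid, "WC", 1L, NA, "A", "consumption", ab$a)
  rows[[2L]] <- .ev_rows(pid, "WC", 1L, NA, "B", "consumption", ab$b)
  for (an in .ANIMALS) {
    side <- if (an == "A") 1 else -1
    rate <- params$wc_push_rate * (1 - params$wc_push_asym * delta * side)
    rows[[length(rows) + 1L]] <- .push_rows(
      params, pid, "WC", 1L, NA, an, rpois(1L, max(rate, 0)),
      0, spec$session_duration, gain = params$wc_success_gain)
    rows[[length(rows) + 1L]] <- .ev_rows(
      pid, "WC", 1L, NA, an, "explore_feeder",
      .place_bouts(1L + rpois(1L, 1), 0, spec$session_duration, 3))
    g_tot <- .clamp(params$groom_total * 0.5 *
                      (1 - params$groom_asym * delta * side), 1, 40)
    rows[[length(rows) + 1L]] <- .ev_rows(
      pid, "WC", 1L, NA, an, "grooming",
      .place_bouts(1L + rpois(1L, 1), 0, spec$session_duration, g_tot / 2))
  }
  .sanitize_events(.bind_rows(rows))
}

#' Simulate the two tube-test sessions of a pair
#'
#' Day-1 trial-1 win probability for animal A is
#' `plogis(tube_delta_gain * delta + tube_weight_gain * weight_diff_pct)`
#' (body size matters in the first territorial encounter); afterwards the
#' winner of each trial wins the next with probability `tube_persist`,
#' producing the polarized win rasters and streak structure seen in this
#' test. Latencies are lognormal, with a higher median on the very first
#' encounter and a stable median of about 3.5 s afterwards. On day 2, pairs
#' whose day-1 wins were strongly polarized (|DI| >= 80) produce resistant
#' trials - the loser refuses to enter - with probability `tube_resist_p`
#' per trial (about 9% of day-2 trials under the defaults).
#'
#' @param params [dyad_params()].
#' @return Tube-trial data frame (2 days x 10 trials).
#' @export
simulate_tube_sessions <- function(params) {
  stopifnot(inherits(params, "dyad_params"))
  wm <- mean(c(params$weight_a, params$weight_b))
  dw_pct <- 100 * (params$weight_a - params$weight_b) / wm
  # body size tips the first-day encounters; afterwards only the latent
  # hierarchy decides contested (non-persisting) trials
  p_day <- c(plogis(params$tube_delta_gain * params$delta +
                      params$tube_weight_gain * dw_pct),
             plogis(params$tube_delta_gain * params$delta))
  rows <- list()
  cur <- NULL
  day1_wins_a <- day1_done <- 0L
  for (day in 1:2) {
    polarized <- day == 2L && day1_done > 0L &&
      abs(dominance_index(day1_wins_a, day1_done - day1_wins_a)) >= 80
    for (trial in 1:10) {
      if (polarized && runif(1L) < params$tube_resist_p) {
        rows[[length(rows) + 1L]] <- data.frame(
          pair_id = params$pair_id, day = day, trial = trial,
          winner = "none", latency_s = NA_real_, completed = FALSE,
          stringsAsFactors = FALSE)
        next
      }
      win_a <- if (!is.null(cur) && runif(1L) < params$tube_persist) {
        cur == "A"
      } else {
        runif(1L) < p_day[day]
      }
      cur <- if (win_a) "A" else "B"
      med <- if (day == 1L && trial == 1L) params$tube_lat_first else
        params$tube_lat_stable
      lat <- rlnorm(1L, log(med), params$tube_lat_sdlog)
      if (day == 1L) {
        day1_done <- day1_done + 1L
        day1_wins_a <- day1_wins_a + as.integer(win_a)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pair_id = params$pair_id, day = day, trial = trial, winner = cur,
        latency_s = lat, completed = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a cohort of dyads across all competition tests
#'
#' Generates the full testing battery for `n_pairs` dyads: modified food
#' competition (2 days), sucrose competition with continuous and intermittent
#' access (2 days each), food competition under deprivation (1 day), water
#' competition (1 day) and the tube test (2 days x 10 trials). By default a
#' single latent `delta` per pair is shared across tests (hierarchy as a
#' stable trait); `shared_delta = FALSE` draws an independent delta per test
#' as the null ablation for reliability analyses. Latent dominance magnitudes
#' are drawn uniformly on `[0.25, 1]` with random sign, so most dyads carry a
#' clear hierarchy and a minority sit near the noise band. Each pair consumes
#' its own seeded random stream, so enlarging a cohort does not perturb
#' existing pairs; the whole cohort is reproducible from `seed`.
#'
#' @param n_pairs number of dyads (default 20).
#' @param seed integer seed for the cohort.
#' @param tests subset of `c("mFC","SC","SCI","mFCD","WC","TT")` to simulate.
#' @param shared_delta share one latent delta across tests (default) or draw
#'   an independent delta per test.
#' @param delta optional fixed delta (scalar or length `n_pairs`) overriding
#'   the cohort distribution.
#' @param ... parameter overrides forwarded to [dyad_params()].
#' @return Object of class `dyad_cohort`: `events`, `tube_trials`, `weights`,
#'   `ground_truth`, `seed`, `shared_delta`.
#' @export
simulate_cohort <- function(n_pairs = 20L, seed = 1L,
                            tests = c("mFC", "SC", "SCI", "mFCD", "WC", "TT"),
                            shared_delta = TRUE, delta = NULL, ...) {
  stopifnot(n_pairs >= 1L)
  tests <- match.arg(tests, several.ok = TRUE)
  set.seed(as.integer(seed))
  pair_ids <- sprintf("pair%03d", seq_len(n_pairs))
  pair_seeds <- sample.int(.Machine$integer.max - 1L, n_pairs)
  draw_delta <- function(n) runif(n, 0.25, 1) * sample(c(-1, 1), n, replace = TRUE)

  deltas <- w_a <- w_b <- numeric(n_pairs)
  delta_mat <- matrix(NA_real_, n_pairs, length(tests),
                      dimnames = list(NULL, tests))
  ev_list <- list()
  tube_list <- list()
  for (i in seq_len(n_pairs)) {
    # each pair owns one seeded stream: cohorts are extensible without
    # perturbing existing pairs
    set.seed(pair_seeds[i])
    deltas[i] <- if (!is.null(delta)) rep_len(delta, n_pairs)[i] else
      draw_delta(1L)
    delta_mat[i, ] <- if (shared_delta) deltas[i] else
      draw_delta(length(tests))
    wm <- runif(1L, 340, 395)
    f <- runif(1L, -0.09, 0.09)
    w_a[i] <- wm * (1 + f / 2)
    w_b[i] <- wm * (1 - f / 2)
    base <- dyad_params(pair_id = pair_ids[i], delta = deltas[i],
                        weight_a = w_a[i], weight_b = w_b[i], ...)
    for (tc in tests) {
      par_i <- base
      par_i$delta <- unname(delta_mat[i, tc])
      ev_list[[length(ev_list) + 1L]] <- switch(
        tc,
        mFC = rbind(simulate_mfc_session(par_i, day = 1L),
                    simulate_mfc_session(par_i, day = 2L)),
        mFCD = simulate_mfc_session(par_i, day = 1L, deprived = TRUE),
        SC = rbind(simulate_sc_session(par_i, day = 1L),
                   simulate_sc_session(par_i, day = 2L)),
        SCI = rbind(simulate_sc_session(par_i, day = 1L, intermittent = TRUE),
                    simulate_sc_session(par_i, day = 2L, intermittent = TRUE)),
        WC = simulate_wc_session(par_i),
        TT = {
          tube_list[[length(tube_list) + 1L]] <- simulate_tube_sessions(par_i)
          NULL
        })
    }
  }
  events <- do.call(rbind, ev_list)
  events <- if (is.null(events)) .empty_events() else validate_events(events)
  tube <- if (length(tube_list) > 0L) {
    read_tube_trials(do.call(rbind, tube_list))
  } else NULL
  weights <- data.frame(
    pair_id = rep(pair_ids, each = 2L),
    animal_id = rep(.ANIMALS, n_pairs),
    body_weight_g = as.vector(rbind(w_a, w_b)), stringsAsFactors = FALSE)
  gt <- data.frame(pair_id = pair_ids, delta = deltas,
                   weight_a = w_a, weight_b = w_b,
                   expected_pellet_share = .clamp(0.5 + 0.2 * deltas, 0.02, 0.98),
                   stringsAsFactors = FALSE)
  if (!shared_delta) {
    for (tc in tests) gt[[paste0("delta_", tc)]] <- delta_mat[, tc]
  }
  structure(list(events = events, tube_trials = tube, weights = weights,
                 ground_truth = gt, seed = as.integer(seed),
                 shared_delta = shared_delta, tests = tests),
            class = "dyad_cohort")
}

#' @export
print.dyad_cohort <- function(x, ...) {
  cat(sprintf("<dyad_cohort> %d pairs, tests: %s (seed %d, %s latent delta)\n",
              nrow(x$ground_truth), paste(x$tests, collapse = ", "), x$seed,
              if (x$shared_delta) "shared" else "per-test"))
  cat(sprintf("  %d event rows, %s tube trials\n", nrow(x$events),
              if (is.null(x$tube_trials)) "no" else nrow(x$tube_trials)))
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes `events.csv`, `tube_trials.csv`, `weights.csv` and
#' `ground_truth.csv` (the latent parameters, for recovery studies) in the
#' same CSV dialects the readers consume.
#'
#' @param cohort [simulate_cohort()] output.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dyad_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_events(cohort$events, file.path(dir, "events.csv"))
  if (!is.null(cohort$tube_trials)) {
    write.csv(cohort$tube_trials, file.path(dir, "tube_trials.csv"),
              row.names = FALSE, na = "")
  }
  write.csv(cohort$weights, file.path(dir, "weights.csv"), row.names = FALSE)
  write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  invisible(dir)
}
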