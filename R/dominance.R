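#' Dominance Index
#'
#' The difference in resource consumption between the two animals of a pair,
#' normalized by their summed consumption:
#' `DI = 100 * (A - B) / (A + B)`. Consumption is pellets eaten in the food
#' competitions, drinking duration in the sucrose/water competitions, and
#' trial wins in the tube test. Positive values mean animal A consumed more;
#' values near 0 mean no detectable asymmetry. Antisymmetric under swapping
#' the animals; `NA` when nothing was consumed.
#'
#' @param consumption_a,consumption_b non-negative consumption of animals A
#'   and B, in the test's units (vectorized).
#' @return DI in `[-100, 100]`, `NA_real_` where the pair total is 0.
#' @export
dominance_index <- function(consumption_a, consumption_b) {
  if (any(consumption_a < 0, na.rm = TRUE) || any(consumption_b < 0, na.rm = TRUE)) {
    stop("consumption must be non-negative", call. = FALSE)
  }
  tot <- consumption_a + consumption_b
  ifelse(is.na(tot) | tot == 0, NA_real_,
         100 * (consumption_a - consumption_b) / tot)
}

#' Classify a pair's hierarchy from its Dominance Index
#'
#' DI values within the noise band (|DI| <= `band`, default 10, i.e. less
#' than a 5% deviation from equal consumption) are considered noise and
#' indicative of no reliable hierarchy ("unstable"). The band is inclusive at
#' the boundary so the 5%-difference rule and the band agree there. A missing
#' DI (no consumption) is classified unstable with a reason attribute.
#'
#' @param di Dominance Index (vectorized).
#' @param band noise-band half width (DI units).
#' @return Character vector: `"A_dominant"`, `"B_dominant"` or `"unstable"`.
#' @export
classify_hierarchy <- function(di, band = 10) {
  stopifnot(band >= 0)
  out <- ifelse(is.na(di), "unstable",
                ifelse(di > band, "A_dominant",
                       ifelse(di < -band, "B_dominant", "unstable")))
  if (any(is.na(di))) attr(out, "reason") <- "missing DI treated as unstable"
  out
}

#' Tube-test Dominance Index
#'
#' DI over trial wins, counting completed trials only. Resistant trials (the
#' presumed loser refused to enter; trial not completed) are excluded from
#' both numerator and denominator but reported as a count.
#'
#' @param trials tube-trial data frame (see [read_tube_trials()]), typically
#'   one pair and one day.
#' @return List: `di`, `wins_a`, `wins_b`, `n_completed`, `resistant_count`,
#'   `mean_latency` (seconds over completed trials).
#' @export
tube_dominance_index <- function(trials) {
  comp <- trials[trials$completed, , drop = FALSE]
  resist <- sum(!trials$completed)
  if (nrow(comp) == 0L) {
    return(list(di = NA_real_, wins_a = 0L, wins_b = 0L, n_completed = 0L,
                resistant_count = resist, mean_latency = NA_real_))
  }
  wa <- sum(comp$winner == "A")
  wb <- sum(comp$winner == "B")
  list(di = dominance_index(wa, wb), wins_a = wa, wins_b = wb,
       n_completed = nrow(comp), resistant_count = resist,
       mean_latency = mean(comp$latency_s))
}

#' Conflict Resolution Index
#'
#' Refines the tube-test DI by how long it took for the conflict to be
#' resolved: `CRI = DI / mean trial latency` (units: percent per second),
#' where the mean is over completed trials. Fast, decisive wins score
#' higher; the sign follows the DI.
#'
#' @param di tube-test Dominance Index.
#' @param mean_trial_latency mean latency over completed trials, seconds > 0.
#' @return CRI, `NA_real_` if either input is missing.
#' @export
conflict_resolution_index <- function(di, mean_trial_latency) {
  ifelse(is.na(di) | is.na(mean_trial_latency) | mean_trial_latency <= 0,
         NA_real_, di / mean_trial_latency)
}

#' Conflict Index
#'
#' Degree of conflict a test induces: pair pushing time divided by (1) the
#' pair's consumption time for the bottle tests (SC, SCI, WC) or (2) the
#' mean latency to eat all pellets for the food competitions (mFC, mFCD).
#'
#' @param pushing_pair_total_s summed pushing duration of both animals (s).
#' @param consumption_or_latency_s denominator in seconds: pair drinking time
#'   or mean latency-to-all-pellets, per `test_code`.
#' @param test_code test the quantities come from (documentation of intent;
#'   the arithmetic is identical).
#' @return Dimensionless CI >= 0; 0 with zero pushing; `NA_real_` with a
#'   non-positive or missing denominator.
#' @export
conflict_index <- function(pushing_pair_total_s, consumption_or_latency_s,
                           test_code = NULL) {
  if (!is.null(test_code) && !all(test_code %in% .TEST_CODES)) {
    stop("unknown test code", call. = FALSE)
  }
  ifelse(is.na(consumption_or_latency_s) | consumption_or_latency_s <= 0,
         NA_real_, pushing_pair_total_s / consumption_or_latency_s)
}

#' Locate the peak-conflict epoch of a continuous session
#'
#' Slides a fixed-length window over the session and returns the one
#' maximizing the pair's summed drinking plus pushing duration - the moments
#' where whole-session consumption (which is near-symmetric in the water
#' competition) can hide asymmetric interactions. Ties are broken by the
#' earliest window. Within-window per-animal summaries support epoch-based
#' re-classification.
#'
#' @param events events of one continuous (typically WC) session.
#' @param epoch_len window length, seconds (default 120, one trial-length of
#'   reward access).
#' @param step step between candidate window starts, seconds (default 1).
#' @param session_duration session length; default 600 s.
#' @return List: `t_lo`, `t_hi`, `score` (s of drinking+pushing inside), and
#'   per-animal `drinking_s`, `pushing_s`, `pushing_success_pct`, plus
#'   `di_epoch` (DI over within-epoch drinking).
#' @export
peak_conflict_epoch <- function(events, epoch_len = 120, step = 1,
                                session_duration = 600) {
  if (epoch_len > session_duration) {
    stop("session shorter than epoch length", call. = FALSE)
  }
  act <- events[events$behavior %in% c("consumption", "pushing"), , drop = FALSE]
  starts <- seq(0, session_duration - epoch_len, by = step)
  if (nrow(act) == 0L) {
    best <- starts[1]
  } else {
    # overlap of every bout with every candidate window, summed per window
    ov <- outer(starts, act$t_stop, function(lo, stop) pmin(stop, lo + epoch_len)) -
      outer(starts, act$t_start, pmax)
    score <- rowSums(pmax(ov, 0))
    best <- starts[which(score >= max(score) - 1e-9)[1]]
  }
  win <- list(t_lo = best, t_hi = best + epoch_len)
  inside <- clip_events(events, win)
  per <- lapply(.ANIMALS, function(an) {
    ev <- inside[inside$animal_id == an, , drop = FALSE]
    list(drink = sum(ev$t_stop[ev$behavior == "consumption"] -
                       ev$t_start[ev$behavior == "consumption"]),
         push = sum(ev$t_stop[ev$behavior == "pushing"] -
                      ev$t_start[ev$behavior == "pushing"]),
         spct = pushing_success_pct(ev))
  })
  list(t_lo = win$t_lo, t_hi = win$t_hi,
       score = per[[1]]$drink + per[[2]]$drink + per[[1]]$push + per[[2]]$push,
       drinking_s = c(A = per[[1]]$drink, B = per[[2]]$drink),
       pushing_s = c(A = per[[1]]$push, B = per[[2]]$push),
       pushing_success_pct = c(A = per[[1]]$spct, B = per[[2]]$spct),
       di_epoch = dominance_index(per[[1]]$drink, per[[2]]$drink))
}

#' Cross-test reliability of dominance indices
#'
#' If social hierarchy is a stable trait of the pair, dominance indices
#' should correlate across tests. Computes the Pearson correlation between
#' every pair of test columns using pairs with a defined DI in both tests;
#' two-sided p-values come from the standard t transform. Cells with fewer
#' than `min_n` overlapping pairs are reported missing.
#'
#' @param di_table data frame: `pair_id` column plus one numeric DI column
#'   per test.
#' @param min_n minimum overlapping pairs per cell (default 3).
#' @return List of matrices `r`, `p`, `n` (symmetric, unit/NA diagonal).
#' @export
cross_test_reliability <- function(di_table, min_n = 3L) {
  tests <- setdiff(names(di_table), "pair_id")
  k <- length(tests)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(tests, tests))
  n <- matrix(0L, k, k, dimnames = list(tests, tests))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      x <- di_table[[tests[i]]]; y <- di_table[[tests[j]]]
      ok <- complete.cases(x, y)
      n[i, j] <- sum(ok)
      if (i == j) { r[i, j] <- 1; p[i, j] <- NA_real_; next }
      if (sum(ok) < min_n || sd(x[ok]) == 0 || sd(y[ok]) == 0) next
      ct <- cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  list(r = r, p = p, n = n)
}

#' Weight-controlled regression of tube-test outcome on food-competition rank
#'
#' Body weight affects who wins the first tube-test encounters but not
#' food-competition consumption, so the link between the two hierarchies is
#' assessed on weight residuals: (i) pellets eaten are regressed on each
#' animal's own body weight and residuals kept; (ii) the day-1 tube-test
#' Conflict Resolution Index is regressed on a weight covariate and residuals
#' kept; (iii) the CRI residuals are regressed on the pellet residuals. The
#' CRI is pair-level, so by default its weight covariate is the within-pair
#' weight difference (A - B) and the pellet residuals enter as their
#' within-pair difference (A - B); `weight_covariate = "own"` instead assigns
#' each animal a signed CRI (+CRI for A, -CRI for B) and works at animal
#' level with each animal's own weight.
#'
#' @param pellets data frame `pair_id, animal_id, pellets` (pellets eaten in
#'   the modified food competition, typically averaged over days).
#' @param weights data frame `pair_id, animal_id, body_weight_g`.
#' @param cri data frame `pair_id, cri` (day-1 tube-test CRI, signed for
#'   animal A).
#' @param weight_covariate `"pair_diff"` (default) or `"own"`; see Details.
#' @return Object of class `weight_residual_fit`: `slope`, `se`, `t`, `p`,
#'   `n`, the two residual tables, and the three underlying [lm()] fits.
#' @export
weight_residual_regression <- function(pellets, weights, cri,
                                       weight_covariate = c("pair_diff", "own")) {
  weight_covariate <- match.arg(weight_covariate)
  pw <- merge(pellets, weights, by = c("pair_id", "animal_id"))
  if (nrow(pw) < 3L) stop("need pellets and weights for at least 3 animals",
                          call. = FALSE)
  if (sd(pw$body_weight_g) == 0) {
    stop("degenerate regressor: body weight is constant", call. = FALSE)
  }
  fit_pellets <- lm(pellets ~ body_weight_g, data = pw)
  pw$pellet_resid <- residuals(fit_pellets)

  wa <- weights[weights$animal_id == "A", c("pair_id", "body_weight_g")]
  wb <- weights[weights$animal_id == "B", c("pair_id", "body_weight_g")]
  names(wa)[2] <- "w_a"; names(wb)[2] <- "w_b"
  pairs <- merge(merge(cri, wa, by = "pair_id"), wb, by = "pair_id")
  pairs <- pairs[!is.na(pairs$cri), , drop = FALSE]

  if (weight_covariate == "pair_diff") {
    pairs$w_cov <- pairs$w_a - pairs$w_b
    ra <- pw[pw$animal_id == "A", c("pair_id", "pellet_resid")]
    rb <- pw[pw$animal_id == "B", c("pair_id", "pellet_resid")]
    names(ra)[2] <- "res_a"; names(rb)[2] <- "res_b"
    pairs <- merge(merge(pairs, ra, by = "pair_id"), rb, by = "pair_id")
    pairs$pellet_resid <- pairs$res_a - pairs$res_b
    resp <- pairs$cri
  } else {
    # animal-level: signed CRI (+ for A, - for B) against own weight
    long <- rbind(
      data.frame(pair_id = pairs$pair_id, animal_id = "A", cri = pairs$cri,
                 w_cov = pairs$w_a, stringsAsFactors = FALSE),
      data.frame(pair_id = pairs$pair_id, animal_id = "B", cri = -pairs$cri,
                 w_cov = pairs$w_b, stringsAsFactors = FALSE))
    pairs <- merge(long, pw[, c("pair_id", "animal_id", "pellet_resid")],
                   by = c("pair_id", "animal_id"))
    resp <- pairs$cri
  }
  if (nrow(pairs) < 3L) stop("need at least 3 pairs with a defined CRI",
                             call. = FALSE)
  if (sd(pairs$w_cov) == 0) {
    stop("degenerate regressor: weight covariate is constant", call. = FALSE)
  }
  fit_cri <- lm(resp ~ w_cov, data = pairs)
  pairs$cri_resid <- residuals(fit_cri)
  if (sd(pairs$pellet_resid) == 0) {
    stop("degenerate regressor: pellet residuals are constant", call. = FALSE)
  }
  fit <- lm(cri_resid ~ pellet_resid, data = pairs)
  sm <- summary(fit)$coefficients
  structure(list(slope = sm["pellet_resid", "Estimate"],
                 se = sm["pellet_resid", "Std. Error"],
                 t = sm["pellet_resid", "t value"],
                 p = sm["pellet_resid", "Pr(>|t|)"],
                 n = nrow(pairs),
                 weight_covariate = weight_covariate,
                 pellet_residuals = pw[, c("pair_id", "animal_id", "pellet_resid")],
                 cri_residuals = pairs[, intersect(
                   c("pair_id", "animal_id", "pellet_resid", "cri_resid"),
                   names(pairs))],
                 fit_pellets = fit_pellets, fit_cri = fit_cri, fit = fit),
            class = "weight_residual_fit")
}

#' @export
print.weight_residual_fit <- function(x, ...) {
  cat("Weight-residualized regression: tube-test CRI residuals ~ pellet residuals\n")
  cat(sprintf("  slope = %.4f (SE %.4f), t = %.3f, p = %.4g, n = %d (%s weight covariate)\n",
              x$slope, x$se, x$t, x$p, x$n, x$weight_covariate))
  invisible(x)
}
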