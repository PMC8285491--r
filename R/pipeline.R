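#' Analysis configuration
#'
#' Bundles the tunable knobs of the pipeline: the DI noise band (half-width,
#' default 10 DI units = a 5% deviation from equal consumption), the
#' peak-conflict epoch length and step for the water competition, which food
#' competition day classifies the hierarchy (day 2, where conflict is
#' higher), the weight covariate used in the residual regression, and whether
#' the dominant-vs-submissive consumption comparisons are Bonferroni-adjusted
#' as one family.
#'
#' @param noise_band DI half-width treated as no reliable hierarchy.
#' @param epoch_len,epoch_step peak-conflict epoch parameters (seconds).
#' @param mfc_classify_day food-competition day used for classification.
#' @param weight_covariate passed to [weight_residual_regression()].
#' @param bonferroni adjust the per-test consumption comparisons as a family.
#' @param seed optional seed recorded in the manifest.
#' @return Object of class `run_config`.
#' @export
run_config <- function(noise_band = 10, epoch_len = 120, epoch_step = 1,
                       mfc_classify_day = 2L,
                       weight_covariate = c("pair_diff", "own"),
                       bonferroni = TRUE, seed = NULL) {
  stopifnot(noise_band >= 0, epoch_len > 0, epoch_step > 0)
  structure(list(noise_band = noise_band, epoch_len = epoch_len,
                 epoch_step = epoch_step,
                 mfc_classify_day = as.integer(mfc_classify_day),
                 weight_covariate = match.arg(weight_covariate),
                 bonferroni = isTRUE(bonferroni), seed = seed),
            class = "run_config")
}

#' Read an analysis configuration from a YAML file
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read config files", call. = FALSE)
  }
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full dominance-assessment pipeline
#'
#' Orchestrates the end-to-end analysis: validates the inputs, windows each
#' session, summarizes behavior per animal, computes per-pair dominance
#' indices and classifications (day-2 DI for the modified food competition,
#' day-averaged DI elsewhere), conflict indices, the water-competition
#' peak-conflict epoch, tube-test DI/CRI with resistant-trial accounting,
#' cross-test reliability, the weight-residualized regression of tube CRI on
#' food-competition pellets, and dominant-vs-submissive consumption tests.
#'
#' @param events event data frame, path to an events CSV, or a
#'   [simulate_cohort()] object (in which case the other inputs are taken
#'   from it).
#' @param tube_trials optional tube-trial table or CSV path.
#' @param weights optional body-weight table or CSV path.
#' @param config a [run_config()].
#' @return Object of class `dominance_analysis` with components `summaries`,
#'   `dominance`, `reliability`, `regression`, `stats`, `peak_epochs`,
#'   `config`, `manifest`.
#' @export
dominance_analysis <- function(events, tube_trials = NULL, weights = NULL,
                               config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(events, "dyad_cohort")) {
    tube_trials <- tube_trials %||% events$tube_trials
    weights <- weights %||% events$weights
    events <- events$events
  }
  if (is.character(events)) events <- read_events(events)
  else events <- validate_events(events)
  if (is.character(tube_trials)) tube_trials <- read_tube_trials(tube_trials)
  else if (!is.null(tube_trials)) tube_trials <- read_tube_trials(tube_trials)
  if (is.character(weights)) weights <- read_weights(weights)
  else if (!is.null(weights)) weights <- read_weights(weights)
  if (nrow(events) == 0L) stop("no events supplied", call. = FALSE)

  ## per-session behavioral summaries
  keys <- unique(events[, c("pair_id", "test_code", "day")])
  keys <- keys[order(keys$pair_id, keys$test_code, keys$day), , drop = FALSE]
  sum_list <- vector("list", nrow(keys))
  ci_rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    ev <- events[events$pair_id == k$pair_id & events$test_code == k$test_code &
                   events$day == k$day, , drop = FALSE]
    spec <- default_session_spec(k$test_code)
    s <- summarize_session(ev, spec)
    sum_list[[i]] <- s
    denom <- if (k$test_code %in% c("mFC", "mFCD")) {
      lat <- attr(s, "latency_all_pellets")
      if (all(is.na(lat))) NA_real_ else mean(lat, na.rm = TRUE)
    } else sum(s$consumption_s)
    ci_rows[[i]] <- data.frame(
      pair_id = k$pair_id, test_code = k$test_code, day = k$day,
      conflict_index = conflict_index(sum(s$pushing_s), denom, k$test_code),
      stringsAsFactors = FALSE)
  }
  summaries <- do.call(rbind, sum_list)
  ci_tab <- do.call(rbind, ci_rows)

  ## per-pair, per-test dominance
  dom_rows <- list()
  for (tc in intersect(.TEST_CODES, unique(summaries$test_code))) {
    st <- summaries[summaries$test_code == tc, , drop = FALSE]
    for (pid in unique(st$pair_id)) {
      sp <- st[st$pair_id == pid, , drop = FALSE]
      days <- sort(unique(sp$day))
      di_day <- vapply(days, function(d) {
        a <- sp$consumption_units[sp$day == d & sp$animal_id == "A"]
        b <- sp$consumption_units[sp$day == d & sp$animal_id == "B"]
        dominance_index(a, b)
      }, numeric(1))
      di_avg <- if (all(is.na(di_day))) NA_real_ else mean(di_day, na.rm = TRUE)
      di_cls <- if (tc == "mFC" && config$mfc_classify_day %in% days) {
        di_day[match(config$mfc_classify_day, days)]
      } else di_avg
      ci <- ci_tab$conflict_index[ci_tab$pair_id == pid & ci_tab$test_code == tc]
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        pair_id = pid, test_code = tc, n_days = length(days),
        consumption_a = mean(sp$consumption_units[sp$animal_id == "A"]),
        consumption_b = mean(sp$consumption_units[sp$animal_id == "B"]),
        di = di_avg, di_classify = di_cls,
        label = classify_hierarchy(di_cls, config$noise_band),
        conflict_index = if (all(is.na(ci))) NA_real_ else mean(ci, na.rm = TRUE),
        cri = NA_real_, resistant_count = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }

  ## water-competition peak-conflict epochs
  peak_epochs <- NULL
  wc_keys <- keys[keys$test_code == "WC", , drop = FALSE]
  if (nrow(wc_keys) > 0L) {
    pe <- lapply(seq_len(nrow(wc_keys)), function(i) {
      k <- wc_keys[i, ]
      ev <- events[events$pair_id == k$pair_id & events$test_code == "WC" &
                     events$day == k$day, , drop = FALSE]
      spec <- default_session_spec("WC")
      res <- peak_conflict_epoch(ev, config$epoch_len, config$epoch_step,
                                 spec$session_duration)
      data.frame(pair_id = k$pair_id, day = k$day, t_lo = res$t_lo,
                 t_hi = res$t_hi, di_epoch = res$di_epoch,
                 label_epoch = classify_hierarchy(res$di_epoch, config$noise_band),
                 drinking_a = res$drinking_s[["A"]],
                 drinking_b = res$drinking_s[["B"]],
                 pushing_a = res$pushing_s[["A"]],
                 pushing_b = res$pushing_s[["B"]],
                 success_pct_a = res$pushing_success_pct[["A"]],
                 success_pct_b = res$pushing_success_pct[["B"]],
                 stringsAsFactors = FALSE)
    })
    peak_epochs <- do.call(rbind, pe)
  }

  ## tube test
  tube_di <- NULL
  if (!is.null(tube_trials) && nrow(tube_trials) > 0L) {
    for (pid in unique(tube_trials$pair_id)) {
      tp <- tube_trials[tube_trials$pair_id == pid, , drop = FALSE]
      days <- sort(unique(tp$day))
      per_day <- lapply(days, function(d) {
        tube_dominance_index(tp[tp$day == d, , drop = FALSE])
      })
      di_day <- vapply(per_day, `[[`, numeric(1), "di")
      cri_day <- vapply(per_day, function(x) {
        conflict_resolution_index(x$di, x$mean_latency)
      }, numeric(1))
      di_avg <- if (all(is.na(di_day))) NA_real_ else mean(di_day, na.rm = TRUE)
      cri_avg <- if (all(is.na(cri_day))) NA_real_ else mean(cri_day, na.rm = TRUE)
      dom_rows[[length(dom_rows) + 1L]] <- data.frame(
        pair_id = pid, test_code = "TT", n_days = length(days),
        consumption_a = mean(vapply(per_day, `[[`, numeric(1), "wins_a")),
        consumption_b = mean(vapply(per_day, `[[`, numeric(1), "wins_b")),
        di = di_avg, di_classify = di_avg,
        label = classify_hierarchy(di_avg, config$noise_band),
        conflict_index = NA_real_, cri = cri_avg,
        resistant_count = sum(vapply(per_day, `[[`, integer(1),
                                     "resistant_count")),
        stringsAsFactors = FALSE)
      tube_di <- rbind(tube_di, data.frame(
        pair_id = pid, di_day1 = di_day[match(1L, days)],
        cri_day1 = cri_day[match(1L, days)], stringsAsFactors = FALSE))
    }
  }
  dominance <- do.call(rbind, dom_rows)
  rownames(dominance) <- NULL

  ## cross-test reliability on day-averaged DIs (tube contributes wins-DI
  ## and the latency-refined CRI as separate columns)
  di_table <- NULL
  reliability <- NULL
  pairs_all <- unique(dominance$pair_id)
  di_table <- data.frame(pair_id = pairs_all, stringsAsFactors = FALSE)
  for (tc in unique(dominance$test_code)) {
    d <- dominance[dominance$test_code == tc, c("pair_id", "di")]
    di_table[[tc]] <- d$di[match(di_table$pair_id, d$pair_id)]
  }
  if ("TT" %in% dominance$test_code) {
    d <- dominance[dominance$test_code == "TT", c("pair_id", "cri")]
    di_table[["TT_CRI"]] <- d$cri[match(di_table$pair_id, d$pair_id)]
  }
  if (ncol(di_table) > 2L) reliability <- cross_test_reliability(di_table)

  ## weight-controlled regression: mFC pellets vs day-1 tube CRI
  regression <- NULL
  if (!is.null(weights) && !is.null(tube_di) &&
      "mFC" %in% summaries$test_code) {
    mfc <- summaries[summaries$test_code == "mFC", , drop = FALSE]
    pellets <- aggregate(consumption_units ~ pair_id + animal_id, data = mfc,
                         FUN = mean)
    names(pellets)[3] <- "pellets"
    cri <- data.frame(pair_id = tube_di$pair_id, cri = tube_di$cri_day1,
                      stringsAsFactors = FALSE)
    regression <- tryCatch(
      weight_residual_regression(pellets, weights, cri,
                                 weight_covariate = config$weight_covariate),
      error = function(e) {
        warning("weight-residual regression skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }

  ## dominant-vs-submissive consumption tests per test (declared family)
  stats_res <- list()
  for (tc in intersect(c(.TEST_CODES, "TT"), unique(dominance$test_code))) {
    d <- dominance[dominance$test_code == tc & dominance$label != "unstable", ,
                   drop = FALSE]
    if (nrow(d) < 2L) next
    dom_cons <- ifelse(d$label == "A_dominant", d$consumption_a, d$consumption_b)
    sub_cons <- ifelse(d$label == "A_dominant", d$consumption_b, d$consumption_a)
    stats_res[[paste0(tc, "_consumption_D_vs_S")]] <-
      wilcoxon_signed_rank(dom_cons, sub_cons)
  }
  if (config$bonferroni && length(stats_res) > 1L) {
    stats_res <- bonferroni_family(stats_res)
  }
  stats_tab <- if (length(stats_res) > 0L) results_table(stats_res) else NULL

  manifest <- list(
    package = "dyadrank",
    version = as.character(packageVersion("dyadrank")),
    config = unclass(config),
    n_pairs = length(pairs_all),
    n_events = nrow(events),
    tests = sort(unique(dominance$test_code)))
  structure(list(summaries = summaries, conflict = ci_tab,
                 dominance = dominance, di_table = di_table,
                 reliability = reliability, peak_epochs = peak_epochs,
                 regression = regression, stats = stats_tab,
                 config = config, manifest = manifest),
            class = "dominance_analysis")
}

#' @rdname dominance_analysis
#' @export
run_analysis <- dominance_analysis

#' @export
print.dominance_analysis <- function(x, ...) {
  cat("Dominance assessment of", x$manifest$n_pairs, "pair(s) across tests:",
      paste(x$manifest$tests, collapse = ", "), "\n")
  tab <- table(x$dominance$test_code, x$dominance$label)
  cat("\nHierarchy classification (pairs per label):\n")
  print(tab)
  if (!is.null(x$reliability)) {
    cat("\nCross-test DI reliability (Pearson r):\n")
    print(round(x$reliability$r, 2))
  }
  if (!is.null(x$regression)) {
    cat("\n")
    print(x$regression)
  }
  invisible(x)
}

#' @export
summary.dominance_analysis <- function(object, ...) {
  x <- object
  cat("== dyadrank analysis summary ==\n")
  print(x)
  if (!is.null(x$stats)) {
    cat("\nDominant vs submissive consumption (Wilcoxon signed-rank",
        if (any(x$stats$correction == "bonferroni")) ", Bonferroni-adjusted" else "",
        "):\n", sep = "")
    print(x$stats, row.names = FALSE, digits = 3)
  }
  if (!is.null(x$peak_epochs)) {
    cat("\nWater-competition peak-conflict epochs: re-classification changed",
        sum(x$peak_epochs$label_epoch != "unstable"), "of",
        nrow(x$peak_epochs), "pairs' calls from whole-session DI\n")
  }
  invisible(x)
}

#' Plot a dominance analysis
#'
#' `type = "di"`: per-test strip plot of pair dominance indices with the
#' noise band shaded; `type = "reliability"`: image of the cross-test Pearson
#' correlation matrix.
#'
#' @param x a `dominance_analysis`.
#' @param type `"di"` or `"reliability"`.
#' @param ... ignored.
#' @export
plot.dominance_analysis <- function(x, type = c("di", "reliability"), ...) {
  type <- match.arg(type)
  if (type == "di") {
    d <- x$dominance
    tests <- unique(d$test_code)
    stripchart(split(d$di, factor(d$test_code, levels = tests)),
               vertical = TRUE, pch = 19, method = "jitter", jitter = 0.1,
               ylab = "Dominance Index", ylim = c(-100, 100),
               main = "Dominance Index by test")
    abline(h = c(-x$config$noise_band, x$config$noise_band), lty = 2,
           col = "grey40")
    abline(h = 0, col = "grey70")
  } else {
    if (is.null(x$reliability)) stop("no reliability matrix available")
    r <- x$reliability$r
    k <- ncol(r)
    image(seq_len(k), seq_len(k), t(r[k:1, , drop = FALSE]),
          zlim = c(-1, 1), axes = FALSE, xlab = "", ylab = "",
          col = hcl.colors(21, "Blue-Red 3", rev = TRUE),
          main = "Cross-test DI reliability (Pearson r)")
    axis(1, seq_len(k), colnames(r), las = 2)
    axis(2, seq_len(k), rev(rownames(r)), las = 2)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (!is.na(r[i, j])) text(j, k - i + 1, sprintf("%.2f", r[i, j]), cex = 0.8)
    }
  }
  invisible(x)
}

#' Write the analysis report bundle
#'
#' Writes the behavior-summary, conflict and dominance tables, the
#' reliability matrices, the regression report and the run manifest to a
#' directory as CSV/JSON. Outputs are deterministic: identical inputs and
#' config reproduce byte-identical files.
#'
#' @param x a `dominance_analysis`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "dominance_analysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$summaries, file.path(dir, "behavior_summary.csv"),
            row.names = FALSE, na = "")
  write.csv(x$dominance, file.path(dir, "dominance.csv"),
            row.names = FALSE, na = "")
  write.csv(x$conflict, file.path(dir, "conflict_index.csv"),
            row.names = FALSE, na = "")
  if (!is.null(x$peak_epochs)) {
    write.csv(x$peak_epochs, file.path(dir, "wc_peak_epochs.csv"),
              row.names = FALSE, na = "")
  }
  if (!is.null(x$reliability)) {
    for (m in c("r", "p", "n")) {
      write.csv(x$reliability[[m]],
                file.path(dir, paste0("reliability_", m, ".csv")), na = "")
    }
  }
  if (!is.null(x$regression)) {
    jsonlite::write_json(
      list(slope = x$regression$slope, se = x$regression$se,
           t = x$regression$t, p = x$regression$p, n = x$regression$n,
           weight_covariate = x$regression$weight_covariate),
      file.path(dir, "regression.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(x$stats)) {
    write.csv(x$stats, file.path(dir, "stats.csv"), row.names = FALSE, na = "")
  }
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
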