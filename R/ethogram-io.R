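#' Canonical event-log columns
#'
#' Event logs are plain CSV, one row per behavioral bout. Canonical columns:
#' `pair_id`, `test_code` (mFC, SC, SCI, mFCD, WC), `day` (integer >= 1),
#' `trial` (optional integer), `animal_id` (A or B), `behavior` (consumption,
#' pushing, explore_feeder, grooming), `outcome` (successful/unsuccessful,
#' pushing bouts only), `t_start_s`, `t_stop_s` (seconds from session start,
#' half-open interval), `pellets` (non-negative integer, food-competition
#' consumption bouts only).
#'
#' @name event-schema
NULL

.EVENT_COLS <- c(pair_id = "pair_id", test_code = "test_code", day = "day",
                 trial = "trial", animal_id = "animal_id",
                 behavior = "behavior", outcome = "outcome",
                 t_start = "t_start_s", t_stop = "t_stop_s",
                 pellets = "pellets")
.EVENT_REQUIRED <- c("pair_id", "test_code", "day", "animal_id", "behavior",
                     "t_start", "t_stop")

.empty_events <- function() {
  data.frame(pair_id = character(), test_code = character(), day = integer(),
             trial = integer(), animal_id = character(),
             behavior = character(), outcome = character(),
             t_start = numeric(), t_stop = numeric(), pellets = integer(),
             stringsAsFactors = FALSE)
}

#' Validate a data frame of behavioral bouts
#'
#' Checks every row of an event table against the bout invariants: positive
#' duration (`t_stop > t_start`), known test/behavior/animal labels, a
#' successful/unsuccessful outcome present if and only if the behavior is
#' pushing, pellet counts only on consumption bouts, and no overlap between
#' bouts of the same animal and behavior within a session. Intervals are
#' half-open `[t_start, t_stop)`, so abutting bouts do not overlap.
#'
#' @param df data frame with canonical event columns (internal names:
#'   `t_start`, `t_stop`).
#' @param on_error `"stop"` (default) aborts with a summary of all row-level
#'   problems; `"report"` returns `list(events, errors)` so that
#'   `nrow(input) == nrow(events) + nrow(errors)`.
#' @return Validated, sorted event data frame (or a list, see `on_error`).
#' @export
validate_events <- function(df, on_error = c("stop", "report")) {
  on_error <- match.arg(on_error)
  for (col in .EVENT_REQUIRED) {
    if (!col %in% names(df)) {
      stop("schema error: missing column '", col, "'", call. = FALSE)
    }
  }
  if (!"trial" %in% names(df)) df$trial <- NA_integer_
  if (!"outcome" %in% names(df)) df$outcome <- NA_character_
  if (!"pellets" %in% names(df)) df$pellets <- NA_integer_
  df <- df[, names(.empty_events())]

  df$day <- suppressWarnings(as.integer(df$day))
  df$trial <- suppressWarnings(as.integer(df$trial))
  df$t_start <- suppressWarnings(as.numeric(df$t_start))
  df$t_stop <- suppressWarnings(as.numeric(df$t_stop))
  df$pellets <- suppressWarnings(as.integer(df$pellets))
  df$outcome[!is.na(df$outcome) & df$outcome == ""] <- NA_character_

  err <- character(nrow(df))
  add <- function(bad, msg) {
    bad <- which(bad)
    err[bad] <<- ifelse(nzchar(err[bad]), paste0(err[bad], "; ", msg), msg)
  }
  add(!df$test_code %in% .TEST_CODES,
      paste0("unknown test_code (accepted: ", paste(.TEST_CODES, collapse = ", "), ")"))
  add(!df$animal_id %in% .ANIMALS, "animal_id must be 'A' or 'B'")
  add(!df$behavior %in% .BEHAVIORS,
      paste0("unknown behavior (accepted: ", paste(.BEHAVIORS, collapse = ", "), ")"))
  add(is.na(df$day) | df$day < 1L, "day must be an integer >= 1")
  add(is.na(df$t_start) | df$t_start < 0, "t_start must be a number >= 0")
  add(is.na(df$t_stop) | !(df$t_stop > df$t_start),
      "t_stop must exceed t_start (zero-length bouts are rejected)")
  add(df$behavior == "pushing" & !(df$outcome %in% .PUSH_OUTCOMES),
      "pushing bouts require outcome 'successful' or 'unsuccessful'")
  add(df$behavior != "pushing" & !is.na(df$outcome),
      "outcome is only valid for pushing bouts")
  add(df$behavior != "consumption" & !is.na(df$pellets),
      "pellets only valid on consumption bouts")
  add(!is.na(df$pellets) & df$pellets < 0L, "pellets must be non-negative")

  # same-animal same-behavior bouts within a session must not overlap
  ok <- !nzchar(err)
  if (any(ok)) {
    key <- interaction(df$pair_id, df$test_code, df$day, df$animal_id,
                       df$behavior, drop = TRUE)
    for (grp in split(which(ok), key[ok], drop = TRUE)) {
      if (length(grp) < 2L) next
      o <- grp[order(df$t_start[grp], df$t_stop[grp])]
      lap <- df$t_start[o][-1] < df$t_stop[o][-length(o)] - 1e-9
      if (any(lap)) {
        bad <- o[-1][lap]
        err[bad] <- ifelse(nzchar(err[bad]), paste0(err[bad], "; "), "")
        err[bad] <- paste0(err[bad],
                           "overlaps an earlier bout of the same animal and behavior")
      }
    }
  }

  errors <- data.frame(row = which(nzchar(err)),
                       message = err[nzchar(err)],
                       stringsAsFactors = FALSE)
  events <- df[!nzchar(err), , drop = FALSE]
  events <- events[order(events$pair_id, events$test_code, events$day,
                         events$animal_id, events$t_start), , drop = FALSE]
  rownames(events) <- NULL
  if (on_error == "report") return(list(events = events, errors = errors))
  if (nrow(errors) > 0L) {
    shown <- head(errors, 5L)
    stop("event validation failed for ", nrow(errors), " row(s):\n",
         paste0("  row ", shown$row, ": ", shown$message, collapse = "\n"),
         if (nrow(errors) > 5L) "\n  ..." else "", call. = FALSE)
  }
  events
}

#' Read an ethogram event log
#'
#' Reads a comma-separated, UTF-8, header-mandatory event log and validates
#' every row (see [validate_events()]). A `schema` mapping allows column
#' renaming so exports from common annotation tools can be consumed without
#' editing files.
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(t_start = "start", t_stop = "end")`.
#'   Unmapped canonical names use the defaults
#'   (`pair_id, test_code, day, trial, animal_id, behavior, outcome,
#'   t_start_s, t_stop_s, pellets`).
#' @param on_error passed to [validate_events()].
#' @return Event data frame sorted by (pair, test, day, animal, t_start).
#' @export
read_events <- function(path, schema = NULL, on_error = c("stop", "report")) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  cols <- .EVENT_COLS
  if (!is.null(schema)) {
    unknown <- setdiff(names(schema), names(cols))
    if (length(unknown) > 0L) {
      stop("schema error: unknown canonical column(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cols[names(schema)] <- schema
  }
  for (canon in .EVENT_REQUIRED) {
    if (!cols[[canon]] %in% names(raw)) {
      stop("schema error: missing column '", cols[[canon]], "'", call. = FALSE)
    }
  }
  out <- .empty_events()[seq_len(nrow(raw)), , drop = FALSE]
  rownames(out) <- NULL
  for (canon in names(cols)) {
    out[[canon]] <- if (cols[[canon]] %in% names(raw)) raw[[cols[[canon]]]] else NA
  }
  validate_events(out, on_error = match.arg(on_error))
}

#' Write an event log to CSV
#'
#' Inverse of [read_events()]: writing then re-reading a valid event table is
#' an identity at field level.
#'
#' @param events validated event data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events
  names(out) <- .EVENT_COLS[names(events)]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a tube-test trial table
#'
#' One row per trial: `pair_id, day, trial, winner (A/B/none), latency_s,
#' completed`. A trial the presumed loser refuses to enter ("resistant"
#' trial) is recorded as `completed = FALSE` with `winner = none` and a
#' missing latency; any other combination is a contradiction and is rejected.
#'
#' @param path CSV path (or a data frame already in memory).
#' @return Trial data frame sorted by (pair, day, trial).
#' @export
read_tube_trials <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  need <- c("pair_id", "day", "trial", "winner", "latency_s", "completed")
  for (col in need) {
    if (!col %in% names(df)) {
      stop("schema error: missing column '", col, "'", call. = FALSE)
    }
  }
  df$day <- as.integer(df$day)
  df$trial <- as.integer(df$trial)
  df$latency_s <- suppressWarnings(as.numeric(df$latency_s))
  df$completed <- as.logical(df$completed)
  err <- character(nrow(df))
  bad <- !df$winner %in% c("A", "B", "none")
  err[bad] <- "winner must be 'A', 'B' or 'none'"
  bad <- !is.na(df$trial) & (df$trial < 1L | df$trial > 10L)
  err[bad] <- paste0(err[bad], ifelse(nzchar(err[bad]), "; ", ""),
                     "trial must be in 1..10")
  bad <- df$completed & (df$winner == "none" | is.na(df$latency_s) |
                           df$latency_s <= 0)
  err[bad] <- paste0(err[bad], ifelse(nzchar(err[bad]), "; ", ""),
                     "completed trials need a winner and a positive latency")
  bad <- !df$completed & (df$winner != "none" | !is.na(df$latency_s))
  err[bad] <- paste0(err[bad], ifelse(nzchar(err[bad]), "; ", ""),
                     "incomplete trials must have winner 'none' and no latency")
  if (any(nzchar(err))) {
    rows <- which(nzchar(err))
    stop("tube-trial validation failed for ", length(rows), " row(s):\n",
         paste0("  row ", head(rows, 5L), ": ", head(err[rows], 5L),
                collapse = "\n"), call. = FALSE)
  }
  df <- df[order(df$pair_id, df$day, df$trial), need, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a body-weight table
#'
#' Columns `pair_id, animal_id, body_weight_g`; exactly one record per
#' (pair, animal) and positive weights.
#'
#' @param path CSV path (or a data frame).
#' @return Weight data frame.
#' @export
read_weights <- function(path) {
  df <- if (is.data.frame(path)) path else {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  need <- c("pair_id", "animal_id", "body_weight_g")
  for (col in need) {
    if (!col %in% names(df)) {
      stop("schema error: missing column '", col, "'", call. = FALSE)
    }
  }
  df$body_weight_g <- as.numeric(df$body_weight_g)
  if (any(!df$animal_id %in% .ANIMALS)) {
    stop("animal_id must be 'A' or 'B'", call. = FALSE)
  }
  if (any(is.na(df$body_weight_g) | df$body_weight_g <= 0)) {
    stop("body_weight_g must be positive", call. = FALSE)
  }
  dup <- duplicated(df[, c("pair_id", "animal_id")])
  if (any(dup)) stop("duplicate (pair_id, animal_id) weight records", call. = FALSE)
  df[order(df$pair_id, df$animal_id), need, drop = FALSE]
}

#' Report structural problems in a single session's event log
#'
#' Report-only consistency checks for the events of one (pair, test, day)
#' session against its schedule: bouts extending beyond the session duration,
#' overlapping same-animal same-behavior bouts, and food-competition trials
#' whose summed pellet count exceeds the 10 pellets available per trial.
#' Consumption bouts are assigned to trials by the reward-access period
#' containing their start time.
#'
#' @param events event data frame for one session.
#' @param spec a [default_session_spec()] session schedule.
#' @return Data frame with columns `check`, `detail` (zero rows if clean).
#' @export
validate_session_completeness <- function(events, spec) {
  stopifnot(inherits(spec, "session_spec"))
  key <- unique(events[, c("pair_id", "test_code", "day")])
  if (nrow(key) > 1L) {
    stop("events must belong to a single (pair, test, day) session", call. = FALSE)
  }
  report <- list()
  flag <- function(check, detail) {
    report[[length(report) + 1L]] <<- data.frame(check = check, detail = detail,
                                                 stringsAsFactors = FALSE)
  }
  beyond <- which(events$t_stop > spec$session_duration + 1e-9)
  for (i in beyond) {
    flag("beyond_session",
         sprintf("row %d: bout [%.2f, %.2f) extends past session end %.0f s",
                 i, events$t_start[i], events$t_stop[i], spec$session_duration))
  }
  key2 <- interaction(events$animal_id, events$behavior, drop = TRUE)
  for (grp in split(seq_len(nrow(events)), key2, drop = TRUE)) {
    if (length(grp) < 2L) next
    o <- grp[order(events$t_start[grp])]
    lap <- which(events$t_start[o][-1] < events$t_stop[o][-length(o)] - 1e-9)
    for (j in lap) {
      flag("overlap",
           sprintf("%s/%s: bouts starting %.2f and %.2f overlap",
                   events$animal_id[o[1]], events$behavior[o[1]],
                   events$t_start[o[j]], events$t_start[o[j + 1L]]))
    }
  }
  if (spec$test_code %in% c("mFC", "mFCD")) {
    cons <- events[events$behavior == "consumption" & !is.na(events$pellets), ]
    if (nrow(cons) > 0L) {
      for (k in seq_along(spec$trial_zero_times)) {
        z <- spec$trial_zero_times[k]
        sel <- cons$t_start >= z & cons$t_start < z + spec$access_duration
        tot <- sum(cons$pellets[sel])
        if (tot > 10L) {
          flag("pellet_excess",
               sprintf("trial %d: %d pellets consumed but only 10 available", k, tot))
        }
      }
    }
  }
  if (length(report) == 0L) {
    return(data.frame(check = character(), detail = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, report)
}
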