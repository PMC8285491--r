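test_that("generated sessions pass the ethogram validators", {
  set.seed(100)
  p <- dyad_params(delta = 0.7)
  for (ev in list(simulate_mfc_session(p, 1), simulate_mfc_session(p, 1, TRUE),
                  simulate_sc_session(p, 1), simulate_sc_session(p, 1, TRUE),
                  simulate_wc_session(p))) {
    res <- validate_events(ev, on_error = "report")
    expect_equal(nrow(res$errors), 0L)
    spec <- default_session_spec(ev$test_code[1])
    expect_equal(nrow(validate_session_completeness(res$events, spec)), 0L)
  }
  tt <- simulate_tube_sessions(p)
  expect_equal(nrow(read_tube_trials(tt)), 20L)
})

test_that("a symmetric dyad produces no average consumption asymmetry", {
  set.seed(200)
  p <- dyad_params(delta = 0)
  dis <- replicate(300, {
    ev <- simulate_mfc_session(p, 1)
    pel <- tapply(ev$pellets[ev$behavior == "consumption"],
                  ev$animal_id[ev$behavior == "consumption"], sum)
    dominance_index(sum(pel["A"], na.rm = TRUE), sum(pel["B"], na.rm = TRUE))
  })
  expect_lt(abs(mean(dis)), 3)
})

test_that("a fully dominant dyad is identified at the binomial-tail rate", {
  set.seed(201)
  p <- dyad_params(delta = 1)    # pellet split Binomial(10, 0.7) per trial
  hits <- replicate(200, {
    ev <- simulate_mfc_session(p, 1)
    s <- summarize_session(ev, default_session_spec("mFC"))
    classify_hierarchy(dominance_index(s$consumption_units[s$animal_id == "A"],
                                       s$consumption_units[s$animal_id == "B"]))
  })
  # theoretical: P(A >= 28 of 50 pellets) for Binomial(50, 0.7) ~ 0.984
  expect_gte(mean(hits == "A_dominant"), 0.95)
})

test_that("water competition yields near-equal totals but asymmetric pushing efficiency", {
  set.seed(202)
  p <- dyad_params(delta = 0.6)
  out <- t(replicate(60, {
    ev <- simulate_wc_session(p)
    s <- summarize_session(ev, default_session_spec("WC"))
    pe <- peak_conflict_epoch(ev)
    c(di = dominance_index(s$consumption_units[s$animal_id == "A"],
                           s$consumption_units[s$animal_id == "B"]),
      dom_gt = isTRUE(pe$pushing_success_pct[["A"]] >
                        pe$pushing_success_pct[["B"]]),
      sub_push_more = s$pushing_s[s$animal_id == "B"] >
        s$pushing_s[s$animal_id == "A"])
  }))
  expect_lt(median(abs(out[, "di"])), 10)
  expect_gte(mean(out[, "dom_gt"]), 0.9)
  expect_gt(mean(out[, "sub_push_more"]), 0.5)  # subordinate pushes longer
})

test_that("tube sessions are polarized, streaky, and weight-sensitive on day 1", {
  set.seed(203)
  p <- dyad_params(delta = 0.9)
  dis <- replicate(100, abs(tube_dominance_index(
    simulate_tube_sessions(p))$di))
  expect_gte(median(dis), 80)    # |DI| near 100 in most replicates

  # null-dominance dyads: day-1 wins follow the weight difference
  wins <- t(replicate(150, {
    wm <- runif(1, 340, 395); f <- runif(1, -0.09, 0.09)
    p0 <- dyad_params(delta = 0, weight_a = wm * (1 + f / 2),
                      weight_b = wm * (1 - f / 2))
    tt <- simulate_tube_sessions(p0)
    c(dw = 100 * f, w = tube_dominance_index(tt[tt$day == 1, ])$wins_a)
  }))
  ct <- cor.test(wins[, "dw"], wins[, "w"])
  expect_gt(unname(ct$estimate), 0)
  expect_lt(ct$p.value, 0.05)

  # zero-everything dyad: day-1 wins are marginally Binomial(10, 0.5)
  set.seed(204)
  w0 <- replicate(200, tube_dominance_index(
    simulate_tube_sessions(dyad_params(delta = 0, weight_a = 370,
                                       weight_b = 370))[1:10, ])$wins_a)
  expect_lt(abs(mean(w0) - 5), 1)   # wins are bimodal; se(mean) ~ 0.27
})

test_that("cohorts are deterministic under a fixed seed and extensible by pair", {
  c1 <- simulate_cohort(n_pairs = 3, seed = 77, tests = c("mFC", "TT"))
  c2 <- simulate_cohort(n_pairs = 3, seed = 77, tests = c("mFC", "TT"))
  expect_identical(c1$events, c2$events)
  expect_identical(c1$tube_trials, c2$tube_trials)
  expect_identical(c1$ground_truth, c2$ground_truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # per-pair streams: enlarging the cohort preserves the first pairs
  c4 <- simulate_cohort(n_pairs = 4, seed = 77, tests = c("mFC", "TT"))
  expect_identical(c4$events[c4$events$pair_id %in% c1$events$pair_id, ],
                   c1$events)
})

test_that("relabeling animals with negated delta mirrors the summary distributions", {
  set.seed(205)
  di_pos <- replicate(120, {
    ev <- simulate_mfc_session(dyad_params(delta = 0.8), 1)
    s <- summarize_session(ev, default_session_spec("mFC"))
    dominance_index(s$consumption_units[s$animal_id == "A"],
                    s$consumption_units[s$animal_id == "B"])
  })
  set.seed(205)
  di_neg <- replicate(120, {
    ev <- simulate_mfc_session(dyad_params(delta = -0.8), 1)
    s <- summarize_session(ev, default_session_spec("mFC"))
    dominance_index(s$consumption_units[s$animal_id == "A"],
                    s$consumption_units[s$animal_id == "B"])
  })
  expect_lt(abs(mean(di_pos) + mean(di_neg)), 6)
  expect_lt(abs(sd(di_pos) - sd(di_neg)), 6)
})

test_that("mFC dominance index tracks latent dominance across a cohort", {
  coh <- simulate_cohort(n_pairs = 20, seed = 31, tests = "mFC")
  mfc <- coh$events
  di <- vapply(coh$ground_truth$pair_id, function(pid) {
    ev <- mfc[mfc$pair_id == pid, ]
    mean(vapply(1:2, function(d) {
      s <- summarize_session(ev[ev$day == d, ], default_session_spec("mFC"))
      dominance_index(s$consumption_units[s$animal_id == "A"],
                      s$consumption_units[s$animal_id == "B"])
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(di, coh$ground_truth$delta), 0.6)
})
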