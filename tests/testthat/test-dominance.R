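test_that("dominance index matches its normalized-difference definition", {
  expect_equal(dominance_index(30, 20), 20)
  expect_equal(dominance_index(7, 7), 0)
  expect_equal(dominance_index(50, 0), 100)
  expect_true(is.na(dominance_index(0, 0)))
  expect_error(dominance_index(-1, 5), "non-negative")
})

test_that("dominance index is antisymmetric and bounded on random inputs", {
  set.seed(12)
  a <- runif(1000, 0, 50); b <- runif(1000, 0, 50)
  di <- dominance_index(a, b)
  expect_equal(di, -dominance_index(b, a))
  expect_true(all(abs(di) <= 100 + 1e-12))
  # independent direct-formula recomputation
  expect_equal(di, 100 * (a - b) / (a + b))
})

test_that("hierarchy classification uses an inclusive +/-10 noise band", {
  expect_equal(classify_hierarchy(8), "unstable")
  expect_equal(classify_hierarchy(25), "A_dominant")
  expect_equal(classify_hierarchy(-10), "unstable")   # boundary inclusive
  expect_equal(classify_hierarchy(10), "unstable")
  expect_equal(classify_hierarchy(-10.001), "B_dominant")
  expect_equal(as.character(classify_hierarchy(NA_real_)), "unstable")
  # relabeling A<->B (DI sign flip) swaps the dominant labels, fixes unstable
  di <- c(-60, -10, 0, 10, 35)
  lab <- classify_hierarchy(di)
  swapped <- classify_hierarchy(-di)
  expect_equal(swapped[lab == "A_dominant"],
               rep("B_dominant", sum(lab == "A_dominant")))
  expect_equal(swapped[lab == "unstable"],
               rep("unstable", sum(lab == "unstable")))
})

test_that("tube DI counts completed trials only and reports resistant trials", {
  expect_equal(tube_dominance_index(make_tube(winner = rep("A", 10)))$di, 100)
  tie <- tube_dominance_index(make_tube(winner = rep(c("A", "B"), 5)))
  expect_equal(tie$di, 0)
  expect_equal(classify_hierarchy(tie$di), "unstable")

  tt <- make_tube(winner = rep("A", 10))
  tt$completed[4] <- FALSE; tt$winner[4] <- "none"; tt$latency_s[4] <- NA
  res <- tube_dominance_index(tt)
  expect_equal(res$di, 100)            # 9 completed, all won by A
  expect_equal(res$resistant_count, 1L)
  expect_equal(res$n_completed, 9L)

  none <- make_tube(winner = rep("none", 3), completed = FALSE)
  expect_true(is.na(tube_dominance_index(none)$di))
})

test_that("conflict resolution index divides DI by mean completed-trial latency", {
  expect_equal(conflict_resolution_index(100, 5), 20)
  expect_equal(conflict_resolution_index(0, 3.7), 0)
  expect_true(is.na(conflict_resolution_index(NA_real_, 4)))
  # direct per-trial recomputation: session DI over mean latency
  set.seed(3)
  for (rep in 1:20) {
    winners <- sample(c("A", "B"), 10, replace = TRUE, prob = c(0.8, 0.2))
    lats <- runif(10, 2, 9)
    tt <- make_tube(winner = winners, latency = lats)
    res <- tube_dominance_index(tt)
    got <- conflict_resolution_index(res$di, res$mean_latency)
    want <- (100 * (sum(winners == "A") - sum(winners == "B")) / 10) / mean(lats)
    expect_equal(got, want)
  }
})

test_that("conflict index uses drinking time or pellet latency as denominator", {
  expect_equal(conflict_index(30, 60, "SC"), 0.5)
  expect_equal(conflict_index(40, 20, "mFC"), 2)
  expect_equal(conflict_index(0, 25, "WC"), 0)
  expect_true(is.na(conflict_index(10, 0, "SC")))
})

test_that("peak-conflict epoch maximizes drinking+pushing and matches an exhaustive scan", {
  # all activity inside [100, 200): chosen 120-s window must contain it
  ev <- make_events(test_code = "WC", animal_id = c("A", "B", "A"),
                    behavior = c("consumption", "consumption", "pushing"),
                    t_start = c(100, 140, 180), t_stop = c(140, 180, 200),
                    outcome = c(NA, NA, "successful"))
  pe <- peak_conflict_epoch(ev)
  expect_lte(pe$t_lo, 100)
  expect_gte(pe$t_hi, 200)
  expect_equal(pe$score, 100)

  # uniform activity: earliest window wins the tie
  unif <- make_events(test_code = "WC", animal_id = "A", behavior = "consumption",
                      t_start = 0, t_stop = 600)
  expect_equal(peak_conflict_epoch(unif)$t_lo, 0)

  expect_error(peak_conflict_epoch(ev, epoch_len = 700), "shorter")

  # maximizer equals an exhaustive 1-s-step scan, and is order-invariant
  set.seed(17)
  for (rep in 1:5) {
    ev <- random_bouts(25, span = 600, test_code = "WC",
                       behaviors = c("consumption", "pushing", "grooming"))
    ev$outcome[ev$behavior == "pushing"] <- "successful"
    pe <- peak_conflict_epoch(ev)
    act <- ev[ev$behavior %in% c("consumption", "pushing"), ]
    scores <- vapply(0:480, function(lo) {
      sum(pmax(0, pmin(act$t_stop, lo + 120) - pmax(act$t_start, lo)))
    }, numeric(1))
    expect_equal(pe$t_lo, (0:480)[which.max(scores)])
    expect_equal(pe$score, max(scores), tolerance = 1e-9)
    shuffled <- ev[sample(nrow(ev)), ]
    expect_equal(peak_conflict_epoch(shuffled)$t_lo, pe$t_lo)
  }
})

test_that("cross-test reliability reproduces hand-computed Pearson correlations", {
  di <- data.frame(pair_id = paste0("p", 1:5),
                   t1 = c(-40, -10, 5, 30, 80))
  di$t2 <- di$t1
  di$t3 <- -di$t1
  set.seed(9); di$t4 <- c(12, -35, 44, 2, -60)
  rel <- cross_test_reliability(di)
  expect_equal(rel$r["t1", "t2"], 1)
  expect_equal(rel$r["t1", "t3"], -1)
  # brute-force covariance formula for the irregular column
  x <- di$t1; y <- di$t4
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(rel$r["t1", "t4"], r_manual)
  expect_equal(rel$r, t(rel$r))
  expect_equal(unname(diag(rel$r)), rep(1, 4))

  # fewer than 3 overlapping pairs -> missing cell
  di$t5 <- c(1, 2, NA, NA, NA)
  rel2 <- cross_test_reliability(di)
  expect_true(is.na(rel2$r["t1", "t5"]))
  expect_equal(rel2$n["t1", "t5"], 2L)
})

test_that("weight-residual regression matches a step-by-step manual recomputation", {
  set.seed(14)
  pairs <- sprintf("p%02d", 1:10)
  wa <- runif(10, 350, 400)
  wb <- wa - runif(10, -20, 20)
  weights <- data.frame(pair_id = rep(pairs, each = 2),
                        animal_id = rep(c("A", "B"), 10),
                        body_weight_g = as.vector(rbind(wa, wb)))
  pel <- data.frame(pair_id = rep(pairs, each = 2),
                    animal_id = rep(c("A", "B"), 10),
                    pellets = rnorm(20, 25, 5))
  cri <- data.frame(pair_id = pairs, cri = rnorm(10, 0, 15))
  fit <- weight_residual_regression(pel, weights, cri)

  # manual three-stage least squares via the covariance formulas
  w_all <- weights$body_weight_g
  b1 <- cov(w_all, pel$pellets) / var(w_all)
  pr <- pel$pellets - (mean(pel$pellets) - b1 * mean(w_all)) - b1 * w_all
  pd <- pr[pel$animal_id == "A"] - pr[pel$animal_id == "B"]  # per-pair diff
  dw <- wa - wb
  b2 <- cov(dw, cri$cri) / var(dw)
  cr <- cri$cri - (mean(cri$cri) - b2 * mean(dw)) - b2 * dw
  b3 <- cov(pd, cr) / var(pd)
  a3 <- mean(cr) - b3 * mean(pd)
  res3 <- cr - a3 - b3 * pd
  se3 <- sqrt(sum(res3^2) / (10 - 2) / sum((pd - mean(pd))^2))
  p3 <- 2 * pt(-abs(b3 / se3), df = 10 - 2)
  expect_equal(fit$slope, b3, tolerance = 1e-10)
  expect_equal(fit$se, se3, tolerance = 1e-10)
  expect_equal(fit$p, p3, tolerance = 1e-10)
  expect_equal(fit$n, 10L)

  # pellets forced independent of weight: residuals are centered pellets
  pel0 <- pel
  pel0$pellets <- pel0$pellets - b1 * w_all
  fit0 <- weight_residual_regression(pel0, weights, cri)
  expect_equal(unname(fit0$pellet_residuals$pellet_resid),
               unname(pel0$pellets - mean(pel0$pellets)), tolerance = 1e-8)

  const_w <- weights
  const_w$body_weight_g <- 350
  expect_error(weight_residual_regression(pel, const_w, cri), "degenerate")
})
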