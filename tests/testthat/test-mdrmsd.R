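test_that("snapshot schedules reproduce the sampling plans", {
  expect_length(snapshot_schedule(10000, 200), 50L)
  expect_length(snapshot_schedule(10000, 100), 100L)
  expect_equal(snapshot_schedule(100, 100), 100)
  expect_equal(snapshot_schedule(600, 200, include_t0 = TRUE),
               c(0, 200, 400, 600))
  expect_warning(s <- snapshot_schedule(950, 200), "multiple")
  expect_equal(s, c(200, 400, 600, 800))
  expect_error(snapshot_schedule(100, 0))
})

test_that("RMSD traces are zero for rigid copies of the reference", {
  ref <- gen_toy_structure()
  ld <- default_loop_definition()

  still <- gen_toy_trajectory(ref, ld, list(cdr1 = rep(0, 8)), seed = 1)
  tr0 <- cdr_rmsd_trace(still, ref, ld)
  expect_lt(max(tr0$cdr1, tr0$cdr2, tr0$cdr3), 1e-9)

  moved <- gen_toy_trajectory(ref, ld, list(cdr1 = rep(0, 8)),
                              rigid_motion = TRUE, seed = 2)
  trm <- cdr_rmsd_trace(moved, ref, ld)
  expect_lt(max(trm$cdr1, trm$cdr2, trm$cdr3), 1e-6)
})

test_that("a scheduled CDR3 step appears in the right loop at the right time", {
  ref <- gen_toy_structure()
  ld <- default_loop_definition()
  sched <- list(cdr3 = c(rep(0, 19), rep(3, 31)))
  trj <- gen_toy_trajectory(ref, ld, sched, rigid_motion = TRUE, seed = 3)
  tr <- cdr_rmsd_trace(trj, ref, ld, times = seq_len(50) * 100)
  expect_lt(max(tr$cdr3[1:19]), 0.01)
  expect_equal(tr$cdr3[20:50], rep(3, 31), tolerance = 0.01)
  expect_lt(max(tr$cdr2), 0.01)
  expect_lt(max(tr$cdr1), 0.01)
  expect_equal(tr$time, seq_len(50) * 100)
})

test_that("traces are invariant to a global rigid motion of all frames", {
  ref <- gen_toy_structure()
  ld <- default_loop_definition()
  sched <- list(cdr2 = seq(0, 2, length.out = 10))
  base <- cdr_rmsd_trace(gen_toy_trajectory(ref, ld, sched, seed = 4),
                         ref, ld)
  spun <- cdr_rmsd_trace(gen_toy_trajectory(ref, ld, sched,
                                            rigid_motion = TRUE, seed = 4),
                         ref, ld)
  expect_equal(spun$cdr2, base$cdr2, tolerance = 1e-6)
})

test_that("topology mismatches are reported with the offending atom", {
  ref <- gen_toy_structure()
  ld <- default_loop_definition()
  frames <- gen_toy_trajectory(ref, ld, list(cdr1 = c(0, 0)), seed = 5)
  frames[[2]]$atoms$res_seq[10] <- 999L
  expect_error(cdr_rmsd_trace(frames, ref, ld), "topology")
})

test_that("run aggregation gives mean and min/max envelope per loop", {
  mk_trace <- function(vals) {
    d <- data.frame(time = seq_along(vals), cdr1 = 0, cdr2 = vals,
                    cdr3 = rev(vals))
    class(d) <- c("rmsd_trace", "data.frame")
    d
  }
  traces <- list(mk_trace(c(1, 2, 3)), mk_trace(c(2, 2, 5)),
                 mk_trace(c(3, 2, 1)))
  agg <- aggregate_runs(traces, n_expected = 3)
  expect_equal(agg$cdr2_mean, c(2, 2, 3))
  expect_equal(agg$cdr2_min, c(1, 2, 1))
  expect_equal(agg$cdr2_max, c(3, 2, 5))
  # mean always inside the envelope
  for (lp in c("cdr1", "cdr2", "cdr3")) {
    expect_true(all(agg[[paste0(lp, "_mean")]] >=
                      agg[[paste0(lp, "_min")]] - 1e-12))
    expect_true(all(agg[[paste0(lp, "_mean")]] <=
                      agg[[paste0(lp, "_max")]] + 1e-12))
  }
  # identical traces collapse the range
  same <- aggregate_runs(list(mk_trace(1:3), mk_trace(1:3)), n_expected = 2)
  expect_equal(same$cdr2_min, same$cdr2_max)

  bad <- mk_trace(c(1, 2, 3)); bad$time <- bad$time + 0.5
  expect_error(aggregate_runs(list(traces[[1]], bad)), "time grid")
})

test_that("flexibility comparison matches the closed-form pooled t", {
  a <- c(2.0, 2.1, 1.9); b <- c(1.0, 1.1, 0.9)
  res <- compare_flexibility(a, b, "A_greater")
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (2 / 3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$t, 12.247, tolerance = 1e-3)
  expect_lt(res$p, 0.001)
  expect_equal(res$p, pt(t_hand, 4, lower.tail = FALSE), tolerance = 1e-12)

  # direction flip keeps t, complements the tail
  flip <- compare_flexibility(a, b, "B_greater")
  expect_equal(flip$t, res$t)
  expect_equal(flip$p, 1 - res$p, tolerance = 1e-12)

  same <- compare_flexibility(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 0.5)
  expect_error(compare_flexibility(c(1, 1), c(2, 2)), "undefined")
  expect_error(compare_flexibility(1, c(1, 2)), "at least 2")
})
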