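test_that("panel reading validates format and path consistency", {
  gr <- graph_id()
  df <- data.frame(subject_id = c(1, 1, 2, 2, 2),
                   time = c(0, 1.5, 0, 2, 4),
                   state = c(1, 2, 1, 1, 3))
  pd <- panel_dataset(df, gr)
  expect_equal(pd$n, 2)
  expect_equal(pd$tau, c(1.5, 2, 4))
  expect_equal(pd$tau0, 0)

  # round trip through CSV
  f <- withr::local_tempfile(fileext = ".csv")
  write_panel(pd, f)
  pd2 <- read_panel(f, gr)
  expect_equal(pd2$observations, pd$observations)
  expect_equal(pd2$intervals, pd$intervals)

  # missing columns / bad file
  expect_error(panel_dataset(df[, 1:2], gr), class = "npmsm_format_error")
  expect_error(read_panel(file.path(tempdir(), "nope.csv"), gr),
               class = "npmsm_format_error")

  # conflicting duplicate observation
  bad <- rbind(df, data.frame(subject_id = 1, time = 1.5, state = 3))
  expect_error(panel_dataset(bad, gr), class = "npmsm_consistency_error")
  # identical duplicates are collapsed
  ok <- rbind(df, df[2, ])
  expect_equal(panel_dataset(ok, gr)$observations, pd$observations)

  # state path with no connecting directed path (3 -> 1 in illness-death)
  back <- data.frame(subject_id = 1, time = c(0, 1), state = c(3, 1))
  expect_error(panel_dataset(back, gr), class = "npmsm_consistency_error")
})

test_that("bin frames implement the bracketing observation intervals", {
  gr <- graph_two_state()
  # subject visited at 0, 1.5, 4; grid forced to {1, 1.5, 2.5, 4}
  df <- data.frame(subject_id = 1, time = c(0, 1.5, 4), state = c(1, 1, 2))
  pd <- panel_dataset(df, gr, extra_times = c(1, 2.5))
  expect_equal(pd$tau, c(1, 1.5, 2.5, 4))
  fr <- bin_frames(pd)
  # bin (1.5, 2.5] is bracketed by the visits at 1.5 and 4
  row <- fr[fr$tau == 2.5, ]
  expect_equal(row$l, 1.5)
  expect_equal(row$r, 4)
  expect_equal(row$a, "1")
  expect_equal(row$b, "2")
  # bin (0, 1] is bracketed by the visits at 0 and 1.5
  row <- fr[fr$tau == 1, ]
  expect_equal(c(row$l, row$r), c(0, 1.5))
  expect_equal(c(row$a, row$b), c("1", "1"))

  # subject observed once contributes no frames
  solo <- panel_dataset(data.frame(subject_id = 1, time = 0, state = 1), gr,
                        extra_times = 1)
  expect_equal(nrow(bin_frames(solo)), 0)
})

test_that("frame counts equal subjects under observation per bin", {
  set.seed(31)
  pd <- random_scenario_panel(1, n = 40, seed = 9)
  fr <- bin_frames(pd)
  obs <- pd$observations
  for (k in sample(seq_len(pd$K), 5)) {
    spans <- vapply(split(obs, obs$subject_id), function(d)
      min(d$time) < pd$tau[k] && max(d$time) >= pd$tau[k], logical(1))
    expect_equal(sum(fr$k == k), sum(spans))
  }
  # grid reconstruction: union of non-baseline visit times is the grid
  later <- unlist(lapply(split(obs, obs$subject_id),
                         function(d) d$time[-1]), use.names = FALSE)
  expect_equal(sort(unique(later)), pd$tau)
  # every active frame connects reachable states
  expect_true(all(pd$graph$reach[cbind(match(fr$a, pd$graph$states),
                                       match(fr$b, pd$graph$states))]))
})

test_that("exact-entry annotation flags the entry interval only", {
  gid <- graph_id(exact = 3)
  df <- data.frame(subject_id = 1, time = c(0, 5), state = c(1, 3))
  pd <- panel_dataset(df, gid, extra_times = c(1, 2))
  fr <- bin_frames(pd)
  expect_true(all(fr$exact_terminal))
  expect_equal(unique(fr$k_ri), 3)   # tau_{k_ri} = 5
  expect_equal(pd$tau[unique(fr$k_ri)], 5)
  expect_true(all(exactness_annotation(pd) == c(FALSE, TRUE)))

  # no exact states: nothing flagged
  pd0 <- panel_dataset(df, graph_id(), extra_times = c(1, 2))
  expect_false(any(bin_frames(pd0)$exact_terminal))

  # extended model: entry into 4 flagged over the bracketing interval
  eid <- graph_eid()
  df2 <- data.frame(subject_id = 1, time = c(0, 4, 9), state = c(1, 2, 4))
  pd2 <- panel_dataset(df2, eid, extra_times = c(6, 8))
  fr2 <- bin_frames(pd2)
  expect_equal(fr2$exact_terminal, fr2$b == "4")
  expect_true(all(fr2$tau[fr2$exact_terminal] > 4))

  # repeated observation of an exact state after entry is not a new entry
  df3 <- data.frame(subject_id = 1, time = c(0, 5, 7), state = c(1, 3, 3))
  pd3 <- panel_dataset(df3, gid)
  expect_equal(pd3$intervals$exact, c(TRUE, FALSE))

  # starting in an exact state is an ordinary initial condition
  df4 <- data.frame(subject_id = c(1, 1, 2, 2), time = c(0, 2, 0, 2),
                    state = c(3, 3, 1, 2))
  expect_silent(pd4 <- panel_dataset(df4, gid))
  expect_false(any(pd4$intervals$exact))
})
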