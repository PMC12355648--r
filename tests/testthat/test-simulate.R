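test_that("scenario presets encode the benchmark designs", {
  s1 <- scenario_preset(1)
  expect_equal(s1$start_dist, c(1, 0, 0))
  expect_equal(s1$hazards[["1->2"]]$rate, 0.1)
  expect_equal(s1$hazards[["1->3"]]$rate, 0.05)
  expect_equal(s1$visits, visits_uniform(0, 4.4))
  expect_equal(s1$horizon, 15)
  expect_length(s1$graph$exact, 0)

  expect_equal(scenario_preset(2)$start_dist, c(0.5, 0.5, 0))

  # Weibull designs are mean-matched to the exponential ones:
  # E[T] = rate^(-1/shape) * gamma(1 + 1/shape) = 10, 20, 10
  s3 <- scenario_preset(3)
  means <- vapply(s3$hazards, function(h)
    h$rate^(-1 / h$shape) * gamma(1 + 1 / h$shape), numeric(1))
  expect_equal(unname(means), c(10, 20, 10))
  expect_equal(vapply(s3$hazards, `[[`, numeric(1), "shape"),
               c("1->2" = 0.5, "1->3" = 0.5, "2->3" = 2))

  s4 <- scenario_preset(4)
  expect_equal(s4$graph$exact, c(3L, 4L))
  expect_equal(s4$graph$states[s4$graph$from], c("1", "1", "2"))
  expect_equal(s4$graph$states[s4$graph$to], c("2", "3", "4"))

  expect_equal(scenario_preset(5)$visits, visits_panel(3, 0.1))
  expect_equal(scenario_preset(6, "dense")$visits, visits_uniform(0, 2.44))
  expect_equal(scenario_preset(6, "sparse")$visits, visits_uniform(0, 7.33))
})

test_that("path sampling matches competing-risks closed forms", {
  set.seed(101)
  spec <- scenario_preset(1)
  n <- 30000
  exits <- replicate(n, {
    p <- sample_path(spec)
    if (nrow(p) > 1) p$time[2] else Inf
  })
  # total exit hazard from the healthy state is 0.15
  for (t in c(2, 5, 10)) {
    expected <- 1 - exp(-0.15 * t)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(mean(exits <= t) - expected), 3 * se)
  }
})

test_that("weibull shape one reduces to the exponential", {
  set.seed(202)
  hz_w <- haz_weibull(1, 0.2)
  hz_e <- haz_exponential(0.2)
  draws_w <- replicate(5000, npmsm:::draw_event_time(hz_w, 0, "forward"))
  draws_e <- replicate(5000, npmsm:::draw_event_time(hz_e, 0, "forward"))
  expect_gt(stats::ks.test(draws_w, draws_e)$p.value, 0.01)
  # forward-clock conditional draws always exceed the entry time
  expect_true(all(replicate(200, npmsm:::draw_event_time(hz_w, 3, "forward")) > 3))
})

test_that("observation schemes censor, truncate and register exact deaths", {
  set.seed(303)
  spec <- scenario_preset(1)
  # a path absorbed before the first follow-up yields two observations
  p <- data.frame(time = c(0, 0.05), state = c(1, 3))
  o <- observe_path(p, spec)
  expect_equal(nrow(o), 2)
  expect_equal(o$state, c(1, 3))
  expect_true(all(o$time <= 15))

  # renewal rate of visits: about 15 / 2.2 follow-ups per subject
  nv <- replicate(3000, {
    path <- data.frame(time = 0, state = 1)  # never leaves; visits run to 15
    nrow(observe_path(path, spec)) - 1
  })
  expect_lt(abs(mean(nv) - 15 / 2.2), 0.1 * 15 / 2.2)

  # scheduled panel visits deviate at most 0.1 from the 3-year schedule
  s5 <- scenario_preset(5)
  for (r in 1:20) {
    o5 <- observe_path(data.frame(time = 0, state = 1), s5)
    expect_true(all(abs(o5$time[-1] - 3 * seq_len(nrow(o5) - 1)) <= 0.1))
    expect_true(all(diff(o5$time) >= 2.8 & diff(o5$time) <= 3.2))
  }

  # exact death states are recorded at their true entry times
  s4 <- scenario_preset(4)
  for (r in 1:50) {
    p <- sample_path(s4)
    o <- observe_path(p, s4)
    dead <- o$state %in% c(3, 4)
    if (any(dead)) {
      expect_equal(o$time[dead], p$time[p$state %in% c(3, 4)])
      # nothing recorded after the absorbing observation
      expect_equal(which(dead), nrow(o))
    }
  }
})

test_that("datasets are reproducible, censored at the horizon, and valid", {
  spec <- scenario_preset(2)
  s1 <- simulate_dataset(spec, 30, 77)
  s2 <- simulate_dataset(spec, 30, 77)
  expect_identical(s1$data$observations, s2$data$observations)
  expect_true(all(s1$data$observations$time <= 15))
  # per-subject substreams: enlarging n preserves earlier subjects
  s3 <- simulate_dataset(spec, 40, 77)
  expect_identical(
    s3$data$observations[s3$data$observations$subject_id %in%
                           sprintf("s%04d", 1:30), ],
    s1$data$observations)
  # scenario 1: everyone starts healthy at time zero
  s0 <- simulate_dataset(scenario_preset(1), 50, 5)
  first <- do.call(rbind, lapply(split(s0$data$observations,
                                       s0$data$observations$subject_id),
                                 function(d) d[1, ]))
  expect_true(all(first$time == 0 & first$state == 1))
  # generated panels pass validation by construction (no error on rebuild)
  expect_silent(panel_dataset(s0$data$observations, s0$spec$graph))
})

test_that("hazards switched off freeze the path", {
  spec <- scenario_spec(graph_two_state(),
                        list("1->2" = haz_exponential(1e-12)),
                        c(1, 0), visits_uniform(0, 4), horizon = 15)
  set.seed(9)
  for (r in 1:5) expect_equal(nrow(sample_path(spec)), 1)
})
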