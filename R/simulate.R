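#' Cause-specific hazard specifications
#'
#' Hazards for the simulator, parameterised with survivor function
#' \eqn{\exp(-\lambda t^{k})}: cumulative hazard \eqn{\Lambda(t) = \lambda
#' t^{k}} and density \eqn{f(t) = \lambda k t^{k-1} e^{-\lambda t^k}}.
#' `haz_exponential(rate)` is the shape-1 special case.
#'
#' @param rate Rate \eqn{\lambda > 0}.
#' @param shape Weibull shape \eqn{k > 0}.
#' @return List of class `npmsm_hazard` with fields `family`, `rate`,
#'   `shape`.
#' @export
haz_exponential <- function(rate) {
  stopifnot(rate > 0)
  structure(list(family = "exponential", rate = rate, shape = 1),
            class = "npmsm_hazard")
}

#' @rdname haz_exponential
#' @export
haz_weibull <- function(shape, rate) {
  stopifnot(shape > 0, rate > 0)
  structure(list(family = "weibull", rate = rate, shape = shape),
            class = "npmsm_hazard")
}

cumhaz <- function(hz, t) hz$rate * t^hz$shape
hazrate <- function(hz, t) hz$rate * hz$shape * t^(hz$shape - 1)

# draw T from the hazard conditional on T > s (forward clock) or s + fresh
# draw (reset clock)
draw_event_time <- function(hz, s, clock) {
  e <- stats::rexp(1)
  if (clock == "forward") (s^hz$shape + e / hz$rate)^(1 / hz$shape)
  else s + (e / hz$rate)^(1 / hz$shape)
}

#' Define a simulation scenario
#'
#' A scenario is a stated data-generating world: a transition structure,
#' cause-specific hazards per transition, a distribution for the state first
#' occupied at time 0, a visit scheme, and an administrative censoring
#' horizon.  With `clock = "forward"` the hazards are functions of study
#' time (sampled conditionally on the entry time into the current state), so
#' the generated process is Markov on the study time scale — the assumption
#' the estimator makes.  `clock = "reset"` gives a semi-Markov process for
#' robustness experiments only.
#'
#' @param graph An [transition_graph()].
#' @param hazards Named list of [haz_exponential()] / [haz_weibull()]
#'   objects; names are `"g->h"` using state labels.
#' @param start_dist Probability vector over states for the state at time 0.
#' @param visits Visit scheme: `visits_uniform(min, max)` draws inter-visit
#'   gaps from U(min, max); `visits_panel(interval, jitter)` schedules visit
#'   j at `interval * j + U(-jitter, jitter)`.
#' @param horizon Administrative censoring time (years).
#' @param clock `"forward"` (Markov, default) or `"reset"` (semi-Markov).
#' @return An object of class `npmsm_scenario`.
#' @export
scenario_spec <- function(graph, hazards, start_dist, visits, horizon = 15,
                          clock = c("forward", "reset")) {
  stopifnot(inherits(graph, "msm_graph"), horizon > 0)
  clock <- match.arg(clock)
  key <- sprintf("%s->%s", graph$states[graph$from], graph$states[graph$to])
  if (!setequal(names(hazards), key))
    stop(sprintf("hazards must be named exactly: %s",
                 paste(key, collapse = ", ")), call. = FALSE)
  stopifnot(length(start_dist) == graph$H, all(start_dist >= 0),
            abs(sum(start_dist) - 1) < 1e-12)
  structure(list(graph = graph, hazards = hazards[key],
                 start_dist = start_dist, visits = visits,
                 horizon = horizon, clock = clock),
            class = "npmsm_scenario")
}

#' @rdname scenario_spec
#' @param min,max Bounds of the uniform inter-visit gap.
#' @export
visits_uniform <- function(min, max) {
  list(type = "uniform", min = min, max = max)
}

#' @rdname scenario_spec
#' @param interval Scheduled panel spacing.
#' @param jitter Maximal uniform deviation of the response time.
#' @export
visits_panel <- function(interval, jitter) {
  list(type = "panel", interval = interval, jitter = jitter)
}

#' The six benchmark simulation scenarios
#'
#' Illness-death (ID: healthy 1, ill 2, dead 3) and extended illness-death
#' (EID: dead without illness 3, dead after illness 4) designs with a
#' 15-year horizon.  Mean transition times are 10 (1->2), 20 (1->3) and 10
#' (2->3 or 2->4) years in every scenario:
#' \describe{
#'   \item{1}{ID, all start healthy, Exp(0.1)/Exp(0.05)/Exp(0.1),
#'     inter-visit gaps U(0, 4.4).}
#'   \item{2}{As 1 but starting healthy or ill with equal probability.}
#'   \item{3}{As 1 with Weibull hazards: shapes (0.5, 0.5, 2) and rates
#'     (1/sqrt(5), 1/sqrt(10), gamma(1.5)^2/100), mean-matched to scenario
#'     1.}
#'   \item{4}{EID, all start healthy, both death states exactly observed.}
#'   \item{5}{As 2 with scheduled panel visits at 3j + U(-0.1, 0.1).}
#'   \item{6}{As 2 with gaps U(0, 2.44) (`variant = "dense"`) or
#'     U(0, 7.33) (`variant = "sparse"`).}
#' }
#'
#' @param number Scenario 1..6.
#' @param variant For scenario 6: `"dense"` or `"sparse"`.
#' @return An [scenario_spec()] object.
#' @export
scenario_preset <- function(number, variant = c("dense", "sparse")) {
  stopifnot(number %in% 1:6)
  variant <- match.arg(variant)
  id <- transition_graph(1:3, rbind(c(1, 2), c(1, 3), c(2, 3)))
  exp_haz <- list("1->2" = haz_exponential(0.1),
                  "1->3" = haz_exponential(0.05),
                  "2->3" = haz_exponential(0.1))
  start1 <- c(1, 0, 0)
  start12 <- c(0.5, 0.5, 0)
  u44 <- visits_uniform(0, 4.4)
  switch(as.character(number),
    "1" = scenario_spec(id, exp_haz, start1, u44),
    "2" = scenario_spec(id, exp_haz, start12, u44),
    "3" = scenario_spec(id, list(
            "1->2" = haz_weibull(0.5, 1 / sqrt(5)),
            "1->3" = haz_weibull(0.5, 1 / sqrt(10)),
            "2->3" = haz_weibull(2, gamma(1.5)^2 / 100)),
          start1, u44),
    "4" = scenario_spec(
      transition_graph(1:4, rbind(c(1, 2), c(1, 3), c(2, 4)),
                       exact_states = c(3, 4)),
      list("1->2" = haz_exponential(0.1), "1->3" = haz_exponential(0.05),
           "2->4" = haz_exponential(0.1)),
      c(1, 0, 0, 0), u44),
    "5" = scenario_spec(id, exp_haz, start12, visits_panel(3, 0.1)),
    "6" = scenario_spec(id, exp_haz, start12,
                        if (variant == "dense") visits_uniform(0, 2.44)
                        else visits_uniform(0, 7.33)))
}

#' Sample a latent multistate path
#'
#' Competing-risks sampling: in transient state g entered at time s, a
#' latent event time is drawn for every transition out of g conditionally on
#' exceeding s; the earliest wins.  Sampling stops in an absorbing state or
#' at the horizon.
#'
#' @param spec An [scenario_spec()].
#' @return Data frame (class `npmsm_path`) with columns `time` (entry
#'   times, starting at 0) and `state` (state indices).
#' @export
sample_path <- function(spec) {
  gr <- spec$graph
  state <- sample.int(gr$H, 1L, prob = spec$start_dist)
  tm <- 0
  path <- list(time = 0, state = state)
  repeat {
    outs <- which(gr$adj[state, ])
    if (!length(outs)) break
    cand <- vapply(outs, function(h) {
      hz <- spec$hazards[[sprintf("%s->%s", gr$states[state], gr$states[h])]]
      draw_event_time(hz, tm, spec$clock)
    }, numeric(1))
    w <- which.min(cand)
    if (cand[w] > spec$horizon) break
    tm <- cand[w]
    state <- outs[w]
    path$time <- c(path$time, tm)
    path$state <- c(path$state, state)
  }
  structure(as.data.frame(path), class = c("npmsm_path", "data.frame"))
}

path_state_at <- function(path, t) {
  path$state[findInterval(t, path$time)]
}

#' Observe a latent path through a visit process
#'
#' Generates visit times from the scenario's scheme, records the state at
#' each visit, inserts the exact entry times of exactly observed states, and
#' truncates everything at the horizon.  Visits after the first observation
#' of an absorbing state are dropped (they carry no information).
#'
#' @param path A path from [sample_path()].
#' @param spec The [scenario_spec()] it was drawn from.
#' @param drop_absorbed Drop scheduled visits after the first observation of
#'   an absorbing state (default).  Retaining them (`FALSE`) adds no
#'   likelihood information but keeps the full schedule of visit times in
#'   the estimation grid, which matters for grid-sensitive summaries such as
#'   EM iteration counts.
#' @return Data frame with columns `time`, `state` (indices), the subject's
#'   observation record.
#' @export
observe_path <- function(path, spec, drop_absorbed = TRUE) {
  vs <- spec$visits
  times <- 0
  if (vs$type == "uniform") {
    t <- 0
    repeat {
      t <- t + stats::runif(1, vs$min, vs$max)
      if (t > spec$horizon) break
      times <- c(times, t)
    }
  } else {
    j <- 1L
    repeat {
      t <- vs$interval * j + stats::runif(1, -vs$jitter, vs$jitter)
      if (t > spec$horizon) break
      times <- c(times, t)
      j <- j + 1L
    }
  }
  states <- path_state_at(path, times)
  # exact entries are registered at their true times (deaths are recorded)
  ex <- which(path$state %in% spec$graph$exact & path$time <= spec$horizon &
                path$time > 0)
  if (length(ex)) {
    times <- c(times, path$time[ex])
    states <- c(states, path$state[ex])
    ord <- order(times)
    times <- times[ord]; states <- states[ord]
    keep <- !duplicated(times)
    times <- times[keep]; states <- states[keep]
  }
  # censor after the first absorbing observation
  absorbed <- which(spec$graph$absorbing[states])
  if (drop_absorbed && length(absorbed) > 1L) {
    cut <- absorbed[1L]
    times <- times[seq_len(cut)]; states <- states[seq_len(cut)]
  }
  data.frame(time = times, state = states)
}

#' Simulate an interval-censored panel study
#'
#' Draws `n` independent subjects from a scenario.  Each subject uses a
#' deterministic RNG substream derived from `seed` and the subject index, so
#' enlarging `n` leaves earlier subjects unchanged.
#'
#' @param spec An [scenario_spec()].
#' @param n Number of subjects.
#' @param seed Master seed (integer).
#' @inheritParams observe_path
#' @return List of class `npmsm_sim`: `data` (an [panel_dataset()]),
#'   `paths` (the latent truths, for evaluation) and `spec`.
#' @export
simulate_dataset <- function(spec, n, seed, drop_absorbed = TRUE) {
  stopifnot(n >= 1)
  paths <- vector("list", n)
  obs <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seed(seed, i))
    p <- sample_path(spec)
    o <- observe_path(p, spec, drop_absorbed = drop_absorbed)
    paths[[i]] <- p
    obs[[i]] <- data.frame(subject_id = sprintf("s%04d", i),
                           time = o$time, state = o$state)
  }
  panel <- panel_dataset(do.call(rbind, obs), spec$graph)
  structure(list(data = panel, paths = paths, spec = spec),
            class = "npmsm_sim")
}

# deterministic per-subject substream seed, kept below 2^31
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 69621) %% 2147483647)
}
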