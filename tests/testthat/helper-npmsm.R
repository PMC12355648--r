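# shared fixtures: graphs and small random panel generators (all built in
# code at test time)

graph_two_state <- function() transition_graph(1:2, rbind(c(1, 2)))

graph_id <- function(exact = NULL)
  transition_graph(1:3, rbind(c(1, 2), c(1, 3), c(2, 3)), exact_states = exact)

graph_eid <- function(exact = c(3, 4))
  transition_graph(1:4, rbind(c(1, 2), c(1, 3), c(2, 4)),
                   exact_states = exact)

# random two-state interval-censored panel: n subjects visited on a jittered
# schedule, event times exponential; visits truncated after the event is seen
random_two_state_panel <- function(n, rate = 0.25, max_visits = 6) {
  obs <- lapply(seq_len(n), function(i) {
    tms <- cumsum(c(0, stats::runif(sample(1:max_visits, 1), 0.2, 3)))
    ev <- stats::rexp(1, rate)
    st <- ifelse(tms < ev, 1L, 2L)
    w <- which(st == 2L)
    if (length(w)) { tms <- tms[seq_len(w[1])]; st <- st[seq_len(w[1])] }
    data.frame(subject_id = i, time = tms, state = st)
  })
  panel_dataset(do.call(rbind, obs), graph_two_state())
}

# random tiny illness-death panel on an integer grid (for the brute-force
# oracle: H = 3, K <= 3, n <= 4)
random_tiny_panel <- function(n = NULL, exact = NULL) {
  gr <- graph_id(exact)
  repeat {
    nn <- if (is.null(n)) sample(2:4, 1) else n
    obs <- lapply(seq_len(nn), function(i) {
      tms <- sort(sample(c(0, 1, 2, 3), sample(2:3, 1)))
      st <- cummax(sample(1:3, length(tms), replace = TRUE,
                          prob = c(0.5, 0.3, 0.2)))
      data.frame(subject_id = i, time = tms, state = st)
    })
    pd <- tryCatch(panel_dataset(do.call(rbind, obs), gr),
                   error = function(e) NULL)
    if (!is.null(pd) && pd$K >= 1 && pd$K <= 3) return(pd)
  }
}

# random small multistate panel from a scenario preset (moderate size)
random_scenario_panel <- function(scenario, n, seed) {
  simulate_dataset(scenario_preset(scenario), n, seed)$data
}

# random jumps inside the constraint region
random_alpha <- function(graph, K, scale = 0.8) {
  H <- graph$H
  alpha <- array(0, c(H, H, K))
  for (k in seq_len(K)) {
    for (g in seq_len(H)) {
      outs <- which(graph$adj[g, ])
      if (!length(outs)) next
      w <- stats::runif(length(outs))
      w <- scale * w / max(1, sum(w))
      alpha[g, outs, k] <- w * stats::runif(1)
    }
  }
  alpha
}
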