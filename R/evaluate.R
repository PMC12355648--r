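#' True cumulative intensity of a scenario
#'
#' For the supported hazard families the cumulative intensity in study time
#' is \eqn{A_{gh}(t) = \lambda t^{k}} (shape `k = 1` for the exponential).
#' Only meaningful for `clock = "forward"`, where the generated process is
#' Markov in study time.
#'
#' @param spec An [scenario_spec()].
#' @param from,to Transition (labels or indices).
#' @param t Evaluation times.
#' @return Numeric vector.
#' @export
true_cumhaz <- function(spec, from, to, t) {
  if (spec$clock != "forward")
    stop("no Markov truth for clock = 'reset'", call. = FALSE)
  g <- state_index(spec$graph, from); h <- state_index(spec$graph, to)
  hz <- spec$hazards[[sprintf("%s->%s", spec$graph$states[g],
                              spec$graph$states[h])]]
  if (is.null(hz))
    stop(errorCondition("transition not in the model",
                        class = c("npmsm_unknown_transition_error",
                                  "npmsm_error")))
  cumhaz(hz, t)
}

# generator matrix Q(t) of the scenario (off-diagonal hazards, diagonal
# minus the row sum)
scenario_generator <- function(spec, t) {
  gr <- spec$graph
  Q <- matrix(0, gr$H, gr$H)
  for (e in seq_along(gr$from)) {
    g <- gr$from[e]; h <- gr$to[e]
    hz <- spec$hazards[[sprintf("%s->%s", gr$states[g], gr$states[h])]]
    Q[g, h] <- hazrate(hz, t)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# matrix exponential by scaled Taylor series (tiny H, tiny norm inputs)
expm_series <- function(A, tol = 1e-14) {
  E <- diag(nrow(A)); term <- diag(nrow(A))
  for (j in 1:50) {
    term <- term %*% A / j
    E <- E + term
    if (max(abs(term)) < tol) break
  }
  E
}

#' True transition probabilities of a scenario
#'
#' Solves the Kolmogorov forward system \eqn{\partial_t P(s,t) = P(s,t)
#' Q(t)} with an adaptive Cash-Karp Runge-Kutta (4,5) integrator.  Weibull
#' hazards with shape below one are singular at the time origin; the first
#' `1e-8` years are then bridged with the exponential of the exact
#' cumulative-hazard increment, which is accurate to the stated tolerance.
#'
#' @param spec An [scenario_spec()] with `clock = "forward"`.
#' @param s Start time.
#' @param times Evaluation times (all `>= s`).
#' @param tol Local error tolerance of the integrator.
#' @return `H x H x length(times)` array of transition probability
#'   matrices.
#' @export
true_probtrans <- function(spec, s, times, tol = 1e-8) {
  if (spec$clock != "forward")
    stop("no Markov truth for clock = 'reset'", call. = FALSE)
  stopifnot(all(times >= s))
  gr <- spec$graph
  H <- gr$H
  ord <- order(times)
  out <- array(NA_real_, c(H, H, length(times)),
               dimnames = list(gr$states, gr$states, NULL))
  P <- diag(H)
  t_cur <- s
  shapes <- vapply(spec$hazards, function(h) h$shape, numeric(1))
  if (any(shapes < 1) && s == 0) {
    # bridge the singular origin with the exact cumulative increments
    eps <- 1e-8
    dA <- matrix(0, H, H)
    for (e in seq_along(gr$from)) {
      hz <- spec$hazards[[sprintf("%s->%s", gr$states[gr$from[e]],
                                  gr$states[gr$to[e]])]]
      dA[gr$from[e], gr$to[e]] <- cumhaz(hz, eps)
    }
    diag(dA) <- -rowSums(dA)
    P <- expm_series(dA)
    t_cur <- eps
  }
  deriv <- function(t, P) P %*% scenario_generator(spec, t)
  for (i in ord) {
    t_target <- times[i]
    if (t_target > t_cur) {
      P <- rk45_mat(deriv, P, t_cur, t_target, tol)
      t_cur <- t_target
    }
    out[, , i] <- P
  }
  out
}

# Cash-Karp embedded RK45 on a matrix ODE, absolute-error control
rk45_mat <- function(deriv, y, t0, t1, tol) {
  b <- list(c2 = 1/5, c3 = 3/10, c4 = 3/5, c5 = 1, c6 = 7/8)
  h <- min(t1 - t0, 0.1)
  t <- t0
  while (t < t1 - 1e-14) {
    h <- min(h, t1 - t)
    k1 <- deriv(t, y)
    k2 <- deriv(t + h/5, y + h/5 * k1)
    k3 <- deriv(t + 3*h/10, y + h * (3/40 * k1 + 9/40 * k2))
    k4 <- deriv(t + 3*h/5, y + h * (3/10 * k1 - 9/10 * k2 + 6/5 * k3))
    k5 <- deriv(t + h, y + h * (-11/54 * k1 + 5/2 * k2 - 70/27 * k3 +
                                  35/27 * k4))
    k6 <- deriv(t + 7*h/8, y + h * (1631/55296 * k1 + 175/512 * k2 +
                                      575/13824 * k3 + 44275/110592 * k4 +
                                      253/4096 * k5))
    y5 <- y + h * (37/378 * k1 + 250/621 * k3 + 125/594 * k4 +
                     512/1771 * k6)
    y4 <- y + h * (2825/27648 * k1 + 18575/48384 * k3 + 13525/55296 * k4 +
                     277/14336 * k5 + 1/4 * k6)
    err <- max(abs(y5 - y4))
    if (err <= tol || h < 1e-12) {
      t <- t + h
      y <- y5
      h <- h * min(5, max(0.2, 0.9 * (tol / max(err, 1e-16))^0.2))
    } else {
      h <- h * max(0.1, 0.9 * (tol / err)^0.25)
    }
  }
  y
}

#' Replication performance metrics
#'
#' Bias, variance (unbiased, divisor N-1) and RMSE of estimated cumulative
#' intensities or transition probabilities against a scenario's truth, on a
#' fixed evaluation grid.  Estimates are right-continuous step functions and
#' are read at each time as such.  `rmse^2 = var + bias^2` by construction.
#'
#' @param estimates List of [fit_npmsm()] fits or [intensity_grid()]s from
#'   replicate datasets of the same scenario.
#' @param spec The generating [scenario_spec()].
#' @param times Evaluation grid (default `seq(0, horizon, 0.1)`).
#' @param what `"intensity"` (cumulative intensities, per allowed
#'   transition) or `"probability"` (transition probabilities from
#'   `from_state` at time 0, per reachable state).
#' @param from_state Start state for `what = "probability"`.
#' @return Data frame with columns `from`, `to`, `t`, `truth`, `mean`,
#'   `bias`, `var`, `rmse`, `n_reps`.
#' @export
metric_curves <- function(estimates, spec,
                          times = seq(0, spec$horizon, by = 0.1),
                          what = c("intensity", "probability"),
                          from_state = 1L) {
  what <- match.arg(what)
  igs <- lapply(estimates, function(e)
    if (inherits(e, "npmsm_fit")) e$alpha else e)
  if (length(igs) < 2L)
    stop("need at least two replicates", call. = FALSE)
  gr <- spec$graph
  ok <- vapply(igs, function(ig) identical(ig$graph$states, gr$states) &&
                 identical(ig$graph$adj, gr$adj), logical(1))
  if (!all(ok))
    stop(errorCondition("replicate fits use a different model structure",
                        class = c("npmsm_shape_error", "npmsm_error")))
  N <- length(igs)
  rows <- list()
  if (what == "intensity") {
    for (e in seq_along(gr$from)) {
      g <- gr$from[e]; h <- gr$to[e]
      est <- vapply(igs, cumulative_intensity, numeric(length(times)),
                    from = g, to = h, t = times)
      truth <- true_cumhaz(spec, g, h, times)
      rows[[length(rows) + 1L]] <-
        summarise_curves(gr$states[g], gr$states[h], times, est, truth, N)
    }
  } else {
    g <- state_index(gr, from_state)
    truthP <- true_probtrans(spec, 0, times)
    estP <- lapply(igs, probtrans_grid, s = 0, times = times)
    for (h in which(gr$reach[g, ])) {
      est <- vapply(estP, function(P) P[g, h, ], numeric(length(times)))
      rows[[length(rows) + 1L]] <-
        summarise_curves(gr$states[g], gr$states[h], times,
                         est, truthP[g, h, ], N)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

summarise_curves <- function(from, to, times, est, truth, N) {
  est <- matrix(est, nrow = length(times))
  m <- rowMeans(est)
  v <- apply(est, 1L, stats::var)
  bias <- m - truth
  data.frame(from = from, to = to, t = times, truth = truth, mean = m,
             bias = bias, var = v, rmse = sqrt(v + bias^2), n_reps = N)
}

#' Run a replicate simulation study
#'
#' Simulates `N` datasets from a scenario, fits each, and collects the
#' iteration counts and the fitted intensity grids.  Replicates that fail
#' (zero-path errors) are dropped from the metric denominators and counted.
#' If `out_dir` is given, per-replicate intensity tables are written as CSV
#' keyed by the replicate seed and existing files are reused, making long
#' studies resumable.
#'
#' @param spec An [scenario_spec()] or a preset number 1..6.
#' @param n Subjects per dataset.
#' @param N Number of replicate datasets.
#' @param seed Master seed; replicate v uses a substream derived from it.
#' @param tol,criterion,max_iter Passed to [fit_npmsm()]; the benchmark
#'   study design stops when every jump changes by less than `1e-3`.
#' @param drop_absorbed Passed to [simulate_dataset()]; retaining
#'   post-absorption visits (`FALSE`) densifies the late grid, which
#'   reduces the step-function reading lag of cumulative intensities near
#'   the horizon.
#' @param out_dir Optional directory for per-replicate CSV results.
#' @return List of class `npmsm_study`: `summary` (one row per replicate:
#'   seed, n_iter, loglik, stop_reason, ok), `fits` (intensity grids of the
#'   completed replicates), `spec`, `n_failed`.
#' @export
run_replicates <- function(spec, n, N, seed, tol = 1e-3,
                           criterion = "intensity", max_iter = 5000L,
                           drop_absorbed = TRUE, out_dir = NULL) {
  if (is.numeric(spec) && length(spec) == 1L) spec <- scenario_preset(spec)
  stopifnot(inherits(spec, "npmsm_scenario"), N >= 1)
  fits <- vector("list", N)
  rows <- vector("list", N)
  for (v in seq_len(N)) {
    rep_seed <- subject_seed(seed, 1000003L + v)
    cache <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("rep_%d.csv", rep_seed)) else NULL
    if (!is.null(cache) && file.exists(cache)) {
      tab <- utils::read.csv(cache)
      tau <- sort(unique(tab$tau))
      alpha <- array(0, c(spec$graph$H, spec$graph$H, length(tau)))
      alpha[cbind(match(tab$transition_from, spec$graph$states),
                  match(tab$transition_to, spec$graph$states),
                  match(tab$tau, tau))] <- tab$jump
      fits[[v]] <- intensity_grid(spec$graph, tau, alpha)
      rows[[v]] <- data.frame(rep = v, seed = rep_seed, n_iter = NA_integer_,
                              loglik = NA_real_, stop_reason = "cached",
                              ok = TRUE)
      next
    }
    sim <- simulate_dataset(spec, n, rep_seed, drop_absorbed = drop_absorbed)
    res <- tryCatch({
      fit <- fit_npmsm(sim$data, tol = tol, criterion = criterion,
                       max_iter = max_iter, keep_loglik = FALSE)
      fits[[v]] <- fit$alpha
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        utils::write.csv(as.data.frame(fit$alpha),
                         file.path(out_dir, sprintf("rep_%d.csv", rep_seed)),
                         row.names = FALSE)
      }
      data.frame(rep = v, seed = rep_seed, n_iter = fit$n_iter,
                 loglik = fit$loglik, stop_reason = fit$stop_reason,
                 ok = TRUE)
    }, npmsm_zero_path_error = function(e) {
      data.frame(rep = v, seed = rep_seed, n_iter = NA_integer_,
                 loglik = NA_real_, stop_reason = "zero_path", ok = FALSE)
    })
    rows[[v]] <- res
  }
  summary <- do.call(rbind, rows)
  structure(list(summary = summary, fits = fits[summary$ok],
                 spec = spec, n_failed = sum(!summary$ok)),
            class = "npmsm_study")
}
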