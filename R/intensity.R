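#' Intensity jumps on a grid of observation times
#'
#' The estimator represents each cumulative transition intensity
#' \eqn{A_{gh}(t)} as a right-continuous step function with jumps
#' \eqn{\alpha_{ghk}} only at the unique observation times
#' \eqn{\tau_1 < \dots < \tau_K}.  Bin `k` is the half-open interval
#' \eqn{(\tau_{k-1}, \tau_k]} and its mass sits at the right endpoint.
#' The jumps are conditional transition probabilities and must satisfy the
#' constraint region \eqn{C_\alpha}: \eqn{\alpha_{ghk} \ge 0} and, for every
#' state and bin, \eqn{\sum_{h \leftarrow g} \alpha_{ghk} \le 1}.
#'
#' @param graph An [transition_graph()].
#' @param tau Strictly increasing positive bin endpoints
#'   \eqn{\tau_1 < \dots < \tau_K}.
#' @param alpha `H x H x K` array of jumps (entries off the allowed
#'   transitions are forced to zero), or a single number recycled to every
#'   allowed transition and bin (e.g. `1/K` for the uniform initialiser).
#' @param tau0 Time origin \eqn{\tau_0} (no mass is ever placed there).
#' @return An object of class `intensity_grid`.
#' @export
intensity_grid <- function(graph, tau, alpha = 0, tau0 = 0) {
  stopifnot(inherits(graph, "msm_graph"))
  tau <- as.numeric(tau)
  K <- length(tau)
  if (K < 1L || any(diff(tau) <= 0))
    stop("'tau' must be strictly increasing with at least one point",
         call. = FALSE)
  if (tau[1L] <= tau0)
    stop("all grid times must exceed the origin tau0", call. = FALSE)
  H <- graph$H
  if (length(alpha) == 1L) {
    a <- array(0, c(H, H, K))
    a[cbind(rep(graph$from, K), rep(graph$to, K),
            rep(seq_len(K), each = length(graph$from)))] <- alpha
    alpha <- a
  }
  alpha <- unname(alpha)
  stopifnot(length(dim(alpha)) == 3L, all(dim(alpha) == c(H, H, K)))
  mask <- array(FALSE, c(H, H, K))
  mask[cbind(rep(graph$from, K), rep(graph$to, K),
             rep(seq_len(K), each = length(graph$from)))] <- TRUE
  alpha[!mask] <- 0
  check_calpha(alpha, graph)
  structure(list(graph = graph, tau = tau, tau0 = tau0, alpha = alpha,
                 K = K),
            class = "intensity_grid")
}

# validate the constraint region C_alpha
check_calpha <- function(alpha, graph, tol = 1e-8) {
  if (any(alpha < -tol))
    stop(errorCondition("negative intensity jump",
                        class = c("npmsm_constraint_error", "npmsm_error")))
  exit_mass <- apply(alpha, c(1, 3), sum)
  if (any(exit_mass > 1 + tol))
    stop(errorCondition(
      "total exit probability exceeds 1 in some bin (outside C_alpha)",
      class = c("npmsm_constraint_error", "npmsm_error")))
  invisible(TRUE)
}

#' One-bin transition matrix `I + dA(tau_k)`
#'
#' Off-diagonal entry (g, h) is the jump \eqn{\alpha_{ghk}}; the diagonal is
#' one minus the total exit mass, so the matrix is row-stochastic whenever
#' the jumps lie in the constraint region.
#'
#' @param ig An [intensity_grid()].
#' @param k Bin index, `1..K`.
#' @return An `H x H` stochastic matrix.
#' @export
bin_generator <- function(ig, k) {
  stopifnot(inherits(ig, "intensity_grid"), k >= 1L, k <= ig$K)
  M <- ig$alpha[, , k]
  diag(M) <- 1 - rowSums(M)
  if (any(diag(M) < -1e-8))
    stop(errorCondition("row mass exceeds 1 beyond tolerance",
                        class = c("npmsm_constraint_error", "npmsm_error")))
  dimnames(M) <- list(ig$graph$states, ig$graph$states)
  M
}

#' Transition probability matrix by product integration
#'
#' \eqn{P(s,t)} is the ordered product of the one-bin matrices over the bins
#' whose right endpoint lies in `(s, t]` (Chapman-Kolmogorov for a Markov
#' process whose intensities jump only at the grid times).  `s` and `t` need
#' not be grid points; `P(s,s)` is the identity.
#'
#' @param ig An [intensity_grid()].
#' @param s,t Times with `s <= t`.
#' @return An `H x H` row-stochastic matrix.
#' @export
transition_probability <- function(ig, s, t) {
  stopifnot(inherits(ig, "intensity_grid"), s <= t)
  P <- diag(ig$graph$H)
  for (k in which(ig$tau > s & ig$tau <= t)) P <- P %*% bin_generator(ig, k)
  dimnames(P) <- list(ig$graph$states, ig$graph$states)
  P
}

#' Transition probabilities from a fixed start time along the grid
#'
#' Evaluates \eqn{P(s, t)} for a vector of times `t` in a single forward
#' sweep over the bins (prefix accumulation), so the cost is one matrix
#' product per bin rather than per query.
#'
#' @inheritParams transition_probability
#' @param times Numeric vector of evaluation times (need not be sorted).
#' @return An `H x H x length(times)` array.
#' @export
probtrans_grid <- function(ig, s = ig$tau0, times = ig$tau) {
  H <- ig$graph$H
  ord <- order(times)
  out <- array(NA_real_, c(H, H, length(times)),
               dimnames = list(ig$graph$states, ig$graph$states, NULL))
  P <- diag(H)
  kk <- which(ig$tau > s)
  j <- if (length(kk)) kk[1L] else ig$K + 1L
  for (i in ord) {
    t <- times[i]
    if (t < s) stop("evaluation time precedes the start time", call. = FALSE)
    while (j <= ig$K && ig$tau[j] <= t) {
      P <- P %*% bin_generator(ig, j)
      j <- j + 1L
    }
    out[, , i] <- P
  }
  out
}

#' Estimated cumulative transition intensity
#'
#' \eqn{\hat A_{gh}(t) = \sum_{k: \tau_k \le t} \alpha_{ghk}}, a
#' right-continuous nondecreasing step function.
#'
#' @param ig An [intensity_grid()].
#' @param from,to State labels or indices of an allowed transition.
#' @param t Numeric vector of evaluation times.
#' @return Numeric vector of the same length as `t`.
#' @export
cumulative_intensity <- function(ig, from, to, t) {
  g <- state_index(ig$graph, from)
  h <- state_index(ig$graph, to)
  if (!ig$graph$adj[g, h])
    stop(errorCondition(
      sprintf("transition %s->%s is not in the model",
              ig$graph$states[g], ig$graph$states[h]),
      class = c("npmsm_unknown_transition_error", "npmsm_error")))
  jumps <- ig$alpha[g, h, ]
  cum <- cumsum(jumps)
  idx <- findInterval(t, ig$tau)
  c(0, cum)[idx + 1L]
}

#' Tabulate estimated intensity jumps
#'
#' @param x An [intensity_grid()].
#' @param row.names,optional,... Ignored (S3 signature).
#' @return Long data frame with columns `transition_from`, `transition_to`,
#'   `tau`, `jump` and `cumulative`.
#' @export
as.data.frame.intensity_grid <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  gr <- x$graph
  out <- do.call(rbind, lapply(seq_along(gr$from), function(e) {
    g <- gr$from[e]; h <- gr$to[e]
    data.frame(transition_from = gr$states[g],
               transition_to = gr$states[h],
               tau = x$tau,
               jump = x$alpha[g, h, ],
               cumulative = cumsum(x$alpha[g, h, ]))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.intensity_grid <- function(x, ...) {
  cat(sprintf("Intensity jumps on %d bins over (%g, %g], %d transitions\n",
              x$K, x$tau0, max(x$tau), length(x$graph$from)))
  tot <- vapply(seq_along(x$graph$from), function(e)
    sum(x$alpha[x$graph$from[e], x$graph$to[e], ]), numeric(1))
  cat(paste(sprintf("  A[%s->%s](%g) = %.4f",
                    x$graph$states[x$graph$from],
                    x$graph$states[x$graph$to], max(x$tau), tot),
            collapse = "\n"), "\n")
  invisible(x)
}
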