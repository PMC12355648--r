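#' @useDynLib npmsm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Coerce an intensity_grid / array / scalar to the alpha array of a panel,
# checking grid compatibility.
as_alpha <- function(pd, alpha) {
  if (inherits(alpha, "intensity_grid")) {
    if (length(alpha$tau) != pd$K || any(alpha$tau != pd$tau))
      stop("intensity grid does not match the panel's observation times",
           call. = FALSE)
    return(alpha$alpha)
  }
  if (length(alpha) == 1L)
    return(intensity_grid(pd$graph, pd$tau, alpha, pd$tau0)$alpha)
  stopifnot(length(dim(alpha)) == 3L,
            all(dim(alpha) == c(pd$graph$H, pd$graph$H, pd$K)))
  unname(alpha)
}

estep_internal <- function(pd, alpha, which = "all") {
  iv <- pd$intervals
  if (which == "exact") iv <- iv[iv$exact, , drop = FALSE]
  if (which == "censored") iv <- iv[!iv$exact, , drop = FALSE]
  gr <- pd$graph
  res <- estep_cpp(as.numeric(alpha), gr$H, pd$K,
                   iv$a - 1L, iv$b - 1L, iv$klo - 1L, iv$khi - 1L,
                   iv$exact, gr$from - 1L, gr$to - 1L)
  if (res$err > 0) {
    bad <- iv[res$err, ]
    stop(errorCondition(
      sprintf(paste0("zero path probability for subject %s on (%g, %g] ",
                     "(%s -> %s): observed pair impossible under current ",
                     "intensities"),
              bad$subject_id, bad$l, bad$r,
              gr$states[bad$a], gr$states[bad$b]),
      class = c("npmsm_zero_path_error", "npmsm_error")))
  }
  d <- array(res$d, c(gr$H, gr$H, pd$K),
             dimnames = list(gr$states, gr$states, NULL))
  Y <- res$Y
  rownames(Y) <- gr$states
  list(d = d, Y = Y)
}

#' E-step: expected transition counts and at-risk totals
#'
#' Given current intensity jumps, computes the conditional expectation of
#' the complete-data sufficient statistics: `d[g,h,k]`, the expected number
#' of g-to-h transitions in bin k summed over subjects, and `Y[g,k]`, the
#' expected number of subjects occupying g just before \eqn{\tau_k}.  Frames
#' ending in an exactly observed entry use the exact-entry expectations
#' (all probability mass is routed through the direct predecessors of the
#' entered state at the entry bin); [e_step_exact()] returns the
#' contributions of those frames alone.
#'
#' @param pd An [panel_dataset()].
#' @param alpha Current jumps: an [intensity_grid()] on the panel's grid, an
#'   `H x H x K` array, or a scalar recycled over transitions and bins.
#' @return List with `d` (`H x H x K` array) and `Y` (`H x K` matrix).
#' @export
e_step <- function(pd, alpha) {
  stopifnot(inherits(pd, "npmsm_panel"))
  estep_internal(pd, as_alpha(pd, alpha), "all")
}

#' @rdname e_step
#' @export
e_step_exact <- function(pd, alpha) {
  stopifnot(inherits(pd, "npmsm_panel"))
  estep_internal(pd, as_alpha(pd, alpha), "exact")
}

#' M-step: constrained maximiser of the expected complete-data likelihood
#'
#' Per state g and bin k the update is \eqn{\alpha_{ghk} = d_{ghk}/Y_{gk}}
#' when the Lagrange multiplier
#' \eqn{\mu_{gk} = \max(0, \sum_{h \leftarrow g} d_{ghk} - Y_{gk})} is zero,
#' and \eqn{d_{ghk} / \sum_{h \leftarrow g} d_{ghk}} otherwise, which keeps
#' the total exit probability within 1.  An empty risk set (`Y = 0`, hence
#' `d = 0`) yields a zero jump, not `NaN`.
#'
#' @param counts List with `d` and `Y` as returned by [e_step()].
#' @param graph The [transition_graph()].
#' @return `H x H x K` array of updated jumps, inside the constraint region.
#' @export
m_step <- function(counts, graph) {
  d <- counts$d; Y <- counts$Y
  H <- graph$H; K <- ncol(Y)
  S <- colSums(aperm(d, c(2L, 1L, 3L)), dims = 1L)  # total exits per (g,k)
  mu <- pmax(S - Y, 0)
  denom <- ifelse(mu > 0, S, Y)
  alpha <- array(0, c(H, H, K))
  for (e in seq_along(graph$from)) {
    g <- graph$from[e]; h <- graph$to[e]
    dn <- denom[g, ]
    alpha[g, h, ] <- ifelse(dn > 0, d[g, h, ] / dn, 0)
  }
  # flush vanishing jumps to exact zero: below this floor a coordinate can
  # get stuck on the subnormal grid (x * c rounds back to x), and the
  # quantised d/alpha ratio corrupts the reduced gradient
  alpha[alpha < 1e-250] <- 0
  alpha
}

#' Observed-data log-likelihood
#'
#' Product over subjects and visit pairs of the transition probability
#' between the observed states; a visit recording an exactly observed entry
#' into state b at \eqn{\tau_k} instead contributes
#' \eqn{\sum_{m \leftarrow b} P_{x,m}(t_{prev}, \tau_{k-1}) \alpha_{mbk}}.
#'
#' @inheritParams e_step
#' @return The log-likelihood; `-Inf` (with attribute `zero_interval` naming
#'   the offending observation interval) if any factor is zero.
#' @export
observed_loglik <- function(pd, alpha) {
  stopifnot(inherits(pd, "npmsm_panel"))
  alpha <- as_alpha(pd, alpha)
  iv <- pd$intervals
  gr <- pd$graph
  res <- obsloglik_cpp(as.numeric(alpha), gr$H, pd$K,
                       iv$a - 1L, iv$b - 1L, iv$klo - 1L, iv$khi - 1L,
                       iv$exact, gr$from - 1L, gr$to - 1L)
  ll <- res$loglik
  if (res$zero_at > 0)
    attr(ll, "zero_interval") <- iv[res$zero_at, c("subject_id", "l", "r")]
  ll
}

#' Reduced gradient and KKT certificate
#'
#' The reduced gradient of the expected complete-data log-likelihood on the
#' constraint region is \eqn{\nabla_{ghk} = d_{ghk}/\alpha_{ghk} - Y_{gk} -
#' \mu_{gk}} at interior coordinates; at \eqn{\alpha_{ghk} = 0} the one-sided
#' directional value \eqn{\max(0, d_{ghk}/\epsilon_0 - Y_{gk} - \mu_{gk})}
#' is used, which is identically zero in EM iterates because `d` carries a
#' factor of the current jump (zero jumps are absorbing).  A (local) maximum
#' is certified when no coordinate can improve the objective:
#' `max reduced gradient < eps`.
#'
#' @param alpha `H x H x K` array (or [intensity_grid()]) at which `counts`
#'   were computed.
#' @param counts List with `d`, `Y` from [e_step()] evaluated at `alpha`.
#' @param graph The [transition_graph()].
#' @param eps0 Guard for the boundary direction (never active in EM runs).
#' @return `reduced_gradient()`: array of gradients (zero off the allowed
#'   transitions); `kkt_check()`: `TRUE` iff the maximum is below `eps`.
#' @export
reduced_gradient <- function(alpha, counts, graph, eps0 = 1e-10) {
  if (inherits(alpha, "intensity_grid")) alpha <- alpha$alpha
  d <- counts$d; Y <- counts$Y
  K <- ncol(Y)
  S <- colSums(aperm(d, c(2L, 1L, 3L)), dims = 1L)
  mu <- pmax(S - Y, 0)
  grad <- array(0, dim(alpha))
  for (e in seq_along(graph$from)) {
    g <- graph$from[e]; h <- graph$to[e]
    a <- alpha[g, h, ]; dd <- d[g, h, ]
    interior <- a > 0
    grad[g, h, interior] <- dd[interior] / a[interior] - Y[g, interior] -
      mu[g, interior]
    grad[g, h, !interior] <- pmax(0, dd[!interior] / eps0 - Y[g, !interior] -
                                    mu[g, !interior])
  }
  grad
}

#' @rdname reduced_gradient
#' @param eps Certificate tolerance.
#' @export
kkt_check <- function(alpha, counts, graph, eps = 1e-4) {
  max(reduced_gradient(alpha, counts, graph)) < eps
}

#' Fit the nonparametric intensity estimator by EM
#'
#' Alternates the E-step expectations with the constrained M-step until the
#' chosen stopping rule fires.  Initial jumps must be strictly positive on
#' every allowed transition and bin (default `1/K` everywhere) because a
#' zero jump can never become positive again.
#'
#' @param pd An [panel_dataset()].
#' @param tol Convergence tolerance.  For `criterion = "intensity"` (the
#'   default) iteration stops when the largest absolute change in any jump
#'   is below `tol`; for `"likelihood"`, when the absolute change in the
#'   observed log-likelihood is below `tol`; for `"kkt"`, when the maximum
#'   reduced gradient falls below `kkt_eps`.
#' @param criterion One of `"intensity"`, `"likelihood"`, `"kkt"`.
#' @param max_iter Iteration cap; hitting it raises a warning and returns
#'   the current estimate flagged as not converged.
#' @param init Initial jumps (scalar, array, or [intensity_grid()]);
#'   `NULL` means uniform `1/K`.
#' @param kkt_eps Tolerance for the KKT certificate.
#' @param keep_loglik Record the observed log-likelihood every iteration
#'   (costs roughly an extra forward sweep; disable for large runs under the
#'   intensity criterion).
#' @param verbose Emit a per-iteration progress line (iteration,
#'   log-likelihood, max jump change, max reduced gradient).
#' @return An object of class `npmsm_fit`: `alpha` (an [intensity_grid()]
#'   with the estimated jumps), `n_iter`, `trace` (data frame with per-
#'   iteration log-likelihood, max jump change, max reduced gradient),
#'   `stop_reason`, `converged`, and the final expected `counts`.
#'
#' @examples
#' gr <- transition_graph(1:2, rbind(c(1, 2)))
#' pd <- panel_dataset(data.frame(subject_id = 1, time = c(0, 1, 2),
#'                                state = c(1, 1, 2)), gr)
#' fit <- fit_npmsm(pd, tol = 1e-8)
#' as.data.frame(fit$alpha)
#' @export
fit_npmsm <- function(pd, tol = 1e-4,
                      criterion = c("intensity", "likelihood", "kkt"),
                      max_iter = 5000L, init = NULL, kkt_eps = 1e-4,
                      keep_loglik = TRUE, verbose = FALSE) {
  stopifnot(inherits(pd, "npmsm_panel"), tol > 0)
  criterion <- match.arg(criterion)
  gr <- pd$graph
  K <- pd$K
  # default uniform 1/K init, shrunk only when a state's out-degree reaches
  # K so that the initial stay probability is positive for every bin
  u <- min(1 / K, 0.9 / max(rowSums(gr$adj)))
  alpha <- if (is.null(init)) as_alpha(pd, u) else as_alpha(pd, init)
  edge_idx <- cbind(rep(gr$from, K), rep(gr$to, K),
                    rep(seq_len(K), each = length(gr$from)))
  if (any(alpha[edge_idx] <= 0))
    warning(paste("initial jumps are not strictly positive on every allowed",
                  "transition and bin; zero jumps stay zero for all",
                  "iterations"))
  check_calpha(alpha, gr)

  need_ll <- keep_loglik || criterion == "likelihood"
  ll_old <- if (criterion == "likelihood") observed_loglik(pd, alpha) else NA_real_
  trace <- matrix(NA_real_, max_iter, 3L,
                  dimnames = list(NULL, c("loglik", "max_delta", "max_grad")))
  stop_reason <- "max_iter"
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    counts <- estep_internal(pd, alpha, "all")
    alpha_new <- m_step(counts, gr)
    delta <- max(abs(alpha_new - alpha))
    maxgrad <- max(reduced_gradient(alpha, counts, gr))
    ll <- if (need_ll) observed_loglik(pd, alpha_new) else NA_real_
    trace[it, ] <- c(ll, delta, maxgrad)
    if (verbose)
      message(sprintf("iter %5d  loglik %14.6f  max|dalpha| %.3e  max grad %.3e",
                      it, ll, delta, maxgrad))
    if (criterion == "intensity" && delta < tol) {
      alpha <- alpha_new; stop_reason <- "intensity"; break
    }
    if (criterion == "likelihood" && abs(ll - ll_old) < tol) {
      alpha <- alpha_new; stop_reason <- "likelihood"; break
    }
    if (criterion == "kkt" && maxgrad < kkt_eps) {
      alpha <- alpha_new; stop_reason <- "kkt"; break
    }
    alpha <- alpha_new
    ll_old <- ll
  }
  if (stop_reason == "max_iter")
    warning(warningCondition(
      sprintf("EM did not converge within %d iterations", max_iter),
      class = c("npmsm_max_iter_warning", "npmsm_warning")))

  counts <- estep_internal(pd, alpha, "all")
  structure(list(
    alpha = intensity_grid(gr, pd$tau, alpha, pd$tau0),
    n_iter = it,
    trace = data.frame(iter = seq_len(it), trace[seq_len(it), , drop = FALSE]),
    stop_reason = stop_reason,
    converged = stop_reason != "max_iter",
    counts = counts,
    loglik = if (need_ll) unname(trace[it, "loglik"])
             else as.numeric(observed_loglik(pd, alpha)),
    config = list(tol = tol, criterion = criterion, max_iter = max_iter,
                  kkt_eps = kkt_eps),
    data = pd), class = "npmsm_fit")
}

#' @export
print.npmsm_fit <- function(x, ...) {
  cat(sprintf(
    "Nonparametric multistate EM fit: %d iterations (%s criterion, tol %g)\n",
    x$n_iter, x$config$criterion, x$config$tol))
  cat(sprintf("  stop reason: %s; log-likelihood %.6f\n",
              x$stop_reason, x$loglik))
  cat(sprintf("  max reduced gradient at the estimate: %.3g\n",
              max(reduced_gradient(x$alpha$alpha, x$counts, x$alpha$graph))))
  print(x$alpha)
  invisible(x)
}
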