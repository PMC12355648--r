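#' Turnbull self-consistency NPMLE for interval-censored survival data
#'
#' Independent reference implementation used for cross-checking the
#' two-state reduction of the multistate estimator.  Event times are known
#' only to lie in half-open intervals `(L_i, R_i]` (`R_i = Inf` for
#' right-censoring).  The distribution places mass on the elementary
#' intervals cut by the unique finite endpoints (a refinement of the
#' Turnbull innermost intervals; the maximised log-likelihood is identical
#' because the likelihood depends on the masses only through their sums over
#' each `(L_i, R_i]`, and the objective is concave in the masses).
#'
#' @param L,R Numeric vectors of interval endpoints, `L < R`, `R` may be
#'   `Inf`.
#' @param tol Self-consistency stopping tolerance on the masses.
#' @param max_iter Iteration cap.
#' @return List of class `turnbull_fit`: `intervals` (two-column matrix of
#'   elementary intervals), `p` (masses), `loglik`, `n_iter`, and `cdf`, a
#'   function evaluating the fitted distribution at the finite cut points.
#' @export
turnbull_fit <- function(L, R, tol = 1e-10, max_iter = 100000L) {
  stopifnot(length(L) == length(R), all(L < R))
  n <- length(L)
  cuts <- sort(unique(c(L, R[is.finite(R)])))
  lo <- c(cuts)
  hi <- c(cuts[-1L], Inf)
  has_inf <- any(!is.finite(R))
  if (!has_inf) { lo <- lo[-length(lo)]; hi <- hi[-length(hi)] }
  J <- length(lo)
  # A[i, j] = 1 iff elementary interval j lies inside (L_i, R_i]
  A <- outer(L, lo, `<=`) & outer(R, hi, `>=`)
  if (any(rowSums(A) == 0))
    stop("an observation interval contains no candidate mass", call. = FALSE)
  p <- rep(1 / J, J)
  for (it in seq_len(max_iter)) {
    denom <- as.numeric(A %*% p)
    p_new <- p * as.numeric(crossprod(A, 1 / denom)) / n
    if (max(abs(p_new - p)) < tol) { p <- p_new; break }
    p <- p_new
  }
  loglik <- sum(log(as.numeric(A %*% p)))
  cdf <- function(t) vapply(t, function(x) sum(p[hi <= x]), numeric(1))
  structure(list(intervals = cbind(lo = lo, hi = hi), p = p,
                 loglik = loglik, n_iter = it, cdf = cdf),
            class = "turnbull_fit")
}

#' Reduce a two-state panel to censoring intervals
#'
#' For the two-state (alive/event) model a subject's whole observation
#' record collapses to the interval between the last visit in state 1 and
#' the first visit in state 2 (`Inf` if the event was never observed), and
#' the multistate likelihood factors into exactly the Turnbull likelihood of
#' these intervals.
#'
#' @param pd An [panel_dataset()] on a two-state model.
#' @return Data frame with columns `L`, `R`.
#' @export
two_state_intervals <- function(pd) {
  stopifnot(inherits(pd, "npmsm_panel"), pd$graph$H == 2L)
  obs <- pd$observations
  out <- lapply(split(obs, obs$subject_id), function(d) {
    t1 <- d$time[d$state == 1L]
    t2 <- d$time[d$state == 2L]
    # a subject first observed in state 2 carries no likelihood information
    if (!length(t1)) return(NULL)
    data.frame(L = max(t1), R = if (length(t2)) min(t2) else Inf)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Brute-force maximiser of the observed-data log-likelihood
#'
#' Test oracle for tiny instances: maximises the observed-data
#' log-likelihood over the constraint region by multi-start quasi-Newton
#' optimisation in a multinomial-logit parameterisation of each (state, bin)
#' exit simplex.  The objective is evaluated by direct matrix products,
#' sharing no code with the EM path.  Exactly observed states are not
#' supported (instances are purely interval-censored).
#'
#' @param pd An [panel_dataset()] with at most 3 states, 3 grid times and 4
#'   subjects.
#' @param n_starts Number of random starts (first start is uniform).
#' @param seed Seed for the random starts.
#' @return List with `alpha` (the best jumps found, `H x H x K`) and
#'   `loglik`.
#' @export
brute_force_mle <- function(pd, n_starts = 20L, seed = 1L) {
  stopifnot(inherits(pd, "npmsm_panel"))
  gr <- pd$graph
  if (gr$H > 3L || pd$K > 3L || pd$n > 4L)
    stop(errorCondition("instance exceeds the brute-force size cap",
                        class = c("npmsm_dimension_error", "npmsm_error")))
  if (length(gr$exact))
    stop("brute-force oracle does not handle exactly observed states",
         call. = FALSE)
  K <- pd$K; H <- gr$H
  edges <- cbind(gr$from, gr$to)
  n_par <- nrow(edges) * K

  theta_to_alpha <- function(theta) {
    alpha <- array(0, c(H, H, K))
    th <- matrix(theta, nrow = nrow(edges))
    for (k in seq_len(K)) {
      for (g in unique(gr$from)) {
        eg <- which(gr$from == g)
        m <- max(0, th[eg, k])  # stable softmax with "stay" as baseline
        w <- exp(th[eg, k] - m)
        alpha[g, gr$to[eg], k] <- w / (exp(-m) + sum(w))
      }
    }
    alpha
  }
  # direct likelihood: product over observation intervals of matrix products
  negll <- function(theta) {
    alpha <- theta_to_alpha(theta)
    ll <- 0
    iv <- pd$intervals
    for (i in seq_len(nrow(iv))) {
      P <- diag(H)
      for (k in iv$klo[i]:iv$khi[i]) {
        M <- alpha[, , k]
        diag(M) <- 1 - rowSums(M)
        P <- P %*% M
      }
      pr <- P[iv$a[i], iv$b[i]]
      if (pr <= 0) return(1e10)
      ll <- ll + log(pr)
    }
    -ll
  }

  set.seed(seed)
  best <- list(value = Inf)
  for (s in seq_len(n_starts)) {
    theta0 <- if (s == 1L) rep(0, n_par) else stats::rnorm(n_par, 0, 2)
    opt <- stats::optim(theta0, negll, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-14))
    # polish with Nelder-Mead to creep along boundary directions
    opt <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (opt$value < best$value) best <- opt
  }
  list(alpha = theta_to_alpha(best$par), loglik = -best$value)
}
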