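#' Assemble an interval-censored panel dataset
#'
#' Takes long-format panel observations (one row per subject visit) and a
#' transition graph, validates them, and derives everything the estimator
#' needs: the grid of unique observation times, and for every subject the
#' observation intervals that bracket each bin.  A subject observed in state
#' `a` at time `l` and next in state `b` at time `r` contributes, for every
#' bin \eqn{(\tau_{k-1}, \tau_k] \subseteq (l, r]}, a *frame* with endpoints
#' `(l, r)` and states `(a, b)`.  When `b` is an exactly observed state and
#' the visit at `r` is the subject's first observation of `b`, the frame is
#' flagged exact-terminal: entry into `b` happened exactly at `r`.
#'
#' @param data Data frame with columns `subject_id`, `time`, `state`.
#'   States may be the graph's labels or 1-based indices.  Duplicate
#'   (subject, time) rows with identical states are collapsed.
#' @param graph An [transition_graph()].
#' @param extra_times Optional additional candidate jump times to include in
#'   the grid beyond the subjects' own visit times (finer bins never change
#'   the attainable likelihood; useful for aligning grids across datasets
#'   and for worked examples).
#' @return An object of class `npmsm_panel` with components `graph`, `tau`
#'   (grid of unique non-baseline visit times), `tau0`, `K`, `n`,
#'   `observations` (normalised long data) and `intervals` (one row per
#'   consecutive visit pair, with the bin range it spans).
#' @export
panel_dataset <- function(data, graph, extra_times = NULL) {
  stopifnot(inherits(graph, "msm_graph"))
  data <- as.data.frame(data)
  need <- c("subject_id", "time", "state")
  if (!all(need %in% names(data)))
    stop(errorCondition(
      sprintf("missing column(s): %s",
              paste(setdiff(need, names(data)), collapse = ", ")),
      class = c("npmsm_format_error", "npmsm_error")))
  if (!is.numeric(data$time) || anyNA(suppressWarnings(as.numeric(data$time))))
    stop(errorCondition("'time' must be numeric",
                        class = c("npmsm_format_error", "npmsm_error")))
  st <- data$state
  if (is.numeric(st)) {
    if (any(st %% 1 != 0) || any(st < 1) || any(st > graph$H))
      stop(errorCondition("integer states must lie in 1..H",
                          class = c("npmsm_unknown_state_error", "npmsm_error")))
    sidx <- as.integer(st)
  } else {
    sidx <- state_index(graph, st)
  }
  obs <- data.frame(subject_id = as.character(data$subject_id),
                    time = as.numeric(data$time), state = sidx)
  obs <- obs[order(obs$subject_id, obs$time, obs$state), ]
  dup <- duplicated(obs[c("subject_id", "time")])
  if (any(dup &
          !duplicated(obs[c("subject_id", "time", "state")])))
    stop(errorCondition(
      "duplicate (subject, time) observations with conflicting states",
      class = c("npmsm_consistency_error", "npmsm_error")))
  obs <- obs[!dup, ]
  rownames(obs) <- NULL

  by_subj <- split(seq_len(nrow(obs)), obs$subject_id)
  # path validity: consecutive states must be connected by a directed path
  for (id in names(by_subj)) {
    ix <- by_subj[[id]]
    s <- obs$state[ix]
    if (length(s) > 1L) {
      ok <- graph$reach[cbind(s[-length(s)], s[-1L])]
      if (!all(ok)) {
        j <- which(!ok)[1L]
        stop(errorCondition(
          sprintf("subject %s: no directed path from state %s to state %s",
                  id, graph$states[s[j]], graph$states[s[j + 1L]]),
          class = c("npmsm_consistency_error", "npmsm_error")))
      }
    }
  }

  first_time <- vapply(by_subj, function(ix) obs$time[ix[1L]], numeric(1))
  tau0 <- if (all(first_time == 0)) 0 else min(first_time)
  later <- unlist(lapply(by_subj, function(ix) ix[-1L]), use.names = FALSE)
  tau <- sort(unique(c(obs$time[later], extra_times)))
  tau <- tau[tau > tau0]
  K <- length(tau)

  intervals <- vector("list", length(by_subj))
  for (s_i in seq_along(by_subj)) {
    ix <- by_subj[[s_i]]
    ni <- length(ix)
    if (ni < 2L) { intervals[[s_i]] <- NULL; next }
    tm <- obs$time[ix]; st <- obs$state[ix]
    seen <- st[1L]
    rows <- vector("list", ni - 1L)
    for (j in 2L:ni) {
      klo <- findInterval(tm[j - 1L], tau) + 1L
      khi <- findInterval(tm[j], tau)
      is_entry <- st[j] != st[j - 1L] && !(st[j] %in% seen)
      exact <- (st[j] %in% graph$exact) && is_entry
      seen <- c(seen, st[j])
      rows[[j - 1L]] <- data.frame(
        subject_id = names(by_subj)[s_i], a = st[j - 1L], b = st[j],
        l = tm[j - 1L], r = tm[j], klo = klo, khi = khi, exact = exact)
    }
    intervals[[s_i]] <- do.call(rbind, rows)
  }
  intervals <- if (length(intervals)) do.call(rbind, intervals) else
    data.frame(subject_id = character(), a = integer(), b = integer(),
               l = numeric(), r = numeric(), klo = integer(),
               khi = integer(), exact = logical())
  rownames(intervals) <- NULL

  structure(list(graph = graph, tau = tau, tau0 = tau0, K = K,
                 n = length(by_subj), observations = obs,
                 intervals = intervals),
            class = "npmsm_panel")
}

#' Read / write long-format panel data
#'
#' The de-facto long format used by panel multistate software: columns
#' `subject_id`, `time`, `state`, one row per visit, comma- or
#' tab-separated by file extension.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @param graph An [transition_graph()] used to validate the data.
#' @return `read_panel()` returns an `npmsm_panel`; `write_panel()` returns
#'   the path, invisibly.
#' @examples
#' gr <- read_model_config(system.file("extdata", "illness_death_model.json",
#'                                     package = "npmsm"))
#' pd <- read_panel(system.file("extdata", "illness_death_panel.csv",
#'                              package = "npmsm"), gr)
#' pd
#' @export
read_panel <- function(path, graph) {
  if (!file.exists(path))
    stop(errorCondition(sprintf("panel file not found: %s", path),
                        class = c("npmsm_format_error", "npmsm_error")))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  panel_dataset(df, graph)
}

#' @param x An `npmsm_panel` or a data frame in the long format.
#' @rdname read_panel
#' @export
write_panel <- function(x, path) {
  df <- if (inherits(x, "npmsm_panel")) {
    data.frame(subject_id = x$observations$subject_id,
               time = x$observations$time,
               state = x$graph$states[x$observations$state])
  } else as.data.frame(x)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-subject, per-bin frames
#'
#' Expands the observation intervals into one row per (subject, bin) pair:
#' the bracketing observation times `l <= tau_{k-1} < tau_k <= r`, the states
#' `a = X(l)`, `b = X(r)` occupied there, and whether the frame ends in an
#' exactly observed entry (in which case `k_ri` is the bin whose right
#' endpoint is the recorded entry time).  Bins outside a subject's
#' observation span carry no information and are not emitted.
#'
#' @param pd An [panel_dataset()].
#' @return Data frame with columns `subject_id`, `k`, `tau`, `l`, `r`,
#'   `a`, `b`, `exact_terminal`, `k_ri`.
#' @export
bin_frames <- function(pd) {
  stopifnot(inherits(pd, "npmsm_panel"))
  iv <- pd$intervals
  nb <- pmax(iv$khi - iv$klo + 1L, 0L)
  idx <- rep(seq_len(nrow(iv)), nb)
  k <- unlist(lapply(seq_len(nrow(iv)),
                     function(i) if (nb[i] > 0) iv$klo[i]:iv$khi[i] else integer(0)),
              use.names = FALSE)
  out <- data.frame(subject_id = iv$subject_id[idx], k = k,
                    tau = pd$tau[k], l = iv$l[idx], r = iv$r[idx],
                    a = pd$graph$states[iv$a[idx]],
                    b = pd$graph$states[iv$b[idx]],
                    exact_terminal = iv$exact[idx],
                    k_ri = ifelse(iv$exact[idx], iv$khi[idx], NA_integer_))
  rownames(out) <- NULL
  out
}

#' Exact-entry annotation of the observations
#'
#' Flags, for every observation row, whether it records an exactly observed
#' entry: the state lies in the declared exact subset and this is the
#' subject's first observation of it (after the baseline visit).
#'
#' @param pd An [panel_dataset()].
#' @return Logical vector aligned with `pd$observations`.
#' @export
exactness_annotation <- function(pd) {
  stopifnot(inherits(pd, "npmsm_panel"))
  obs <- pd$observations
  flag <- logical(nrow(obs))
  for (ix in split(seq_len(nrow(obs)), obs$subject_id)) {
    st <- obs$state[ix]
    first <- !duplicated(st)
    flag[ix] <- first & st %in% pd$graph$exact & seq_along(ix) > 1L
  }
  flag
}

#' @export
print.npmsm_panel <- function(x, ...) {
  cat(sprintf(
    "Interval-censored panel: %d subjects, %d observations, %d grid times\n",
    x$n, nrow(x$observations), x$K))
  if (any(x$intervals$exact))
    cat(sprintf("  %d exactly observed entries\n", sum(x$intervals$exact)))
  invisible(x)
}
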