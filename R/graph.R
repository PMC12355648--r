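#' Define a multistate transition structure
#'
#' A multistate model without loops is described by its state labels, the set
#' of allowed direct transitions, and an optional subset of *exactly observed*
#' states: states (typically death) whose entry time is recorded exactly
#' rather than interval-censored.  The directed graph of allowed transitions
#' must be acyclic and free of self-loops; without this, the number of visits
#' to a state is not identifiable from panel data and no nonparametric
#' estimator can be consistent.
#'
#' @param states Character or integer vector of state labels, in display
#'   order.  Internally states are indexed `1..H` in this order.
#' @param transitions Two-column matrix or data frame of allowed direct
#'   transitions (from, to), using the labels in `states`; alternatively a
#'   list of length-2 vectors.
#' @param exact_states Subset of `states` whose entry times are exactly
#'   observed (may be empty, the default).
#'
#' @return An object of class `msm_graph` with components `states`, `H`,
#'   `from`/`to` (integer edge lists), `adj` (H x H logical adjacency),
#'   `reach` (H x H logical reachability, including staying put),
#'   `exact` (integer indices of exact states), `topo_order` (a topological
#'   order of the state indices) and `absorbing` (logical, no out-edges).
#'
#' @examples
#' # illness-death model with exactly observed death
#' gr <- transition_graph(c("healthy", "ill", "dead"),
#'                        rbind(c("healthy", "ill"),
#'                              c("healthy", "dead"),
#'                              c("ill", "dead")),
#'                        exact_states = "dead")
#' gr
#' @export
transition_graph <- function(states, transitions, exact_states = NULL) {
  states <- as.character(states)
  if (anyDuplicated(states))
    stop("duplicate state labels", call. = FALSE)
  H <- length(states)
  if (is.list(transitions) && !is.data.frame(transitions))
    transitions <- do.call(rbind, transitions)
  transitions <- as.matrix(transitions)
  if (ncol(transitions) != 2L)
    stop("'transitions' must have two columns (from, to)", call. = FALSE)
  lab2idx <- function(x, what) {
    i <- match(as.character(x), states)
    if (anyNA(i)) {
      bad <- unique(as.character(x)[is.na(i)])
      stop(errorCondition(
        sprintf("unknown state label(s) in %s: %s", what,
                paste(bad, collapse = ", ")),
        class = c("npmsm_unknown_state_error", "npmsm_error")))
    }
    i
  }
  from <- lab2idx(transitions[, 1L], "transitions")
  to <- lab2idx(transitions[, 2L], "transitions")
  if (any(from == to))
    stop(errorCondition("self-loop transitions are not allowed",
                        class = c("npmsm_cycle_error", "npmsm_error")))
  if (anyDuplicated(cbind(from, to))) {
    keep <- !duplicated(cbind(from, to))
    from <- from[keep]; to <- to[keep]
  }
  adj <- matrix(FALSE, H, H, dimnames = list(states, states))
  adj[cbind(from, to)] <- TRUE

  topo <- topo_sort(adj)  # errors on cycles
  exact <- if (is.null(exact_states) || length(exact_states) == 0L) integer(0)
           else sort(unique(lab2idx(exact_states, "exact_states")))

  # reachability by directed path (reflexive transitive closure)
  reach <- diag(TRUE, H)
  for (g in rev(topo)) {
    for (h in which(adj[g, ])) reach[g, ] <- reach[g, ] | reach[h, ]
  }
  dimnames(reach) <- list(states, states)

  structure(list(states = states, H = H, from = from, to = to,
                 adj = adj, reach = reach, exact = exact,
                 topo_order = topo,
                 absorbing = rowSums(adj) == 0L),
            class = "msm_graph")
}

# Kahn's algorithm; raises a classed cycle error if no topological order.
topo_sort <- function(adj) {
  H <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  avail <- which(indeg == 0L)
  while (length(avail)) {
    g <- avail[1L]; avail <- avail[-1L]
    order <- c(order, g)
    for (h in which(adj[g, ])) {
      indeg[h] <- indeg[h] - 1L
      if (indeg[h] == 0L) avail <- c(avail, h)
    }
  }
  if (length(order) < H)
    stop(errorCondition("transition graph contains a directed cycle",
                        class = c("npmsm_cycle_error", "npmsm_error")))
  unname(order)
}

#' States from which a state is directly reachable
#'
#' Returns the set of states with a direct edge into `state`; for an exactly
#' observed state this is the set of states the process can have occupied
#' just before its recorded entry.
#'
#' @param graph An [transition_graph()] object.
#' @param state A state label or index.
#' @return Integer vector of state indices (named by label).
#' @export
reachable_from <- function(graph, state) {
  h <- state_index(graph, state)
  idx <- which(graph$adj[, h])
  stats::setNames(idx, graph$states[idx])
}

state_index <- function(graph, state) {
  if (is.numeric(state) && all(state %in% seq_len(graph$H)))
    return(as.integer(state))
  i <- match(as.character(state), graph$states)
  if (anyNA(i))
    stop(errorCondition(
      sprintf("unknown state label: %s", paste(state[is.na(i)], collapse = ", ")),
      class = c("npmsm_unknown_state_error", "npmsm_error")))
  i
}

#' @export
print.msm_graph <- function(x, ...) {
  cat(sprintf("Multistate transition graph: %d states, %d transitions\n",
              x$H, length(x$from)))
  cat("  states:", paste(x$states, collapse = ", "), "\n")
  cat("  transitions:",
      paste(sprintf("%s->%s", x$states[x$from], x$states[x$to]),
            collapse = ", "), "\n")
  if (length(x$exact))
    cat("  exactly observed:", paste(x$states[x$exact], collapse = ", "), "\n")
  invisible(x)
}

#' Read a model configuration file
#'
#' JSON with fields `states` (array), `transitions` (array of two-element
#' arrays) and optionally `exact_states`.
#'
#' @param path Path to a JSON model config.
#' @return An [transition_graph()] object.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("model config not found: %s", path), call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$states) || is.null(cfg$transitions))
    stop("model config must contain 'states' and 'transitions'", call. = FALSE)
  tr <- cfg$transitions
  if (is.list(tr)) tr <- do.call(rbind, tr)
  transition_graph(cfg$states, tr, cfg$exact_states)
}
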