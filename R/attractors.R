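# Attractor enumeration by generate-and-test over length-n cycles:
# enumerate every path of length n that loops back to its start, keep those
# whose trace is a trap domain (closed under successors), and keep only the
# minimal covering cycles -- those whose length equals the length of the
# shortest closed walk through all trace states.  Each surviving trace is an
# attractor; traces are canonicalized so an attractor is reported once
# regardless of starting state or traversal.

# Internal: all cycles of length n as character-key vectors (length n+1,
# first == last), one per (start state, traversal).  Depth-first extension
# with reachability pruning: a branch is abandoned as soon as the start
# state cannot be reached within the remaining step budget.
cycles_from_adjacency <- function(adj, n) {
  radj <- reverse_adjacency(adj)
  out <- list()
  for (s0 in names(adj)) {
    dist <- bfs_dist_to(radj, s0)
    # s0 must lie on some cycle at all
    if (!any(!is.na(dist[adj[[s0]]]))) next
    dfs <- function(path, cur, depth) {
      if (depth == n) {
        if (cur == s0) out[[length(out) + 1L]] <<- path
        return(invisible(NULL))
      }
      for (nxt in adj[[cur]]) {
        dn <- dist[[nxt]]
        if (!is.na(dn) && dn <= n - depth - 1L)
          dfs(c(path, nxt), nxt, depth + 1L)
      }
    }
    dfs(s0, s0, 0L)
  }
  out
}

is_trap_trace <- function(adj, trace)
  all(vapply(trace, function(k) all(adj[[k]] %in% trace), logical(1)))

check_cycle_keys <- function(adj, keys) {
  if (keys[1] != keys[length(keys)])
    an_stop("not a cycle: the path does not loop back to its first state")
  for (i in seq_len(length(keys) - 1))
    if (!keys[i + 1] %in% adj[[keys[i]]])
      an_stop("not a valid path: ", keys[i + 1],
              " is not a successor of ", keys[i])
  invisible(keys)
}

#' Enumerate all cycles of length n
#'
#' Every path of length `n` whose last state equals its first, found by
#' depth-first extension from every possible initial state; each witnessing
#' traversal is returned once, so a simple cycle appears once per rotation.
#' The scheme's constraints are inherited from the successor relation
#' (asynchronous: one automaton changes per step; synchronous: every
#' automaton with a playable transition changes).
#'
#' @param x An [automata_network()] or a `successor_provider`.
#' @param n Cycle length, >= 1.
#' @param scheme Update scheme (required for a network, forbidden to
#'   disagree with a provider).
#' @return List of `an_path`-like objects (fields `keys`, `scheme`).
#' @export
enumerate_cycles <- function(x, n, scheme = NULL) {
  p <- as_provider(x, scheme)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    an_stop("cycle length n must be a positive integer",
            class = "an_usage_error")
  adj <- full_adjacency(p)
  lapply(cycles_from_adjacency(adj, as.integer(n)), function(keys)
    structure(list(keys = keys, scheme = p$scheme), class = "an_path"))
}

#' Is a cycle a trap cycle?
#'
#' TRUE iff every successor of every state of the cycle's trace lies inside
#' the trace.  Successors that jump between trace states through transitions
#' not on the cycle are allowed (they are shortcuts within the same
#' attractor); only transitions escaping the trace disqualify it.
#'
#' @inheritParams enumerate_cycles
#' @param path A cycle: `an_path`, character key vector, or list of states.
#' @return Logical scalar.
#' @export
is_trap_cycle <- function(x, path, scheme = NULL) {
  p <- as_provider(x, scheme)
  adj <- full_adjacency(p)
  keys <- check_cycle_keys(adj, path_keys(path))
  is_trap_trace(adj, unique(keys))
}

# Internal: length of the shortest closed walk visiting every state of
# `trace`, restricted to edges inside the trace.  Breadth-first search over
# (state, visited-set bitmask) pairs from each possible start.  Inf when no
# covering closed walk exists (trace not strongly connected).
covering_walk_adj <- function(adj, trace) {
  t <- length(trace)
  if (t > 16)
    an_stop("covering-walk search is limited to traces of at most 16 states")
  idx <- stats::setNames(seq_len(t), trace)
  nb <- lapply(trace, function(k) unname(idx[intersect(adj[[k]], trace)]))
  full <- bitwShiftL(1L, t) - 1L
  best <- Inf
  for (s in seq_len(t)) {
    start_mask <- bitwShiftL(1L, s - 1L)
    visited <- matrix(FALSE, nrow = t, ncol = full + 1L)  # column = mask + 1
    visited[s, start_mask + 1L] <- TRUE
    qn <- s
    qm <- start_mask
    d <- 0L
    found <- Inf
    while (length(qn) > 0 && is.infinite(found)) {
      d <- d + 1L
      nn <- integer(0)
      nm <- integer(0)
      for (i in seq_along(qn)) {
        for (v in nb[[qn[i]]]) {
          m2 <- bitwOr(qm[i], bitwShiftL(1L, v - 1L))
          if (v == s && m2 == full) found <- min(found, d)
          if (!visited[v, m2 + 1L]) {
            visited[v, m2 + 1L] <- TRUE
            nn <- c(nn, v)
            nm <- c(nm, m2)
          }
        }
      }
      qn <- nn
      qm <- nm
    }
    best <- min(best, found)
  }
  best
}

#' Shortest covering closed walk of a state set
#'
#' The minimal n such that some cycle of length n visits every state of the
#' set (using only edges within the set).  For most attractors this equals
#' the trace size; for complex "star" attractors it is strictly larger, as
#' a hub state must be revisited.
#'
#' @inheritParams enumerate_cycles
#' @param states Character vector of state keys, or list of states.
#' @return Integer length, or `Inf` when the set is not strongly connected.
#' @examples
#' shortest_covering_walk(star_model(), c("s0", "s1", "s2", "s3"))  # 6
#' @export
shortest_covering_walk <- function(x, states, scheme = NULL) {
  p <- as_provider(x, scheme)
  adj <- full_adjacency(p)
  trace <- unique(path_keys(states))
  covering_walk_adj(adj, trace)
}

#' Is a trap cycle minimal?
#'
#' A witnessing cycle of length n is minimal iff n equals the length of the
#' shortest closed walk covering its trace.  This single criterion subsumes
#' the usual non-minimality symptoms: a shorter repetition-free covering
#' cycle, shortcut edges that shorten the traversal, repetitions between
#' successive states, and whole-cycle repetition.
#'
#' @inheritParams is_trap_cycle
#' @return Logical scalar.
#' @export
is_minimal_cycle <- function(x, path, scheme = NULL) {
  p <- as_provider(x, scheme)
  adj <- full_adjacency(p)
  keys <- check_cycle_keys(adj, path_keys(path))
  n <- length(keys) - 1L
  covering_walk_adj(adj, unique(keys)) == n
}

make_attractor <- function(p, trace, n) {
  trace <- sort(trace)
  structure(list(
    keys = trace,
    states = lapply(trace, p$decode),
    size = length(trace),
    cycle_length = as.integer(n),
    scheme = p$scheme,
    id = paste(trace, collapse = " | ")
  ), class = "an_attractor")
}

#' @export
print.an_attractor <- function(x, ...) {
  cat(sprintf("Attractor of size %d (%s), covering cycle length %d:\n",
              x$size, x$scheme, x$cycle_length))
  cat(paste0("  ", x$keys, collapse = "\n"), "\n")
  invisible(x)
}

attractors_from_adjacency <- function(p, adj, n, dedupe = TRUE) {
  cycles <- cycles_from_adjacency(adj, n)
  walk_len <- new.env(parent = emptyenv())
  res <- list()
  for (keys in cycles) {
    trace <- unique(keys)
    if (length(trace) < 2) next       # singleton traces are fixed-point land
    if (!is_trap_trace(adj, trace)) next
    tk <- paste(sort(trace), collapse = "|")
    L <- walk_len[[tk]]
    if (is.null(L)) {
      L <- covering_walk_adj(adj, trace)
      walk_len[[tk]] <- L
    }
    if (L == n)
      res[[length(res) + 1L]] <- make_attractor(p, trace, n)
  }
  if (dedupe) {
    ids <- vapply(res, function(a) a$id, character(1))
    res <- res[!duplicated(ids)]
  }
  ids <- vapply(res, function(a) a$id, character(1))
  res[order(ids)]
}

#' Enumerate the attractors covered by a cycle of length n
#'
#' Generate-and-test: all length-n cycles, filtered to trap cycles, filtered
#' to minimal covering cycles (see [is_minimal_cycle()]).  Each surviving
#' trace is an attractor of the model.  With `dedupe = TRUE` (default) each
#' attractor is reported once; with `dedupe = FALSE` one result is returned
#' per witnessing cycle (answer-set-like multiplicity, distinguished by
#' starting state and traversal).
#'
#' @inheritParams enumerate_cycles
#' @param dedupe Canonicalize and deduplicate traces (default `TRUE`).
#' @return List of `an_attractor` objects in deterministic order.  Empty
#'   when no attractor is covered by a minimal cycle of length exactly `n`.
#' @examples
#' a <- enumerate_attractors(toy_model(), 2, "asynchronous")
#' a[[1]]$keys
#' @export
enumerate_attractors <- function(x, n, scheme = NULL, dedupe = TRUE) {
  p <- as_provider(x, scheme)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1)
    an_stop("attractor search needs a cycle length n >= 1; ",
            "steady states are enumerated by enumerate_fixed_points()",
            class = "an_usage_error")
  adj <- full_adjacency(p)
  attractors_from_adjacency(p, adj, as.integer(n), dedupe = dedupe)
}

#' Enumerate all attractors up to a covering-cycle length bound
#'
#' Unions [enumerate_attractors()] over n = 1..`max_n` with trace-level
#' deduplication; each attractor reports the smallest covering cycle length
#' at which it was found.  Completeness holds whenever `max_n` is at least
#' the shortest covering walk length of every attractor (for an attractor of
#' trace size s this can exceed s, but never exceeds the number of states
#' squared).
#'
#' @inheritParams enumerate_cycles
#' @param max_n Largest cycle length to consider.
#' @return List of `an_attractor` objects in deterministic order.
#' @examples
#' length(enumerate_all_attractors(star_model(), 6))  # 1
#' @export
enumerate_all_attractors <- function(x, max_n, scheme = NULL) {
  p <- as_provider(x, scheme)
  if (!is.numeric(max_n) || length(max_n) != 1 || is.na(max_n) || max_n < 1)
    an_stop("max_n must be a positive integer", class = "an_usage_error")
  adj <- full_adjacency(p)
  seen <- character(0)
  res <- list()
  for (n in seq_len(as.integer(max_n))) {
    for (a in attractors_from_adjacency(p, adj, n)) {
      if (!a$id %in% seen) {
        seen <- c(seen, a$id)
        res[[length(res) + 1L]] <- a
      }
    }
  }
  ids <- vapply(res, function(a) a$id, character(1))
  res[order(ids)]
}
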