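# Steady-state enumeration: prefilter local states that can never be stable
# (origins of condition-free "self-transitions", which are playable in every
# state where the origin is active), then iterate the product of surviving
# candidates and keep the states with no playable transition at all.

#' Per-automaton local states that can still be stable
#'
#' A local state that is the origin of a transition with an empty condition
#' can never belong to a fixed point: such a transition is playable in every
#' global state where that local state is active.  This prefilter removes
#' those levels; it is a pure optimization and never changes the enumerated
#' set of fixed points.
#'
#' @param net An [automata_network()].
#' @return Named list: automaton -> sorted integer vector of surviving
#'   levels.  An automaton with an empty vector means the network has no
#'   fixed point at all.
#' @export
stable_candidates <- function(net) {
  stopifnot(inherits(net, "automata_network"))
  excluded <- lapply(net$transitions, function(tr)
    if (length(tr$condition) == 0) c(tr$automaton, tr$origin) else NULL)
  cand <- lapply(stats::setNames(names(net$automata), names(net$automata)),
                 function(a) 0:(net$automata[[a]] - 1))
  for (e in excluded)
    if (!is.null(e))
      cand[[e[1]]] <- setdiff(cand[[e[1]]], as.integer(e[2]))
  lapply(cand, function(v) sort(as.integer(v)))
}

#' Enumerate all fixed points (steady states)
#'
#' Returns exactly the global states in which no local transition is
#' playable.  The set is identical under the asynchronous and synchronous
#' schemes, since both have an empty update-set family exactly there.
#' Enumeration iterates the Cartesian product of [stable_candidates()] with
#' a mixed-radix counter (no materialization of the full product), so large
#' candidate spaces stay memory-bounded.
#'
#' @param net An [automata_network()].
#' @param guard Refuse candidate spaces larger than this many states.
#' @return List of global states, in lexicographic order of the automaton
#'   declaration.
#' @examples
#' fp <- enumerate_fixed_points(toy_model())
#' vapply(fp, state_key, character(1))
#' @export
enumerate_fixed_points <- function(net, guard = 1e8) {
  cand <- stable_candidates(net)
  sizes <- vapply(cand, length, integer(1))
  if (any(sizes == 0)) return(list())
  if (prod(as.numeric(sizes)) > guard)
    an_stop("candidate space has ", format(prod(as.numeric(sizes))),
            " states, above the guard")
  auts <- names(net$automata)
  m <- length(auts)
  # per-transition requirements: automaton indices and required levels
  reqs <- lapply(net$transitions, function(tr) {
    req_auts <- c(tr$automaton, names(tr$condition))
    list(idx = match(req_auts, auts),
         lev = as.integer(c(tr$origin, tr$condition)))
  })
  counter <- rep(1L, m)
  out <- list()
  repeat {
    st <- vapply(seq_len(m), function(i) cand[[i]][counter[i]], integer(1))
    names(st) <- auts
    is_fixed <- TRUE
    for (r in reqs)
      if (all(st[r$idx] == r$lev)) { is_fixed <- FALSE; break }
    if (is_fixed) out[[length(out) + 1L]] <- st
    # increment mixed-radix counter, last automaton fastest
    i <- m
    repeat {
      counter[i] <- counter[i] + 1L
      if (counter[i] <= sizes[i]) break
      counter[i] <- 1L
      i <- i - 1L
      if (i == 0L) break
    }
    if (i == 0L) break
  }
  out
}
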