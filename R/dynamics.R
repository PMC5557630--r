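# Update semantics.  A playable transition has its origin active and its
# condition satisfied.  The asynchronous scheme plays exactly one playable
# transition per global step; the synchronous scheme plays one playable
# transition per automaton that has any (empty steps are forbidden in both
# schemes, so no state is ever its own successor).

match_scheme <- function(scheme) {
  if (is.null(scheme) || length(scheme) != 1 || is.na(scheme))
    an_stop("an update scheme is required: 'asynchronous' or 'synchronous'",
            class = "an_usage_error")
  s <- tolower(scheme)
  if (s %in% c("asynchronous", "asyn")) return("asynchronous")
  if (s %in% c("synchronous", "syn")) return("synchronous")
  an_stop("unknown update scheme '", scheme,
          "' (use asynchronous/asyn or synchronous/syn)",
          class = "an_usage_error")
}

#' Playable local transitions in a global state
#'
#' @param net An [automata_network()].
#' @param state A global state (named vector or literal, see [as_state()]).
#' @return List of [local_transition()] objects, in label order.
#' @examples
#' net <- toy_model()
#' length(playable(net, "a:1 b:2 c:0 d:1"))  # 3
#' length(playable(net, "a:1 b:1 c:1 d:0"))  # 0: a fixed point
#' @export
playable <- function(net, state) {
  state <- as_state(net, state)
  Filter(function(tr) {
    state[[tr$automaton]] == tr$origin &&
      (length(tr$condition) == 0 ||
         all(state[names(tr$condition)] == tr$condition))
  }, net$transitions)
}

#' Update sets of a global state under a scheme
#'
#' Asynchronous: one singleton set per playable transition.  Synchronous:
#' the Cartesian product, over each automaton with at least one playable
#' transition, of its playable transitions (exponential in the number of
#' simultaneously non-deterministic automata; fine at desk scale).  Both
#' yield the empty list exactly on fixed points.
#'
#' @inheritParams playable
#' @param scheme `"asynchronous"` or `"synchronous"` (aliases `asyn`/`syn`).
#' @return List of update sets, each a sorted integer vector of transition
#'   labels, in deterministic order.
#' @export
update_sets <- function(net, state, scheme) {
  scheme <- match_scheme(scheme)
  pl <- playable(net, state)
  if (length(pl) == 0) return(list())
  labs <- vapply(pl, function(tr) tr$label, integer(1))
  if (scheme == "asynchronous")
    return(lapply(sort(labs), function(l) l))
  by_aut <- split(labs, vapply(pl, function(tr) tr$automaton, character(1)))
  grid <- expand.grid(by_aut, KEEP.OUT.ATTRS = FALSE)
  sets <- lapply(seq_len(nrow(grid)), function(i)
    sort(as.integer(unlist(grid[i, , drop = FALSE], use.names = FALSE))))
  sets[order(vapply(sets, paste, character(1), collapse = ","))]
}

#' Apply an update set to a global state
#'
#' Replaces the level of every automaton named in the update set by the
#' corresponding transition's destination; all other automata are unchanged.
#' Since origin and destination always differ, the result never equals the
#' input state.
#'
#' @inheritParams playable
#' @param u Update set: integer vector of transition labels (at most one per
#'   automaton, all playable in `state`).
#' @return The successor global state (named integer vector).
#' @export
apply_update <- function(net, state, u) {
  state <- as_state(net, state)
  u <- as.integer(u)
  if (length(u) == 0)
    an_stop("empty update sets are not allowed")
  trs <- lapply(u, function(l) as_transition(net, l))
  auts <- vapply(trs, function(tr) tr$automaton, character(1))
  if (anyDuplicated(auts))
    an_stop("update set fires automaton '", auts[duplicated(auts)][1],
            "' more than once")
  pl <- vapply(playable(net, state), function(tr) tr$label, integer(1))
  if (!all(u %in% pl))
    an_stop("update set contains a transition not playable in state ",
            state_key(state), ": label ", setdiff(u, pl)[1])
  for (tr in trs) state[[tr$automaton]] <- tr$destination
  state
}

#' Successor states under a scheme
#'
#' The image of [update_sets()] under [apply_update()], deduplicated.  Empty
#' exactly on fixed points.
#'
#' @inheritParams update_sets
#' @return List of global states in deterministic (canonical key) order.
#' @examples
#' net <- toy_model()
#' length(successors(net, "a:1 b:2 c:0 d:1", "asynchronous"))  # 3
#' length(successors(net, "a:1 b:0 c:1 d:0", "synchronous"))   # 2
#' @export
successors <- function(net, state, scheme) {
  state <- as_state(net, state)
  res <- lapply(update_sets(net, state, scheme),
                function(u) apply_update(net, state, u))
  keys <- vapply(res, state_key, character(1))
  res <- res[!duplicated(keys)]
  res[order(vapply(res, state_key, character(1)))]
}

#' Are two local transitions in conflict?
#'
#' Two transitions of the same automaton are in conflict when they share
#' their origin, differ in destination, and are jointly playable in some
#' global state.  In-conflict transitions are the only source of synchronous
#' non-determinism; in a Boolean network none can exist.  The witness state
#' is decided by constraint merging: with equal origins, a witness exists
#' iff the two conditions assign no automaton two different levels (no state
#' enumeration is needed).
#'
#' @param net An [automata_network()].
#' @param t1,t2 Transition labels or [local_transition()] objects of the
#'   same automaton.
#' @return Logical scalar.
#' @export
in_conflict <- function(net, t1, t2) {
  t1 <- as_transition(net, t1)
  t2 <- as_transition(net, t2)
  if (t1$automaton != t2$automaton)
    an_stop("in-conflict is only defined for transitions of one automaton")
  if (t1$origin != t2$origin || t1$destination == t2$destination)
    return(FALSE)
  shared <- intersect(names(t1$condition), names(t2$condition))
  all(t1$condition[shared] == t2$condition[shared])
}

# ---- successor providers -------------------------------------------------
# The seam between network semantics and graph algorithms: attractor and
# oracle machinery only ever see an enumerable state set and a successor
# function over canonical state keys, so an explicit edge list (e.g. the
# 4-state star system) is interchangeable with a network.

#' Successor provider backed by an automata network
#'
#' Wraps a network and an update scheme as a generic finite transition
#' system: an enumerable set of state keys plus a successor function.
#' All attractor and state-transition-graph machinery runs on providers, so
#' explicit transition systems ([graph_provider()]) can be analyzed with the
#' same code paths.
#'
#' @param net An [automata_network()].
#' @param scheme Update scheme (see [update_sets()]).
#' @return An object of class `successor_provider` with fields `states()`
#'   (character vector of keys), `succ(key)` (character vector of successor
#'   keys), `decode(key)` and `n_states`.
#' @export
an_provider <- function(net, scheme) {
  scheme <- match_scheme(scheme)
  force(net)
  structure(list(
    kind = "an", net = net, scheme = scheme,
    n_states = state_space_size(net),
    states = function() vapply(an_states(net), state_key, character(1)),
    succ = function(key)
      vapply(successors(net, as_state(net, key), scheme), state_key, character(1)),
    decode = function(key) as_state(net, key)
  ), class = "successor_provider")
}

#' Successor provider from an explicit edge list
#'
#' @param edges Data frame (or list) with character columns `from` and `to`;
#'   self-edges are rejected to match the network semantics.
#' @param states Optional character vector of state names (defaults to the
#'   names appearing in `edges`); isolated states may be added here.
#' @param scheme Tag recorded on results (defaults to `"explicit"`).
#' @return A `successor_provider`.
#' @seealso [star_model()] for the packaged 4-state example.
#' @export
graph_provider <- function(edges, states = NULL, scheme = "explicit") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && any(edges$from == edges$to))
    an_stop("self-edges are not allowed: a state is never its own successor")
  if (is.null(states))
    states <- sort(unique(c(edges$from, edges$to)))
  adj <- lapply(stats::setNames(states, states),
                function(s) sort(unique(edges$to[edges$from == s])))
  structure(list(
    kind = "graph", scheme = scheme,
    n_states = length(states),
    states = function() states,
    succ = function(key) {
      if (is.null(adj[[key]])) an_stop("unknown state '", key, "'")
      adj[[key]]
    },
    decode = function(key) key
  ), class = "successor_provider")
}

#' @export
print.successor_provider <- function(x, ...) {
  cat(sprintf("Successor provider (%s, %s): %s states\n",
              x$kind, x$scheme, format(x$n_states, big.mark = ",")))
  invisible(x)
}

as_provider <- function(x, scheme = NULL) {
  if (inherits(x, "successor_provider")) {
    if (!is.null(scheme) && !identical(match_scheme(scheme), x$scheme))
      an_stop("provider is bound to scheme '", x$scheme,
              "' but '", scheme, "' was requested")
    return(x)
  }
  if (inherits(x, "automata_network")) return(an_provider(x, scheme))
  an_stop("expected an automata_network or a successor_provider")
}

# Full successor map over every state: named list key -> character vector.
full_adjacency <- function(p, guard = 1e6) {
  if (p$n_states > guard)
    an_stop("state space has ", format(p$n_states, big.mark = ","),
            " states, above the guard of ", format(guard, big.mark = ","))
  keys <- p$states()
  stats::setNames(lapply(keys, p$succ), keys)
}

reverse_adjacency <- function(adj) {
  radj <- stats::setNames(vector("list", length(adj)), names(adj))
  for (k in names(adj)) if (is.null(radj[[k]])) radj[[k]] <- character(0)
  for (k in names(adj))
    for (s in adj[[k]])
      radj[[s]] <- c(radj[[s]], k)
  radj
}

# BFS distances (in steps) from every node to `target`, computed on the
# reversed relation; NA when target is unreachable.
bfs_dist_to <- function(radj, target) {
  dist <- stats::setNames(rep(NA_integer_, length(radj)), names(radj))
  dist[[target]] <- 0L
  frontier <- target
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- character(0)
    for (k in frontier)
      for (pr in radj[[k]])
        if (is.na(dist[[pr]])) {
          dist[[pr]] <- d
          nxt <- c(nxt, pr)
        }
    frontier <- nxt
  }
  dist
}
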