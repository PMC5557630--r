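# Independent brute-force oracles used to cross-check the implementation,
# plus fixtures shared across test files.

# Update sets by naive power-set enumeration over the playable transitions,
# filtered by the defining per-scheme predicates (asynchronous: singletons;
# synchronous: exactly one member per automaton that has any playable
# transition, no empty sets).
naive_update_sets <- function(net, state, scheme) {
  state <- as_state(net, state)
  pl <- playable(net, state)
  labs <- vapply(pl, function(tr) tr$label, integer(1))
  auts <- vapply(pl, function(tr) tr$automaton, character(1))
  m <- length(labs)
  if (m == 0) return(list())
  out <- list()
  for (mask in 1:(2^m - 1)) {
    pick <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0)
    ok <- if (scheme == "asynchronous") {
      length(pick) == 1
    } else {
      tab <- table(auts[pick])
      setequal(names(tab), unique(auts)) && all(tab == 1)
    }
    if (ok) out[[length(out) + 1L]] <- sort(labs[pick])
  }
  out
}

# Independent substitution semantics.
naive_apply <- function(net, state, u) {
  state <- as_state(net, state)
  for (lab in u) {
    tr <- net$transitions[[lab]]
    state[[tr$automaton]] <- tr$destination
  }
  state
}

naive_successor_keys <- function(net, state, scheme) {
  us <- naive_update_sets(net, state, scheme)
  sort(unique(vapply(us, function(u)
    state_key(naive_apply(net, state, u)), character(1))))
}

successor_keys <- function(net, state, scheme)
  sort(vapply(successors(net, state, scheme), state_key, character(1)))

# Number of closed walks of length n in a directed graph, by matrix power:
# sum over v of (A^n)[v, v].
closed_walk_count <- function(provider, n) {
  keys <- provider$states()
  m <- length(keys)
  A <- matrix(0, m, m, dimnames = list(keys, keys))
  for (k in keys) A[k, provider$succ(k)] <- 1
  P <- diag(m)
  for (i in seq_len(n)) P <- P %*% A
  sum(diag(P))
}

# Deterministic small-network ensemble used by the property suites.
random_test_net <- function(seed)
  random_an(n_automata = 2 + seed %% 4, max_levels = 3,
            n_transitions = 4 + seed %% 7, seed = seed)

attractor_key_sets <- function(atts) lapply(atts, function(a) a$keys)

# The worked length-6 asynchronous path over the 4 yellow states.
example_path_states <- function() {
  list("a:1 b:2 c:1 d:1", "a:0 b:2 c:1 d:1", "a:1 b:2 c:1 d:1",
       "a:1 b:2 c:1 d:0", "a:0 b:2 c:1 d:0", "a:0 b:2 c:1 d:1",
       "a:1 b:2 c:1 d:1")
}
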