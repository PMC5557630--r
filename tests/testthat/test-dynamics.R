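net <- toy_model()

test_that("playable returns exactly the enabled transitions", {
  pl <- playable(net, "a:1 b:2 c:0 d:1")
  expect_setequal(vapply(pl, function(tr) tr$label, integer(1)), c(2L, 6L, 11L))
  expect_length(playable(net, "a:1 b:1 c:1 d:0"), 0)
  # a condition-free transition is playable wherever its origin is active
  selfnet <- parse_an("automaton a 2\nautomaton b 2\ntrans a 0 -> 1 when -")
  expect_length(playable(selfnet, c(a = 0, b = 0)), 1)
  expect_length(playable(selfnet, c(a = 0, b = 1)), 1)
})

test_that("synchronous update sets take the per-automaton product", {
  us <- update_sets(net, "a:1 b:0 c:1 d:0", "synchronous")
  expect_identical(us, list(3L, 4L))  # two in-conflict choices for b
  us2 <- update_sets(net, "a:1 b:2 c:0 d:1", "synchronous")
  expect_identical(us2, list(c(2L, 6L, 11L)))  # all three fire together
  expect_identical(update_sets(net, "a:1 b:1 c:1 d:0", "asyn"), list())
  expect_identical(update_sets(net, "a:1 b:1 c:1 d:0", "syn"), list())
  expect_error(update_sets(net, "a:1 b:1 c:1 d:0", "sequential"),
               "unknown update scheme")
})

test_that("apply_update substitutes destinations and rejects bad sets", {
  s <- as_state(net, "a:1 b:2 c:0 d:1")
  expect_identical(state_key(apply_update(net, s, 11L)), "a:1 b:2 c:0 d:0")
  expect_identical(state_key(apply_update(net, s, c(2L, 6L, 11L))),
                   "a:0 b:0 c:0 d:0")
  expect_error(apply_update(net, s, integer(0)), "empty update sets")
  expect_error(apply_update(net, s, 1L), "not playable")
  # applying a pair of inverse transitions returns to the start
  s2 <- apply_update(net, c(a = 0, b = 0, c = 1, d = 0), 1L)  # a0 -> a1
  expect_identical(state_key(s2), "a:1 b:0 c:1 d:0")
})

test_that("successor sets match the printed examples", {
  expect_identical(successor_keys(net, "a:1 b:2 c:0 d:1", "asynchronous"),
                   c("a:0 b:2 c:0 d:1", "a:1 b:0 c:0 d:1", "a:1 b:2 c:0 d:0"))
  expect_identical(successor_keys(net, "a:1 b:0 c:1 d:0", "synchronous"),
                   c("a:1 b:1 c:1 d:0", "a:1 b:2 c:1 d:0"))
  expect_length(successors(net, "a:0 b:0 c:0 d:1", "asynchronous"), 0)
})

test_that("update sets and successors agree with the power-set oracle", {
  for (seed in 1:25) {
    rnet <- random_test_net(seed)
    states <- an_states(rnet)
    probe <- states[seq(1, length(states), by = 3)]
    for (scheme in c("asynchronous", "synchronous")) {
      set_sigs <- function(us)
        sort(vapply(us, function(u)
          paste(sprintf("%04d", u), collapse = ","), character(1)))
      for (s in probe) {
        expect_identical(set_sigs(update_sets(rnet, s, scheme)),
                         set_sigs(naive_update_sets(rnet, s, scheme)),
                         label = paste("update_sets seed", seed, scheme,
                                       state_key(s)))
        expect_identical(successor_keys(rnet, s, scheme),
                         naive_successor_keys(rnet, s, scheme),
                         label = paste("successors seed", seed, scheme))
      }
    }
  }
})

test_that("no state is ever its own successor", {
  for (seed in c(2, 9, 17, 33)) {
    rnet <- random_test_net(seed)
    for (scheme in c("asynchronous", "synchronous"))
      for (s in an_states(rnet))
        expect_false(state_key(s) %in% successor_keys(rnet, s, scheme))
  }
})

test_that("per-step change sets follow the scheme", {
  for (seed in c(5, 12)) {
    rnet <- random_test_net(seed)
    for (s in an_states(rnet)) {
      changed_auts <- unique(vapply(playable(rnet, s),
                                    function(tr) tr$automaton, character(1)))
      for (nx in successors(rnet, s, "asynchronous"))
        expect_equal(sum(nx != s), 1)
      for (nx in successors(rnet, s, "synchronous"))
        expect_setequal(names(s)[nx != s], changed_auts)
    }
  }
})

test_that("Boolean networks are synchronously deterministic", {
  # Two playable same-origin transitions of a Boolean automaton share their
  # destination, so they are never in conflict: the *successor* is unique
  # even when several update sets witness it.
  for (seed in 101:120) {
    rnet <- random_an(n_automata = 3 + seed %% 3, max_levels = 2,
                      n_transitions = 5 + seed %% 4, seed = seed)
    expect_true(all(rnet$automata == 2L))
    for (s in an_states(rnet))
      expect_lte(length(successors(rnet, s, "synchronous")), 1)
  }
})

test_that("synchronous branching implies a playable in-conflict pair", {
  for (seed in 1:40) {
    rnet <- random_test_net(seed)
    for (s in an_states(rnet)) {
      if (length(successors(rnet, s, "synchronous")) < 2) next
      pl <- playable(rnet, s)
      labs <- vapply(pl, function(tr) tr$label, integer(1))
      pairs <- which(outer(labs, labs, Vectorize(function(x, y) {
        tx <- rnet$transitions[[x]]; ty <- rnet$transitions[[y]]
        x < y && tx$automaton == ty$automaton && in_conflict(rnet, x, y)
      })), arr.ind = TRUE)
      expect_gt(nrow(pairs), 0)
    }
  }
})

test_that("in_conflict is decided by condition merging", {
  expect_true(in_conflict(net, 3, 4))    # b0 -> b1 vs b0 -> b2
  expect_false(in_conflict(net, 3, 3))   # equal destinations
  expect_false(in_conflict(net, 3, 5))   # different origins
  expect_error(in_conflict(net, 1, 3), "one automaton")
  # contradictory conditions on a shared automaton: no witness state
  cnet <- automata_network(
    c(a = 3, b = 2),
    list(local_transition("a", 0, 1, c(b = 0)),
         local_transition("a", 0, 2, c(b = 1))))
  expect_false(in_conflict(cnet, 1, 2))
  # and with compatible conditions the witness exists
  cnet2 <- automata_network(
    c(a = 3, b = 2),
    list(local_transition("a", 0, 1, c(b = 0)),
         local_transition("a", 0, 2)))
  expect_true(in_conflict(cnet2, 1, 2))
})

test_that("network and explicit-graph providers are interchangeable", {
  p <- an_provider(net, "asynchronous")
  edges <- do.call(rbind, lapply(p$states(), function(k) {
    to <- p$succ(k)
    if (length(to)) data.frame(from = k, to = to, stringsAsFactors = FALSE)
  }))
  q <- graph_provider(edges, states = p$states(), scheme = "asynchronous")
  for (k in p$states())
    expect_identical(sort(p$succ(k)), q$succ(k))
  a1 <- attractor_key_sets(enumerate_attractors(p, 2))
  a2 <- attractor_key_sets(enumerate_attractors(q, 2))
  expect_identical(a1, a2)
})
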