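net <- toy_model()

test_that("cycle enumeration finds the printed 2-cycle and nothing at n=1", {
  cycles <- enumerate_cycles(net, 2, "asynchronous")
  traces <- unique(lapply(cycles, function(p) sort(unique(p$keys))))
  expect_true(list(c("a:1 b:2 c:0 d:0", "a:1 b:2 c:0 d:1")) %in% traces ||
                any(vapply(traces, identical,
                           logical(1), c("a:1 b:2 c:0 d:0", "a:1 b:2 c:0 d:1"))))
  expect_length(enumerate_cycles(net, 1, "asynchronous"), 0)
  expect_length(enumerate_cycles(net, 1, "synchronous"), 0)
})

test_that("cycle counts equal the matrix-power closed-walk count", {
  for (seed in c(1, 7, 14, 22)) {
    rnet <- random_test_net(seed)
    for (scheme in c("asynchronous", "synchronous")) {
      p <- an_provider(rnet, scheme)
      for (n in 1:4)
        expect_equal(length(enumerate_cycles(p, n)), closed_walk_count(p, n),
                     label = paste("seed", seed, scheme, "n", n))
    }
  }
  star <- star_model()
  for (n in 1:6)
    expect_equal(length(enumerate_cycles(star, n)), closed_walk_count(star, n))
})

test_that("trap-cycle detection matches the worked examples", {
  escaping <- c("a:1 b:2 c:0 d:1", "a:1 b:2 c:0 d:0", "a:1 b:2 c:0 d:1")
  expect_false(is_trap_cycle(net, escaping, "asynchronous"))

  yellow <- c("a:0 b:2 c:1 d:0", "a:0 b:2 c:1 d:1", "a:1 b:2 c:1 d:1",
              "a:1 b:2 c:1 d:0", "a:0 b:2 c:1 d:0")
  expect_true(is_trap_cycle(net, yellow, "asynchronous"))

  blue <- c("a:0 b:1 c:0 d:0", "a:0 b:1 c:0 d:2", "a:0 b:1 c:0 d:0")
  expect_true(is_trap_cycle(net, blue, "asynchronous"))
  expect_true(is_trap_cycle(net, blue, "synchronous"))

  expect_error(is_trap_cycle(net, escaping[1:2], "asynchronous"), "not a cycle")
})

test_that("minimality is the shortest covering closed walk", {
  yellow4 <- c("a:0 b:2 c:1 d:0", "a:0 b:2 c:1 d:1", "a:1 b:2 c:1 d:1",
               "a:1 b:2 c:1 d:0", "a:0 b:2 c:1 d:0")
  expect_true(is_minimal_cycle(net, yellow4, "asynchronous"))

  # the same attractor covered by the worked length-6 path is not minimal
  p6 <- an_path(net, example_path_states(), "asynchronous")
  expect_false(is_minimal_cycle(net, p6, "asynchronous"))

  # a 2-cycle repeated three times is not minimal
  blue6 <- c(rep(c("a:0 b:1 c:0 d:0", "a:0 b:1 c:0 d:2"), 3),
             "a:0 b:1 c:0 d:0")
  expect_false(is_minimal_cycle(net, blue6, "asynchronous"))

  # the star system needs its full length-6 walk
  star <- star_model()
  star6 <- c("s0", "s1", "s2", "s1", "s3", "s1", "s0")
  expect_true(is_minimal_cycle(star, star6))
  expect_equal(shortest_covering_walk(star, c("s0", "s1", "s2", "s3")), 6)
})

test_that("the example model has exactly the printed attractors per scheme", {
  a2 <- enumerate_attractors(net, 2, "asynchronous")
  expect_identical(attractor_key_sets(a2),
                   list(c("a:0 b:1 c:0 d:0", "a:0 b:1 c:0 d:2")))
  a4 <- enumerate_attractors(net, 4, "asynchronous")
  expect_identical(attractor_key_sets(a4),
                   list(c("a:0 b:2 c:1 d:0", "a:0 b:2 c:1 d:1",
                          "a:1 b:2 c:1 d:0", "a:1 b:2 c:1 d:1")))
  for (n in c(1, 3, 5, 6, 7, 8))
    expect_length(enumerate_attractors(net, n, "asynchronous"), 0)

  s2 <- enumerate_attractors(net, 2, "synchronous")
  expect_identical(attractor_key_sets(s2),
                   list(c("a:0 b:1 c:0 d:0", "a:0 b:1 c:0 d:2"),
                        c("a:0 b:2 c:1 d:0", "a:1 b:2 c:1 d:1")))
})

test_that("answer-set-like multiplicity is restored with dedupe = FALSE", {
  raw <- enumerate_attractors(net, 2, "asynchronous", dedupe = FALSE)
  expect_length(raw, 2)  # one witnessing cycle per starting state
  expect_length(unique(vapply(raw, function(a) a$id, character(1))), 1)
})

test_that("the union over lengths reports the smallest covering cycle", {
  all_a <- enumerate_all_attractors(net, 6, "asynchronous")
  expect_equal(sort(vapply(all_a, function(a) a$size, integer(1))), c(2L, 4L))
  expect_equal(sort(vapply(all_a, function(a) a$cycle_length, integer(1))),
               c(2L, 4L))

  star <- star_model()
  sa <- enumerate_all_attractors(star, 6)
  expect_length(sa, 1)
  expect_equal(sa[[1]]$size, 4)
  expect_equal(sa[[1]]$cycle_length, 6)
  for (n in 1:5) expect_length(enumerate_attractors(star, n), 0)
})

test_that("n = 0 is rejected toward the fixed-point entry point", {
  expect_error(enumerate_attractors(net, 0, "asynchronous"), "fixed_points")
})

test_that("every reported attractor satisfies the defining invariants", {
  for (seed in 1:20) {
    rnet <- random_test_net(seed)
    for (scheme in c("asynchronous", "synchronous")) {
      p <- an_provider(rnet, scheme)
      fp_keys <- vapply(enumerate_fixed_points(rnet), state_key, character(1))
      for (n in 1:5) {
        for (a in enumerate_attractors(p, n)) {
          # trap domain, strongly connected, disjoint from fixed points
          for (k in a$keys) expect_true(all(p$succ(k) %in% a$keys))
          expect_lt(shortest_covering_walk(p, a$keys), Inf)
          expect_length(intersect(a$keys, fp_keys), 0)
          expect_gte(a$size, 2)
        }
      }
    }
  }
})

test_that("Boolean synchronous cycles are always trap cycles", {
  for (seed in 201:215) {
    rnet <- random_an(n_automata = 3 + seed %% 3, max_levels = 2,
                      n_transitions = 5 + seed %% 5, seed = seed)
    p <- an_provider(rnet, "synchronous")
    for (n in 1:4)
      for (cyc in enumerate_cycles(p, n))
        expect_true(is_trap_cycle(p, cyc))
  }
})

test_that("trace accounting follows the size formula on witnessing cycles", {
  for (seed in c(6, 18)) {
    rnet <- random_test_net(seed)
    p <- an_provider(rnet, "asynchronous")
    for (n in 1:5)
      for (cyc in enumerate_cycles(p, n))
        expect_equal(trace_size(cyc), n + 1 - length(repetitions(cyc)))
  }
})
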