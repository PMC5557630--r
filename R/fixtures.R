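# Packaged example systems and a seeded random-network generator, so the
# whole test suite runs without downloads.

#' The packaged four-component example network
#'
#' Four automata (a, c Boolean; b, d with 3 levels) and 12 local
#' transitions; 36 global states.  Under the asynchronous scheme it has 3
#' fixed points and attractors of sizes 2 and 4; under the synchronous
#' scheme the same 3 fixed points and two attractors of size 2.
#'
#' @return An [automata_network()] parsed from the packaged fixture file.
#' @examples
#' toy_model()
#' @export
toy_model <- function() {
  read_an(system.file("extdata", "toy_example.an", package = "andyn",
                      mustWork = TRUE))
}

#' The 4-state "star" transition system
#'
#' An explicit transition system (no network realization is given for it):
#' a hub `s1` connected both ways to `s0`, `s2` and `s3`.  Its unique
#' attractor is the whole 4-state set, and no closed walk shorter than 6
#' covers it -- the hub must be visited three times.  It exercises the
#' complex-attractor machinery, where the covering cycle is strictly longer
#' than the trace.
#'
#' @return A [graph_provider()] with 4 states and 6 edges.
#' @examples
#' star_model()$succ("s1")
#' @export
star_model <- function() {
  graph_provider(data.frame(
    from = c("s0", "s1", "s1", "s1", "s2", "s3"),
    to   = c("s1", "s0", "s2", "s3", "s1", "s1"),
    stringsAsFactors = FALSE))
}

sample1 <- function(x) x[sample.int(length(x), 1L)]

#' Seeded random automata network
#'
#' Draws level counts uniformly in 2..`max_levels`, then rejection-samples
#' `n_transitions` structurally distinct valid transitions; condition sizes
#' are uniform on 0..min(2, n_automata - 1).  Reproducible for a given
#' seed; the caller's RNG state is left untouched.
#'
#' @param n_automata Number of automata (>= 1; named a, b, c, ...).
#' @param max_levels Maximum level count per automaton (>= 2).
#' @param n_transitions Number of distinct local transitions to draw.
#' @param seed Integer seed.
#' @return A validated [automata_network()].
#' @export
random_an <- function(n_automata = 4, max_levels = 3, n_transitions = 8,
                      seed = 1) {
  if (n_automata < 1) an_stop("n_automata must be >= 1")
  if (max_levels < 2) an_stop("max_levels must be >= 2")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed))
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)

  auts <- if (n_automata <= 26) letters[seq_len(n_automata)] else
    paste0("v", seq_len(n_automata))
  counts <- vapply(seq_len(n_automata),
                   function(i) sample1(2:max_levels), integer(1))
  names(counts) <- auts

  # capacity: distinct (automaton, origin, destination, condition) tuples
  cond_space <- vapply(auts, function(a) {
    others <- counts[setdiff(auts, a)]
    pairs <- if (length(others) >= 2) {
      cmb <- utils::combn(length(others), 2)
      sum(others[cmb[1, ]] * others[cmb[2, ]])
    } else 0
    1 + sum(others) + pairs
  }, numeric(1))
  capacity <- sum(counts * (counts - 1) * cond_space)
  if (n_transitions > capacity)
    an_stop("infeasible: ", n_transitions, " distinct transitions requested",
            " but only ", capacity, " exist for these automata")

  sigs <- character(0)
  transitions <- list()
  max_cond <- min(2L, n_automata - 1L)
  while (length(transitions) < n_transitions) {
    a <- sample1(auts)
    k <- counts[[a]]
    o <- sample1(0:(k - 1))
    d <- sample1(setdiff(0:(k - 1), o))
    csize <- sample1(0:max_cond)
    cond <- integer(0)
    if (csize > 0) {
      bs <- sort(sample(setdiff(auts, a), csize))
      cond <- vapply(bs, function(b) sample1(0:(counts[[b]] - 1)), integer(1))
      names(cond) <- bs
    }
    sig <- paste(a, o, d, paste(names(cond), cond, sep = ":", collapse = ","),
                 sep = "|")
    if (sig %in% sigs) next
    sigs <- c(sigs, sig)
    transitions[[length(transitions) + 1L]] <- local_transition(a, o, d, cond)
  }
  automata_network(counts, transitions)
}
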