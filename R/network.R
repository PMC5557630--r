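# Core data model: an automata network is an ordered set of named automata,
# each with >= 2 discrete levels (0-based), plus a list of conditional local
# transitions.  A global state assigns one active level to every automaton.

an_stop <- function(..., class = "an_validation_error", call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "an_error")))
}

#' Create a local transition
#'
#' A local transition moves one automaton from its `origin` level to a
#' different `destination` level, and is playable in a global state exactly
#' when the origin level is active and every local state in `condition`
#' (levels of *other* automata) is active.
#'
#' @param automaton Name of the automaton the transition acts on.
#' @param origin,destination Level indices (0-based); must differ.
#' @param condition Named integer vector of required levels of other
#'   automata (possibly empty).  At most one level per automaton.
#' @param label Positive integer identifier, unique within a network.
#'   Usually assigned by [automata_network()].
#' @return An object of class `local_transition`.
#' @seealso [automata_network()], [playable()]
#' @export
local_transition <- function(automaton, origin, destination,
                             condition = integer(0), label = NA_integer_) {
  if (length(condition) > 0 &&
      (is.null(names(condition)) || any(!nzchar(names(condition)))))
    an_stop("transition condition must be a named vector (automaton = level)")
  cond <- as.integer(condition)
  if (length(cond) > 0) names(cond) <- names(condition)
  structure(
    list(label = as.integer(label),
         automaton = as.character(automaton),
         origin = as.integer(origin),
         destination = as.integer(destination),
         condition = cond),
    class = "local_transition")
}

#' @export
format.local_transition <- function(x, ...) {
  cond <- if (length(x$condition) == 0) "-" else
    paste(names(x$condition), x$condition, sep = ":", collapse = ", ")
  sprintf("trans %s %d -> %d when %s", x$automaton, x$origin, x$destination, cond)
}

#' @export
print.local_transition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

describe_transition <- function(tr) {
  lab <- if (is.na(tr$label)) "" else sprintf(" (label %d)", tr$label)
  paste0("'", format.local_transition(tr), "'", lab)
}

#' Construct and validate an automata network
#'
#' @param automata Named integer vector mapping automaton name to its level
#'   count (each >= 2); names give the declaration order used everywhere for
#'   deterministic output.
#' @param transitions List of [local_transition()] objects.  If labels are
#'   missing they are assigned in list order starting at 1; if present they
#'   must be unique and contiguous from 1.
#' @return An object of class `automata_network` with fields `automata`
#'   (named integer vector) and `transitions` (list ordered by label).
#' @details Validation enforces the structural invariants of the formalism:
#'   origin and destination levels differ, conditions never mention the
#'   transition's own automaton, conditions hold at most one level per
#'   automaton (a transition with two required levels of one automaton could
#'   never be played and is rejected at construction), and all referenced
#'   automata and levels exist.  Conditions are canonicalized to automaton
#'   declaration order so that structurally equal networks are `identical()`.
#' @examples
#' net <- automata_network(
#'   c(a = 2, b = 2),
#'   list(local_transition("a", 0, 1, c(b = 1)),
#'        local_transition("b", 0, 1)))
#' state_space_size(net)
#' @export
automata_network <- function(automata, transitions = list()) {
  if (length(automata) == 0)
    an_stop("a network needs at least one automaton")
  if (is.null(names(automata)) || any(!nzchar(names(automata))))
    an_stop("'automata' must be a named vector of level counts")
  if (anyDuplicated(names(automata)))
    an_stop("duplicated automaton name: ",
            names(automata)[duplicated(names(automata))][1])
  counts <- as.integer(automata)
  names(counts) <- names(automata)
  if (any(counts < 2))
    an_stop("every automaton needs at least 2 levels; offending: ",
            paste(names(counts)[counts < 2], collapse = ", "))

  auts <- names(counts)
  transitions <- lapply(transitions, function(tr) {
    if (!inherits(tr, "local_transition"))
      tr <- do.call(local_transition, tr)
    tr
  })

  # label assignment / check: unique and contiguous from 1
  labs <- vapply(transitions, function(tr) tr$label, integer(1))
  if (all(is.na(labs))) {
    for (i in seq_along(transitions)) transitions[[i]]$label <- i
  } else if (anyNA(labs) || !setequal(labs, seq_along(transitions))) {
    an_stop("transition labels must be unique and contiguous from 1")
  } else {
    transitions <- transitions[order(labs)]
  }

  for (tr in transitions) {
    who <- describe_transition(tr)
    if (!tr$automaton %in% auts)
      an_stop("unknown automaton '", tr$automaton, "' in transition ", who)
    k <- counts[[tr$automaton]]
    if (tr$origin < 0 || tr$origin >= k || tr$destination < 0 || tr$destination >= k)
      an_stop("level out of range [0,", k - 1, "] for automaton '",
              tr$automaton, "' in transition ", who)
    if (tr$origin == tr$destination)
      an_stop("origin equals destination in transition ", who)
    cn <- names(tr$condition)
    if (tr$automaton %in% cn)
      an_stop("condition mentions the transition's own automaton in ", who)
    if (anyDuplicated(cn))
      an_stop("condition holds two levels of automaton '",
              cn[duplicated(cn)][1], "' (unplayable transition) in ", who)
    if (!all(cn %in% auts))
      an_stop("unknown automaton '", setdiff(cn, auts)[1],
              "' in the condition of transition ", who)
    for (b in cn)
      if (tr$condition[[b]] < 0 || tr$condition[[b]] >= counts[[b]])
        an_stop("condition level out of range for automaton '", b,
                "' in transition ", who)
  }

  # canonicalize condition element order to declaration order
  transitions <- lapply(transitions, function(tr) {
    if (length(tr$condition) > 1)
      tr$condition <- tr$condition[order(match(names(tr$condition), auts))]
    tr
  })

  structure(list(automata = counts, transitions = transitions),
            class = "automata_network")
}

#' @export
print.automata_network <- function(x, ...) {
  cat(sprintf("Automata network: %d automata, %d local transitions, %s global states\n",
              length(x$automata), length(x$transitions),
              format(state_space_size(x), big.mark = ",")))
  cat("  levels:", paste(names(x$automata), x$automata, sep = ":", collapse = " "), "\n")
  for (tr in x$transitions)
    cat(sprintf("  [%d] %s\n", tr$label, format(tr)))
  invisible(x)
}

#' Number of global states of a network
#'
#' The size of the global state space: the product of the per-automaton
#' level counts.
#'
#' @param net An [automata_network()].
#' @return A (double) count of global states.
#' @examples
#' state_space_size(toy_model())  # 2 * 3 * 2 * 3 = 36
#' @export
state_space_size <- function(net) {
  stopifnot(inherits(net, "automata_network"))
  prod(as.numeric(net$automata))
}

#' Serialize a global state to its canonical text form
#'
#' States print as `a:1 b:2 c:0 d:1`, automata in declaration order, which is
#' also the canonical key used for set membership and deduplication.
#'
#' @param state Named integer vector (one level per automaton).
#' @return Character scalar.
#' @export
state_key <- function(state) {
  paste(names(state), state, sep = ":", collapse = " ")
}

#' Coerce a value to a global state of a network
#'
#' Accepts a named integer vector or a text literal such as
#' `"a:1 b:2 c:0 d:1"` (commas also accepted as separators, as on the
#' command line: `a:1,b:2,c:0,d:1`).  The result always carries exactly one
#' in-range level per automaton, in declaration order.
#'
#' @param net An [automata_network()].
#' @param x State literal or named vector.
#' @return Named integer vector of class-free canonical form.
#' @export
as_state <- function(net, x) {
  auts <- names(net$automata)
  if (is.character(x) && length(x) == 1) {
    parts <- strsplit(trimws(x), "[,[:space:]]+")[[1]]
    parts <- parts[nzchar(parts)]
    kv <- strsplit(parts, ":", fixed = TRUE)
    if (any(lengths(kv) != 2))
      an_stop("malformed state literal: '", x, "'")
    lv <- suppressWarnings(as.integer(vapply(kv, `[`, character(1), 2)))
    names(lv) <- vapply(kv, `[`, character(1), 1)
    if (anyNA(lv)) an_stop("malformed state literal: '", x, "'")
    x <- lv
  }
  if (is.null(names(x)))
    an_stop("a global state must be a named vector or state literal")
  if (!setequal(names(x), auts))
    an_stop("state must assign exactly one level to each of: ",
            paste(auts, collapse = ", "))
  s <- as.integer(x[auts])
  names(s) <- auts
  bad <- s < 0 | s >= net$automata
  if (any(bad))
    an_stop("level out of range for automaton '", auts[bad][1], "'")
  s
}

#' Enumerate every global state of a network
#'
#' @param net An [automata_network()].
#' @param guard Refuse enumeration above this many states.
#' @return List of named integer vectors in lexicographic order of the
#'   automaton declaration (last automaton varies fastest).
#' @export
an_states <- function(net, guard = 1e6) {
  n <- state_space_size(net)
  if (n > guard)
    an_stop("state space has ", format(n, big.mark = ","),
            " states, above the guard of ", format(guard, big.mark = ","))
  auts <- names(net$automata)
  grid <- expand.grid(rev(lapply(net$automata, function(k) 0:(k - 1))),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(auts)), drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) {
    s <- as.integer(grid[i, ])
    names(s) <- auts
    s
  })
}

as_transition <- function(net, x) {
  if (inherits(x, "local_transition")) return(x)
  lab <- as.integer(x)
  if (is.na(lab) || lab < 1 || lab > length(net$transitions))
    an_stop("no transition with label ", x)
  net$transitions[[lab]]
}

#' Structural equality of two automata networks
#'
#' Networks are equal when they declare the same automata (names, level
#' counts, order) and the same labeled transitions.  Constructors
#' canonicalize condition order, so this reduces to [identical()].
#'
#' @param a,b Two [automata_network()] objects.
#' @return Logical scalar.
#' @export
an_equal <- function(a, b) {
  identical(unclass(a), unclass(b))
}
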