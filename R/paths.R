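# Paths: ordered state sequences linked by the global transition relation.
# A path of length n has n+1 entries; its trace is the set of distinct
# visited states, of size n + 1 - (number of repeated steps).

#' Construct and validate a path over a network
#'
#' Checks that each consecutive pair is a global transition under `scheme`
#' and records, per step, one witnessing update set.
#'
#' @param net An [automata_network()].
#' @param states List of global states (or state literals), length n+1 with
#'   n >= 1.
#' @param scheme Update scheme.
#' @return An object of class `an_path` with fields `keys` (character,
#'   length n+1), `states`, `played` (list of n update sets) and `scheme`.
#' @examples
#' net <- toy_model()
#' p <- an_path(net, list("a:1 b:2 c:0 d:1", "a:1 b:2 c:0 d:0",
#'                        "a:1 b:2 c:0 d:1"), "asynchronous")
#' trace_size(p)
#' @export
an_path <- function(net, states, scheme) {
  scheme <- match_scheme(scheme)
  if (length(states) < 2)
    an_stop("a path must have strictly positive length (>= 2 states)")
  states <- lapply(states, function(s) as_state(net, s))
  played <- vector("list", length(states) - 1)
  for (i in seq_len(length(states) - 1)) {
    us <- update_sets(net, states[[i]], scheme)
    nxt_key <- state_key(states[[i + 1]])
    hit <- NULL
    for (u in us)
      if (state_key(apply_update(net, states[[i]], u)) == nxt_key) {
        hit <- u
        break
      }
    if (is.null(hit))
      an_stop("not a valid ", scheme, " path: no global transition from ",
              state_key(states[[i]]), " to ", nxt_key, " (step ", i, ")")
    played[[i]] <- hit
  }
  structure(list(keys = vapply(states, state_key, character(1)),
                 states = states, played = played, scheme = scheme),
            class = "an_path")
}

path_keys <- function(path) {
  if (inherits(path, "an_path")) return(path$keys)
  if (is.character(path)) return(path)
  if (is.list(path)) {
    if (!is.null(path$keys)) return(path$keys)
    return(vapply(path, function(s)
      if (is.character(s)) s else state_key(s), character(1)))
  }
  an_stop("cannot interpret this object as a path")
}

#' @export
print.an_path <- function(x, ...) {
  cat(sprintf("Path of length %d (%s), trace size %d:\n",
              length(x$keys) - 1, x$scheme, length(unique(x$keys))))
  cat(paste0("  ", x$keys, collapse = "\n"), "\n")
  invisible(x)
}

#' Repeated steps of a path
#'
#' Step i (1-based, over steps 1..n) is a repetition when its state already
#' occurs at an earlier index of the path.
#'
#' @param path An [an_path()], a character vector of state keys, or a list
#'   of states.
#' @return Sorted integer vector of repeated step indices.
#' @examples
#' repetitions(c("s0", "s1", "s0", "s2", "s0"))  # c(2, 4)
#' @export
repetitions <- function(path) {
  keys <- path_keys(path)
  sort(which(duplicated(keys)) - 1L)
}

#' Trace size of a path
#'
#' The number of distinct visited states; for a path of length n with k
#' repeated steps this is n + 1 - k.
#'
#' @inheritParams repetitions
#' @return Positive integer.
#' @export
trace_size <- function(path) {
  keys <- path_keys(path)
  length(unique(keys))
}
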