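# Text formats: a line-oriented network format ("AN format") and a
# logic-programming facts dialect (automatonLevel/2, automaton/1,
# localTrans/1, condition/3, target/3).  In the facts dialect the origin of
# a transition is serialized as the condition element on the transition's
# own automaton; the reader splits it back out.

#' Parse the plain-text network format
#'
#' One statement per line, `#` comments allowed:
#' \preformatted{
#' automaton <name> <levelCount>
#' trans <name> <origin> -> <destination> when <name>:<level>[, ...]
#' trans <name> <origin> -> <destination> when -
#' }
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @return A validated [automata_network()]; transition labels follow file
#'   order starting at 1.
#' @seealso [read_an()] to load from a file, [write_an()] for the inverse.
#' @export
parse_an <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  automata <- integer(0)
  transitions <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    if (toks[1] == "automaton") {
      if (length(toks) != 3)
        an_stop("line ", i, ": expected 'automaton <name> <levelCount>'")
      k <- suppressWarnings(as.integer(toks[3]))
      if (is.na(k)) an_stop("line ", i, ": level count is not an integer")
      automata[toks[2]] <- k
    } else if (toks[1] == "trans") {
      m <- regmatches(line, regexec(
        "^trans[[:space:]]+([^[:space:]]+)[[:space:]]+([0-9]+)[[:space:]]*->[[:space:]]*([0-9]+)[[:space:]]+when[[:space:]]+(.*)$",
        line))[[1]]
      if (length(m) == 0)
        an_stop("line ", i,
                ": expected 'trans <name> <origin> -> <destination> when ...'")
      cond_txt <- trimws(m[5])
      cond <- integer(0)
      if (cond_txt != "-") {
        parts <- trimws(strsplit(cond_txt, ",", fixed = TRUE)[[1]])
        kv <- strsplit(parts, ":", fixed = TRUE)
        if (any(lengths(kv) != 2))
          an_stop("line ", i, ": malformed condition '", cond_txt, "'")
        cond <- suppressWarnings(as.integer(vapply(kv, `[`, character(1), 2)))
        names(cond) <- vapply(kv, `[`, character(1), 1)
        if (anyNA(cond))
          an_stop("line ", i, ": malformed condition '", cond_txt, "'")
      }
      transitions[[length(transitions) + 1]] <-
        local_transition(m[2], as.integer(m[3]), as.integer(m[4]), cond)
    } else {
      an_stop("line ", i, ": unknown statement '", toks[1], "'")
    }
  }
  automata_network(automata, transitions)
}

#' Read a network file in either supported text format
#'
#' @param path File path.
#' @return An [automata_network()].
#' @details [read_model()] sniffs the content: files mentioning
#'   `automatonLevel(` are parsed as logic facts, everything else as the
#'   plain-text format.
#' @export
read_an <- function(path) {
  parse_an(readLines(path, warn = FALSE))
}

#' @rdname read_an
#' @export
read_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("automatonLevel(", lines, fixed = TRUE)))
    parse_asp_facts(lines)
  else
    parse_an(lines)
}

#' Serialize a network to the plain-text format
#'
#' @param net An [automata_network()].
#' @return A single string; `parse_an(write_an(net))` reproduces `net`.
#' @export
write_an <- function(net) {
  stopifnot(inherits(net, "automata_network"))
  head <- sprintf("automaton %s %d", names(net$automata), net$automata)
  body <- vapply(net$transitions, format.local_transition, character(1))
  paste(c(head, body, ""), collapse = "\n")
}

#' Serialize a network as logic-programming facts
#'
#' Emits, per automaton `a` with `k` levels, `automatonLevel("a",0..k-1).`
#' and `automaton("a").`; per transition with label `L`, one `localTrans(L).`
#' fact, one `condition(L,"a",i).` fact for the origin and for each condition
#' element, and exactly one `target(L,"a",j).` fact.  Automaton names are
#' double-quoted so that capitalized component names stay constants.
#'
#' @param net An [automata_network()].
#' @return A single string of facts, one per line.
#' @seealso [parse_asp_facts()] for the inverse.
#' @export
write_asp_facts <- function(net) {
  stopifnot(inherits(net, "automata_network"))
  out <- character(0)
  for (a in names(net$automata))
    out <- c(out, sprintf('automatonLevel("%s",0..%d).', a, net$automata[[a]] - 1))
  for (a in names(net$automata))
    out <- c(out, sprintf('automaton("%s").', a))
  for (tr in net$transitions)
    out <- c(out, sprintf("localTrans(%d).", tr$label))
  for (tr in net$transitions) {
    conds <- c(sprintf('condition(%d,"%s",%d).', tr$label, tr$automaton, tr$origin),
               sprintf('condition(%d,"%s",%d).', tr$label,
                       names(tr$condition), tr$condition))
    out <- c(out, conds, sprintf('target(%d,"%s",%d).', tr$label,
                                 tr$automaton, tr$destination))
  }
  paste(c(out, ""), collapse = "\n")
}

strip_quotes <- function(x) gsub('^"|"$', "", x)

#' Parse the logic-programming facts dialect
#'
#' Accepts exactly the five predicates produced by [write_asp_facts()];
#' `I..J` range sugar in `automatonLevel` is expanded.  The origin of each
#' transition is recovered as the condition element whose automaton equals
#' the target's automaton.
#'
#' @param text Character vector of lines, or one string.
#' @return An [automata_network()] equal to the one that produced the facts.
#' @export
parse_asp_facts <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("%.*$", "", lines)
  # split on '.' statement terminators (facts may share a line)
  stmts <- unlist(regmatches(lines, gregexpr("[a-zA-Z]+\\([^)]*\\)[[:space:]]*\\.", lines)))
  stmts <- trimws(sub("\\.$", "", trimws(stmts)))
  leftovers <- trimws(gsub("[a-zA-Z]+\\([^)]*\\)[[:space:]]*\\.", "", lines))
  if (any(nzchar(leftovers)))
    an_stop("unparseable facts text near: '",
            leftovers[nzchar(leftovers)][1], "'")

  automata <- integer(0)
  declared <- character(0)
  trans_labels <- integer(0)
  conds <- list()   # label -> list of c(automaton=, level=)
  targets <- list() # label -> c(automaton=, level=)

  for (s in stmts) {
    m <- regmatches(s, regexec("^([a-zA-Z]+)\\((.*)\\)$", s))[[1]]
    pred <- m[2]
    args <- trimws(strsplit(m[3], ",(?=(?:[^\"]*\"[^\"]*\")*[^\"]*$)", perl = TRUE)[[1]])
    if (pred == "automatonLevel") {
      if (length(args) != 2) an_stop("automatonLevel needs 2 arguments: ", s)
      a <- strip_quotes(args[1])
      if (grepl("\\.\\.", args[2])) {
        rng <- as.integer(strsplit(args[2], "..", fixed = TRUE)[[1]])
        if (anyNA(rng) || rng[1] > rng[2])
          an_stop("bad level range in: ", s)
        hi <- rng[2]
      } else {
        hi <- as.integer(args[2])
      }
      automata[a] <- max(automata[a], hi + 1L, 2L, na.rm = TRUE)
    } else if (pred == "automaton") {
      declared <- union(declared, strip_quotes(args[1]))
    } else if (pred == "localTrans") {
      trans_labels <- union(trans_labels, as.integer(args[1]))
    } else if (pred == "condition") {
      lab <- args[1]
      conds[[lab]] <- c(conds[[lab]],
                        list(list(automaton = strip_quotes(args[2]),
                                  level = as.integer(args[3]))))
    } else if (pred == "target") {
      lab <- args[1]
      if (!is.null(targets[[lab]]))
        an_stop("transition ", lab, " has more than one target fact")
      targets[[lab]] <- list(automaton = strip_quotes(args[2]),
                             level = as.integer(args[3]))
    } else {
      an_stop("unknown predicate '", pred, "' in: ", s)
    }
  }

  labs <- sort(unique(c(trans_labels,
                        as.integer(names(targets)), as.integer(names(conds)))))
  transitions <- vector("list", length(labs))
  for (i in seq_along(labs)) {
    lab <- as.character(labs[i])
    tgt <- targets[[lab]]
    if (is.null(tgt))
      an_stop("transition ", lab, " has no target fact")
    cc <- conds[[lab]]
    if (is.null(cc))
      an_stop("transition ", lab, " has a target but no condition facts ",
              "(the origin is serialized as a condition element)")
    own <- vapply(cc, function(e) e$automaton == tgt$automaton, logical(1))
    if (sum(own) == 0)
      an_stop("transition ", lab, " has no condition element on its own ",
              "automaton '", tgt$automaton, "' (missing origin)")
    if (sum(own) > 1)
      an_stop("transition ", lab, " has several condition elements on its ",
              "own automaton '", tgt$automaton, "'")
    origin <- cc[own][[1]]$level
    rest <- cc[!own]
    cond <- vapply(rest, function(e) e$level, integer(1))
    names(cond) <- vapply(rest, function(e) e$automaton, character(1))
    transitions[[i]] <- local_transition(tgt$automaton, origin, tgt$level,
                                         cond, label = labs[i])
  }

  for (a in declared)
    if (is.na(automata[a])) automata[a] <- 2L
  automata_network(automata, transitions)
}

#' Export a network as JSON
#'
#' A machine-readable rendering: the automata map plus the transition list
#' (label, automaton, origin, destination, condition).
#'
#' @param net An [automata_network()].
#' @param pretty Pretty-print the JSON.
#' @return JSON text (class `json` from jsonlite).
#' @export
an_to_json <- function(net, pretty = TRUE) {
  stopifnot(inherits(net, "automata_network"))
  obj <- list(
    automata = as.list(net$automata),
    transitions = lapply(net$transitions, function(tr) {
      list(label = tr$label, automaton = tr$automaton,
           origin = tr$origin, destination = tr$destination,
           condition = as.list(tr$condition))
    }))
  jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = pretty)
}
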