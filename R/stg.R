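# Brute-force oracle: build the explicit state-transition graph and read
# fixed points and attractors off its terminal strongly connected
# components (singleton terminal SCCs are fixed points, larger ones are the
# attractors).  This implements the defining characterization directly and
# is the acceptance authority for the enumeration machinery.

#' Build the explicit state-transition graph
#'
#' @param x An [automata_network()] or a `successor_provider`.
#' @param scheme Update scheme (for a network input).
#' @param roots Optional set of states (keys, literals or named vectors):
#'   when given, only the forward-reachable subgraph from these states is
#'   built; otherwise the full graph over all states.
#' @param guard Refuse graphs above this many nodes.
#' @return An object of class `stg`: fields `nodes` (character keys),
#'   `edges` (data frame `from`/`to`), `scheme`.
#' @examples
#' g <- build_stg(toy_model(), "asynchronous")
#' length(g$nodes)  # 36
#' @export
build_stg <- function(x, scheme = NULL, roots = NULL, guard = 1e6) {
  p <- as_provider(x, scheme)
  norm_key <- function(s) {
    if (is.character(s) && p$kind == "graph") return(s)
    state_key(p$decode(if (is.character(s)) s else state_key(s)))
  }
  if (is.null(roots)) {
    adj <- full_adjacency(p, guard = guard)
    nodes <- names(adj)
  } else {
    if (!is.list(roots)) roots <- as.list(roots)
    frontier <- unique(vapply(roots, norm_key, character(1)))
    adj <- list()
    while (length(frontier) > 0) {
      k <- frontier[[1]]
      frontier <- frontier[-1]
      if (!is.null(adj[[k]])) next
      adj[[k]] <- p$succ(k)
      if (length(adj) > guard)
        an_stop("reachable graph exceeds the guard of ",
                format(guard, big.mark = ","), " nodes")
      frontier <- c(frontier, setdiff(adj[[k]], names(adj)))
    }
    nodes <- names(adj)
  }
  edges <- data.frame(
    from = rep(nodes, times = lengths(adj)),
    to = unlist(adj, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(edges) == 0)
    edges <- data.frame(from = character(0), to = character(0),
                        stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, scheme = p$scheme),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat(sprintf("State-transition graph (%s): %d nodes, %d edges\n",
              x$scheme, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Fixed points and attractors by terminal-SCC analysis
#'
#' Strongly connected components with no edge leaving the component are the
#' terminal components of the dynamics: singletons are fixed points (no
#' self-edges exist, so a terminal singleton has no successor at all) and
#' larger components are exactly the attractors.
#'
#' @param stg A state-transition graph from [build_stg()]; it must be the
#'   full graph unless only reachable attractors are wanted.
#' @return List with `fixed_points` (sorted character keys) and `attractors`
#'   (list of sorted character key vectors, ordered deterministically).
#' @examples
#' oracle_attractors(build_stg(star_model()))
#' @export
oracle_attractors <- function(stg) {
  stopifnot(inherits(stg, "stg"))
  g <- igraph::graph_from_data_frame(
    stg$edges, directed = TRUE,
    vertices = data.frame(name = stg$nodes, stringsAsFactors = FALSE))
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  if (nrow(stg$edges) > 0) {
    from_c <- memb[stg$edges$from]
    to_c <- memb[stg$edges$to]
    escaping <- unique(from_c[from_c != to_c])
  } else {
    escaping <- integer(0)
  }
  terminal <- setdiff(seq_len(comp$no), escaping)
  fixed <- character(0)
  attractors <- list()
  for (cc in terminal) {
    members <- sort(names(memb)[memb == cc])
    if (length(members) == 1)
      fixed <- c(fixed, members)
    else
      attractors[[length(attractors) + 1L]] <- members
  }
  ord <- order(vapply(attractors, function(m) m[1], character(1)))
  list(fixed_points = sort(fixed), attractors = attractors[ord])
}

#' Export a state-transition graph as text
#'
#' @param stg A graph from [build_stg()].
#' @param format `"dot"` for Graphviz or `"json"` for an edge-list document.
#' @param color_attractors In DOT output, fill fixed points and attractor
#'   states (mirrors the usual figure coloring).
#' @return Character text.  JSON output round-trips through
#'   [import_graph_json()].
#' @export
export_graph <- function(stg, format = c("dot", "json"),
                         color_attractors = FALSE) {
  stopifnot(inherits(stg, "stg"))
  format <- match.arg(format)
  if (format == "dot") {
    fills <- stats::setNames(rep(NA_character_, length(stg$nodes)), stg$nodes)
    if (color_attractors) {
      o <- oracle_attractors(stg)
      fills[o$fixed_points] <- "salmon"
      for (a in o$attractors) fills[a] <- "gold"
    }
    nodes <- sort(stg$nodes)
    node_lines <- vapply(nodes, function(k) {
      if (!is.na(fills[[k]]))
        sprintf('  "%s" [style=filled, fillcolor=%s];', k, fills[[k]])
      else
        sprintf('  "%s";', k)
    }, character(1))
    e <- stg$edges[order(stg$edges$from, stg$edges$to), , drop = FALSE]
    edge_lines <- sprintf('  "%s" -> "%s";', e$from, e$to)
    return(paste(c("digraph stg {", node_lines, edge_lines, "}", ""),
                 collapse = "\n"))
  }
  as.character(jsonlite::toJSON(
    list(scheme = stg$scheme, nodes = sort(stg$nodes),
         edges = stg$edges[order(stg$edges$from, stg$edges$to), , drop = FALSE]),
    auto_unbox = TRUE, dataframe = "rows", pretty = TRUE))
}

#' @rdname export_graph
#' @param text JSON text produced by `export_graph(..., format = "json")`.
#' @export
import_graph_json <- function(text) {
  obj <- jsonlite::fromJSON(text)
  edges <- if (length(obj$edges) == 0)
    data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE)
  else
    data.frame(from = obj$edges$from, to = obj$edges$to,
               stringsAsFactors = FALSE)
  structure(list(nodes = obj$nodes, edges = edges, scheme = obj$scheme),
            class = "stg")
}
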