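# Undirected simple-graph model over gene symbols. Networks are plain igraph
# objects (undirected, simple, vertex attribute `name`) with vertices kept in
# lexicographic order so every downstream listing is byte-stable.

#' Canonicalize gene symbols
#'
#' Gene symbols are HGNC-style tokens (e.g. `"TP53"`). Canonical form is
#' uppercase with surrounding whitespace removed; comparison throughout the
#' package is on the canonical form.
#'
#' @param x character vector of raw symbols.
#' @return character vector of canonical symbols.
#' @examples
#' canonical_symbol(c(" tp53", "Tspo"))
#' @export
canonical_symbol <- function(x) {
  if (length(x) == 0L) return(character(0))
  x <- toupper(trimws(as.character(x)))
  bad <- which(is.na(x) | x == "" | grepl("[[:space:]]", x))
  if (length(bad) > 0L) {
    stop("malformed gene symbol at position ", bad[1L], ": ",
         deparse(x[bad[1L]]), call. = FALSE)
  }
  x
}

#' Build an undirected simple network
#'
#' Constructs the graph object used by every analysis stage: an undirected
#' simple graph over canonical gene symbols. Self-loops are dropped and
#' duplicate edges (in either orientation) are collapsed, with a message
#' reporting how many records were discarded; interaction-table exports
#' routinely contain both orientations of the same pair.
#'
#' @param edges two-column character matrix or data frame of endpoint pairs
#'   (may be `NULL` or zero-row for an edgeless network).
#' @param extra_nodes character vector of symbols to include even when they
#'   touch no edge (kept as isolated nodes).
#' @return an [igraph][igraph::igraph-package] undirected simple graph with
#'   vertices in lexicographic order.
#' @examples
#' net <- build_network(rbind(c("a", "b"), c("B", "A")), extra_nodes = "C")
#' igraph::vcount(net)  # 3
#' igraph::ecount(net)  # 1
#' @export
build_network <- function(edges = NULL, extra_nodes = character(0)) {
  extra_nodes <- canonical_symbol(extra_nodes)
  if (is.null(edges) || NROW(edges) == 0L) {
    a <- b <- character(0)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2L) stop("edges must have two columns", call. = FALSE)
    a <- canonical_symbol(edges[, 1L])
    b <- canonical_symbol(edges[, 2L])
  }
  loops <- a == b
  if (any(loops)) {
    message("dropped ", sum(loops), " self-loop record(s)")
    a <- a[!loops]; b <- b[!loops]
  }
  # canonical unordered orientation, then dedup
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    message("collapsed ", sum(dup), " duplicate edge record(s)")
    lo <- lo[!dup]; hi <- hi[!dup]
  }
  nodes <- sort(unique(c(lo, hi, extra_nodes)))
  igraph::graph_from_data_frame(
    data.frame(from = lo, to = hi, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes
  )
}

#' Node symbols of a network
#' @param net a network built by [build_network()].
#' @return sorted character vector of vertex names.
#' @export
network_nodes <- function(net) {
  sort(igraph::V(net)$name)
}

#' Connected components
#'
#' Partitions the node set into maximal connected sets, ordered by decreasing
#' size with ties broken by the lexicographically smallest member. The
#' extended disease network is typically one large component plus several
#' detached small ones.
#'
#' @param net a network built by [build_network()].
#' @return list of sorted character vectors, one per component (empty list
#'   for an empty network).
#' @export
connected_components <- function(net) {
  if (igraph::vcount(net) == 0L) return(list())
  memb <- igraph::components(net)$membership
  comps <- split(names(memb), memb)
  comps <- lapply(comps, sort)
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1), 1L))
  unname(comps[ord])
}

#' Giant component
#'
#' Induced subgraph on the largest connected component — the object on which
#' all centrality analysis is performed.
#'
#' @param net a non-empty network.
#' @return the induced subgraph on the largest component.
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0L) {
    stop("giant_component() requires a network with at least one node",
         call. = FALSE)
  }
  comps <- connected_components(net)
  igraph::induced_subgraph(net, comps[[1L]])
}

#' Single-source shortest path lengths
#'
#' Unweighted breadth-first distances from `source`. Unreachable nodes are
#' absent from the result; the distance to `source` itself is 0.
#'
#' @param net a network.
#' @param source a gene symbol present in `net`.
#' @return named integer vector of geodesic distances, sorted by symbol.
#' @export
shortest_path_lengths <- function(net, source) {
  source <- canonical_symbol(source)
  if (length(source) != 1L || !source %in% igraph::V(net)$name) {
    stop("source node not present in network: ", source, call. = FALSE)
  }
  d <- igraph::distances(net, v = source)[1L, ]
  d <- d[is.finite(d)]
  out <- as.integer(d[order(names(d))])
  names(out) <- sort(names(d))
  out
}

#' All geodesics between two nodes
#'
#' Enumerates every shortest path between `s` and `t` — all of them, not one
#' representative — because the candidate-gene subnetwork is defined as the
#' union of all geodesics, and dropping co-optimal paths would silently shrink
#' it.
#'
#' @param net a network.
#' @param s,t distinct gene symbols present in `net`.
#' @return list of character vectors, each a path from `s` to `t`, in a
#'   deterministic order; empty list when `t` is unreachable from `s`.
#' @export
all_shortest_paths <- function(net, s, t) {
  s <- canonical_symbol(s); t <- canonical_symbol(t)
  vn <- igraph::V(net)$name
  if (!s %in% vn) stop("node not present in network: ", s, call. = FALSE)
  if (!t %in% vn) stop("node not present in network: ", t, call. = FALSE)
  if (s == t) stop("s and t must be distinct", call. = FALSE)
  res <- igraph::all_shortest_paths(net, from = s, to = t)$vpaths
  paths <- lapply(res, function(p) igraph::as_ids(p))
  if (length(paths) == 0L) return(list())
  keys <- vapply(paths, paste, character(1), collapse = "\r")
  paths[order(keys)]
}
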