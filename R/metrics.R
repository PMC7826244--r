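# Node centralities and whole-network statistics. Betweenness is computed by
# a from-scratch Brandes accumulation; closeness and the summary statistics
# are derived from the all-pairs geodesic distances.

#' Node degrees
#'
#' @param net a network built by [build_network()].
#' @return named integer vector of degrees (K), sorted by symbol; isolated
#'   nodes have degree 0, empty network gives an empty vector.
#' @export
degree_map <- function(net) {
  d <- igraph::degree(net)
  out <- as.integer(d[order(names(d))])
  names(out) <- sort(names(d))
  out
}

# Brandes (2001) betweenness for an undirected unweighted graph given an
# adjacency list of integer indices. Returns raw BC per vertex: the sum over
# unordered pairs s != v != t of sigma_st(v)/sigma_st, endpoints excluded;
# pairs in different components contribute nothing.
brandes_raw <- function(adj) {
  n <- length(adj)
  bc <- numeric(n)
  if (n == 0L) return(bc)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep.int(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      dv1 <- dist[v] + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv1
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dv1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    # accumulate pair dependencies in reverse BFS order
    delta <- numeric(n)
    for (i in rev(seq_len(tail))) {
      w <- queue[i]
      coef <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  bc / 2  # each unordered pair was visited from both endpoints
}

#' Betweenness centrality (Brandes)
#'
#' Fraction of all-pairs geodesics passing through a node, endpoints
#' excluded: raw BC(v) = sum over unordered pairs s,t of
#' sigma_st(v)/sigma_st, where sigma_st counts the geodesics between s and t.
#' High-BC nodes are the network's bottlenecks — nodes through which most of
#' the shortest-path traffic is funneled. The normalized variant divides by
#' (n-1)(n-2)/2, the number of pairs a node could possibly sit between, so
#' values lie in \[0, 1\] and match the NetworkAnalyzer convention used for
#' published PPI centrality tables.
#'
#' @param net a network.
#' @param normalized divide raw values by (n-1)(n-2)/2 (default `TRUE`).
#' @return named numeric vector sorted by symbol.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  vn <- igraph::V(net)$name
  n <- length(vn)
  if (n == 0L) return(stats::setNames(numeric(0), character(0)))
  adj <- lapply(igraph::as_adj_list(net), as.integer)
  bc <- brandes_raw(adj)
  if (normalized) {
    denom <- (n - 1) * (n - 2) / 2
    bc <- if (denom > 0) bc / denom else numeric(n)
  }
  names(bc) <- vn
  bc[order(names(bc))]
}

#' Closeness centrality
#'
#' CC(v) = (r - 1) / sum of geodesic distances from v to the other nodes of
#' its component, where r is the component size — i.e. the reciprocal of the
#' mean within-component geodesic length. Isolated nodes get 0. This is the
#' within-component convention of Cytoscape/NetworkAnalyzer (not harmonic
#' centrality), the one under which published PPI closeness values like 0.754
#' arise.
#'
#' @param net a network.
#' @return named numeric vector in \[0, 1\], sorted by symbol.
#' @export
closeness_centrality <- function(net) {
  vn <- igraph::V(net)$name
  if (length(vn) == 0L) return(stats::setNames(numeric(0), character(0)))
  D <- igraph::distances(net)
  cc <- apply(D, 1L, function(row) {
    reach <- row[is.finite(row)]
    r <- length(reach)               # component size incl. the node itself
    if (r <= 1L) 0 else (r - 1) / sum(reach)
  })
  cc[order(names(cc))]
}

#' Whole-network summary statistics
#'
#' Average degree `<K>` = 2E/N, mean shortest path length (mspl) and diameter
#' (D). Because the extended network is usually disconnected, mspl and D are
#' taken over connected node pairs only; an edgeless network reports both as
#' 0 with a warning.
#'
#' @param net a non-empty network.
#' @return list with `n_nodes`, `n_edges`, `avg_degree`, `mspl`, `diameter`.
#' @export
network_summary <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) {
    stop("network_summary() requires a network with at least one node",
         call. = FALSE)
  }
  e <- igraph::ecount(net)
  if (e == 0L) {
    warning("edgeless network: mspl and diameter reported as 0",
            call. = FALSE)
    mspl <- 0; diam <- 0L
  } else {
    D <- igraph::distances(net)
    d <- D[upper.tri(D)]
    d <- d[is.finite(d) & d > 0]
    mspl <- mean(d)
    diam <- as.integer(max(d))
  }
  list(n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
       mspl = mspl, diameter = diam)
}

#' Per-node metric table
#'
#' One row per node combining degree (K), normalized betweenness (BC) and
#' closeness (CC), ordered by descending degree with ties broken by symbol —
#' the table from which hubs and bottlenecks are ranked.
#'
#' @param net a network.
#' @return data frame with columns `symbol`, `degree`, `betweenness`,
#'   `closeness`.
#' @export
compute_node_metrics <- function(net) {
  k <- degree_map(net)
  bc <- betweenness_centrality(net, normalized = TRUE)
  cc <- closeness_centrality(net)
  out <- data.frame(symbol = names(k), degree = unname(k),
                    betweenness = unname(bc), closeness = unname(cc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a node-metric table as TSV
#'
#' Fixed 8-decimal format for the real-valued columns so repeated runs are
#' byte-identical.
#'
#' @param metrics data frame from [compute_node_metrics()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_node_metrics <- function(metrics, path) {
  lines <- c("symbol\tdegree\tbetweenness\tcloseness",
             sprintf("%s\t%d\t%.8f\t%.8f", metrics$symbol,
                     as.integer(metrics$degree), metrics$betweenness,
                     metrics$closeness))
  writeLines(lines, path)
  invisible(path)
}
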