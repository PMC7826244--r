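# Independent oracles for the graph algorithms: union-find components,
# Floyd-Warshall all-pairs distances, and exhaustive geodesic enumeration.
# They work on plain node/edge vectors and share no code with the package's
# BFS/Brandes path, so agreement is a genuine cross-check.

# random G(n, p) over symbols "N01".."Nn"; returns list(nodes, edges)
rand_graph <- function(n, p) {
  syms <- sprintf("N%02d", seq_len(n))
  ij <- utils::combn(n, 2L)
  keep <- stats::runif(ncol(ij)) < p
  list(nodes = syms,
       edges = cbind(syms[ij[1L, keep]], syms[ij[2L, keep]]))
}

# uniform random labelled tree: node i attaches to a random earlier node
rand_tree <- function(n) {
  syms <- sprintf("N%02d", seq_len(n))
  parent <- vapply(seq(2L, n), function(i) sample.int(i - 1L, 1L), integer(1))
  list(nodes = syms, edges = cbind(syms[parent], syms[seq(2L, n)]))
}

# connected components by union-find, as a list of sorted member vectors
# ordered by decreasing size then smallest member
uf_components <- function(nodes, edges) {
  idx <- stats::setNames(seq_along(nodes), nodes)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (NROW(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(idx[[edges[r, 1L]]]); rb <- find(idx[[edges[r, 2L]]])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comps <- lapply(split(nodes, roots), sort)
  ord <- order(-lengths(comps), vapply(comps, `[`, character(1), 1L))
  unname(comps[ord])
}

# Floyd-Warshall all-pairs distance matrix with dimnames
fw_dist <- function(nodes, edges) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  if (NROW(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      D[edges[r, 1L], edges[r, 2L]] <- 1
      D[edges[r, 2L], edges[r, 1L]] <- 1
    }
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      dk <- D[i, k]
      if (is.finite(dk)) D[i, ] <- pmin(D[i, ], dk + D[k, ])
    }
  }
  D
}

# adjacency list (symbol -> sorted neighbor symbols) from an edge matrix
adj_from_edges <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  if (NROW(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      a <- edges[r, 1L]; b <- edges[r, 2L]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  lapply(adj, function(x) sort(unique(x)))
}

# every geodesic from s to t, by DFS restricted to distance-decreasing moves
enum_geodesics <- function(adj, D, s, t) {
  if (!is.finite(D[s, t])) return(list())
  out <- list()
  walk <- function(path, cur) {
    if (cur == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nb in adj[[cur]]) {
      if (D[nb, t] == D[cur, t] - 1) walk(c(path, nb), nb)
    }
  }
  walk(s, s)
  out
}

# raw betweenness by exhaustive enumeration of all geodesics per pair
oracle_bc_raw <- function(nodes, edges) {
  D <- fw_dist(nodes, edges)
  adj <- adj_from_edges(nodes, edges)
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  n <- length(nodes)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- nodes[i]; t <- nodes[j]
      if (!is.finite(D[s, t]) || D[s, t] < 2) next
      paths <- enum_geodesics(adj, D, s, t)
      npath <- length(paths)
      for (p in paths) {
        interior <- p[-c(1L, length(p))]
        bc[interior] <- bc[interior] + 1 / npath
      }
    }
  }
  bc
}

# small helpers for fixtures built in code
path_graph <- function(syms) {
  build_network(cbind(syms[-length(syms)], syms[-1L]))
}

complete_graph <- function(syms) {
  ij <- utils::combn(syms, 2L)
  build_network(cbind(ij[1L, ], ij[2L, ]))
}

# two K3 cliques joined through the single bridge node "BB"
bridged_cliques <- function() {
  build_network(rbind(
    c("A1", "A2"), c("A1", "A3"), c("A2", "A3"),
    c("B1", "B2"), c("B1", "B3"), c("B2", "B3"),
    c("A1", "BB"), c("BB", "B1")
  ))
}

edge_set <- function(net) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0L) return(character(0))
  sort(paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "|"))
}

expect_same_network <- function(a, b) {
  expect_identical(network_nodes(a), network_nodes(b))
  expect_identical(edge_set(a), edge_set(b))
}
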