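# The analysis pipeline: extended first-neighbor network, key-node selection,
# high-BC backbone, candidate shortest-path subnetwork, and seed-resampling
# validation of the backbone.

#' Build the extended network around a seed gene list
#'
#' Grows the analyzed network from the disease-associated seed genes: keep
#' every interaction with combined score >= `min_score`, take the seeds plus
#' all of their first neighbors as the node set, and keep every qualifying
#' edge with both endpoints inside that set (seed-seed, seed-neighbor and
#' neighbor-neighbor edges alike, i.e. the induced subgraph on seeds plus
#' neighbors). Seeds that match nothing in the table are retained as isolated
#' nodes, with a warning.
#'
#' @param seeds character vector of seed gene symbols (non-empty).
#' @param interactions data frame with columns `protein_a`, `protein_b`,
#'   `score` (combined score on the 0-1000 scale), e.g. from
#'   [load_interactions()] or [emit_interaction_table()].
#' @param min_score minimum combined score for an edge to qualify; default
#'   400, the conventional medium-confidence cutoff.
#' @return a network ([build_network()]) on seeds plus first neighbors.
#' @export
build_extended_network <- function(seeds, interactions, min_score = 400) {
  seeds <- unique(canonical_symbol(seeds))
  if (length(seeds) == 0L) stop("empty seed list", call. = FALSE)
  stopifnot(is.data.frame(interactions),
            all(c("protein_a", "protein_b", "score") %in% names(interactions)))
  a <- canonical_symbol(interactions$protein_a)
  b <- canonical_symbol(interactions$protein_b)
  keep <- interactions$score >= min_score & a != b
  a <- a[keep]; b <- b[keep]
  inc <- a %in% seeds | b %in% seeds
  neighbors <- unique(c(a[inc], b[inc]))
  nodes <- unique(c(seeds, neighbors))
  absent <- setdiff(seeds, neighbors)
  if (length(absent) > 0L) {
    warning(length(absent), " seed gene(s) absent from the interaction ",
            "table at min_score=", min_score, "; kept as isolated nodes",
            call. = FALSE)
  }
  both <- a %in% nodes & b %in% nodes
  suppressMessages(
    build_network(cbind(a[both], b[both]), extra_nodes = seeds)
  )
}

# Rank symbols by a metric value, descending, ties broken by symbol, and cut
# at the top ceiling(fraction * n) / top k with all nodes tied at the cutoff
# value included. Shared by key-node selection and backbone extraction.
rank_and_cut <- function(symbols, values, k) {
  ord <- order(-values, symbols)
  cutoff <- values[ord][k]
  sel <- ord[values[ord] >= cutoff]
  symbols[sel]
}

#' Select key nodes by degree or betweenness
#'
#' The hub/bottleneck selection rule: rank all nodes by the chosen metric and
#' keep the top `ceiling(fraction * n)`. Nodes tied with the cutoff value are
#' all included (deterministic, never a random drop), with symbol order as
#' the secondary sort.
#'
#' @param metrics data frame with at least `symbol` and the criterion column
#'   (from [compute_node_metrics()] or an external ranking table).
#' @param criterion `"degree"` or `"betweenness"`.
#' @param fraction fraction of nodes to keep, in (0, 1\]; default 0.10.
#' @return ranked character vector of selected symbols.
#' @export
select_key_nodes <- function(metrics, criterion = c("degree", "betweenness"),
                             fraction = 0.10) {
  criterion <- match.arg(criterion)
  if (!is.data.frame(metrics) || nrow(metrics) == 0L) {
    stop("empty metrics table", call. = FALSE)
  }
  if (!(fraction > 0 && fraction <= 1)) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  syms <- canonical_symbol(metrics$symbol)
  vals <- metrics[[criterion]]
  k <- ceiling(fraction * length(syms))
  rank_and_cut(syms, vals, k)
}

#' Intersection of two key-node selections
#'
#' The nodes that are simultaneously hubs (high degree) and bottlenecks
#' (high betweenness).
#'
#' @param by_degree,by_bc character vectors of selected symbols.
#' @return sorted character vector of common symbols.
#' @export
key_node_intersection <- function(by_degree, by_bc) {
  sort(intersect(canonical_symbol(by_degree), canonical_symbol(by_bc)))
}

#' Extract the high-betweenness backbone
#'
#' Computes normalized betweenness on `net` (normally the giant component),
#' takes the top `k` nodes — ties at the k-th value all included, the
#' effective count recorded — and returns the induced subgraph on them: the
#' heavily used crossing points of the network together with their mutual
#' connections.
#'
#' @param net a network; a connected graph (giant component) is recommended.
#' @param k number of top-BC nodes to request; default 15. Values above the
#'   node count are clamped with a warning.
#' @return list with `backbone` (induced subgraph), `selected` (data frame
#'   `symbol`, `betweenness`, ranked), `k_requested`, `k_effective`.
#' @export
build_backbone <- function(net, k = 15) {
  n <- igraph::vcount(net)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  k_req <- as.integer(k)
  if (k_req > n) {
    warning("k = ", k_req, " exceeds node count ", n, "; clamped",
            call. = FALSE)
    k_req <- n
  }
  bc <- betweenness_centrality(net, normalized = TRUE)
  sel <- rank_and_cut(names(bc), unname(bc), k_req)
  list(
    backbone = igraph::induced_subgraph(net, sort(sel)),
    selected = data.frame(symbol = sel, betweenness = unname(bc[sel]),
                          stringsAsFactors = FALSE),
    k_requested = k_req,
    k_effective = length(sel)
  )
}

#' Shortest-path subnetwork among the candidate genes
#'
#' Candidate genes are often not directly connected; the paths that link them
#' run through intermediate proteins. For every unordered pair of candidates
#' present and mutually reachable in `net`, all geodesics are collected, and
#' the subnetwork is the induced subgraph on the union of every node lying on
#' any of them. Candidates sitting in components without another candidate
#' remain as nodes of the subnetwork but connect no pair.
#'
#' @param net a network.
#' @param candidates character vector of candidate gene symbols.
#' @return list with `subnet` (induced subgraph),
#'   `candidate_pairs_connected`, `candidate_pairs_total` (pairs of
#'   candidates present in `net`).
#' @export
shortest_path_subnetwork <- function(net, candidates) {
  candidates <- unique(canonical_symbol(candidates))
  present <- sort(intersect(candidates, igraph::V(net)$name))
  n_pres <- length(present)
  total <- n_pres * (n_pres - 1) / 2
  connected <- 0L
  on_path <- character(0)
  if (n_pres >= 2L) {
    memb <- igraph::components(net)$membership[present]
    for (i in seq_len(n_pres - 1L)) {
      targets <- present[(i + 1L):n_pres]
      targets <- targets[memb[(i + 1L):n_pres] == memb[i]]
      if (length(targets) == 0L) next
      connected <- connected + length(targets)
      res <- igraph::all_shortest_paths(net, from = present[i],
                                        to = targets)$vpaths
      on_path <- unique(c(on_path,
                          unlist(lapply(res, igraph::as_ids),
                                 use.names = FALSE)))
    }
  }
  nodes <- sort(unique(c(present, on_path)))
  subnet <- if (length(nodes) == 0L) {
    build_network(NULL, character(0))
  } else {
    igraph::induced_subgraph(net, nodes)
  }
  list(subnet = subnet,
       candidate_pairs_connected = as.integer(connected),
       candidate_pairs_total = as.integer(total))
}

#' Validate backbone robustness by seed resampling
#'
#' Jackknife-style check that the backbone does not hinge on any particular
#' subset of the seed list: each replicate samples a fraction of the seeds
#' without replacement, rebuilds the extended network, takes its giant
#' component and records the top-`k` BC node set (ties included). The
#' reported frequency of a backbone node is the fraction of replicates in
#' which it reappears in that set.
#'
#' @param interactions interaction table (see [build_extended_network()]).
#' @param seeds full seed gene list.
#' @param backbone_nodes character vector of backbone node symbols to score.
#' @param seed_fraction fraction of seeds kept per replicate, in (0, 1\];
#'   default 0.8.
#' @param n_replicates number of resampled replicates; default 100.
#' @param k top-BC set size per replicate; default 15.
#' @param rng_seed integer seed making the replicate stream reproducible.
#' @param min_score score threshold passed through to the network rebuild.
#' @return list with `frequencies` (named numeric over backbone nodes,
#'   sorted), `n_replicates`, `seed_fraction`, `k`, `rng_seed`.
#' @export
validate_backbone <- function(interactions, seeds, backbone_nodes,
                              seed_fraction = 0.8, n_replicates = 100,
                              k = 15, rng_seed = 1, min_score = 400) {
  if (!(seed_fraction > 0 && seed_fraction <= 1)) {
    stop("seed_fraction must be in (0, 1]", call. = FALSE)
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  seeds <- unique(canonical_symbol(seeds))
  backbone_nodes <- sort(unique(canonical_symbol(backbone_nodes)))
  m <- ceiling(seed_fraction * length(seeds))
  hits <- stats::setNames(numeric(length(backbone_nodes)), backbone_nodes)
  withr::with_seed(rng_seed, {
    for (r in seq_len(n_replicates)) {
      sub <- sample(seeds, m)
      net <- suppressWarnings(
        build_extended_network(sub, interactions, min_score)
      )
      giant <- giant_component(net)
      bc <- betweenness_centrality(giant, normalized = TRUE)
      kk <- min(k, length(bc))
      top <- rank_and_cut(names(bc), unname(bc), kk)
      inset <- backbone_nodes %in% top
      hits[inset] <- hits[inset] + 1
    }
  })
  list(frequencies = hits / n_replicates,
       n_replicates = as.integer(n_replicates),
       seed_fraction = seed_fraction,
       k = as.integer(k),
       rng_seed = as.integer(rng_seed))
}
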