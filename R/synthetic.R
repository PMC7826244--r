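# Synthetic network generators. PPI networks are dominated by a few highly
# connected hubs; the preferential-attachment generator reproduces that
# degree structure, and the planted-bottleneck generator builds graphs whose
# top-betweenness node is known by construction, giving every pipeline stage
# a ground truth to recover. Symbols are formatted "G0001"... so synthetic
# fixtures cannot collide with real HGNC symbols.

synthetic_symbols <- function(n) sprintf("G%04d", seq_len(n))

#' Generate a scale-free network by preferential attachment
#'
#' Barabasi-Albert-style growth: start from a complete graph on
#' `attachment + 1` nodes, then attach each new node to `attachment` distinct
#' existing nodes chosen with probability proportional to their current
#' degree. The result is connected, has exactly
#' `choose(attachment + 1, 2) + attachment * (n_nodes - attachment - 1)`
#' edges, and develops the small set of very highly connected hubs typical
#' of PPI networks.
#'
#' @param n_nodes total number of nodes; must exceed `attachment`.
#' @param attachment edges added per new node (>= 1); default 2.
#' @param rng_seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return a network with nodes `"G0001"...`.
#' @export
generate_scale_free <- function(n_nodes, attachment = 2, rng_seed = 1) {
  if (attachment < 1) stop("attachment must be >= 1", call. = FALSE)
  if (n_nodes <= attachment) {
    stop("n_nodes must exceed attachment", call. = FALSE)
  }
  m <- as.integer(attachment)
  n <- as.integer(n_nodes)
  core <- seq_len(m + 1L)
  ij <- utils::combn(core, 2L)
  from <- ij[1L, ]; to <- ij[2L, ]
  deg <- integer(n)
  deg[core] <- m
  withr::with_seed(rng_seed, {
    for (i in seq.int(m + 2L, length.out = n - m - 1L)) {
      existing <- seq_len(i - 1L)
      targets <- if (length(existing) == m) existing else {
        sample(existing, m, prob = deg[existing])
      }
      from <- c(from, targets)
      to <- c(to, rep.int(i, m))
      deg[targets] <- deg[targets] + 1L
      deg[i] <- m
    }
  })
  sym <- synthetic_symbols(n)
  build_network(cbind(sym[from], sym[to]))
}

#' Generate a network with a planted bottleneck
#'
#' Two complete cliques of `clique_size` nodes joined through a chain of
#' `n_bridges` bridge nodes: clique anchor - B1 - ... - Bn - clique anchor.
#' Every geodesic between the two cliques runs through every bridge node, so
#' each bridge has strictly higher raw betweenness than any clique node —
#' a known answer for bottleneck-recovery tests. The anchors within each
#' clique are drawn with `rng_seed` (cliques are vertex-transitive, so this
#' only permutes labels).
#'
#' @param clique_size nodes per clique (>= 3).
#' @param n_bridges number of bridge nodes (>= 1); default 1.
#' @param rng_seed integer seed.
#' @return list with `network` and `planted` (the bridge node symbols).
#' @export
generate_planted_bottleneck <- function(clique_size, n_bridges = 1,
                                        rng_seed = 1) {
  if (clique_size < 3) stop("clique_size must be >= 3", call. = FALSE)
  if (n_bridges < 1) stop("n_bridges must be >= 1", call. = FALSE)
  cs <- as.integer(clique_size); nb <- as.integer(n_bridges)
  sym <- synthetic_symbols(2L * cs + nb)
  clique_a <- sym[seq_len(cs)]
  bridges <- sym[cs + seq_len(nb)]
  clique_b <- sym[cs + nb + seq_len(cs)]
  clique_edges <- function(members) {
    ij <- utils::combn(members, 2L)
    cbind(ij[1L, ], ij[2L, ])
  }
  anchors <- withr::with_seed(rng_seed,
                              c(sample(clique_a, 1L), sample(clique_b, 1L)))
  chain <- c(anchors[1L], bridges, anchors[2L])
  chain_edges <- cbind(chain[-length(chain)], chain[-1L])
  net <- build_network(rbind(clique_edges(clique_a),
                             clique_edges(clique_b),
                             chain_edges))
  list(network = net, planted = bridges)
}

#' Emit a scored interaction table for a network
#'
#' One STRING-style record per edge with a uniform random integer combined
#' score in `[score_low, score_high]`. A fraction of records can additionally
#' be duplicated in reversed orientation, mimicking database exports that
#' list both directions of an undirected interaction (the loader collapses
#' them).
#'
#' @param net a network.
#' @param score_low,score_high inclusive score bounds within 0-1000.
#' @param rng_seed integer seed.
#' @param reversed_fraction fraction of records to duplicate reversed, in
#'   \[0, 1\]; default 0.
#' @return data frame with columns `protein_a`, `protein_b`, `score`.
#' @export
emit_interaction_table <- function(net, score_low = 400, score_high = 1000,
                                   rng_seed = 1, reversed_fraction = 0) {
  stopifnot(score_low <= score_high, score_low >= 0, score_high <= 1000)
  el <- igraph::as_edgelist(net)
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  ord <- order(a, b)
  a <- a[ord]; b <- b[ord]
  ne <- length(a)
  withr::with_seed(rng_seed, {
    score <- if (ne == 0L) integer(0) else {
      as.integer(score_low) +
        sample.int(as.integer(score_high) - as.integer(score_low) + 1L,
                   ne, replace = TRUE) - 1L
    }
    tab <- data.frame(protein_a = a, protein_b = b, score = score,
                      stringsAsFactors = FALSE)
    if (reversed_fraction > 0 && ne > 0L) {
      idx <- sample.int(ne, floor(reversed_fraction * ne))
      if (length(idx) > 0L) {
        rev_rows <- data.frame(protein_a = b[idx], protein_b = a[idx],
                               score = score[idx], stringsAsFactors = FALSE)
        tab <- rbind(tab, rev_rows)
      }
    }
    tab
  })
}

#' Sample a seed gene list from a network
#'
#' Uniform sample of node symbols without replacement, reproducible from
#' `rng_seed`; stands in for a literature-derived candidate gene list when
#' exercising the pipeline on synthetic data.
#'
#' @param net a network.
#' @param n_seeds number of seeds, at most the node count.
#' @param rng_seed integer seed.
#' @return character vector of sampled symbols.
#' @export
sample_seed_list <- function(net, n_seeds, rng_seed = 1) {
  nodes <- network_nodes(net)
  if (n_seeds > length(nodes)) {
    stop("n_seeds exceeds node count", call. = FALSE)
  }
  withr::with_seed(rng_seed, sample(nodes, n_seeds))
}
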