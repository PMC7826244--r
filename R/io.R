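# Readers and writers for the plain-text formats the pipeline consumes and
# produces: seed gene lists, SIF and STRING-style TSV edge lists, metric and
# frequency tables, JSON summaries. All writers are byte-stable: sorted
# records, fixed decimal formats, no timestamps.

#' Load a seed gene list
#'
#' One symbol per line, or the first column of a TSV. Symbols are
#' canonicalized to uppercase; duplicates after canonicalization are
#' collapsed with a warning. The packaged oral-cancer candidate list (208
#' literature-derived genes) ships at
#' `system.file("extdata", "oral_cancer_seed_genes.txt", package = "ppitopo")`.
#'
#' @param path file path.
#' @return character vector of unique canonical symbols, in file order.
#' @export
load_seed_genes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  first <- vapply(strsplit(lines, "\t", fixed = TRUE),
                  function(x) if (length(x) == 0L) "" else x[[1L]],
                  character(1))
  first <- trimws(first)
  first <- first[first != ""]
  if (length(first) == 0L) stop("empty seed gene file: ", path, call. = FALSE)
  syms <- canonical_symbol(first)
  dup <- duplicated(syms)
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicate seed symbol(s) in ", path,
            call. = FALSE)
  }
  syms[!dup]
}

#' Load an interaction table
#'
#' Two dialects:
#' * `"string_tsv"`: tab-separated `protein1  protein2  combined_score`
#'   rows, score an integer on the 0-1000 scale; a non-numeric first row is
#'   treated as a header and skipped.
#' * `"sif"`: tab-separated `A  relation  B` rows (further targets on the
#'   same row allowed, single-token rows are isolated nodes and yield no
#'   record); every record gets score 1000 since SIF carries no confidence.
#'
#' Malformed rows abort with their line numbers.
#'
#' @param path file path.
#' @param dialect `"string_tsv"` (default) or `"sif"`.
#' @return data frame with columns `protein_a`, `protein_b`, `score`.
#' @export
load_interactions <- function(path, dialect = c("string_tsv", "sif")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- trimws(lines) != ""
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  if (dialect == "string_tsv") {
    if (length(fields) > 0L && length(fields[[1L]]) >= 3L &&
        is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) {
      fields <- fields[-1L]; lineno <- lineno[-1L]
    }
    bad <- which(lengths(fields) < 3L)
    score <- suppressWarnings(
      as.numeric(vapply(fields, function(x) x[min(3L, length(x))],
                        character(1)))
    )
    bad <- sort(unique(c(bad, which(is.na(score) | score < 0 | score > 1000))))
    if (length(bad) > 0L) {
      stop("malformed interaction row(s) at line(s) ",
           paste(lineno[bad], collapse = ", "), " of ", path, call. = FALSE)
    }
    data.frame(
      protein_a = canonical_symbol(vapply(fields, `[`, character(1), 1L)),
      protein_b = canonical_symbol(vapply(fields, `[`, character(1), 2L)),
      score = as.integer(round(score)),
      stringsAsFactors = FALSE
    )
  } else {
    bad <- which(lengths(fields) == 2L)
    if (length(bad) > 0L) {
      stop("malformed SIF row(s) at line(s) ",
           paste(lineno[bad], collapse = ", "), " of ", path, call. = FALSE)
    }
    fields <- fields[lengths(fields) >= 3L]
    if (length(fields) == 0L) {
      return(data.frame(protein_a = character(0), protein_b = character(0),
                        score = integer(0), stringsAsFactors = FALSE))
    }
    src <- rep(vapply(fields, `[`, character(1), 1L),
               lengths(fields) - 2L)
    dst <- unlist(lapply(fields, function(x) x[-(1:2)]), use.names = FALSE)
    data.frame(protein_a = canonical_symbol(src),
               protein_b = canonical_symbol(dst),
               score = rep.int(1000L, length(src)),
               stringsAsFactors = FALSE)
  }
}

#' Read a network from a SIF file
#'
#' Inverse of [write_network()] for the SIF dialect: edge rows plus
#' single-token rows for isolated nodes.
#'
#' @param path file path.
#' @return a network.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  fields <- strsplit(lines[trimws(lines) != ""], "\t", fixed = TRUE)
  singles <- unlist(fields[lengths(fields) == 1L], use.names = FALSE)
  tab <- load_interactions(path, dialect = "sif")
  suppressMessages(
    build_network(cbind(tab$protein_a, tab$protein_b),
                  extra_nodes = if (is.null(singles)) character(0) else singles)
  )
}

#' Write a network
#'
#' SIF output is canonical and byte-stable: edge lines `A<TAB>pp<TAB>B` with
#' `A < B`, sorted; isolated nodes as single-token lines after the edges.
#' GraphML (export only, for graph viewers) delegates to
#' [igraph::write_graph()].
#'
#' @param net a network.
#' @param path output file path.
#' @param format `"sif"` (default) or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(net)
  a <- pmin(el[, 1L], el[, 2L]); b <- pmax(el[, 1L], el[, 2L])
  ord <- order(a, b)
  iso <- setdiff(network_nodes(net), c(a, b))
  writeLines(c(sprintf("%s\tpp\t%s", a[ord], b[ord]), sort(iso)), path)
  invisible(path)
}

#' Write a seed-resampling validation report
#'
#' `symbol<TAB>frequency` TSV plus a JSON sidecar recording the resampling
#' parameters.
#'
#' @param report list from [validate_backbone()].
#' @param path path of the TSV; the sidecar gets the extension `.json`.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  freq <- report$frequencies
  writeLines(c("symbol\tfrequency",
               sprintf("%s\t%.8f", names(freq), unname(freq))), path)
  sidecar <- sub("\\.tsv$", "", path)
  jsonlite::write_json(
    report[c("seed_fraction", "n_replicates", "k", "rng_seed")],
    paste0(sidecar, ".json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the tunable parameters of [run_pipeline()] with their defaults:
#' medium-confidence score threshold 400, 15-node backbone, top-10% key-node
#' fraction, and an 80%/100-replicate resampling validation.
#'
#' @param min_score combined-score threshold on the 0-1000 scale.
#' @param backbone_k top-BC backbone size.
#' @param key_fraction key-node selection fraction in (0, 1\].
#' @param seed_fraction resampling fraction in (0, 1\].
#' @param n_replicates number of validation replicates.
#' @param rng_seed integer seed for the validation resampling.
#' @return named list of validated parameters.
#' @export
pipeline_config <- function(min_score = 400, backbone_k = 15,
                            key_fraction = 0.10, seed_fraction = 0.8,
                            n_replicates = 100, rng_seed = 1) {
  stopifnot(min_score >= 0, min_score <= 1000, backbone_k >= 1,
            key_fraction > 0, key_fraction <= 1,
            seed_fraction > 0, seed_fraction <= 1,
            n_replicates >= 1)
  list(min_score = min_score, backbone_k = as.integer(backbone_k),
       key_fraction = key_fraction, seed_fraction = seed_fraction,
       n_replicates = as.integer(n_replicates),
       rng_seed = as.integer(rng_seed))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order — extended network, giant component, node
#' metrics, key-node selection by degree and betweenness plus their
#' intersection, high-BC backbone, candidate shortest-path subnetwork, and
#' seed-resampling backbone validation — and writes each intermediate
#' artifact plus a JSON summary under `out_dir`. Output is a pure function
#' of the configuration and the input files: a rerun produces byte-identical
#' files.
#'
#' @param config list from [pipeline_config()].
#' @param seed_path seed gene list file (see [load_seed_genes()]).
#' @param interaction_path interaction table file.
#' @param out_dir output directory (created if missing).
#' @param dialect interaction-table dialect, see [load_interactions()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config, seed_path, interaction_path, out_dir,
                         dialect = c("string_tsv", "sif")) {
  dialect <- match.arg(dialect)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  seeds <- stage("load_seeds", load_seed_genes(seed_path))
  interactions <- stage("load_interactions",
                        load_interactions(interaction_path, dialect))
  extended <- stage("extended_network",
                    build_extended_network(seeds, interactions,
                                           config$min_score))
  giant <- stage("giant_component", giant_component(extended))
  metrics <- stage("node_metrics", compute_node_metrics(giant))
  key_deg <- stage("key_nodes_degree",
                   select_key_nodes(metrics, "degree", config$key_fraction))
  key_bc <- stage("key_nodes_betweenness",
                  select_key_nodes(metrics, "betweenness",
                                   config$key_fraction))
  key_both <- key_node_intersection(key_deg, key_bc)
  bb <- stage("backbone", build_backbone(giant, config$backbone_k))
  sub <- stage("subnetwork", shortest_path_subnetwork(giant, seeds))
  val <- stage("validation",
               validate_backbone(interactions, seeds, bb$selected$symbol,
                                 seed_fraction = config$seed_fraction,
                                 n_replicates = config$n_replicates,
                                 k = config$backbone_k,
                                 rng_seed = config$rng_seed,
                                 min_score = config$min_score))

  write_network(extended, file.path(out_dir, "extended_network.sif"))
  write_network(giant, file.path(out_dir, "giant_component.sif"))
  write_node_metrics(metrics, file.path(out_dir, "node_metrics.tsv"))
  writeLines(key_deg, file.path(out_dir, "key_nodes_degree.txt"))
  writeLines(key_bc, file.path(out_dir, "key_nodes_betweenness.txt"))
  writeLines(key_both, file.path(out_dir, "key_nodes_intersection.txt"))
  write_network(bb$backbone, file.path(out_dir, "backbone.sif"))
  writeLines(c("symbol\tbetweenness",
               sprintf("%s\t%.8f", bb$selected$symbol,
                       bb$selected$betweenness)),
             file.path(out_dir, "backbone_nodes.tsv"))
  write_network(sub$subnet, file.path(out_dir, "subnetwork.sif"))
  write_validation_report(val, file.path(out_dir, "validation.tsv"))

  summary <- list(
    config = config,
    n_seed_genes = length(seeds),
    n_interaction_records = nrow(interactions),
    extended = list(n_nodes = igraph::vcount(extended),
                    n_edges = igraph::ecount(extended)),
    giant = network_summary(giant),
    top_degree_node = metrics$symbol[1L],
    top_betweenness_node =
      metrics$symbol[order(-metrics$betweenness, metrics$symbol)][1L],
    key_nodes = list(by_degree = key_deg, by_betweenness = key_bc,
                     intersection = key_both),
    backbone = list(k_requested = bb$k_requested,
                    k_effective = bb$k_effective,
                    n_nodes = igraph::vcount(bb$backbone),
                    n_edges = igraph::ecount(bb$backbone),
                    nodes = bb$selected$symbol),
    subnetwork = list(n_nodes = igraph::vcount(sub$subnet),
                      n_edges = igraph::ecount(sub$subnet),
                      candidate_pairs_connected =
                        sub$candidate_pairs_connected,
                      candidate_pairs_total = sub$candidate_pairs_total),
    validation = list(frequencies = as.list(val$frequencies),
                      n_replicates = val$n_replicates,
                      seed_fraction = val$seed_fraction)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
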