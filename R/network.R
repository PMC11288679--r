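#' Weighted undirected colony network
#'
#' A colony interaction network: a symmetric nonnegative matrix of pairwise
#' interaction counts plus per-ant metadata. Exactly one node may carry the
#' queen flag (zero is tolerated; queen-dependent operations then error or
#' fall back as documented).
#'
#' @param W symmetric nonnegative numeric matrix with zero diagonal;
#'   dimnames give ant ids (generated if absent).
#' @param metadata data.frame with one row per node. Recognised columns:
#'   `ant_id`, `is_queen` (logical), `foraging_proportion`,
#'   `detection_count`. Missing columns are filled with defaults.
#' @param colony,species optional labels carried through reports.
#' @return an object of class `weighted_network`.
#' @export
weighted_network <- function(W, metadata = NULL, colony = NA_character_,
                             species = NA_character_) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop_data("weight matrix must be square")
  if (any(W < 0)) stop_data("weights must be nonnegative")
  if (max(abs(W - t(W))) > 1e-8) stop_data("weight matrix must be symmetric")
  W <- (W + t(W)) / 2
  diag(W) <- 0
  ids <- rownames(W)
  if (is.null(ids)) ids <- paste0("ant_", seq_len(nrow(W)))
  dimnames(W) <- list(ids, ids)

  if (is.null(metadata)) metadata <- data.frame(ant_id = ids)
  metadata <- as.data.frame(metadata)
  if (!"ant_id" %in% names(metadata)) metadata$ant_id <- ids
  metadata$ant_id <- as.character(metadata$ant_id)
  if (!setequal(metadata$ant_id, ids) || nrow(metadata) != length(ids)) {
    stop_data("metadata ant_id set must match matrix dimnames")
  }
  metadata <- metadata[match(ids, metadata$ant_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!"is_queen" %in% names(metadata)) metadata$is_queen <- FALSE
  metadata$is_queen <- isTRUE_vec(metadata$is_queen)
  if (sum(metadata$is_queen) > 1) stop_data("at most one queen node allowed")
  if (!"foraging_proportion" %in% names(metadata)) {
    metadata$foraging_proportion <- NA_real_
  }
  if (!"detection_count" %in% names(metadata)) {
    metadata$detection_count <- NA_real_
  }

  structure(list(W = W, meta = metadata, colony = colony, species = species),
            class = "weighted_network")
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d nodes, %d edges, total weight %g\n",
              nrow(x$W), sum(x$W[upper.tri(x$W)] > 0),
              sum(x$W[upper.tri(x$W)])))
  if (any(x$meta$is_queen)) {
    cat("  queen:", x$meta$ant_id[x$meta$is_queen], "\n")
  }
  invisible(x)
}

n_nodes <- function(net) nrow(net$W)

queen_id <- function(net) {
  q <- net$meta$ant_id[net$meta$is_queen]
  if (length(q) == 0) NA_character_ else q
}

#' Build a colony network from a count matrix, dropping excluded ants
#'
#' @param count_matrix symmetric pairwise interaction-count matrix.
#' @param metadata per-ant metadata (see [weighted_network()]).
#' @param excluded character vector of ant ids to drop (e.g. from
#'   [low_detection_filter()]). Isolated nodes are retained.
#' @inheritParams weighted_network
#' @return a `weighted_network`.
#' @export
build_network <- function(count_matrix, metadata = NULL,
                          excluded = character(0),
                          colony = NA_character_, species = NA_character_) {
  net <- weighted_network(count_matrix, metadata, colony, species)
  if (length(excluded) > 0) {
    keep <- !(net$meta$ant_id %in% excluded)
    if (!any(keep)) stop_data("exclusion removed every node")
    net$W <- net$W[keep, keep, drop = FALSE]
    net$meta <- net$meta[keep, , drop = FALSE]
    rownames(net$meta) <- NULL
  }
  net
}

#' Node strength (summed edge weight)
#'
#' @param network a `weighted_network`.
#' @param node optional ant id (or vector of ids); default all nodes.
#' @return named numeric vector of strengths.
#' @export
node_strength <- function(network, node = NULL) {
  s <- rowSums(network$W)
  if (is.null(node)) return(s)
  if (!all(node %in% names(s))) {
    stop_data("unknown node: ", paste(setdiff(node, names(s)), collapse = ", "))
  }
  s[node]
}

total_weight <- function(network) sum(network$W[upper.tri(network$W)])

edge_list <- function(network) {
  idx <- which(upper.tri(network$W) & network$W > 0, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             weight = network$W[idx])
}

#' Degree-preserving rewiring null model
#'
#' Produces a randomised replica of the network that preserves the node
#' set, the binary degree sequence and the multiset of edge weights
#' exactly. The default strategy performs weighted double-edge swaps:
#' weights travel with their edge slot and swaps that would create a
#' self-loop or merge onto an existing edge are rejected. The alternative
#' `"configuration"` strategy rebuilds a simple graph with the same degree
#' sequence and deals the observed weight multiset onto it at random.
#'
#' @param network a `weighted_network`.
#' @param n_swap_multiplier accepted swaps per edge (default 10).
#' @param seed integer seed for reproducibility.
#' @param strategy `"swap"` (default) or `"configuration"`.
#' @return a `weighted_network`; attribute `degenerate` is TRUE if the
#'   graph was too small to randomise (a copy is returned with a warning).
#' @export
rewire <- function(network, n_swap_multiplier = 10, seed = NULL,
                   strategy = c("swap", "configuration")) {
  strategy <- match.arg(strategy)
  el <- edge_list(network)
  n <- n_nodes(network)
  if (nrow(el) < 2) {
    warning("network too small to rewire; returning a copy")
    out <- network
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  with_seed(seed, {
    if (strategy == "swap") {
      res <- rewire_swaps_cpp(as.integer(el$i - 1L), as.integer(el$j - 1L),
                              n, as.integer(n_swap_multiplier * nrow(el)),
                              200 * n_swap_multiplier * nrow(el))
      # dense count networks rarely admit the full budget; only warn when
      # fewer than one accepted swap per edge was possible (poor mixing)
      if (isTRUE(res$exhausted) && res$accepted < nrow(el)) {
        warning("graph too rigid to rewire thoroughly (",
                res$accepted, " swaps for ", nrow(el), " edges)")
      }
      ei <- res$ei + 1L
      ej <- res$ej + 1L
      w <- el$weight
      accepted <- res$accepted
    } else {
      deg <- tabulate(c(el$i, el$j), nbins = n)
      g <- igraph::sample_degseq(deg, method = "vl")
      e <- igraph::as_edgelist(g, names = FALSE)
      ei <- pmin(e[, 1], e[, 2])
      ej <- pmax(e[, 1], e[, 2])
      w <- sample(el$weight)
      accepted <- NA_integer_
    }
    W2 <- matrix(0, n, n, dimnames = dimnames(network$W))
    W2[cbind(ei, ej)] <- w
    W2[cbind(ej, ei)] <- w
    out <- weighted_network(W2, network$meta, network$colony, network$species)
    attr(out, "degenerate") <- FALSE
    attr(out, "accepted_swaps") <- accepted
    out
  })
}

#' Write / read a network as a weighted edge-list CSV
#'
#' Columns: `ant_i`, `ant_j`, `count`, plus a node table side-car is not
#' needed because metadata columns are replicated per endpoint on read
#' via `metadata`.
#'
#' @param network a `weighted_network`.
#' @param path output CSV path.
#' @export
write_edgelist <- function(network, path) {
  el <- edge_list(network)
  ids <- network$meta$ant_id
  df <- data.frame(ant_i = ids[el$i], ant_j = ids[el$j], count = el$weight)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @param metadata optional metadata passed to [build_network()]; node set
#'   defaults to the ids appearing in the file.
#' @export
read_edgelist <- function(path, metadata = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("ant_i", "ant_j", "count")
  if (!all(need %in% names(df))) {
    stop_data("edge list must have columns ant_i, ant_j, count")
  }
  ids <- if (!is.null(metadata)) as.character(metadata$ant_id) else
    sort(unique(c(as.character(df$ant_i), as.character(df$ant_j))))
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  W[cbind(match(as.character(df$ant_i), ids),
          match(as.character(df$ant_j), ids))] <- df$count
  W <- W + t(W)
  weighted_network(W, metadata)
}

#' Write / read a network as GraphML (via igraph)
#'
#' Node attributes `is_queen` and `foraging_proportion` are carried.
#'
#' @param network a `weighted_network`.
#' @param path file path.
#' @export
write_graphml <- function(network, path) {
  g <- igraph::graph_from_adjacency_matrix(network$W, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$is_queen <- as.integer(network$meta$is_queen)
  igraph::V(g)$foraging_proportion <- network$meta$foraging_proportion
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = FALSE))
  rownames(W) <- colnames(W) <- igraph::V(g)$name
  meta <- data.frame(ant_id = igraph::V(g)$name,
                     is_queen = igraph::V(g)$is_queen > 0,
                     foraging_proportion =
                       if ("foraging_proportion" %in%
                           igraph::vertex_attr_names(g))
                         igraph::V(g)$foraging_proportion else NA_real_)
  weighted_network(W, meta)
}
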