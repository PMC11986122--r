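#' Build the weighted IBD-sharing network
#'
#' Nodes are samples; an edge joins two samples iff at least one IBD
#' segment of length >= `min_segment_cM` links any of their haplotypes.
#' Edge weights: `weight_total_cM` (sum of qualifying segment lengths —
#' the clustering weight) and `weight_mean_cM` (mean qualifying length,
#' carried for display/top-k export).
#'
#' @param segments IBD segment data.frame.
#' @param min_segment_cM minimum qualifying segment length (default 4 cM).
#' @param samples optional full sample roster (nodes without qualifying
#'   edges are kept); defaults to all samples seen in `segments`.
#' @return object of class `sharing_network`: list with `nodes`, `edges`
#'   (data.frame from, to, weight_total_cM, weight_mean_cM, n_segments)
#'   and `min_segment_cM`.
#' @export
build_network <- function(segments, min_segment_cM = 4.0, samples = NULL) {
  nodes <- sort(unique(c(segments$sample1, segments$sample2, samples)))
  seg <- segments[segments$length_cM >= min_segment_cM &
                    segments$sample1 != segments$sample2, , drop = FALSE]
  if (nrow(seg) == 0) {
    edges <- data.frame(from = character(), to = character(),
                        weight_total_cM = numeric(),
                        weight_mean_cM = numeric(),
                        n_segments = integer(), stringsAsFactors = FALSE)
  } else {
    a <- pmin(seg$sample1, seg$sample2)
    b <- pmax(seg$sample1, seg$sample2)
    key <- paste(a, b, sep = "\r")
    tot <- tapply(seg$length_cM, key, sum)
    cnt <- tapply(seg$length_cM, key, length)
    ab <- do.call(rbind, strsplit(names(tot), "\r", fixed = TRUE))
    edges <- data.frame(from = ab[, 1], to = ab[, 2],
                        weight_total_cM = as.numeric(tot),
                        weight_mean_cM = as.numeric(tot) / as.numeric(cnt),
                        n_segments = as.integer(cnt),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges,
                 min_segment_cM = min_segment_cM),
            class = "sharing_network")
}

#' @export
print.sharing_network <- function(x, ...) {
  cat(sprintf("<sharing_network> %d nodes, %d edges (segments >= %g cM)\n",
              length(x$nodes), nrow(x$edges), x$min_segment_cM))
  invisible(x)
}

#' Remove close relatives from a sharing network
#'
#' While any edge carries more than `max_total_cM` of total sharing, the
#' offending edge earliest in (from, to) order is examined and its
#' higher-degree endpoint removed (tie: lexicographically larger id).
#' Deterministic; the returned network contains no edge above threshold.
#'
#' @param network a `sharing_network`.
#' @param max_total_cM relatedness threshold in total shared cM. The
#'   default used in this package is 1400 cM (about second-degree kin on a
#'   3500 cM genome); the appropriate value is data-dependent.
#' @return list with `retained`, `removed` (sample id vectors) and
#'   `network` (the filtered `sharing_network`).
#' @export
filter_relatives <- function(network, max_total_cM = 1400) {
  stopifnot(inherits(network, "sharing_network"))
  if (max_total_cM <= 0) stop("max_total_cM must be positive")
  edges <- network$edges
  active <- network$nodes
  removed <- character()
  repeat {
    keep <- edges$from %in% active & edges$to %in% active
    e <- edges[keep, , drop = FALSE]
    off <- e[e$weight_total_cM > max_total_cM, , drop = FALSE]
    if (nrow(off) == 0) break
    off <- off[order(off$from, off$to), , drop = FALSE][1, ]
    deg <- table(c(e$from, e$to))
    d1 <- as.integer(deg[off$from]); d2 <- as.integer(deg[off$to])
    drop_id <- if (d1 > d2) off$from
               else if (d2 > d1) off$to
               else max(off$from, off$to)
    removed <- c(removed, drop_id)
    active <- setdiff(active, drop_id)
  }
  net <- network
  net$nodes <- active
  net$edges <- edges[edges$from %in% active & edges$to %in% active, ,
                     drop = FALSE]
  rownames(net$edges) <- NULL
  list(retained = active, removed = removed, network = net)
}

#' Recursive Leiden community detection
#'
#' Level 1 partitions the full network with the Leiden algorithm
#' (modularity objective, edge weights = total shared cM). Each community
#' of size >= `min_size` is then re-clustered on its induced subgraph for
#' the next level; smaller communities keep their parent label at deeper
#' levels, so every sample is labeled at every level. Labels are
#' dot-joined paths ("2.1.3"); sibling communities are numbered by
#' decreasing size (ties by smallest member id).
#'
#' @param network a `sharing_network` (must have >= 1 node).
#' @param levels number of recursion levels (default 3).
#' @param resolutions numeric vector, one modularity resolution per level
#'   (default all 1).
#' @param min_size minimum community size to recurse into (default 30).
#' @param seed integer seed (Leiden refinement is stochastic).
#' @return data.frame sample_id, level1, level2, level3, ... (path labels).
#' @export
recursive_leiden <- function(network, levels = 3,
                             resolutions = rep(1, levels),
                             min_size = 30, seed = 1) {
  stopifnot(inherits(network, "sharing_network"))
  if (length(network$nodes) == 0) stop("empty network")
  if (length(resolutions) != levels)
    stop("resolutions must have one value per level")
  if (min_size < 2) stop("min_size must be >= 2")
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to", "weight_total_cM")],
    directed = FALSE, vertices = data.frame(name = network$nodes))
  set.seed(seed)
  labels <- stats::setNames(rep("", length(network$nodes)), network$nodes)
  out <- data.frame(sample_id = network$nodes, stringsAsFactors = FALSE)

  groups <- list(list(vids = network$nodes, path = character(0)))
  for (lev in seq_len(levels)) {
    nxt <- list()
    col <- stats::setNames(rep(NA_character_, length(network$nodes)),
                           network$nodes)
    for (grp in groups) {
      if (lev > 1 && length(grp$vids) < min_size) {
        # too small to subdivide: keep parent path
        col[grp$vids] <- paste(grp$path, collapse = ".")
        nxt[[length(nxt) + 1]] <- grp
        next
      }
      sub <- igraph::induced_subgraph(g, grp$vids)
      memb <- leiden_membership(sub, resolutions[lev])
      for (cid in unique(memb)) {
        vids <- names(memb)[memb == cid]
        path <- c(grp$path, cid)
        col[vids] <- paste(path, collapse = ".")
        nxt[[length(nxt) + 1]] <- list(vids = vids, path = path)
      }
    }
    out[[paste0("level", lev)]] <- unname(col[out$sample_id])
    groups <- nxt
  }
  out
}

# Leiden membership with stable community numbering: communities ordered
# by decreasing size, ties by smallest member id.
leiden_membership <- function(g, resolution) {
  if (igraph::vcount(g) == 1)
    return(stats::setNames("1", igraph::V(g)$name))
  w <- igraph::E(g)$weight_total_cM
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               weights = w, n_iterations = 5)
  memb <- igraph::membership(cl)
  nm <- igraph::V(g)$name
  sizes <- table(memb)
  first <- tapply(nm, memb, min)
  ord <- order(-as.integer(sizes), first)
  relabel <- stats::setNames(as.character(seq_along(ord)),
                             names(sizes)[ord])
  stats::setNames(unname(relabel[as.character(memb)]), nm)
}

#' Top-k edges per node
#'
#' For plotting exports: the union over nodes of each node's `k`
#' highest-mean-length edges (ties broken by higher total weight, then by
#' lexicographic pair id).
#'
#' @param network a `sharing_network`.
#' @param k edges to keep per node (default 10).
#' @return edge data.frame (subset of `network$edges`).
#' @export
top_k_edges <- function(network, k = 10) {
  stopifnot(inherits(network, "sharing_network"), k >= 1)
  edges <- network$edges
  if (nrow(edges) == 0) return(edges)
  keep <- logical(nrow(edges))
  for (v in network$nodes) {
    idx <- which(edges$from == v | edges$to == v)
    if (length(idx) == 0) next
    e <- edges[idx, , drop = FALSE]
    ord <- order(-e$weight_mean_cM, -e$weight_total_cM, e$from, e$to)
    keep[idx[ord[seq_len(min(k, length(idx)))]]] <- TRUE
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
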