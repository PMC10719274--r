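#' Structural connectivity edge weight
#'
#' Weight of the connection between two parcellation regions:
#' fiber count times mean fractional anisotropy along the connecting
#' streamlines, divided by the average volume of the two regions. The volume
#' normalization reduces the bias by which larger cortical regions receive
#' more streamlines.
#'
#' @param fn streamline (fiber) count, >= 0.
#' @param fa mean fractional anisotropy in [0, 1].
#' @param vol_i,vol_j region volumes in mm^3, > 0.
#' @return edge weight (fn * fa) / ((vol_i + vol_j) / 2). Vectorized.
#' @export
edge_weight <- function(fn, fa, vol_i, vol_j) {
  if (any(fn < 0)) stop("fiber count must be nonnegative")
  if (any(fa < 0 | fa > 1)) stop("mean FA must lie in [0, 1]")
  if (any(vol_i <= 0) || any(vol_j <= 0)) stop("region volumes must be positive")
  (fn * fa) / ((vol_i + vol_j) / 2)
}

#' Construct a weighted network container
#'
#' @param weights symmetric nonnegative matrix with zero diagonal.
#' @param nodes optional node table (`node_id`, `label`, `volume_mm3`).
#' @return object of class `weighted_network`.
#' @export
weighted_network <- function(weights, nodes = NULL) {
  .check_weights(weights)
  if (!is.null(nodes)) {
    if (nrow(nodes) != nrow(weights)) stop("node table size must match matrix")
    rownames(weights) <- colnames(weights) <- nodes$label
  }
  structure(list(weights = weights, nodes = nodes), class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  n <- nrow(x$weights)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("weighted_network: %d nodes, %d edges, density %.3f\n",
              n, m, m / (n * (n - 1) / 2)))
  invisible(x)
}

#' Build a subject's weighted connectome from tractography summaries
#'
#' Applies [edge_weight()] to every edge record and assembles the symmetric
#' connectivity matrix. Node pairs without a record get weight zero;
#' disconnected nodes are retained.
#'
#' @param edges data.frame with columns `node_i`, `node_j` (0-based indices,
#'   i != j), `fiber_count`, `mean_fa`. Each unordered pair may appear once.
#' @param nodes data.frame with columns `node_id` (0..n-1), `label`,
#'   `volume_mm3`.
#' @return a [weighted_network()].
#' @export
build_network <- function(edges, nodes) {
  need_e <- c("node_i", "node_j", "fiber_count", "mean_fa")
  if (!all(need_e %in% names(edges))) {
    stop("edge table must have columns ", paste(need_e, collapse = ", "))
  }
  need_n <- c("node_id", "label", "volume_mm3")
  if (!all(need_n %in% names(nodes))) {
    stop("node table must have columns ", paste(need_n, collapse = ", "))
  }
  n <- nrow(nodes)
  if (!setequal(nodes$node_id, 0:(n - 1))) stop("node_id must cover 0..n-1")
  if (anyDuplicated(nodes$label)) stop("node labels must be unique")
  if (any(nodes$volume_mm3 <= 0)) stop("region volumes must be positive")
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]

  W <- matrix(0, n, n)
  if (nrow(edges) > 0) {
    i <- edges$node_i
    j <- edges$node_j
    if (any(i == j)) stop("self-loops are not allowed")
    if (any(i < 0 | i >= n | j < 0 | j >= n)) stop("edge node index out of range")
    canon <- paste(pmin(i, j), pmax(i, j))
    if (anyDuplicated(canon)) {
      stop("duplicate edge pair: ", canon[duplicated(canon)][1])
    }
    w <- edge_weight(edges$fiber_count, edges$mean_fa,
                     nodes$volume_mm3[i + 1], nodes$volume_mm3[j + 1])
    W[cbind(i + 1, j + 1)] <- w
    W[cbind(j + 1, i + 1)] <- w
  }
  weighted_network(W, nodes)
}

#' Packaged AAL-90 node table
#'
#' The 90 cerebral regions (45 per hemisphere) of the Anatomical Automatic
#' Labeling atlas, in the standard left/right-interleaved order. Region
#' volumes are synthetic plausible values (real native-space volumes are
#' subject-specific and not distributed); replace the volume column with
#' measured volumes for real analyses.
#'
#' @return data.frame with `node_id`, `label`, `volume_mm3` (90 rows).
#' @export
aal90_nodes <- function() {
  read_node_table(system.file("extdata", "aal90_nodes_synthetic.tsv",
                              package = "ddtopo"))
}

#' Read a node table TSV
#'
#' @param path TSV with header `node_id`, `label`, `volume_mm3`.
#' @return data.frame.
#' @export
read_node_table <- function(path) {
  nodes <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_id", "label", "volume_mm3")
  if (!all(need %in% names(nodes))) {
    stop("node table ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  nodes
}

#' Read a tractography edge list TSV
#'
#' @param path TSV with header `node_i`, `node_j`, `fiber_count`, `mean_fa`
#'   (0-based node indices).
#' @return data.frame.
#' @export
read_edge_list <- function(path) {
  edges <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("node_i", "node_j", "fiber_count", "mean_fa")
  if (!all(need %in% names(edges))) {
    stop("edge list ", path, " must have columns ",
         paste(need, collapse = ", "))
  }
  edges
}

#' Read a dense connectivity matrix CSV (no header)
#'
#' @param path CSV of n rows x n columns.
#' @param nodes optional node table attached to the result.
#' @return a [weighted_network()].
#' @export
read_network_matrix <- function(path, nodes = NULL) {
  W <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(W) <- NULL
  weighted_network(W, nodes)
}

#' Write a dense connectivity matrix CSV (no header)
#'
#' @param network a [weighted_network()] or matrix.
#' @param path output path.
#' @export
write_network_matrix <- function(network, path) {
  W <- .as_weights(network)
  utils::write.table(W, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}
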