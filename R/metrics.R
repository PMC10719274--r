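# Weighted graph metrics for structural connectomes.
#
# Convention throughout: connectivity weights measure coupling strength, so
# the topological distance along an edge is the reciprocal weight
# (d_ij = 1 / W_ij); stronger connections are shorter. Shortest paths,
# betweenness and efficiencies all use that map.

# internal: igraph view of a weight matrix (undirected, 'weight' attribute)
.as_graph <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Map connection weights to topological distances
#'
#' d_ij = 1 / W_ij for present edges, Inf for absent ones, 0 on the diagonal.
#'
#' @param network [weighted_network()] or weight matrix.
#' @return distance matrix (edge lengths, not shortest paths).
#' @export
weight_to_distance <- function(network) {
  W <- .as_weights(network)
  .check_weights(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  D
}

# internal: all-pairs shortest-path matrix under d = 1/W
.shortest_paths <- function(W) {
  g <- .as_graph(W)
  if (igraph::ecount(g) == 0) {
    D <- matrix(Inf, nrow(W), nrow(W))
    diag(D) <- 0
    return(D)
  }
  igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                    algorithm = "dijkstra")
}

#' Weighted clustering coefficient
#'
#' Onnela-type per-node clustering: geometric mean of the weights of each
#' triangle around a node, on weights rescaled by the network-wide maximum,
#' divided by the number of possible neighbor pairs (binary degree). Values
#' lie in [0, 1]; nodes with fewer than two neighbors get 0. For a
#' unit-weight network this reduces to the binary clustering coefficient.
#'
#' @param network [weighted_network()] or weight matrix.
#' @return list with `Cp` (mean over all nodes) and `nodal` values.
#' @export
clustering_coefficient <- function(network) {
  W <- .as_weights(network)
  .check_weights(W)
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(list(Cp = 0, nodal = numeric(n)))
  S <- (W / mx)^(1 / 3)
  tri <- diag(S %*% S %*% S)       # 2 x sum of cube-root triangle products
  kbin <- rowSums(W > 0)
  nodal <- ifelse(kbin >= 2, tri / (kbin * (kbin - 1)), 0)
  list(Cp = mean(nodal), nodal = nodal)
}

#' Characteristic path length
#'
#' Mean shortest-path distance (under d = 1/W) over all pairs of distinct
#' nodes with a finite path. The number of unreachable (unordered) pairs is
#' reported alongside so disconnection is never silent.
#'
#' @param network [weighted_network()] or weight matrix.
#' @return list with `Lp` and `n_unreachable` (unordered pairs).
#' @export
characteristic_path_length <- function(network) {
  W <- .as_weights(network)
  D <- .shortest_paths(W)
  off <- upper.tri(D)
  finite <- is.finite(D[off])
  if (!any(finite)) stop("no finite paths: network has no edges")
  list(Lp = mean(D[off][finite]), n_unreachable = sum(!finite))
}

#' Global efficiency
#'
#' Mean of the reciprocal shortest-path distances over all ordered pairs of
#' distinct nodes (1/Inf = 0), i.e. the harmonic-mean-based integration
#' measure that remains defined for disconnected networks.
#'
#' @param network [weighted_network()] or weight matrix.
#' @return scalar efficiency.
#' @export
global_efficiency <- function(network) {
  W <- .as_weights(network)
  n <- nrow(W)
  if (n < 2) stop("global efficiency needs at least 2 nodes")
  D <- .shortest_paths(W)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Local efficiency
#'
#' Nodal local efficiency is the global efficiency of the subgraph induced
#' on a node's neighbors (weights retained) — the fault-tolerance of the
#' network around that node. Nodes with fewer than two neighbors get 0. The
#' global value is the mean over nodes.
#'
#' @param network [weighted_network()] or weight matrix.
#' @return list with `Eloc` (mean) and `nodal` values.
#' @export
local_efficiency <- function(network) {
  W <- .as_weights(network)
  .check_weights(W)
  n <- nrow(W)
  nodal <- vapply(seq_len(n), function(i) {
    nb <- which(W[i, ] > 0)
    if (length(nb) < 2) return(0)
    global_efficiency(W[nb, nb, drop = FALSE])
  }, numeric(1))
  list(Eloc = mean(nodal), nodal = nodal)
}

#' Degree centrality
#'
#' Strength mode sums each node's connection weights; binary mode counts its
#' connections.
#'
#' @param network [weighted_network()] or weight matrix.
#' @param mode "strength" (default) or "binary".
#' @return numeric vector of per-node centralities.
#' @export
degree_centrality <- function(network, mode = c("strength", "binary")) {
  mode <- match.arg(mode)
  W <- .as_weights(network)
  .check_weights(W)
  if (mode == "strength") rowSums(W) else rowSums(W > 0)
}

#' Betweenness centrality
#'
#' Fraction of shortest paths (under d = 1/W) passing through each node,
#' with ties over equally short paths shared fractionally and endpoints
#' excluded (Brandes' algorithm). Each unordered pair contributes once.
#'
#' @param network [weighted_network()] or weight matrix.
#' @return numeric vector of per-node betweenness values.
#' @export
betweenness_centrality <- function(network) {
  W <- .as_weights(network)
  .check_weights(W)
  g <- .as_graph(W)
  if (igraph::ecount(g) == 0) return(numeric(nrow(W)))
  igraph::betweenness(g, directed = FALSE,
                      weights = 1 / igraph::E(g)$weight)
}

#' Mean-normalize nodal values
#'
#' Divides each nodal value by the mean over nodes, so the normalized vector
#' has mean 1 and values are comparable across subjects.
#'
#' @param values numeric vector with at least one positive entry.
#' @return normalized vector.
#' @export
normalize_nodal <- function(values) {
  if (!any(values > 0)) stop("cannot normalize an all-zero nodal vector")
  values / mean(values)
}

#' Identify hub nodes
#'
#' Hubs are nodes whose centrality exceeds the across-node mean by more than
#' one (sample, n-1 denominator) standard deviation.
#'
#' @param values numeric vector of nodal centralities (length >= 2).
#' @return integer vector of hub indices (possibly empty).
#' @export
identify_hubs <- function(values) {
  if (length(values) < 2) stop("need at least 2 nodes")
  which(values > mean(values) + stats::sd(values))
}

#' Generate a degree-matched null ensemble
#'
#' Each null network is produced by degree-preserving double-edge-swap
#' rewiring of the binary topology (default 10 attempted swaps per edge),
#' after which the original weight multiset is randomly reassigned to the
#' rewired edges. Degree sequences and the weight multiset are exactly
#' preserved. On a complete graph no legal swap exists, so nulls keep the
#' source topology (a warning is emitted).
#'
#' @param network [weighted_network()] or weight matrix with >= 2 edges.
#' @param n_nulls ensemble size (default 100).
#' @param seed integer seed for reproducibility.
#' @param rewires_per_edge attempted swaps per edge (default 10).
#' @return object of class `null_ensemble`: list with `networks` (list of
#'   weight matrices), `seed`, `rewires_per_edge`.
#' @export
generate_matched_nulls <- function(network, n_nulls = 100, seed = NULL,
                                   rewires_per_edge = 10) {
  W <- .as_weights(network)
  .check_weights(W)
  g <- .as_graph(W)
  m <- igraph::ecount(g)
  n <- nrow(W)
  if (m < 2) stop("need at least 2 edges to rewire")
  if (n_nulls < 1) stop("n_nulls must be >= 1")
  if (m == n * (n - 1) / 2) {
    warning("complete graph: no legal degree-preserving swap; ",
            "null networks keep the source topology")
  }
  if (!is.null(seed)) set.seed(seed)
  w <- igraph::E(g)$weight
  networks <- vector("list", n_nulls)
  for (b in seq_len(n_nulls)) {
    gr <- igraph::rewire(
      g, igraph::keeping_degseq(loops = FALSE, niter = rewires_per_edge * m))
    el <- igraph::as_edgelist(gr, names = FALSE)
    ws <- sample(w)
    Wb <- matrix(0, n, n)
    Wb[el] <- ws
    Wb[el[, c(2, 1), drop = FALSE]] <- ws
    networks[[b]] <- Wb
  }
  structure(list(networks = networks, seed = seed,
                 rewires_per_edge = rewires_per_edge),
            class = "null_ensemble")
}

#' Small-worldness via null-ensemble normalization
#'
#' gamma = Cp / mean(Cp over nulls), lambda = Lp / mean(Lp over nulls),
#' sigma = gamma / lambda. A small-world network satisfies gamma > 1,
#' lambda ~ 1, sigma > 1.
#'
#' @param network [weighted_network()] or weight matrix.
#' @param ensemble a `null_ensemble` or plain list of weight matrices.
#' @return list with `gamma`, `lambda`, `sigma`, `Cp`, `Lp`, `Cp_rand`,
#'   `Lp_rand`.
#' @export
small_worldness <- function(network, ensemble) {
  W <- .as_weights(network)
  nulls <- if (inherits(ensemble, "null_ensemble")) ensemble$networks
           else ensemble
  if (length(nulls) == 0) stop("null ensemble is empty")
  cp <- clustering_coefficient(W)$Cp
  lp <- characteristic_path_length(W)$Lp
  cp_rand <- mean(vapply(nulls, function(x) clustering_coefficient(x)$Cp,
                         numeric(1)))
  lp_rand <- mean(vapply(nulls, function(x) characteristic_path_length(x)$Lp,
                         numeric(1)))
  if (cp_rand <= 0 || lp_rand <= 0) stop("null ensemble means must be positive")
  gamma <- cp / cp_rand
  lambda <- lp / lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       Cp = cp, Lp = lp, Cp_rand = cp_rand, Lp_rand = lp_rand)
}

#' Full topology report for one subject's network
#'
#' Computes the global metrics (Cp, Lp, gamma, lambda, sigma, global and
#' local efficiency) with null-ensemble normalization, plus nodal degree and
#' betweenness centrality, their mean-normalized variants, and hub flags
#' (> mean + 1 SD on the normalized values).
#'
#' @param network [weighted_network()] or weight matrix.
#' @param subject_id identifier copied into the output rows.
#' @param n_nulls,seed,rewires_per_edge passed to [generate_matched_nulls()].
#' @param degree_mode "strength" or "binary" (see [degree_centrality()]).
#' @return list with data.frames `global` (one row) and `nodal` (one row per
#'   node).
#' @export
topology_report <- function(network, subject_id = "subject",
                            n_nulls = 100, seed = NULL,
                            rewires_per_edge = 10,
                            degree_mode = c("strength", "binary")) {
  degree_mode <- match.arg(degree_mode)
  W <- .as_weights(network)
  labels <- if (inherits(network, "weighted_network") &&
                !is.null(network$nodes)) network$nodes$label
            else sprintf("node%03d", seq_len(nrow(W)) - 1)

  ens <- generate_matched_nulls(W, n_nulls = n_nulls, seed = seed,
                                rewires_per_edge = rewires_per_edge)
  sw <- small_worldness(W, ens)
  lp <- characteristic_path_length(W)
  eglob <- global_efficiency(W)
  eloc <- local_efficiency(W)

  deg <- degree_centrality(W, mode = degree_mode)
  btw <- betweenness_centrality(W)
  deg_norm <- normalize_nodal(deg)
  btw_norm <- if (any(btw > 0)) normalize_nodal(btw) else btw
  hubs_d <- identify_hubs(deg_norm)
  hubs_b <- identify_hubs(btw_norm)

  global <- data.frame(
    subject_id = subject_id, Cp = sw$Cp, Lp = sw$Lp,
    gamma = sw$gamma, lambda = sw$lambda, sigma = sw$sigma,
    Eglob = eglob, Eloc = eloc$Eloc,
    n_unreachable_pairs = lp$n_unreachable,
    stringsAsFactors = FALSE)
  nodal <- data.frame(
    subject_id = subject_id, node_id = seq_along(labels) - 1L,
    label = labels, degree = deg, degree_norm = deg_norm,
    betweenness = btw, betweenness_norm = btw_norm,
    is_hub_degree = seq_along(labels) %in% hubs_d,
    is_hub_betweenness = seq_along(labels) %in% hubs_b,
    stringsAsFactors = FALSE)
  list(global = global, nodal = nodal)
}
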