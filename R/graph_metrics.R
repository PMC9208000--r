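# Endogenous network measures on weighted, nonnegative, zero-diagonal
# adjacency matrices, and their conversion to dyad-level model covariates.

.check_adjacency <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("adjacency matrix must be square")
  if (max(abs(W - t(W))) > 1e-10) stop("adjacency matrix must be symmetric")
  if (any(W < 0)) stop("adjacency matrix must be nonnegative")
  if (any(diag(W) != 0)) stop("adjacency matrix must have a zero diagonal")
  W
}

#' Node degree of a weighted network
#'
#' Degree is the count of nonzero edges incident to each node (not the sum of
#' weights), the classical basis for degree-difference "assortativity"
#' covariates.
#'
#' @param W Symmetric nonnegative P x P matrix with zero diagonal.
#' @return Integer vector of length P.
#' @export
node_degree <- function(W) {
  W <- .check_adjacency(W)
  as.integer(rowSums(W > 0))
}

#' Weighted clustering coefficient (geometric-mean form)
#'
#' Onnela-type weighted clustering: with weights rescaled by the network
#' maximum, `C_i = sum_{j,h} (w_ij w_ih w_jh)^(1/3) / (k_i (k_i - 1))`.
#' Nodes with degree < 2 have `C_i = 0`.
#'
#' @inheritParams node_degree
#' @return Numeric vector in `[0, 1]`.
#' @export
node_clustering <- function(W) {
  W <- .check_adjacency(W)
  mx <- max(W)
  if (mx == 0) return(rep(0, nrow(W)))
  Wh <- (W / mx)^(1 / 3)
  k <- as.numeric(node_degree(W))
  num <- diag(Wh %*% Wh %*% Wh)  # 2 x (weighted triangle intensity)
  denom <- k * (k - 1)
  C <- ifelse(denom > 0, num / denom, 0)
  pmin(pmax(C, 0), 1)
}

#' Nodal and global efficiency
#'
#' Shortest paths use edge length `1/w` (zero weight = absent edge). Nodal
#' efficiency is the mean inverse shortest-path distance to all other nodes
#' (`1/Inf = 0` for unreachable pairs); global efficiency is the mean nodal
#' efficiency.
#'
#' @inheritParams node_degree
#' @return List with `nodal` (length-P vector) and `global` (scalar).
#' @export
node_efficiency <- function(W) {
  W <- .check_adjacency(W)
  P <- nrow(W)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    return(list(nodal = rep(0, P), global = 0))
  }
  D <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / D
  diag(inv) <- 0
  nodal <- rowSums(inv) / (P - 1)
  list(nodal = as.numeric(nodal), global = mean(nodal))
}

#' Leverage centrality
#'
#' A node's mean normalized degree contrast with its neighbors:
#' `l_i = mean_{j in N(i)} (k_i - k_j) / (k_i + k_j)`, with `l_i = 0` for
#' isolated nodes (the formula is undefined at degree 0).
#'
#' @inheritParams node_degree
#' @return Numeric vector in `[-1, 1]`.
#' @export
leverage_centrality <- function(W) {
  W <- .check_adjacency(W)
  k <- as.numeric(node_degree(W))
  P <- nrow(W)
  l <- numeric(P)
  A <- W > 0
  for (i in seq_len(P)) {
    if (k[i] == 0) next
    nb <- which(A[i, ])
    l[i] <- mean((k[i] - k[nb]) / (k[i] + k[nb]))
  }
  l
}

#' Weighted modularity via seeded Louvain community detection
#'
#' Finds a partition by Louvain-type greedy modularity maximization (seeded
#' for reproducibility) and returns the weighted Newman modularity
#' `Q = sum_c (e_cc - a_c^2)` of that partition.
#'
#' @inheritParams node_degree
#' @param seed Integer seed controlling the community-detection randomness.
#' @return List with `Q` (scalar) and `membership` (integer vector).
#' @export
modularity_weighted <- function(W, seed = 1L) {
  W <- .check_adjacency(W)
  if (sum(W) == 0) stop("graph has zero total weight; modularity undefined")
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comm <- withr::with_seed(as.integer(seed),
                           igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  memb <- igraph::membership(comm)
  Q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
  list(Q = as.numeric(Q), membership = as.integer(memb))
}

#' Recompute Newman modularity for a given partition
#'
#' Direct evaluation of `Q = sum_c (e_cc - a_c^2)` from the weight matrix and
#' a membership vector, independent of any community-detection machinery.
#'
#' @inheritParams node_degree
#' @param membership Integer community labels, length P.
#' @return Scalar Q.
#' @export
modularity_from_partition <- function(W, membership) {
  W <- .check_adjacency(W)
  m2 <- sum(W)  # total weight counted twice (both triangle halves)
  if (m2 == 0) stop("graph has zero total weight")
  comms <- unique(membership)
  Q <- 0
  strength <- rowSums(W)
  for (cc in comms) {
    idx <- membership == cc
    e_cc <- sum(W[idx, idx]) / m2
    a_c <- sum(strength[idx]) / m2
    Q <- Q + (e_cc - a_c^2)
  }
  Q
}

#' Per-window node and global metrics for a set of dynamic networks
#'
#' @param nets_list List of `dyn_nets` objects (one per participant) with
#'   nonnegative weights.
#' @param seed Seed forwarded to [modularity_weighted()]; each
#'   (participant, window) uses a deterministic sub-seed.
#' @return List with `nodes` — data.frame keyed (participant, window, node)
#'   holding degree `k`, clustering `C`, nodal efficiency `E`, leverage `l` —
#'   and `globals` — data.frame keyed (participant, window) holding `Q` and
#'   `Eglob`.
#' @export
node_metric_table <- function(nets_list, seed = 1L) {
  if (inherits(nets_list, "dyn_nets")) nets_list <- list(nets_list)
  nodes <- list(); globals <- list(); idx <- 1L
  for (nets in nets_list) {
    P <- length(nets$node_labels)
    for (w in seq_along(nets$windows)) {
      W <- nets$windows[[w]]
      k <- node_degree(W)
      C <- node_clustering(W)
      eff <- node_efficiency(W)
      l <- leverage_centrality(W)
      Q <- if (sum(W) > 0) {
        modularity_weighted(W, seed = .sub_seed(seed, idx))$Q
      } else 0
      nodes[[idx]] <- data.frame(
        participant = nets$participant_id, window = w,
        node = nets$node_labels, k = k, C = C, E = eff$nodal, l = l,
        stringsAsFactors = FALSE)
      globals[[idx]] <- data.frame(
        participant = nets$participant_id, window = w,
        Q = Q, Eglob = eff$global, stringsAsFactors = FALSE)
      idx <- idx + 1L
    }
  }
  list(nodes = do.call(rbind, nodes), globals = do.call(rbind, globals))
}

# deterministic sub-seed below 2^31
.sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 69621) %% 2147483587) + 1L
}

#' Dyad-level covariates from node metrics and coordinates
#'
#' For every unordered node pair (j < k): means of clustering, nodal
#' efficiency and leverage; absolute degree difference; the window modularity;
#' and Euclidean inter-node distance (mm) with its square.
#'
#' @param metrics Output of [node_metric_table()].
#' @param coords Data frame with columns `node`, `x`, `y`, `z` (mm), one row
#'   per node label appearing in `metrics$nodes`.
#' @return Data frame keyed (participant, window, node_j, node_k) with columns
#'   `C_avg`, `E_avg`, `l_avg`, `k_diff`, `Q`, `dist`, `dist2`.
#' @export
dyad_covariates <- function(metrics, coords) {
  nodes <- metrics$nodes
  globals <- metrics$globals
  labels <- unique(nodes$node)
  missing_nodes <- setdiff(labels, coords$node)
  if (length(missing_nodes))
    stop("missing coordinates for node(s): ",
         paste(missing_nodes, collapse = ", "))
  xyz <- as.matrix(coords[match(labels, coords$node), c("x", "y", "z")])
  rownames(xyz) <- labels
  P <- length(labels)
  pair <- which(upper.tri(matrix(0, P, P)), arr.ind = TRUE)  # j < k
  dvec <- sqrt(rowSums((xyz[pair[, 1L], , drop = FALSE] -
                          xyz[pair[, 2L], , drop = FALSE])^2))
  out <- list(); idx <- 1L
  keys <- unique(nodes[, c("participant", "window")])
  for (r in seq_len(nrow(keys))) {
    sel <- nodes$participant == keys$participant[r] &
      nodes$window == keys$window[r]
    nm <- nodes[sel, ]
    nm <- nm[match(labels, nm$node), ]
    Qw <- globals$Q[globals$participant == keys$participant[r] &
                      globals$window == keys$window[r]]
    out[[idx]] <- data.frame(
      participant = keys$participant[r], window = keys$window[r],
      node_j = labels[pair[, 1L]], node_k = labels[pair[, 2L]],
      C_avg = (nm$C[pair[, 1L]] + nm$C[pair[, 2L]]) / 2,
      E_avg = (nm$E[pair[, 1L]] + nm$E[pair[, 2L]]) / 2,
      l_avg = (nm$l[pair[, 1L]] + nm$l[pair[, 2L]]) / 2,
      k_diff = abs(nm$k[pair[, 1L]] - nm$k[pair[, 2L]]),
      Q = Qw, dist = dvec, dist2 = dvec^2,
      stringsAsFactors = FALSE)
    idx <- idx + 1L
  }
  do.call(rbind, out)
}

#' Number of dyads in a P-node network
#'
#' @param P Number of nodes.
#' @return `P (P - 1) / 2`.
#' @export
dyad_count <- function(P) {
  P <- as.integer(P)
  (P * (P - 1L)) %/% 2L
}
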