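#' Euler-Mascheroni constant used in the random-graph path-length estimate
#' @keywords internal
EULER_GAMMA <- 0.5772156649

adjacency_of <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  A <- graph$binary
  storage.mode(A) <- "double"
  A
}

# all-pairs BFS hop distances; Inf for unreachable pairs, 0 on the diagonal
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (n == 0) return(D)
  adj <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  for (s in seq_len(n)) {
    frontier <- s
    d <- 0L
    visited <- logical(n)
    visited[s] <- TRUE
    while (length(frontier)) {
      d <- d + 1L
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[!visited[nxt]]
      if (!length(nxt)) break
      visited[nxt] <- TRUE
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

#' Nodal degree, mean degree, and network density
#'
#' Degree `K_i` is the number of edges incident to node i (the row sum of
#' the binary adjacency matrix); the network degree `K` is the mean over
#' nodes, and density is the fraction of realized edges among the
#' `N (N - 1) / 2` possible, so `density = K / (N - 1)` identically.
#'
#' @param graph A `network_graph`.
#' @return List: `K_i` (per node), `K` (mean), `density`.
#' @export
degree_and_density <- function(graph) {
  A <- adjacency_of(graph)
  n <- nrow(A)
  K_i <- rowSums(A)
  K <- mean(K_i)
  density <- if (n > 1) sum(A) / (n * (n - 1)) else 0
  list(K_i = K_i, K = K, density = density)
}

#' Nodal and mean connection strength
#'
#' Strength `S_i` is the sum of a node's connection weights, i.e. the sum of
#' partial correlations over its valid edges; the network value is the mean
#' over nodes.
#'
#' @param graph A `network_graph`.
#' @return List: `S_i` (per node), `S` (mean).
#' @export
strength <- function(graph) {
  stopifnot(inherits(graph, "network_graph"))
  S_i <- rowSums(graph$weights)
  list(S_i = S_i, S = mean(S_i))
}

#' Nodal and mean clustering coefficient
#'
#' `C_i` is the number of existing connections among node i's neighbours
#' divided by all their possible connections `K_i (K_i - 1) / 2`; nodes with
#' fewer than two neighbours get `C_i = 0` by convention (avoiding 0/0).
#' The network coefficient is the mean over all nodes.
#'
#' @param graph A `network_graph`.
#' @return List: `C_i` (per node), `C` (mean),
#'   `neighbor_edge_count` (per node).
#' @export
clustering <- function(graph) {
  A <- adjacency_of(graph)
  n <- nrow(A)
  K_i <- rowSums(A)
  # diag(A %*% A %*% A) counts closed triangles through each node, twice
  tri2 <- diag(A %*% A %*% A)
  neighbor_edges <- tri2 / 2
  C_i <- ifelse(K_i >= 2, neighbor_edges / (K_i * (K_i - 1) / 2), 0)
  list(C_i = C_i, C = mean(C_i), neighbor_edge_count = neighbor_edges)
}

#' Nodal and mean local efficiency
#'
#' Local efficiency of node i measures how efficiently its first neighbours
#' communicate once i itself is removed:
#' `Eloc_i = (1 / (K_i (K_i - 1))) * sum over ordered neighbour pairs of
#' 1 / d_jh(G_i)`, with distances computed inside the neighbour-induced
#' subgraph `G_i` (node i excluded) and `1 / Inf = 0`. Nodes with fewer than
#' two neighbours get 0.
#'
#' @param graph A `network_graph`.
#' @return List: `Eloc_i` (per node), `Eloc` (mean).
#' @export
local_efficiency <- function(graph) {
  A <- adjacency_of(graph)
  n <- nrow(A)
  Eloc_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    sub <- A[nb, nb, drop = FALSE]
    D <- bfs_distances(sub)
    inv <- 1 / D
    diag(inv) <- 0
    Eloc_i[i] <- sum(inv) / (k * (k - 1))
  }
  list(Eloc_i = Eloc_i, Eloc = mean(Eloc_i))
}

#' Nodal mean path length, network path length, and global efficiency
#'
#' `L_i` is the mean over reachable peers of the smallest number of edges
#' that must be traversed from node i; unreachable pairs are excluded from
#' the average rather than imputed, and a node with no reachable peer has
#' `L_i = NA` and is excluded from the network mean `L`. Global efficiency —
#' the disconnection-robust companion — is the mean over all ordered pairs
#' of inverse distances, with `1 / Inf = 0`.
#'
#' @param graph A `network_graph`.
#' @return List: `L_i` (per node, `NA` for isolated nodes), `L` (mean over
#'   non-missing nodes), `global_efficiency`.
#' @export
path_lengths <- function(graph) {
  A <- adjacency_of(graph)
  n <- nrow(A)
  D <- bfs_distances(A)
  L_i <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  inv <- 1 / D
  diag(inv) <- 0
  geff <- if (n > 1) sum(inv) / (n * (n - 1)) else 0
  list(L_i = L_i, L = if (all(is.na(L_i))) NA_real_ else mean(L_i,
                                                              na.rm = TRUE),
       global_efficiency = geff)
}

#' Nodal and mean betweenness centrality
#'
#' `b_i` counts, over unordered pairs `(h, j)` with both endpoints different
#' from i, the fraction of shortest h-j paths that pass through i
#' (unnormalized counts). Computed with Brandes' dependency-accumulation
#' algorithm.
#'
#' @param graph A `network_graph`.
#' @return List: `b_i` (per node), `b` (mean).
#' @export
betweenness <- function(graph) {
  A <- adjacency_of(graph)
  n <- nrow(A)
  bc <- numeric(n)
  adj <- lapply(seq_len(n), function(i) which(A[i, ] != 0))
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    head <- 1L
    while (head <= length(queue)) {
      v <- queue[head]; head <- head + 1L
      order_visited <- c(order_visited, v)
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  b_i <- bc / 2 # each unordered pair was counted from both endpoints
  list(b_i = b_i, b = mean(b_i))
}

#' Small-world normalization ratios
#'
#' Normalizes observed mean clustering and path length against analytic
#' estimates for a random graph with the same number of nodes `N` and mean
#' degree `K`: `C_rand = K / N` and
#' `L_rand = ((ln N - gamma) / ln K) + 0.5` with `gamma` the
#' Euler-Mascheroni constant (0.5772156649). Small-world topology shows a
#' clustering ratio well above 1 with a path-length ratio near 1.
#'
#' @param C Observed mean clustering coefficient.
#' @param L Observed mean path length.
#' @param K Observed mean degree; must exceed 1 (`ln K > 0`).
#' @param N Number of nodes.
#' @return List: `C_rand`, `L_rand`, `swn_clustering_ratio` (`C / C_rand`),
#'   `swn_path_ratio` (`L / L_rand`).
#' @examples
#' small_world(C = 0.29, L = 1.97, K = 4.84, N = 21)
#' @export
small_world <- function(C, L, K, N) {
  stopifnot(is.numeric(C), is.numeric(L), is.numeric(K), is.numeric(N))
  if (K <= 1) {
    stop("mean degree K must exceed 1 for the random-graph estimates",
         call. = FALSE)
  }
  C_rand <- K / N
  L_rand <- (log(N) - EULER_GAMMA) / log(K) + 0.5
  list(C_rand = C_rand, L_rand = L_rand,
       swn_clustering_ratio = C / C_rand,
       swn_path_ratio = L / L_rand)
}

#' All nodal and network metrics of a thresholded graph
#'
#' One-stop computation of every graph-theoretical measure of the analysis:
#' degree, strength, clustering, local efficiency, path length, betweenness
#' per node, and their network means plus density, global efficiency and
#' the small-world ratios. Small-world ratios are `NA` when mean degree is
#' `<= 1` (the analytic random-graph estimate is undefined there).
#'
#' @param graph A `network_graph`.
#' @return List with `nodal` (data frame, one row per node) and `network`
#'   (one-row data frame).
#' @export
graph_metrics <- function(graph) {
  deg <- degree_and_density(graph)
  str_ <- strength(graph)
  clu <- clustering(graph)
  eff <- local_efficiency(graph)
  pl <- path_lengths(graph)
  btw <- betweenness(graph)
  n <- length(graph$nodes)
  nodal <- data.frame(
    node = graph$nodes,
    degree = deg$K_i,
    strength = str_$S_i,
    cluster_coef = clu$C_i,
    local_efficiency = eff$Eloc_i,
    path_length = pl$L_i,
    betweenness = btw$b_i,
    stringsAsFactors = FALSE, row.names = NULL)
  swn <- if (deg$K > 1 && !is.na(pl$L)) {
    small_world(clu$C, pl$L, deg$K, n)
  } else {
    list(swn_clustering_ratio = NA_real_, swn_path_ratio = NA_real_)
  }
  network <- data.frame(
    n_nodes = n,
    n_edges = edge_count(graph),
    degree = deg$K,
    density = deg$density,
    strength = str_$S,
    cluster_coef = clu$C,
    local_efficiency = eff$Eloc,
    global_efficiency = pl$global_efficiency,
    path_length = pl$L,
    betweenness = btw$b,
    swn_cluster_coef = swn$swn_clustering_ratio,
    swn_path_length = swn$swn_path_ratio)
  list(nodal = nodal, network = network)
}
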