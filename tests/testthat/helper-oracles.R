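# Brute-force graph oracles: slow, independent re-implementations used to
# verify the package's metric code on small graphs.

rand_adj <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(stats::runif(length(up)) < p)
  A + t(A)
}

# random connected graph: spanning tree plus extra random edges
rand_connected_adj <- function(n, extra = n) {
  A <- matrix(0, n, n)
  for (v in 2:n) {
    u <- sample(seq_len(v - 1), 1)
    A[u, v] <- A[v, u] <- 1
  }
  up <- which(upper.tri(A) & A == 0)
  add <- sample(up, min(extra, length(up)))
  A[add] <- 1
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

# Floyd-Warshall all-pairs hop distances
bf_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[A == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

bf_clustering <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    e <- sum(A[nb, nb]) / 2
    e / (k * (k - 1) / 2)
  }, numeric(1))
}

bf_local_efficiency <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    D <- bf_distances(A[nb, nb, drop = FALSE])
    inv <- 1 / D
    diag(inv) <- 0
    sum(inv) / (k * (k - 1))
  }, numeric(1))
}

bf_path_lengths <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
}

# exhaustive shortest-path enumeration betweenness (unordered pairs)
bf_betweenness <- function(A) {
  n <- nrow(A)
  D <- bf_distances(A)
  b <- numeric(n)
  for (h in seq_len(n - 1)) {
    for (j in seq(h + 1, n)) {
      if (!is.finite(D[h, j]) || D[h, j] == 0) next
      paths <- list()
      walk <- function(v, path) {
        if (v == j) {
          paths[[length(paths) + 1]] <<- path
          return(invisible())
        }
        for (w in which(A[v, ] == 1)) {
          if (is.finite(D[w, j]) && D[v, j] == D[w, j] + 1) {
            walk(w, c(path, w))
          }
        }
      }
      walk(h, h)
      sigma <- length(paths)
      for (pth in paths) {
        interior <- pth[-c(1, length(pth))]
        for (v in interior) b[v] <- b[v] + 1 / sigma
      }
    }
  }
  b
}

# residual-regression definition of the partial correlation of rows i and j
bf_partial_cor_residual <- function(x, i, j) {
  others <- setdiff(seq_len(nrow(x)), c(i, j))
  ri <- if (length(others)) {
    stats::lm.fit(cbind(1, t(x[others, , drop = FALSE])), x[i, ])$residuals
  } else {
    x[i, ] - mean(x[i, ])
  }
  rj <- if (length(others)) {
    stats::lm.fit(cbind(1, t(x[others, , drop = FALSE])), x[j, ])$residuals
  } else {
    x[j, ] - mean(x[j, ])
  }
  stats::cor(ri, rj)
}

# sample a zero-mean MVN data matrix (nodes x scans) with covariance Sigma
mvn_series <- function(Sigma, n_scans) {
  L <- t(chol(Sigma))
  L %*% matrix(stats::rnorm(nrow(Sigma) * n_scans), nrow(Sigma), n_scans)
}

# balanced split-plot records data frame
make_records <- function(values, n_per_group) {
  grid <- expand.grid(subject = seq_len(2 * n_per_group),
                      condition = c("AP", "IP"))
  grid$subject_id <- sprintf("s%02d", grid$subject)
  grid$group <- ifelse(grid$subject <= n_per_group, "old", "young")
  data.frame(subject_id = grid$subject_id, group = grid$group,
             condition = as.character(grid$condition), value = values,
             stringsAsFactors = FALSE)
}

graph_from_adj <- function(A, weights = NULL) {
  network_graph(A, weights = weights)
}

tmp_node_table <- function(hemispheres, id = "TT") {
  df <- data.frame(
    network_id = id, figure_index = seq_along(hemispheres),
    label = sprintf("Region %d", seq_along(hemispheres)), brodmann = "1",
    hemisphere = hemispheres, x = seq_along(hemispheres), y = 0L, z = 0L,
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  load_node_table(path)
}
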