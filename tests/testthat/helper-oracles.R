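# Independent brute-force oracles used to check the package's
# implementations on tiny instances. Deliberately naive.

# all-pairs shortest paths by Floyd-Warshall on a binary adjacency matrix
oracle_mean_path <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  mean(d[row(d) != col(d)])
}

# Newman modularity recomputed straight from the adjacency matrix
oracle_modularity <- function(adj, labels) {
  m <- sum(adj) / 2
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj)))
    for (j in seq_len(nrow(adj)))
      if (labels[i] == labels[j])
        q <- q + adj[i, j] - deg[i] * deg[j] / (2 * m)
  q / (2 * m)
}

# enumerate all set partitions of 1..n with at most max_blocks blocks
# (restricted growth strings), returning the maximum modularity
oracle_best_modularity <- function(adj, max_blocks = 4L) {
  n <- nrow(adj)
  best <- -Inf
  rgs <- function(prefix, mx) {
    k <- length(prefix)
    if (k == n) {
      best <<- max(best, oracle_modularity(adj, prefix))
      return(invisible())
    }
    for (v in seq_len(min(mx + 1L, max_blocks)))
      rgs(c(prefix, v), max(mx, v))
    invisible()
  }
  rgs(integer(0), 0L)
  best
}

# spectral-sum pseudoinverse: sum_{k: lambda_k > 0} u_k u_k^T / lambda_k
oracle_pinv <- function(m) {
  e <- eigen(as.matrix(m), symmetric = TRUE)
  keep <- e$values > 1e-9 * max(e$values)
  v <- e$vectors[, keep, drop = FALSE]
  v %*% diag(1 / e$values[keep], nrow = sum(keep)) %*% t(v)
}

# binary adjacency matrix of a contact network
net_adjacency <- function(net) {
  a <- matrix(0, net$n_nodes, net$n_nodes)
  a[net$edges] <- 1
  a + t(a)
}

# random connected geometric point cloud (retries until connected)
random_connected_chain <- function(n, r_cut = 9, seed = 1) {
  for (k in 0:50) {
    pts <- critnet:::with_seed(seed + k,
                               matrix(stats::runif(3 * n, 0, n^(1 / 3) * 4), ncol = 3))
    ch <- coord_chain(pts, source_id = sprintf("random_n%d", n))
    net <- suppressWarnings(build_kirchhoff(ch, r_cut = r_cut))
    if (igraph::components(critnet:::as_igraph(net))$no == 1L)
      return(list(chain = ch, net = net))
  }
  stop("could not draw a connected random cloud")
}

# contact_network built directly from an explicit edge list (unit springs)
net_from_edges <- function(n, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
  gamma <- Matrix::sparseMatrix(
    i = c(edges[, 1L], edges[, 2L], seq_len(n)),
    j = c(edges[, 2L], edges[, 1L], seq_len(n)),
    x = c(rep(-1, 2L * nrow(edges)), deg), dims = c(n, n))
  structure(list(n_nodes = n, edges = edges,
                 weights = rep(1, nrow(edges)), r_cut = NULL,
                 kirchhoff = gamma, degrees = deg, model = "gnm_cutoff",
                 source_id = "edgelist"),
            class = "contact_network")
}

# random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function(seed = 1) {
  critnet:::with_seed(seed, {
    qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
    r <- qr.Q(qr_)
    if (det(r) < 0) r[, 1] <- -r[, 1]
    r
  })
}
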