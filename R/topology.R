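# Graph-topology descriptors of the contact network: average shortest-path
# length and Louvain-maximized modularity. All descriptors act on the
# binary (unweighted) contact graph, regardless of spring model.

#' Average shortest-path length
#'
#' Mean number of steps along unweighted shortest paths over all ordered
#' node pairs, `<l> = sum_{i != j} l_ij / (N (N-1))`. For systems with more
#' than `sample_threshold` nodes the mean is estimated from breadth-first
#' searches out of a fixed-seed random sample of source nodes (unbiased
#' over sources); the result then carries attribute `sampled = TRUE`.
#'
#' @param net a connected `contact_network`.
#' @param sample_threshold exact all-sources BFS up to this size
#'   (default 2000).
#' @param n_sources number of sampled sources above the threshold.
#' @param seed seed for the source sample.
#' @return numeric scalar (dimensionless step count).
#' @export
average_path_length <- function(net, sample_threshold = 2000L,
                                n_sources = 1000L, seed = 1L) {
  g <- as_igraph(net)
  comp <- igraph::components(g)
  if (comp$no > 1L)
    stop(sprintf("network is disconnected (%d components, sizes: %s)",
                 comp$no, paste(sort(comp$csize, decreasing = TRUE),
                                collapse = ", ")))
  n <- net$n_nodes
  if (n <= sample_threshold)
    return(igraph::mean_distance(g, directed = FALSE))
  sources <- with_seed(seed, sample.int(n, min(n_sources, n)))
  d <- igraph::distances(g, v = sources, algorithm = "unweighted")
  out <- mean(d[d > 0])  # excludes the zero self-distances
  attr(out, "sampled") <- TRUE
  out
}

#' Newman modularity of a partition
#'
#' `Q = sum_c [ m_c / M - (K_c / 2M)^2 ]` on the binary adjacency: the
#' within-community edge fraction minus its degree-preserving random
#' expectation, summed over communities. Bipartitions reproduce the
#' two-module `+/-1` spin form; `Q` lies in `[-1, 1]` and the
#' all-in-one-community partition scores exactly 0.
#'
#' @param net a `contact_network` with at least one edge.
#' @param partition integer/character community label per node.
#' @return numeric scalar in `[-1, 1]`.
#' @export
modularity_q <- function(net, partition) {
  if (length(partition) != net$n_nodes)
    stop(sprintf("partition labels %d node(s) but the network has %d",
                 length(partition), net$n_nodes))
  if (anyNA(partition)) {
    bad <- which(is.na(partition))
    stop(sprintf("node(s) missing from the assignment: %s",
                 paste(utils::head(bad, 10L), collapse = ", ")))
  }
  m <- nrow(net$edges)
  if (m < 1L) stop("network has no edges")
  lab <- as.integer(factor(partition))
  deg <- tabulate(c(net$edges[, 1L], net$edges[, 2L]), nbins = net$n_nodes)
  within <- lab[net$edges[, 1L]] == lab[net$edges[, 2L]]
  # edges within community c, and total degree per community
  mc <- rep(0, max(lab))
  tab <- table(lab[net$edges[, 1L]][within])
  mc[as.integer(names(tab))] <- as.numeric(tab)
  Kc <- vapply(seq_len(max(lab)), function(cc) sum(deg[lab == cc]), numeric(1L))
  sum(mc / m - (Kc / (2 * m))^2)
}

#' Louvain-maximized partition
#'
#' Runs the Louvain multilevel heuristic `n_restarts` times with derived
#' sub-seeds (restarts differ in the randomized vertex processing order)
#' and keeps the partition with the highest modularity. Deterministic for a
#' given `(seed, n_restarts)`; ties keep the earliest restart.
#'
#' @param net a `contact_network`.
#' @param n_restarts number of restarts (default 10).
#' @param seed base seed for the restarts.
#' @return An object of class `network_partition`: `membership` (integer
#'   label per node), `n_communities`, `q` (the maximized modularity).
#' @export
best_partition <- function(net, n_restarts = 10L, seed = 1L) {
  stopifnot(n_restarts >= 1L)
  g <- as_igraph(net)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    memb <- with_seed(seed + r, igraph::membership(igraph::cluster_louvain(g)))
    q <- modularity_q(net, as.integer(memb))
    if (is.null(best) || q > best$q)
      best <- list(membership = as.integer(memb), q = q)
  }
  structure(
    list(membership = best$membership,
         n_communities = length(unique(best$membership)),
         q = best$q),
    class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("<network_partition> %d communities, Q = %.4f\n",
              x$n_communities, x$q))
  invisible(x)
}
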