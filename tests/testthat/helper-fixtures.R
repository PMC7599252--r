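# shared in-code fixtures for the test suite

# path graph a-b-c-...; returns igraph with given vertex names
path_graph <- function(nodes) {
  make_network(nodes[-length(nodes)], nodes[-1L])
}

star_graph <- function(hub = "hub", n_leaves = 5L) {
  leaves <- sprintf("leaf%02d", seq_len(n_leaves))
  make_network(rep(hub, n_leaves), leaves)
}

# random connected graph: random spanning tree plus extra random edges
random_connected_graph <- function(n, extra = n) {
  stopifnot(n >= 2L)
  nodes <- sprintf("v%03d", seq_len(n))
  from <- nodes[vapply(2:n, function(i) sample.int(i - 1L, 1L), integer(1L))]
  to <- nodes[2:n]
  if (extra > 0L) {
    a <- sample(nodes, extra, replace = TRUE)
    b <- sample(nodes, extra, replace = TRUE)
    ok <- a != b
    from <- c(from, a[ok])
    to <- c(to, b[ok])
  }
  make_network(from, to)
}

# independent BFS oracle: shortest hop distances from one source, plain R
bfs_distances <- function(net, source) {
  nodes <- igraph::V(net)$name
  adj <- lapply(igraph::adjacent_vertices(net, nodes), function(v) v$name)
  names(adj) <- nodes
  dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
  dist[source] <- 0
  queue <- source
  while (length(queue) > 0L) {
    cur <- queue[1L]
    queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist
}

# oracle closest distance via bfs_distances
oracle_closest_distance <- function(net, targets, pathway) {
  mean(vapply(targets, function(t) min(bfs_distances(net, t)[pathway]),
              numeric(1L)))
}

# small expression fixture with named genes/samples
toy_expression <- function(n_genes = 20L, n_samples = 5L, seed = 1L) {
  set.seed(seed)
  m <- matrix(stats::rexp(n_genes * n_samples, rate = 0.1),
              nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  expression_matrix(m, value_scale = "raw")
}

# scaled-down scenario for fast end-to-end tests; overrides win
quick_config <- function(seed = 1L, ...) {
  args <- list(n_genes = 300L, n_pathways = 20L,
               pathway_size_range = c(8L, 12L), n_organoids = 16L,
               n_patients_treated = 40L, n_patients_untreated = 40L,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(scenario_config, args)
}
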