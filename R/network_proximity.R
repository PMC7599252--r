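#' Closest network distance from drug targets to a pathway
#'
#' The closest-distance measure between a drug's target genes T and a pathway
#' gene set S on an unweighted interaction network:
#' \deqn{d_c = \frac{1}{|T|} \sum_{t \in T} \min_{s \in S} d(s, t)}
#' i.e. the average over targets of the shortest-path length to the nearest
#' pathway gene. A target that is itself a pathway member contributes 0.
#' The measure is deliberately asymmetric: it averages over T only.
#'
#' @param net An `igraph` network (connected; see
#'   [largest_connected_component()]).
#' @param targets Character vector of drug target genes (T).
#' @param pathway Character vector of pathway genes (S).
#' @param D Optional precomputed distance matrix (`igraph::distances(net)`)
#'   with dimnames; supplying it avoids repeated BFS in tight loops.
#' @return The closest distance, a non-negative scalar in edge hops.
#' @export
closest_distance <- function(net, targets, pathway, D = NULL) {
  nodes <- if (is.null(D)) igraph::V(net)$name else rownames(D)
  t_in <- intersect(targets, nodes)
  s_in <- intersect(pathway, nodes)
  if (length(t_in) == 0L) stop("no target gene present in the network")
  if (length(s_in) == 0L) stop("no pathway gene present in the network")
  if (is.null(D)) {
    d <- igraph::distances(net, v = t_in, to = s_in)
  } else {
    d <- D[t_in, s_in, drop = FALSE]
  }
  if (any(is.infinite(d) & apply(d, 1L, min) == Inf)) {
    stop("unreachable target-pathway pair; use a connected network")
  }
  mean(apply(d, 1L, min))
}

# row-index variant used inside the randomization loop: tidx/sidx are integer
# row/column indices into a precomputed distance matrix
closest_distance_idx <- function(D, tidx, sidx) {
  tot <- 0
  for (t in tidx) tot <- tot + min(D[t, sidx])
  tot / length(tidx)
}

#' Bin network nodes by degree
#'
#' Groups nodes into contiguous-degree bins for degree-preserving
#' randomization. Nodes are sorted by degree and adjacent degree values are
#' merged until each bin holds at least `min_bin_size` nodes; a final
#' undersized bin is merged into its predecessor.
#'
#' @param net An `igraph` network.
#' @param min_bin_size Minimum nodes per bin. The default (`NULL`) uses 100,
#'   lowered to `max(3, n/10)` on networks with fewer than 1000 nodes so that
#'   small graphs still bin sensibly.
#' @return An object of class `degree_binning`: list with `bins` (list of
#'   character vectors), `assignment` (named integer: node -> bin index) and
#'   `min_bin_size`.
#' @export
build_degree_bins <- function(net, min_bin_size = NULL) {
  deg <- igraph::degree(net)
  n <- length(deg)
  if (is.null(min_bin_size)) min_bin_size <- min(100L, max(3L, floor(n / 10)))
  if (min_bin_size < 1L) stop("min_bin_size must be >= 1")
  if (min_bin_size > n) stop("min_bin_size (", min_bin_size,
                             ") exceeds node count (", n, ")")
  degs <- sort(unique(deg))
  bins <- list()
  cur <- character(0L)
  for (d in degs) {
    cur <- c(cur, names(deg)[deg == d])
    if (length(cur) >= min_bin_size) {
      bins[[length(bins) + 1L]] <- cur
      cur <- character(0L)
    }
  }
  if (length(cur) > 0L) {
    if (length(bins) == 0L) {
      bins[[1L]] <- cur
    } else {
      bins[[length(bins)]] <- c(bins[[length(bins)]], cur)
    }
  }
  assignment <- integer(n)
  names(assignment) <- names(deg)
  for (i in seq_along(bins)) assignment[bins[[i]]] <- i
  structure(list(bins = bins, assignment = assignment,
                 min_bin_size = min_bin_size),
            class = "degree_binning")
}

#' Draw a degree-matched random gene set
#'
#' For each input gene one node is drawn uniformly, without replacement
#' within a draw, from the gene's degree bin, yielding a random set of the
#' same size and (binned) degree profile.
#'
#' @param net An `igraph` network (used only for validation).
#' @param genes Character vector of genes to match.
#' @param binning A `degree_binning` from [build_degree_bins()].
#' @param seed Optional integer; when given the draw is made reproducible by
#'   seeding a local RNG state.
#' @return Character vector of sampled genes, same length as `genes`.
#' @export
sample_degree_matched <- function(net, genes, binning, seed = NULL) {
  if (!all(genes %in% names(binning$assignment))) {
    stop("gene(s) not in the network/binning: ",
         paste(setdiff(genes, names(binning$assignment)), collapse = ", "))
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  bin_idx <- binning$assignment[genes]
  out <- character(length(genes))
  for (b in unique(bin_idx)) {
    members <- binning$bins[[b]]
    want <- sum(bin_idx == b)
    if (want > length(members)) {
      stop("degree bin ", b, " has ", length(members), " node(s) but ", want,
           " draws requested; increase min_bin_size")
    }
    out[bin_idx == b] <- members[sample.int(length(members), want)]
  }
  out
}

#' Proximity z-score against a degree-matched random null
#'
#' Builds a reference distribution of closest distances by replacing both the
#' target set and the pathway set with degree-matched random gene sets for
#' `n_iter` iterations (one joint draw over the union of the two sets, so
#' the observed overlap structure between targets and pathway is preserved),
#' then standardizes the observed closest distance:
#' `z = (d_c - mean(null)) / sd(null)`. A pathway is flagged proximal when
#' `z <= qnorm(alpha)` (-1.2816 at the default `alpha = 0.10`). When the null
#' distribution is degenerate (`sd = 0`), z is defined as 0 and the pathway
#' is not proximal.
#'
#' @inheritParams closest_distance
#' @param n_iter Number of random draws for the reference distribution.
#' @param min_bin_size Passed to [build_degree_bins()] when `binning` is NULL.
#' @param seed Integer seed for the randomization (required for
#'   reproducibility).
#' @param alpha Lower-tail significance level for the proximal call.
#' @param binning Optional prebuilt `degree_binning`.
#' @return A one-row `data.frame`: `d_c`, `mu_null`, `sigma_null`, `z`,
#'   `proximal`.
#' @export
proximity_zscore <- function(net, targets, pathway, n_iter = 1000,
                             min_bin_size = NULL, seed, alpha = 0.10,
                             D = NULL, binning = NULL) {
  if (missing(seed)) stop("seed is required")
  if (is.null(D)) D <- igraph::distances(net)
  if (is.null(binning)) binning <- build_degree_bins(net, min_bin_size)
  set.seed(seed)
  rec <- proximity_zscore_impl(D, binning, targets, pathway, n_iter, alpha)
  as.data.frame(rec)
}

# internal: assumes RNG already seeded; D has dimnames matching the binning.
# bins are carried as integer indices into rownames(D) for speed.
proximity_zscore_impl <- function(D, binning, targets, pathway, n_iter, alpha,
                                  bin_index = NULL) {
  nodes <- rownames(D)
  t_in <- intersect(targets, nodes)
  s_in <- intersect(pathway, nodes)
  if (length(t_in) == 0L) stop("no target gene present in the network")
  if (length(s_in) == 0L) stop("no pathway gene present in the network")
  if (is.null(bin_index)) {
    bin_index <- lapply(binning$bins, function(b) match(b, nodes))
  }
  tidx <- match(t_in, nodes)
  sidx <- match(s_in, nodes)
  d_obs <- closest_distance_idx(D, tidx, sidx)

  # both endpoint sets are randomized jointly over their union so the draw
  # preserves the observed T/S overlap structure (disjoint sets stay
  # disjoint, shared genes map to one shared replacement)
  u <- union(t_in, s_in)
  u_bins <- binning$assignment[u]
  pos_t <- match(t_in, u)
  pos_s <- match(s_in, u)
  null_d <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    ru <- draw_idx(bin_index, u_bins)
    null_d[i] <- closest_distance_idx(D, ru[pos_t], ru[pos_s])
  }
  mu <- mean(null_d)
  sigma <- stats::sd(null_d)
  if (is.na(sigma) || sigma == 0) {
    z <- 0
    proximal <- FALSE
  } else {
    z <- (d_obs - mu) / sigma
    proximal <- z <= stats::qnorm(alpha)
  }
  list(d_c = d_obs, mu_null = mu, sigma_null = if (is.na(sigma)) 0 else sigma,
       z = z, proximal = proximal)
}

# one degree-matched draw as integer node indices; without replacement
# within each bin
draw_idx <- function(bin_index, gene_bins) {
  out <- integer(length(gene_bins))
  for (b in unique(gene_bins)) {
    members <- bin_index[[b]]
    sel <- gene_bins == b
    want <- sum(sel)
    if (want > length(members)) {
      stop("degree bin exhausted (", length(members), " node(s), ", want,
           " requested); increase min_bin_size")
    }
    out[sel] <- members[sample.int(length(members), want)]
  }
  out
}

#' Select pathways proximal to a drug's targets
#'
#' Computes the proximity z-score of every pathway in a network-filtered
#' collection against the drug target set and flags pathways with
#' `z <= qnorm(alpha)` as proximal.
#'
#' @inheritParams proximity_zscore
#' @param coll Named list of gene sets, already filtered with
#'   [filter_to_network()].
#' @return A `data.frame` with one row per pathway (`pathway`, `d_c`,
#'   `mu_null`, `sigma_null`, `z`, `proximal`), sorted by z ascending.
#' @export
select_proximal_pathways <- function(net, targets, coll, alpha = 0.10,
                                     n_iter = 1000, min_bin_size = NULL,
                                     seed) {
  if (missing(seed)) stop("seed is required")
  if (length(coll) == 0L) stop("empty pathway collection")
  D <- igraph::distances(net)
  binning <- build_degree_bins(net, min_bin_size)
  bin_index <- lapply(binning$bins, function(b) match(b, rownames(D)))
  set.seed(seed)
  recs <- lapply(names(coll), function(nm) {
    r <- proximity_zscore_impl(D, binning, targets, coll[[nm]], n_iter, alpha,
                               bin_index = bin_index)
    data.frame(pathway = nm, d_c = r$d_c, mu_null = r$mu_null,
               sigma_null = r$sigma_null, z = r$z, proximal = r$proximal,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out[order(out$z, out$pathway), , drop = FALSE]
}

#' Mean gene centrality per pathway
#'
#' Pathway centrality score: per-gene centrality computed on the whole
#' network, averaged over the pathway's member genes. Used as a baseline
#' feature-selection strategy in place of network proximity.
#'
#' @param net An `igraph` network.
#' @param coll Named list of network-filtered gene sets.
#' @param measure One of `"degree"`, `"betweenness"`, `"closeness"`
#'   (closeness is normalized: `(n-1) / sum of distances`).
#' @return Named numeric vector of pathway scores.
#' @export
pathway_centrality <- function(net, coll,
                               measure = c("degree", "betweenness", "closeness")) {
  measure <- match.arg(measure)
  cent <- switch(measure,
    degree = igraph::degree(net),
    betweenness = igraph::betweenness(net),
    closeness = igraph::closeness(net, normalized = TRUE)
  )
  vapply(coll, function(s) {
    s <- intersect(s, names(cent))
    if (length(s) == 0L) stop("pathway with no gene in the network")
    mean(cent[s])
  }, numeric(1L))
}

#' Top-k pathways by network centrality
#'
#' Baseline selector matching the count of proximal pathways: the k pathways
#' with the highest mean-centrality score, ties broken lexicographically.
#'
#' @inheritParams pathway_centrality
#' @param k Number of pathways to keep.
#' @return Character vector of k pathway names.
#' @export
select_central_pathways <- function(net, coll, measure, k) {
  if (k <= 0L) stop("k must be positive")
  if (k > length(coll)) stop("k exceeds number of pathways")
  sc <- pathway_centrality(net, coll, measure)
  ord <- order(-sc, names(sc))
  names(sc)[ord][seq_len(k)]
}

#' Genes within k hops of the drug targets
#'
#' Baseline gene-level feature set: the union of all nodes within shortest
#' path distance `depth` of any target. Depth 0 returns the targets
#' themselves.
#'
#' @param net An `igraph` network.
#' @param targets Character vector of target genes (must be in the network).
#' @param depth Integer hop radius in `[0, max_depth]`.
#' @param max_depth Cap on the allowed depth (default 3).
#' @return Character vector of gene names.
#' @export
neighbor_gene_set <- function(net, targets, depth, max_depth = 3L) {
  if (depth < 0L || depth > max_depth) {
    stop("depth must be in [0, ", max_depth, "]")
  }
  if (!all(targets %in% igraph::V(net)$name)) {
    stop("target(s) not in network: ",
         paste(setdiff(targets, igraph::V(net)$name), collapse = ", "))
  }
  if (depth == 0L) return(sort(unique(targets)))
  nb <- igraph::ego(net, order = depth, nodes = targets)
  sort(unique(unlist(lapply(nb, function(v) v$name))))
}
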