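test_that("closest distance averages each target's hop count to the nearest
           pathway gene", {
  p5 <- path_graph(letters[1:5])
  expect_equal(closest_distance(p5, "a", c("d", "e")), 3)
  expect_equal(closest_distance(p5, c("a", "b"), c("a", "b", "c")), 0)
  p3 <- path_graph(letters[1:3])
  expect_equal(closest_distance(p3, c("a", "c"), "b"), 1)
  expect_error(closest_distance(p3, "zz", "b"), "no target gene")
  expect_error(closest_distance(p3, "a", "zz"), "no pathway gene")
})

test_that("closest distance matches the BFS oracle on random connected
           graphs and is monotone in the pathway set", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    g <- random_connected_graph(n)
    nodes <- igraph::V(g)$name
    targets <- sample(nodes, sample(1:4, 1))
    pw <- sample(nodes, sample(2:8, 1))
    expect_identical(closest_distance(g, targets, pw),
                     oracle_closest_distance(g, targets, pw))
    # growing S cannot increase any min term
    pw_big <- union(pw, sample(nodes, 3))
    expect_lte(closest_distance(g, targets, pw_big),
               closest_distance(g, targets, pw))
  }
})

test_that("closest distance is asymmetric in targets and pathway", {
  # star: hub is 1 hop from everything, leaves are 2 hops apart
  g <- star_graph(n_leaves = 4)
  t_set <- c("leaf01", "leaf02")
  s_set <- "leaf03"
  expect_equal(closest_distance(g, t_set, s_set), 2)     # avg over 2 leaves
  expect_equal(closest_distance(g, s_set, t_set), 2)     # same here...
  t2 <- c("hub", "leaf01")
  expect_equal(closest_distance(g, t2, s_set), 1.5)      # (1 + 2)/2
  expect_equal(closest_distance(g, s_set, t2), 1)        # nearest is hub
})

test_that("degree bins merge contiguous degrees up to the size floor", {
  # path a-b-c-d: degrees a=1, d=1, b=2, c=2
  g <- path_graph(letters[1:4])
  b1 <- build_degree_bins(g, min_bin_size = 2)
  expect_length(b1$bins, 2)
  expect_setequal(b1$bins[[1]], c("a", "d"))
  expect_setequal(b1$bins[[2]], c("b", "c"))

  # degrees {1,1,1,2,2,3}: floor 3 gives [{deg1}, {deg2+deg3}]
  g2 <- make_network(c("a", "a", "a", "b"), c("b", "c", "d", "c"))
  deg <- igraph::degree(g2)
  g2 <- igraph::add_vertices(g2, 2, name = c("e", "f"))
  g2 <- igraph::add_edges(g2, c("e", "f"))
  expect_setequal(as.integer(igraph::degree(g2)), c(1L, 2L, 3L))
  b2 <- build_degree_bins(g2, min_bin_size = 3)
  expect_length(b2$bins, 2)
  expect_setequal(b2$bins[[1]],
                  names(igraph::degree(g2))[igraph::degree(g2) == 1])

  # floor 1 on all-distinct degrees: one bin per degree
  p4 <- path_graph(letters[1:3])  # degrees 1,1,2
  b3 <- build_degree_bins(p4, min_bin_size = 1)
  expect_length(b3$bins, 2)
  # floor = node count: a single bin
  b4 <- build_degree_bins(p4, min_bin_size = 3)
  expect_length(b4$bins, 1)
  expect_error(build_degree_bins(p4, min_bin_size = 10), "exceeds")
})

test_that("degree-matched sampling preserves cardinality and bin membership", {
  set.seed(7)
  g <- random_connected_graph(40)
  binning <- build_degree_bins(g, min_bin_size = 5)
  genes <- sample(igraph::V(g)$name, 6)
  for (i in 1:20) {
    s <- sample_degree_matched(g, genes, binning)
    expect_length(s, length(genes))
    expect_false(anyDuplicated(s) > 0)
    expect_identical(unname(binning$assignment[s]),
                     unname(binning$assignment[genes]))
  }
  # fixed seed reproduces the draw exactly
  s1 <- sample_degree_matched(g, genes, binning, seed = 11)
  s2 <- sample_degree_matched(g, genes, binning, seed = 11)
  expect_identical(s1, s2)
  # one-node bins force the identity
  b1 <- build_degree_bins(path_graph(letters[1:3]), min_bin_size = 1)
  forced <- sample_degree_matched(path_graph(letters[1:3]), "b", b1)
  expect_identical(forced, "b")
  # more requests than bin members errors
  tiny <- build_degree_bins(path_graph(letters[1:3]), min_bin_size = 1)
  expect_error(sample_degree_matched(path_graph(letters[1:3]),
                                     c("a", "c", "b", "b"), tiny),
               "min_bin_size")
})

test_that("a degenerate null yields z = 0 and no proximal call", {
  # complete graph: every pairwise distance is 1, the null has sd 0
  k5 <- make_network(rep(letters[1:4], times = 4:1),
                     unlist(lapply(2:5, function(i) letters[i:5])))
  expect_equal(igraph::ecount(k5), 10)
  rec <- proximity_zscore(k5, c("a", "b"), c("d", "e"), n_iter = 50,
                          min_bin_size = 1, seed = 1)
  expect_equal(rec$z, 0)
  expect_false(rec$proximal)
  expect_equal(rec$sigma_null, 0)
})

test_that("sampled proximity z agrees with exhaustive enumeration on a toy
           graph", {
  # 8-node graph; singleton T and S so the degree-matched null enumerates
  # as the cross product of the two bins
  set.seed(5)
  g <- random_connected_graph(8, extra = 4)
  D <- igraph::distances(g)
  binning <- build_degree_bins(g, min_bin_size = 2)
  t_gene <- igraph::V(g)$name[1]
  s_gene <- igraph::V(g)$name[8]
  t_bin <- binning$bins[[binning$assignment[t_gene]]]
  s_bin <- binning$bins[[binning$assignment[s_gene]]]
  null_exact <- as.vector(outer(t_bin, s_bin,
                                Vectorize(function(t, s) D[t, s])))
  mu_e <- mean(null_exact)
  sd_e <- stats::sd(null_exact)
  z_exact <- (D[t_gene, s_gene] - mu_e) / sd_e
  rec <- proximity_zscore(g, t_gene, s_gene, n_iter = 1000,
                          min_bin_size = 2, seed = 3)
  expect_equal(rec$mu_null, mu_e, tolerance = 4 * sd_e / sqrt(1000) / mu_e)
  expect_lt(abs(rec$z - z_exact), 0.3)
})

test_that("proximal selection uses the lower-tail normal quantile and sorts
           by z", {
  expect_equal(round(stats::qnorm(0.10), 4), -1.2816)
  expect_equal(stats::qnorm(0.5), 0)
  set.seed(2)
  g <- random_connected_graph(60)
  nodes <- igraph::V(g)$name
  coll <- list(A = sample(nodes, 6), B = sample(nodes, 6),
               C = sample(nodes, 6))
  recs <- select_proximal_pathways(g, sample(nodes, 3), coll,
                                   n_iter = 100, seed = 9)
  expect_equal(nrow(recs), 3)
  expect_false(is.unsorted(recs$z))
  expect_identical(recs$proximal, recs$z <= stats::qnorm(0.10))
})

test_that("pathway centrality averages member-gene centrality", {
  g <- star_graph(n_leaves = 5)
  sc <- pathway_centrality(g, list(H = "hub", L = "leaf01"), "degree")
  expect_equal(unname(sc["H"]), 5)
  expect_equal(unname(sc["L"]), 1)
  # identical sets get identical scores
  sc2 <- pathway_centrality(g, list(X = c("hub", "leaf01"),
                                    Y = c("hub", "leaf01")), "betweenness")
  expect_equal(unname(sc2["X"]), unname(sc2["Y"]))
  # normalized closeness of the middle of a 3-path is (n-1)/sum(d) = 1
  p3 <- path_graph(letters[1:3])
  sc3 <- pathway_centrality(p3, list(M = "b"), "closeness")
  expect_equal(unname(sc3["M"]), 1)
  expect_error(pathway_centrality(g, list(H = "hub"), "pagerank"))
})

test_that("central-pathway selection takes top-k with lexicographic ties", {
  g <- star_graph(n_leaves = 5)
  coll <- list(H = c("hub", "leaf01"), B = "leaf02", A = "leaf03")
  expect_setequal(select_central_pathways(g, coll, "degree", 3),
                  c("H", "A", "B"))
  expect_equal(select_central_pathways(g, coll, "degree", 1), "H")
  # B and A tie at rank 2; the lexicographically smaller name is kept
  expect_equal(select_central_pathways(g, coll, "degree", 2), c("H", "A"))
  expect_error(select_central_pathways(g, coll, "degree", 0), "positive")
  expect_error(select_central_pathways(g, coll, "degree", 9), "exceeds")
})

test_that("neighbor gene sets grow by BFS depth", {
  p4 <- path_graph(letters[1:4])
  expect_equal(neighbor_gene_set(p4, "a", 1), c("a", "b"))
  expect_equal(neighbor_gene_set(p4, "a", 0), "a")
  expect_equal(neighbor_gene_set(p4, "a", 3), letters[1:4])
  expect_error(neighbor_gene_set(p4, "a", 4), "depth")
  expect_error(neighbor_gene_set(p4, "zz", 1), "not in network")
})
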