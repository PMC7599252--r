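write_tsv_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_edge_list applies a strict score threshold and cleans edges", {
  f <- write_tsv_lines(c("a\tb\t800", "b\tc\t600"))
  net <- read_edge_list(f, min_score = 700)
  expect_equal(igraph::ecount(net), 1)
  expect_setequal(igraph::V(net)$name, c("a", "b"))

  # a score exactly at the threshold is excluded (> is strict)
  f2 <- write_tsv_lines(c("a\tb\t700", "b\tc\t701"))
  net2 <- read_edge_list(f2, min_score = 700)
  expect_setequal(igraph::V(net2)$name, c("b", "c"))

  # symmetric duplicates collapse to one undirected edge
  f3 <- write_tsv_lines(c("a\tb\t800", "b\ta\t800"))
  net3 <- read_edge_list(f3, min_score = 700)
  expect_equal(igraph::ecount(net3), 1)
  expect_equal(igraph::vcount(net3), 2)

  # 5-edge toy with one self-loop keeps 4 edges
  f4 <- write_tsv_lines(c("a\tb\t900", "b\tc\t900", "c\tc\t900",
                          "c\td\t900", "d\te\t900"))
  expect_equal(igraph::ecount(read_edge_list(f4, min_score = 0)), 4)
})

test_that("read_edge_list rejects malformed input and empty results", {
  f <- write_tsv_lines(c("a\tb\t800", "b\tc"))
  expect_error(read_edge_list(f, 700), "line 2")
  f2 <- write_tsv_lines(c("a\tb\t100"))
  expect_error(read_edge_list(f2, 700), "no edges")
  # min_score = 0 on uniform scores retains all non-loop edges
  f3 <- write_tsv_lines(c("a\tb\t1", "b\tc\t1", "c\tc\t1"))
  expect_equal(igraph::ecount(read_edge_list(f3, min_score = 0)), 2)
})

test_that("largest_connected_component keeps the biggest component with a
           deterministic tie-break", {
  net <- make_network(c("a", "b", "d"), c("b", "c", "e"))
  lcc <- largest_connected_component(net)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c"))

  # connected graph is returned unchanged
  p <- path_graph(letters[1:4])
  expect_setequal(igraph::V(largest_connected_component(p))$name, letters[1:4])

  # two size-3 components: the one holding the smallest name wins
  tie <- make_network(c("x", "y", "a", "b"), c("y", "z", "b", "c"))
  expect_setequal(igraph::V(largest_connected_component(tie))$name,
                  c("a", "b", "c"))
  expect_error(largest_connected_component(make_network(character(0),
                                                        character(0))),
               "empty")
})

test_that("read_gmt parses sets, deduplicates genes, and rejects bad files", {
  f <- write_tsv_lines(c("P1\tdesc\tg1\tg2\tg2", "P2\tdesc\tg3"))
  coll <- read_gmt(f)
  expect_length(coll, 2)
  expect_setequal(coll$P1, c("g1", "g2"))

  f_dup <- write_tsv_lines(c("P1\td\tg1", "P1\td\tg2"))
  expect_error(read_gmt(f_dup), "duplicate pathway name")
  f_short <- write_tsv_lines(c("P1\td\tg1", "P2\tdesc"))
  expect_error(read_gmt(f_short), "line 2")
})

test_that("filter_to_network intersects, drops empty sets, and is idempotent", {
  net <- path_graph(c("g1", "g2"))
  coll <- list(P1 = c("g1", "gX"), P2 = "gX", P3 = c("g1", "g2"))
  suppressMessages(out <- filter_to_network(coll, net))
  expect_named(out, c("P1", "P3"))
  expect_equal(out$P1, "g1")
  suppressMessages(again <- filter_to_network(out, net))
  expect_identical(out, again)
})

test_that("drug targets with no network gene are dropped with a warning", {
  net <- path_graph(c("g1", "g2"))
  tg <- list(dA = c("g1", "gX"), dB = "gZ")
  expect_warning(out <- filter_targets_to_network(tg, net), "dB")
  expect_named(out, "dA")
  expect_equal(out$dA, "g1")
})

test_that("every format round-trips through write and read", {
  dir <- withr::local_tempdir()
  net <- make_network(c("a", "b", "c"), c("b", "c", "d"),
                      score = c(800L, 900L, 750L))
  write_edge_list(net, file.path(dir, "net.tsv"))
  net2 <- read_edge_list(file.path(dir, "net.tsv"), min_score = 0)
  expect_setequal(igraph::V(net2)$name, igraph::V(net)$name)
  expect_equal(igraph::ecount(net2), igraph::ecount(net))

  coll <- list(P1 = c("a", "b"), P2 = c("c", "d", "e"))
  write_gmt(coll, file.path(dir, "sets.gmt"))
  expect_identical(read_gmt(file.path(dir, "sets.gmt")), coll)

  m <- toy_expression(6, 3)
  write_expression(m, file.path(dir, "expr.tsv"))
  m2 <- read_expression(file.path(dir, "expr.tsv"))
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(dimnames(m2), dimnames(m))

  y <- c(s01 = 0.5, s02 = 2.4, s03 = 10)
  write_response(y, file.path(dir, "ic50.tsv"))
  expect_equal(read_response(file.path(dir, "ic50.tsv")), y)

  cl <- data.frame(patient_id = c("p1", "p2"), time_days = c(100, 250.5),
                   event = c(1L, 0L), treated = c(TRUE, FALSE),
                   mutation_marker = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  write_clinical(cl, file.path(dir, "clin.tsv"))
  expect_equal(read_clinical(file.path(dir, "clin.tsv")), cl)
})

test_that("expression rows with missing values are dropped on load", {
  dir <- withr::local_tempdir()
  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\tNA\t3", "g3\t4\t5"),
             file.path(dir, "expr.tsv"))
  expect_message(m <- read_expression(file.path(dir, "expr.tsv")), "1 feature")
  expect_equal(rownames(m), c("g1", "g3"))
})

test_that("response and clinical validation rejects bad values", {
  dir <- withr::local_tempdir()
  writeLines(c("s1\t-1"), file.path(dir, "bad_ic50.tsv"))
  expect_error(read_response(file.path(dir, "bad_ic50.tsv")), "positive")
  writeLines(c("patient_id\ttime_days\tevent\ttreated", "p1\t-5\t1\tTRUE"),
             file.path(dir, "bad_clin.tsv"))
  expect_error(read_clinical(file.path(dir, "bad_clin.tsv")), "negative")
  writeLines(c("patient_id\ttime_days\tevent\ttreated", "p1\t5\t2\tTRUE"),
             file.path(dir, "bad_clin2.tsv"))
  expect_error(read_clinical(file.path(dir, "bad_clin2.tsv")), "event")
})
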