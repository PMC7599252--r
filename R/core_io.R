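#' Read a scored protein-protein interaction edge list
#'
#' Reads a STRING-style tab-separated edge list (`geneA`, `geneB`, `score`)
#' and returns an undirected [igraph::igraph] network keeping only edges whose
#' confidence score is strictly greater than `min_score`. Self-loops are
#' discarded and symmetric duplicate edges are collapsed to a single
#' undirected edge.
#'
#' @param path Path to a TSV file with at least three columns: gene A, gene B,
#'   integer confidence score (0-1000). A header line is detected and skipped
#'   when its third field is not numeric.
#' @param min_score Keep edges with `score > min_score` (strict). The
#'   high-confidence convention for STRING-style networks is `min_score = 700`.
#' @return An undirected `igraph` graph with vertex names set to gene
#'   identifiers and an integer edge attribute `score`.
#' @export
read_edge_list <- function(path, min_score = 700) {
  stopifnot(is.character(path), length(path) == 1L, min_score >= 0)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty edge-list file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (length(fields[[1L]]) >= 3L && is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) {
    start <- 2L  # header row
  }
  n_ok <- vapply(fields, length, integer(1L)) >= 3L
  bad <- which(!n_ok & seq_along(fields) >= start & nzchar(trimws(lines)))
  if (length(bad) > 0L) {
    stop("malformed edge-list line ", bad[1L], " in ", path,
         " (need at least 3 tab-separated fields)")
  }
  keep <- seq.int(start, length(fields))
  keep <- keep[nzchar(trimws(lines[keep]))]
  if (length(keep) == 0L) stop("edge-list file has no data rows: ", path)
  a <- vapply(fields[keep], `[[`, character(1L), 1L)
  b <- vapply(fields[keep], `[[`, character(1L), 2L)
  s <- suppressWarnings(as.numeric(vapply(fields[keep], `[[`, character(1L), 3L)))
  if (anyNA(s)) {
    stop("malformed edge-list line ", keep[which(is.na(s))[1L]], " in ", path,
         " (non-numeric score)")
  }
  pass <- s > min_score & a != b
  if (!any(pass)) stop("no edges with score > ", min_score, " in ", path)
  make_network(a[pass], b[pass], s[pass])
}

#' Build an interaction network from edge vectors
#'
#' Constructs an undirected, simple (no loops, no multi-edges) gene network.
#' Used by [read_edge_list()] and the synthetic-data generators.
#'
#' @param from,to Character vectors of gene identifiers, one edge per element.
#' @param score Optional numeric confidence per edge.
#' @return An undirected `igraph` graph.
#' @export
make_network <- function(from, to, score = NULL) {
  df <- data.frame(from = as.character(from), to = as.character(to),
                   stringsAsFactors = FALSE)
  if (!is.null(score)) df$score <- score
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  # collapse symmetric duplicates, keeping the first score seen
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(score = "first", "ignore"))
}

#' Largest connected component of a network
#'
#' Returns the induced subgraph of the largest connected component. Ties in
#' component size are broken deterministically by the lexicographically
#' smallest member vertex name.
#'
#' @param net An `igraph` network.
#' @return The induced subgraph on the winning component.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network")
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # smallest member name decides
    firsts <- vapply(best, function(ci) {
      min(igraph::V(net)$name[comp$membership == ci])
    }, character(1L))
    best <- best[order(firsts)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description column is
#' ignored and duplicate genes within a set are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one gene set per element).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1L)) < 3L)
  if (length(short) > 0L) {
    stop("GMT line ", short[1L], " in ", path, " has fewer than 3 fields")
  }
  nm <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate pathway name in ", path, ": ",
         nm[duplicated(nm)][1L])
  }
  sets <- lapply(fields, function(f) unique(f[-c(1L, 2L)]))
  names(sets) <- nm
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Restrict gene sets to network genes
#'
#' Intersects every set with the network's vertex set and drops sets with no
#' gene left. Retained/dropped counts are reported via `message()`.
#'
#' @param coll Named list of gene sets.
#' @param net An `igraph` network.
#' @return The filtered collection.
#' @export
filter_to_network <- function(coll, net) {
  nodes <- igraph::V(net)$name
  out <- lapply(coll, function(s) intersect(s, nodes))
  keep <- vapply(out, length, integer(1L)) > 0L
  message(sum(keep), " of ", length(coll),
          " gene sets retained after network filtering (",
          sum(!keep), " dropped)")
  out[keep]
}

#' Restrict a drug-target table to network genes
#'
#' Drops, with a warning, drugs that have no target gene in the network.
#'
#' @param targets Named list: drug name -> character vector of target genes.
#' @param net An `igraph` network.
#' @return The filtered drug-target list.
#' @export
filter_targets_to_network <- function(targets, net) {
  nodes <- igraph::V(net)$name
  out <- lapply(targets, function(s) intersect(s, nodes))
  keep <- vapply(out, length, integer(1L)) > 0L
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " drug(s) with no target in the network: ",
            paste(names(out)[!keep], collapse = ", "))
  }
  out[keep]
}

#' Read a drug-target TSV
#'
#' Two columns, `drug<TAB>gene`, one association per line (header optional).
#'
#' @param path Path to the TSV.
#' @return Named list: drug -> character vector of target genes.
#' @export
read_drug_targets <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("drug-target file needs 2 columns: drug, gene")
  if (identical(tolower(df[1L, 1L]), "drug")) df <- df[-1L, , drop = FALSE]
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write a drug-target list to TSV
#' @param targets Named list drug -> genes.
#' @param path Output path.
#' @export
write_drug_targets <- function(targets, path) {
  df <- data.frame(
    drug = rep(names(targets), lengths(targets)),
    gene = unlist(targets, use.names = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Construct an expression matrix with a declared value scale
#'
#' An expression matrix is a plain numeric matrix (features x samples) with
#' unique dimnames and a `value_scale` attribute recording what the values
#' mean: `"raw"` (linear-scale expression), `"log2p1"` (log2(x+1)),
#' `"nes"` (ssGSEA normalized enrichment scores), or `"zscore"`
#' (per-feature standardized).
#'
#' @param x Numeric matrix with rownames (genes or pathways) and colnames
#'   (samples).
#' @param value_scale One of `"raw"`, `"log2p1"`, `"nes"`, `"zscore"`.
#' @return The matrix with class `expr_matrix` and the scale attribute set.
#' @export
expression_matrix <- function(x, value_scale = c("raw", "log2p1", "nes", "zscore")) {
  value_scale <- match.arg(value_scale)
  x <- as.matrix(x)
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs row (feature) and column (sample) names")
  }
  if (anyDuplicated(rownames(x))) stop("duplicate feature labels")
  if (anyDuplicated(colnames(x))) stop("duplicate sample labels")
  attr(x, "value_scale") <- value_scale
  class(x) <- c("expr_matrix", class(x))
  x
}

#' Value scale of an expression matrix
#' @param x An `expr_matrix`.
#' @return The `value_scale` attribute (or `"raw"` when unset).
#' @export
value_scale <- function(x) {
  vs <- attr(x, "value_scale")
  if (is.null(vs)) "raw" else vs
}

#' Read an expression matrix TSV
#'
#' First column is the feature label, remaining columns are samples, header
#' row carries sample names. Rows containing any missing value are dropped
#' and the count reported via `message()`.
#'
#' @param path Path to the TSV.
#' @param value_scale Declared scale of the stored values (see
#'   [expression_matrix()]).
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, value_scale = "raw") {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a label column plus samples")
  feats <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- feats
  drop <- rowSums(is.na(m)) > 0L
  if (any(drop)) {
    message("dropping ", sum(drop), " feature row(s) with missing values")
    m <- m[!drop, , drop = FALSE]
  }
  expression_matrix(m, value_scale = value_scale)
}

#' Write an expression matrix to TSV
#' @param m An `expr_matrix` (or plain matrix with dimnames).
#' @param path Output path.
#' @param label Name of the first (feature label) column.
#' @export
write_expression <- function(m, path, label = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- label
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an IC50 dose-response table
#'
#' TSV with columns `sample` and `ic50` (header optional). IC50 values must
#' be positive.
#'
#' @param path Path to the TSV.
#' @param expr Optional paired `expr_matrix`; when given, sample labels must
#'   be a subset of its columns.
#' @return Named numeric vector of IC50 values.
#' @export
read_response <- function(path, expr = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("response file needs 2 columns: sample, ic50")
  if (is.na(suppressWarnings(as.numeric(df[1L, 2L])))) df <- df[-1L, , drop = FALSE]
  y <- as.numeric(df[[2L]])
  names(y) <- as.character(df[[1L]])
  if (any(y <= 0)) stop("IC50 values must be positive")
  if (!is.null(expr) && !all(names(y) %in% colnames(expr))) {
    stop("response samples missing from expression matrix: ",
         paste(setdiff(names(y), colnames(expr)), collapse = ", "))
  }
  y
}

#' Write an IC50 table to TSV
#' @param y Named numeric vector of IC50 values.
#' @param path Output path.
#' @export
write_response <- function(y, path) {
  utils::write.table(data.frame(sample = names(y), ic50 = unname(y)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a patient clinical table
#'
#' TSV with header columns `patient_id`, `time_days`, `event`, `treated`,
#' plus optional `mutation_<gene>` boolean columns and free covariates.
#'
#' @param path Path to the TSV.
#' @return A `data.frame` with validated `time_days >= 0` and
#'   `event %in% c(0, 1)`; `treated` coerced to logical.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_days", "event", "treated")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) stop("clinical table missing column(s): ",
                              paste(miss, collapse = ", "))
  df$time_days <- as.numeric(df$time_days)
  df$event <- as.integer(df$event)
  df$treated <- as.logical(df$treated)
  if (any(df$time_days < 0)) stop("negative survival time")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 (censored) or 1 (death)")
  df
}

#' Write a clinical table to TSV
#' @param clinical A clinical `data.frame` (see [read_clinical()]).
#' @param path Output path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network to an edge-list TSV
#' @param net An `igraph` network with optional `score` edge attribute.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  el <- igraph::as_edgelist(net)
  score <- if ("score" %in% igraph::edge_attr_names(net)) {
    igraph::E(net)$score
  } else {
    rep(1000L, nrow(el))
  }
  utils::write.table(data.frame(el[, 1L], el[, 2L], score),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
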