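#' Scenario configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic pharmacogenomic study: an interaction
#' network with one synthetic drug's targets, a pathway collection with one
#' planted biomarker pathway near the targets, an organoid cohort whose IC50
#' depends on the planted pathway's latent activity, treated/untreated
#' patient cohorts whose hazard depends on the planted pathway only under
#' treatment, and isogenic sensitive/resistant expression profiles.
#'
#' Defaults describe the reference scenario: a 1000-gene preferential-
#' attachment network, 50 pathways of 10-20 genes, 5 drug targets with the
#' planted pathway within 1 hop, 20 organoids with an activity-IC50
#' correlation of -0.9, cohort sizes mirroring a typical treated/untreated
#' tumor registry split (114 treated, 298 untreated), a treatment-specific
#' hazard ratio of 3, 30% censoring, and 3 sensitive vs 9 resistant
#' isogenic lines shifted by 2 standard deviations.
#'
#' @param n_genes Number of genes (network nodes).
#' @param network_model `"preferential_attachment"` or `"erdos_renyi"`.
#' @param n_pathways Number of pathways (including the planted one).
#' @param pathway_size_range Length-2 integer range of pathway sizes.
#' @param n_targets Number of drug target genes.
#' @param planted_pathway_distance Max hops from targets to planted-pathway
#'   genes.
#' @param n_organoids Organoid cohort size.
#' @param biomarker_effect Correlation between planted-pathway activity and
#'   log10 IC50 (negative: high activity sensitizes).
#' @param noise_sd Gene-level noise standard deviation around the latent
#'   pathway activity factors.
#' @param n_patients_treated,n_patients_untreated Patient cohort sizes.
#' @param hazard_ratio Hazard multiplier for the resistance-direction half of
#'   the treated cohort (1 = no effect).
#' @param censoring_rate Probability that an observation is censored.
#' @param n_sensitive,n_resistant Isogenic cell-line group sizes.
#' @param isogenic_shift_sd Expression shift (in SDs) of planted-pathway
#'   genes in resistant lines, applied in the resistance direction.
#' @param seed Master seed; all generators derive their streams from it.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_genes = 1000L,
                            network_model = c("preferential_attachment",
                                              "erdos_renyi"),
                            n_pathways = 50L,
                            pathway_size_range = c(10L, 20L),
                            n_targets = 5L,
                            planted_pathway_distance = 1L,
                            n_organoids = 20L,
                            biomarker_effect = -0.9,
                            noise_sd = 0.5,
                            n_patients_treated = 114L,
                            n_patients_untreated = 298L,
                            hazard_ratio = 3,
                            censoring_rate = 0.3,
                            n_sensitive = 3L,
                            n_resistant = 9L,
                            isogenic_shift_sd = 2,
                            seed = 1L) {
  network_model <- match.arg(network_model)
  stopifnot(n_genes > 0, n_pathways > 0, n_targets > 0, n_organoids > 0,
            n_patients_treated > 0, n_patients_untreated > 0,
            n_sensitive > 0, n_resistant > 0,
            abs(biomarker_effect) <= 1, hazard_ratio > 0,
            censoring_rate >= 0, censoring_rate <= 1,
            length(pathway_size_range) == 2L,
            pathway_size_range[1L] <= pathway_size_range[2L])
  structure(as.list(environment()), class = "scenario_config")
}

# deterministic sub-seed per generator stage, kept below 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1009L + sum(utf8ToInt(stage))) %% 2000000011L
}

#' Synthetic interaction network, pathways and drug targets
#'
#' Builds a connected gene network, marks `n_targets` target genes for one
#' synthetic drug, plants one pathway whose members all lie within
#' `planted_pathway_distance` hops of the targets, and draws the remaining
#' pathways uniformly with no distance constraint (decoys).
#'
#' @param cfg A `scenario_config`.
#' @return List with `network` (igraph), `pathways` (named list of gene
#'   sets), `targets` (named list with one drug), and `planted` (name of the
#'   planted pathway).
#' @export
make_network_and_pathways <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "network"))
  g <- switch(cfg$network_model,
    preferential_attachment =
      igraph::sample_pa(cfg$n_genes, m = 3, directed = FALSE),
    erdos_renyi = {
      gg <- igraph::sample_gnp(cfg$n_genes, p = 6 / cfg$n_genes)
      gg
    }
  )
  igraph::V(g)$name <- sprintf("g%04d", seq_len(cfg$n_genes))
  g <- largest_connected_component(g)
  nodes <- igraph::V(g)$name
  deg <- igraph::degree(g)

  # targets drawn from mid-degree nodes so neighborhoods are non-trivial
  eligible <- names(deg)[deg >= 3]
  if (length(eligible) < cfg$n_targets) eligible <- names(deg)
  targets <- sample(eligible, cfg$n_targets)

  hood <- neighbor_gene_set(g, targets, depth = cfg$planted_pathway_distance,
                            max_depth = max(3L, cfg$planted_pathway_distance))
  sz <- sample(seq(cfg$pathway_size_range[1L], cfg$pathway_size_range[2L]), 1L)
  if (length(hood) < sz) {
    stop("target neighborhood (", length(hood), " genes) smaller than the ",
         "requested planted pathway size (", sz,
         "); widen planted_pathway_distance or shrink pathway_size_range")
  }
  # cover every target: one member drawn from each target's own
  # neighborhood, so the closest distance from the targets is bounded by
  # the planted distance by construction; the rest fill in from the union
  cover <- vapply(targets, function(t) {
    sample(neighbor_gene_set(g, t, depth = cfg$planted_pathway_distance,
                             max_depth = max(3L, cfg$planted_pathway_distance)),
           1L)
  }, character(1L))
  cover <- unique(cover)
  if (length(cover) > sz) sz <- length(cover)
  planted_genes <- c(cover, sample(setdiff(hood, cover), sz - length(cover)))

  pathways <- vector("list", cfg$n_pathways)
  names(pathways) <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  planted <- sample(names(pathways), 1L)
  for (nm in names(pathways)) {
    if (nm == planted) {
      pathways[[nm]] <- planted_genes
    } else {
      s <- sample(seq(cfg$pathway_size_range[1L], cfg$pathway_size_range[2L]), 1L)
      pathways[[nm]] <- sample(nodes, s)
    }
  }
  list(network = g, pathways = pathways,
       targets = list(drug_X = targets), planted = planted)
}

# latent-factor expression model shared by the cohort generators:
# activity[pathway, sample] ~ N(0,1); a gene's log2 expression is the sum of
# the activities of the pathways containing it plus N(0, noise_sd) noise,
# returned on a positive raw scale (2^(8+z), FPKM-like magnitudes) whose
# log2(x + 1) transform is strictly monotone in the latent value.
factor_expression <- function(cfg, coll, nodes, sample_ids, activity) {
  n <- length(sample_ids)
  z <- matrix(stats::rnorm(length(nodes) * n, sd = cfg$noise_sd),
              nrow = length(nodes), dimnames = list(nodes, sample_ids))
  for (nm in names(coll)) {
    g_in <- intersect(coll[[nm]], nodes)
    z[g_in, ] <- z[g_in, ] + rep(activity[nm, ], each = length(g_in))
  }
  raw <- 2^(8 + z)
  expression_matrix(raw, value_scale = "raw")
}

draw_activity <- function(coll, sample_ids) {
  matrix(stats::rnorm(length(coll) * length(sample_ids)),
         nrow = length(coll),
         dimnames = list(names(coll), sample_ids))
}

#' Synthetic organoid pharmacogenomic cohort
#'
#' Gene expression follows the latent pathway-activity factor model; IC50 is
#' generated so that the correlation between the planted pathway's activity
#' and log10 IC50 is approximately `cfg$biomarker_effect`, while every other
#' pathway's activity is independent of IC50.
#'
#' @param cfg A `scenario_config`.
#' @param net The network from [make_network_and_pathways()].
#' @param coll The pathway collection.
#' @param planted Name of the planted pathway.
#' @return List with `expression` (raw-scale `expr_matrix`), `response`
#'   (named IC50 vector, concentration units), and `activity` (the latent
#'   pathway-activity matrix, for diagnostics).
#' @export
make_organoid_cohort <- function(cfg, net, coll, planted) {
  set.seed(stage_seed(cfg$seed, "organoids"))
  ids <- sprintf("org%02d", seq_len(cfg$n_organoids))
  act <- draw_activity(coll, ids)
  expr <- factor_expression(cfg, coll, igraph::V(net)$name, ids, act)
  e <- cfg$biomarker_effect
  lat <- e * act[planted, ] + sqrt(1 - e^2) * stats::rnorm(cfg$n_organoids)
  # IC50 linear in the latent response (10 +/- 2 concentration units) so the
  # planted correlation holds on the scale the regression is fit on; the
  # floor keeps the value positive in extreme tails without breaking
  # monotonicity in practice
  y <- pmax(10 + 2 * lat, 0.05)
  names(y) <- ids
  list(expression = expr, response = y, activity = act)
}

#' Synthetic treated and untreated patient cohorts
#'
#' Treated patients follow exponential survival whose hazard is multiplied
#' by `cfg$hazard_ratio` for the half of the cohort on the resistance side
#' of the planted pathway's activity (low activity when `biomarker_effect`
#' is negative). Untreated patients' survival is independent of every
#' pathway. Censoring is independent: with probability `censoring_rate` an
#' observation is censored at a uniform time before its event. A binary
#' mutation marker correlated with the resistance direction is included for
#' concordance testing.
#'
#' @inheritParams make_organoid_cohort
#' @param baseline_hazard Events per day for the biomarker-low treated group
#'   and all untreated patients (default 1/365).
#' @return List with `expression` (raw-scale `expr_matrix`, both cohorts),
#'   `clinical` (data frame: `patient_id`, `time_days`, `event`, `treated`,
#'   `mutation_marker`), and `activity`.
#' @export
make_patient_cohorts <- function(cfg, net, coll, planted,
                                 baseline_hazard = 1 / 365) {
  set.seed(stage_seed(cfg$seed, "patients"))
  n_tr <- cfg$n_patients_treated
  n_un <- cfg$n_patients_untreated
  ids <- c(sprintf("pt%03d", seq_len(n_tr)),
           sprintf("pu%03d", seq_len(n_un)))
  treated <- rep(c(TRUE, FALSE), c(n_tr, n_un))
  act <- draw_activity(coll, ids)
  expr <- factor_expression(cfg, coll, igraph::V(net)$name, ids, act)

  # resistance direction: sign(biomarker_effect) maps activity to IC50
  res_latent <- sign(cfg$biomarker_effect) * act[planted, ]
  hazard <- rep(baseline_hazard, length(ids))
  hi <- res_latent >= stats::median(res_latent[treated])
  hazard[treated & hi] <- baseline_hazard * cfg$hazard_ratio
  t_event <- stats::rexp(length(ids), rate = hazard)
  censored <- stats::runif(length(ids)) < cfg$censoring_rate
  time <- ifelse(censored, stats::runif(length(ids)) * t_event, t_event)
  event <- as.integer(!censored)

  p_mut <- stats::plogis(-2 + 1.5 * res_latent)
  mutation <- stats::runif(length(ids)) < p_mut

  clinical <- data.frame(patient_id = ids, time_days = time, event = event,
                         treated = treated, mutation_marker = mutation,
                         stringsAsFactors = FALSE)
  list(expression = expr, clinical = clinical, activity = act)
}

#' Synthetic isogenic sensitive/resistant cell lines
#'
#' Resistant lines shift the planted pathway's member-gene expression by
#' `isogenic_shift_sd` standard deviations in the resistance direction (down
#' when `biomarker_effect` is negative, i.e. resistance = low biomarker
#' activity); all other genes are unshifted.
#'
#' @inheritParams make_organoid_cohort
#' @return List with `expression` (raw-scale `expr_matrix`) and `labels`
#'   (`"sensitive"`/`"resistant"` per column).
#' @export
make_isogenic_lines <- function(cfg, net, coll, planted) {
  set.seed(stage_seed(cfg$seed, "isogenic"))
  n <- cfg$n_sensitive + cfg$n_resistant
  labels <- rep(c("sensitive", "resistant"), c(cfg$n_sensitive, cfg$n_resistant))
  ids <- sprintf("line%02d_%s", seq_len(n), substr(labels, 1L, 1L))
  nodes <- igraph::V(net)$name
  z <- matrix(stats::rnorm(length(nodes) * n), nrow = length(nodes),
              dimnames = list(nodes, ids))
  g_in <- intersect(coll[[planted]], nodes)
  shift <- sign(cfg$biomarker_effect) * cfg$isogenic_shift_sd
  z[g_in, labels == "resistant"] <- z[g_in, labels == "resistant"] + shift
  raw <- 2^(8 + z)
  list(expression = expression_matrix(raw, value_scale = "raw"),
       labels = labels)
}

#' Generate a complete synthetic study
#'
#' Runs all four generators under the config's master seed.
#'
#' @param cfg A `scenario_config`.
#' @return List with `config`, `network`, `pathways`, `targets`, `planted`,
#'   `organoids`, `patients`, `isogenic`.
#' @export
simulate_scenario <- function(cfg = scenario_config()) {
  base <- make_network_and_pathways(cfg)
  organoids <- make_organoid_cohort(cfg, base$network, base$pathways,
                                    base$planted)
  patients <- make_patient_cohorts(cfg, base$network, base$pathways,
                                   base$planted)
  isogenic <- make_isogenic_lines(cfg, base$network, base$pathways,
                                  base$planted)
  list(config = cfg, network = base$network, pathways = base$pathways,
       targets = base$targets, planted = base$planted, organoids = organoids,
       patients = patients, isogenic = isogenic)
}

#' Write a synthetic study to disk in the standard formats
#'
#' Writes the edge-list TSV, GMT pathway file, drug-target TSV, organoid and
#' patient expression TSVs, IC50 TSV, clinical TSV, and isogenic expression
#' and label TSVs, all loadable through the package readers.
#'
#' @param scenario Output of [simulate_scenario()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_fixtures <- function(scenario, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_edge_list(scenario$network, p("network.tsv"))
  write_gmt(scenario$pathways, p("pathways.gmt"))
  write_drug_targets(scenario$targets, p("targets.tsv"))
  write_expression(scenario$organoids$expression, p("organoid_expr.tsv"),
                   label = "gene")
  write_response(scenario$organoids$response, p("organoid_ic50.tsv"))
  write_expression(scenario$patients$expression, p("patient_expr.tsv"),
                   label = "gene")
  write_clinical(scenario$patients$clinical, p("clinical.tsv"))
  write_expression(scenario$isogenic$expression, p("isogenic_expr.tsv"),
                   label = "gene")
  utils::write.table(
    data.frame(line = colnames(scenario$isogenic$expression),
               label = scenario$isogenic$labels),
    p("isogenic_labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  files <- c(network = p("network.tsv"), pathways = p("pathways.gmt"),
             targets = p("targets.tsv"),
             organoid_expr = p("organoid_expr.tsv"),
             organoid_ic50 = p("organoid_ic50.tsv"),
             patient_expr = p("patient_expr.tsv"),
             clinical = p("clinical.tsv"),
             isogenic_expr = p("isogenic_expr.tsv"),
             isogenic_labels = p("isogenic_labels.tsv"))
  invisible(files)
}
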