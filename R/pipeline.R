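# resolve a config entry that may be an in-memory object or a file path
resolve_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

run_manifest <- function(config, seeds, counts) {
  paths <- Filter(function(x) is.character(x) && length(x) == 1L &&
                    file.exists(x), config)
  digests <- if (length(paths) > 0L) {
    as.list(tools::md5sum(unlist(paths)))
  } else {
    list()
  }
  list(tool = "proximarker",
       version = as.character(utils::packageVersion("proximarker")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seeds = seeds,
       input_digests = digests,
       counts = counts)
}

#' Discovery pipeline: proximity filtering, activity, training, ranking
#'
#' Runs the discovery half of the framework: read/filter the network (score
#' threshold, largest connected component), filter pathways and drug targets
#' to the network, select pathways proximal to the drug's targets, compute
#' organoid pathway activity (log2(x+1) on raw input, ssGSEA NES,
#' per-pathway z-standardization), and train the IC50 regression on the
#' proximal pathways' activities.
#'
#' @param config Named list. Inputs (each a file path or the in-memory
#'   object): `network` (edge-list TSV / igraph), `pathways` (GMT / named
#'   list), `targets` (TSV / named list), `organoid_expr` (TSV /
#'   `expr_matrix`), `organoid_ic50` (TSV / named vector). Parameters:
#'   `drug` (name in the target table; default its first entry),
#'   `min_score` (default 700), `alpha` (0.10), `n_iter` (1000),
#'   `min_bin_size` (NULL = automatic), `model` ("ridge"), `log2p1`
#'   (TRUE when organoid expression is raw-scale), `seed` (required).
#' @param out_dir Optional directory for intermediate TSVs and the manifest.
#' @return List of class `discovery_result`: `proximity` (per-pathway
#'   records), `proximal` (names), `activity` (organoid NES, standardized),
#'   `ranking` (`coef_ranking`), `network`, `pathways`, `targets`,
#'   `manifest`.
#' @export
run_discovery <- function(config, out_dir = NULL) {
  if (is.null(config$seed)) stop("config$seed is required")
  seed <- as.integer(config$seed)
  min_score <- config$min_score %||% 700
  alpha <- config$alpha %||% 0.10
  n_iter <- config$n_iter %||% 1000L
  model <- config$model %||% "ridge"

  net <- resolve_input(config$network, read_edge_list, min_score = min_score)
  net <- largest_connected_component(net)
  pathways <- resolve_input(config$pathways, read_gmt)
  pathways <- filter_to_network(pathways, net)
  targets <- resolve_input(config$targets, read_drug_targets)
  targets <- filter_targets_to_network(targets, net)
  drug <- config$drug %||% names(targets)[1L]
  if (!drug %in% names(targets)) stop("unknown drug: ", drug)

  prox <- select_proximal_pathways(net, targets[[drug]], pathways,
                                   alpha = alpha, n_iter = n_iter,
                                   min_bin_size = config$min_bin_size,
                                   seed = stage_seed(seed, "proximity"))
  proximal <- prox$pathway[prox$proximal]
  message(length(proximal), " of ", nrow(prox), " pathways proximal to ",
          drug, " targets at alpha = ", alpha)
  if (length(proximal) == 0L) {
    stop("no proximal pathways at alpha=", alpha, "; nothing to train")
  }

  expr <- resolve_input(config$organoid_expr, read_expression)
  if (config$log2p1 %||% (value_scale(expr) == "raw")) {
    expr <- log2_plus_one(expr)
  }
  y <- resolve_input(config$organoid_ic50, read_response)
  nes <- ssgsea_scores(expr, pathways)
  act <- standardize(nes)
  feats <- intersect(proximal, rownames(act))
  ranking <- fit_model(unclass(act)[feats, , drop = FALSE], y, kind = model,
                       seed = stage_seed(seed, "folds"),
                       log10_ic50 = isTRUE(config$log10_ic50))

  manifest <- run_manifest(config,
                           seeds = list(master = seed,
                                        proximity = stage_seed(seed, "proximity"),
                                        folds = stage_seed(seed, "folds")),
                           counts = list(nodes = igraph::vcount(net),
                                         edges = igraph::ecount(net),
                                         pathways = length(pathways),
                                         proximal = length(proximal),
                                         organoids = ncol(act),
                                         features_trained = length(feats)))
  res <- list(proximity = prox, proximal = proximal, activity = act,
              response = y, ranking = ranking, network = net,
              pathways = pathways, targets = targets, drug = drug,
              manifest = manifest)
  class(res) <- "discovery_result"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(prox, file.path(out_dir, "proximity.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cf <- data.frame(feature = names(ranking$coefficients),
                     beta = unname(ranking$coefficients),
                     abs_beta = abs(unname(ranking$coefficients)),
                     rank = unname(ranking$ranks),
                     alpha = ranking$alpha)
    utils::write.table(cf[order(cf$rank), ],
                       file.path(out_dir, "coefficients.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_expression(act, file.path(out_dir, "organoid_nes.tsv"),
                     label = "pathway")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

#' Validation pipeline: patient scoring, survival, concordance, bootstrap
#'
#' Runs the validation half of the framework on a discovery result: computes
#' patient pathway activity (same transforms as discovery, standardized
#' within the patient dataset), scores patients with the top `n_top`
#' biomarker coefficients, median-splits each cohort into responders and
#' non-responders, compares overall survival by log-rank in the treated and
#' untreated cohorts, and optionally runs the isogenic contrast, the
#' mutation-concordance test and the random-pathway bootstrap.
#'
#' @param discovery A `discovery_result` from [run_discovery()].
#' @param config Named list. Inputs: `patient_expr` (TSV / `expr_matrix`),
#'   `clinical` (TSV / data frame), optional `isogenic_expr` and
#'   `isogenic_labels` (TSV / objects), optional `mutation_col` naming a
#'   logical column of the clinical table. Parameters: `n_top` (default 1),
#'   `bootstrap_iter` (0 = skip bootstrap), `mutation_alternative`
#'   ("greater"), `seed` (defaults to the discovery seed).
#' @param out_dir Optional directory for the report TSVs.
#' @return List of class `validation_result`: `scores` (both cohorts, with
#'   classes), `survival` (`biomarker_validation`), `isogenic`,
#'   `concordance`, `bootstrap`, `manifest`.
#' @export
run_validation <- function(discovery, config, out_dir = NULL) {
  if (!inherits(discovery, "discovery_result")) {
    stop("run_discovery() output required")
  }
  seed <- as.integer(config$seed %||% discovery$manifest$seeds$master)
  n_top <- config$n_top %||% 1L

  p_expr <- resolve_input(config$patient_expr, read_expression)
  if (value_scale(p_expr) == "raw") p_expr <- log2_plus_one(p_expr)
  clinical <- resolve_input(config$clinical, read_clinical)
  nes <- ssgsea_scores(p_expr, discovery$pathways)
  p_act <- standardize(nes)

  all_scores <- score_patients(p_act, discovery$ranking, n_top = n_top)
  split_cohort <- function(flag) {
    ids <- clinical$patient_id[clinical$treated == flag]
    median_split(all_scores[all_scores$patient_id %in% ids, , drop = FALSE])
  }
  scores_treated <- split_cohort(TRUE)
  scores_untreated <- split_cohort(FALSE)
  surv <- validate_biomarker(clinical, scores_treated, scores_untreated)

  iso <- NULL
  iso_act <- NULL
  iso_labels <- NULL
  if (!is.null(config$isogenic_expr)) {
    iso_expr <- resolve_input(config$isogenic_expr, read_expression)
    if (value_scale(iso_expr) == "raw") iso_expr <- log2_plus_one(iso_expr)
    iso_labels <- config$isogenic_labels
    if (is.character(iso_labels) && length(iso_labels) == 1L &&
        file.exists(iso_labels)) {
      iso_labels <- utils::read.delim(iso_labels)$label
    }
    iso_act <- standardize(ssgsea_scores(iso_expr, discovery$pathways))
    top1 <- top_features(discovery$ranking, 1L)
    iso <- isogenic_contrast(iso_act, iso_labels, top1)
  }

  conc <- NULL
  if (!is.null(config$mutation_col)) {
    status <- stats::setNames(as.logical(clinical[[config$mutation_col]]),
                              clinical$patient_id)
    conc <- mutation_concordance(
      scores_treated, status[scores_treated$patient_id],
      alternative = config$mutation_alternative %||% "greater"
    )
  }

  boot <- NULL
  boot_iter <- config$bootstrap_iter %||% 0L
  if (boot_iter > 0L) {
    if (is.null(iso_act)) stop("bootstrap needs isogenic inputs")
    org_act_all <- discovery$activity
    # bootstrap draws from the full filtered collection; activities for all
    # pathways are needed, so recompute on the complete collection once
    if (!all(names(discovery$pathways) %in% rownames(org_act_all))) {
      stop("discovery activity must cover the full pathway collection")
    }
    boot <- bootstrap_empirical_p(
      pathways = rownames(org_act_all),
      k = length(discovery$proximal),
      organoid_activity = org_act_all,
      y = discovery$response,
      observed_ranking = discovery$ranking,
      patient_activity = p_act, clinical = clinical,
      isogenic_activity = iso_act, isogenic_labels = iso_labels,
      n_iter = boot_iter, seed = stage_seed(seed, "bootstrap")
    )
  }

  manifest <- run_manifest(config,
                           seeds = list(master = seed),
                           counts = list(patients = ncol(p_act),
                                         treated = nrow(scores_treated),
                                         untreated = nrow(scores_untreated),
                                         n_pathways_used = n_top))
  res <- list(scores = rbind(scores_treated, scores_untreated),
              survival = surv, isogenic = iso, concordance = conc,
              bootstrap = boot, manifest = manifest)
  class(res) <- "validation_result"
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(res$scores, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep <- data.frame(
      cohort = c("treated", "untreated"),
      n_responder = c(surv$treated$n_responder, surv$untreated$n_responder),
      n_nonresponder = c(surv$treated$n_nonresponder,
                         surv$untreated$n_nonresponder),
      logrank_chi2 = c(surv$treated$logrank_chi2, surv$untreated$logrank_chi2),
      p = c(surv$treated$p, surv$untreated$p)
    )
    utils::write.table(rep, file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
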