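#' Default pipeline configuration
#'
#' One nested list with a block per stage; every analysis threshold lives
#' here (selection FDR 0.001, VIP > 1, network edge FDR 1e-07 and rho 0.38,
#' clinical report cuts 0.12 / 0.07 / 0.01, structural FDR 0.01), never in
#' the stage logic. The rdCV block defaults to a desk-scale setting
#' (2 repetitions, 5 outer folds); [rdcv_rf_select()] itself defaults to the
#' fuller 5 x 6 schedule.
#'
#' @param seed Master seed (default 1).
#' @return A nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    input = list(synthetic = TRUE, dir = NULL),
    cohort = list(),                     # overrides for cohort_config()
    preprocess = list(zeros_as_missing = TRUE, freq_ratio_cut = 19,
                      unique_cut_pct = 10),
    differential = list(q_cut = 0.001),
    plsda = list(n_components = 2, vip_cut = 1, k_folds = 7,
                 standardize = TRUE),
    rf = list(n_rep = 2, n_outer = 5, var_ratio = 0.75, tol = 0.05,
              num_trees = 100),
    structure = list(q_cut = 0.01),
    network = list(fdr_cut = 1e-07, rho_cut = 0.38, resolution = 1,
                   n_null = 50, leiden_seed = 1, community_q = 0.12,
                   feature_q = 0.01, top_fraction = 0.1)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults of
#' [default_pipeline_config()]; absent blocks keep their defaults.
#'
#' @param path YAML file path.
#' @return A configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(default_pipeline_config())
  utils::modifyList(default_pipeline_config(), user)
}

#' Read cohort inputs from a directory
#'
#' Expects the files written by [write_cohort()]: `lipids.csv`,
#' `metabolites.csv`, `clinical.csv` and optionally `truth.json`.
#'
#' @param dir Input directory.
#' @return A list shaped like a [generate_cohort()] result (class
#'   `synthetic_cohort` without a config).
#' @export
read_cohort <- function(dir) {
  clin <- utils::read.csv(file.path(dir, "clinical.csv"),
                          stringsAsFactors = FALSE)
  group <- factor(clin$group, levels = unique(clin$group))
  lipids <- read_abundance(file.path(dir, "lipids.csv"), group)
  mets <- read_abundance(file.path(dir, "metabolites.csv"), group)
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    unlist(jsonlite::read_json(truth_path, simplifyVector = TRUE))
  } else character(0)
  structure(list(lipids = lipids, metabolites = mets, clinical = clin,
                 truth = truth,
                 lipid_meta = parse_lipid_names(rownames(lipids$values)),
                 config = NULL),
            class = "synthetic_cohort")
}

#' Run the full analysis pipeline
#'
#' Executes preprocess (minimum imputation, median centering,
#' near-zero-variance filter, log transform), the four-method differential
#' analysis (Mann-Whitney on centered raw data, moderated t on log data,
#' PLS-DA VIP, rdCV random forest), the consensus intersection, the
#' structural composition map, the lipid-metabolite network stage (Spearman
#' network, Erdos-Renyi null, Leiden communities, degree hubs,
#' community- and feature-clinical regression, class-term ORA) and the
#' clinical cohort comparison. When `out_dir` is set, TSV/GraphML/JSON
#' outputs and a run manifest are written.
#'
#' @param config Configuration list, see [default_pipeline_config()].
#' @param cohort Optional pre-built cohort (a [generate_cohort()] /
#'   [read_cohort()] result); otherwise generated or read per
#'   `config$input`.
#' @param out_dir Optional output directory.
#' @param stages Character vector of stages to run, a prefix-closed subset
#'   of `c("preprocess", "differential", "consensus", "structure",
#'   "network", "cohort_stats")`; later stages require the earlier ones.
#' @param verbose Narrate feature counts per stage (default TRUE).
#' @return An object of class `pipeline_result`.
#' @export
run_pipeline <- function(config = default_pipeline_config(), cohort = NULL,
                         out_dir = NULL,
                         stages = c("preprocess", "differential",
                                    "consensus", "structure", "network",
                                    "cohort_stats"),
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stages <- match.arg(stages, several.ok = TRUE)

  if (is.null(cohort)) {
    if (isTRUE(config$input$synthetic)) {
      cc <- do.call(cohort_config,
                    utils::modifyList(list(seed = config$seed),
                                      config$cohort))
      cohort <- generate_cohort(cc)
      say("generated synthetic cohort: %d lipids, %d metabolites, %d samples",
          nrow(cohort$lipids$values), nrow(cohort$metabolites$values),
          ncol(cohort$lipids$values))
    } else {
      if (is.null(config$input$dir)) stop("config$input$dir is required")
      cohort <- read_cohort(config$input$dir)
      say("read cohort from %s", config$input$dir)
    }
  }
  meta <- cohort$lipid_meta
  res <- list(cohort = cohort, config = config)
  counts_log <- c(input_features = nrow(cohort$lipids$values))

  # --- preprocess -----------------------------------------------------
  pp <- config$preprocess
  centered <- impute_and_center(cohort$lipids,
                                zeros_as_missing = pp$zeros_as_missing)
  nzv <- filter_near_zero_variance(centered, pp$freq_ratio_cut,
                                   pp$unique_cut_pct)
  lipids_c <- nzv$matrix
  lipids_log <- log_transform(lipids_c)
  mets_c <- impute_and_center(cohort$metabolites,
                              zeros_as_missing = pp$zeros_as_missing)
  mets_log <- log_transform(mets_c)
  say("near-zero-variance filter removed %d of %d features",
      length(nzv$removed), nrow(centered$values))
  counts_log["after_nzv"] <- nrow(lipids_c$values)
  res$preprocess <- list(lipids_centered = lipids_c,
                         lipids_log = lipids_log,
                         metabolites_log = mets_log,
                         removed = nzv$removed)
  if (!("differential" %in% stages)) return(.finish_pipeline(res, counts_log, out_dir))

  # --- four-method differential --------------------------------------
  q_cut <- config$differential$q_cut
  res$mann_whitney <- diff_mann_whitney(lipids_c, q_cut = q_cut)
  res$moderated <- fit_moderated(lipids_log, q_cut = q_cut)
  pl <- config$plsda
  res$plsda <- fit_plsda(lipids_log, n_components = pl$n_components,
                         standardize = pl$standardize)
  res$q2y <- q2y(lipids_log, n_components = pl$n_components,
                 k_folds = pl$k_folds, seed = config$seed,
                 standardize = pl$standardize)
  res$rf <- rdcv_rf_select(lipids_log,
                           params = config$rf, seed = config$seed)
  say("selected: MW %d, moderated %d, VIP>%g %d, RF max %d",
      length(res$mann_whitney$selected), length(res$moderated$selected),
      pl$vip_cut, sum(res$plsda$vip > pl$vip_cut),
      length(res$rf$max_set))
  if (!("consensus" %in% stages)) return(.finish_pipeline(res, counts_log, out_dir))

  # --- consensus ------------------------------------------------------
  universe <- rownames(lipids_c$values)
  vip_set <- names(res$plsda$vip)[res$plsda$vip > pl$vip_cut]
  res$consensus <- consensus_features(
    list(mann_whitney = res$mann_whitney$selected,
         moderated_t = res$moderated$selected,
         plsda_vip = vip_set,
         rf_rdcv = res$rf$max_set),
    universe = universe)
  counts_log["consensus"] <- length(res$consensus$intersection)
  say("consensus intersection: %d features",
      length(res$consensus$intersection))
  if (!("structure" %in% stages)) return(.finish_pipeline(res, counts_log, out_dir))

  # --- structural composition ----------------------------------------
  meta_kept <- meta[meta$name %in% universe, ]
  res$composition <- composition_map(res$moderated$table, meta_kept,
                                     q_cut = config$structure$q_cut)
  res$trends <- class_trend_summary(res$composition)
  if (!("network" %in% stages)) return(.finish_pipeline(res, counts_log, out_dir))

  # --- network integration -------------------------------------------
  nw <- config$network
  combined <- abundance_matrix(
    rbind(lipids_log$values, mets_log$values),
    lipids_log$group, scale = "log")
  node_type <- stats::setNames(
    c(rep("lipid", nrow(lipids_log$values)),
      rep("metabolite", nrow(mets_log$values))),
    rownames(combined$values))
  res$network <- spearman_network(combined, node_type = node_type,
                                  fdr_cut = nw$fdr_cut,
                                  rho_cut = nw$rho_cut)
  say("network: %d nodes, %d edges", igraph::vcount(res$network$graph),
      igraph::ecount(res$network$graph))
  res$null_comparison <- er_null_compare(res$network, n_draws = nw$n_null,
                                         seed = config$seed)
  res$partition <- detect_communities(res$network,
                                      resolution = nw$resolution,
                                      seed = nw$leiden_seed,
                                      species = meta_kept)
  res$hubs <- centrality_rank(res$network,
                              top_fraction = nw$top_fraction)
  res$community_assoc <- community_clinical_assoc(
    res$partition, combined, cohort$clinical)
  res$feature_assoc_vat <- feature_clinical_assoc(
    combined, cohort$clinical$vat, q_cut = nw$feature_q)
  largest <- res$partition$summary$community[1]
  members <- names(res$partition$membership)[
    res$partition$membership == largest]
  annotation <- split(meta_kept$name, meta_kept$class)
  res$ora <- ora_enrichment(members, annotation,
                            background = igraph::V(res$network$graph)$name)
  if (!("cohort_stats" %in% stages)) return(.finish_pipeline(res, counts_log, out_dir))

  # --- cohort comparison ---------------------------------------------
  res$cohort_comparison <- cohort_table(cohort$clinical)

  .finish_pipeline(res, counts_log, out_dir)
}

.finish_pipeline <- function(res, counts_log, out_dir) {
  cfg <- res$config
  res$manifest <- list(
    package_version = as.character(utils::packageVersion("lipidmets")),
    seed = cfg$seed,
    thresholds = list(
      differential_fdr = cfg$differential$q_cut,
      vip = cfg$plsda$vip_cut,
      network_edge_fdr = cfg$network$fdr_cut,
      network_rho = cfg$network$rho_cut,
      community_clinical_fdr = cfg$network$community_q,
      feature_clinical_fdr = cfg$network$feature_q,
      structural_fdr = cfg$structure$q_cut),
    leiden_seed = cfg$network$leiden_seed,
    feature_counts = as.list(counts_log))
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  features after filtering: %s\n",
              x$manifest$feature_counts$after_nzv))
  if (!is.null(x$consensus))
    cat(sprintf("  consensus: %d features\n",
                length(x$consensus$intersection)))
  if (!is.null(x$network))
    cat(sprintf("  network: %d nodes, %d edges, %d communities (>= 3 members, %d singletons)\n",
                igraph::vcount(x$network$graph),
                igraph::ecount(x$network$graph),
                sum(x$partition$summary$size >= 3),
                sum(x$partition$summary$size == 1)))
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' TSV tables per stage, GraphML + weighted edge list for the network, and
#' a JSON run manifest recording versions, seeds, thresholds and the
#' feature-universe sizes at each stage.
#'
#' @param res A [run_pipeline()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(res, out_dir) {
  stopifnot(inherits(res, "pipeline_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  meta <- res$cohort$lipid_meta
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$mann_whitney))
    write_differential(res$mann_whitney, meta,
                       file.path(out_dir, "mann_whitney.tsv"))
  if (!is.null(res$moderated))
    write_differential(res$moderated, meta,
                       file.path(out_dir, "moderated_t.tsv"))
  if (!is.null(res$plsda))
    wt(data.frame(feature_id = names(res$plsda$vip),
                  vip = unname(res$plsda$vip)), "vip.tsv")
  if (!is.null(res$rf)) {
    wt(res$rf$validation_curve, "rf_validation_curve.tsv")
    wt(data.frame(model = names(res$rf$auroc),
                  n_features = unname(res$rf$n_features),
                  auroc = unname(res$rf$auroc)), "rf_models.tsv")
  }
  if (!is.null(res$consensus)) {
    wt(res$consensus$upset, "upset_intersections.tsv")
    wt(data.frame(feature_id = res$consensus$intersection),
       "consensus.tsv")
  }
  if (!is.null(res$composition))
    write_composition_map(res$composition,
                          file.path(out_dir, "composition_map.tsv"))
  if (!is.null(res$network)) {
    write_network_graphml(res$network, file.path(out_dir, "network.graphml"))
    write_edge_list(res$network, file.path(out_dir, "network_edges.tsv"))
    wt(data.frame(node = names(res$partition$membership),
                  community = unname(res$partition$membership)),
       "communities.tsv")
    wt(as.data.frame(res$community_assoc), "community_clinical.tsv")
    wt(as.data.frame(res$feature_assoc_vat), "feature_vat.tsv")
    wt(res$ora, "ora.tsv")
  }
  if (!is.null(res$cohort_comparison))
    wt(as.data.frame(res$cohort_comparison), "cohort_table.tsv")
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
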