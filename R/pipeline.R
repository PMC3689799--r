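# End-to-end orchestration: differential expression -> profile clustering ->
# category enrichment -> genomic distribution -> optional cross-species
# overlap, with every threshold echoed in the run report and all randomness
# derived from the single configured seed.

#' Run the full analysis pipeline
#'
#' @param dataset `expression_dataset`.
#' @param gene_map validated gene map covering the dataset's genes.
#' @param config `analysis_config`.
#' @param categories optional named list of category gene sets for
#'   enrichment; when NULL, categories are collected from the gene map's
#'   `categories` column plus the secretome classifier labels.
#' @param ortholog_pairs optional pair data.frame for cross-species overlap.
#' @param set_b optional regulated gene set of the comparison species (B
#'   identifiers); required for the overlap stage.
#' @param out_dir optional directory; when given, all stage tables are
#'   written as TSV plus a JSON run summary.
#' @return `run_report` list: `de`, `kinetics`, `clustering`, `enrichment_up`,
#'   `enrichment_down`, `runs_up`, `runs_down`, `null_table_up`,
#'   `null_table_down`, `chromosome_enrichment`, `window_density`, `overlap`
#'   (or NULL), `config`.
#' @export
run_pipeline <- function(dataset, gene_map, config = analysis_config(),
                         categories = NULL, ortholog_pairs = NULL,
                         set_b = NULL, out_dir = NULL) {
  validate_gene_map(gene_map)
  stage <- function(name, expr) {
    tryCatch(expr, incompatscan_error = function(e) {
      isc_stop(paste0("stage '", name, "': ", conditionMessage(e)),
               "isc_stage_error")
    })
  }

  de <- stage("differential_expression", call_genes(dataset, config))
  kin <- summarize_kinetics(de, config)
  sets <- regulated_sets(de)

  pm <- profile_matrix(de, config)
  clust <- if (nrow(pm) > max(config$kmeans_k, config$min_cluster_size))
    stage("clustering", cluster_profiles(pm, config)) else NULL

  if (is.null(categories)) {
    categories <- list()
    if (!is.null(gene_map$categories)) {
      all_labels <- unique(unlist(gene_map$categories))
      for (lab in all_labels)
        categories[[lab]] <- gene_map$gene_id[
          vapply(gene_map$categories, function(x) lab %in% x, logical(1))]
    }
    if (!is.null(gene_map$secreted))
      categories <- c(categories, secretome_categories(gene_map))
  }
  universe <- gene_map$gene_id
  enr_up <- if (length(categories) > 0)
    stage("enrichment", enrich_categories(sets$up, categories, universe)) else NULL
  enr_down <- if (length(categories) > 0)
    stage("enrichment", enrich_categories(sets$down, categories, universe)) else NULL

  g_placed <- sum(gene_map$chromosome != "UNPLACED")
  runs_up <- stage("genomic_distribution", detect_runs(gene_map, sets$up))
  runs_down <- stage("genomic_distribution", detect_runs(gene_map, sets$down))
  null_up <- run_null_table(runs_up, g_placed, config)
  null_down <- run_null_table(runs_down, g_placed, config)
  chrom <- chromosome_enrichment(gene_map, sets$up)
  dens <- sliding_window_density(gene_map, sets$up, window = config$window_size)

  overlap <- NULL
  if (!is.null(ortholog_pairs) && !is.null(set_b))
    overlap <- stage("cross_species", ortholog_overlap(ortholog_pairs, sets$up, set_b))

  report <- structure(list(
    de = de, kinetics = kin, clustering = clust,
    enrichment_up = enr_up, enrichment_down = enr_down,
    runs_up = runs_up, runs_down = runs_down,
    null_table_up = null_up, null_table_down = null_down,
    chromosome_enrichment = chrom, window_density = dens,
    overlap = overlap, config = config
  ), class = "run_report")

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' Write all run-report tables under a directory
#'
#' Tab-separated tables per stage plus `summary.json` echoing the
#' configuration, seed, and headline counts.
#'
#' @param report `run_report`.
#' @param out_dir destination directory (created if needed).
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wt(report$de, "differential_expression.tsv")
  wt(report$kinetics$per_time, "kinetics.tsv")
  if (!is.null(report$enrichment_up)) wt(report$enrichment_up, "enrichment_up.tsv")
  if (!is.null(report$enrichment_down)) wt(report$enrichment_down, "enrichment_down.tsv")
  wt(report$runs_up$runs, "runs_up.tsv")
  wt(report$runs_down$runs, "runs_down.tsv")
  wt(report$null_table_up, "null_model_up.tsv")
  wt(report$null_table_down, "null_model_down.tsv")
  wt(report$chromosome_enrichment, "chromosome_enrichment.tsv")
  wt(report$window_density, "window_density.tsv")
  if (!is.null(report$clustering)) {
    memb <- do.call(rbind, lapply(names(report$clustering$clustering$clusters),
      function(nm) data.frame(gene_id = report$clustering$clustering$clusters[[nm]],
                              robust_cluster = nm, stringsAsFactors = FALSE)))
    wt(memb, "robust_clusters.tsv")
    wt(report$clustering$centroids, "cluster_centroids.tsv")
  }
  counts <- report$kinetics$status_counts
  summary <- list(
    config = unclass(report$config),
    status_counts = as.list(stats::setNames(as.integer(counts), names(counts))),
    n_robust_clusters = if (!is.null(report$clustering))
      length(report$clustering$clustering$clusters) else 0L,
    overlap = if (!is.null(report$overlap)) unclass(report$overlap) else NULL
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report\n")
  print(x$kinetics$status_counts)
  cat("robust clusters:", if (!is.null(x$clustering))
    length(x$clustering$clustering$clusters) else 0, "\n")
  cat("up-regulated maximal runs >= 2:", sum(x$runs_up$counts_by_length), "\n")
  invisible(x)
}
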