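#' Pipeline configuration
#'
#' Collects every stage threshold with the pipeline's defaults (the
#' conventional gates: |log2FC| > 1 and FDR < 0.05 per study, combined
#' p < 0.05 in >= 2 stress types, co-expression adjusted p < 5e-4,
#' k = 5 profile groups, 1000 trees) plus the seed and output directory.
#'
#' @param normalize Quantile-normalize each dataset before the contrast.
#'   Default `FALSE`: the pipeline's canonical inputs are already
#'   normalized log2 matrices (RMA or equivalent happens upstream);
#'   enable for inputs that still need across-sample normalization.
#' @param lfc_threshold Per-study absolute log2FC gate.
#' @param deg_fdr Per-study FDR gate.
#' @param meta_p Combined-p gate for common-responsive calling.
#' @param meta_adjust BH-adjust combined p-values within each stress
#'   type before the gate (default `TRUE`; see
#'   [call_common_responsive()]).
#' @param min_stress_types Minimum stress types passing.
#' @param edge_fdr Adjusted-p gate for co-expression edges.
#' @param k Number of k-means profile groups.
#' @param n_trees Random-forest trees per target.
#' @param grn_top_n Directed edges kept after importance thresholding.
#' @param seed Integer seed.
#' @param out_dir Optional output directory; `NULL` keeps everything in
#'   memory.
#' @return Object of class `pipeline_config` (validated list).
#' @export
pipeline_config <- function(normalize = FALSE, lfc_threshold = 1,
                            deg_fdr = 0.05, meta_p = 0.05,
                            meta_adjust = TRUE, min_stress_types = 2L,
                            edge_fdr = 5e-4, k = 5L, n_trees = 1000L,
                            grn_top_n = 100L, seed = 1L, out_dir = NULL) {
  cfg <- list(normalize = isTRUE(normalize), lfc_threshold = lfc_threshold,
              deg_fdr = deg_fdr,
              meta_p = meta_p, meta_adjust = isTRUE(meta_adjust),
              min_stress_types = as.integer(min_stress_types),
              edge_fdr = edge_fdr, k = as.integer(k),
              n_trees = as.integer(n_trees), grn_top_n = as.integer(grn_top_n),
              seed = as.integer(seed), out_dir = out_dir)
  if (cfg$lfc_threshold < 0) stop("'lfc_threshold' must be >= 0")
  for (f in c("deg_fdr", "meta_p", "edge_fdr"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop("'", f, "' must lie in (0, 1)")
  if (cfg$min_stress_types < 1L) stop("'min_stress_types' must be >= 1")
  if (cfg$k < 1L) stop("'k' must be >= 1")
  if (cfg$n_trees < 1L) stop("'n_trees' must be >= 1")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' [pipeline_config()].
#'
#' @param path Path to a YAML file.
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Validate pipeline inputs
#'
#' Checks matrix/sample-sheet consistency, duplicate identifiers, value
#' sanity (a warning when the values look unlogged, i.e. max > 30), and
#' TF-list membership. Never throws: problems are returned as report
#' rows.
#'
#' @param datasets List of per-study entries (`matrix` + `sample_info`),
#'   as produced by [simulate_multistudy()] or [read_datasets()].
#' @param tfs Optional TF list to check against the gene identifiers.
#' @return data.frame of class `validation_report` with columns
#'   `severity` ("error"/"warning") and `message`; attribute `ok` is
#'   `TRUE` when no errors were found.
#' @export
validate_inputs <- function(datasets, tfs = NULL) {
  rows <- list()
  note <- function(severity, message)
    rows[[length(rows) + 1L]] <<- data.frame(severity = severity,
                                             message = message,
                                             stringsAsFactors = FALSE)
  for (d in datasets) {
    id <- if (!is.null(d$study)) d$study else "<unnamed>"
    m <- d$matrix
    info <- d$sample_info
    if (anyDuplicated(rownames(m)))
      note("error", paste0(id, ": duplicate gene identifiers"))
    if (anyDuplicated(colnames(m)))
      note("error", paste0(id, ": duplicate sample identifiers"))
    missing_in_matrix <- setdiff(info$sample, colnames(m))
    for (s in missing_in_matrix)
      note("error", paste0(id, ": sample '", s, "' in sheet but not in matrix"))
    extra <- setdiff(colnames(m), info$sample)
    for (s in extra)
      note("warning", paste0(id, ": sample '", s, "' in matrix but not in sheet"))
    if (any(!is.finite(m)))
      note("error", paste0(id, ": non-finite expression values"))
    else if (max(m) > 30)
      note("warning", paste0(id, ": values appear unlogged (max = ",
                             format(max(m), digits = 4), " > 30)"))
    if (!all(c("control", "stress") %in% info$condition))
      note("error", paste0(id, ": needs both 'control' and 'stress' samples"))
  }
  if (!is.null(tfs) && length(datasets)) {
    genes <- rownames(datasets[[1L]]$matrix)
    miss <- setdiff(tfs, genes)
    if (length(miss))
      note("warning", paste0("TF(s) absent from the matrices: ",
                             paste(utils::head(miss, 5L), collapse = ", ")))
  }
  report <- if (length(rows)) do.call(rbind, rows)
            else data.frame(severity = character(0), message = character(0),
                            stringsAsFactors = FALSE)
  structure(report, ok = !any(report$severity == "error"),
            class = c("validation_report", "data.frame"))
}

#' Read a compendium written by [write_simulation()] back from disk
#'
#' @param dir Directory containing per-study TSV matrices and
#'   `sample_sheet.tsv`.
#' @return List with `datasets` and `sample_sheet` in the layout of
#'   [simulate_multistudy()].
#' @export
read_datasets <- function(dir) {
  sheet <- utils::read.delim(file.path(dir, "sample_sheet.tsv"),
                             stringsAsFactors = FALSE)
  datasets <- list()
  for (st in unique(sheet$study)) {
    info <- sheet[sheet$study == st, , drop = FALSE]
    m <- read_expression_tsv(file.path(dir, paste0(st, ".tsv")))
    datasets[[st]] <- list(matrix = m, sample_info = info,
                           stress = info$stress[1L], study = st)
  }
  list(datasets = datasets, sample_sheet = sheet)
}

#' Run the full meta-analysis and network pipeline
#'
#' Executes normalization, per-study differential expression,
#' cross-study inverse-normal combination, common-responsive calling,
#' mutant-set overlap statistics, profile clustering with PCA,
#' co-expression network construction with hub ranking, and (when a
#' regulatory input is supplied) random-forest network inference. Every
#' gate count is recorded in the returned manifest; with `out_dir` set,
#' all intermediate tables are written in plain-text exchange formats
#' and the manifest as JSON. Runs are deterministic for a given seed.
#'
#' @param datasets List of per-study entries (`matrix`, `sample_info`,
#'   `stress`, `study`).
#' @param config A [pipeline_config()].
#' @param mutant_sets Optional named list of genotype-specific gene sets.
#' @param grn_input Optional list with `matrix`, `tfs`, and optionally
#'   `priors` for the directed network stage.
#' @return List of class `pipeline_result` with elements `deg` (per-study
#'   tables), `meta`, `common_responsive`, `overlaps`, `clusters`, `pca`,
#'   `coexpr`, `hubs`, `grn_scores`, `grn_network`, and `manifest`.
#' @export
run_pipeline <- function(datasets, config = pipeline_config(),
                         mutant_sets = NULL, grn_input = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  report <- validate_inputs(datasets)
  if (!attr(report, "ok"))
    stop("input validation failed:\n",
         paste(report$message[report$severity == "error"], collapse = "\n"))

  studies <- list()
  deg_tables <- list()
  for (d in datasets) {
    norm <- if (config$normalize) quantile_normalize(d$matrix) else d$matrix
    grp <- stats::setNames(d$sample_info$condition, d$sample_info$sample)
    deg <- run_deg(norm, grp, contrast = c("stress", "control"),
                   lfc_threshold = config$lfc_threshold,
                   fdr_threshold = config$deg_fdr)
    deg_tables[[d$study]] <- deg
    studies[[d$study]] <- list(stress = d$stress, study = d$study, deg = deg)
  }

  meta <- meta_combine(studies)
  common <- call_common_responsive(meta, p_threshold = config$meta_p,
                                   min_stress_types = config$min_stress_types,
                                   adjust = config$meta_adjust)

  universe <- sort(unique(unlist(lapply(deg_tables, `[[`, "gene"))))
  overlaps <- NULL
  if (!is.null(mutant_sets) && length(common))
    overlaps <- mutant_nutrient_intersections(common, mutant_sets, universe)

  profiles <- build_profile_matrix(studies, genes = common)
  clusters <- NULL
  pca <- NULL
  if (nrow(profiles) >= config$k && ncol(profiles) >= 2L) {
    clusters <- kmeans_profiles(profiles, k = config$k, seed = config$seed)
    pca <- pca_scores(profiles)
  }

  coexpr <- NULL
  hubs <- NULL
  if (length(common) >= 2L) {
    compendium <- do.call(cbind, lapply(datasets, function(d) {
      m <- if (config$normalize) quantile_normalize(d$matrix) else d$matrix
      m[common, , drop = FALSE]
    }))
    coexpr <- correlation_edges(compendium, fdr_threshold = config$edge_fdr)
    hubs <- hub_nodes(coexpr)
  }

  grn_scores <- NULL
  grn_network <- NULL
  if (!is.null(grn_input)) {
    grn_targets <- setdiff(rownames(grn_input$matrix), grn_input$tfs)
    grn_scores <- rf_importance_network(grn_input$matrix, grn_input$tfs,
                                        n_trees = config$n_trees,
                                        priors = grn_input$priors,
                                        targets = grn_targets,
                                        seed = config$seed)
    grn_network <- threshold_directed(grn_scores, top_n = config$grn_top_n)
  }

  manifest <- list(
    seed = config$seed,
    thresholds = config[c("normalize", "lfc_threshold", "deg_fdr", "meta_p",
                          "meta_adjust", "min_stress_types", "edge_fdr", "k",
                          "n_trees", "grn_top_n")],
    n_datasets = length(datasets),
    degs_per_dataset = vapply(deg_tables, function(t) sum(t$is_deg),
                              integer(1L)),
    n_genes_tested = length(universe),
    n_common_responsive = length(common),
    overlaps = overlaps,
    cluster_sizes = if (!is.null(clusters)) clusters$sizes,
    n_coexpr_edges = if (!is.null(coexpr)) nrow(coexpr) else 0L,
    top_hubs = if (!is.null(hubs)) utils::head(hubs, 10L),
    n_grn_edges = if (!is.null(grn_network)) nrow(grn_network) else 0L
  )

  result <- structure(list(deg = deg_tables, meta = meta,
                           common_responsive = common, overlaps = overlaps,
                           clusters = clusters, pca = pca, coexpr = coexpr,
                           hubs = hubs, grn_scores = grn_scores,
                           grn_network = grn_network, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  m <- x$manifest
  cat("Pipeline run (seed ", m$seed, "): ", m$n_datasets, " datasets, ",
      m$n_genes_tested, " genes\n", sep = "")
  cat("  DEGs per dataset: ",
      paste(names(m$degs_per_dataset), m$degs_per_dataset, sep = "=",
            collapse = ", "), "\n", sep = "")
  cat("  common responsive genes:", m$n_common_responsive, "\n")
  if (!is.null(m$overlaps)) {
    cat("  mutant-set overlaps:\n")
    print(m$overlaps)
  }
  cat("  co-expression edges:", m$n_coexpr_edges,
      " | directed GRN edges:", m$n_grn_edges, "\n")
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' DEG tables, per-stress meta tables, the common-responsive set (text
#' and GMT), overlap statistics, cluster assignments and centroids, PCA
#' scores, networks (edge list, SIF, GraphML), GRN scores, and the JSON
#' manifest. Output is deterministic: rerunning with the same seed gives
#' byte-identical files.
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(result$deg))
    write_deg_table(result$deg[[st]], file.path(dir, paste0("deg_", st, ".tsv")))
  write_meta_result(result$meta, dir)
  writeLines(result$common_responsive, file.path(dir, "common_responsive.txt"))
  write_gmt(list(common_responsive = result$common_responsive),
            file.path(dir, "common_responsive.gmt"))
  if (!is.null(result$overlaps))
    utils::write.table(result$overlaps, file.path(dir, "overlaps.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$clusters)) {
    utils::write.table(
      data.frame(gene = names(result$clusters$cluster),
                 group = unname(result$clusters$cluster)),
      file.path(dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_expression_tsv(result$clusters$centroids,
                         file.path(dir, "centroids.tsv"), id_column = "group")
  }
  if (!is.null(result$pca))
    write_expression_tsv(result$pca$scores, file.path(dir, "pca_scores.tsv"))
  if (!is.null(result$coexpr)) {
    write_edge_list(result$coexpr, file.path(dir, "coexpr_edges.tsv"))
    write_sif(result$coexpr, file.path(dir, "coexpr.sif"))
    write_graphml(result$coexpr, file.path(dir, "coexpr.graphml"))
    utils::write.table(result$hubs, file.path(dir, "hubs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$grn_scores)) {
    write_grn_scores(result$grn_scores, file.path(dir, "grn_scores.tsv"))
    write_edge_list(result$grn_network, file.path(dir, "grn_edges.tsv"))
    write_graphml(result$grn_network, file.path(dir, "grn.graphml"),
                  tfs = attr(result$grn_network, "tfs"))
  }
  manifest <- result$manifest
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(dir)
}
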