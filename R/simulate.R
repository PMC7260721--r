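#' Configuration for the synthetic multi-study generator
#'
#' Collects every knob of the synthetic-data layer: the multi-study
#' expression design (several independent studies per stress type, a
#' control and a treatment group with a few replicates each, Gaussian
#' noise on the log2 scale), the planted gene sets (per-stress responsive
#' genes, a common pool responsive under two or more stresses, two
#' genotype-specific sets with fixed intersections with the common pool),
#' and a TF-to-target regulatory layer with an optional prior-knowledge
#' matrix for network inference.
#'
#' @param n_genes Number of genes in every study.
#' @param stress_types Character vector of stress labels.
#' @param studies_per_stress Independent studies simulated per stress type.
#' @param samples_per_group Replicates per condition group (>= 2).
#' @param frac_responsive_per_stress Fraction of genes truly responsive to
#'   each stress, in (0, 1).
#' @param frac_common_responsive Fraction of each stress's responsive genes
#'   drawn from the shared pool that responds to two or more stresses,
#'   in (0, 1).
#' @param effect_lfc_mean,effect_lfc_sd Mean and sd (log2 units) of the
#'   absolute log2 fold change of true responders.
#' @param noise_sd Residual standard deviation on the log2 scale.
#' @param n_mutant_specific Named integer vector (two genotypes) with the
#'   sizes of the genotype-specific gene sets.
#' @param planted_intersection Named integer vector (same names) with the
#'   planted intersection size of each genotype set with the common
#'   responsive pool.
#' @param n_tfs,targets_per_tf Regulatory-layer dimensions: number of
#'   transcription factors and targets regulated per TF.
#' @param n_grn_samples Samples simulated for the regulatory layer.
#' @param grn_signal_sd Scale of the TF-to-target coupling coefficients.
#' @param grn_noise_sd Residual sd of target expression given its parents.
#' @param prior_accuracy Fraction of prior mass concentrated on true edges,
#'   in \[0, 1\].
#' @param seed Master seed; identical seeds give bit-identical output.
#' @return Object of class `sim_config` (a validated list).
#' @export
simulate_config <- function(n_genes = 2000L,
                            stress_types = c("Fe-def", "Zn-def", "Zn-excess"),
                            studies_per_stress = 4L,
                            samples_per_group = 3L,
                            frac_responsive_per_stress = 0.05,
                            frac_common_responsive = 0.3,
                            effect_lfc_mean = 2,
                            effect_lfc_sd = 0.5,
                            noise_sd = 0.25,
                            n_mutant_specific = c(gpa1 = 150L, agb1 = 120L),
                            planted_intersection = c(gpa1 = 15L, agb1 = 25L),
                            n_tfs = 20L,
                            targets_per_tf = 5L,
                            n_grn_samples = 60L,
                            grn_signal_sd = 1,
                            grn_noise_sd = 0.5,
                            prior_accuracy = 0.8,
                            seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), stress_types = as.character(stress_types),
    studies_per_stress = as.integer(studies_per_stress),
    samples_per_group = as.integer(samples_per_group),
    frac_responsive_per_stress = frac_responsive_per_stress,
    frac_common_responsive = frac_common_responsive,
    effect_lfc_mean = effect_lfc_mean, effect_lfc_sd = effect_lfc_sd,
    noise_sd = noise_sd,
    n_mutant_specific = n_mutant_specific,
    planted_intersection = planted_intersection,
    n_tfs = as.integer(n_tfs), targets_per_tf = as.integer(targets_per_tf),
    n_grn_samples = as.integer(n_grn_samples),
    grn_signal_sd = grn_signal_sd, grn_noise_sd = grn_noise_sd,
    prior_accuracy = prior_accuracy, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk_count <- function(x, field) {
    if (length(x) < 1L || any(!is.finite(x)) || any(x < 1))
      stop("configuration error: '", field, "' must be a positive count")
  }
  chk_count(cfg$n_genes, "n_genes")
  chk_count(cfg$studies_per_stress, "studies_per_stress")
  chk_count(cfg$n_tfs, "n_tfs")
  chk_count(cfg$targets_per_tf, "targets_per_tf")
  chk_count(cfg$n_grn_samples, "n_grn_samples")
  if (cfg$samples_per_group < 2L)
    stop("configuration error: 'samples_per_group' must be >= 2")
  if (length(cfg$stress_types) < 2L || anyDuplicated(cfg$stress_types))
    stop("configuration error: 'stress_types' must be >= 2 unique labels")
  # frac_responsive_per_stress = 0 is allowed as the exact null model
  if (cfg$frac_responsive_per_stress < 0 || cfg$frac_responsive_per_stress >= 1)
    stop("configuration error: 'frac_responsive_per_stress' must be in [0, 1)")
  if (cfg$frac_common_responsive <= 0 || cfg$frac_common_responsive >= 1)
    stop("configuration error: 'frac_common_responsive' must be in (0, 1)")
  if (cfg$noise_sd <= 0)
    stop("configuration error: 'noise_sd' must be positive")
  if (cfg$prior_accuracy < 0 || cfg$prior_accuracy > 1)
    stop("configuration error: 'prior_accuracy' must be in [0, 1]")
  nm <- names(cfg$n_mutant_specific)
  if (is.null(nm) || !identical(sort(nm), sort(names(cfg$planted_intersection))))
    stop("configuration error: 'n_mutant_specific' and 'planted_intersection' ",
         "must share genotype names")
  n_resp <- round(cfg$frac_responsive_per_stress * cfg$n_genes)
  n_common <- round(cfg$frac_common_responsive * n_resp)
  for (g in nm) {
    if (cfg$planted_intersection[[g]] > cfg$n_mutant_specific[[g]])
      stop("configuration error: 'planted_intersection[", g,
           "]' exceeds 'n_mutant_specific[", g, "]'")
    if (cfg$planted_intersection[[g]] > n_common)
      stop("configuration error: 'planted_intersection[", g,
           "]' exceeds the planted common-responsive pool size (", n_common, ")")
  }
  invisible(cfg)
}

gene_names <- function(n) sprintf("g%05d", seq_len(n))

#' Simulate a multi-study expression compendium with planted truth
#'
#' Emulates a compendium of independent two-group microarray studies:
#' several studies per stress type, each with a control and a treatment
#' group of a few replicates on the log2 intensity scale. A per-gene
#' baseline is drawn once and shared by all studies so that genes are
#' correlated across the compendium; true responders add a per-(gene,
#' stress) log2 fold change whose sign is fixed across studies of that
#' stress, so directional cross-study combination is coherent. Two
#' genotype-specific gene sets with fixed intersections with the common
#' responsive pool are planted alongside.
#'
#' @param config A [simulate_config()] object.
#' @return List with elements:
#'   \describe{
#'     \item{datasets}{list of per-study lists: `matrix` (genes x samples,
#'       log2), `sample_info` (sample, study, stress, condition, genotype),
#'       `stress`, `study`.}
#'     \item{sample_sheet}{all `sample_info` rows bound together.}
#'     \item{truth}{`ground_truth` list: `responsive_sets`, `effects`
#'       (per-stress signed log2FC of responders), `common_responsive`,
#'       `mutant_sets`, `planted_intersections`, `cluster_labels`.}
#'   }
#' @export
simulate_multistudy <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genes <- gene_names(config$n_genes)
  S <- config$stress_types
  n_resp <- round(config$frac_responsive_per_stress * config$n_genes)
  n_common <- round(config$frac_common_responsive * n_resp)

  responsive <- stats::setNames(vector("list", length(S)), S)
  effects <- stats::setNames(vector("list", length(S)), S)
  common_pool <- character(0)
  if (n_resp > 0L) {
    common_pool <- sample(genes, n_common)
    # each common gene responds under a random subset of >= 2 stress types
    membership <- lapply(common_pool, function(g) {
      sample(S, sample(2:length(S), 1L))
    })
    for (s in S) {
      in_pool <- common_pool[vapply(membership, function(m) s %in% m, logical(1L))]
      n_extra <- max(0L, n_resp - length(in_pool))
      extra <- sample(setdiff(genes, common_pool), n_extra)
      responsive[[s]] <- sort(c(in_pool, extra))
      sgn <- sample(c(-1, 1), length(responsive[[s]]), replace = TRUE)
      mag <- abs(stats::rnorm(length(responsive[[s]]),
                              config$effect_lfc_mean, config$effect_lfc_sd))
      effects[[s]] <- stats::setNames(sgn * mag, responsive[[s]])
    }
  } else {
    for (s in S) {
      responsive[[s]] <- character(0)
      effects[[s]] <- stats::setNames(numeric(0), character(0))
    }
  }

  baseline <- stats::setNames(stats::rnorm(config$n_genes, mean = 8, sd = 1.5),
                              genes)

  # common responsive = responsive under >= 2 stress types (by construction
  # exactly the common pool, but recomputed from the per-stress sets)
  counts <- table(unlist(responsive, use.names = FALSE))
  common <- sort(names(counts)[counts >= 2L])

  mutant_sets <- list()
  planted <- list()
  for (g in names(config$n_mutant_specific)) {
    k_in <- config$planted_intersection[[g]]
    k_out <- config$n_mutant_specific[[g]] - k_in
    inside <- if (k_in > 0L) sample(common, k_in) else character(0)
    outside <- sample(setdiff(genes, common), k_out)
    mutant_sets[[g]] <- sort(c(inside, outside))
    planted[[g]] <- k_in
  }

  cluster_labels <- NULL
  if (length(common)) {
    pat <- vapply(common, function(g) {
      paste(vapply(S, function(s) {
        e <- effects[[s]][g]
        if (is.na(e)) "0" else if (e > 0) "+" else "-"
      }, character(1L)), collapse = "")
    }, character(1L))
    cluster_labels <- pat
  }

  datasets <- list()
  sheets <- list()
  idx <- 0L
  n <- config$samples_per_group
  for (s in S) {
    for (j in seq_len(config$studies_per_stress)) {
      idx <- idx + 1L
      set.seed(config$seed + 7919L * idx)  # per-study substream
      study_id <- paste0(gsub("[^A-Za-z0-9]", "", s), "_s", j)
      samples <- c(paste0(study_id, "_ctrl_", seq_len(n)),
                   paste0(study_id, "_trt_", seq_len(n)))
      condition <- rep(c("control", "stress"), each = n)
      m <- matrix(stats::rnorm(config$n_genes * 2L * n, sd = config$noise_sd),
                  nrow = config$n_genes, ncol = 2L * n,
                  dimnames = list(genes, samples))
      m <- m + baseline
      if (length(responsive[[s]]))
        m[responsive[[s]], condition == "stress"] <-
          m[responsive[[s]], condition == "stress"] + effects[[s]]
      info <- data.frame(sample = samples, study = study_id, stress = s,
                         condition = condition, genotype = "Col-0",
                         stringsAsFactors = FALSE)
      datasets[[study_id]] <- list(matrix = m, sample_info = info,
                                   stress = s, study = study_id)
      sheets[[study_id]] <- info
    }
  }

  truth <- structure(list(
    responsive_sets = responsive,
    effects = effects,
    common_responsive = common,
    mutant_sets = mutant_sets,
    planted_intersections = planted,
    cluster_labels = cluster_labels
  ), class = "ground_truth")

  list(datasets = datasets,
       sample_sheet = do.call(rbind, c(sheets, list(make.row.names = FALSE))),
       truth = truth)
}

#' Simulate a TF-to-target regulatory layer with priors
#'
#' TF expression is drawn independently (standard normal across samples);
#' each target is a weighted sum of its true TF parents plus Gaussian
#' noise. Each TF regulates `targets_per_tf` targets chosen at random, so
#' targets can have zero, one, or several parents. The prior matrix puts
#' `prior_accuracy` of each target's prior mass on its true parents and
#' spreads the remainder uniformly over the other TFs (uniform when a
#' target has no parent).
#'
#' @param config A [simulate_config()] object.
#' @return List with elements `matrix` (TF and target rows x samples),
#'   `tfs` (TF identifiers), `truth` (`true_edges` data.frame with columns
#'   `tf`, `target`, `coefficient`), and `priors` (TF x target matrix).
#' @export
simulate_grn <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$prior_accuracy < 0 || config$prior_accuracy > 1)
    stop("configuration error: 'prior_accuracy' must be in [0, 1]")
  set.seed(config$seed + 104729L)  # regulatory-layer substream
  n_tf <- config$n_tfs
  n_tg <- config$n_tfs * config$targets_per_tf
  n <- config$n_grn_samples
  tfs <- sprintf("TF%03d", seq_len(n_tf))
  targets <- sprintf("t%04d", seq_len(n_tg))
  samples <- sprintf("grn_%03d", seq_len(n))

  edges <- do.call(rbind, lapply(seq_len(n_tf), function(i) {
    data.frame(tf = tfs[i],
               target = sample(targets, config$targets_per_tf),
               stringsAsFactors = FALSE)
  }))
  edges$coefficient <- sample(c(-1, 1), nrow(edges), replace = TRUE) *
    stats::runif(nrow(edges), 0.5, 1.5) * config$grn_signal_sd

  tf_expr <- matrix(stats::rnorm(n_tf * n), nrow = n_tf,
                    dimnames = list(tfs, samples))
  B <- matrix(0, nrow = n_tf, ncol = n_tg, dimnames = list(tfs, targets))
  B[cbind(edges$tf, edges$target)] <- edges$coefficient
  tg_expr <- t(B) %*% tf_expr
  if (config$grn_noise_sd > 0)
    tg_expr <- tg_expr + matrix(stats::rnorm(n_tg * n, sd = config$grn_noise_sd),
                                nrow = n_tg)
  dimnames(tg_expr) <- list(targets, samples)

  a <- config$prior_accuracy
  priors <- matrix(0, nrow = n_tf, ncol = n_tg, dimnames = list(tfs, targets))
  truth_mask <- B != 0
  for (j in seq_len(n_tg)) {
    k <- sum(truth_mask[, j])
    if (k == 0L) {
      priors[, j] <- 1 / n_tf
    } else {
      priors[truth_mask[, j], j] <- a / k
      if (k < n_tf) priors[!truth_mask[, j], j] <- (1 - a) / (n_tf - k)
    }
  }

  list(matrix = rbind(tf_expr, tg_expr), tfs = tfs,
       truth = structure(list(true_edges = edges), class = "ground_truth"),
       priors = priors)
}

#' Write a simulated compendium to disk in the pipeline's exchange formats
#'
#' Expression matrices and the prior matrix as TSV, the sample sheet as
#' TSV, planted gene sets as GMT, and the full ground truth as JSON.
#'
#' @param sim Output of [simulate_multistudy()].
#' @param dir Output directory (created if missing).
#' @param grn Optional output of [simulate_grn()].
#' @return Invisibly, the output directory.
#' @export
write_simulation <- function(sim, dir, grn = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (d in sim$datasets)
    write_expression_tsv(d$matrix, file.path(dir, paste0(d$study, ".tsv")))
  utils::write.table(sim$sample_sheet, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- c(sim$truth$responsive_sets,
            list(common_responsive = sim$truth$common_responsive),
            sim$truth$mutant_sets)
  write_gmt(sets, file.path(dir, "planted_sets.gmt"))
  jsonlite::write_json(unclass(sim$truth), file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(grn)) {
    write_expression_tsv(grn$matrix, file.path(dir, "grn_expression.tsv"))
    write_prior_matrix(grn$priors, file.path(dir, "grn_priors.tsv"))
    jsonlite::write_json(unclass(grn$truth), file.path(dir, "grn_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
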