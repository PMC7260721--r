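#' Random-forest TF-to-target importance network
#'
#' For every target gene, fits an ensemble of `n_trees` regression trees
#' predicting the target from TF expression (the target itself is
#' excluded from its own candidate regulators). Candidate regulators at
#' each split are drawn with size `ceiling(sqrt(#TFs))`, uniformly by
#' default or with probability proportional to the prior weight when a
#' prior matrix is supplied — uniform priors recover the unweighted
#' behavior. Edge importance is the total variance (impurity) reduction
#' attributed to each TF over all trees, normalized per target to sum
#' to 1. Deterministic for a given seed and input ordering.
#'
#' @param matrix Numeric genes x samples matrix containing both TFs and
#'   targets.
#' @param tfs Character vector of TF identifiers (>= 2, all rows of
#'   `matrix`).
#' @param n_trees Trees per target ensemble (default 1000).
#' @param priors Optional TF x gene nonnegative weight matrix; every
#'   target needs at least one positive weight.
#' @param targets Character vector of targets to score (default: every
#'   gene in `matrix`).
#' @param min_node_size Minimum terminal node size (default 2).
#' @param mtry Candidate-regulator subset size per split (default
#'   `ceiling(sqrt(#TFs))`).
#' @param seed Integer seed; per-target tree seeds are derived from it.
#' @return Object of class `grn_scores`: data.frame with columns `tf`,
#'   `target`, `importance` (per-target sum 1, no self edges); attributes
#'   `n_trees`, `seed`, `tfs`, `normalized = TRUE`.
#' @export
rf_importance_network <- function(matrix, tfs, n_trees = 1000L, priors = NULL,
                                  targets = rownames(matrix),
                                  min_node_size = 2L, mtry = NULL, seed = 1L) {
  missing_tfs <- setdiff(tfs, rownames(matrix))
  if (length(missing_tfs))
    stop("TF(s) absent from the matrix: ", paste(missing_tfs, collapse = ", "))
  if (length(tfs) < 2L) stop("need >= 2 TFs")
  if (ncol(matrix) < 10L)
    warning("fewer than 10 samples; importance estimates will be unstable")
  if (!is.null(priors)) {
    if (any(priors < 0)) stop("prior weights must be nonnegative")
    if (!all(tfs %in% rownames(priors)))
      stop("priors must have one row per TF")
  }
  res <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    tg <- targets[i]
    regs <- setdiff(tfs, tg)
    X <- t(matrix[regs, , drop = FALSE])
    y <- matrix[tg, ]
    m <- if (is.null(mtry)) ceiling(sqrt(length(regs))) else min(mtry, length(regs))
    ssw <- NULL
    if (!is.null(priors)) {
      w <- priors[regs, tg]
      if (all(w == 0))
        stop("all-zero prior weights for target '", tg, "'")
      ssw <- w / max(w)
    }
    fit <- suppressWarnings(ranger::ranger(
      x = X, y = y, num.trees = n_trees, mtry = m,
      importance = "impurity", min.node.size = min_node_size,
      split.select.weights = ssw, num.threads = 1L,
      verbose = FALSE, seed = seed + i
    ))
    imp <- pmax(fit$variable.importance, 0)
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
    res[[i]] <- data.frame(tf = regs, target = tg, importance = unname(imp),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, n_trees = n_trees, seed = seed, tfs = tfs, normalized = TRUE,
            class = c("grn_scores", "data.frame"))
}

#' Threshold directed edge scores into a network
#'
#' Exactly one of `top_n` (keep the highest-scoring edges; ties broken by
#' `(tf, target)` order for determinism) or `score_cutoff` (keep edges
#' with importance >= cutoff) must be given.
#'
#' @param scores A [rf_importance_network()] result.
#' @param top_n Number of edges to keep.
#' @param score_cutoff Importance cut-off.
#' @return Directed `gene_network` data.frame with columns `u` (TF), `v`
#'   (target), `weight` (importance); attribute `tfs` carries the TF
#'   flags.
#' @export
threshold_directed <- function(scores, top_n = NULL, score_cutoff = NULL) {
  if (is.null(top_n) == is.null(score_cutoff))
    stop("give exactly one of 'top_n' or 'score_cutoff'")
  ord <- order(-scores$importance, scores$tf, scores$target)
  s <- scores[ord, , drop = FALSE]
  keep <- if (!is.null(top_n)) seq_len(min(top_n, nrow(s)))
          else which(s$importance >= score_cutoff)
  edges <- data.frame(u = s$tf[keep], v = s$target[keep],
                      weight = s$importance[keep], stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  nodes <- sort(unique(c(scores$tf, scores$target)))
  structure(edges, nodes = nodes, tfs = attr(scores, "tfs"), directed = TRUE,
            class = c("gene_network", "data.frame"))
}

#' Area under the ROC curve for edge recovery
#'
#' Scores every candidate (TF, target) pair against a set of true edges
#' by the Mann-Whitney rank statistic (ties midranked).
#'
#' @param scores A [rf_importance_network()] result (or data.frame with
#'   `tf`, `target`, `importance`).
#' @param true_edges data.frame with columns `tf`, `target`.
#' @return AUROC in \[0, 1\].
#' @export
edge_recovery_auroc <- function(scores, true_edges) {
  lab <- paste(scores$tf, scores$target, sep = "\r") %in%
    paste(true_edges$tf, true_edges$target, sep = "\r")
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L) stop("need both true and false candidate edges")
  r <- rank(scores$importance)
  (sum(r[lab]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write directed edge scores as TSV
#'
#' @param scores A [rf_importance_network()] result.
#' @param path Output path.
#' @export
write_grn_scores <- function(scores, path) {
  utils::write.table(as.data.frame(scores), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
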