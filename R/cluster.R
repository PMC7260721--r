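#' Build a gene-by-stress profile matrix of mean log2 fold changes
#'
#' For each stress type, averages the per-study log2 fold changes of each
#' gene; genes absent from every study of a stress get `NA` (and are
#' dropped when `complete = TRUE`).
#'
#' @param studies List of per-study entries as for [meta_combine()].
#' @param genes Optional character vector restricting the rows (e.g. the
#'   common-responsive set).
#' @param complete Drop genes with any missing stress profile
#'   (default `TRUE`).
#' @return Numeric genes x stress-types matrix of mean log2FC.
#' @export
build_profile_matrix <- function(studies, genes = NULL, complete = TRUE) {
  stress <- vapply(studies, `[[`, character(1L), "stress")
  all_genes <- sort(unique(unlist(lapply(studies, function(g) g$deg$gene))))
  if (!is.null(genes)) all_genes <- intersect(all_genes, genes)
  if (length(all_genes) == 0L)
    return(matrix(numeric(0), nrow = 0L, ncol = length(unique(stress)),
                  dimnames = list(NULL, unique(stress))))
  out <- sapply(unique(stress), function(s) {
    grp <- studies[stress == s]
    acc <- matrix(NA_real_, length(all_genes), length(grp))
    for (k in seq_along(grp)) {
      deg <- grp[[k]]$deg
      i <- match(all_genes, deg$gene)
      acc[, k] <- deg$log2fc[i]
    }
    rowMeans(acc, na.rm = TRUE)
  })
  rownames(out) <- all_genes
  if (complete) out <- out[stats::complete.cases(out), , drop = FALSE]
  out
}

dist2_to_centers <- function(x, centers) {
  # squared Euclidean distances, n x k
  n <- nrow(x); k <- nrow(centers)
  matrix(rowSums(x^2), n, k) - 2 * x %*% t(centers) +
    matrix(rowSums(centers^2), n, k, byrow = TRUE)
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1L, ] <- x[sample.int(n, 1L), ]
  if (k > 1L) for (j in 2:k) {
    d2 <- apply(dist2_to_centers(x, centers[seq_len(j - 1L), , drop = FALSE]),
                1L, min)
    d2 <- pmax(d2, 0)
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- x[sample.int(n, 1L, prob = prob), ]
  }
  centers
}

lloyd_once <- function(x, centers, max_iter) {
  assign_prev <- rep(0L, nrow(x))
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    d2 <- pmax(dist2_to_centers(x, centers), 0)
    assign <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the point farthest from its centroid
    empty <- setdiff(seq_len(nrow(centers)), unique(assign))
    tries <- 0L
    while (length(empty) && tries < nrow(centers)) {
      far <- which.max(d2[cbind(seq_len(nrow(x)), assign)])
      centers[empty[1L], ] <- x[far, ]
      d2 <- pmax(dist2_to_centers(x, centers), 0)
      assign <- max.col(-d2, ties.method = "first")
      assign[far] <- empty[1L]
      empty <- setdiff(seq_len(nrow(centers)), unique(assign))
      tries <- tries + 1L
    }
    obj <- sum(d2[cbind(seq_len(nrow(x)), assign)])
    # Lloyd's objective never increases between iterations (a re-seed of an
    # empty cluster restarts the descent)
    if (tries == 0L)
      stopifnot(obj <= obj_prev + 1e-8 * (1 + abs(obj_prev)))
    if (identical(assign, assign_prev)) break
    assign_prev <- assign
    obj_prev <- obj
    for (j in seq_len(nrow(centers)))
      centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  list(assign = assign, centers = centers, objective = obj)
}

#' k-means clustering of log2FC profiles
#'
#' Lloyd's algorithm with k-means++ initialization, best of `n_init`
#' restarts by total within-cluster sum of squares; deterministic for a
#' given seed. Empty clusters are re-seeded from the point farthest from
#' its assigned centroid. Clusters are relabeled G1..Gk by decreasing
#' size for stable reporting.
#'
#' @param matrix Numeric genes x conditions matrix (e.g. mean log2FC per
#'   stress type).
#' @param k Number of groups (default 5).
#' @param n_init Number of random restarts (default 25).
#' @param max_iter Maximum Lloyd iterations per restart (default 100).
#' @param seed Optional seed for reproducibility.
#' @param standardize z-score each gene's profile first (default `FALSE`;
#'   log2FC values are already on a common scale).
#' @return Object of class `profile_clusters`: list with `cluster` (named
#'   character vector of G labels), `centroids` (k x conditions, G-label
#'   rownames), `withinss`, `tot_withinss`, `sizes`.
#' @export
kmeans_profiles <- function(matrix, k = 5L, n_init = 25L, max_iter = 100L,
                            seed = NULL, standardize = FALSE) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (k > nrow(matrix)) stop("k exceeds the number of genes")
  if (!is.null(seed)) set.seed(seed)
  x <- matrix
  if (standardize) {
    sdv <- apply(x, 1L, stats::sd)
    x <- (x - rowMeans(x)) / ifelse(sdv > 0, sdv, 1)
  }
  best <- NULL
  for (r in seq_len(n_init)) {
    fit <- lloyd_once(x, kmeanspp_init(x, k), max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  sizes <- tabulate(best$assign, nbins = k)
  ord <- order(-sizes, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- paste0("G", relabel[best$assign])
  centroids <- best$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("G", seq_len(k))
  colnames(centroids) <- colnames(x)
  d2 <- pmax(dist2_to_centers(x, best$centers), 0)
  withinss <- vapply(seq_len(k), function(j) {
    sum(d2[best$assign == j, j])
  }, numeric(1L))[ord]
  names(withinss) <- paste0("G", seq_len(k))
  structure(list(cluster = stats::setNames(labels, rownames(matrix)),
                 centroids = centroids,
                 withinss = withinss,
                 tot_withinss = best$objective,
                 sizes = stats::setNames(sizes[ord], paste0("G", seq_len(k)))),
            class = "profile_clusters")
}

#' @export
print.profile_clusters <- function(x, ...) {
  cat("k-means profile clusters (k =", length(x$sizes), "):\n")
  print(x$sizes)
  cat("total within-cluster SS:", format(x$tot_withinss, digits = 6), "\n")
  invisible(x)
}

#' Principal component analysis by centered SVD
#'
#' Column-mean-centered singular value decomposition; no scaling. A
#' constant (zero total variance) input is flagged degenerate rather than
#' erroring.
#'
#' @param matrix Numeric matrix, >= 2 rows and columns (observations in
#'   rows).
#' @return List with `scores` (observations x components), `loadings`
#'   (orthonormal columns), `variance_explained` (sums to 1; `NA` when
#'   degenerate), `degenerate` flag.
#' @export
pca_scores <- function(matrix) {
  if (!is.matrix(matrix)) matrix <- as.matrix(matrix)
  if (nrow(matrix) < 2L || ncol(matrix) < 2L)
    stop("PCA needs >= 2 rows and >= 2 columns")
  pr <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  tot <- sum(pr$sdev^2)
  degenerate <- tot <= .Machine$double.eps
  ve <- if (degenerate) rep(NA_real_, length(pr$sdev)) else pr$sdev^2 / tot
  list(scores = pr$x, loadings = pr$rotation,
       variance_explained = ve, degenerate = degenerate)
}
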