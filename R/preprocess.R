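#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) to share the identical value distribution:
#' each value is replaced by the across-sample mean of the values occupying
#' its rank. Ties share the mean of the quantile values of their occupied
#' ranks (midrank convention). Row and column labels are preserved.
#'
#' @param matrix Numeric genes x samples matrix, no missing values,
#'   >= 2 samples.
#' @return Matrix of the same shape with identical sorted column vectors.
#' @export
quantile_normalize <- function(matrix) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("'matrix' must be a numeric matrix")
  if (ncol(matrix) < 2L)
    stop("quantile normalization needs >= 2 samples")
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stop("missing or non-finite values are not supported; impute upstream")
  out <- limma::normalizeQuantiles(matrix, ties = TRUE)
  dimnames(out) <- dimnames(matrix)
  out
}

#' Collapse probe rows to gene (locus) rows
#'
#' Applies the probe filtering rule used throughout the pipeline: probes
#' with no locus match and probes ambiguously matching more than one locus
#' are discarded; several probes matching the same single locus are
#' collapsed to one row.
#'
#' @param matrix Numeric probes x samples matrix with probe rownames.
#' @param map data.frame with columns `probe` and `locus`; a probe on
#'   several rows is ambiguous.
#' @param collapse `"mean"` (per-sample arithmetic mean of the probes'
#'   log2 values, the default) or `"max_intensity"` (keep the probe with
#'   the highest average intensity across samples).
#' @return Numeric genes x samples matrix with unique locus rownames.
#' @export
collapse_probes <- function(matrix, map, collapse = c("mean", "max_intensity")) {
  collapse <- match.arg(collapse)
  if (is.null(rownames(matrix))) stop("'matrix' must have probe rownames")
  if (!all(c("probe", "locus") %in% colnames(map)))
    stop("'map' must have columns 'probe' and 'locus'")
  map <- unique(map[c("probe", "locus")])
  n_loci <- table(map$probe)
  unambiguous <- names(n_loci)[n_loci == 1L]
  keep <- intersect(rownames(matrix), unambiguous)
  if (length(keep) == 0L)
    stop("no probes survive filtering: all rows are unmapped or ambiguous")
  locus <- map$locus[match(keep, map$probe)]
  sub <- matrix[keep, , drop = FALSE]
  if (collapse == "mean") {
    out <- rowsum(sub, group = locus, reorder = TRUE) /
      as.vector(table(locus)[sort(unique(locus))])
  } else {
    intensity <- rowMeans(sub)
    best <- vapply(split(seq_along(keep), locus), function(ix) {
      ix[which.max(intensity[ix])]
    }, integer(1L))
    out <- sub[best, , drop = FALSE]
    rownames(out) <- names(best)
    out <- out[sort(rownames(out)), , drop = FALSE]
  }
  out
}
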