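#' Inverse-normal (Stouffer) combination of directional p-values
#'
#' Each study's two-sided p-value is halved into a one-sided p-value on
#' its observed direction, converted to a signed normal quantile
#' `z_i = sign_i * qnorm(1 - p_i/2)`, and the combined statistic is
#' `Z = sum(w_i z_i) / sqrt(sum(w_i^2))` with a two-sided normal p-value.
#' One-sided p-values of exactly 0 or 1 are clamped to
#' `[1e-300, 1 - 1e-16]` with a warning.
#'
#' @param p_values Per-study two-sided p-values.
#' @param directions Per-study effect signs in \{-1, 0, +1\} (0 gives z = 0).
#' @param weights Positive per-study weights (e.g. `sqrt(n)`); default
#'   equal.
#' @return List with `z` (combined signed statistic) and `p` (two-sided).
#' @export
combine_inverse_normal <- function(p_values, directions,
                                   weights = rep(1, length(p_values))) {
  k <- length(p_values)
  if (k < 1L) stop("need >= 1 study")
  if (length(directions) != k || length(weights) != k)
    stop("'p_values', 'directions', 'weights' must have equal length")
  if (any(weights <= 0)) stop("weights must be positive")
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (!all(directions %in% c(-1, 0, 1)))
    stop("directions must be -1, 0, or +1")
  p_one <- p_values / 2
  if (any(p_one == 0 | p_one >= 1)) {
    warning("one-sided p-values of 0 or 1 clamped to [1e-300, 1 - 1e-16]")
    p_one <- pmin(pmax(p_one, 1e-300), 1 - 1e-16)
  }
  z_i <- ifelse(directions == 0, 0,
                directions * stats::qnorm(1 - p_one))
  z <- sum(weights * z_i) / sqrt(sum(weights^2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Fixed-effect inverse-variance pooling of effect sizes
#'
#' @param effects Per-study effects (log2 fold changes).
#' @param variances Positive per-study variances of the effects.
#' @return List with `pooled` effect, `pooled_var`, `z`, and two-sided `p`.
#' @export
combine_effect_sizes <- function(effects, variances) {
  if (length(effects) < 2L) stop("need >= 2 studies")
  if (length(variances) != length(effects))
    stop("'effects' and 'variances' must have equal length")
  if (any(variances <= 0)) stop("variances must be positive")
  w <- 1 / variances
  pooled <- sum(w * effects) / sum(w)
  pooled_var <- 1 / sum(w)
  z <- pooled / sqrt(pooled_var)
  list(pooled = pooled, pooled_var = pooled_var, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Combine per-study evidence within each stress type
#'
#' Aligns the per-study DEG tables of each stress type by gene and applies
#' the inverse-normal combination with weights `sqrt(n_samples)` per study
#' (the pipeline default). Genes absent from a study are skipped for that
#' study; `n_studies` records how many studies contributed.
#'
#' @param studies List of per-study entries, each a list with elements
#'   `stress` (label), `study` (id), and `deg` (a [run_deg()] table).
#' @return Object of class `meta_result`: named list (one element per
#'   stress type) of data.frames with columns `gene`, `combined_z`,
#'   `combined_p`, `n_studies`, `direction_consistency` (fraction of
#'   contributing studies sharing the majority sign).
#' @export
meta_combine <- function(studies) {
  stress <- vapply(studies, `[[`, character(1L), "stress")
  out <- list()
  for (s in unique(stress)) {
    grp <- studies[stress == s]
    genes <- sort(unique(unlist(lapply(grp, function(g) g$deg$gene))))
    K <- length(grp)
    P <- matrix(NA_real_, length(genes), K)
    D <- matrix(NA_real_, length(genes), K)
    w <- numeric(K)
    for (k in seq_len(K)) {
      deg <- grp[[k]]$deg
      i <- match(deg$gene, genes)
      P[i, k] <- deg$p_value
      D[i, k] <- sign(deg$log2fc)
      n_k <- attr(deg, "n_treatment") + attr(deg, "n_control")
      w[k] <- sqrt(if (is.null(n_k) || length(n_k) == 0L) 1 else n_k)
    }
    p_one <- pmin(pmax(P / 2, 1e-300), 1 - 1e-16)
    Z <- ifelse(D == 0, 0, D * stats::qnorm(1 - p_one))
    used <- !is.na(Z)
    Zw <- sweep(Z, 2L, w, `*`)
    Zw[!used] <- 0
    w2 <- matrix(w^2, length(genes), K, byrow = TRUE)
    w2[!used] <- 0
    z <- rowSums(Zw) / sqrt(rowSums(w2))
    n_used <- rowSums(used)
    maj <- rowSums(D > 0, na.rm = TRUE)
    consist <- pmax(maj, n_used - maj) / pmax(n_used, 1L)
    out[[s]] <- data.frame(gene = genes,
                           combined_z = z,
                           combined_p = 2 * stats::pnorm(-abs(z)),
                           n_studies = n_used,
                           direction_consistency = consist,
                           stringsAsFactors = FALSE)
  }
  structure(out, class = "meta_result")
}

#' Call the common stress-responsive gene set
#'
#' A gene is common-responsive when its combined p-value passes the
#' threshold in at least `min_stress_types` stress types.
#'
#' @param meta A [meta_combine()] result.
#' @param p_threshold Combined-p cut-off (strict `<`), default 0.05.
#' @param min_stress_types Minimum number of stress types passing,
#'   default 2.
#' @param adjust If `TRUE` (the default), BH-adjust the combined p-values
#'   within each stress type before thresholding — the default behavior
#'   of standard inverse-normal meta-analysis workflows, which report
#'   FDR-adjusted combined p-values. Set `FALSE` to threshold the raw
#'   combined p.
#' @return Character vector of gene identifiers, with attribute
#'   `n_stress_passing` (named integer vector over all scored genes).
#' @export
call_common_responsive <- function(meta, p_threshold = 0.05,
                                   min_stress_types = 2L, adjust = TRUE) {
  stopifnot(inherits(meta, "meta_result"))
  if (length(meta) < 2L) stop("need >= 2 stress types")
  genes <- sort(unique(unlist(lapply(meta, `[[`, "gene"))))
  passing <- stats::setNames(integer(length(genes)), genes)
  for (s in names(meta)) {
    p <- if (adjust) bh_adjust(meta[[s]]$combined_p) else meta[[s]]$combined_p
    hits <- meta[[s]]$gene[p < p_threshold]
    passing[hits] <- passing[hits] + 1L
  }
  out <- names(passing)[passing >= min_stress_types]
  attr(out, "n_stress_passing") <- passing
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat("Meta-combination over", length(x), "stress types:\n")
  for (s in names(x))
    cat("  ", s, ": ", nrow(x[[s]]), " genes, ",
        sum(x[[s]]$combined_p < 0.05), " at combined p < 0.05\n", sep = "")
  invisible(x)
}

#' Write per-stress meta results as TSV files
#'
#' @param meta A [meta_combine()] result.
#' @param dir Output directory (one `meta_<stress>.tsv` per stress type).
#' @export
write_meta_result <- function(meta, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(meta)) {
    f <- file.path(dir, paste0("meta_", gsub("[^A-Za-z0-9]", "", s), ".tsv"))
    utils::write.table(meta[[s]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(dir)
}
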