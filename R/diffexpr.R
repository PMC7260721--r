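#' Gene-wise two-group linear contrast
#'
#' Fits the two-group linear model gene by gene: the effect is the
#' difference of group means on the log2 scale (log2 fold change), the
#' residual variance is the pooled within-group variance, and the residual
#' degrees of freedom are `n_total - 2`.
#'
#' @param matrix Numeric genes x samples matrix (log2 scale).
#' @param group Character/factor vector of group labels, one per column
#'   (or named by sample).
#' @param contrast Length-2 character vector `c(treatment, control)`.
#' @return List with per-gene vectors `log2fc`, `residual_var`, and
#'   scalars `residual_df`, `n_treatment`, `n_control`.
#' @export
fit_contrasts <- function(matrix, group, contrast) {
  if (length(contrast) != 2L) stop("'contrast' must be c(treatment, control)")
  group <- as.character(group)
  if (!is.null(names(group)) && !is.null(colnames(matrix)))
    group <- group[colnames(matrix)]
  if (length(group) != ncol(matrix))
    stop("'group' must label every sample column")
  t_idx <- which(group == contrast[1L])
  c_idx <- which(group == contrast[2L])
  if (length(t_idx) < 2L || length(c_idx) < 2L)
    stop("each contrast group needs >= 2 samples (within-group variance ",
         "is undefined otherwise)")
  nt <- length(t_idx); nc <- length(c_idx)
  mt <- matrix[, t_idx, drop = FALSE]
  mc <- matrix[, c_idx, drop = FALSE]
  log2fc <- rowMeans(mt) - rowMeans(mc)
  ss_t <- rowSums((mt - rowMeans(mt))^2)
  ss_c <- rowSums((mc - rowMeans(mc))^2)
  df <- nt + nc - 2L
  list(log2fc = log2fc,
       residual_var = (ss_t + ss_c) / df,
       residual_df = df,
       n_treatment = nt, n_control = nc)
}

trigamma_inverse <- function(y) {
  # Newton iteration for trigamma(x) = y; y > 0
  if (y <= 0) stop("trigamma_inverse needs a positive argument")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Estimate empirical-Bayes variance-moderation hyperparameters
#'
#' Moment-matching on the log sample variances: under the scaled
#' inverse-chi-squared prior, `log(s^2)` has known mean and variance in
#' terms of digamma/trigamma functions of the prior and residual degrees
#' of freedom. The prior df solves a trigamma equation (Newton); the prior
#' variance follows from the mean of the adjusted log variances. When the
#' observed spread of log variances does not exceed the spread expected
#' under a single common variance, the prior df is infinite and the prior
#' variance is the geometric-mean-based estimate.
#'
#' @param residual_vars Per-gene residual variances (>= 30 positive values).
#' @param residual_df Residual degrees of freedom (scalar).
#' @return Object of class `moderation_params`: list with `prior_df`
#'   (possibly `Inf`) and `prior_var`.
#' @export
estimate_moderation <- function(residual_vars, residual_df) {
  if (all(residual_vars <= 0)) stop("all residual variances are zero")
  v <- residual_vars[residual_vars > 0 & is.finite(residual_vars)]
  if (length(v) < 30L)
    stop("need >= 30 genes with positive variance to estimate moderation")
  d <- residual_df
  e <- log(v) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(d / 2)
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  structure(list(prior_df = d0, prior_var = s02), class = "moderation_params")
}

#' Moderated t-statistics and p-values
#'
#' Shrinks each gene's residual variance toward the prior:
#' `post_var = (d0 * s0^2 + d * s^2) / (d0 + d)`, forms
#' `t = log2fc / sqrt(post_var * (1/n_t + 1/n_c))`, and takes two-sided
#' p-values from a t distribution with `d0 + d` degrees of freedom
#' (standard normal when `d0` is infinite). `prior_df = 0` recovers the
#' ordinary pooled two-sample t-statistic.
#'
#' @param log2fc Per-gene effects.
#' @param residual_vars Per-gene residual variances.
#' @param residual_df Residual degrees of freedom (scalar).
#' @param n_treatment,n_control Group sizes.
#' @param params A [estimate_moderation()] result (`moderation_params`).
#' @return List with per-gene vectors `t` and `p_value` and scalar
#'   `total_df`.
#' @export
moderated_statistics <- function(log2fc, residual_vars, residual_df,
                                 n_treatment, n_control, params) {
  stopifnot(inherits(params, "moderation_params"))
  d0 <- params$prior_df; s02 <- params$prior_var
  if (d0 < 0 || s02 <= 0) stop("invalid moderation parameters")
  d <- residual_df
  post_var <- if (is.infinite(d0)) rep(s02, length(residual_vars))
              else (d0 * s02 + d * residual_vars) / (d0 + d)
  se <- sqrt(post_var * (1 / n_treatment + 1 / n_control))
  t <- log2fc / se
  p <- if (is.infinite(d0)) 2 * stats::pnorm(-abs(t))
       else 2 * stats::pt(-abs(t), df = d0 + d)
  list(t = t, p_value = p, total_df = d0 + d)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (monotone step-up, capped at 1), in the input
#'   order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-study differential expression table
#'
#' Runs the full per-study stage: linear contrast, empirical-Bayes
#' moderation, moderated t-statistics, BH adjustment, and DEG calling at
#' the fold-change and FDR gates.
#'
#' @param matrix Numeric genes x samples matrix (log2).
#' @inheritParams fit_contrasts
#' @param lfc_threshold Absolute log2 fold-change gate (strict `>`),
#'   default 1.
#' @param fdr_threshold FDR gate (strict `<`), default 0.05.
#' @return data.frame of class `deg_table` with columns `gene`, `log2fc`,
#'   `residual_var`, `t`, `p_value`, `fdr`, `is_deg`; attributes
#'   `moderation`, `residual_df`, `n_treatment`, `n_control`, `thresholds`.
#' @export
run_deg <- function(matrix, group, contrast, lfc_threshold = 1,
                    fdr_threshold = 0.05) {
  fit <- fit_contrasts(matrix, group, contrast)
  params <- estimate_moderation(fit$residual_var, fit$residual_df)
  mod <- moderated_statistics(fit$log2fc, fit$residual_var, fit$residual_df,
                              fit$n_treatment, fit$n_control, params)
  fdr <- bh_adjust(mod$p_value)
  out <- data.frame(gene = rownames(matrix),
                    log2fc = unname(fit$log2fc),
                    residual_var = unname(fit$residual_var),
                    t = unname(mod$t),
                    p_value = unname(mod$p_value),
                    fdr = unname(fdr),
                    stringsAsFactors = FALSE)
  out$is_deg <- abs(out$log2fc) > lfc_threshold & out$fdr < fdr_threshold
  attr(out, "moderation") <- params
  attr(out, "residual_df") <- fit$residual_df
  attr(out, "n_treatment") <- fit$n_treatment
  attr(out, "n_control") <- fit$n_control
  attr(out, "thresholds") <- c(lfc = lfc_threshold, fdr = fdr_threshold)
  class(out) <- c("deg_table", "data.frame")
  out
}

#' Call differentially expressed genes from a DEG table
#'
#' A gene is a DEG when `|log2fc| > lfc_threshold` and
#' `fdr < fdr_threshold` (both gates strict, matching the conventional
#' ">1 and FDR < 0.05" rule).
#'
#' @param table A `deg_table` (or any data.frame with `gene`, `log2fc`,
#'   `fdr`).
#' @param lfc_threshold Absolute log2 fold-change gate, default 1.
#' @param fdr_threshold FDR gate, default 0.05.
#' @return Character vector of gene identifiers.
#' @export
call_degs <- function(table, lfc_threshold = 1, fdr_threshold = 0.05) {
  if (nrow(table) == 0L) return(character(0))
  table$gene[abs(table$log2fc) > lfc_threshold & table$fdr < fdr_threshold]
}

#' @export
print.deg_table <- function(x, ...) {
  cat("DEG table:", nrow(x), "genes,", sum(x$is_deg), "DEGs at |log2FC| >",
      attr(x, "thresholds")[["lfc"]], "and FDR <",
      attr(x, "thresholds")[["fdr"]], "\n")
  mp <- attr(x, "moderation")
  cat("moderation: prior_df =", format(mp$prior_df, digits = 4),
      ", prior_var =", format(mp$prior_var, digits = 4), "\n")
  invisible(x)
}

#' Write a DEG table as TSV
#'
#' @param table A `deg_table`.
#' @param path Output path.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
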