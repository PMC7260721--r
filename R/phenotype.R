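#' Wavy root index
#'
#' Root path length divided by the root's vertical depth; exactly 1 for a
#' perfectly straight vertical root, larger for wavy roots, and invariant
#' to measurement units.
#'
#' @param root_length Root path length(s), > 0.
#' @param root_depth Vertical extent(s) in the same units, > 0 and
#'   <= `root_length` (a path is at least as long as its vertical span).
#' @return Numeric ratio(s) >= 1.
#' @export
wavy_root_index <- function(root_length, root_depth) {
  if (any(root_depth <= 0)) stop("root depth must be positive")
  if (any(root_length <= 0)) stop("root length must be positive")
  if (any(root_length < root_depth))
    stop("root length cannot be smaller than root depth")
  root_length / root_depth
}

#' Growth-arrest fraction with a Wilson confidence interval
#'
#' Point estimate `n_arrested / n_germinated` with the Wilson score
#' interval at the requested confidence level.
#'
#' @param n_arrested Number of arrested plants, `0 <= n_arrested <=
#'   n_germinated`.
#' @param n_germinated Total number of germinated plants, > 0.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `estimate`, `lower`, `upper`, `n`.
#' @export
growth_arrest_fraction <- function(n_arrested, n_germinated,
                                   conf_level = 0.95) {
  if (n_germinated <= 0) stop("need at least one germinated plant")
  if (n_arrested < 0 || n_arrested > n_germinated)
    stop("'n_arrested' must lie in [0, n_germinated]")
  p <- n_arrested / n_germinated
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  n <- n_germinated
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lower = max(0, center - half),
       upper = min(1, center + half), n = n)
}

#' Relative expression by the delta-delta-Ct method
#'
#' `2^-ddCt` with `dCt = Ct_target - Ct_reference` per sample and
#' `ddCt = dCt_treatment - dCt_control`; amplification efficiency is
#' fixed at 2 (one cycle = one doubling).
#'
#' @param ct_target_treatment,ct_ref_treatment Treatment-sample cycle
#'   thresholds of the gene of interest and the reference gene.
#' @param ct_target_control,ct_ref_control The same for the control
#'   sample.
#' @return Fold change(s) > 0; `log2` of the result equals `-ddCt`
#'   exactly.
#' @export
qpcr_relative_expression <- function(ct_target_treatment, ct_ref_treatment,
                                     ct_target_control, ct_ref_control) {
  ct <- c(ct_target_treatment, ct_ref_treatment,
          ct_target_control, ct_ref_control)
  if (any(!is.finite(ct)) || any(ct <= 0))
    stop("Ct values must be positive and finite")
  ddct <- (ct_target_treatment - ct_ref_treatment) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Summarize replicate fold changes by their geometric mean
#'
#' Fold changes are ratios, so replicates are averaged on the log scale.
#'
#' @param fold_changes Positive fold changes from biological replicates.
#' @return Geometric mean.
#' @export
qpcr_summary <- function(fold_changes) {
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  exp(mean(log(fold_changes)))
}
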