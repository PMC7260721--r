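#' Overlapping coefficient of two gene sets
#'
#' `|A n B| / min(|A|, |B|)` — ranges from 1 (one set nested in the
#' other) to 0 (disjoint sets).
#'
#' @param a,b Character vectors of gene identifiers (duplicates ignored).
#' @return Numeric scalar in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("overlap coefficient is undefined for an empty set")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Hypergeometric overlap test (upper tail)
#'
#' Probability of drawing at least the observed intersection when `|B|`
#' genes are drawn without replacement from a universe of size `N`
#' containing `|A|` "successes": `P(X >= |A n B|)`, the standard
#' enrichment convention (observed count included).
#'
#' @param a,b Character vectors, both subsets of `universe`.
#' @param universe Character vector defining the population.
#' @return Numeric upper-tail p-value.
#' @export
hypergeometric_overlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  bad <- setdiff(c(a, b), universe)
  if (length(bad))
    stop("genes outside the universe: ", paste(utils::head(bad, 5L),
                                               collapse = ", "),
         if (length(bad) > 5L) " ..." else "")
  k <- length(intersect(a, b))
  stats::phyper(k - 1L, m = length(a), n = length(universe) - length(a),
                k = length(b), lower.tail = FALSE)
}

#' Venn partition of two or three gene sets
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector over the `2^k - 1` non-empty membership
#'   patterns (names like `"A"`, `"A&B"`); counts sum to the union size.
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L) stop("venn_partition supports 2 or 3 sets")
  if (is.null(names(sets))) names(sets) <- LETTERS[seq_len(k)]
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  member <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) member <- matrix(member, nrow = 1L,
                                                dimnames = list(NULL, names(sets)))
  patterns <- lapply(seq_len(2^k - 1L), function(code) {
    as.logical(intToBits(code)[seq_len(k)])
  })
  counts <- vapply(patterns, function(pat) {
    sum(apply(member, 1L, function(row) all(row == pat)))
  }, integer(1L))
  names(counts) <- vapply(patterns, function(pat) {
    paste(names(sets)[pat], collapse = "&")
  }, character(1L))
  if (length(all_genes) == 0L) counts[] <- 0L
  counts
}

#' Overlap statistics of mutant-specific sets with the common set
#'
#' One row per mutant set: intersection size with the common
#' stress-responsive set, overlapping coefficient, and upper-tail
#' hypergeometric p-value against the supplied universe. The universe is
#' an explicit required argument and is always reported, since overlap
#' p-values are meaningless without it.
#'
#' @param common Character vector: the common stress-responsive set.
#' @param mutant_sets Named list of character vectors.
#' @param universe Character vector containing all tested genes.
#' @return data.frame with columns `set`, `n_common`, `n_set`,
#'   `n_overlap`, `universe_size`, `overlap_coefficient`,
#'   `hypergeometric_p`.
#' @export
mutant_nutrient_intersections <- function(common, mutant_sets, universe) {
  if (is.null(names(mutant_sets))) stop("'mutant_sets' must be named")
  common <- unique(common)
  rows <- lapply(names(mutant_sets), function(nm) {
    m <- unique(mutant_sets[[nm]])
    data.frame(set = nm,
               n_common = length(common),
               n_set = length(m),
               n_overlap = length(intersect(common, m)),
               universe_size = length(unique(universe)),
               overlap_coefficient = overlap_coefficient(common, m),
               hypergeometric_p = hypergeometric_overlap(common, m, universe),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
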