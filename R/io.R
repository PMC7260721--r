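#' Read a tab-separated expression matrix
#'
#' The expected layout is the one the pipeline writes: first column gene
#' identifiers, remaining columns one sample each, values on the log2 scale.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus >=1 sample column")
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene identifiers in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write an expression matrix as TSV
#'
#' @param matrix Numeric matrix, gene rownames and sample colnames.
#' @param path Output path.
#' @param id_column Name of the identifier column (default `"gene"`).
#' @export
write_expression_tsv <- function(matrix, path, id_column = "gene") {
  df <- data.frame(rownames(matrix), matrix, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-to-locus map
#'
#' Two-column TSV (probe, locus); a probe appearing on several rows maps to
#' several loci and is treated as ambiguous by [collapse_probes()].
#'
#' @param path Path to a TSV file with columns `probe` and `locus`.
#' @return data.frame with character columns `probe` and `locus`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("probe", "locus") %in% colnames(df)))
    stop("probe map must have columns 'probe' and 'locus'")
  df[c("probe", "locus")]
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (name, description, members per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions;
#'   defaults to the set names.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every gene set must be named")
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-gene-per-line text file
#'
#' @param path Path to a plain-text file, one identifier per line.
#' @return Character vector (blank lines dropped).
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Read a TF-by-gene prior weight matrix from TSV
#'
#' First column TF identifiers, remaining columns one target gene each,
#' entries nonnegative weights.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (TFs in rows, genes in columns).
#' @export
read_prior_matrix <- function(path) {
  m <- read_expression_tsv(path)
  if (any(m < 0)) stop("prior weights must be nonnegative")
  m
}

#' Write a TF-by-gene prior weight matrix as TSV
#'
#' @param priors Numeric matrix (TFs in rows, genes in columns).
#' @param path Output path.
#' @export
write_prior_matrix <- function(priors, path) {
  write_expression_tsv(priors, path, id_column = "tf")
}
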