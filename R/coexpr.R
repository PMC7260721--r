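#' Co-expression network by Pearson edge significance
#'
#' Computes all-pairs Pearson correlations across samples, converts each
#' to `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of freedom
#' (two-sided), adjusts across all pairs (BH by default), and keeps edges
#' with adjusted p below the threshold. Edge weights are the signed
#' correlations; zero-variance genes are excluded with a warning.
#'
#' @param matrix Numeric genes x samples matrix; >= 4 samples.
#' @param fdr_threshold Adjusted-p cut-off (strict `<`), default 5e-4.
#' @param adjust_method `"BH"` (default) or `"bonferroni"`.
#' @return Object of class `gene_network`: data.frame with columns `u`,
#'   `v` (u before v in gene ordering), `weight` (r), `p`, `fdr`;
#'   attributes `nodes`, `n_samples`, `directed = FALSE`.
#' @export
correlation_edges <- function(matrix, fdr_threshold = 5e-4,
                              adjust_method = c("BH", "bonferroni")) {
  adjust_method <- match.arg(adjust_method)
  if (ncol(matrix) < 4L)
    stop("need >= 4 samples (the correlation t-test needs n - 2 >= 2)")
  v <- apply(matrix, 1L, stats::var)
  if (any(v == 0)) {
    warning(sum(v == 0), " zero-variance gene(s) excluded from the network")
    matrix <- matrix[v > 0, , drop = FALSE]
  }
  g <- rownames(matrix)
  if (length(g) < 2L) stop("need >= 2 genes with positive variance")
  n <- ncol(matrix)
  r <- stats::cor(t(matrix))
  iu <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[iu]
  rv2 <- pmin(rv^2, 1)
  tt <- abs(rv) * sqrt((n - 2) / pmax(1 - rv2, .Machine$double.eps))
  p <- 2 * stats::pt(-tt, df = n - 2)
  p[rv2 >= 1] <- 0
  fdr <- stats::p.adjust(p, method = adjust_method)
  keep <- fdr < fdr_threshold
  g1 <- g[iu[keep, 1L]]; g2 <- g[iu[keep, 2L]]
  edges <- data.frame(u = pmin(g1, g2), v = pmax(g1, g2),
                      weight = rv[keep], p = p[keep], fdr = fdr[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$u, edges$v), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, nodes = g, n_samples = n, directed = FALSE,
            class = c("gene_network", "data.frame"))
}

#' Rank network hubs by degree
#'
#' @param net A `gene_network` (or any edge data.frame with columns `u`,
#'   `v`).
#' @param top_k Number of nodes to return; larger than the node count (or
#'   `Inf`, the default) returns the full ranking.
#' @return data.frame with columns `gene`, `degree`, sorted by decreasing
#'   degree, ties broken lexicographically by gene identifier.
#' @export
hub_nodes <- function(net, top_k = Inf) {
  if (nrow(net) == 0L && is.null(attr(net, "nodes")))
    stop("network is empty")
  nodes <- attr(net, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(c(net$u, net$v)))
  deg <- table(factor(c(net$u, net$v), levels = nodes))
  out <- data.frame(gene = nodes, degree = as.integer(deg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, min(top_k, nrow(out)))
}

#' @export
print.gene_network <- function(x, ...) {
  cat(if (isTRUE(attr(x, "directed"))) "Directed" else "Undirected",
      "network:", length(attr(x, "nodes")), "nodes,", nrow(x), "edges\n")
  invisible(x)
}

#' Write a network as an edge-list TSV
#'
#' @param net A `gene_network` data.frame.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(as.data.frame(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a network in SIF format
#'
#' Interaction type is `pp` for undirected co-expression edges and `pd`
#' for directed TF-to-target edges.
#'
#' @param net A `gene_network` data.frame.
#' @param path Output path.
#' @export
write_sif <- function(net, path) {
  type <- if (isTRUE(attr(net, "directed"))) "pd" else "pp"
  writeLines(paste(net$u, type, net$v), path)
  invisible(path)
}

#' Write a network as GraphML
#'
#' @param net A `gene_network` data.frame.
#' @param path Output path.
#' @param tfs Optional character vector of TF identifiers used to set the
#'   `is_tf` node attribute.
#' @export
write_graphml <- function(net, path, tfs = NULL) {
  nodes <- attr(net, "nodes")
  if (is.null(nodes)) nodes <- sort(unique(c(net$u, net$v)))
  g <- igraph::graph_from_data_frame(as.data.frame(net),
                                     directed = isTRUE(attr(net, "directed")),
                                     vertices = data.frame(name = nodes))
  if (!is.null(tfs))
    igraph::V(g)$is_tf <- igraph::V(g)$name %in% tfs
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
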