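test_that("correlation edges use the documented t transform", {
  set.seed(60)
  m <- matrix(rnorm(5 * 12), 5, 12, dimnames = list(paste0("g", 1:5), NULL))
  net <- correlation_edges(m, fdr_threshold = 1)  # keep everything
  expect_equal(nrow(net), choose(5, 2))
  # spot-check each edge against the closed form and cor.test
  for (i in seq_len(nrow(net))) {
    r <- net$weight[i]
    tt <- abs(r) * sqrt((12 - 2) / (1 - r^2))
    expect_equal(net$p[i], 2 * pt(-tt, df = 10), tolerance = 1e-10)
    ct <- cor.test(m[net$u[i], ], m[net$v[i], ])
    expect_equal(net$p[i], ct$p.value, tolerance = 1e-10)
  }
  # the worked value: r = 0.8, n = 12 -> t = 4.216
  expect_equal(0.8 * sqrt(10 / (1 - 0.64)), 4.2164, tolerance = 1e-4)

  # a duplicated gene gives r = 1 and is always retained
  m2 <- rbind(m, g6 = m["g1", ] )
  net2 <- correlation_edges(m2, fdr_threshold = 5e-4)
  dup <- net2[net2$u == "g1" & net2$v == "g6", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$weight, 1)

  expect_error(correlation_edges(m[, 1:3]), ">= 4 samples")
  m3 <- m; m3[2, ] <- 7
  expect_warning(correlation_edges(m3, fdr_threshold = 1), "zero-variance")
})

test_that("edge sets are invariant to row permutation and degrees add up", {
  set.seed(61)
  m <- matrix(rnorm(30 * 20), 30, 20,
              dimnames = list(sprintf("g%02d", 1:30), NULL))
  m[2, ] <- m[1, ] + rnorm(20, sd = 0.1)
  m[3, ] <- m[1, ] + rnorm(20, sd = 0.1)
  net <- correlation_edges(m, fdr_threshold = 0.01)
  perm <- sample(30)
  net_p <- correlation_edges(m[perm, ], fdr_threshold = 0.01)
  key <- function(n) sort(paste(n$u, n$v))
  expect_equal(key(net), key(net_p))

  hubs <- hub_nodes(net)
  expect_equal(sum(hubs$degree), 2 * nrow(net))
})

test_that("hub ranking is by degree with lexicographic ties", {
  star <- structure(
    data.frame(u = rep("ctr", 5), v = paste0("leaf", 1:5),
               weight = 1, p = 0, fdr = 0),
    nodes = c("ctr", paste0("leaf", 1:5)), directed = FALSE,
    class = c("gene_network", "data.frame"))
  h <- hub_nodes(star)
  expect_equal(h$gene[1], "ctr")
  expect_equal(h$degree[1], 5L)

  # two components interleave by degree only
  edges <- data.frame(
    u = c("a", "a", "a", "a", "x", "x", "x"),
    v = c("b", "c", "d", "e", "y", "z", "w"),
    weight = 1, p = 0, fdr = 0)
  net <- structure(edges, nodes = sort(unique(c(edges$u, edges$v))),
                   directed = FALSE, class = c("gene_network", "data.frame"))
  h2 <- hub_nodes(net, top_k = 2)
  expect_equal(h2$gene, c("a", "x"))
  expect_equal(h2$degree, c(4L, 3L))
  # top_k beyond node count clamps to the full ranking
  expect_equal(nrow(hub_nodes(net, top_k = 100)), 9L)
})

test_that("targets sharing a TF parent are enriched among retained edges", {
  grn <- simulate_grn(simulate_config(seed = 3))
  tg <- setdiff(rownames(grn$matrix), grn$tfs)
  net <- correlation_edges(grn$matrix[tg, ], fdr_threshold = 5e-4)
  expect_gt(nrow(net), 0)
  parents <- split(grn$truth$true_edges$tf, grn$truth$true_edges$target)
  pairs <- t(utils::combn(sort(tg), 2))
  share <- mapply(function(u, v) {
    length(intersect(parents[[u]], parents[[v]])) > 0
  }, pairs[, 1], pairs[, 2])
  has_edge <- paste(pairs[, 1], pairs[, 2]) %in% paste(net$u, net$v)
  rate_shared <- mean(has_edge[share])
  rate_other <- mean(has_edge[!share])
  odds <- (rate_shared / (1 - rate_shared)) /
    max(rate_other / (1 - rate_other), 1e-12)
  expect_gt(odds, 1)
})

test_that("network export formats round-trip the edge structure", {
  edges <- data.frame(u = c("a", "b"), v = c("b", "c"),
                      weight = c(0.9, -0.8), p = c(1e-6, 1e-5),
                      fdr = c(1e-5, 1e-4))
  net <- structure(edges, nodes = c("a", "b", "c", "d"), directed = FALSE,
                   class = c("gene_network", "data.frame"))
  tmp <- withr::local_tempdir()
  write_edge_list(net, file.path(tmp, "e.tsv"))
  back <- utils::read.delim(file.path(tmp, "e.tsv"))
  expect_equal(back$u, edges$u)
  expect_equal(back$weight, edges$weight)

  write_sif(net, file.path(tmp, "e.sif"))
  expect_equal(readLines(file.path(tmp, "e.sif")),
               c("a pp b", "b pp c"))

  write_graphml(net, file.path(tmp, "e.graphml"), tfs = "a")
  g <- igraph::read_graph(file.path(tmp, "e.graphml"), format = "graphml")
  expect_equal(igraph::gorder(g), 4)   # isolated node d is kept
  expect_equal(igraph::gsize(g), 2)
  expect_equal(sum(igraph::V(g)$is_tf), 1)
})
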