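test_that("network edges are exactly the significant, strong-enough records", {
  rec <- dplyr::bind_rows(
    fake_records("a", "b", "c1", "enhancing", 0.70, q_value = 0.01),
    fake_records("a", "b", "c2", "enhancing", 0.80, q_value = 0.02),
    fake_records("a", "c", "c1", "suppressing", 1.30, q_value = 0.04),
    fake_records("b", "c", "c1", "enhancing", 0.90, q_value = 0.01),  # <15%
    fake_records("c", "d", "c1", "enhancing", 0.60, q_value = 0.20))  # q>alpha
  rec$class[4:5] <- c("enhancing", "none")
  net <- build_network(rec, min_deviation = 0.15, alpha = 0.05)
  expect_equal(nrow(net$edges), 3)
  expect_equal(nrow(net$nodes), 4)  # isolated gene d retained
  expect_true(all(net$edges$q_value <= 0.05))
  expect_true(all(abs(net$edges$deviation_ratio - 1) >= 0.15))
  # no qualifying record omitted
  qual <- rec[rec$q_value <= 0.05 & abs(rec$deviation_ratio - 1) >= 0.15, ]
  expect_equal(nrow(net$edges), nrow(qual))

  none <- build_network(rec[rec$class == "none", ])
  expect_equal(nrow(none$edges), 0)
  expect_equal(nrow(none$nodes), 2)

  one <- build_network(fake_records("a", "b", "c1", "enhancing", 0.70,
                                    q_value = 0.01))
  expect_equal(nrow(one$edges), 1)
})

test_that("Louvain separates disjoint cliques and is seed-deterministic", {
  clique_records <- function(genes, cond) {
    pr <- enumerate_pairs(genes)
    fake_records(pr$gene_a, pr$gene_b, cond, "enhancing", 0.7)
  }
  rec <- dplyr::bind_rows(clique_records(paste0("a", 1:5), "c1"),
                          clique_records(paste0("b", 1:5), "c1"))
  net <- detect_communities(build_network(rec), seed = 1)
  cm <- net$nodes$community
  names(cm) <- net$nodes$gene
  expect_equal(length(unique(cm)), 2)
  expect_equal(length(unique(cm[paste0("a", 1:5)])), 1)
  expect_equal(length(unique(cm[paste0("b", 1:5)])), 1)
  expect_equal(sort(unique(cm)), c(0L, 1L))  # contiguous ids from 0

  tri <- clique_records(c("x", "y", "z"), "c1")
  expect_equal(length(unique(
    detect_communities(build_network(tri), seed = 1)$nodes$community)), 1)

  net2 <- detect_communities(build_network(rec), seed = 1)
  expect_identical(net$nodes$community, net2$nodes$community)
})

test_that("Louvain modularity attains the exhaustive optimum on a barbell", {
  # two 4-cliques joined by one bridge edge
  cl1 <- enumerate_pairs(paste0("a", 1:4))
  cl2 <- enumerate_pairs(paste0("b", 1:4))
  rec <- dplyr::bind_rows(
    fake_records(cl1$gene_a, cl1$gene_b, "c1", "enhancing", 0.7),
    fake_records(cl2$gene_a, cl2$gene_b, "c1", "enhancing", 0.7),
    fake_records("a1", "b1", "c1", "enhancing", 0.7))
  net <- detect_communities(build_network(rec), seed = 2)
  g <- igraph::simplify(net$graph)

  best <- -Inf
  for (p in set_partitions(igraph::vcount(g))) {
    member <- integer(igraph::vcount(g))
    for (k in seq_along(p)) member[p[[k]]] <- k
    best <- max(best, igraph::modularity(g, member))
  }
  got <- igraph::modularity(g, net$nodes$community + 1)
  expect_equal(got, best, tolerance = 1e-12)
  # and never below the singleton partition
  expect_gte(got, igraph::modularity(g, seq_len(igraph::vcount(g))))
})

test_that("force-directed layout is deterministic and separates cliques", {
  cl1 <- enumerate_pairs(paste0("a", 1:5))
  cl2 <- enumerate_pairs(paste0("b", 1:5))
  rec <- dplyr::bind_rows(
    fake_records(cl1$gene_a, cl1$gene_b, "c1", "enhancing", 0.7),
    fake_records(cl2$gene_a, cl2$gene_b, "c1", "enhancing", 0.7),
    fake_records("a1", "b1", "c1", "enhancing", 0.7))
  n1 <- layout_network(build_network(rec), seed = 9)
  n2 <- layout_network(build_network(rec), seed = 9)
  expect_identical(n1$nodes[c("x", "y")], n2$nodes[c("x", "y")])
  expect_true(all(is.finite(c(n1$nodes$x, n1$nodes$y))))

  xy <- as.matrix(n1$nodes[c("x", "y")])
  rownames(xy) <- n1$nodes$gene
  d <- as.matrix(dist(xy))
  a <- paste0("a", 1:5); b <- paste0("b", 1:5)
  intra <- mean(c(d[a, a][upper.tri(d[a, a])], d[b, b][upper.tri(d[b, b])]))
  inter <- mean(d[a, b])
  expect_lt(intra, inter)

  # single node sits at the origin
  single <- build_network(fake_records("a", "b", "c1", "none", 1,
                                       q_value = 1),
                          genes = "solo")
  s <- layout_network(single, seed = 1)
  expect_equal(unname(unlist(s$nodes[s$nodes$gene == "solo", c("x", "y")])),
               c(0, 0))
})

test_that("networks export and re-import losslessly", {
  rec <- dplyr::bind_rows(
    fake_records("a", "b", "c1", "enhancing", 0.7, q_value = 0.01),
    fake_records("a", "b", "c2", "suppressing", 1.4, q_value = 0.02),
    fake_records("b", "c", "c1", "enhancing", 0.6, q_value = 0.03))
  net <- build_network(rec) |> detect_communities(seed = 1) |>
    layout_network(seed = 1)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- import_network(gml, "graphml")
  expect_equal(nrow(back$edges), 3)
  expect_equal(sort(back$nodes$gene), sort(net$nodes$gene))
  expect_equal(back$nodes$community[match(net$nodes$gene, back$nodes$gene)],
               net$nodes$community)
  expect_equal(sort(back$edges$condition), sort(net$edges$condition))
  expect_equal(sort(back$edges$deviation_ratio),
               sort(net$edges$deviation_ratio))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  expect_equal(nrow(readr::read_tsv(tsv, show_col_types = FALSE)), 3)
  back2 <- import_network(tsv, "tsv")
  expect_equal(nrow(back2$edges), 3)

  # edgeless networks still export
  empty <- build_network(fake_records("a", "b", "c1", "none", 1,
                                      q_value = 1))
  gml2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, gml2, "graphml")
  expect_equal(nrow(import_network(gml2)$edges), 0)

  expect_error(export_network(net, tsv, "gexf"), "should be one of|arg")
})
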