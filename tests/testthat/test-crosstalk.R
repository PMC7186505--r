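test_that("Jaccard and overlap coefficients follow their set formulas", {
  a <- c("X", "Y", "Z")
  expect_equal(jaccard(a, a), 1)
  expect_equal(overlap_coefficient(a, a), 1)
  expect_equal(jaccard(a, c("P", "Q")), 0)
  expect_equal(overlap_coefficient(a, c("P", "Q")), 0)
  expect_equal(overlap_coefficient(c("X", "Y"), a), 1)  # subset saturates OC

  fat <- c("PLPP3", "APOA1", "APOB", "ABCG5", "ABCG8")
  bile <- c("LDLR", "ABCG5", "ABCG8")
  expect_equal(jaccard(fat, bile), 2 / 6)
  expect_equal(overlap_coefficient(fat, bile), 2 / 3)

  expect_error(jaccard(character(), character()), "undefined")
  expect_error(overlap_coefficient(character(), a), "undefined")
})

test_that("JC never exceeds OC and both are symmetric, over random set pairs", {
  set.seed(13)
  pool <- sprintf("g%d", 1:40)
  for (i in 1:200) {
    a <- sample(pool, sample(1:15, 1))
    b <- sample(pool, sample(1:15, 1))
    jc <- jaccard(a, b); oc <- overlap_coefficient(a, b)
    expect_lte(jc, oc + 1e-15)
    expect_true(jc >= 0 && oc <= 1)
    expect_equal(jc, jaccard(b, a))
    expect_equal(oc, overlap_coefficient(b, a))
  }
})

test_that("pathway eligibility applies the p-value and gene-count rules", {
  pw <- read_pathways(fx("table2_pathways.tsv"))
  expect_equal(nrow(pw), 24)
  el <- filter_eligible(pw, p_max = 0.05, min_genes = 3)
  expect_equal(nrow(el), 22)
  # single- and two-gene pathways fall out
  expect_false(any(c("hsa00091", "hsa04977") %in% el$id))
  expect_equal(nrow(filter_eligible(pw, p_max = 1, min_genes = 1)), 24)
  # tightening thresholds never adds pathways
  expect_true(all(filter_eligible(pw, 0.01, 4)$id %in% el$id))
})

test_that("crosstalk edges equal a brute-force pairwise enumeration", {
  pw <- filter_eligible(read_pathways(fx("table2_pathways.tsv")))
  g <- build_crosstalk(pw, min_shared = 2)
  expect_equal(nrow(g$edges), brute_crosstalk_edges(pw$genes, 2))
  expect_true(all(g$edges$intersection >= 2))
  expect_true(all(g$edges$jc <= g$edges$oc + 1e-15))
  expect_equal(g$edges$weight, (g$edges$jc + g$edges$oc) / 2)

  set.seed(21)
  for (i in 1:10) {
    genes <- replicate(8, sample(sprintf("g%d", 1:30), sample(3:10, 1)),
                       simplify = FALSE)
    nodes <- pathway_nodes(sprintf("p%d", 1:8), sprintf("p%d", 1:8),
                           runif(8, 0, 0.04), genes)
    for (ms in 1:4) {
      expect_equal(nrow(build_crosstalk(nodes, ms)$edges),
                   brute_crosstalk_edges(genes, ms))
    }
  }
})

test_that("raising min_shared never adds edges; degenerate inputs behave", {
  pw <- filter_eligible(read_pathways(fx("table2_pathways.tsv")))
  e2 <- build_crosstalk(pw, 2)$edges
  e3 <- build_crosstalk(pw, 3)$edges
  expect_lte(nrow(e3), nrow(e2))
  key <- function(e) paste(e$pathway_a, e$pathway_b)
  expect_true(all(key(e3) %in% key(e2)))

  disjoint <- pathway_nodes(c("a", "b"), c("a", "b"), c(0.01, 0.01),
                            list(c("X", "Y", "Z"), c("P", "Q", "R")))
  gd <- build_crosstalk(disjoint)
  expect_equal(nrow(gd$edges), 0)
  expect_setequal(gd$isolates, c("a", "b"))
  expect_length(gd$components, 0)

  twin <- pathway_nodes(c("a", "b"), c("a", "b"), c(0.01, 0.01),
                        list(c("X", "Y", "Z"), c("X", "Y", "Z")))
  gt <- build_crosstalk(twin)
  expect_equal(nrow(gt$edges), 1)
  expect_equal(gt$edges$jc, 1)
  expect_equal(gt$edges$oc, 1)
  expect_equal(gt$edges$weight, 1)
})

test_that("components partition the non-isolate nodes", {
  g <- build_crosstalk(filter_eligible(read_pathways(fx("table2_pathways.tsv"))))
  in_comp <- unlist(g$components)
  expect_equal(sort(c(in_comp, g$isolates)), sort(g$nodes$id))
  expect_false(any(g$isolates %in% in_comp))
})

test_that("centralities follow closed forms on stars and paths", {
  star <- pathway_nodes(
    sprintf("n%d", 1:5), sprintf("n%d", 1:5), rep(0.01, 5),
    c(list(c("A", "B", "C", "D", "E", "F", "G", "H")),
      lapply(1:4, function(i) c(LETTERS[2 * i - 1], LETTERS[2 * i], "ZZ"))))
  # hub shares 2 genes with each leaf; leaves share only "ZZ" pairwise? no:
  # leaves pairwise share just ZZ (1 gene) so only hub-leaf edges remain
  gs <- build_crosstalk(star, min_shared = 2)
  expect_equal(nrow(gs$edges), 4)
  cr <- centrality_report(gs)
  expect_equal(cr$id[1], "n1")
  expect_equal(cr$degree[1], 4L)
  expect_equal(cr$betweenness[1], 1)
  expect_true(all(cr$betweenness[-1] == 0))

  chain <- pathway_nodes(c("A", "B", "C"), c("A", "B", "C"), rep(0.01, 3),
                         list(c("g1", "g2", "g3"),
                              c("g2", "g3", "g4", "g5"),
                              c("g4", "g5", "g6")))
  gc <- build_crosstalk(chain, 2)
  crc <- centrality_report(gc)
  expect_equal(crc$betweenness[crc$id == "B"], 1)
  expect_equal(sum(crc$betweenness[crc$id != "B"]), 0)

  expect_error(centrality_report(build_crosstalk(chain, 5)), "no edges")
})

test_that("the enriched-pathway fixture graph has its known topology", {
  g <- build_crosstalk(filter_eligible(read_pathways(fx("table2_pathways.tsv"))))
  cr <- centrality_report(g)
  expect_equal(cr$name[1], "Pathways in cancer")
  expect_equal(cr$degree[1], 16L)
  expect_equal(sort(lengths(g$components), decreasing = TRUE), c(19, 2))
  expect_equal(g$isolates, "hsa00561")
})

test_that("graph export round-trips through GraphML and TSV", {
  g <- build_crosstalk(filter_eligible(read_pathways(fx("table2_pathways.tsv"))))
  dir <- withr::local_tempdir()
  gml <- file.path(dir, "graph.graphml")
  export_graph(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_equal(igraph::vcount(back), igraph::vcount(g$graph))
  expect_setequal(igraph::V(back)$name, igraph::V(g$graph)$name)
  ord <- order(igraph::E(back)$jc)
  expect_equal(igraph::E(back)$jc[ord], sort(g$edges$jc), tolerance = 1e-9)

  tsv <- file.path(dir, "graph.tsv")
  export_graph(g, tsv)
  back_tsv <- read.delim(tsv)
  expect_equal(nrow(back_tsv), nrow(g$edges))
  expect_equal(back_tsv$weight, g$edges$weight, tolerance = 1e-9)

  empty <- build_crosstalk(pathway_nodes("a", "a", 0.01,
                                         list(c("X", "Y", "Z"))))
  export_graph(empty, tsv)
  expect_equal(nrow(read.delim(tsv)), 0)
  expect_error(export_graph(g, file.path(dir, "graph.xyz")), "format")
})
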