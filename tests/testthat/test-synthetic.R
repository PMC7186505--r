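small_cfg <- function(...) {
  defaults <- list(n_genes = 300, n_true = 40, module_size = 12,
                   network_n_nodes = 80, n_pathways = 12,
                   pathway_size_range = c(8, 20), n_tissues = 8,
                   planted_tissue = "T02", seed = 5)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

test_that("the generator is byte-identical given the same configuration", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_cfg()
  out1 <- generate_synthetic_data(cfg, d1)
  out2 <- generate_synthetic_data(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
  }
  expect_identical(out1$truth, out2$truth)
})

test_that("every generated file parses through its loader without warnings", {
  dir <- withr::local_tempdir()
  out <- generate_synthetic_data(small_cfg(), dir)
  expect_no_warning(tab <- load_evidence(out$evidence_files))
  expect_equal(length(tab$sources), 9)
  expect_no_warning(coll <- read_gmt(out$pathways$gmt))
  expect_equal(length(coll$ids), 12)
  expect_no_warning(net <- load_edges(out$network$edges))
  expect_true(igraph::vcount(net) <= 80)
  expect_no_warning(psi <- read_psi_matrix(out$psi$psi))
  expect_equal(dim(psi), c(300, 8))
})

test_that("sensitivity and false-positive settings shape the reported lists", {
  dir <- withr::local_tempdir()
  perfect <- synthetic_config(
    n_genes = 200, n_true = 30, module_size = 10,
    sources = data.frame(label = "s1", sensitivity = 1,
                         n_false_positives = 0L), seed = 9)
  out <- generate_evidence(perfect, dir)
  expect_setequal(out$truth$reported$s1, out$truth$true_genes)

  blind <- synthetic_config(
    n_genes = 200, n_true = 30, module_size = 10,
    sources = data.frame(label = "s1", sensitivity = 0,
                         n_false_positives = 5L), seed = 9)
  out2 <- generate_evidence(blind, dir)
  expect_length(out2$truth$reported$s1, 5)
  expect_false(any(out2$truth$reported$s1 %in% out2$truth$true_genes))

  expect_error(synthetic_config(sources = data.frame(
    label = "s1", sensitivity = 1.4, n_false_positives = 0L)), "\\[0, 1\\]")
})

test_that("mean cumulative score of planted genes matches the binomial expectation", {
  cfg <- synthetic_config(
    n_genes = 2000, n_true = 200,
    sources = data.frame(label = sprintf("s%d", 1:9), sensitivity = 0.9,
                         n_false_positives = 20L),
    seed = 123)
  dir <- withr::local_tempdir()
  out <- generate_evidence(cfg, dir)
  sc <- cumulative_score(load_evidence(out$files))
  true_scores <- sc$score[sc$gene %in% out$truth$true_genes]
  expect_length(true_scores, 200)
  # per-gene score ~ Binomial(9, 0.9); mean of 200 genes within 3 SE of 8.1
  se <- sqrt(9 * 0.9 * 0.1 / 200)
  expect_lt(abs(mean(true_scores) - 8.1), 3 * se)
})

test_that("fully planted pathways are subsets of the true genes and rank first", {
  cfg <- small_cfg(planted_pathway_fraction = 1, n_planted_pathways = 1,
                   pathway_size_range = c(8, 15))
  dir <- withr::local_tempdir()
  ev <- generate_evidence(cfg, dir)
  pw <- generate_pathways(cfg, ev$truth, dir)
  coll <- read_gmt(pw$gmt, universe = sprintf("G%06d", 1:300))
  planted <- pw$planted_pathways
  expect_true(all(coll$genes[[planted]] %in% ev$truth$true_genes))
  res <- enrich_collection(ev$truth$true_genes, coll)
  expect_equal(res$set_id[1], planted)
  expect_equal(res$p_bh[1], min(res$p_bh))
})

test_that("forcing shared genes between pathways yields the constructed intersection", {
  shared <- sprintf("g%d", 1:4)
  nodes <- pathway_nodes(c("p1", "p2"), c("p1", "p2"), c(0.01, 0.02),
                         list(c(shared, "a1", "a2"), c(shared, "b1")))
  g <- build_crosstalk(nodes, min_shared = 2)
  expect_equal(g$edges$intersection, 4L)
})

test_that("edge probabilities bound the generated network structure", {
  dir <- withr::local_tempdir()
  clique_cfg <- small_cfg(background_edge_prob = 0, module_edge_prob = 1)
  ev <- generate_evidence(clique_cfg, dir)
  net_out <- generate_network(clique_cfg, ev$truth, dir)
  net <- load_edges(net_out$edges)
  m <- length(ev$truth$planted_module_nodes)
  expect_equal(igraph::ecount(net), choose(m, 2))
  expect_setequal(igraph::V(net)$name, ev$truth$planted_module_nodes)

  expect_error(small_cfg(background_edge_prob = 0.5, module_edge_prob = 0.1),
               "module_edge_prob")
})

test_that("planted pSI entries always pass the conventional threshold", {
  cfg <- small_cfg(psi_signal_quantile = 0.01)
  dir <- withr::local_tempdir()
  ev <- generate_evidence(cfg, dir)
  psi <- read_psi_matrix(generate_psi(cfg, ev$truth, dir)$psi)
  sets <- threshold_psi(psi, 0.05)
  expect_true(all(ev$truth$true_genes %in% sets$genes[[cfg$planted_tissue]]))
})

test_that("without planted tissue signal, Bonferroni rarely flags any tissue", {
  hits <- 0L
  n_seeds <- 50
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(n_genes = 400, n_true = 0, module_size = 0,
                            n_tissues = 10, planted_tissue = "T01", seed = 1000 + s)
    dir <- withr::local_tempdir()
    truth <- list(true_genes = character(), planted_tissue = "T01")
    psi <- read_psi_matrix(generate_psi(cfg, truth, dir)$psi)
    cand <- evigene:::with_seed(2000 + s, sample(rownames(psi), 40))
    res <- tissue_enrichment(cand, threshold_psi(psi, 0.05))
    if (any(res$significant)) hits <- hits + 1L
  }
  expect_lte(hits, ceiling(0.05 * n_seeds))
})
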