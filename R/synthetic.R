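#' Configuration for the synthetic benchmark generator
#'
#' Defines a benchmark with known planted structure: a gene universe with a
#' subset of planted "true" genes; evidence sources that each report true
#' genes with a given sensitivity plus uniform background false positives;
#' overlapping pathway annotations with designated enriched pathways drawn
#' from the true genes; an interaction network with a dense module planted
#' over true genes; and a specificity (pSI) matrix in which the true genes
#' are planted as specific to one tissue.
#'
#' Defaults describe a benchmark of realistic scale for this analysis: a
#' 2,000-gene universe with 200 planted genes, nine evidence sources at
#' sensitivity 0.8 with 20 false positives each, a 300-node network with a
#' 30-gene module (background edge probability 0.05, module 0.5), 50
#' pathways of 10-40 genes, and 25 tissues with planted pSI values below
#' the 0.01 quantile.
#'
#' @param n_genes gene universe size.
#' @param n_true number of planted true genes.
#' @param sources data.frame with columns \code{label}, \code{sensitivity}
#'   (in [0, 1]) and \code{n_false_positives} (>= 0); default nine sources
#'   at sensitivity 0.8 with 20 false positives each.
#' @param n_pathways number of pathway gene sets.
#' @param pathway_size_range length-2 integer range of pathway sizes.
#' @param planted_pathway_fraction fraction of a designated pathway's
#'   members drawn from the true genes.
#' @param n_planted_pathways number of designated enriched pathways.
#' @param network_n_nodes number of network nodes (true-gene module plus a
#'   background sample of the universe).
#' @param background_edge_prob background (Erdos-Renyi) edge probability.
#' @param module_edge_prob edge probability within the planted module; must
#'   be >= \code{background_edge_prob}.
#' @param module_size number of planted module genes (drawn from the true
#'   genes).
#' @param n_tissues number of tissues in the pSI matrix.
#' @param planted_tissue label of the tissue the true genes are planted in;
#'   tissues are labeled \code{T01}, \code{T02}, ...
#' @param psi_signal_quantile planted pSI values are drawn uniformly below
#'   this quantile, in (0, 1).
#' @param seed integer seed making all generated files byte-identical across
#'   runs.
#' @return A validated list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_genes = 2000L,
                             n_true = 200L,
                             sources = NULL,
                             n_pathways = 50L,
                             pathway_size_range = c(10L, 40L),
                             planted_pathway_fraction = 0.8,
                             n_planted_pathways = 3L,
                             network_n_nodes = 300L,
                             background_edge_prob = 0.05,
                             module_edge_prob = 0.5,
                             module_size = 30L,
                             n_tissues = 25L,
                             planted_tissue = "T01",
                             psi_signal_quantile = 0.01,
                             seed = 1L) {
  if (is.null(sources)) {
    sources <- data.frame(
      label = sprintf("source%d", 1:9),
      sensitivity = 0.8,
      n_false_positives = 20L,
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(sources),
            all(c("label", "sensitivity", "n_false_positives") %in% names(sources)))
  if (anyDuplicated(sources$label)) {
    stop("duplicate source label in synthetic config", call. = FALSE)
  }
  check_prob(sources$sensitivity, "`sensitivity`")
  if (any(sources$n_false_positives < 0)) {
    stop("`n_false_positives` must be >= 0", call. = FALSE)
  }
  n_genes <- check_count(n_genes, "`n_genes`", min = 1L)
  n_true <- check_count(n_true, "`n_true`", min = 0L)
  if (n_true > n_genes) stop("`n_true` exceeds `n_genes`", call. = FALSE)
  check_prob(c(background_edge_prob, module_edge_prob,
               planted_pathway_fraction), "edge/fraction probabilities")
  if (module_edge_prob < background_edge_prob) {
    stop("`module_edge_prob` must be >= `background_edge_prob`", call. = FALSE)
  }
  if (psi_signal_quantile <= 0 || psi_signal_quantile >= 1) {
    stop("`psi_signal_quantile` must be in (0, 1)", call. = FALSE)
  }
  module_size <- check_count(module_size, "`module_size`", min = 0L)
  if (module_size > max(n_true, 1L)) {
    stop("`module_size` exceeds `n_true`", call. = FALSE)
  }
  n_tissues <- check_count(n_tissues, "`n_tissues`", min = 1L)
  tissues <- sprintf("T%02d", seq_len(n_tissues))
  if (!planted_tissue %in% tissues) {
    stop(sprintf("unknown `planted_tissue` '%s' (tissues are %s..%s)",
                 planted_tissue, tissues[1L], tissues[n_tissues]),
         call. = FALSE)
  }
  structure(list(
    n_genes = n_genes, n_true = n_true, sources = sources,
    n_pathways = check_count(n_pathways, "`n_pathways`", min = 1L),
    pathway_size_range = as.integer(pathway_size_range),
    planted_pathway_fraction = planted_pathway_fraction,
    n_planted_pathways = check_count(n_planted_pathways,
                                     "`n_planted_pathways`", min = 0L),
    network_n_nodes = check_count(network_n_nodes, "`network_n_nodes`",
                                  min = 2L),
    background_edge_prob = background_edge_prob,
    module_edge_prob = module_edge_prob,
    module_size = module_size,
    n_tissues = n_tissues, tissues = tissues,
    planted_tissue = planted_tissue,
    psi_signal_quantile = psi_signal_quantile,
    seed = check_count(seed, "`seed`", min = -.Machine$integer.max)
  ), class = "synthetic_config")
}

synthetic_universe <- function(config) {
  sprintf("G%06d", seq_len(config$n_genes))
}

# planted structure shared by all generator stages; deterministic in the seed
synthetic_truth <- function(config) {
  universe <- synthetic_universe(config)
  with_seed(config$seed, {
    true_genes <- sort(sample(universe, config$n_true))
    module <- sort(sample(true_genes, config$module_size))
    list(true_genes = true_genes,
         planted_module_nodes = module,
         planted_tissue = config$planted_tissue)
  })
}

#' Generate per-source evidence files with planted true genes
#'
#' Each source independently reports each true gene with the source's
#' sensitivity and adds its configured number of false positives sampled
#' uniformly from the non-true genes. Output is one TSV per source
#' (column \code{gene}).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param outdir output directory (created if needed).
#' @return List with \code{files} (named label -> path, usable directly by
#'   \code{\link{load_evidence}}) and \code{truth} (the planted-signal
#'   ledger: \code{true_genes}, per-source \code{reported},
#'   \code{planted_module_nodes}, \code{planted_tissue}).
#' @export
generate_evidence <- function(config, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  universe <- synthetic_universe(config)
  truth <- synthetic_truth(config)
  non_true <- setdiff(universe, truth$true_genes)
  reported <- list()
  files <- character()
  with_seed(config$seed + 1L, {
    for (i in seq_len(nrow(config$sources))) {
      lab <- config$sources$label[i]
      sens <- config$sources$sensitivity[i]
      nfp <- config$sources$n_false_positives[i]
      tp <- truth$true_genes[stats::runif(length(truth$true_genes)) < sens]
      fp <- if (nfp > 0L) sample(non_true, min(nfp, length(non_true))) else character()
      genes <- c(tp, fp)
      path <- file.path(outdir, sprintf("evidence_%s.tsv",
                                        gsub("[^A-Za-z0-9_.-]", "_", lab)))
      utils::write.table(data.frame(gene = genes), path, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      reported[[lab]] <- genes
      files[[lab]] <- path
    }
  })
  truth$reported <- reported
  list(files = files, truth = truth)
}

#' Generate overlapping pathway gene sets with designated enriched pathways
#'
#' Pathway sizes are drawn uniformly from the configured range. The first
#' \code{n_planted_pathways} pathways draw \code{planted_pathway_fraction}
#' of their members from the true genes (the rest from non-true genes);
#' remaining pathways are sampled uniformly from the universe. Adjusted
#' p-values are assigned below 0.05 for designated pathways and above for
#' the rest, so downstream filtering recovers the designated set.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param truth planted-signal ledger from \code{\link{generate_evidence}}.
#' @param outdir output directory.
#' @return List with \code{gmt} (path), \code{pvalues} (path to a TSV
#'   \code{id<TAB>p_adjusted}) and \code{planted_pathways} (ids).
#' @export
generate_pathways <- function(config, truth, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  universe <- synthetic_universe(config)
  rng <- config$pathway_size_range
  if (max(rng) > config$n_genes) {
    stop("pathway size exceeds the gene universe", call. = FALSE)
  }
  non_true <- setdiff(universe, truth$true_genes)
  n_planted <- min(config$n_planted_pathways, config$n_pathways)
  ids <- sprintf("PW%03d", seq_len(config$n_pathways))
  with_seed(config$seed + 2L, {
    sizes <- sample(seq.int(rng[1L], rng[2L]), config$n_pathways,
                    replace = TRUE)
    members <- lapply(seq_len(config$n_pathways), function(i) {
      if (i <= n_planted) {
        k_true <- min(round(config$planted_pathway_fraction * sizes[i]),
                      length(truth$true_genes))
        c(sample(truth$true_genes, k_true),
          sample(non_true, sizes[i] - k_true))
      } else {
        sample(universe, sizes[i])
      }
    })
    p_adj <- c(stats::runif(n_planted, 1e-6, 0.04),
               stats::runif(config$n_pathways - n_planted, 0.06, 1))
    collection <- geneset_collection(stats::setNames(members, ids),
                                     names = ids, universe = universe)
    gmt_path <- file.path(outdir, "pathways.gmt")
    write_gmt(collection, gmt_path)
    pv_path <- file.path(outdir, "pathway_pvalues.tsv")
    utils::write.table(data.frame(id = ids, p_adjusted = p_adj),
                       pv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(gmt = gmt_path, pvalues = pv_path,
         planted_pathways = ids[seq_len(n_planted)])
  })
}

#' Generate an interaction network with a planted dense module
#'
#' Node set: the planted module genes plus a background sample of the
#' universe up to \code{network_n_nodes}. Each unordered node pair receives
#' an edge with probability \code{module_edge_prob} when both endpoints are
#' module genes and \code{background_edge_prob} otherwise (an Erdos-Renyi
#' background with an upgraded module block).
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param truth planted-signal ledger from \code{\link{generate_evidence}}.
#' @param outdir output directory.
#' @return List with \code{edges} (path to a two-column TSV) and
#'   \code{nodes} (the node symbols).
#' @export
generate_network <- function(config, truth, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  universe <- synthetic_universe(config)
  module <- truth$planted_module_nodes
  if (config$network_n_nodes < length(module)) {
    stop("`network_n_nodes` smaller than the planted module", call. = FALSE)
  }
  with_seed(config$seed + 3L, {
    background <- sample(setdiff(universe, module),
                         config$network_n_nodes - length(module))
    nodes <- c(module, background)
    n <- length(nodes)
    pair <- utils::combn(n, 2L)
    in_module <- seq_len(n) <= length(module)
    p <- ifelse(in_module[pair[1L, ]] & in_module[pair[2L, ]],
                config$module_edge_prob, config$background_edge_prob)
    keep <- stats::runif(ncol(pair)) < p
    edges <- data.frame(from = nodes[pair[1L, keep]],
                        to = nodes[pair[2L, keep]],
                        stringsAsFactors = FALSE)
    path <- file.path(outdir, "edges.tsv")
    utils::write.table(edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    list(edges = path, nodes = nodes)
  })
}

#' Generate a pSI specificity matrix with planted tissue-specific genes
#'
#' Background entries are uniform on (0, 1); the (true gene, planted
#' tissue) entries are drawn uniformly below \code{psi_signal_quantile},
#' so at the conventional 0.05 cutoff every planted entry qualifies as
#' tissue-enriched.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param truth planted-signal ledger from \code{\link{generate_evidence}}.
#' @param outdir output directory.
#' @return List with \code{psi} (path to the TSV readable by
#'   \code{\link{read_psi_matrix}}).
#' @export
generate_psi <- function(config, truth, outdir) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!truth$planted_tissue %in% config$tissues) {
    stop(sprintf("unknown planted tissue '%s'", truth$planted_tissue),
         call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  universe <- synthetic_universe(config)
  with_seed(config$seed + 4L, {
    mat <- matrix(stats::runif(config$n_genes * config$n_tissues),
                  nrow = config$n_genes,
                  dimnames = list(universe, config$tissues))
    mat[truth$true_genes, truth$planted_tissue] <-
      stats::runif(length(truth$true_genes), 0, config$psi_signal_quantile)
    path <- file.path(outdir, "psi.tsv")
    tab <- data.frame(gene = universe, signif(mat, 6), check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(psi = path)
  })
}

#' Generate the complete synthetic benchmark
#'
#' Runs all four generator stages and writes the planted-signal ledger to
#' \code{truth.json}. With the same configuration (including seed) the
#' output files are byte-identical across runs.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param outdir output directory.
#' @return List with \code{evidence_files}, \code{pathways} (gmt/pvalues
#'   paths), \code{network}, \code{psi}, \code{truth} and
#'   \code{truth_json}.
#' @export
generate_synthetic_data <- function(config, outdir) {
  ev <- generate_evidence(config, outdir)
  pw <- generate_pathways(config, ev$truth, outdir)
  net <- generate_network(config, ev$truth, outdir)
  psi <- generate_psi(config, ev$truth, outdir)
  truth <- ev$truth
  truth$planted_pathways <- pw$planted_pathways
  truth_json <- file.path(outdir, "truth.json")
  jsonlite::write_json(truth, truth_json, auto_unbox = TRUE, pretty = TRUE)
  list(evidence_files = ev$files, pathways = pw, network = net, psi = psi,
       truth = truth, truth_json = truth_json)
}
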