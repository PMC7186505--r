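# Independent brute-force oracles used to check the implementation paths.

# Cumulative score by direct counting over raw (source, gene) records.
brute_scores <- function(records) {
  records <- unique(records[, c("source", "gene")])
  counts <- table(records$gene)
  out <- data.frame(gene = names(counts), score = as.integer(counts),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$gene), ]
}

# Hypergeometric upper tail by exhaustive enumeration of all C(N, q) draws
# of the query from a universe 1..N containing target 1..m.
brute_hyper_tail <- function(k, m, N, q) {
  draws <- utils::combn(N, q)
  hits <- colSums(draws <= m)  # target is 1..m
  mean(hits >= k)
}

# Crosstalk edges by a direct double loop over pathway gene sets.
brute_crosstalk_edges <- function(genes, min_shared = 2L) {
  n <- length(genes)
  out <- 0L
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (length(intersect(genes[[i]], genes[[j]])) >= min_shared) {
        out <- out + 1L
      }
    }
  }
  out
}

# Fixture paths
fx <- function(name) evigene_example(name)

table1_fixture <- function() {
  al <- read_alias_map(fx("gene_aliases.tsv"))
  tab <- read_method_table(fx("table1_genes.tsv"), al)
  files <- evidence_files_from_methods(tab, withr::local_tempdir(.local_envir = parent.frame()))
  load_evidence(files, al)
}

# small Erdos-Renyi igraph with named vertices
random_er_graph <- function(n, p, seed) {
  g <- evigene:::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("N%04d", seq_len(n))
  g
}
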