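#' Load an undirected gene-interaction network from an edge list
#'
#' Expected layout: two tab- or whitespace-separated symbol columns per line
#' (an optional third weight column is ignored); lines starting with \code{#}
#' are skipped. Symbols are normalized through the alias map; duplicate and
#' reversed edges are collapsed and self-loops dropped with a warning.
#'
#' @param path path to the edge-list file.
#' @param aliases optional \code{\link{alias_map}}.
#' @return An undirected simple \code{igraph} graph over gene symbols.
#' @export
load_edges <- function(path, aliases = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  }
  fields <- strsplit(trimws(lines), "[\t ]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge on line %d of '%s': need two symbols",
                 bad[1L], path), call. = FALSE)
  }
  a <- normalize_genes(vapply(fields, `[[`, character(1L), 1L), aliases)
  b <- normalize_genes(vapply(fields, `[[`, character(1L), 2L), aliases)
  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s) in '%s'", sum(loops), path),
            call. = FALSE)
    a <- a[!loops]; b <- b[!loops]
  }
  g <- igraph::graph_from_data_frame(data.frame(from = a, to = b),
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Within-set interaction count
#'
#' The connectivity statistic of a gene set in a network: the number of
#' network edges with both endpoints in the set. Genes absent from the
#' network contribute nothing.
#'
#' @param net an undirected \code{igraph} network over gene symbols.
#' @param genes character vector of gene symbols.
#' @return Non-negative integer edge count.
#' @export
connectivity_stat <- function(net, genes) {
  stopifnot(igraph::is_igraph(net))
  present <- intersect(unique(as.character(genes)),
                       igraph::V(net)$name %||% character())
  if (length(present) < 2L) return(0L)
  igraph::ecount(igraph::induced_subgraph(net, present))
}

#' Permutation test of gene-set network connectivity
#'
#' Compares the within-set edge count of a gene set against a null of random
#' gene sets of the same size drawn uniformly (without replacement) from the
#' network's nodes, summarized as a Z statistic against the null sample mean
#' and standard deviation, with a one-sided upper-tail normal p-value. An
#' empirical permutation p-value \code{(r + 1) / (n + 1)} is reported
#' alongside for robustness. Genes absent from the network are dropped
#' before sizing the null sets.
#'
#' When the null is degenerate (zero standard deviation, e.g. on a complete
#' graph where every same-size set has the same statistic), \code{z} is
#' \code{NA} and \code{p} is 1 if the observed count does not exceed the
#' null mean, else 0.
#'
#' @param net an undirected \code{igraph} network.
#' @param genes character vector of query genes; at least 2 must be present
#'   in the network.
#' @param n_permutations number of random sets (default 1000).
#' @param seed integer RNG seed (required for reproducibility).
#' @return Object of class \code{permutation_test_result}: a list with
#'   \code{observed}, \code{null_mean}, \code{null_sd}, \code{z}, \code{p},
#'   \code{p_empirical}, \code{n_genes_used}, \code{n_permutations},
#'   \code{seed}, \code{degenerate}.
#' @export
permutation_test <- function(net, genes, n_permutations = 1000L, seed) {
  stopifnot(igraph::is_igraph(net))
  n_permutations <- check_count(n_permutations, "`n_permutations`", min = 1L)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  seed <- check_count(seed, "`seed`", min = -.Machine$integer.max)
  nodes <- igraph::V(net)$name
  present <- intersect(unique(as.character(genes)), nodes)
  k <- length(present)
  if (k < 2L) {
    stop("fewer than 2 query genes present in the network", call. = FALSE)
  }
  if (k > length(nodes)) {
    stop("gene set larger than the network", call. = FALSE)
  }
  # index edges once; each null draw costs O(|E|) membership lookups
  ends <- igraph::as_edgelist(net, names = FALSE)
  n_nodes <- length(nodes)
  idx <- match(present, nodes)
  member <- logical(n_nodes); member[idx] <- TRUE
  observed <- sum(member[ends[, 1L]] & member[ends[, 2L]])
  null_counts <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      s <- sample.int(n_nodes, k)
      m <- logical(n_nodes); m[s] <- TRUE
      sum(m[ends[, 1L]] & m[ends[, 2L]])
    }, numeric(1L))
  })
  null_mean <- mean(null_counts)
  null_sd <- stats::sd(null_counts)
  if (n_permutations == 1L) null_sd <- 0
  degenerate <- !is.finite(null_sd) || null_sd == 0
  if (degenerate) {
    message("permutation_test: degenerate null (zero variance); z undefined")
    z <- NA_real_
    p <- if (observed <= null_mean) 1 else 0
  } else {
    z <- (observed - null_mean) / null_sd
    p <- stats::pnorm(z, lower.tail = FALSE)
  }
  structure(list(
    observed = as.integer(observed),
    null_mean = null_mean,
    null_sd = null_sd,
    z = z,
    p = p,
    p_empirical = (sum(null_counts >= observed) + 1) / (n_permutations + 1),
    n_genes_used = k,
    n_permutations = n_permutations,
    seed = seed,
    degenerate = degenerate
  ), class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("<permutation_test_result> observed = %d edges over %d genes\n",
              x$observed, x$n_genes_used))
  cat(sprintf("null: mean %.3f, sd %.3f (%d permutations, seed %d)\n",
              x$null_mean, x$null_sd, x$n_permutations, x$seed))
  if (x$degenerate) {
    cat(sprintf("degenerate null; p = %g\n", x$p))
  } else {
    cat(sprintf("z = %.3f, p = %.3g (empirical p = %.3g)\n",
                x$z, x$p, x$p_empirical))
  }
  invisible(x)
}
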