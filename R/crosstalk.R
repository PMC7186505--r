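#' Jaccard coefficient of two gene sets
#'
#' \eqn{JC = |A \cap B| / |A \cup B|}.
#'
#' @param a,b character vectors of gene symbols; at least one non-empty.
#' @return Value in [0, 1].
#' @export
jaccard <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L) {
    stop("Jaccard coefficient undefined for two empty sets", call. = FALSE)
  }
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap coefficient of two gene sets
#'
#' \eqn{OC = |A \cap B| / \min(|A|, |B|)}; always at least as large as the
#' Jaccard coefficient on the same pair.
#'
#' @param a,b non-empty character vectors of gene symbols.
#' @return Value in [0, 1].
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L || length(b) == 0L) {
    stop("overlap coefficient undefined for an empty set", call. = FALSE)
  }
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Read enriched pathways with their candidate-gene memberships
#'
#' Expected layout: TSV with columns \code{id}, \code{name},
#' \code{p_adjusted} and \code{genes} (comma- or semicolon-separated
#' candidate genes in the pathway); lines starting with \code{#} are
#' ignored. Gene symbols are normalized through the alias map so symbol
#' variants from different tables unify.
#'
#' @param path path to the TSV file.
#' @param aliases optional \code{\link{alias_map}}.
#' @return data.frame with columns \code{id}, \code{name},
#'   \code{p_adjusted}, \code{n_genes} and a list-column \code{genes}.
#' @export
read_pathways <- function(path, aliases = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "name", "p_adjusted", "genes")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("pathway table '%s' lacks column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  check_prob(tab$p_adjusted, "`p_adjusted`")
  genes <- lapply(strsplit(tab$genes, "[,;]"), function(g) {
    unique(normalize_genes(g, aliases))
  })
  pathway_nodes(tab$id, tab$name, tab$p_adjusted, genes)
}

#' Assemble a pathway-node table
#'
#' @param id,name character vectors identifying each pathway.
#' @param p_adjusted adjusted enrichment p-values in [0, 1].
#' @param genes list of character vectors: the candidate genes in each
#'   pathway.
#' @return data.frame with list-column \code{genes} and column
#'   \code{n_genes}.
#' @export
pathway_nodes <- function(id, name, p_adjusted, genes) {
  stopifnot(length(id) == length(name), length(id) == length(p_adjusted),
            length(id) == length(genes))
  if (anyDuplicated(id)) {
    stop(sprintf("duplicate pathway id '%s'", id[duplicated(id)][1L]),
         call. = FALSE)
  }
  check_prob(p_adjusted, "`p_adjusted`")
  genes <- lapply(genes, function(g) unique(as.character(g)))
  out <- data.frame(id = as.character(id), name = as.character(name),
                    p_adjusted = as.numeric(p_adjusted),
                    n_genes = lengths(genes), stringsAsFactors = FALSE)
  out$genes <- genes
  out
}

#' Filter pathways eligible for crosstalk analysis
#'
#' Applies the first two inclusion rules: adjusted p-value strictly below
#' \code{p_max} and at least \code{min_genes} candidate genes.
#'
#' @param pathways data.frame from \code{\link{read_pathways}} /
#'   \code{\link{pathway_nodes}}.
#' @param p_max adjusted p-value threshold (default 0.05).
#' @param min_genes minimum candidate genes per pathway (default 3).
#' @return The eligible subset, input order preserved.
#' @export
filter_eligible <- function(pathways, p_max = 0.05, min_genes = 3L) {
  stopifnot(is.data.frame(pathways),
            all(c("id", "p_adjusted", "genes") %in% names(pathways)))
  min_genes <- check_count(min_genes, "`min_genes`", min = 1L)
  keep <- pathways$p_adjusted < p_max & lengths(pathways$genes) >= min_genes
  out <- pathways[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the pathway crosstalk graph
#'
#' Connects every unordered pair of eligible pathways sharing at least
#' \code{min_shared} candidate genes (the third inclusion rule; the
#' convention is 2). Each edge carries the intersection size, the Jaccard
#' and overlap coefficients, and their arithmetic mean as the edge weight.
#' Connected components are computed over the nodes incident to at least
#' one retained edge; eligible pathways without any edge are reported as
#' isolates.
#'
#' @param eligible data.frame of eligible pathways (see
#'   \code{\link{filter_eligible}}).
#' @param min_shared minimum shared candidate genes per retained pair
#'   (default 2).
#' @return Object of class \code{crosstalk_graph}: list with \code{nodes}
#'   (the eligible pathway table), \code{edges} (data.frame
#'   \code{pathway_a}, \code{pathway_b}, \code{intersection}, \code{jc},
#'   \code{oc}, \code{weight}), \code{graph} (an \code{igraph} over the
#'   non-isolate nodes), \code{components} (list of id vectors) and
#'   \code{isolates} (character vector of ids).
#' @export
build_crosstalk <- function(eligible, min_shared = 2L) {
  stopifnot(is.data.frame(eligible),
            all(c("id", "name", "p_adjusted", "genes") %in% names(eligible)))
  min_shared <- check_count(min_shared, "`min_shared`", min = 1L)
  n <- nrow(eligible)
  rows <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        gi <- eligible$genes[[i]]; gj <- eligible$genes[[j]]
        shared <- length(intersect(gi, gj))
        if (shared >= min_shared) {
          jc <- jaccard(gi, gj)
          oc <- overlap_coefficient(gi, gj)
          rows[[length(rows) + 1L]] <- data.frame(
            pathway_a = eligible$id[i], pathway_b = eligible$id[j],
            intersection = shared, jc = jc, oc = oc, weight = (jc + oc) / 2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  edges <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    data.frame(pathway_a = character(), pathway_b = character(),
               intersection = integer(), jc = numeric(), oc = numeric(),
               weight = numeric(), stringsAsFactors = FALSE)
  }
  connected_ids <- unique(c(edges$pathway_a, edges$pathway_b))
  isolates <- setdiff(eligible$id, connected_ids)
  vert <- eligible[eligible$id %in% connected_ids,
                   c("id", "name", "p_adjusted", "n_genes")]
  # igraph reserves the vertex attribute "name" for the id
  names(vert)[names(vert) == "name"] <- "pathway_name"
  g <- igraph::graph_from_data_frame(
    edges[, c("pathway_a", "pathway_b", "intersection", "jc", "oc", "weight")],
    directed = FALSE, vertices = vert)
  comp <- igraph::components(g)
  components <- unname(split(names(comp$membership), comp$membership))
  components <- components[order(-lengths(components))]
  structure(list(nodes = eligible, edges = edges, graph = g,
                 components = components, isolates = isolates),
            class = "crosstalk_graph")
}

#' @export
print.crosstalk_graph <- function(x, ...) {
  cat(sprintf("<crosstalk_graph> %d eligible pathway(s), %d edge(s)\n",
              nrow(x$nodes), nrow(x$edges)))
  if (length(x$components) > 0L) {
    cat("component sizes:", paste(lengths(x$components), collapse = ", "), "\n")
  }
  if (length(x$isolates) > 0L) {
    cat("isolates:", paste(x$isolates, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Degree and betweenness centrality of crosstalk pathways
#'
#' Centralities are computed on the unweighted retained graph: degree is the
#' number of incident retained edges and betweenness is normalized
#' shortest-path betweenness. Nodes are ranked by degree descending with
#' betweenness as tie-break; isolated eligible pathways appear with zeros.
#'
#' @param graph a \code{\link{build_crosstalk}} result with at least one
#'   edge.
#' @return data.frame with columns \code{id}, \code{name}, \code{degree},
#'   \code{betweenness}, ranked.
#' @export
centrality_report <- function(graph) {
  stopifnot(inherits(graph, "crosstalk_graph"))
  if (nrow(graph$edges) == 0L) {
    stop("crosstalk graph has no edges; centralities undefined", call. = FALSE)
  }
  g <- graph$graph
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, normalized = TRUE)
  out <- data.frame(id = names(deg),
                    degree = as.integer(deg),
                    betweenness = unname(btw),
                    stringsAsFactors = FALSE)
  iso <- graph$isolates
  if (length(iso) > 0L) {
    out <- rbind(out, data.frame(id = iso, degree = 0L, betweenness = 0,
                                 stringsAsFactors = FALSE))
  }
  out$name <- graph$nodes$name[match(out$id, graph$nodes$id)]
  out <- out[order(-out$degree, -out$betweenness, out$id),
             c("id", "name", "degree", "betweenness")]
  rownames(out) <- NULL
  out
}

#' Export a crosstalk graph to file
#'
#' Supported formats: \code{"tsv"} (edge list with all edge attributes) and
#' \code{"graphml"} (full node and edge attributes, importable by Cytoscape
#' or \code{igraph::read_graph}).
#'
#' @param graph a \code{\link{build_crosstalk}} result.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"graphml"}; defaults from the file
#'   extension.
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(graph, path,
                         format = c("auto", "tsv", "graphml")) {
  stopifnot(inherits(graph, "crosstalk_graph"))
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, graphml = "graphml", tsv = "tsv", txt = "tsv",
                     stop(sprintf("cannot infer export format from extension '%s'",
                                  ext), call. = FALSE))
  }
  if (format == "tsv") {
    utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(graph$graph, path, format = "graphml")
  }
  invisible(path)
}
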