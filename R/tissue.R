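#' Read a gene x tissue specificity (pSI) matrix
#'
#' The specificity index (pSI) quantifies how specifically a gene is
#' expressed in a tissue; low values mean highly tissue-specific expression.
#' Expected layout: TSV with a first column \code{gene} and one column per
#' tissue; \code{NA} marks missing values.
#'
#' @param path path to the TSV file.
#' @param aliases optional \code{\link{alias_map}} applied to gene symbols.
#' @return Numeric matrix with genes as rownames and tissues as colnames,
#'   all present values in [0, 1].
#' @export
read_psi_matrix <- function(path, aliases = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (!"gene" %in% names(tab)) {
    stop(sprintf("pSI matrix '%s' lacks required 'gene' column", path),
         call. = FALSE)
  }
  genes <- normalize_genes(tab$gene, aliases)
  mat <- as.matrix(tab[, setdiff(names(tab), "gene"), drop = FALSE])
  storage.mode(mat) <- "double"
  check_prob(mat, sprintf("pSI values in '%s'", path), allow_na = TRUE)
  if (anyDuplicated(genes)) {
    stop(sprintf("duplicate gene symbol '%s' in pSI matrix",
                 genes[duplicated(genes)][1L]), call. = FALSE)
  }
  rownames(mat) <- genes
  mat
}

#' Threshold a pSI matrix into tissue-enriched gene sets
#'
#' A gene belongs to a tissue's enriched set when its pSI in that tissue is
#' strictly below the cutoff (the conventional cutoff is 0.05). Missing
#' values never qualify.
#'
#' @param psi numeric gene x tissue matrix (rownames genes, colnames
#'   tissues), values in [0, 1] or \code{NA}.
#' @param cutoff pSI cutoff in (0, 1); strict inequality.
#' @return A \code{\link{geneset_collection}} with one set per tissue, over
#'   the universe of all genes in the matrix.
#' @export
threshold_psi <- function(psi, cutoff = 0.05) {
  stopifnot(is.matrix(psi), !is.null(rownames(psi)), !is.null(colnames(psi)))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff >= 1) {
    stop("`cutoff` must be a single value in [0, 1)", call. = FALSE)
  }
  sets <- lapply(seq_len(ncol(psi)), function(j) {
    v <- psi[, j]
    rownames(psi)[!is.na(v) & v < cutoff]
  })
  names(sets) <- colnames(psi)
  geneset_collection(sets, universe = rownames(psi))
}

#' Tissue enrichment of a candidate gene set
#'
#' Tests, per tissue, whether the candidate genes over-represent the
#' tissue-enriched gene set using a one-sided Fisher's exact test on the
#' 2x2 table (candidate / not) x (in tissue set / not) over the universe,
#' with Bonferroni correction across tissues for the significance flag.
#'
#' @param candidates character vector of candidate genes.
#' @param tissue_sets a \code{\link{geneset_collection}} of tissue-enriched
#'   sets, e.g. from \code{\link{threshold_psi}}.
#' @param universe background gene universe; defaults to the collection's
#'   universe (all genes in the pSI matrix).
#' @param alpha family-wise error rate; the per-tissue cutoff is
#'   \code{alpha / n_tissues} (25 tissues at alpha 0.05 gives 0.002).
#' @return data.frame with columns \code{tissue}, \code{n_tissue_genes},
#'   \code{overlap_count}, \code{p_fisher}, \code{significant}, sorted by
#'   \code{p_fisher} ascending.
#' @export
tissue_enrichment <- function(candidates, tissue_sets, universe = NULL,
                              alpha = 0.05) {
  stopifnot(inherits(tissue_sets, "geneset_collection"))
  universe <- unique(as.character(universe %||% tissue_sets$universe))
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  candidates <- unique(as.character(candidates))
  outside <- setdiff(candidates, universe)
  if (length(outside) > 0L) {
    warning(sprintf("dropped %d candidate gene(s) outside the universe",
                    length(outside)), call. = FALSE)
    candidates <- intersect(candidates, universe)
  }
  n_tissues <- length(tissue_sets$ids)
  cutoff <- bonferroni_threshold(alpha, max(1L, n_tissues))
  rows <- lapply(tissue_sets$ids, function(tt) {
    tset <- intersect(tissue_sets$genes[[tt]], universe)
    k <- length(intersect(candidates, tset))
    tab <- matrix(c(k,
                    length(candidates) - k,
                    length(tset) - k,
                    length(universe) - length(candidates) - length(tset) + k),
                  nrow = 2L)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(tissue = tt, n_tissue_genes = length(tset), overlap_count = k,
               p_fisher = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_fisher < cutoff
  out <- out[order(out$p_fisher, out$tissue), , drop = FALSE]
  rownames(out) <- NULL
  out
}
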