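#' Construct an evidence table
#'
#' An evidence table records, for every gene, which evidence sources
#' (prioritization method-dataset combinations) nominated it. It is the
#' substrate of the cumulative scoring strategy: a gene's score is the number
#' of distinct sources attesting it.
#'
#' @param entries named list mapping gene symbol to a character vector of
#'   attesting source labels.
#' @param sources character vector of all configured source labels, in run
#'   order. Defaults to the union of labels seen in \code{entries}.
#' @return An object of class \code{evidence_table} with fields
#'   \code{sources} and \code{entries} (per-gene labels, deduplicated).
#' @export
evidence_table <- function(entries, sources = NULL) {
  stopifnot(is.list(entries))
  if (length(entries) > 0L && is.null(names(entries))) {
    stop("`entries` must be a named list (gene -> source labels)", call. = FALSE)
  }
  entries <- lapply(entries, function(s) unique(as.character(s)))
  seen <- unique(unlist(entries, use.names = FALSE))
  if (is.null(sources)) sources <- seen
  sources <- as.character(sources)
  if (anyDuplicated(sources)) {
    stop("duplicate source label in `sources`", call. = FALSE)
  }
  unknown <- setdiff(seen, sources)
  if (length(unknown) > 0L) {
    stop(sprintf("entries attest unknown source label(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  structure(list(sources = sources, entries = entries),
            class = "evidence_table")
}

#' @export
print.evidence_table <- function(x, ...) {
  cat(sprintf("<evidence_table> %d gene(s) x %d source(s)\n",
              length(x$entries), length(x$sources)))
  cat("sources:", paste(x$sources, collapse = ", "), "\n")
  invisible(x)
}

#' Load per-source candidate-gene lists into an evidence table
#'
#' Each file is a TSV with a required \code{gene} column and optional
#' \code{p_primary}, \code{p_secondary} and \code{stat} columns; lines
#' starting with \code{#} are ignored. Genes are normalized through the alias
#' map and deduplicated within each source; the union of genes across all
#' sources forms the table.
#'
#' @param files named character vector mapping source label to file path.
#'   Source order in the table follows the order given here.
#' @param aliases optional \code{\link{alias_map}}.
#' @return An \code{\link{evidence_table}}.
#' @export
load_evidence <- function(files, aliases = NULL) {
  if (is.null(names(files)) || any(names(files) == "")) {
    stop("`files` must be a named vector: source label -> path", call. = FALSE)
  }
  labels <- names(files)
  if (anyDuplicated(labels)) {
    stop(sprintf("duplicate source label '%s'", labels[duplicated(labels)][1L]),
         call. = FALSE)
  }
  entries <- list()
  for (i in seq_along(files)) {
    recs <- read_evidence_file(files[[i]], aliases)
    for (g in unique(recs$gene)) {
      entries[[g]] <- c(entries[[g]], labels[[i]])
    }
  }
  evidence_table(entries, sources = labels)
}

#' Read one evidence source file
#'
#' @param path path to a TSV with at least a \code{gene} column.
#' @param aliases optional \code{\link{alias_map}}.
#' @return data.frame with columns \code{gene}, \code{p_primary},
#'   \code{p_secondary}, \code{stat} (missing optional columns filled with
#'   \code{NA}).
#' @export
read_evidence_file <- function(path, aliases = NULL) {
  tab <- tryCatch(
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse evidence file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  if (!"gene" %in% names(tab)) {
    stop(sprintf("evidence file '%s' lacks required 'gene' column (found: %s)",
                 path, paste(names(tab), collapse = ", ")), call. = FALSE)
  }
  for (col in c("p_primary", "p_secondary", "stat")) {
    if (!col %in% names(tab)) tab[[col]] <- rep(NA_real_, nrow(tab))
    tab[[col]] <- as.numeric(tab[[col]])
  }
  for (col in c("p_primary", "p_secondary")) {
    check_prob(tab[[col]], sprintf("'%s' in %s", col, path), allow_na = TRUE)
  }
  genes <- normalize_genes(tab$gene, aliases)
  keep <- toupper(trimws(as.character(tab$gene))) != ""
  keep[is.na(keep)] <- FALSE
  out <- tab[keep, c("gene", "p_primary", "p_secondary", "stat"), drop = FALSE]
  out$gene <- genes
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected significance threshold
#'
#' Divides the family-wise error rate by the number of tests, e.g.
#' 0.05 / 5747 genes tested gives 8.7e-6.
#'
#' @param alpha family-wise error rate, in (0, 1].
#' @param n_tests number of tests in the family (>= 1).
#' @return The per-test threshold \code{alpha / n_tests}.
#' @examples
#' bonferroni_threshold(0.05, 25) # 0.002
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single value in (0, 1]", call. = FALSE)
  }
  n_tests <- check_count(n_tests, "`n_tests`", min = 1L)
  alpha / n_tests
}

#' Retain genes passing both the association and the heterogeneity test
#'
#' Implements the two-step retention rule used with summary-data Mendelian
#' randomization: a gene is kept only when its association p-value is below
#' the (typically Bonferroni-corrected) significance threshold AND its
#' heterogeneity (HEIDI) p-value is at or above the heterogeneity cutoff --
#' a low heterogeneity p-value indicates linkage rather than a shared causal
#' variant, so such genes are discarded.
#'
#' @param records data.frame with columns \code{gene}, \code{p_primary} (the
#'   association p-value) and \code{p_secondary} (the heterogeneity p-value).
#' @param p_primary_max association significance threshold (retain strictly
#'   below).
#' @param p_secondary_min heterogeneity cutoff (retain at or above), default
#'   0.05.
#' @return Character vector of retained gene symbols, input order preserved.
#' @export
smr_heidi_filter <- function(records, p_primary_max, p_secondary_min = 0.05) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) return(character())
  for (col in c("gene", "p_primary", "p_secondary")) {
    if (!col %in% names(records)) {
      stop(sprintf("`records` lacks required column '%s'", col), call. = FALSE)
    }
  }
  if (anyNA(records$p_secondary)) {
    stop("heterogeneity p-value (p_secondary) missing on some records; the retention rule is undefined without it",
         call. = FALSE)
  }
  if (anyNA(records$p_primary)) {
    stop("association p-value (p_primary) missing on some records", call. = FALSE)
  }
  check_prob(records$p_primary, "p_primary")
  check_prob(records$p_secondary, "p_secondary")
  keep <- records$p_primary < p_primary_max &
    records$p_secondary >= p_secondary_min
  as.character(records$gene[keep])
}

#' Cumulative evidence scores
#'
#' Scores every gene in an evidence table by the number of distinct sources
#' attesting it (equal weight per source). A gene nominated only by one
#' method scores 1; one nominated by two methods scores 2; and so on. The
#' result is ranked by score descending with ties broken by gene symbol.
#'
#' @param table an \code{\link{evidence_table}}.
#' @return data.frame with columns \code{gene}, \code{score} (integer) and
#'   \code{sources} (semicolon-joined attesting labels), ranked.
#' @export
cumulative_score <- function(table) {
  stopifnot(inherits(table, "evidence_table"))
  if (length(table$sources) < 1L) {
    stop("evidence table has no sources", call. = FALSE)
  }
  genes <- names(table$entries)
  score <- vapply(table$entries, length, integer(1L))
  # report attesting labels in the configured source order
  srcs <- vapply(table$entries, function(s) {
    paste(table$sources[table$sources %in% s], collapse = ";")
  }, character(1L))
  ord <- order(-score, genes)
  out <- data.frame(gene = genes[ord], score = score[ord],
                    sources = srcs[ord], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Select candidate genes by minimum cumulative score
#'
#' @param scores ranked data.frame from \code{\link{cumulative_score}}.
#' @param min_score minimum score to retain (>= 1); the headline selection
#'   uses 2, the high-confidence tier 3.
#' @return Character vector of genes with \code{score >= min_score}, in the
#'   ranked order of \code{scores}.
#' @export
select_candidates <- function(scores, min_score = 2L) {
  stopifnot(is.data.frame(scores), all(c("gene", "score") %in% names(scores)))
  min_score <- check_count(min_score, "`min_score`", min = 1L)
  as.character(scores$gene[scores$score >= min_score])
}
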