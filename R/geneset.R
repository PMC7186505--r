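#' Construct a gene-set collection
#'
#' A collection of named gene sets (pathways, tissue-enriched sets) over a
#' background universe. Set members outside the universe are dropped at
#' construction with a message reporting the count, so the hypergeometric
#' margins stay consistent.
#'
#' @param genes named list mapping set id to a character vector of member
#'   symbols (duplicates collapsed).
#' @param names optional character vector of human-readable set names
#'   (defaults to the ids).
#' @param p_adjusted optional numeric vector of adjusted enrichment p-values
#'   per set (e.g. published pathway-level BH values), in [0, 1].
#' @param universe background gene universe; defaults to the union of all
#'   set members.
#' @return Object of class \code{geneset_collection} with fields \code{ids},
#'   \code{names}, \code{genes}, \code{p_adjusted}, \code{universe}.
#' @export
geneset_collection <- function(genes, names = NULL, p_adjusted = NULL,
                               universe = NULL) {
  stopifnot(is.list(genes))
  ids <- base::names(genes)
  if (length(genes) > 0L && (is.null(ids) || any(ids == ""))) {
    stop("`genes` must be a named list (set id -> members)", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate set id '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  genes <- lapply(genes, function(g) unique(as.character(g)))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(genes, use.names = FALSE)))
  }
  universe <- unique(as.character(universe))
  dropped <- sum(vapply(genes, function(g) sum(!g %in% universe), integer(1L)))
  if (dropped > 0L) {
    message(sprintf("geneset_collection: dropped %d symbol(s) outside the universe",
                    dropped))
    genes <- lapply(genes, function(g) g[g %in% universe])
  }
  if (!is.null(p_adjusted)) {
    if (length(p_adjusted) != length(genes)) {
      stop("`p_adjusted` must have one value per set", call. = FALSE)
    }
    check_prob(p_adjusted, "`p_adjusted`", allow_na = TRUE)
    p_adjusted <- stats::setNames(as.numeric(p_adjusted), ids)
  }
  if (is.null(names)) names <- ids
  structure(list(ids = ids, names = stats::setNames(as.character(names), ids),
                 genes = genes, p_adjusted = p_adjusted, universe = universe),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  sizes <- lengths(x$genes)
  cat(sprintf("<geneset_collection> %d set(s) over %d background gene(s)\n",
              length(x$ids), length(x$universe)))
  if (length(sizes) > 0L) {
    cat(sprintf("set sizes: %d-%d (median %.0f)\n",
                min(sizes), max(sizes), stats::median(sizes)))
  }
  invisible(x)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, \code{name<TAB>description<TAB>gene...}.
#' Duplicate genes within a line are collapsed.
#'
#' @param path path to the GMT file.
#' @param universe optional background universe passed to
#'   \code{\link{geneset_collection}}.
#' @return A \code{\link{geneset_collection}}.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(geneset_collection(stats::setNames(list(), character()),
                              universe = universe %||% character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop(sprintf("malformed GMT line %d in '%s': expected at least 3 tab-separated fields",
                 short[1L], path), call. = FALSE)
  }
  ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate gene-set name '%s' in '%s'",
                 ids[duplicated(ids)][1L], path), call. = FALSE)
  }
  descs <- vapply(fields, `[[`, character(1L), 2L)
  members <- lapply(fields, function(f) unique(f[-(1:2)]))
  geneset_collection(stats::setNames(members, ids), names = descs,
                     universe = universe)
}

#' Write a gene-set collection to GMT
#'
#' @param collection a \code{\link{geneset_collection}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(collection$ids, function(id) {
    paste(c(id, collection$names[[id]], collection$genes[[id]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric overlap enrichment test
#'
#' One-sided upper-tail probability of observing at least the actual overlap
#' between a query gene set and a target set when \code{|query|} genes are
#' drawn without replacement from a universe of \code{universe_size} genes.
#'
#' @param query character vector of query genes (assumed within the
#'   universe).
#' @param target character vector of target-set genes.
#' @param universe_size size of the background universe.
#' @return The p-value \eqn{P(X \ge k)} where \eqn{k} is the observed
#'   overlap.
#' @export
overlap_test <- function(query, target, universe_size) {
  query <- unique(as.character(query))
  target <- unique(as.character(target))
  universe_size <- check_count(universe_size, "`universe_size`", min = 0L)
  if (length(query) > universe_size || length(target) > universe_size) {
    stop("query/target larger than the universe", call. = FALSE)
  }
  k <- length(intersect(query, target))
  # P(X >= k) for X ~ Hypergeometric(m = |target|, n = N - |target|, draws = |query|)
  stats::phyper(k - 1L, length(target), universe_size - length(target),
                length(query), lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR-controlling step-up adjusted p-values, capped at 1 and
#' returned in input order.
#'
#' @param p_values numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values)) stop("p-values must not be missing", call. = FALSE)
  check_prob(p_values, "`p_values`")
  stats::p.adjust(p_values, method = "BH")
}

#' Enrichment of a query gene list against a gene-set collection
#'
#' Applies \code{\link{overlap_test}} to every set in the collection over the
#' collection's universe, then adjusts across sets by Benjamini-Hochberg and
#' Bonferroni. Query genes outside the universe are dropped with a warning.
#'
#' @param query character vector of query genes.
#' @param collection a \code{\link{geneset_collection}} with at least one
#'   set.
#' @return data.frame with one row per set, columns \code{set_id},
#'   \code{set_name}, \code{overlap_count}, \code{set_size},
#'   \code{query_size}, \code{universe_size}, \code{p_raw}, \code{p_bh},
#'   \code{p_bonferroni}, sorted by \code{p_raw} ascending.
#' @export
enrich_collection <- function(query, collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  if (length(collection$ids) == 0L) {
    stop("empty gene-set collection", call. = FALSE)
  }
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside) > 0L) {
    warning(sprintf("dropped %d query gene(s) outside the background universe",
                    length(outside)), call. = FALSE)
    query <- intersect(query, collection$universe)
  }
  n_univ <- length(collection$universe)
  p_raw <- vapply(collection$genes, function(g) {
    overlap_test(query, g, n_univ)
  }, numeric(1L))
  m <- length(p_raw)
  out <- data.frame(
    set_id = collection$ids,
    set_name = unname(collection$names[collection$ids]),
    overlap_count = vapply(collection$genes,
                           function(g) length(intersect(query, g)), integer(1L)),
    set_size = unname(lengths(collection$genes)),
    query_size = length(query),
    universe_size = n_univ,
    p_raw = unname(p_raw),
    p_bh = unname(bh_adjust(p_raw)),
    p_bonferroni = pmin(1, unname(p_raw) * m),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p_raw, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
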