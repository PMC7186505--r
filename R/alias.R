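#' Build an alias map for gene-symbol canonicalization
#'
#' Gene symbols drift between resources (for example the phosphatidic acid
#' phosphatase gene appears both as \code{PPAP2B} and \code{PLPP3}); an alias
#' map unifies such variants onto one canonical symbol so that evidence from
#' different sources accumulates on a single gene. Canonicalization must be
#' idempotent: a canonical symbol may not itself be an alias for a different
#' symbol.
#'
#' @param alias character vector of alias symbols.
#' @param canonical character vector of the same length with the canonical
#'   symbol for each alias.
#' @return A named character vector of class \code{alias_map}: names are
#'   upper-cased aliases, values the upper-cased canonical symbols.
#' @examples
#' alias_map("PLPP3", "PPAP2B")
#' @export
alias_map <- function(alias = character(), canonical = character()) {
  if (length(alias) != length(canonical)) {
    stop("`alias` and `canonical` must have equal length", call. = FALSE)
  }
  alias <- toupper(trimws(as.character(alias)))
  canonical <- toupper(trimws(as.character(canonical)))
  if (any(alias == "") || any(canonical == "")) {
    stop("alias map entries must be non-empty symbols", call. = FALSE)
  }
  if (anyDuplicated(alias)) {
    dup <- alias[duplicated(alias)][1L]
    stop(sprintf("alias '%s' mapped more than once", dup), call. = FALSE)
  }
  map <- stats::setNames(canonical, alias)
  # idempotence: following the map twice must not move a symbol further
  chained <- canonical %in% alias & map[canonical] != canonical
  chained[is.na(chained)] <- FALSE
  if (any(chained)) {
    stop(sprintf("canonical symbol '%s' is itself an alias for '%s'; chains are not allowed",
                 canonical[chained][1L], map[[canonical[chained][1L]]]),
         call. = FALSE)
  }
  structure(map, class = "alias_map")
}

#' Read an alias map from a two-column TSV
#'
#' Expected layout: \code{alias<TAB>canonical}, no header; lines starting with
#' \code{#} are ignored.
#'
#' @param path path to the TSV file.
#' @return An \code{\link{alias_map}}.
#' @export
read_alias_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           colClasses = "character", blank.lines.skip = TRUE)
  if (nrow(tab) == 0L) return(alias_map())
  if (ncol(tab) < 2L) {
    stop(sprintf("alias map '%s' must have two tab-separated columns", path),
         call. = FALSE)
  }
  alias_map(tab[[1L]], tab[[2L]])
}

#' Normalize gene symbols
#'
#' Upper-cases, trims whitespace and replaces aliases by their canonical
#' symbol. Order is preserved and duplicates are retained; deduplication is
#' the responsibility of the container being built. Symbols that are empty
#' after trimming are dropped with a warning rather than aborting the run.
#'
#' @param raw_symbols character vector of raw gene symbols.
#' @param aliases an \code{\link{alias_map}}, or \code{NULL} for none.
#' @return Character vector of normalized symbols (possibly shorter than the
#'   input if empty symbols were dropped).
#' @examples
#' normalize_genes(c(" fn1 ", "FN1"))
#' normalize_genes("plpp3", alias_map("PLPP3", "PPAP2B"))
#' @export
normalize_genes <- function(raw_symbols, aliases = NULL) {
  x <- toupper(trimws(as.character(raw_symbols)))
  empty <- is.na(x) | x == ""
  if (any(empty)) {
    warning(sprintf("dropped %d empty gene symbol(s) during normalization",
                    sum(empty)), call. = FALSE)
    x <- x[!empty]
  }
  if (!is.null(aliases) && length(aliases) > 0L) {
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  x
}
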