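#' Path to a packaged example/fixture file
#'
#' The package ships the worked-example tables driving its tests: the
#' 55-gene prioritization table (\code{table1_genes.tsv}: gene, locus,
#' semicolon-joined evidence-source labels), the 24 enriched KEGG pathways
#' with their candidate-gene memberships (\code{table2_pathways.tsv}) and a
#' small symbol alias map (\code{gene_aliases.tsv}).
#'
#' @param filename file name under the package's \code{extdata}; with no
#'   argument, lists available files.
#' @return Full path to the file (or a vector of available names).
#' @export
evigene_example <- function(filename = NULL) {
  if (is.null(filename)) {
    return(dir(system.file("extdata", package = "evigene")))
  }
  path <- system.file("extdata", filename, package = "evigene")
  if (path == "") stop(sprintf("no packaged file '%s'", filename), call. = FALSE)
  path
}

#' Read a gene/locus/methods prioritization table
#'
#' Reads a TSV with columns \code{gene}, \code{locus} and \code{methods}
#' (semicolon-joined evidence-source labels), the layout of the packaged
#' 55-gene table.
#'
#' @param path path to the TSV.
#' @param aliases optional \code{\link{alias_map}} applied to gene symbols.
#' @return data.frame with columns \code{gene}, \code{locus} and
#'   list-column \code{methods}.
#' @export
read_method_table <- function(path, aliases = NULL) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene", "methods")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("method table '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  tab$gene <- normalize_genes(tab$gene, aliases)
  tab$methods <- lapply(strsplit(tab$methods, ";"), trimws)
  tab
}

#' Explode a method table into per-source evidence files
#'
#' Writes one single-column evidence TSV per distinct source label, so the
#' combined table can be fed through \code{\link{load_evidence}} exactly as
#' separate per-method result files would be.
#'
#' @param table data.frame from \code{\link{read_method_table}}.
#' @param dir output directory (created if needed).
#' @return Named character vector label -> path for
#'   \code{\link{load_evidence}}.
#' @export
evidence_files_from_methods <- function(table, dir) {
  stopifnot(is.data.frame(table), all(c("gene", "methods") %in% names(table)))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- unique(unlist(table$methods, use.names = FALSE))
  files <- character()
  for (lab in labels) {
    genes <- table$gene[vapply(table$methods, function(m) lab %in% m,
                               logical(1L))]
    path <- file.path(dir, sprintf("evidence_%s.tsv",
                                   gsub("[^A-Za-z0-9_.-]", "_", lab)))
    utils::write.table(data.frame(gene = genes), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files[[lab]] <- path
  }
  files
}

stage_names <- c("score", "enrichment", "tissue", "network", "crosstalk")

run_stage <- function(report, name, runner) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(runner(), error = function(e) e)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (inherits(res, "error")) {
    report$stages[[name]] <- list(status = "failed",
                                  error = conditionMessage(res),
                                  elapsed_s = round(elapsed, 3))
    attr(report, "failed") <- name
  } else {
    report$stages[[name]] <- c(list(status = "ok",
                                    elapsed_s = round(elapsed, 3)), res)
  }
  report
}

#' Run the full prioritization and characterization pipeline
#'
#' Orchestrates cumulative evidence scoring, candidate selection, gene-set
#' enrichment, tissue enrichment, network permutation testing and pathway
#' crosstalk from a single configuration. Stages whose inputs are omitted
#' from the configuration are recorded as skipped; a failing stage is
#' recorded in the report (preserving upstream results) before the error is
#' re-signaled.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{evidence}{named list/vector: source label -> evidence TSV path}
#'     \item{aliases}{optional alias-map TSV path}
#'     \item{min_score}{candidate selection threshold (default 2)}
#'     \item{gmt}{optional gene-set GMT path for enrichment}
#'     \item{universe}{optional newline-delimited background gene file}
#'     \item{psi}{optional pSI matrix TSV; \code{psi_cutoff} (default 0.05),
#'       \code{tissue_alpha} (default 0.05)}
#'     \item{network_edges}{optional edge-list TSV; \code{n_permutations}
#'       (default 1000), \code{permutation_seed} (default 1)}
#'     \item{pathways}{optional pathway TSV (id, name, p_adjusted, genes);
#'       \code{p_max} (default 0.05), \code{min_genes} (default 3),
#'       \code{min_shared} (default 2)}
#'     \item{outdir}{output directory for stage files and report.json}
#'   }
#' @return The run report (class \code{run_report}), invisibly written to
#'   \code{<outdir>/report.json}.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  outdir <- config$outdir %||% stop("`outdir` is required", call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  aliases <- if (!is.null(config$aliases)) read_alias_map(config$aliases)
  report <- structure(list(
    schema_version = "1.0",
    package_version = as.character(utils::packageVersion("evigene")),
    config = config[setdiff(names(config), "evidence")],
    stages = stats::setNames(vector("list", length(stage_names)), stage_names)
  ), class = "run_report")
  for (s in stage_names) report$stages[[s]] <- list(status = "skipped")

  candidates <- NULL
  if (!is.null(config$evidence)) {
    report <- run_stage(report, "score", function() {
      files <- unlist(config$evidence)
      tab <- load_evidence(files, aliases)
      scores <- cumulative_score(tab)
      min_score <- config$min_score %||% 2L
      sel <- select_candidates(scores, min_score)
      candidates <<- sel
      utils::write.table(scores, file.path(outdir, "scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(sel, file.path(outdir, "candidates.txt"))
      list(n_sources = length(tab$sources), n_genes = length(tab$entries),
           min_score = min_score,
           candidates_min2 = sum(scores$score >= 2L),
           candidates_min3 = sum(scores$score >= 3L),
           n_candidates = length(sel))
    })
  }
  if (!is.null(config$query)) {
    candidates <- normalize_genes(readLines(config$query, warn = FALSE),
                                  aliases)
  }

  if (!is.null(config$gmt) && !is.null(candidates)) {
    report <- run_stage(report, "enrichment", function() {
      universe <- if (!is.null(config$universe)) {
        normalize_genes(readLines(config$universe, warn = FALSE), aliases)
      }
      collection <- read_gmt(config$gmt, universe = universe)
      res <- enrich_collection(candidates, collection)
      utils::write.table(res, file.path(outdir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_sets = nrow(res), n_significant_bh = sum(res$p_bh < 0.05),
           top_set = res$set_id[1L])
    })
  }

  if (!is.null(config$psi) && !is.null(candidates)) {
    report <- run_stage(report, "tissue", function() {
      psi <- read_psi_matrix(config$psi, aliases)
      cutoff <- config$psi_cutoff %||% 0.05
      alpha <- config$tissue_alpha %||% 0.05
      sets <- threshold_psi(psi, cutoff)
      res <- tissue_enrichment(candidates, sets, alpha = alpha)
      utils::write.table(res, file.path(outdir, "tissue.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(n_tissues = nrow(res), n_significant = sum(res$significant),
           top_tissue = res$tissue[1L], top_p = res$p_fisher[1L])
    })
  }

  if (!is.null(config$network_edges) && !is.null(candidates)) {
    report <- run_stage(report, "network", function() {
      net <- load_edges(config$network_edges, aliases)
      res <- permutation_test(net, candidates,
                              n_permutations = config$n_permutations %||% 1000L,
                              seed = config$permutation_seed %||% 1L)
      jsonlite::write_json(unclass(res),
                           file.path(outdir, "netperm.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      res[c("observed", "null_mean", "null_sd", "z", "p", "p_empirical",
            "n_genes_used")]
    })
  }

  if (!is.null(config$pathways)) {
    report <- run_stage(report, "crosstalk", function() {
      pw <- read_pathways(config$pathways, aliases)
      eligible <- filter_eligible(pw, config$p_max %||% 0.05,
                                  config$min_genes %||% 3L)
      graph <- build_crosstalk(eligible, config$min_shared %||% 2L)
      export_graph(graph, file.path(outdir, "crosstalk.graphml"),
                   format = "graphml")
      export_graph(graph, file.path(outdir, "crosstalk_edges.tsv"),
                   format = "tsv")
      if (nrow(graph$edges) > 0L) {
        cr <- centrality_report(graph)
        utils::write.table(cr, file.path(outdir, "crosstalk_nodes.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      list(n_input_pathways = nrow(pw), n_eligible = nrow(eligible),
           n_edges = nrow(graph$edges),
           component_sizes = lengths(graph$components),
           n_isolates = length(graph$isolates))
    })
  }

  write_report(report, file.path(outdir, "report.json"))
  failed <- attr(report, "failed")
  if (!is.null(failed)) {
    stop(sprintf("pipeline stage '%s' failed: %s", failed,
                 report$stages[[failed]]$error), call. = FALSE)
  }
  invisible(report)
}

#' Write a pipeline run report as pretty-printed JSON
#'
#' @param report a \code{run_report} from \code{\link{run_pipeline}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "run_report") || is.list(report))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> evigene %s\n", x$package_version))
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(sprintf("  %-10s %s\n", s, st$status))
  }
  invisible(x)
}
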