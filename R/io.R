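#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("expression file has no data rows: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("expression file needs a gene column and >= 1 sample column")
  genes <- as.character(tab[[1]])
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0) {
    stop("duplicate gene id(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  vals <- tab[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) & !is.na(vals[[j]]))
    if (length(bad) > 0) {
      stop("non-numeric value in ", path, ", line ", bad[1] + 1,
           ", column '", names(vals)[j], "'")
    }
    if (anyNA(col)) stop("missing value in ", path, ", column '", names(vals)[j], "'")
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  if (any(m < 0)) stop("expression values must be non-negative: ", path)
  m
}

#' Write an expression matrix as TSV
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-group map from TSV
#'
#' Two columns, `sample` and `group` (values `disease` / `control`), with
#' a header row.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `sample` and `group`.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("group map not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  as_group_map(tab)  # validates
  tab
}

#' Read a prior-knowledge network edge table
#'
#' Four tab-separated columns without a header: source gene, effect
#' (`activation` / `inhibition` / `unknown`, case-insensitive), target
#' gene, interaction category. Blank lines and lines starting with `#`
#' are skipped; input order is preserved.
#'
#' @param path path to the edge TSV.
#' @return data.frame with columns `source`, `effect`, `target`,
#'   `category`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("^\\s*#", lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  if (length(rows) == 0) stop("network file has no edges: ", path)
  nfield <- lengths(rows)
  if (any(nfield < 4)) {
    stop("network file ", path, ", line ", lineno[which(nfield < 4)[1]],
         ": expected 4 tab-separated fields (source, effect, target, category)")
  }
  effect <- tolower(vapply(rows, `[[`, character(1), 2))
  bad <- which(!effect %in% c("activation", "inhibition", "unknown"))
  if (length(bad) > 0) {
    stop("network file ", path, ", line ", lineno[bad[1]],
         ": invalid effect '", vapply(rows, `[[`, character(1), 2)[bad[1]],
         "'; allowed values: activation, inhibition, unknown")
  }
  data.frame(source = vapply(rows, `[[`, character(1), 1),
             effect = effect,
             target = vapply(rows, `[[`, character(1), 3),
             category = vapply(rows, `[[`, character(1), 4),
             stringsAsFactors = FALSE)
}

#' Write a signed edge table as 4-column TSV
#' @param edges data.frame with `source`, `effect`, `target` and
#'   optionally `category` (filled with `"-"` when absent).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path) {
  category <- if (is.null(edges$category)) rep("-", nrow(edges)) else edges$category
  tab <- data.frame(edges$source, edges$effect, edges$target, category)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a precomputed differential-expression table
#'
#' Three tab-separated columns with a header: `gene`, `log2fc`, `pvalue`.
#'
#' @param path path to the TSV file.
#' @return data.frame with those columns.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene", "log2fc", "pvalue")
  if (!all(need %in% names(tab))) {
    stop("DE table needs columns ", paste(need, collapse = ", "))
  }
  if (any(tab$pvalue < 0 | tab$pvalue > 1)) stop("p-values must lie in [0, 1]")
  tab
}

#' Pipeline configuration
#'
#' Collects the analysis parameters and input/output paths. Either
#' `expression` + `groups` or a precomputed `de_table` must be given.
#'
#' @param pkn path to the prior-knowledge edge TSV.
#' @param out_dir output directory for all stage results.
#' @param expression,groups paths to the expression matrix and group map
#'   TSVs (mutually exclusive with `de_table`).
#' @param de_table path to a precomputed 3-column DE table TSV.
#' @param gmt optional path to a GMT gene-set collection for the
#'   enrichment stage.
#' @param alpha BH significance threshold (default 0.05, inclusive).
#' @param lfc_threshold strict |log2FC| threshold (default 1).
#' @param kept_categories interaction categories retained from the PKN.
#' @param max_combo largest perturbation size, 1-4 (default 4).
#' @param top_k ranking length (default 10).
#' @param max_circuit_length elementary-circuit length cap (default 12).
#' @param candidate_cap refuse larger candidate sets (default 25).
#' @param pseudocount offset inside fold change / log transform.
#' @param step_cap Boolean-simulation iteration guard.
#' @param seed master seed for any stage that draws random numbers.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(pkn, out_dir, expression = NULL, groups = NULL,
                            de_table = NULL, gmt = NULL, alpha = 0.05,
                            lfc_threshold = 1,
                            kept_categories = c("Transcription regulation", "Binding"),
                            max_combo = 4, top_k = 10, max_circuit_length = 12,
                            candidate_cap = 25, pseudocount = 1,
                            step_cap = 10000, seed = 1) {
  if (alpha <= 0 || lfc_threshold < 0) stop("thresholds must be positive")
  if (max_combo < 1 || max_combo > 4) stop("max_combo must lie in [1, 4]")
  if (is.null(de_table) && (is.null(expression) || is.null(groups))) {
    stop("provide either `expression` + `groups` or a `de_table`")
  }
  structure(list(pkn = pkn, out_dir = out_dir, expression = expression,
                 groups = groups, de_table = de_table, gmt = gmt,
                 alpha = alpha, lfc_threshold = lfc_threshold,
                 kept_categories = kept_categories, max_combo = as.integer(max_combo),
                 top_k = top_k, max_circuit_length = max_circuit_length,
                 candidate_cap = as.integer(candidate_cap),
                 pseudocount = pseudocount, step_cap = as.integer(step_cap),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration (YAML)
#'
#' The round trip through the file is lossless: reading a written config
#' reproduces the original object.
#'
#' @param path YAML file path.
#' @return [read_config()] returns a `pipeline_config`;
#'   [write_config()] returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @param config a `pipeline_config`.
#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}
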