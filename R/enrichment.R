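#' Upper-tail hypergeometric p-value for gene-set overlap
#'
#' Probability of observing at least `overlap` query genes inside a gene
#' set, when `query_size` genes are drawn without replacement from a
#' universe of `universe_size` genes of which `set_size` belong to the set.
#'
#' @param overlap observed overlap count.
#' @param query_size number of (deduplicated, in-universe) query genes.
#' @param set_size gene-set size within the universe.
#' @param universe_size background universe size.
#' @return `P(X >= overlap)` for `X ~ Hypergeometric`.
#' @export
hypergeom_pvalue <- function(overlap, query_size, set_size, universe_size) {
  counts <- c(overlap, query_size, set_size, universe_size)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("all counts must be non-negative integers")
  }
  if (query_size > universe_size || set_size > universe_size) {
    stop("query and set sizes cannot exceed the universe size")
  }
  if (overlap > min(query_size, set_size)) {
    stop("overlap cannot exceed min(query_size, set_size)")
  }
  stats::phyper(overlap - 1, set_size, universe_size - set_size, query_size,
                lower.tail = FALSE)
}

#' Build a gene-set collection over a background universe
#'
#' Sets are restricted to the universe; sets that become empty are kept
#' (they simply can never be enriched).
#'
#' @param sets named list of character vectors (set name -> member genes).
#' @param universe character vector of background gene ids.
#' @return a `gene_set_collection`: list with `sets` (restricted,
#'   deduplicated) and `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("`sets` must be a named list of gene id vectors")
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  restricted <- lapply(sets, function(s) intersect(unique(as.character(s)), universe))
  structure(list(sets = restricted, universe = universe),
            class = "gene_set_collection")
}

#' Over-representation analysis of a query gene list
#'
#' Hypergeometric upper-tail test of each set's overlap with the query,
#' with BH correction across sets. Query genes outside the universe are
#' dropped (their count is reported in a message); duplicates are removed.
#' One-sided over-representation only.
#'
#' @param query character vector of gene ids.
#' @param collection a `gene_set_collection`.
#' @param alpha BH significance threshold for the `significant` flag.
#' @return data.frame sorted by ascending p: `term`, `overlap`,
#'   `query_size`, `set_size`, `universe_size`, `pvalue`, `qvalue`,
#'   `significant`.
#' @export
enrich <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0) stop("empty gene-set collection")
  query <- unique(as.character(query))
  dropped <- setdiff(query, collection$universe)
  if (length(dropped) > 0) {
    message(length(dropped), " query gene(s) outside the universe were dropped")
    query <- intersect(query, collection$universe)
  }
  N <- length(collection$universe)
  q <- length(query)
  terms <- names(collection$sets)
  overlap <- vapply(collection$sets, function(s) length(intersect(s, query)), integer(1))
  set_size <- lengths(collection$sets)
  pvalue <- mapply(hypergeom_pvalue, overlap, q, set_size,
                   MoreArgs = list(universe_size = N))
  out <- data.frame(term = terms, overlap = unname(overlap), query_size = q,
                    set_size = unname(set_size), universe_size = N,
                    pvalue = unname(pvalue), stringsAsFactors = FALSE)
  out$qvalue <- bh_adjust(out$pvalue)
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  out$significant <- out$qvalue <= alpha
  rownames(out) <- NULL
  out
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member gene
#' ids. Blank lines are skipped.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors (set name -> members).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields (name, description, genes)")
    }
    sets[[parts[1]]] <- unique(parts[-(1:2)])
  }
  sets
}
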