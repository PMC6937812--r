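#' Two-group differential expression on an expression matrix
#'
#' Computes, per gene, the pseudocount-stabilized log2 fold change
#' (disease vs control) and a Welch unequal-variance two-sample p-value
#' on `log2(x + pseudocount)`-transformed values. This is a deliberately
#' simple substitute for a full count-model DE engine: the downstream
#' network stages accept any externally produced DE table with the same
#' three columns.
#'
#' Degenerate genes are handled explicitly: if both groups have zero
#' variance on the log scale, the p-value is 1 when the group means are
#' equal and 0 when they differ (the zero-noise limit of the Welch
#' statistic).
#'
#' @param expr numeric matrix, genes x samples, non-negative; rownames are
#'   gene ids, colnames are sample ids.
#' @param groups a data.frame with columns `sample` and `group`
#'   (values `"disease"` / `"control"`), or a named character vector
#'   mapping sample id to group.
#' @param pseudocount positive offset added inside the fold change and the
#'   log transform; avoids division by zero for unexpressed genes.
#' @return data.frame with columns `gene`, `log2fc`, `pvalue`.
#' @seealso [filter_degs()], [discretize()]
#' @export
compute_de <- function(expr, groups, pseudocount = 1) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("`expr` must be a numeric matrix (genes x samples)")
  }
  if (any(expr < 0)) stop("`expr` must be non-negative")
  grp <- as_group_map(groups)
  missing <- setdiff(colnames(expr), names(grp))
  if (length(missing) > 0) {
    stop("samples without a group assignment: ", paste(missing, collapse = ", "))
  }
  g <- grp[colnames(expr)]
  idx_d <- which(g == "disease")
  idx_c <- which(g == "control")
  if (length(idx_d) < 2 || length(idx_c) < 2) {
    stop("each group needs at least 2 samples (got ", length(idx_d),
         " disease, ", length(idx_c), " control)")
  }

  mean_d <- rowMeans(expr[, idx_d, drop = FALSE])
  mean_c <- rowMeans(expr[, idx_c, drop = FALSE])
  log2fc <- log2((mean_d + pseudocount) / (mean_c + pseudocount))

  lx <- log2(expr + pseudocount)
  pvalue <- welch_p(lx[, idx_d, drop = FALSE], lx[, idx_c, drop = FALSE])

  data.frame(gene = rownames(expr), log2fc = unname(log2fc),
             pvalue = unname(pvalue), stringsAsFactors = FALSE)
}

# Row-wise Welch t-test p-values; zero-variance rows resolved by the limit
# of the statistic (equal means -> p = 1, unequal -> p = 0).
welch_p <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  p <- rep(NA_real_, length(m1))
  degen <- se2 == 0
  p[degen] <- ifelse(abs(m1[degen] - m2[degen]) == 0, 1, 0)
  ok <- !degen
  if (any(ok)) {
    tstat <- (m1[ok] - m2[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
    p[ok] <- 2 * stats::pt(-abs(tstat), df)
  }
  p
}

as_group_map <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("sample", "group") %in% names(groups))) {
      stop("`groups` data.frame needs `sample` and `group` columns")
    }
    grp <- stats::setNames(as.character(groups$group), as.character(groups$sample))
  } else if (is.character(groups) && !is.null(names(groups))) {
    grp <- groups
  } else {
    stop("`groups` must be a data.frame(sample, group) or a named character vector")
  }
  bad <- setdiff(unique(grp), c("disease", "control"))
  if (length(bad) > 0) {
    stop("group labels must be 'disease' or 'control'; found: ",
         paste(bad, collapse = ", "))
  }
  grp
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Direct step-up implementation: with p-values sorted ascending,
#' `q(i) = min_{j >= i} p(j) * m / j`, clipped at 1, and returned in the
#' original input order.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of BH-adjusted q-values, same order as input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || !is.numeric(pvalues)) {
    stop("p-values must be numeric and non-missing")
  }
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  o <- order(pvalues)
  q_sorted <- rev(cummin(rev(pvalues[o] * m / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

#' Flag differentially expressed genes
#'
#' Adds BH q-values (if not already present) and the DEG flag to a DE
#' table. A gene is a DEG iff `qvalue <= alpha` (inclusive) and
#' `|log2fc| > lfc_threshold` (strict).
#'
#' @param de data.frame with columns `gene`, `log2fc`, `pvalue`
#'   (optionally a precomputed `qvalue`).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param lfc_threshold strict absolute log2 fold-change threshold
#'   (default 1).
#' @return the input data.frame with `qvalue` and logical `is_deg` columns.
#' @export
filter_degs <- function(de, alpha = 0.05, lfc_threshold = 1) {
  stopifnot(is.data.frame(de), all(c("gene", "log2fc", "pvalue") %in% names(de)))
  if (is.null(de$qvalue)) de$qvalue <- bh_adjust(de$pvalue)
  de$is_deg <- de$qvalue <= alpha & abs(de$log2fc) > lfc_threshold
  de
}

#' DEG gene ids from an annotated DE table
#' @param de a DE table with an `is_deg` column (see [filter_degs()]).
#' @return character vector of DEG gene ids.
#' @export
deg_genes <- function(de) {
  stopifnot(!is.null(de$is_deg))
  as.character(de$gene[de$is_deg])
}

#' Discretize DEGs into two-phenotype Boolean steady states
#'
#' Up-regulation in disease maps to active-in-disease / inactive-in-healthy;
#' down-regulation to the opposite. Only DEGs receive states.
#'
#' @param de annotated DE table (see [filter_degs()]).
#' @return data.frame with columns `gene`, `state_disease`, `state_healthy`
#'   (0/1), one row per DEG.
#' @export
discretize <- function(de) {
  stopifnot(!is.null(de$is_deg))
  d <- de[de$is_deg, , drop = FALSE]
  if (any(d$log2fc == 0)) {
    stop("DEG with log2fc == 0 cannot be discretized (excluded by the fold-change filter)")
  }
  up <- as.integer(d$log2fc > 0)
  data.frame(gene = as.character(d$gene), state_disease = up,
             state_healthy = 1L - up, stringsAsFactors = FALSE)
}

# Named 0/1 vector for one phenotype from a state table.
state_vector <- function(states, phenotype = c("disease", "healthy")) {
  phenotype <- match.arg(phenotype)
  col <- if (phenotype == "disease") "state_disease" else "state_healthy"
  stats::setNames(as.integer(states[[col]]), as.character(states$gene))
}
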