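#' Generate a ground-truth prior-knowledge network
#'
#' Samples a simple signed digraph uniformly over loop-free ordered node
#' pairs (optionally with a degree-skewed generator), plants a chosen
#' number of short circuits among the planted DEGs, assigns true signs,
#' and masks a fraction of edges as `"unknown"` in the emitted network
#' while the truth object retains the real sign. The truth object also
#' fixes the planted-DEG set and the expression-simulation parameters used
#' by [generate_expression()].
#'
#' @param n_genes number of genes.
#' @param n_edges number of distinct directed edges; at most
#'   `n_genes * (n_genes - 1)` for a loop-free simple digraph.
#' @param inhibition_fraction expected share of inhibition edges.
#' @param masked_fraction share of edges emitted with effect `"unknown"`
#'   (`round(masked_fraction * n_edges)` edges, chosen at random).
#' @param seed integer seed; the whole object is reproducible given it.
#' @param n_degs number of planted DEGs (default: half the genes).
#' @param lfc_magnitude planted absolute log2 fold change (default 2).
#' @param noise_sigma log-scale standard deviation of the multiplicative
#'   expression noise (default 0.2).
#' @param n_replicates samples per group for the expression simulation
#'   (default 6).
#' @param n_planted_cycles number of directed cycles planted among DEG
#'   genes (default 0); their edges count toward `n_edges`.
#' @param planted_cycle_length length of each planted cycle (default 3).
#' @param allow_self_loops permit `u -> u` edges (default `FALSE`).
#' @param scale_free use degree-skewed (rank-weighted) endpoint sampling
#'   instead of uniform pairs (default `FALSE`).
#' @return a `synthetic_truth` object; see [pkn_edges()] for the emitted
#'   network and [generate_states()] for the next stage.
#' @export
generate_pkn <- function(n_genes, n_edges, inhibition_fraction = 0.3,
                         masked_fraction = 0.25, seed = NULL,
                         n_degs = ceiling(n_genes / 2), lfc_magnitude = 2,
                         noise_sigma = 0.2, n_replicates = 6,
                         n_planted_cycles = 0, planted_cycle_length = 3,
                         allow_self_loops = FALSE, scale_free = FALSE) {
  if (inhibition_fraction < 0 || inhibition_fraction > 1 ||
      masked_fraction < 0 || masked_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  capacity <- n_genes * (n_genes - 1) + if (allow_self_loops) n_genes else 0
  if (n_edges > capacity) {
    stop("n_edges = ", n_edges, " exceeds the simple-digraph capacity of ",
         capacity, " for ", n_genes, " genes")
  }
  if (n_degs > n_genes) stop("n_degs cannot exceed n_genes")
  if (!is.null(seed)) set.seed(seed)

  width <- max(3, nchar(as.character(n_genes)))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(n_genes))
  deg_ids <- sort(sample(genes, n_degs))

  # planted cycles first (among DEGs), then fill up uniformly
  src <- integer(0); tgt <- integer(0)
  if (n_planted_cycles > 0) {
    if (planted_cycle_length > n_degs) {
      stop("planted_cycle_length cannot exceed n_degs")
    }
    for (i in seq_len(n_planted_cycles)) {
      cyc <- match(sample(deg_ids, planted_cycle_length), genes)
      src <- c(src, cyc)
      tgt <- c(tgt, c(cyc[-1], cyc[1]))
    }
    dup <- duplicated(paste(src, tgt))
    src <- src[!dup]; tgt <- tgt[!dup]
    if (length(src) > n_edges) stop("planted cycles alone exceed n_edges")
  }

  need <- n_edges - length(src)
  if (need > 0) {
    if (scale_free) {
      w <- 1 / seq_len(n_genes)
      have <- paste(src, tgt)
      guard <- 0
      while (need > 0) {
        u <- sample.int(n_genes, 1, prob = w)
        v <- sample.int(n_genes, 1, prob = w)
        if (!allow_self_loops && u == v) next
        key <- paste(u, v)
        if (key %in% have) {
          guard <- guard + 1
          if (guard > 1e6) stop("degree-skewed sampler failed to place all edges")
          next
        }
        src <- c(src, u); tgt <- c(tgt, v); have <- c(have, key)
        need <- need - 1
      }
    } else {
      pool <- sample.int(capacity, min(capacity, n_edges + length(src)))
      dec <- decode_pairs(pool, n_genes, allow_self_loops)
      have <- paste(src, tgt)
      fresh <- !(paste(dec$u, dec$v) %in% have)
      src <- c(src, dec$u[fresh][seq_len(need)])
      tgt <- c(tgt, dec$v[fresh][seq_len(need)])
    }
  }

  effect_true <- ifelse(stats::runif(n_edges) < inhibition_fraction,
                        "inhibition", "activation")
  masked <- rep(FALSE, n_edges)
  n_mask <- round(masked_fraction * n_edges)
  if (n_mask > 0) masked[sample.int(n_edges, n_mask)] <- TRUE

  edges <- data.frame(source = genes[src], target = genes[tgt],
                      effect_true = effect_true, masked = masked,
                      decoy = FALSE,
                      category = sample(c("Transcription regulation", "Binding"),
                                        n_edges, replace = TRUE),
                      stringsAsFactors = FALSE)
  structure(list(genes = genes, edges = edges, deg_ids = deg_ids,
                 masked_fraction = masked_fraction,
                 lfc_magnitude = lfc_magnitude, noise_sigma = noise_sigma,
                 n_replicates = n_replicates, states = NULL, seed = seed),
            class = "synthetic_truth")
}

# decode linear indices into ordered (u, v) pairs; loop-free unless allowed
decode_pairs <- function(idx, n, allow_self_loops) {
  if (allow_self_loops) {
    u <- (idx - 1) %/% n + 1
    v <- (idx - 1) %% n + 1
  } else {
    u <- (idx - 1) %/% (n - 1) + 1
    r <- (idx - 1) %% (n - 1) + 1
    v <- r + (r >= u)
  }
  list(u = u, v = v)
}

#' Emitted prior-knowledge network of a synthetic truth
#'
#' The 4-column edge table as the pipeline sees it: masked edges carry
#' effect `"unknown"`, all others their true sign.
#'
#' @param truth a `synthetic_truth`.
#' @return data.frame with columns `source`, `effect`, `target`,
#'   `category`.
#' @export
pkn_edges <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  e <- truth$edges
  data.frame(source = e$source,
             effect = ifelse(e$masked, "unknown", e$effect_true),
             target = e$target, category = e$category,
             stringsAsFactors = FALSE)
}

#' Assign ground-truth phenotype states
#'
#' Every gene gets a random disease state in \{0, 1\}; for planted DEGs the
#' healthy state is the negation (up in disease means active in disease,
#' inactive in healthy), for non-DEGs the two phenotypes share the state.
#'
#' @param truth a `synthetic_truth`.
#' @param seed integer seed for the assignment.
#' @return the truth object augmented with a `states` table (`gene`,
#'   `state_disease`, `state_healthy`, `is_deg`).
#' @export
generate_states <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(truth$genes)
  disease <- stats::rbinom(n, 1, 0.5)
  is_deg <- truth$genes %in% truth$deg_ids
  healthy <- ifelse(is_deg, 1L - disease, disease)
  truth$states <- data.frame(gene = truth$genes,
                             state_disease = as.integer(disease),
                             state_healthy = as.integer(healthy),
                             is_deg = is_deg, stringsAsFactors = FALSE)
  truth
}

#' Reassign true signs so every edge is compatible with both phenotypes
#'
#' For each edge, picks the sign that satisfies the pruning compatibility
#' rule in every phenotype where the source is active (active source with
#' active target requires activation; with inactive target, inhibition).
#' Edges whose source is a non-DEG gene active in both phenotypes and
#' whose target is a DEG admit no such sign; they are rewired to a
#' uniformly chosen non-DEG target (or dropped when none is free).
#'
#' @param truth a `synthetic_truth` with states
#'   (see [generate_states()]).
#' @param seed integer seed for the rewiring choices.
#' @return the truth object with consistent `effect_true` signs.
#' @export
make_consistent <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.null(truth$states))
  if (!is.null(seed)) set.seed(seed)
  st <- truth$states
  sd <- stats::setNames(st$state_disease, st$gene)
  sh <- stats::setNames(st$state_healthy, st$gene)
  is_deg <- stats::setNames(st$is_deg, st$gene)
  e <- truth$edges
  keep <- rep(TRUE, nrow(e))
  non_deg <- truth$genes[!is_deg[truth$genes]]
  for (i in seq_len(nrow(e))) {
    u <- e$source[i]; v <- e$target[i]
    req <- character(0)
    if (sd[u] == 1) req <- c(req, if (sd[v] == 1) "activation" else "inhibition")
    if (sh[u] == 1) req <- c(req, if (sh[v] == 1) "activation" else "inhibition")
    req <- unique(req)
    if (length(req) == 0) next
    if (length(req) == 1) {
      e$effect_true[i] <- req
      next
    }
    # source active in both phenotypes, DEG target: rewire to a non-DEG target
    free <- setdiff(non_deg, c(u, e$target[keep][e$source[keep] == u]))
    if (length(free) == 0) {
      keep[i] <- FALSE
      next
    }
    v2 <- if (length(free) == 1) free else sample(free, 1)
    e$target[i] <- v2
    e$effect_true[i] <- if (sd[v2] == 1) "activation" else "inhibition"
  }
  dropped <- sum(!keep)
  if (dropped > 0) {
    warning(dropped, " edge(s) dropped: no consistent sign or rewiring available")
  }
  truth$edges <- e[keep, , drop = FALSE]
  rownames(truth$edges) <- NULL
  truth
}

#' Plant decoy edges that contradict the disease expression program
#'
#' Turns a fraction of edges whose endpoints are both active in the
#' disease phenotype into inhibitions — exactly the configuration the
#' pruning rule removes — giving the pruning stage known true negatives.
#' Decoys are unmasked (a masked decoy would be sign-resolved back to a
#' consistent activation).
#'
#' @param truth a `synthetic_truth` with states.
#' @param decoy_fraction fraction of all edges to convert
#'   (`round(decoy_fraction * n_edges)`, limited by the number of eligible
#'   edges, with a warning when fewer are available).
#' @param seed integer seed for the choice of edges.
#' @return the truth object with `decoy` flags set.
#' @export
plant_decoys <- function(truth, decoy_fraction, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.null(truth$states))
  if (decoy_fraction < 0 || decoy_fraction > 1) stop("decoy_fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  st <- truth$states
  sd <- stats::setNames(st$state_disease, st$gene)
  e <- truth$edges
  eligible <- which(sd[e$source] == 1 & sd[e$target] == 1 & !e$decoy)
  want <- round(decoy_fraction * nrow(e))
  if (want > length(eligible)) {
    warning("only ", length(eligible), " of ", want,
            " requested decoys are placeable (need both endpoints active in disease)")
    want <- length(eligible)
  }
  if (want > 0) {
    pick <- if (length(eligible) == 1) eligible else sample(eligible, want)
    e$effect_true[pick] <- "inhibition"
    e$masked[pick] <- FALSE
    e$decoy[pick] <- TRUE
  }
  truth$edges <- e
  truth
}

#' Simulate a noisy expression matrix with planted DEGs
#'
#' Control samples have mean `base_mean` for every gene; disease samples
#' of planted DEGs have mean `base_mean * 2^(+/- lfc_magnitude)` (up for
#' DEGs active in disease, down otherwise). Values carry multiplicative
#' log-normal noise with log-scale standard deviation `noise_sigma`,
#' mean-corrected so group means match their targets in expectation.
#'
#' @param truth a `synthetic_truth` with states.
#' @param base_mean positive baseline expression level (FPKM-like units,
#'   default 100).
#' @param seed integer seed.
#' @return list with `expr` (genes x 2*n_replicates matrix) and `groups`
#'   (data.frame `sample`, `group`).
#' @export
generate_expression <- function(truth, base_mean = 100, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"), !is.null(truth$states))
  if (base_mean <= 0) stop("`base_mean` must be positive")
  if (truth$n_replicates < 2) stop("need at least 2 replicates per group")
  if (!is.null(seed)) set.seed(seed)
  st <- truth$states
  n <- length(truth$genes)
  nr <- truth$n_replicates
  shift <- ifelse(st$is_deg, ifelse(st$state_disease == 1, 1, -1), 0)
  mu_d <- base_mean * 2^(shift * truth$lfc_magnitude)
  mu_c <- rep(base_mean, n)
  sig <- truth$noise_sigma
  draw <- function(mu) {
    matrix(stats::rlnorm(n * nr, meanlog = rep(log(mu) - sig^2 / 2, nr),
                         sdlog = sig), nrow = n)
  }
  expr <- cbind(draw(mu_d), draw(mu_c))
  rownames(expr) <- truth$genes
  colnames(expr) <- c(paste0("disease_", seq_len(nr)), paste0("control_", seq_len(nr)))
  groups <- data.frame(sample = colnames(expr),
                       group = rep(c("disease", "control"), each = nr),
                       stringsAsFactors = FALSE)
  list(expr = expr, groups = groups)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: %d genes (%d planted DEGs), %d edges",
                     " (%d masked, %d decoys)%s\n"),
              length(x$genes), length(x$deg_ids), nrow(x$edges),
              sum(x$edges$masked), sum(x$edges$decoy),
              if (is.null(x$states)) ", states unset" else ""))
  invisible(x)
}

#' Simulate a complete, self-consistent input bundle
#'
#' Convenience wrapper chaining [generate_pkn()], [generate_states()],
#' [make_consistent()], [plant_decoys()] and [generate_expression()] with
#' deterministic sub-seeds derived from one master seed. The defaults
#' describe a compact two-phenotype study: 80 genes of which 40 are
#' differentially expressed at |log2FC| = 2 with log-normal noise
#' sigma = 0.2 and 6 replicates per group, a 240-edge prior network with
#' a quarter of the signs unknown, three planted 3-gene circuits among
#' the DEGs, and 10% decoy edges.
#'
#' @param n_genes,n_edges,n_degs,inhibition_fraction,masked_fraction
#'   network parameters, see [generate_pkn()].
#' @param decoy_fraction fraction of edges turned into decoys.
#' @param n_planted_cycles,planted_cycle_length planted circuits.
#' @param lfc_magnitude,noise_sigma,n_replicates,base_mean expression
#'   parameters.
#' @param seed master seed; all stages derive from it.
#' @return list with `truth`, `expr`, `groups`.
#' @export
simulate_bundle <- function(n_genes = 80, n_edges = 240, n_degs = 40,
                            inhibition_fraction = 0.3, masked_fraction = 0.25,
                            decoy_fraction = 0.1, n_planted_cycles = 3,
                            planted_cycle_length = 3, lfc_magnitude = 2,
                            noise_sigma = 0.2, n_replicates = 6,
                            base_mean = 100, seed = 1) {
  sub <- function(k) (seed + k * 1000003L) %% 2147483647L
  truth <- generate_pkn(n_genes, n_edges,
                        inhibition_fraction = inhibition_fraction,
                        masked_fraction = masked_fraction, seed = sub(1),
                        n_degs = n_degs, lfc_magnitude = lfc_magnitude,
                        noise_sigma = noise_sigma, n_replicates = n_replicates,
                        n_planted_cycles = n_planted_cycles,
                        planted_cycle_length = planted_cycle_length)
  truth <- generate_states(truth, seed = sub(2))
  truth <- make_consistent(truth, seed = sub(3))
  truth <- plant_decoys(truth, decoy_fraction, seed = sub(4))
  ex <- generate_expression(truth, base_mean = base_mean, seed = sub(5))
  list(truth = truth, expr = ex$expr, groups = ex$groups)
}

#' Write a synthetic bundle as the pipeline's standard input files
#'
#' Writes `expression.tsv`, `groups.tsv`, `pkn.tsv` and `truth.tsv`
#' (gene, state_disease, is_deg) into a directory.
#'
#' @param bundle a list from [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(bundle$expr, file.path(dir, "expression.tsv"))
  utils::write.table(bundle$groups, file.path(dir, "groups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pkn_edges(bundle$truth), file.path(dir, "pkn.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  st <- bundle$truth$states
  utils::write.table(st[, c("gene", "state_disease", "is_deg")],
                     file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
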