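#' Candidate genes for network perturbation
#'
#' The candidate set is the union of (i) all genes appearing in any
#' differential-regulator set and (ii) all genes lying on an elementary
#' circuit of the diseased network, in deterministic lexicographic order.
#' These genes sit at the points where the two phenotype networks differ
#' or where feedback maintains a steady state, making them the natural
#' levers for reverting the expression program.
#'
#' @param net_d the diseased `phenotype_network`.
#' @param circuits_d circuit table of the diseased network
#'   (see [enumerate_circuits()]).
#' @param diff_regs differential-regulator list
#'   (see [differential_regulators()]).
#' @return sorted character vector of candidate gene ids (possibly empty,
#'   with a warning).
#' @export
candidate_genes <- function(net_d, circuits_d, diff_regs) {
  cand <- sort(union(unlist(diff_regs, use.names = FALSE),
                     circuit_genes(circuits_d)))
  cand <- intersect(cand, names(net_d$states))
  if (length(cand) == 0) {
    warning("empty candidate set: no circuits and no differential regulators")
  }
  cand
}

#' Score one clamped perturbation of the diseased network
#'
#' Starts the diseased network at its disease steady state, clamps the
#' combination's genes at their healthy-state values, iterates the
#' synchronous Boolean dynamics to an attractor, and counts the
#' non-clamped genes that were dysregulated (disease state differing from
#' healthy state) and whose state equals their healthy state in every
#' attractor state (oscillating genes never count; genes whose phenotype
#' states agree were never dysregulated and cannot be reverted). Clamped
#' genes are forced, not reverted, so they are excluded from the score by
#' default.
#'
#' @param net the diseased `phenotype_network`.
#' @param states state table (see [discretize()]) covering the network's
#'   nodes.
#' @param combo character vector of genes to clamp (may be empty for the
#'   baseline).
#' @param step_cap iteration guard passed to [find_attractor()].
#' @param count_clamped if `TRUE`, clamped genes whose healthy state
#'   differs from their disease state also count toward the score.
#' @param baseline_score precomputed empty-perturbation score; computed
#'   when `NULL`.
#' @return a `simulation_result`: list with `combo`, `attractor`,
#'   `reverted` (sorted gene ids), `score` and `baseline_score`.
#' @export
reversion_score <- function(net, states, combo = character(0), step_cap = 10000,
                            count_clamped = FALSE, baseline_score = NULL) {
  stopifnot(inherits(net, "phenotype_network"))
  combo <- unique(as.character(combo))
  bad <- setdiff(combo, names(net$states))
  if (length(bad) > 0) {
    stop("combo gene(s) not in the network: ", paste(bad, collapse = ", "))
  }
  bn <- compile_boolean(net)
  sd <- state_vector(states, "disease")
  sh <- state_vector(states, "healthy")
  missing <- setdiff(bn$nodes, names(sd))
  if (length(missing) > 0) {
    stop("no states for network node(s): ", paste(missing, collapse = ", "))
  }
  init <- sd[bn$nodes]
  init[combo] <- sh[combo]
  att <- find_attractor(bn, init, clamped = combo, step_cap = step_cap)

  healthy <- sh[bn$nodes]
  matched <- colSums(att$states == rep(healthy, each = nrow(att$states))) ==
    nrow(att$states)
  names(matched) <- bn$nodes
  differing <- bn$nodes[sd[bn$nodes] != sh[bn$nodes]]
  scored <- if (count_clamped) differing else setdiff(differing, combo)
  reverted <- sort(scored[matched[scored]])
  score <- length(reverted)
  if (is.null(baseline_score)) {
    baseline_score <- if (length(combo) == 0) {
      score
    } else {
      reversion_score(net, states, character(0), step_cap = step_cap,
                      count_clamped = count_clamped)$score
    }
  }
  structure(list(combo = sort(combo), attractor = att, reverted = reverted,
                 score = score, baseline_score = baseline_score),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("perturbation {%s}: score %d (baseline %d), %d gene(s) reverted\n",
              paste(x$combo, collapse = ";"), x$score, x$baseline_score,
              length(x$reverted)))
  invisible(x)
}

#' Exhaustively rank 1- to `max_combo`-gene perturbations
#'
#' Evaluates every combination of 1 to `max_combo` candidate genes with
#' [reversion_score()] and ranks them by score (descending), then combo
#' size (ascending, so the most parsimonious intervention wins ties), then
#' lexicographically. The module is fully deterministic.
#'
#' @param net the diseased `phenotype_network`.
#' @param states state table covering the network's nodes.
#' @param candidates character vector of candidate genes (all must be
#'   network nodes).
#' @param max_combo largest combination size (default 4).
#' @param top_k number of top-ranked combinations returned (default 10;
#'   `Inf` returns all).
#' @param candidate_cap refuse candidate sets larger than this (default
#'   25): the exhaustive search is binomial in the candidate count.
#' @param step_cap iteration guard per simulation.
#' @return data.frame with columns `rank`, `genes` (semicolon-joined),
#'   `size`, `score`, `baseline_score`, `reverted` (semicolon-joined);
#'   attribute `n_evaluated` carries the number of combinations simulated.
#' @export
rank_combinations <- function(net, states, candidates, max_combo = 4,
                              top_k = 10, candidate_cap = 25,
                              step_cap = 10000) {
  stopifnot(inherits(net, "phenotype_network"))
  candidates <- sort(unique(as.character(candidates)))
  if (length(candidates) > candidate_cap) {
    stop(length(candidates), " candidates exceed the cap of ", candidate_cap,
         "; shrink the candidate set (e.g. tighter DEG thresholds) or raise",
         " `candidate_cap` knowingly")
  }
  empty <- data.frame(rank = integer(0), genes = character(0),
                      size = integer(0), score = integer(0),
                      baseline_score = integer(0), reverted = character(0),
                      stringsAsFactors = FALSE)
  if (length(candidates) == 0) {
    attr(empty, "n_evaluated") <- 0L
    return(empty)
  }
  bad <- setdiff(candidates, names(net$states))
  if (length(bad) > 0) {
    stop("candidate gene(s) not in the network: ", paste(bad, collapse = ", "))
  }
  max_combo <- min(max_combo, length(candidates))

  baseline <- reversion_score(net, states, character(0), step_cap = step_cap)$score
  rows <- list()
  for (k in seq_len(max_combo)) {
    combos <- utils::combn(candidates, k, simplify = FALSE)
    for (cmb in combos) {
      res <- reversion_score(net, states, cmb, step_cap = step_cap,
                             baseline_score = baseline)
      rows[[length(rows) + 1L]] <- data.frame(
        genes = paste(cmb, collapse = ";"), size = k, score = res$score,
        baseline_score = baseline,
        reverted = paste(res$reverted, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  n_eval <- nrow(out)
  out <- out[order(-out$score, out$size, out$genes), , drop = FALSE]
  out <- utils::head(out, top_k)
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "n_evaluated") <- n_eval
  out
}
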