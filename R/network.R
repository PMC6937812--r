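#' Keep prior-knowledge edges of selected interaction categories
#'
#' @param pkn edge data.frame with columns `source`, `effect`, `target`,
#'   `category`.
#' @param kept character vector of category labels to retain; defaults to
#'   transcription regulation and binding interactions.
#' @return the filtered edge data.frame.
#' @export
filter_categories <- function(pkn, kept = c("Transcription regulation", "Binding")) {
  check_pkn(pkn)
  pkn[pkn$category %in% kept, , drop = FALSE]
}

#' Restrict a prior-knowledge network to differentially expressed genes
#'
#' An edge is kept only if both its endpoints are DEGs.
#'
#' @param pkn edge data.frame (`source`, `effect`, `target`, ...).
#' @param deg_set character vector of DEG gene ids.
#' @return the restricted edge data.frame.
#' @export
restrict_to_degs <- function(pkn, deg_set) {
  check_pkn(pkn, need_category = FALSE)
  pkn[pkn$source %in% deg_set & pkn$target %in% deg_set, , drop = FALSE]
}

#' Resolve unknown interaction signs from the discretized disease states
#'
#' Interactions of unknown regulatory effect are signed from the expression
#' pattern: activation if source and target share the same disease state,
#' inhibition otherwise. Known signs are left untouched.
#'
#' @param pkn edge data.frame (`source`, `effect`, `target`, ...), effects
#'   in `activation` / `inhibition` / `unknown`.
#' @param states state table from [discretize()].
#' @return the edge data.frame with no `unknown` effects remaining.
#' @export
resolve_signs <- function(pkn, states) {
  check_pkn(pkn, need_category = FALSE)
  s <- state_vector(states, "disease")
  unk <- pkn$effect == "unknown"
  if (any(unk)) {
    ends <- unique(c(pkn$source[unk], pkn$target[unk]))
    missing <- setdiff(ends, names(s))
    if (length(missing) > 0) {
      stop("cannot resolve signs: no disease state for ",
           paste(missing, collapse = ", "))
    }
    same <- s[pkn$source[unk]] == s[pkn$target[unk]]
    pkn$effect[unk] <- ifelse(same, "activation", "inhibition")
  }
  pkn
}

#' Prune edges incompatible with one phenotype's expression program
#'
#' Applies local Boolean-consistency semantics (a target is ON iff some
#' activator is ON and no inhibitor is ON, with inhibitor dominance) to the
#' fully signed network under the steady state `s` of the requested
#' phenotype. An edge `u -> v` is removed iff
#' \itemize{
#'   \item effect is inhibition with `s(u) = 1` and `s(v) = 1` (an active
#'     inhibitor contradicts an active target), or
#'   \item effect is activation with `s(u) = 1`, `s(v) = 0`, and `v` has no
#'     inhibition in-edge from an active source (an unexplained active
#'     activator of an inactive target; an active inhibitor on the same
#'     target dominates and rescues the edge).
#' }
#' All other edges are retained. Edges from sources inactive in this
#' phenotype are never removed, which is what lets the two phenotype
#' networks share topology.
#'
#' @param edges fully signed edge data.frame (no `unknown` effects).
#' @param states state table from [discretize()]; every edge endpoint must
#'   have a state.
#' @param phenotype `"disease"` or `"healthy"`.
#' @return a `phenotype_network`: list with elements `phenotype`, `edges`
#'   (retained signed edges) and `states` (named 0/1 vector over the nodes,
#'   which are exactly the endpoints of retained edges).
#' @export
prune_network <- function(edges, states, phenotype = c("disease", "healthy")) {
  phenotype <- match.arg(phenotype)
  check_pkn(edges, need_category = FALSE)
  if (any(edges$effect == "unknown")) {
    stop("all signs must be resolved before pruning; see resolve_signs()")
  }
  s <- state_vector(states, phenotype)
  ends <- unique(c(edges$source, edges$target))
  missing <- setdiff(ends, names(s))
  if (length(missing) > 0) {
    stop("no ", phenotype, " state for: ", paste(missing, collapse = ", "))
  }
  keep <- edge_retention(edges, s)
  kept <- edges[keep, , drop = FALSE]
  rownames(kept) <- NULL
  nodes <- sort(unique(c(kept$source, kept$target)))
  structure(list(phenotype = phenotype,
                 edges = kept[, c("source", "effect", "target"), drop = FALSE],
                 states = s[nodes]),
            class = "phenotype_network")
}

# Retention rule over a signed edge table under state vector s.
# Rescue (inhibitor dominance) is evaluated against the full input edge
# set; rescuing inhibition edges are themselves never removable (rule (a)
# needs an active target), so auditing retained edges alone is equivalent.
edge_retention <- function(edges, s) {
  su <- s[edges$source]
  sv <- s[edges$target]
  inhibited_active <- unique(edges$target[edges$effect == "inhibition" &
                                            s[edges$source] == 1])
  rescued <- edges$target %in% inhibited_active
  remove <- (edges$effect == "inhibition" & su == 1 & sv == 1) |
    (edges$effect == "activation" & su == 1 & sv == 0 & !rescued)
  !remove
}

#' Verify a pruned phenotype network against its own retention rule
#'
#' Re-checks, over the retained edges only, that no edge violates the
#' compatibility rule used by [prune_network()], that no unknown signs
#' remain, and that no node is isolated.
#'
#' @param net a `phenotype_network`.
#' @return `TRUE` invisibly; stops with a message on any violation.
#' @export
audit_network <- function(net) {
  stopifnot(inherits(net, "phenotype_network"))
  if (any(net$edges$effect == "unknown")) stop("audit: unknown effect present")
  touched <- unique(c(net$edges$source, net$edges$target))
  if (!setequal(touched, names(net$states))) stop("audit: isolated node present")
  if (!all(edge_retention(net$edges, net$states))) {
    stop("audit: retained edge violates the compatibility rule")
  }
  invisible(TRUE)
}

#' @export
print.phenotype_network <- function(x, ...) {
  cat(sprintf("phenotype_network [%s]: %d genes, %d interactions\n",
              x$phenotype, length(x$states), nrow(x$edges)))
  invisible(x)
}

#' Differential regulators of genes shared by both phenotype networks
#'
#' For every gene present in both networks, computes the symmetric
#' difference of its in-neighbour (regulator) sets; genes whose regulators
#' agree are omitted.
#'
#' @param net_d,net_h the diseased and healthy `phenotype_network`s.
#' @return named list: target gene -> character vector of regulators
#'   present in exactly one of the two networks.
#' @export
differential_regulators <- function(net_d, net_h) {
  stopifnot(inherits(net_d, "phenotype_network"),
            inherits(net_h, "phenotype_network"))
  common <- intersect(names(net_d$states), names(net_h$states))
  out <- list()
  for (g in common) {
    in_d <- unique(net_d$edges$source[net_d$edges$target == g])
    in_h <- unique(net_h$edges$source[net_h$edges$target == g])
    diff <- union(setdiff(in_d, in_h), setdiff(in_h, in_d))
    if (length(diff) > 0) out[[g]] <- sort(diff)
  }
  out
}

#' Regulator sign differences between the two phenotype networks
#'
#' Secondary report: source-target pairs present in both networks whose
#' sets of effects (parallel edges allowed) differ.
#'
#' @param net_d,net_h the two `phenotype_network`s.
#' @return data.frame with columns `source`, `target`, `effects_disease`,
#'   `effects_healthy` (comma-joined).
#' @export
differential_edge_signs <- function(net_d, net_h) {
  key_d <- paste(net_d$edges$source, net_d$edges$target)
  key_h <- paste(net_h$edges$source, net_h$edges$target)
  shared <- intersect(key_d, key_h)
  rows <- lapply(shared, function(k) {
    ed <- sort(unique(net_d$edges$effect[key_d == k]))
    eh <- sort(unique(net_h$edges$effect[key_h == k]))
    if (identical(ed, eh)) return(NULL)
    parts <- strsplit(k, " ", fixed = TRUE)[[1]]
    data.frame(source = parts[1], target = parts[2],
               effects_disease = paste(ed, collapse = ","),
               effects_healthy = paste(eh, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(source = character(0), target = character(0),
                      effects_disease = character(0),
                      effects_healthy = character(0))
  }
  out
}

check_pkn <- function(pkn, need_category = TRUE) {
  need <- c("source", "effect", "target", if (need_category) "category")
  if (!is.data.frame(pkn) || !all(need %in% names(pkn))) {
    stop("edge table must have columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(pkn$effect), c("activation", "inhibition", "unknown"))
  if (length(bad) > 0) {
    stop("invalid effect value(s): ", paste(bad, collapse = ", "),
         "; allowed: activation, inhibition, unknown")
  }
  invisible(pkn)
}
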