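#' Enumerate signed elementary circuits of a network
#'
#' An elementary circuit is a directed path that starts and ends at the
#' same node with all intermediate nodes visited exactly once. Enumeration
#' is a Johnson-style blocked depth-first search rooted at each node in
#' increasing id order over the subgraph of not-smaller ids, so every
#' circuit is produced exactly once, already in canonical rotation
#' (smallest gene id first). A vertex is blocked only when its subtree was
#' fully explored without reaching the root; subtrees cut short by the
#' length cap never block, which keeps the bounded search exact up to
#' `max_length`.
#'
#' Parallel edges between the same node pair with different signs yield
#' distinct circuits. Self-loops are circuits of length 1. Directed
#' circuits are not merged with their reversals.
#'
#' @param net a `phenotype_network` or a signed edge data.frame
#'   (`source`, `effect`, `target`; no `unknown` effects).
#' @param max_length maximum circuit length (number of nodes); default 12.
#'   `Inf` removes the cap. A warning is emitted if the cap truncated the
#'   search.
#' @return data.frame with one row per circuit: `nodes` (semicolon-joined
#'   canonical node sequence), `length`, `signs` (semicolon-joined edge
#'   effects along the circuit), `n_inhibitions`, and `sign`
#'   (`"positive"` / `"negative"`).
#' @export
enumerate_circuits <- function(net, max_length = 12) {
  edges <- if (inherits(net, "phenotype_network")) net$edges else net
  check_pkn(edges, need_category = FALSE)
  if (any(edges$effect == "unknown")) stop("circuit enumeration needs a fully signed network")
  if (max_length < 1) stop("`max_length` must be >= 1")

  nodes <- sort(unique(c(edges$source, edges$target)))
  n <- length(nodes)
  empty <- data.frame(nodes = character(0), length = integer(0),
                      signs = character(0), n_inhibitions = integer(0),
                      sign = character(0), stringsAsFactors = FALSE)
  if (n == 0 || nrow(edges) == 0) return(empty)

  idx <- stats::setNames(seq_len(n), nodes)
  ui <- idx[edges$source]
  vi <- idx[edges$target]
  succ <- lapply(seq_len(n), function(i) sort(unique(vi[ui == i])))

  env <- new.env(parent = emptyenv())
  env$cycles <- list()
  env$truncated <- FALSE

  for (root in seq_len(n)) {
    if (length(succ[[root]]) == 0) next
    env$blocked <- rep(FALSE, n)
    env$blist <- lapply(seq_len(n), function(i) integer(0))
    env$path <- integer(0)
    johnson_visit(root, root, succ, max_length, env)
  }
  if (env$truncated) {
    warning("circuit enumeration truncated at max_length = ", max_length,
            "; longer circuits exist and were not reported")
  }
  if (length(env$cycles) == 0) return(empty)

  # expand vertex cycles over parallel signed edges
  ekey <- paste(ui, vi)
  rows <- lapply(env$cycles, function(cyc) {
    k <- length(cyc)
    steps <- paste(cyc, c(cyc[-1], cyc[1]))
    eff_per_step <- lapply(steps, function(s) sort(unique(edges$effect[ekey == s])))
    combos <- expand.grid(rev(eff_per_step), stringsAsFactors = FALSE)
    combos <- combos[, rev(seq_len(k)), drop = FALSE]
    node_str <- paste(nodes[cyc], collapse = ";")
    n_inh <- apply(combos, 1, function(e) sum(e == "inhibition"))
    data.frame(nodes = node_str, length = k,
               signs = apply(combos, 1, paste, collapse = ";"),
               n_inhibitions = as.integer(n_inh),
               sign = ifelse(n_inh %% 2 == 0, "positive", "negative"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$length, out$nodes, out$signs), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Blocked DFS from Johnson's elementary-circuit algorithm, restricted to
# vertices >= root and bounded by max_length. Returns c(found, hit_cap).
johnson_visit <- function(v, root, succ, max_length, env) {
  found <- FALSE
  hit_cap <- FALSE
  env$blocked[v] <- TRUE
  env$path <- c(env$path, v)
  for (w in succ[[v]]) {
    if (w < root) next
    if (w == root) {
      env$cycles[[length(env$cycles) + 1L]] <- env$path
      found <- TRUE
    } else if (length(env$path) < max_length) {
      if (!env$blocked[w]) {
        res <- johnson_visit(w, root, succ, max_length, env)
        found <- found || res[1]
        hit_cap <- hit_cap || res[2]
      }
    } else {
      hit_cap <- TRUE
      env$truncated <- TRUE
    }
  }
  if (found || hit_cap) {
    johnson_unblock(v, env)
  } else {
    for (w in succ[[v]]) {
      if (w >= root && !(v %in% env$blist[[w]])) {
        env$blist[[w]] <- c(env$blist[[w]], v)
      }
    }
  }
  env$path <- env$path[-length(env$path)]
  c(found, hit_cap)
}

johnson_unblock <- function(v, env) {
  env$blocked[v] <- FALSE
  pending <- env$blist[[v]]
  env$blist[[v]] <- integer(0)
  for (w in pending) {
    if (env$blocked[w]) johnson_unblock(w, env)
  }
}

#' Sign of an elementary circuit
#'
#' Positive iff the circuit traverses an even number of inhibition edges.
#'
#' @param circuit either a character vector of edge effects along the
#'   circuit, or a circuit table row from [enumerate_circuits()] (its
#'   `signs` column is used).
#' @return `"positive"` or `"negative"` (vectorized over rows for a table).
#' @export
circuit_sign <- function(circuit) {
  effects <- if (is.data.frame(circuit)) {
    strsplit(circuit$signs, ";", fixed = TRUE)
  } else {
    list(circuit)
  }
  vapply(effects, function(e) {
    if (!all(e %in% c("activation", "inhibition"))) {
      stop("circuit effects must be 'activation' or 'inhibition'")
    }
    if (sum(e == "inhibition") %% 2 == 0) "positive" else "negative"
  }, character(1))
}

#' Partition circuits into common and phenotype-specific sets
#'
#' A circuit is common iff an identical canonical node sequence with
#' identical edge signs exists in both lists; the partition is disjoint
#' and exhaustive.
#'
#' @param circ_d,circ_h circuit tables from [enumerate_circuits()] for the
#'   diseased and healthy networks.
#' @return list of three circuit tables: `common`, `disease_specific`,
#'   `healthy_specific` (common circuits are reported once, as found in
#'   the diseased network).
#' @export
compare_circuits <- function(circ_d, circ_h) {
  key_d <- paste(circ_d$nodes, circ_d$signs, sep = "|")
  key_h <- paste(circ_h$nodes, circ_h$signs, sep = "|")
  list(common = circ_d[key_d %in% key_h, , drop = FALSE],
       disease_specific = circ_d[!key_d %in% key_h, , drop = FALSE],
       healthy_specific = circ_h[!key_h %in% key_d, , drop = FALSE])
}

# Genes appearing on any circuit of a circuit table.
circuit_genes <- function(circuits) {
  sort(unique(unlist(strsplit(circuits$nodes, ";", fixed = TRUE))))
}
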