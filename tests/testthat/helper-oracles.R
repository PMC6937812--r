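# Independent reference implementations used to validate the package's
# algorithms. These deliberately use different (simpler, brute-force)
# strategies than the implementations they check.

# Direct BH step-up: q(i) = min_{j >= i} p(j) * m / j over sorted p,
# clipped at 1, mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Exact combinatorial upper-tail hypergeometric probability.
hyper_oracle <- function(overlap, query, set, universe) {
  ks <- overlap:min(query, set)
  sum(choose(set, ks) * choose(universe - set, query - ks)) / choose(universe, query)
}

# Brute-force signed elementary-circuit enumeration: plain DFS over simple
# paths from each start node (restricted to not-smaller nodes so each
# cycle is found once, rooted at its smallest node), traversing edges so
# parallel edges of different sign give distinct circuits.
# Returns a sorted character vector of "nodes|signs" keys.
cycle_oracle <- function(edges, max_length = Inf) {
  nodes <- sort(unique(c(edges$source, edges$target)))
  found <- character(0)
  walk <- function(start, path, signs) {
    v <- path[length(path)]
    out <- which(edges$source == v)
    for (i in out) {
      w <- edges$target[i]
      if (w < start) next
      if (w == start) {
        found <<- c(found, paste(paste(path, collapse = ";"),
                                 paste(c(signs, edges$effect[i]), collapse = ";"),
                                 sep = "|"))
      } else if (!(w %in% path) && length(path) < max_length) {
        walk(start, c(path, w), c(signs, edges$effect[i]))
      }
    }
  }
  for (s in nodes) walk(s, s, character(0))
  sort(unique(found))
}

circuit_keys <- function(circuits) {
  sort(paste(circuits$nodes, circuits$signs, sep = "|"))
}

# Independent synchronous-update rule evaluated state by state: for each
# node, scan the edge table for its regulators.
step_oracle <- function(edges, state, clamped = character(0)) {
  nxt <- state
  for (g in names(state)) {
    if (g %in% clamped) next
    acts <- edges$source[edges$target == g & edges$effect == "activation"]
    inhs <- edges$source[edges$target == g & edges$effect == "inhibition"]
    if (length(acts) + length(inhs) == 0) next
    on <- if (length(acts) == 0) TRUE else any(state[acts] == 1)
    nxt[[g]] <- as.integer(on && !any(state[inhs] == 1))
  }
  nxt
}

# Brute-force attractor: build the full synchronous transition graph over
# all 2^n states (vectorized over states, node by node), then follow the
# trajectory from the initial state until it revisits a state.
attractor_oracle <- function(edges, initial, clamped = character(0)) {
  nodes <- names(initial)
  n <- length(nodes)
  S <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(S) <- nodes
  Nx <- S
  for (j in seq_len(n)) {
    g <- nodes[j]
    if (g %in% clamped) next
    acts <- edges$source[edges$target == g & edges$effect == "activation"]
    inhs <- edges$source[edges$target == g & edges$effect == "inhibition"]
    if (length(acts) + length(inhs) == 0) next
    a <- if (length(acts)) rowSums(S[, acts, drop = FALSE]) > 0 else TRUE
    i <- if (length(inhs)) rowSums(S[, inhs, drop = FALSE]) > 0 else FALSE
    Nx[, j] <- as.integer(a & !i)
  }
  id <- function(m) as.vector(m %*% 2^(seq_len(n) - 1)) + 1
  trans <- id(Nx)
  cur <- id(matrix(initial[nodes], nrow = 1))
  seen <- integer(0)
  while (!(cur %in% seen)) {
    seen <- c(seen, cur)
    cur <- trans[cur]
  }
  cyc <- seen[which(seen == cur):length(seen)]
  m <- S[cyc, , drop = FALSE]
  rownames(m) <- NULL
  m
}

# Sort attractor state matrices into a canonical row order for comparison.
canon_states <- function(m) {
  m <- m[, sort(colnames(m)), drop = FALSE]
  m[order(apply(m, 1, paste, collapse = "")), , drop = FALSE]
}

# Independent audit of the pruning compatibility rule: returns the logical
# keep/remove decision per edge of `edges` under state vector `s`,
# evaluated edge by edge with explicit loops.
retention_oracle <- function(edges, s) {
  keep <- logical(nrow(edges))
  for (i in seq_len(nrow(edges))) {
    u <- edges$source[i]; v <- edges$target[i]; eff <- edges$effect[i]
    if (eff == "inhibition" && s[[u]] == 1 && s[[v]] == 1) {
      keep[i] <- FALSE
    } else if (eff == "activation" && s[[u]] == 1 && s[[v]] == 0) {
      rescuers <- which(edges$target == v & edges$effect == "inhibition")
      keep[i] <- any(s[edges$source[rescuers]] == 1)
    } else {
      keep[i] <- TRUE
    }
  }
  keep
}

# Small random signed digraph as an edge table (no unknowns, no parallel
# duplicates unless asked).
random_signed_edges <- function(n_nodes, n_edges, p_inh = 0.4) {
  nodes <- sprintf("N%02d", seq_len(n_nodes))
  cap <- n_nodes * (n_nodes - 1)
  n_edges <- min(n_edges, cap)
  idx <- sample.int(cap, n_edges)
  u <- (idx - 1) %/% (n_nodes - 1) + 1
  r <- (idx - 1) %% (n_nodes - 1) + 1
  v <- r + (r >= u)
  data.frame(source = nodes[u],
             effect = ifelse(runif(n_edges) < p_inh, "inhibition", "activation"),
             target = nodes[v], stringsAsFactors = FALSE)
}
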