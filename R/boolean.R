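# Compiled Boolean form of a signed network: activation and inhibition
# adjacency matrices (target rows x source columns) for fast synchronous
# updates via matrix-vector products.
compile_boolean <- function(net) {
  edges <- if (inherits(net, "phenotype_network")) net$edges else net
  check_pkn(edges, need_category = FALSE)
  if (any(edges$effect == "unknown")) stop("Boolean dynamics need a fully signed network")
  nodes <- if (inherits(net, "phenotype_network")) {
    names(net$states)
  } else {
    sort(unique(c(edges$source, edges$target)))
  }
  n <- length(nodes)
  A <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  I <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  act <- edges$effect == "activation"
  A[cbind(edges$target[act], edges$source[act])] <- 1L
  I[cbind(edges$target[!act], edges$source[!act])] <- 1L
  structure(list(nodes = nodes, A = A, I = I,
                 has_act = rowSums(A) > 0,
                 has_in = rowSums(A) + rowSums(I) > 0),
            class = "boolean_network")
}

step_state <- function(bn, s, clamp_idx = integer(0)) {
  # nodes without activators (but with inhibitors) are active unless inhibited
  act_on <- (bn$A %*% s > 0) | !bn$has_act
  nxt <- as.integer(act_on & !(bn$I %*% s > 0))
  nxt[!bn$has_in] <- s[!bn$has_in]
  nxt[clamp_idx] <- s[clamp_idx]
  nxt
}

#' One synchronous Boolean update
#'
#' Each non-clamped node with at least one regulator moves to
#' `OR(activators) AND NOT OR(inhibitors)`, where a node regulated only by
#' inhibitors treats the activator clause as satisfied (active unless
#' inhibited — without this default such nodes would switch off forever,
#' and negative feedback loops could not oscillate). Nodes without
#' regulators hold their state; clamped nodes hold their current value.
#'
#' @param net a `phenotype_network` or signed edge data.frame.
#' @param state named 0/1 vector covering every node of the network.
#' @param clamped character vector of gene ids held fixed at their value
#'   in `state`.
#' @return the next state, a named 0/1 vector in the same node order.
#' @export
boolean_step <- function(net, state, clamped = character(0)) {
  bn <- if (inherits(net, "boolean_network")) net else compile_boolean(net)
  s <- check_state(bn, state)
  clamp_idx <- clamp_indices(bn, clamped)
  stats::setNames(step_state(bn, s, clamp_idx), bn$nodes)
}

#' Attractor reached by deterministic synchronous iteration
#'
#' Iterates the synchronous update from `initial`, hashing visited states;
#' the first repeated state closes the attractor cycle (a fixpoint is a
#' cycle of length 1).
#'
#' @param net a `phenotype_network` or signed edge data.frame.
#' @param initial named 0/1 starting state covering every node.
#' @param clamped character vector of gene ids held fixed throughout.
#' @param step_cap maximum number of updates before giving up
#'   (default 10000); exceeding it is an error, guarding memory on large
#'   state spaces.
#' @return an `attractor`: list with `states` (0/1 matrix, one row per
#'   state on the cycle, columns named by gene) and `period`.
#' @export
find_attractor <- function(net, initial, clamped = character(0), step_cap = 10000) {
  if (step_cap < 1) stop("`step_cap` must be >= 1")
  bn <- if (inherits(net, "boolean_network")) net else compile_boolean(net)
  s <- check_state(bn, initial)
  clamp_idx <- clamp_indices(bn, clamped)

  seen <- new.env(parent = emptyenv())
  trace <- vector("list", 64)
  t <- 0L
  repeat {
    key <- paste(s, collapse = "")
    hit <- seen[[key]]
    if (!is.null(hit)) {
      cyc <- trace[seq(hit, t)]
      m <- do.call(rbind, cyc)
      colnames(m) <- bn$nodes
      return(structure(list(states = m, period = nrow(m)),
                       class = "attractor"))
    }
    t <- t + 1L
    if (t > step_cap) stop("no attractor found within step_cap = ", step_cap, " updates")
    seen[[key]] <- t
    if (t > length(trace)) trace <- c(trace, vector("list", length(trace)))
    trace[[t]] <- s
    s <- step_state(bn, s, clamp_idx)
  }
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("attractor: period %d over %d genes\n", x$period, ncol(x$states)))
  invisible(x)
}

check_state <- function(bn, state) {
  if (is.null(names(state)) || !all(bn$nodes %in% names(state))) {
    stop("`state` must be a named 0/1 vector covering every network node")
  }
  s <- as.integer(state[bn$nodes])
  if (any(is.na(s)) || !all(s %in% c(0L, 1L))) {
    stop("states must be 0 or 1")
  }
  s
}

clamp_indices <- function(bn, clamped) {
  clamped <- unique(as.character(clamped))
  bad <- setdiff(clamped, bn$nodes)
  if (length(bad) > 0) {
    stop("clamped gene(s) not in the network: ", paste(bad, collapse = ", "))
  }
  match(clamped, bn$nodes)
}
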