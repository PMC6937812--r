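# Hand-built diseased networks with explicit states; prune_network is
# bypassed by constructing the network from already-compatible edges.
make_net <- function(edges, disease) {
  st <- data.frame(gene = names(disease), state_disease = as.integer(disease),
                   state_healthy = 1L - as.integer(disease),
                   stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$source, edges$target)))
  net <- structure(list(phenotype = "disease",
                        edges = edges[, c("source", "effect", "target")],
                        states = setNames(st$state_disease, st$gene)[nodes]),
                   class = "phenotype_network")
  list(net = net, states = st)
}
sedge <- function(source, effect, target) {
  data.frame(source = source, effect = effect, target = target,
             stringsAsFactors = FALSE)
}

test_that("candidate set is the union of circuit genes and differential regulators", {
  e <- rbind(sedge("A", "activation", "B"), sedge("B", "activation", "A"),
             sedge("C", "activation", "B"))
  m <- make_net(e, c(A = 1, B = 1, C = 1))
  circ <- enumerate_circuits(m$net)
  expect_equal(candidate_genes(m$net, circ, list(B = "C")), c("A", "B", "C"))
  # duplicates collapse; genes outside the network are not candidates
  expect_equal(candidate_genes(m$net, circ, list(B = c("A", "B"))), c("A", "B"))
  empty_circ <- enumerate_circuits(sedge("X", "activation", "Y"))
  expect_warning(cand <- candidate_genes(m$net, empty_circ, list()), "empty")
  expect_equal(length(cand), 0)
})

test_that("synchronous update follows OR-activators AND-NOT-OR-inhibitors", {
  e <- sedge("A", "activation", "B")
  s <- c(A = 0, B = 1)
  nxt <- boolean_step(e, s, clamped = "A")
  expect_equal(nxt, c(A = 0, B = 0))      # activator off -> target decays

  # a node with no regulators holds its state
  expect_equal(boolean_step(e, c(A = 1, B = 0))[["A"]], 1)

  # inhibitor dominance: active inhibitor silences an activated target
  e2 <- rbind(sedge("A", "activation", "B"), sedge("C", "inhibition", "B"))
  expect_equal(boolean_step(e2, c(A = 1, B = 1, C = 1))[["B"]], 0)

  # a node with only inhibitors is active unless inhibited
  e3 <- sedge("C", "inhibition", "B")
  expect_equal(boolean_step(e3, c(B = 0, C = 0))[["B"]], 1)
  expect_equal(boolean_step(e3, c(B = 1, C = 1))[["B"]], 0)
})

test_that("attractor detection handles fixpoints, cycles and full clamping", {
  e <- rbind(sedge("A", "activation", "B"), sedge("B", "activation", "A"))
  fix <- find_attractor(e, c(A = 1, B = 1))
  expect_equal(fix$period, 1)
  expect_equal(fix$states[1, ], c(A = 1, B = 1))

  neg <- rbind(sedge("A", "activation", "B"), sedge("B", "inhibition", "A"))
  osc <- find_attractor(neg, c(A = 1, B = 1))
  expect_gt(osc$period, 1)

  clamped <- find_attractor(neg, c(A = 1, B = 1), clamped = c("A", "B"))
  expect_equal(clamped$period, 1)
  expect_equal(clamped$states[1, ], c(A = 1, B = 1))

  expect_error(find_attractor(neg, c(A = 1, B = 1), step_cap = 1), "step_cap")
  expect_error(find_attractor(neg, c(A = 2, B = 1)), "0 or 1")
  expect_error(find_attractor(neg, c(A = 1, B = 1), clamped = "Z"), "Z")
})

test_that("attractors agree with the transition-graph oracle on random nets", {
  set.seed(37)
  for (i in 1:25) {
    n <- sample(3:8, 1)
    e <- random_signed_edges(n, sample(n:(3 * n), 1))
    nodes <- sort(unique(c(e$source, e$target)))
    init <- setNames(rbinom(length(nodes), 1, 0.5), nodes)
    clamped <- if (runif(1) < 0.3) sample(nodes, 1) else character(0)
    att <- find_attractor(e, init, clamped = clamped)
    expect_equal(canon_states(att$states),
                 canon_states(attractor_oracle(e, init, clamped = clamped)),
                 ignore_attr = TRUE)
  }
})

test_that("clamping the chain root reverts its downstream target", {
  m <- make_net(sedge("A", "activation", "B"), c(A = 1, B = 1))
  res <- reversion_score(m$net, m$states, "A")
  expect_equal(res$score, 1)
  expect_equal(res$reverted, "B")
  expect_s3_class(res$attractor, "attractor")
})

test_that("clamping a star root reverts all k targets", {
  k <- 5
  targets <- paste0("T", 1:k)
  e <- sedge(rep("R", k), "activation", targets)
  m <- make_net(e, setNames(rep(1, k + 1), c("R", targets)))
  res <- reversion_score(m$net, m$states, "R")
  expect_equal(res$score, k)
  expect_setequal(res$reverted, targets)
})

test_that("the empty perturbation of a disease fixpoint scores zero", {
  e <- rbind(sedge("A", "activation", "B"), sedge("B", "activation", "A"))
  m <- make_net(e, c(A = 1, B = 1))
  res <- reversion_score(m$net, m$states, character(0))
  expect_equal(res$score, 0)
  expect_equal(res$baseline_score, 0)
})

test_that("scores never exceed the number of differing, non-clamped genes", {
  set.seed(41)
  for (i in 1:10) {
    e <- random_signed_edges(6, sample(8:14, 1))
    nodes <- sort(unique(c(e$source, e$target)))
    disease <- setNames(rbinom(length(nodes), 1, 0.5), nodes)
    st <- data.frame(gene = nodes, state_disease = disease,
                     state_healthy = rbinom(length(nodes), 1, 0.5))
    net <- structure(list(phenotype = "disease",
                          edges = e, states = disease),
                     class = "phenotype_network")
    differing <- st$gene[st$state_disease != st$state_healthy]
    combo <- sample(nodes, min(2, length(nodes)))
    res <- reversion_score(net, st, combo)
    expect_lte(res$score, length(setdiff(differing, combo)))
  }
})

test_that("clamping every differing gene accounts for all of them", {
  # with discretized DEG states every network node differs between phenotypes
  set.seed(43)
  e <- random_signed_edges(6, 12)
  nodes <- sort(unique(c(e$source, e$target)))
  m <- make_net(e, setNames(rbinom(length(nodes), 1, 0.5), nodes))
  res <- reversion_score(m$net, m$states, nodes)
  expect_setequal(union(res$reverted, nodes), nodes)
  expect_equal(res$score, 0)  # every differing gene is clamped, none scored
})

test_that("rank_combinations evaluates all binomial sums and orders ties", {
  targets <- paste0("T", 1:5)
  e <- sedge(rep("R", 5), "activation", targets)
  m <- make_net(e, setNames(rep(1, 6), c("R", targets)))
  cand <- c("R", targets)  # 6 candidates
  rk <- rank_combinations(m$net, m$states, cand, max_combo = 4, top_k = Inf)
  expect_equal(attr(rk, "n_evaluated"), 6 + 15 + 20 + 15)  # 56
  # best single intervention is the root
  expect_equal(rk$genes[1], "R")
  expect_equal(rk$score[1], 5)
  # ties order by size, then lexicographically
  same <- rk[rk$score == rk$score[2] & rk$size <= 2, ]
  expect_true(all(diff(same$size) >= 0))
  within <- rk$genes[rk$score == 4 & rk$size == 2]
  expect_equal(within, sort(within))
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(rk$baseline_score == rk$baseline_score[1]))
})

test_that("rank_combinations is deterministic and guards its inputs", {
  m <- make_net(rbind(sedge("A", "activation", "B"),
                      sedge("B", "inhibition", "A")), c(A = 1, B = 1))
  r1 <- rank_combinations(m$net, m$states, c("A", "B"))
  r2 <- rank_combinations(m$net, m$states, c("A", "B"))
  expect_identical(r1, r2)
  expect_equal(attr(rank_combinations(m$net, m$states, "A", max_combo = 4),
                    "n_evaluated"), 1)
  expect_error(rank_combinations(m$net, m$states, paste0("X", 1:30)),
               "cap")
  expect_error(reversion_score(m$net, m$states, "nope"), "nope")
  rk0 <- rank_combinations(m$net, m$states, character(0)) |> suppressWarnings()
  expect_equal(nrow(rk0), 0)
})
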