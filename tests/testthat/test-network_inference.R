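edge <- function(source, effect, target, category = "Binding") {
  data.frame(source = source, effect = effect, target = target,
             category = category, stringsAsFactors = FALSE)
}
states_tab <- function(genes, disease) {
  data.frame(gene = genes, state_disease = as.integer(disease),
             state_healthy = 1L - as.integer(disease),
             stringsAsFactors = FALSE)
}

test_that("category filter keeps only transcription regulation and binding by default", {
  pkn <- rbind(edge("a", "activation", "b", "Transcription regulation"),
               edge("b", "inhibition", "c", "Phosphorylation"),
               edge("c", "unknown", "a", "Binding"))
  kept <- filter_categories(pkn)
  expect_equal(kept$source, c("a", "c"))
  expect_equal(nrow(filter_categories(pkn, kept = character(0))), 0)
  expect_equal(filter_categories(kept), kept)
})

test_that("DEG restriction requires both endpoints to be differential", {
  pkn <- rbind(edge("a", "activation", "b"), edge("b", "activation", "x"),
               edge("x", "inhibition", "a"))
  expect_equal(restrict_to_degs(pkn, c("a", "b"))$target, "b")
  expect_equal(nrow(restrict_to_degs(pkn, character(0))), 0)
})

test_that("unknown signs resolve from state agreement; known signs persist", {
  st <- states_tab(c("u", "v", "w"), c(1, 1, 0))
  pkn <- rbind(edge("u", "unknown", "v"), edge("u", "unknown", "w"),
               edge("w", "unknown", "v"), edge("v", "inhibition", "u"))
  out <- resolve_signs(pkn, st)
  expect_equal(out$effect, c("activation", "inhibition", "inhibition", "inhibition"))
  expect_error(resolve_signs(edge("u", "unknown", "zz"), st), "zz")
})

test_that("pruning removes active-inhibitor/active-target contradictions", {
  st <- states_tab(c("u", "v"), c(1, 1))
  net <- prune_network(edge("u", "inhibition", "v"), st, "disease")
  expect_equal(nrow(net$edges), 0)
  expect_equal(length(net$states), 0)
  # same edge is compatible in the healthy phenotype (source inactive)
  net_h <- prune_network(edge("u", "inhibition", "v"), st, "healthy")
  expect_equal(nrow(net_h$edges), 1)
})

test_that("an active inhibitor on the target rescues an unexplained activation", {
  st <- states_tab(c("u", "v", "w"), c(1, 0, 1))
  bare <- edge("u", "activation", "v")
  expect_equal(nrow(prune_network(bare, st, "disease")$edges), 0)
  rescued <- rbind(bare, edge("w", "inhibition", "v"))
  net <- prune_network(rescued, st, "disease")
  expect_equal(nrow(net$edges), 2)
  expect_true(all(c("u", "v", "w") %in% names(net$states)))
})

test_that("edges from inactive sources are always retained", {
  st <- states_tab(c("u", "v"), c(0, 1))
  for (eff in c("activation", "inhibition")) {
    for (sv in c("disease")) {
      expect_equal(nrow(prune_network(edge("u", eff, "v"), st, sv)$edges), 1)
    }
  }
})

test_that("pruning matches the independent audit on random instances", {
  set.seed(19)
  for (i in 1:50) {
    edges <- random_signed_edges(sample(4:12, 1), sample(6:25, 1))
    genes <- sort(unique(c(edges$source, edges$target)))
    st <- states_tab(genes, rbinom(length(genes), 1, 0.5))
    for (ph in c("disease", "healthy")) {
      s <- setNames(if (ph == "disease") st$state_disease else st$state_healthy,
                    st$gene)
      net <- prune_network(edges, st, ph)
      keep <- retention_oracle(edges, s)
      expect_equal(nrow(net$edges), sum(keep))
      expect_identical(
        sort(paste(net$edges$source, net$edges$effect, net$edges$target)),
        sort(paste(edges$source, edges$effect, edges$target)[keep]))
      expect_silent(audit_network(net))
      # nodes are exactly the endpoints of retained edges
      expect_setequal(names(net$states),
                      unique(c(net$edges$source, net$edges$target)))
    }
  }
})

test_that("both phenotype networks are subsets of the resolved PKN and can share edges", {
  st <- states_tab(c("u", "v", "w"), c(0, 0, 1))
  st$state_healthy <- st$state_disease  # u, v inactive in both phenotypes
  pkn <- rbind(edge("u", "activation", "v"), edge("w", "activation", "v"))
  net_d <- prune_network(pkn, st, "disease")
  net_h <- prune_network(pkn, st, "healthy")
  expect_true(all(paste(net_d$edges$source, net_d$edges$target) %in%
                    paste(pkn$source, pkn$target)))
  # the u -> v edge (inactive source in both) survives in both networks
  expect_true("u" %in% net_d$edges$source && "u" %in% net_h$edges$source)
})

test_that("differential regulators are the symmetric in-neighbour difference", {
  st <- states_tab(c("a", "b", "v", "x"), c(0, 0, 0, 0))
  st$state_healthy <- st$state_disease
  net_d <- prune_network(rbind(edge("a", "activation", "v"),
                               edge("x", "activation", "a")), st, "disease")
  net_h <- prune_network(rbind(edge("a", "activation", "v"),
                               edge("b", "activation", "v"),
                               edge("x", "activation", "a")), st, "healthy")
  dr <- differential_regulators(net_d, net_h)
  expect_equal(dr, list(v = "b"))

  # identical in-neighbourhoods are omitted entirely
  expect_equal(differential_regulators(net_d, net_d), list())

  # genes absent from one network never appear
  net_h2 <- prune_network(edge("b", "activation", "x"), st, "healthy")
  expect_false("v" %in% names(differential_regulators(net_d, net_h2)))
})

test_that("sign differences between phenotypes are reported separately", {
  st <- states_tab(c("a", "v"), c(0, 0))
  st$state_healthy <- st$state_disease
  net_d <- prune_network(edge("a", "activation", "v"), st, "disease")
  net_h <- prune_network(edge("a", "inhibition", "v"), st, "healthy")
  ds <- differential_edge_signs(net_d, net_h)
  expect_equal(ds$effects_disease, "activation")
  expect_equal(ds$effects_healthy, "inhibition")
  expect_equal(nrow(differential_edge_signs(net_d, net_d)), 0)
})

test_that("malformed edge tables and unresolved signs are rejected", {
  st <- states_tab(c("u", "v"), c(1, 0))
  expect_error(prune_network(edge("u", "unknown", "v"), st, "disease"),
               "resolve_signs")
  expect_error(filter_categories(data.frame(source = "a", target = "b")),
               "columns")
  expect_error(prune_network(edge("u", "represses", "v"), st, "disease"),
               "invalid effect")
})
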