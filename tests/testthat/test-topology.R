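test_that("embedded networks have the prescribed node and edge counts", {
  net <- generate_embedded_network("TS", order_N = 5, connectivity_x = 4,
                                   seed = 1)
  expect_equal(length(net$nodes), 7L)   # 5 background + 2 motif nodes
  expect_equal(nrow(net$edges), 22L)    # 5*4 random + 2 motif edges

  net2 <- generate_embedded_network("TT", order_N = 5, connectivity_x = 2,
                                    seed = 2)
  expect_equal(length(net2$nodes), 8L)
  expect_equal(nrow(net2$edges), 16L)   # 5*2 + 6

  # edge-count identity across a grid of classes and motifs
  for (nm in c("TS", "TT-SA")) {
    msize <- nrow(build_motif(nm)$edges)
    for (N in c(3, 5, 10)) {
      for (x in c(2, 6)) {
        net <- generate_embedded_network(nm, N, x, seed = N * 100 + x)
        expect_equal(nrow(net$edges), x * N + msize)
      }
    }
  }
})

test_that("generation is reproducible and respects the simple-graph rules", {
  a <- generate_embedded_network("TS", 10, 4, seed = 42)
  b <- generate_embedded_network("TS", 10, 4, seed = 42)
  expect_identical(a$edges, b$edges)

  for (seed in 1:20) {
    net <- generate_embedded_network("TT", 5, 6, seed = seed)
    key <- paste(net$edges$source, net$edges$target)
    expect_false(any(duplicated(key)))                      # one edge per pair
    expect_false(any(net$edges$source == net$edges$target)) # no self-edges
    expect_true(is_connected(net))
  }
  # SA variant keeps exactly the motif's own self-loops
  net <- generate_embedded_network("TS-SA", 5, 2, seed = 3)
  self <- net$edges[net$edges$source == net$edges$target, ]
  expect_setequal(self$source, c("A", "B"))
  expect_true(all(self$sign == 1L))
})

test_that("infeasible edge counts are rejected", {
  # 3 nodes (A, B, n1) leave only 4 free ordered pairs after the TS edges
  expect_error(generate_embedded_network("TS", 1, 5, seed = 1),
               "infeasible")
})

test_that("connectivity is detected on the underlying undirected graph", {
  ts <- build_motif("TS")
  # two disjoint mutually-inhibiting pairs
  disjoint <- structure(list(
    nodes = c("A", "B", "n1", "n2"),
    edges = rbind(ts$edges,
                  data.frame(source = c("n1", "n2"), target = c("n2", "n1"),
                             sign = 2L)),
    order_N = 2L, connectivity_x = 1L, motif = ts),
    class = "network_topology")
  expect_false(is_connected(disjoint))

  # a directed chain covering all nodes
  chain <- structure(list(
    nodes = c("A", "B", "n1", "n2"),
    edges = data.frame(source = c("A", "B", "n1"),
                       target = c("B", "n1", "n2"), sign = 1L),
    order_N = 2L, connectivity_x = 1L, motif = ts),
    class = "network_topology")
  expect_true(is_connected(chain))
})

test_that("in-degree profiles count motif-internal and incoming edges", {
  iso <- motif_topology("TS")
  p <- in_degree_profile(iso)
  expect_equal(c(p$in_A, p$in_B, p$in_motif), c(1L, 1L, 2L))

  # TS with 1 and 5 extra incoming edges: in_A = 2, in_B = 6, in_TS = 8
  ts <- build_motif("TS")
  extra <- data.frame(
    source = paste0("n", 1:6),
    target = c("A", rep("B", 5)),
    sign = rep(c(1L, 2L), 3))
  topo <- structure(list(
    nodes = c("A", "B", paste0("n", 1:6)),
    edges = rbind(ts$edges, extra),
    order_N = 6L, connectivity_x = 1L, motif = ts),
    class = "network_topology")
  p <- in_degree_profile(topo)
  expect_equal(c(p$in_A, p$in_B, p$in_motif), c(2L, 6L, 8L))
  expect_equal(p$in_A_act + p$in_A_inh, p$in_A)
  expect_equal(p$in_B_act + p$in_B_inh, p$in_B)

  p3 <- in_degree_profile(motif_topology("TT"))
  expect_equal(c(p3$in_A, p3$in_B, p3$in_C, p3$in_motif), c(2L, 2L, 2L, 6L))
})

test_that("network batches are unique, connected and seed-deterministic", {
  batch <- generate_network_batch("TS", 5, 2, count = 100, seed = 7)
  expect_length(batch, 100L)
  keys <- vapply(batch, motifResilience:::topology_key, character(1))
  expect_false(any(duplicated(keys)))
  expect_true(all(vapply(batch, is_connected, logical(1))))

  batch2 <- generate_network_batch("TS", 5, 2, count = 100, seed = 7)
  expect_identical(lapply(batch, `[[`, "edges"), lapply(batch2, `[[`, "edges"))

  single <- generate_network_batch("TT", 5, 2, count = 1, seed = 1)
  expect_length(single, 1L)
})

test_that("a tiny graph space is exhausted with an informative error", {
  # N = 1, x = 1: one random edge among the 4 free ordered pairs touching
  # n1, times 2 signs = 8 distinct connected topologies in total
  batch <- generate_network_batch("TS", 1, 1, count = 8, seed = 11,
                                  max_attempts = 5000)
  expect_length(batch, 8L)
  expect_error(
    generate_network_batch("TS", 1, 1, count = 9, seed = 11,
                           max_attempts = 2000),
    "attempts")
})

test_that("random edge signs are balanced (Bernoulli 1/2)", {
  batch <- generate_network_batch("TS", 5, 4, count = 50, seed = 13)
  signs <- unlist(lapply(batch, function(net) {
    e <- net$edges[-(1:2), ]  # drop motif edges
    e$sign
  }))
  frac_act <- mean(signs == 1L)
  expect_length(signs, 50L * 20L)
  expect_gt(frac_act, 0.45)
  expect_lt(frac_act, 0.55)
})

test_that("batch manifests carry class annotations and in-degrees", {
  batch <- generate_network_batch("TT", 5, 2, count = 3, seed = 5)
  man <- batch_manifest(batch)
  expect_equal(nrow(man), 3L)
  expect_true(all(c("network_id", "motif", "order_N", "connectivity_x",
                    "seed", "in_A", "in_B", "in_C", "in_motif") %in%
                    names(man)))
  expect_equal(man$motif, rep("TT", 3))
  expect_true(all(man$in_motif >= 6))  # motif-internal inhibitions included
})
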