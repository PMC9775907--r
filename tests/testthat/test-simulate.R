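test_that("shifted Hill function has its limiting and midpoint values", {
  for (lambda in c(0.01, 0.3, 1, 7, 100)) {
    for (n in 1:6) {
      expect_equal(shifted_hill(0, 10, n, lambda), 1)
      expect_equal(shifted_hill(1e12, 10, n, lambda), lambda,
                   tolerance = 1e-6)
      expect_equal(shifted_hill(10, 10, n, lambda), (1 + lambda) / 2)
    }
  }
  expect_error(shifted_hill(1, 0, 2, 0.5), "positive")
  expect_error(shifted_hill(1, -3, 2, 0.5), "positive")
  expect_error(shifted_hill(-1, 3, 2, 0.5), "non-negative")
})

test_that("shifted Hill output is bounded between 1 and lambda", {
  set.seed(1)
  B <- 10^runif(500, -3, 3)
  for (lambda in c(0.02, 0.7, 5, 60)) {
    h <- shifted_hill(B, B0 = 8, n = 3, lambda = lambda)
    expect_true(all(h >= min(1, lambda) - 1e-12))
    expect_true(all(h <= max(1, lambda) + 1e-12))
    # monotone in B
    ord <- order(B)
    expect_true(all(diff(h[ord]) * sign(lambda - 1) >= -1e-12))
  }
})

test_that("sampled parameters respect the randomization ranges", {
  topo <- generate_embedded_network("TT", 5, 2, seed = 8)
  set.seed(2)
  p <- motifResilience:::sample_params_matrices(topo, 2000)
  expect_true(all(p$G >= 1 & p$G <= 100))
  expect_true(all(p$K >= 0.1 & p$K <= 1))
  expect_true(all(p$HN %in% 1:6))
  act <- p$sign == 1L
  expect_true(all(p$LAM[, act] >= 1 & p$LAM[, act] <= 100))
  expect_true(all(p$LAM[, !act] >= 0.01 & p$LAM[, !act] <= 1))
  expect_true(all(p$B0 > 0))
  # thresholds stay within the half-functional window of the source median
  src_m <- p$median_levels[p$src_idx]
  for (j in seq_along(src_m)) {
    expect_true(all(p$B0[, j] >= 0.02 * src_m[j] &
                      p$B0[, j] <= 1.98 * src_m[j]))
  }
})

test_that("threshold medians of an unregulated node match the G/k median", {
  # single node with no incoming edges: median level is the median of G/k
  lone <- structure(list(
    nodes = "A", edges = data.frame(source = character(0),
                                    target = character(0),
                                    sign = integer(0)),
    order_N = 0L, connectivity_x = 0L, motif = NULL),
    class = "network_topology")
  set.seed(3)
  m <- median_node_levels(lone, n_draws = 2e5)
  set.seed(4)
  oracle <- median(runif(2e5, 1, 100) / runif(2e5, 0.1, 1))
  expect_equal(unname(m), oracle, tolerance = 0.03)
})

test_that("the circuit derivative matches its closed forms", {
  topo <- motif_topology("TS")
  set.seed(5)
  ps <- sample_parameter_set(topo)
  # with B = 0 the inhibitory Hill factor is 1: dA/dt = G_A - k_A * A
  for (A in c(0, 5, 80)) {
    d <- circuit_derivative(c(A = A, B = 0), ps, topo)
    expect_equal(d[1], ps$G[["A"]] - ps$k[["A"]] * A)
  }
  expect_error(circuit_derivative(c(1, 2, 3), ps, topo), "match")

  # an unregulated node has fixed point G/k
  lone <- structure(list(
    nodes = "A", edges = data.frame(source = character(0),
                                    target = character(0),
                                    sign = integer(0)),
    order_N = 0L, connectivity_x = 0L, motif = NULL),
    class = "network_topology")
  set.seed(6)
  psl <- sample_parameter_set(lone)
  expect_equal(circuit_derivative(psl$G / psl$k, psl, lone), 0)
})

test_that("an unregulated node converges to G/k from every start", {
  lone <- structure(list(
    nodes = "A", edges = data.frame(source = character(0),
                                    target = character(0),
                                    sign = integer(0)),
    order_N = 0L, connectivity_x = 0L, motif = NULL),
    class = "network_topology")
  set.seed(7)
  ps <- sample_parameter_set(lone)
  st <- find_steady_states(lone, ps, n_init = 25, seed = 8)
  expect_equal(nrow(st), 1L)
  expect_equal(st$hits, 25L)
  expect_equal(st$A, unname(ps$G / ps$k), tolerance = 1e-4)
})

test_that("steady states reported by the integrator are fixed points", {
  topo <- generate_embedded_network("TT", 5, 2, seed = 12)
  set.seed(13)
  ps <- sample_parameter_set(topo)
  st <- find_steady_states(topo, ps, n_init = 30, seed = 14)
  expect_gte(nrow(st), 1L)
  for (r in seq_len(nrow(st))) {
    state <- as.numeric(st[r, topo$nodes])
    d <- circuit_derivative(state, ps, topo)
    expect_lt(max(abs(d)) / max(state), 1e-4)
  }
})

test_that("integrator state counts match the nullcline oracle", {
  topo <- motif_topology("TS")
  set.seed(20)
  M <- median_node_levels(topo)
  for (i in 1:30) {
    ps <- sample_parameter_set(topo, median_levels = M)
    st <- find_steady_states(topo, ps, n_init = 60, seed = 1000 + i)
    expect_equal(nrow(st), ts_nullcline_count(ps), info = paste("model", i))
  }
})

test_that("symmetric-switch state counts match the oracle over a fold-change sweep", {
  topo <- motif_topology("TS")
  lambdas <- exp(seq(log(0.01), log(1), length.out = 20))
  for (lam in lambdas) {
    ps <- symmetric_ts_params(lam)
    st <- find_steady_states(topo, ps, n_init = 60, seed = 300)
    expect_equal(nrow(st), ts_nullcline_count(ps),
                 info = paste("lambda", signif(lam, 3)))
  }
})

test_that("nearby endpoints are merged by the deduplication tolerance", {
  # strongly bistable symmetric switch: exactly 2 mirror states
  topo <- motif_topology("TS")
  ps <- symmetric_ts_params(0.01)
  st <- find_steady_states(topo, ps, n_init = 80, seed = 21)
  expect_equal(nrow(st), 2L)
  expect_equal(sort(st$A), sort(st$B), tolerance = 1e-3)  # mirror symmetry
  expect_equal(sum(st$hits), 80L)
})

test_that("ensembles are reproducible and keep multiplicity books", {
  topo <- generate_embedded_network("TS", 3, 2, seed = 30)
  e1 <- simulate_ensemble(topo, n_models = 60, n_init = 20, seed = 31)
  e2 <- simulate_ensemble(topo, n_models = 60, n_init = 20, seed = 31)
  expect_identical(e1$states, e2$states)
  expect_identical(e1$model_id, e2$model_id)

  # per-model hit counts never exceed the number of initial conditions
  hits_by_model <- tapply(e1$hits, e1$model_id, sum)
  expect_true(all(hits_by_model <= 20L))
  expect_true(all(e1$multiplicity ==
                    tabulate(e1$model_id, 60)[e1$model_id]))
  expect_gte(nrow(e1$states), 60 - e1$n_empty_models)
})

test_that("trajectories keep non-negative finite states", {
  topo <- generate_embedded_network("TT", 4, 3, seed = 40)
  ens <- simulate_ensemble(topo, n_models = 40, n_init = 10, seed = 41)
  expect_true(all(is.finite(ens$states)))
  expect_true(all(ens$states >= 0))
})
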