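#' Shifted Hill regulation function
#'
#' The regulation multiplier used in the randomized-parameter circuit ODEs:
#' `H(B) = B0^n/(B0^n + B^n) + lambda * B^n/(B0^n + B^n)`. It interpolates
#' monotonically from 1 at `B = 0` (no regulator) to the fold change
#' `lambda` at saturation; `lambda > 1` is activation, `lambda < 1`
#' inhibition.
#'
#' @param B Regulator concentration(s), >= 0.
#' @param B0 Threshold concentration, > 0.
#' @param n Hill coefficient (positive integer).
#' @param lambda Fold change, > 0.
#' @return Regulation multiplier(s), bounded between `min(1, lambda)` and
#'   `max(1, lambda)`.
#' @examples
#' shifted_hill(0, 10, 4, 0.01)    # 1: basal term only
#' shifted_hill(10, 10, 4, 0.01)   # (1 + lambda)/2 at the threshold
#' @export
shifted_hill <- function(B, B0, n, lambda) {
  if (any(B0 <= 0)) stop("threshold B0 must be positive")
  if (any(B < 0)) stop("regulator concentration B must be non-negative")
  if (any(n < 1)) stop("Hill coefficient n must be >= 1")
  if (any(lambda <= 0)) stop("fold change lambda must be positive")
  bn <- B^n
  b0n <- B0^n
  (b0n + lambda * bn) / (b0n + bn)
}

# sampling ranges of the randomized-parameter formalism
.param_ranges <- list(G = c(1, 100), k = c(0.1, 1), n = c(1L, 6L),
                      lambda_act = c(1, 100), lambda_inh_inv = c(1, 100))

#' Median attainable expression level per node (half-functional rule)
#'
#' For each node R, estimates by Monte Carlo the median of its attainable
#' steady-state level `G_R/k_R` multiplied by one shifted-Hill fold factor
#' per incoming edge of R, with each regulator equally likely fully
#' occupying or vacating its target site (factor `lambda` or 1) and
#' `lambda`, `n` drawn from their sampling ranges. Edge thresholds are then
#' drawn uniformly on `[0.02 M, 1.98 M]` of the regulator's median `M`, so
#' that a regulator is above its threshold in about half of the sampled
#' models.
#'
#' @param topology A `network_topology`.
#' @param n_draws Monte-Carlo draws per node.
#' @return Named numeric vector of median levels, one per node.
#' @export
median_node_levels <- function(topology, n_draws = 10000L) {
  r <- .param_ranges
  vapply(topology$nodes, function(nd) {
    lvl <- runif(n_draws, r$G[1], r$G[2]) / runif(n_draws, r$k[1], r$k[2])
    inc <- which(topology$edges$target == nd)
    for (e in inc) {
      lam <- if (topology$edges$sign[e] == 1L) {
        runif(n_draws, r$lambda_act[1], r$lambda_act[2])
      } else {
        1 / runif(n_draws, r$lambda_inh_inv[1], r$lambda_inh_inv[2])
      }
      occupied <- runif(n_draws) < 0.5
      lvl <- lvl * ifelse(occupied, lam, 1)
    }
    stats::median(lvl)
  }, numeric(1))
}

# Vectorized range sampling for a whole ensemble: one row per model.
# Inhibitory fold changes are sampled as 1/U(1,100) so fold-repression is
# distributed symmetrically to fold-activation.
sample_params_matrices <- function(topology, n_models,
                                   median_levels = NULL,
                                   median_draws = 10000L) {
  r <- .param_ranges
  if (is.null(median_levels)) {
    median_levels <- median_node_levels(topology, median_draws)
  }
  n_nodes <- length(topology$nodes)
  e <- topology$edges
  n_edges <- nrow(e)
  src_idx <- match(e$source, topology$nodes)
  G <- matrix(runif(n_models * n_nodes, r$G[1], r$G[2]), n_models)
  K <- matrix(runif(n_models * n_nodes, r$k[1], r$k[2]), n_models)
  HN <- matrix(sample.int(6L, n_models * n_edges, replace = TRUE), n_models)
  LAM <- matrix(NA_real_, n_models, n_edges)
  B0 <- matrix(NA_real_, n_models, n_edges)
  for (j in seq_len(n_edges)) {
    LAM[, j] <- if (e$sign[j] == 1L) {
      runif(n_models, r$lambda_act[1], r$lambda_act[2])
    } else {
      1 / runif(n_models, r$lambda_inh_inv[1], r$lambda_inh_inv[2])
    }
    m_src <- median_levels[src_idx[j]]
    B0[, j] <- runif(n_models, 0.02 * m_src, 1.98 * m_src)
  }
  colnames(G) <- colnames(K) <- topology$nodes
  list(G = G, K = K, HN = HN, LAM = LAM, B0 = B0,
       median_levels = median_levels, sign = e$sign,
       src_idx = src_idx, tgt_idx = match(e$target, topology$nodes))
}

#' Sample one randomized kinetic parameter set for a topology
#'
#' Production and degradation rates are uniform on their ranges (G in
#' \[1, 100\], k in \[0.1, 1\]), Hill coefficients uniform on the integers
#' 1..6, activating fold changes uniform on \[1, 100\], inhibitory fold
#' changes the reciprocal of a uniform \[1, 100\] variate, and each edge
#' threshold follows the half-functional rule (see
#' [median_node_levels()]).
#'
#' @param topology A `network_topology`.
#' @param median_levels Optional precomputed [median_node_levels()] result.
#' @return A `parameter_set`: list with named vectors `G`, `k` (per node)
#'   and a data frame `edges` with per-edge `n`, `lambda`, `threshold`.
#' @export
sample_parameter_set <- function(topology, median_levels = NULL) {
  p <- sample_params_matrices(topology, 1L, median_levels)
  ed <- topology$edges
  structure(list(
    G = stats::setNames(p$G[1, ], topology$nodes),
    k = stats::setNames(p$K[1, ], topology$nodes),
    edges = data.frame(source = ed$source, target = ed$target,
                       sign = ed$sign, n = p$HN[1, ], lambda = p$LAM[1, ],
                       threshold = p$B0[1, ], stringsAsFactors = FALSE)
  ), class = "parameter_set")
}

#' Right-hand side of the circuit ODE system
#'
#' `dT/dt = G_T * prod_i H(P_i) * prod_j H(N_j) - k_T * T` for every node T,
#' with one shifted-Hill factor per incoming edge; nodes with no regulators
#' reduce to `G_T - k_T * T`.
#'
#' @param state Non-negative concentration vector in `topology$nodes` order.
#' @param params A `parameter_set` from [sample_parameter_set()].
#' @param topology The matching `network_topology`.
#' @return Rate-of-change vector, same order as `state`.
#' @export
circuit_derivative <- function(state, params, topology) {
  nodes <- topology$nodes
  if (length(state) != length(nodes)) {
    stop("state length ", length(state), " does not match topology with ",
         length(nodes), " nodes")
  }
  if (is.null(names(state))) names(state) <- nodes
  prod_h <- stats::setNames(rep(1, length(nodes)), nodes)
  ed <- params$edges
  for (j in seq_len(nrow(ed))) {
    h <- shifted_hill(state[[ed$source[j]]], ed$threshold[j], ed$n[j],
                      ed$lambda[j])
    prod_h[ed$target[j]] <- prod_h[ed$target[j]] * h
  }
  unname(params$G * prod_h - params$k * state[nodes])
}

#' Numerical controls of the ensemble integrator
#'
#' @param dt Euler step (time units).
#' @param t_max Integration horizon; trajectories not converged by then are
#'   discarded and counted.
#' @param conv_tol Convergence threshold on the relative max-norm state
#'   change over 10 consecutive steps.
#' @param dedup_tol Relative Euclidean distance below which two endpoints
#'   are the same stable state.
#' @param check_every Steps between convergence checks.
#' @param max_states Cap on distinct states kept per model (most-visited
#'   first); exceeding it is logged.
#' @param median_draws Monte-Carlo depth of the half-functional threshold
#'   rule.
#' @return List of controls for [simulate_ensemble()].
#' @export
sim_control <- function(dt = 0.1, t_max = 1000, conv_tol = 1e-6,
                        dedup_tol = 1e-2, check_every = 10L,
                        max_states = 10L, median_draws = 10000L,
                        keep_unconverged = FALSE) {
  list(dt = dt, t_max = t_max, conv_tol = conv_tol, dedup_tol = dedup_tol,
       check_every = check_every, max_states = max_states,
       median_draws = median_draws,
       keep_unconverged = isTRUE(keep_unconverged))
}

# log-uniform initial conditions spanning each node's reachable range
# [1e-2, G/k * prod(activating lambda)], laid out [traj][node][model]
sample_initial_conditions <- function(p, n_init) {
  n_models <- nrow(p$G)
  n_nodes <- ncol(p$G)
  hi <- p$G / p$K
  for (j in which(p$sign == 1L)) {
    tg <- p$tgt_idx[j]
    hi[, tg] <- hi[, tg] * p$LAM[, j]
  }
  log_lo <- log10(1e-2)
  log_hi <- log10(hi)                      # n_models x n_nodes
  lh <- rep(as.vector(t(log_hi)), each = n_init)
  u <- runif(n_models * n_nodes * n_init)
  10^(log_lo + u * (lh - log_lo))
}

#' Find the stable steady states of one parameterized circuit
#'
#' Integrates the circuit ODEs from `n_init` random log-uniform initial
#' conditions with a fixed-step Euler scheme until the relative state change
#' over ten consecutive steps falls below `conv_tol`; converged endpoints are
#' merged when their relative Euclidean distance is below `dedup_tol`.
#'
#' @param topology A `network_topology`.
#' @param params A `parameter_set` for it.
#' @param n_init Number of initial conditions.
#' @param seed Optional seed for the initial conditions.
#' @param control Numerical controls, see [simulate_ensemble()].
#' @return Data frame of distinct stable states (one column per node) with a
#'   `hits` column counting initial conditions that reached each; attribute
#'   `n_unconverged` counts discarded trajectories.
#' @export
find_steady_states <- function(topology, params, n_init = 100L, seed = NULL,
                               control = sim_control()) {
  stopifnot(inherits(params, "parameter_set"))
  if (!is.null(seed)) set.seed(seed)
  nodes <- topology$nodes
  ed <- params$edges
  p <- list(G = matrix(params$G, 1L), K = matrix(params$k, 1L),
            HN = matrix(as.integer(ed$n), 1L), LAM = matrix(ed$lambda, 1L),
            B0 = matrix(ed$threshold, 1L), sign = ed$sign,
            src_idx = match(ed$source, nodes),
            tgt_idx = match(ed$target, nodes))
  init <- sample_initial_conditions(p, n_init)
  res <- sim_ensemble_cpp(length(nodes), p$src_idx - 1L, p$tgt_idx - 1L,
                          p$G, p$K, p$HN, p$LAM, p$B0, init, n_init,
                          control$dt, control$t_max, control$conv_tol,
                          control$dedup_tol, control$check_every,
                          control$max_states,
                          isTRUE(control$keep_unconverged))
  states <- as.data.frame(res$states)
  names(states) <- nodes
  states$hits <- res$hits
  attr(states, "n_unconverged") <- res$n_unconverged
  states
}

#' Simulate a randomized-parameter circuit ensemble for one topology
#'
#' The core of the randomized circuit perturbation (RACIPE) formalism:
#' samples `n_models` kinetic parameter sets from the standard randomization ranges
#' (production rate uniform on \[1, 100\], degradation uniform on
#' \[0.1, 1\], integer Hill coefficients 1..6, activating fold change
#' uniform on \[1, 100\], inhibitory fold change reciprocal-uniform on
#' \[0.01, 1\], thresholds by the half-functional rule), integrates each
#' from `n_init` random initial conditions, and pools the distinct stable
#' steady states of every model into one table.
#'
#' @param topology A `network_topology`.
#' @param n_models Number of randomized parameter sets.
#' @param n_init Initial conditions per parameter set.
#' @param seed Integer seed making the whole ensemble reproducible.
#' @param control Numerical controls from `sim_control()`: Euler step `dt`
#'   (0.1), horizon `t_max` (1000 time units), convergence tolerance
#'   `conv_tol` (1e-6 relative change over 10 steps), state deduplication
#'   tolerance `dedup_tol` (1e-2 relative Euclidean distance), and the
#'   Monte-Carlo depth of the half-functional rule.
#' @return A `racipe_ensemble`: list with `states` (matrix of stable states,
#'   one column per node), `model_id` (parameter set of each row),
#'   `multiplicity` (number of distinct states of that model), `hits`
#'   (initial conditions reaching each state), the sampled parameter
#'   matrices in `params`, and bookkeeping (`n_unconverged`,
#'   `n_truncated_models`, `seed`, `control`).
#' @examples
#' ts <- generate_embedded_network("TS", 1, 1, seed = 1)
#' ens <- simulate_ensemble(ts, n_models = 10, n_init = 5, seed = 42)
#' summary(ens)
#' @export
simulate_ensemble <- function(topology, n_models = 10000L, n_init = 100L,
                              seed = NULL, control = sim_control()) {
  stopifnot(inherits(topology, "network_topology"), n_models >= 1,
            n_init >= 1)
  if (!is.null(seed)) set.seed(seed)
  nodes <- topology$nodes
  p <- sample_params_matrices(topology, n_models,
                              median_draws = control$median_draws)
  init <- sample_initial_conditions(p, n_init)
  res <- sim_ensemble_cpp(length(nodes), p$src_idx - 1L, p$tgt_idx - 1L,
                          p$G, p$K, p$HN, p$LAM, p$B0, init, n_init,
                          control$dt, control$t_max, control$conv_tol,
                          control$dedup_tol, control$check_every,
                          control$max_states,
                          isTRUE(control$keep_unconverged))
  states <- res$states
  colnames(states) <- nodes
  model_id <- res$model_id
  mult <- tabulate(model_id, nbins = n_models)
  structure(list(
    topology = topology,
    states = states,
    model_id = model_id,
    multiplicity = mult[model_id],
    hits = res$hits,
    params = p[c("G", "K", "HN", "LAM", "B0", "median_levels")],
    n_models = n_models,
    n_init = n_init,
    n_unconverged = res$n_unconverged,
    n_truncated_models = res$n_truncated_models,
    n_empty_models = sum(mult == 0L),
    seed = seed,
    control = control
  ), class = "racipe_ensemble")
}

#' @export
print.racipe_ensemble <- function(x, ...) {
  cat(sprintf("Randomized circuit ensemble: %d nodes, %d models x %d inits\n",
              ncol(x$states), x$n_models, x$n_init))
  cat(sprintf("  %d pooled stable states; %d non-converged trajectories\n",
              nrow(x$states), x$n_unconverged))
  invisible(x)
}

#' @export
summary.racipe_ensemble <- function(object, ...) {
  mult <- tabulate(object$model_id, nbins = object$n_models)
  tab <- table(factor(mult, levels = 0:max(1, max(mult))))
  cat(sprintf("Ensemble of %d models (%d initial conditions each)\n",
              object$n_models, object$n_init))
  cat("Models by number of distinct stable states:\n")
  print(tab)
  cat(sprintf("Non-converged trajectories: %d; truncated models: %d\n",
              object$n_unconverged, object$n_truncated_models))
  invisible(tab)
}
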