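#' Define an experiment plan over network classes
#'
#' A plan enumerates the network classes (order x mean-connectivity
#' combinations), the number of random networks per class, the replicate
#' count, and the per-network ensemble depth. The full design for a plain
#' motif is 12 classes (orders 5, 10, 15, 20 x connectivities E:2N, E:4N,
#' E:6N) of 100 networks simulated in triplicate with 10,000 parameter sets
#' x 100 initial conditions; the self-regulation variants use the 4 classes
#' (5N, 20N) x (E:2N, E:6N). The `"scaled_down"` preset (40 networks/class,
#' 1,000 parameter sets x 20 initial conditions, one replicate) preserves
#' the rank-correlation structure at desk scale.
#'
#' @param motif Motif name or `motif_spec`.
#' @param orders,connectivities Network orders N and connectivity
#'   multipliers x defining the classes.
#' @param n_networks Networks per class.
#' @param replicates Simulation replicates per network (fresh parameter
#'   seeds each).
#' @param n_models,n_init Ensemble depth per network and replicate.
#' @param seed Master seed; every other seed is derived from it.
#' @param preset `NULL`, `"full"`, or `"scaled_down"`.
#' @param control Integrator controls ([sim_control()]); the scaled-down
#'   preset shortens the integration horizon to 200 time units (the
#'   stand-alone statistics are indistinguishable from the 1000-unit
#'   horizon, and slow non-converging trajectories dominate runtime on
#'   dense embedded networks).
#' @return An `experiment_plan` object.
#' @export
experiment_plan <- function(motif, orders = c(5, 10, 15, 20),
                            connectivities = c(2, 4, 6),
                            n_networks = 100L, replicates = 3L,
                            n_models = 10000L, n_init = 100L, seed = 1L,
                            preset = NULL, control = NULL) {
  if (is.character(motif)) motif <- build_motif(motif)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "scaled_down"))
    if (preset == "scaled_down") {
      n_networks <- 40L
      replicates <- 1L
      n_models <- 1000L
      n_init <- 20L
      if (is.null(control)) control <- sim_control(t_max = 200)
    }
  }
  if (is.null(control)) control <- sim_control()
  classes <- expand.grid(order_N = orders, connectivity_x = connectivities)
  classes <- classes[order(classes$order_N, classes$connectivity_x), ]
  rownames(classes) <- NULL
  structure(list(motif = motif, classes = classes,
                 n_networks = as.integer(n_networks),
                 replicates = as.integer(replicates),
                 n_models = as.integer(n_models),
                 n_init = as.integer(n_init),
                 seed = as.integer(seed), preset = preset,
                 control = control),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf(
    "Experiment plan: motif %s, %d classes x %d networks x %d replicate(s)\n",
    x$motif$name, nrow(x$classes), x$n_networks, x$replicates))
  cat(sprintf("  ensemble depth %d models x %d inits, master seed %d\n",
              x$n_models, x$n_init, x$seed))
  invisible(x)
}

#' Run an experiment plan: generate, simulate and score every network
#'
#' For every class in the plan, generates a batch of unique connected
#' networks, simulates each with a fresh parameter seed per replicate,
#' binarizes the pooled steady states, and computes the per-network metric
#' record together with its in-degree profile. Per-network failures are
#' logged and skipped, never aborting the batch.
#'
#' @param plan An [experiment_plan()].
#' @param cache_dir Optional directory for per-network result caching keyed
#'   by seed; reruns with identical seeds reuse cached records.
#' @param progress Print one line per class as it completes.
#' @param ... Passed on to [motif_metrics()] (e.g. `state_scale = "log2"`
#'   for motifs with self-regulation loops, whose expression levels span
#'   decades).
#' @return Data frame of metric records (one row per network x replicate)
#'   with class annotations, seeds and in-degree columns; the number of
#'   failed simulations is carried in attribute `"n_failed"`.
#' @export
run_experiment <- function(plan, cache_dir = NULL, progress = FALSE, ...) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE)
  }
  set.seed(plan$seed)
  class_seeds <- sample.int(.Machine$integer.max, nrow(plan$classes))
  rows <- list()
  n_failed <- 0L
  for (ci in seq_len(nrow(plan$classes))) {
    ord <- plan$classes$order_N[ci]
    conn <- plan$classes$connectivity_x[ci]
    set.seed(class_seeds[ci])
    batch_seed <- sample.int(.Machine$integer.max, 1L)
    sim_seeds <- matrix(sample.int(.Machine$integer.max,
                                   plan$n_networks * plan$replicates),
                        nrow = plan$n_networks)
    batch <- generate_network_batch(plan$motif, ord, conn, plan$n_networks,
                                    seed = batch_seed)
    t0 <- proc.time()[["elapsed"]]
    for (ni in seq_along(batch)) {
      topo <- batch[[ni]]
      prof <- in_degree_profile(topo)
      for (ri in seq_len(plan$replicates)) {
        sseed <- sim_seeds[ni, ri]
        key <- sprintf("%s_N%d_x%d_net%03d_rep%d_%d_%d_seed%d.rds",
                       plan$motif$name, ord, conn, ni, ri,
                       plan$n_models, plan$n_init, sseed)
        rec <- NULL
        if (!is.null(cache_dir) && file.exists(file.path(cache_dir, key))) {
          rec <- readRDS(file.path(cache_dir, key))
        } else {
          rec <- tryCatch({
            ens <- simulate_ensemble(topo, plan$n_models, plan$n_init,
                                     seed = sseed, control = plan$control)
            cbind(data.frame(motif = plan$motif$name, order_N = ord,
                             connectivity_x = conn, network_id = ni,
                             replicate = ri, sim_seed = sseed,
                             topo_seed = attr(topo, "seed")),
                  prof, motif_metrics(ens, ...))
          }, error = function(e) {
            warning(sprintf("network %d (N=%d, x=%d, rep %d) failed: %s",
                            ni, ord, conn, ri, conditionMessage(e)),
                    call. = FALSE)
            NULL
          })
          if (!is.null(rec) && !is.null(cache_dir)) {
            saveRDS(rec, file.path(cache_dir, key))
          }
        }
        if (is.null(rec)) n_failed <- n_failed + 1L else
          rows[[length(rows) + 1L]] <- rec
      }
    }
    if (progress) {
      message(sprintf("class N=%d E:%dN done in %.1fs", ord, conn,
                      proc.time()[["elapsed"]] - t0))
    }
  }
  out <- rbind_fill(rows)
  attr(out, "n_failed") <- n_failed
  out
}

signif_category <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 1e-2, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

#' Pairwise Mann-Whitney U comparisons of a metric between groups
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) tests for every pair of
#' groups, with the usual significance categories (`ns`, `*` for
#' 0.01 < p <= 0.05, `**` for 0.001 < p <= 0.01, `***` for
#' 0.0001 < p <= 0.001, `****` for p <= 0.0001). P-values are reported raw,
#' without multiplicity correction.
#'
#' @param records Metric record data frame.
#' @param metric Name of the metric column to compare.
#' @param group_by Name of the grouping column (e.g. `"order_N"` or
#'   `"connectivity_x"`).
#' @return Data frame with columns `group1`, `group2`, `p_value`,
#'   `category`.
#' @export
compare_groups <- function(records, metric, group_by) {
  stopifnot(metric %in% names(records), group_by %in% names(records))
  g <- split(records[[metric]], records[[group_by]])
  g <- lapply(g, function(v) v[is.finite(v)])
  if (length(g) < 2L) stop("need at least 2 groups")
  if (any(vapply(g, length, 0L) < 2L)) stop("each group needs >= 2 records")
  nm <- names(g)
  pairs <- utils::combn(length(g), 2)
  out <- data.frame(group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
                    p_value = NA_real_, category = NA_character_)
  for (j in seq_len(ncol(pairs))) {
    p <- suppressWarnings(stats::wilcox.test(g[[pairs[1, j]]],
                                             g[[pairs[2, j]]],
                                             exact = FALSE)$p.value)
    out$p_value[j] <- p
    out$category[j] <- signif_category(p)
  }
  out
}

# append normalized in-degree descriptors (triads): in_X/in_motif and
# pairwise in_XY/in_motif
with_normalized_indegree <- function(records) {
  nds <- intersect(c("A", "B", "C"),
                   sub("^in_", "", grep("^in_[ABC]$", names(records),
                                        value = TRUE)))
  for (nd in nds) {
    records[[paste0("in_", nd, "_frac")]] <-
      records[[paste0("in_", nd)]] / records$in_motif
  }
  if (length(nds) == 3L) {
    prs <- utils::combn(nds, 2)
    for (j in seq_len(ncol(prs))) {
      records[[paste0("in_", prs[1, j], prs[2, j], "_frac")]] <-
        (records[[paste0("in_", prs[1, j])]] +
           records[[paste0("in_", prs[2, j])]]) / records$in_motif
    }
  }
  records
}

#' Spearman correlations of resilience metrics with in-degree descriptors
#'
#' The meta-analysis across network orders and mean connectivities: for
#' every (in-degree descriptor, metric) pair, the Spearman rho and its
#' p-value over all network records. Descriptors cover the raw in-degrees
#' (`in_A`, ..., `in_motif`) and, when requested, the normalized forms
#' `in_X/in_motif` and `in_XY/in_motif`.
#'
#' @param records Metric record data frame (>= 10 rows).
#' @param metrics Metric column names; defaults to the metric columns
#'   present.
#' @param normalized Also include normalized in-degree descriptors.
#' @return List with matrices `rho` and `p` (descriptors x metrics);
#'   entries for constant columns are `NA`.
#' @export
indegree_metric_correlations <- function(records, metrics = NULL,
                                         normalized = FALSE) {
  if (nrow(records) < 10L) stop("need at least 10 records")
  if (normalized) records <- with_normalized_indegree(records)
  descriptors <- grep("^in_([ABC]|motif|[ABC]+_frac)$", names(records),
                      value = TRUE)
  if (is.null(metrics)) {
    metrics <- intersect(c("BiC_A", "BiC_B", "BiC_C", "CC_AB", "CC_AC",
                           "CC_BC", "MaxCC", "MinCC", "F1", "F2", "F3",
                           "F1_over_F2", "B_to_M", "ACoeff", "BCoeff", "R2"),
                         names(records))
  }
  rho <- p <- matrix(NA_real_, length(descriptors), length(metrics),
                     dimnames = list(descriptors, metrics))
  for (d in descriptors) {
    for (m in metrics) {
      ok <- is.finite(records[[d]]) & is.finite(records[[m]])
      if (sum(ok) < 3L) next
      x <- records[[d]][ok]
      y <- records[[m]][ok]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) next
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      rho[d, m] <- unname(ct$estimate)
      p[d, m] <- ct$p.value
    }
  }
  list(rho = rho, p = p)
}

#' Mean metrics per in-degree bin and in-degree asymmetry table
#'
#' Bins network records by the in-degree pair of the two switch nodes and
#' averages each metric per cell (the heatmap data), and tabulates the
#' asymmetry analysis: `log2(in_A/in_B)` against `log2(BiC_A/BiC_B)` and
#' `CC_AB` per record.
#'
#' @param records Metric record data frame with `in_A`, `in_B` columns.
#' @param metrics Metric columns to average; defaults to those present.
#' @return List with `bins` (one row per non-empty `(in_A, in_B)` cell:
#'   mean metrics and `n_records`) and `asymmetry` (per-record log-ratios).
#' @export
indegree_bin_summary <- function(records, metrics = NULL) {
  stopifnot(all(c("in_A", "in_B") %in% names(records)))
  if (is.null(metrics)) {
    metrics <- intersect(c("CC_AB", "BiC_A", "BiC_B", "F1", "B_to_M"),
                         names(records))
  }
  key <- interaction(records$in_A, records$in_B, drop = TRUE)
  bins <- do.call(rbind, lapply(split(records, key), function(d) {
    cell <- data.frame(in_A = d$in_A[1], in_B = d$in_B[1],
                       n_records = nrow(d))
    for (m in metrics) cell[[paste0("mean_", m)]] <-
        mean(d[[m]], na.rm = TRUE)
    cell
  }))
  rownames(bins) <- NULL
  bins <- bins[order(bins$in_A, bins$in_B), ]
  asym <- data.frame(log2_inA_inB = log2(records$in_A / records$in_B),
                     CC_AB = records$CC_AB)
  if (all(c("BiC_A", "BiC_B") %in% names(records))) {
    asym$log2_BiCA_BiCB <- log2(records$BiC_A / records$BiC_B)
  }
  list(bins = bins, asymmetry = asym)
}

#' Random non-motif node control metrics
#'
#' Recomputes the motif metrics on a uniformly chosen set of background
#' (non-motif) nodes of the same size as the motif, as a specificity
#' control: the metric distributions of the actual motif nodes should
#' differ from those of arbitrary nodes of the same networks.
#'
#' @param ensemble A `racipe_ensemble` whose topology has at least as many
#'   background nodes as the motif has nodes.
#' @param seed Optional seed for the node choice.
#' @return One-row data frame of metrics over the chosen nodes, with
#'   columns `control = TRUE` and `control_nodes`.
#' @export
random_node_control <- function(ensemble, seed = NULL) {
  stopifnot(inherits(ensemble, "racipe_ensemble"))
  if (!is.null(seed)) set.seed(seed)
  topo <- ensemble$topology
  k <- length(topo$motif$nodes)
  background <- setdiff(topo$nodes, topo$motif$nodes)
  if (length(background) < k) {
    stop("need at least ", k, " background nodes for the control")
  }
  pick <- sample(background, k)
  rec <- motif_metrics(ensemble, nodes = pick)
  rec$control <- TRUE
  rec$control_nodes <- paste(pick, collapse = ",")
  rec
}
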