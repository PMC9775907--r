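#' Generate a random directed signed network with an embedded motif
#'
#' Builds a network of `order_N` background nodes plus the motif nodes, adds
#' the motif edges, and then places `connectivity_x * order_N` random signed
#' edges uniformly over the remaining ordered node pairs (no self-edges
#' outside the motif's own self-loops, at most one edge per ordered pair).
#' Random edges may source or target motif nodes, which is what makes the
#' motif in-degree vary across networks. Each random edge is activating or
#' inhibiting with probability 1/2. Networks whose underlying undirected
#' graph is disconnected are discarded and regenerated.
#'
#' @param motif A `motif_spec` from [build_motif()], or a motif name.
#' @param order_N Number of background nodes (network order), >= 1.
#' @param connectivity_x Mean-connectivity multiplier: `connectivity_x *
#'   order_N` random edges are added (the E:xN convention).
#' @param seed Optional integer seed for reproducibility.
#' @param max_attempts Regeneration cap before giving up on connectivity.
#' @return An object of class `network_topology`: list with `nodes` (motif
#'   nodes first, then `n1..nN`), `edges` (data frame `source`, `target`,
#'   `sign` with 1 = activation, 2 = inhibition), `order_N`,
#'   `connectivity_x`, `motif`.
#' @examples
#' net <- generate_embedded_network("TS", order_N = 5, connectivity_x = 4,
#'                                  seed = 1)
#' nrow(net$edges)  # 5*4 random + 2 motif edges = 22
#' @export
generate_embedded_network <- function(motif, order_N, connectivity_x,
                                      seed = NULL, max_attempts = 10000L) {
  if (is.character(motif)) motif <- build_motif(motif)
  stopifnot(inherits(motif, "motif_spec"))
  if (order_N < 1 || connectivity_x < 1) {
    stop("order_N and connectivity_x must be positive integers")
  }
  if (!is.null(seed)) set.seed(seed)
  nodes <- c(motif$nodes, paste0("n", seq_len(order_N)))
  n_total <- length(nodes)
  n_random <- as.integer(connectivity_x * order_N)

  # candidate ordered pairs: all non-self pairs not already a motif edge
  cand <- expand.grid(source = nodes, target = nodes,
                      stringsAsFactors = FALSE)
  cand <- cand[cand$source != cand$target, , drop = FALSE]
  motif_keys <- paste(motif$edges$source, motif$edges$target)
  cand <- cand[!(paste(cand$source, cand$target) %in% motif_keys), ,
               drop = FALSE]
  if (n_random > nrow(cand)) {
    stop("infeasible edge count: ", n_random, " random edges requested but ",
         nrow(cand), " free ordered pairs available")
  }

  for (attempt in seq_len(max_attempts)) {
    pick <- sample.int(nrow(cand), n_random)
    rand_edges <- data.frame(source = cand$source[pick],
                             target = cand$target[pick],
                             sign = sample(c(1L, 2L), n_random, replace = TRUE),
                             stringsAsFactors = FALSE)
    edges <- rbind(motif$edges, rand_edges)
    rownames(edges) <- NULL
    topo <- structure(list(nodes = nodes, edges = edges, order_N = order_N,
                           connectivity_x = connectivity_x, motif = motif),
                      class = "network_topology")
    if (is_connected(topo)) return(topo)
  }
  stop("no connected network found after ", max_attempts, " attempts")
}

#' Test whether a network's underlying undirected graph is connected
#'
#' @param topology A `network_topology`.
#' @return `TRUE` iff every node is reachable from every other node when edge
#'   directions are ignored.
#' @export
is_connected <- function(topology) {
  stopifnot(inherits(topology, "network_topology"))
  if (length(topology$nodes) < 1L) stop("topology has no nodes")
  g <- igraph::graph_from_data_frame(topology$edges[, c("source", "target")],
                                     directed = TRUE,
                                     vertices = topology$nodes)
  igraph::is_connected(g, mode = "weak")
}

#' In-degree profile of the embedded motif
#'
#' Counts all incoming edges on each motif node, including the motif-internal
#' ones (an isolated toggle switch therefore has `in_A = in_B = 1`), split by
#' edge sign, plus their sum over motif nodes (`in_motif`).
#'
#' @param topology A `network_topology` with an embedded motif.
#' @return One-row data frame with columns `in_A`, `in_B` (`in_C` for
#'   triads), activating/inhibiting splits `in_A_act`, `in_A_inh`, ..., and
#'   `in_motif`.
#' @export
in_degree_profile <- function(topology) {
  stopifnot(inherits(topology, "network_topology"))
  motif <- topology$motif
  if (is.null(motif)) stop("topology carries no motif specification")
  edges <- topology$edges
  out <- list()
  for (nd in motif$nodes) {
    inc <- edges$target == nd
    out[[paste0("in_", nd)]] <- sum(inc)
    out[[paste0("in_", nd, "_act")]] <- sum(inc & edges$sign == 1L)
    out[[paste0("in_", nd, "_inh")]] <- sum(inc & edges$sign == 2L)
  }
  out$in_motif <- sum(edges$target %in% motif$nodes)
  as.data.frame(out)
}

#' Stand-alone motif as a simulatable topology
#'
#' Wraps a bare motif (no background nodes, no random edges) as a
#' `network_topology`, for simulating the isolated toggle switch or triad.
#'
#' @param motif Motif name or `motif_spec`.
#' @return A `network_topology` with `order_N = 0`.
#' @examples
#' motif_topology("TS")
#' @export
motif_topology <- function(motif) {
  if (is.character(motif)) motif <- build_motif(motif)
  stopifnot(inherits(motif, "motif_spec"))
  structure(list(nodes = motif$nodes, edges = motif$edges, order_N = 0L,
                 connectivity_x = 0L, motif = motif),
            class = "network_topology")
}

topology_key <- function(topology) {
  e <- topology$edges
  paste(sort(paste(e$source, e$target, e$sign, sep = ">")), collapse = ";")
}

#' Generate a batch of unique connected embedded networks
#'
#' Draws `count` networks with [generate_embedded_network()]; duplicates
#' (identical signed edge sets) are discarded and regenerated, mirroring the
#' replacement rule used when building network ensembles.
#'
#' @inheritParams generate_embedded_network
#' @param count Number of pairwise distinct networks required.
#' @param seed Optional master seed; per-network seeds are derived from it.
#' @param max_attempts Total generation attempts before giving up (for tiny
#'   graph spaces that cannot host `count` distinct topologies).
#' @return List of `network_topology` objects of length `count`; each carries
#'   its derived seed as attribute `"seed"`.
#' @export
generate_network_batch <- function(motif, order_N, connectivity_x, count,
                                   seed = NULL, max_attempts = 10000L) {
  if (count < 1) stop("count must be >= 1")
  if (is.character(motif)) motif <- build_motif(motif)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", count)
  seen <- character(0)
  got <- 0L
  for (attempt in seq_len(max_attempts)) {
    sub_seed <- sample.int(.Machine$integer.max, 1L)
    topo <- generate_embedded_network(motif, order_N, connectivity_x,
                                      seed = sub_seed)
    key <- topology_key(topo)
    if (key %in% seen) next
    seen <- c(seen, key)
    got <- got + 1L
    attr(topo, "seed") <- sub_seed
    out[[got]] <- topo
    if (got == count) return(out)
  }
  stop("could not generate ", count, " distinct networks within ",
       max_attempts, " attempts (", got, " found)")
}

#' @export
print.network_topology <- function(x, ...) {
  cat("Random network:", length(x$nodes), "nodes,", nrow(x$edges), "edges",
      sprintf("(motif %s, order %dN, connectivity E:%dN)\n",
              if (is.null(x$motif)) "none" else x$motif$name,
              x$order_N, x$connectivity_x))
  invisible(x)
}

#' Batch manifest for a list of generated networks
#'
#' @param batch List of `network_topology` objects (e.g. from
#'   [generate_network_batch()]).
#' @return Data frame with one row per network: `network_id`, `motif`,
#'   `order_N`, `connectivity_x`, `seed`, and the in-degree profile columns.
#' @export
batch_manifest <- function(batch) {
  rows <- lapply(seq_along(batch), function(i) {
    topo <- batch[[i]]
    prof <- in_degree_profile(topo)
    base <- data.frame(network_id = i, motif = topo$motif$name,
                       order_N = topo$order_N,
                       connectivity_x = topo$connectivity_x,
                       seed = if (is.null(attr(topo, "seed"))) NA_integer_
                              else attr(topo, "seed"))
    cbind(base, prof)
  })
  rbind_fill(rows)
}

# rbind a list of data frames, padding missing columns with NA
# (TS profiles have no in_C columns; TT profiles do)
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  dfs <- lapply(dfs, function(d) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA
    d[, cols, drop = FALSE]
  })
  do.call(rbind, dfs)
}
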