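#' Normalize a steady-state level by its node's kinetic scale
#'
#' Divides a steady-state concentration by the node's unregulated level
#' `G/k`, i.e. returns `S * k / G`, making levels comparable across
#' randomized parameter sets.
#'
#' @param S Steady-state concentration(s), >= 0.
#' @param G Production rate(s), > 0.
#' @param k Degradation rate(s), > 0.
#' @return Dimensionless normalized level(s).
#' @examples
#' normalize_steady_state(50, 100, 0.5)  # 0.25
#' @export
normalize_steady_state <- function(S, G, k) {
  if (any(G <= 0) || any(k <= 0)) {
    stop("production and degradation rates must be positive")
  }
  S * k / G
}

#' Normalized steady-state matrix of an ensemble
#'
#' Applies [normalize_steady_state()] row-wise, using each row's own model
#' parameters.
#'
#' @param ensemble A `racipe_ensemble`.
#' @return Matrix of normalized levels, same shape as `ensemble$states`.
#' @export
normalized_states <- function(ensemble) {
  stopifnot(inherits(ensemble, "racipe_ensemble"))
  idx <- ensemble$model_id
  ensemble$states * ensemble$params$K[idx, , drop = FALSE] /
    ensemble$params$G[idx, , drop = FALSE]
}

#' Z-score and binarize pooled steady states into ON/OFF strings
#'
#' Z-scores each node's column across all pooled steady-state rows of one
#' network's ensemble, then thresholds at zero: a node with z-score above
#' zero is ON (1), otherwise OFF (0). The motif-state string concatenates
#' the motif nodes' bits in A, B(, C) order.
#'
#' @param norm Matrix of (normalized) steady-state levels with node-named
#'   columns; typically [normalized_states()] output.
#' @param motif_nodes Character vector of motif node labels (columns of
#'   `norm` to assemble into the state string), in order.
#' @param log2_transform If `TRUE`, z-score `log2(norm)` instead of `norm`
#'   (an upstream convention some pipelines use); default `FALSE`, i.e.
#'   z-scores of the normalized values themselves.
#' @return A `binarized_states` object: list with `z` (z-score matrix over
#'   all columns), `bits` (0/1 matrix), `state` (character vector of motif
#'   state strings), `motif_nodes`, and the per-node `center`/`scale` used.
#' @examples
#' m <- rbind(c(2, 0), c(0, 2))
#' colnames(m) <- c("A", "B")
#' zscore_binarize(m, c("A", "B"))$state  # "10" "01"
#' @export
zscore_binarize <- function(norm, motif_nodes, log2_transform = FALSE) {
  norm <- as.matrix(norm)
  if (nrow(norm) < 2L) stop("need at least 2 pooled steady-state rows")
  if (!all(motif_nodes %in% colnames(norm))) {
    stop("motif nodes missing from state table: ",
         paste(setdiff(motif_nodes, colnames(norm)), collapse = ","))
  }
  x <- if (log2_transform) log2(pmax(norm, .Machine$double.xmin)) else norm
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  if (any(scl == 0)) {
    stop("zero variance in node(s): ",
         paste(colnames(x)[scl == 0], collapse = ","))
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  bits <- (z > 0) + 0L
  state <- apply(bits[, motif_nodes, drop = FALSE], 1, paste, collapse = "")
  structure(list(z = z, bits = bits, state = as.character(state),
                 motif_nodes = motif_nodes, center = ctr, scale = scl,
                 log2_transform = log2_transform),
            class = "binarized_states")
}

#' @export
print.binarized_states <- function(x, ...) {
  cat("Binarized steady states:", length(x$state), "rows over motif nodes",
      paste(x$motif_nodes, collapse = ","), "\n")
  print(utils::head(sort(table(x$state), decreasing = TRUE)))
  invisible(x)
}
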