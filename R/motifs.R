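#' Build a mutually repressing motif specification
#'
#' Constructs the edge set of a toggle switch (TS), a toggle triad (TT), or
#' one of their self-regulation variants. A toggle switch is two nodes A and
#' B that mutually inhibit each other; a toggle triad is three nodes A, B and
#' C with all six ordered inter-node inhibitions. The `-SA` variants add one
#' self-activation loop on every motif node, the `-SI` variants one
#' self-inhibition loop.
#'
#' @param name One of `"TS"`, `"TT"`, `"TS-SA"`, `"TS-SI"`, `"TT-SA"`,
#'   `"TT-SI"`.
#' @return An object of class `motif_spec`: a list with elements `name`,
#'   `nodes` (ordered node labels) and `edges` (a data frame with columns
#'   `source`, `target`, `sign`, where `sign` is `1` for activation and `2`
#'   for inhibition, the RACIPE `.topo` convention).
#' @examples
#' build_motif("TS")
#' build_motif("TT-SA")
#' @export
build_motif <- function(name) {
  choices <- c("TS", "TT", "TS-SA", "TS-SI", "TT-SA", "TT-SI")
  if (!is.character(name) || length(name) != 1L || !(name %in% choices)) {
    stop("unknown motif name; must be one of: ", paste(choices, collapse = ", "))
  }
  base <- sub("-S[AI]$", "", name)
  nodes <- if (base == "TS") c("A", "B") else c("A", "B", "C")
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  edges <- data.frame(source = pairs$source, target = pairs$target,
                      sign = 2L, stringsAsFactors = FALSE)
  if (grepl("-SA$", name)) {
    edges <- rbind(edges, data.frame(source = nodes, target = nodes, sign = 1L))
  } else if (grepl("-SI$", name)) {
    edges <- rbind(edges, data.frame(source = nodes, target = nodes, sign = 2L))
  }
  rownames(edges) <- NULL
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "motif_spec")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("Motif", x$name, "with", length(x$nodes), "nodes and",
      nrow(x$edges), "edges\n")
  invisible(x)
}

motif_size <- function(motif) length(motif$nodes)
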