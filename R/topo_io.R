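#' Write a topology in RACIPE `.topo` format
#'
#' One header line `Source Target Type`, then one whitespace-separated edge
#' per line with Type 1 = activation, 2 = inhibition.
#'
#' @param topology A `network_topology`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topo <- function(topology, path) {
  stopifnot(inherits(topology, "network_topology"))
  e <- topology$edges
  lines <- c("Source Target Type",
             paste(e$source, e$target, e$sign))
  writeLines(lines, path)
  invisible(path)
}

#' Read a RACIPE `.topo` file
#'
#' @param path Path to a `.topo` file.
#' @param motif Optional `motif_spec` (or motif name) identifying the
#'   embedded motif; required downstream by the motif metrics. Motif node
#'   labels must be present in the file.
#' @param order_N,connectivity_x Optional class annotations to carry along.
#' @return A `network_topology`.
#' @export
read_topo <- function(path, motif = NULL, order_N = NA_integer_,
                      connectivity_x = NA_integer_) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L || trimws(lines[1]) != "Source Target Type") {
    stop("not a .topo file: first line must be 'Source Target Type'")
  }
  body <- lines[-1]
  edges <- data.frame(source = character(0), target = character(0),
                      sign = integer(0), stringsAsFactors = FALSE)
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(tok) != 3L) {
      stop("malformed .topo line ", i + 1L, ": expected 3 fields, got ",
           length(tok))
    }
    ty <- suppressWarnings(as.integer(tok[3]))
    if (is.na(ty) || !(ty %in% c(1L, 2L))) {
      stop("malformed .topo line ", i + 1L, ": Type must be 1 or 2, got '",
           tok[3], "'")
    }
    edges[i, ] <- list(tok[1], tok[2], ty)
  }
  if (is.character(motif)) motif <- build_motif(motif)
  node_first <- unique(c(edges$source, edges$target))
  if (!is.null(motif)) {
    if (!all(motif$nodes %in% node_first)) {
      stop("motif nodes ", paste(motif$nodes, collapse = ","),
           " not all present in file")
    }
    nodes <- c(motif$nodes, sort(setdiff(node_first, motif$nodes)))
  } else {
    nodes <- node_first
  }
  structure(list(nodes = nodes, edges = edges, order_N = order_N,
                 connectivity_x = connectivity_x, motif = motif),
            class = "network_topology")
}
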