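#' Build the interaction-radius graph of a C-alpha chain
#'
#' Nodes sit at the C-alpha positions; every unordered residue pair whose
#' Euclidean distance is strictly less than the interaction radius `R_C`
#' becomes a link. Each link carries its length `l_ij` (Angstrom) and the
#' cross-sectional area between the two interaction spheres,
#' `A_ij = pi * (R_C^2 - l_ij^2 / 4)` (Angstrom^2), which is positive for
#' every admitted pair. Coincident nodes are rejected as malformed input.
#'
#' @param chain a [calpha_chain()].
#' @param r_c interaction radius in Angstrom (> 0). Values just above the
#'   3.8 Angstrom backbone spacing give a sparse chain-like network; beyond
#'   the structure's diameter every pair is linked and the impedance
#'   saturates.
#' @return A `protein_graph`: list with `nodes` (the chain), `links`
#'   (data frame `i, j, l, A`, `i < j`) and `r_c`.
#' @examples
#' g <- build_graph(make_helix(10), r_c = 6)
#' nrow(g$links)
#' @export
build_graph <- function(chain, r_c) {
  if (r_c <= 0) abort_inpa("r_c must be positive")
  n <- nrow(chain)
  if (n < 2L) abort_inpa("need at least 2 nodes to build a graph")
  D <- as.matrix(stats::dist(coords(chain)))
  hit <- which(upper.tri(D) & D < r_c, arr.ind = TRUE)
  l <- D[hit]
  if (any(l == 0))
    abort_inpa("coincident C-alpha nodes (zero distance): malformed input")
  links <- data.frame(i = hit[, 1L], j = hit[, 2L], l = l,
                      A = pi * (r_c^2 - l^2 / 4))
  links <- links[order(links$i, links$j), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(nodes = chain, links = links, r_c = r_c),
            class = "protein_graph")
}

#' @export
print.protein_graph <- function(x, ...) {
  cat(sprintf("Protein graph: %d nodes, %d links, R_C = %g Angstrom\n",
              nrow(x$nodes), nrow(x$links), x$r_c))
  invisible(x)
}

#' Is there a conducting path between two nodes?
#'
#' A two-terminal network with disconnected contacts has infinite
#' impedance, so connectivity between the chosen source and sink is the
#' first thing to check for a given `R_C`.
#'
#' @param graph a [build_graph()] result.
#' @param source,sink node indices.
#' @return `TRUE` iff a path of links joins source and sink.
#' @export
is_connected <- function(graph, source, sink) {
  n <- nrow(graph$nodes)
  if (source < 1L || source > n || sink < 1L || sink > n)
    abort_inpa("node index out of range")
  if (source == sink) return(TRUE)
  if (nrow(graph$links) == 0L) return(FALSE)
  ig <- igraph::graph_from_edgelist(as.matrix(graph$links[, c("i", "j")]),
                                    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, n - igraph::vcount(ig)))
  memb <- igraph::components(ig)$membership
  memb[source] == memb[sink]
}

#' Scan link count and static impedance across interaction radii
#'
#' Diagnostic for choosing `R_C`: the link count is non-decreasing in
#' `R_C` (link sets are nested) and, once `R_C` exceeds the structure's
#' diameter, reaches the complete-graph value `N(N-1)/2` and stops
#' changing — beyond that point the network is no longer descriptive of
#' the protein topology, and the absolute impedance retains only the
#' geometric scale factor of the growing link areas (`A ~ pi R_C^2`, so
#' `Z(0) * R_C^2` tends to a constant while all impedance ratios and
#' spectral shapes freeze). Disconnected endpoint contacts are reported as
#' `Inf` impedance.
#'
#' @param chain a [calpha_chain()].
#' @param rc_values positive, increasing radii in Angstrom.
#' @param params a [material_params()] used for the impedance proxy.
#' @param contact optional [point_contacts()]; default first vs last node.
#' @return data frame with columns `r_c`, `link_count`, `z0_ohm`.
#' @export
rc_saturation_scan <- function(chain, rc_values, params = material_params(),
                               contact = NULL) {
  if (length(rc_values) == 0L) abort_inpa("rc_values must be non-empty")
  if (any(rc_values <= 0) || is.unsorted(rc_values, strictly = TRUE))
    abort_inpa("rc_values must be positive and strictly increasing")
  contact <- contact %||% point_contacts(1L, nrow(chain))
  rows <- lapply(rc_values, function(rc) {
    g <- build_graph(chain, rc)
    z0 <- if (nrow(g$links) == 0L) Inf else {
      el <- assign_elements(g, params)
      Re(solve_impedance(el, contact, omega = 0, on_disconnect = "inf"))
    }
    data.frame(r_c = rc, link_count = nrow(g$links), z0_ohm = z0)
  })
  do.call(rbind, rows)
}

#' Export / import a graph edge list as CSV
#'
#' Plain CSV with header `i,j,l_ij,A_ij` (Angstrom units), for solver-only
#' workflows that bypass structure reading.
#'
#' @param graph a `protein_graph`.
#' @param path file path.
#' @return `write_graph_csv`: `path` invisibly. `read_graph_csv`: a link
#'   data frame with columns `i, j, l, A` and attributes `r_c`, `n_nodes`.
#' @export
write_graph_csv <- function(graph, path) {
  df <- graph$links
  names(df) <- c("i", "j", "l_ij", "A_ij")
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_graph_csv
#' @param r_c interaction radius the edge list was built with.
#' @param n_nodes total node count (defaults to the largest index seen).
#' @export
read_graph_csv <- function(path, r_c = NA_real_, n_nodes = NULL) {
  df <- utils::read.csv(path)
  names(df) <- c("i", "j", "l", "A")
  structure(df, r_c = r_c, n_nodes = n_nodes %||% max(df$i, df$j))
}
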