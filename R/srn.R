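#' Build the sequence recurrence network (SRN) of a protein sequence
#'
#' The SRN places one node per residue position (1-based), plus an optional
#' dummy non-residue node at index 0 attached to position 1. Two nodes are
#' linked (`alpha[a, b] = 1`) when they are chain neighbours (positions `i`
#' and `i + 1`), or when the later of the two is the nearest earlier
#' occurrence of the same residue type seen from the other — the recurrence
#' edges that give the network its name. The adjacency matrix is binary,
#' symmetric, with zero diagonal; recurrence edges that coincide with chain
#' edges are collapsed.
#'
#' @param residues A residue string over the alphabet of [aa_alphabet()]
#'   (case-folded to upper), or a one-row `data.frame` with a `residues`
#'   column as produced by [read_fasta()].
#' @param include_dummy Attach the dummy centre node (index 0) to the first
#'   residue position. Default `TRUE`.
#' @return An object of class `srn`: a list with `adjacency` (binary
#'   symmetric matrix), `labels` (residue letter per node, `"."` for the
#'   dummy), `L` (sequence length), `include_dummy`, and `node_ids`
#'   (0-based when the dummy is present, 1-based otherwise).
#' @examples
#' net <- build_srn("AGA")
#' srn_edges(net)
#' @export
build_srn <- function(residues, include_dummy = TRUE) {
  if (is.data.frame(residues)) {
    stopifnot("residues" %in% names(residues), nrow(residues) == 1L)
    residues <- residues$residues
  }
  residues <- check_residues(residues)
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  offset <- if (include_dummy) 1L else 0L
  n <- L + offset
  A <- matrix(0, n, n)
  # chain edges between consecutive positions
  if (L >= 2L) {
    for (i in seq_len(L - 1L)) {
      A[i + offset, i + 1L + offset] <- 1
    }
  }
  # recurrence edges: each position to its nearest earlier same-type position
  last_seen <- integer(0)
  for (j in seq_len(L)) {
    prev <- last_seen[chars[j]]
    if (!is.na(prev) && length(prev) == 1L && !is.null(prev)) {
      A[prev + offset, j + offset] <- 1
    }
    last_seen[chars[j]] <- j
  }
  if (include_dummy) A[1L, 2L] <- 1
  A <- pmax(A, t(A))
  labels <- if (include_dummy) c(".", chars) else chars
  node_ids <- if (include_dummy) 0:L else 1:L
  dimnames(A) <- list(node_ids, node_ids)
  structure(
    list(adjacency = A, labels = labels, L = L,
         include_dummy = include_dummy, node_ids = node_ids),
    class = "srn"
  )
}

#' @export
print.srn <- function(x, ...) {
  cat("Sequence recurrence network: L =", x$L,
      if (x$include_dummy) "(+ dummy node)" else "", "\n")
  cat("  nodes:", nrow(x$adjacency),
      " edges:", sum(x$adjacency) / 2, "\n")
  invisible(x)
}

# Map user-facing node ids (0-based with dummy) to matrix row indices.
srn_row <- function(net, node) {
  idx <- match(node, net$node_ids)
  if (anyNA(idx)) stop("invalid node id(s): ",
                       paste(node[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Edge list of an SRN
#'
#' @param net An `srn` object.
#' @return A two-column `data.frame` (`node_a`, `node_b`) of undirected
#'   edges in the node-id scheme of the network (dummy node is 0).
#' @export
srn_edges <- function(net) {
  stopifnot(inherits(net, "srn"))
  idx <- which(upper.tri(net$adjacency) & net$adjacency > 0, arr.ind = TRUE)
  data.frame(node_a = net$node_ids[idx[, 1]],
             node_b = net$node_ids[idx[, 2]])
}

#' Export an SRN as an edge-list TSV
#'
#' @param net An `srn` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_srn_edges <- function(net, path) {
  utils::write.table(srn_edges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Minimal topological distance between two SRN nodes
#'
#' Shortest-path length in edges between nodes `a` and `b`; 0 iff `a == b`.
#' Valid SRNs are connected by construction (chain edges), so an infinite
#' distance indicates a corrupted network and raises an error.
#'
#' @param net An `srn` object.
#' @param a,b Node ids (0 = dummy node when present).
#' @return Integer shortest-path distance.
#' @export
topological_distance <- function(net, a, b) {
  stopifnot(inherits(net, "srn"))
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  d <- igraph::distances(g, v = srn_row(net, a), to = srn_row(net, b))[1, 1]
  if (!is.finite(d)) {
    stop("nodes ", a, " and ", b, " are disconnected (corrupt network)",
         call. = FALSE)
  }
  as.integer(d)
}
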