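# Independent brute-force oracles, deliberately written as direct
# transcriptions of the construction rules (O(L^2) scans, explicit walk
# enumeration) so they share no code path with the package internals.

# Edge set of the recurrence network by double loop: chain neighbours, plus
# each position linked to the nearest earlier position of the same residue,
# scanned backwards one position at a time.
oracle_srn_edges <- function(residues, include_dummy = TRUE) {
  chars <- strsplit(toupper(residues), "")[[1]]
  L <- length(chars)
  edges <- list()
  add <- function(a, b) {
    key <- paste(min(a, b), max(a, b))
    edges[[key]] <<- c(min(a, b), max(a, b))
  }
  if (include_dummy) add(0L, 1L)
  for (i in seq_len(L - 1L)) add(i, i + 1L)
  for (j in seq_len(L)) {
    if (j < 2L) next
    for (i in (j - 1L):1L) {
      if (chars[i] == chars[j]) {
        add(i, j)
        break
      }
    }
  }
  if (length(edges) == 0L) {
    return(data.frame(node_a = integer(0), node_b = integer(0)))
  }
  m <- do.call(rbind, unname(edges))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(node_a = m[, 1], node_b = m[, 2])
}

# trace(M^k) as the sum over all closed walks of length k of the products
# of traversed entries, enumerated recursively.
oracle_trace_walks <- function(M, k) {
  n <- nrow(M)
  total <- 0
  walk <- function(start, current, depth, prod) {
    if (depth == k) {
      if (current == start) total <<- total + prod
      return(invisible())
    }
    for (nxt in seq_len(n)) {
      if (M[current, nxt] != 0) {
        walk(start, nxt, depth + 1L, prod * M[current, nxt])
      }
    }
  }
  for (s in seq_len(n)) walk(s, s, 0L, 1)
  total
}

# Random residue string over a restricted alphabet.
random_residues <- function(L, alphabet = c("A", "G", "R")) {
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

edge_key <- function(df) {
  paste(pmin(df$node_a, df$node_b), pmax(df$node_a, df$node_b))
}
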