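#' Row-stochastic Markov matrix of an SRN
#'
#' Converts the binary adjacency `alpha` of a sequence recurrence network
#' into the one-step transition matrix with entries
#' `p[a, b] = alpha[a, b] / sum_b alpha[a, b]`: the probability of reaching
#' node `b` in a single step of an unbiased walk from node `a`.
#'
#' @param net An `srn` object.
#' @return An object of class `stochastic_matrix`: a list with `P` (the
#'   row-stochastic matrix) and `n` (its dimension).
#' @export
to_stochastic <- function(net) {
  stopifnot(inherits(net, "srn"))
  deg <- rowSums(net$adjacency)
  if (any(deg == 0)) {
    stop("isolated node(s) at index ",
         paste(net$node_ids[deg == 0], collapse = ", "), call. = FALSE)
  }
  structure(list(P = net$adjacency / deg, n = nrow(net$adjacency)),
            class = "stochastic_matrix")
}

#' @export
print.stochastic_matrix <- function(x, ...) {
  cat("Row-stochastic SRN matrix,", x$n, "x", x$n, "\n")
  invisible(x)
}

# k-th matrix power by repeated multiplication (k is small in practice).
mat_power <- function(M, k) {
  out <- diag(nrow(M))
  for (i in seq_len(k)) out <- out %*% M
  out
}

# Resolve srn / stochastic_matrix input to the requested matrix.
resolve_matrix <- function(x, matrix_kind) {
  if (inherits(x, "srn")) {
    if (matrix_kind == "adjacency") return(x$adjacency)
    return(to_stochastic(x)$P)
  }
  if (inherits(x, "stochastic_matrix")) {
    if (matrix_kind == "adjacency") {
      stop("adjacency traces need the `srn` object, not the stochastic matrix",
           call. = FALSE)
    }
    return(x$P)
  }
  stop("expected an `srn` or `stochastic_matrix` object", call. = FALSE)
}

#' Trace descriptor of order k
#'
#' `Tr_k = trace(M^k)`, where `M` is by default the row-stochastic SRN
#' matrix (every matrix the method defines is the stochastic one) and
#' optionally the raw binary adjacency. For the stochastic matrix, `Tr_k`
#' is the total probability mass on closed walks of length `k`, so
#' `0 <= Tr_k <= n` for even `k` and `|Tr_k| <= n` in general.
#'
#' @param x An `srn` or `stochastic_matrix` object.
#' @param k Order (power) of the matrix, a positive integer. `k = 0` is
#'   degenerate (trace of the identity, i.e. `n`) and raises a warning.
#' @param matrix_kind `"stochastic"` (default) or `"adjacency"`.
#' @return Numeric trace value.
#' @export
trace_descriptor <- function(x, k, matrix_kind = c("stochastic", "adjacency")) {
  matrix_kind <- match.arg(matrix_kind)
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0, k == round(k))
  M <- resolve_matrix(x, matrix_kind)
  if (k == 0) {
    warning("k = 0 is degenerate: trace of the identity", call. = FALSE)
    return(nrow(M))
  }
  sum(diag(mat_power(M, k)))
}

#' Markov-Shannon entropy of order k
#'
#' Starting from the uniform node-occupancy distribution
#' `pi_0 = (1/n, ..., 1/n)`, propagates `pi_k = pi_0 P^k` and returns the
#' Shannon entropy `theta_k = -sum_a pi_k(a) log pi_k(a)` of the occupancy
#' after `k` steps of the walk (zero-probability terms contribute 0).
#' `theta_0 = log(n)` and, for a regular graph, `theta_k = log(n)` for all
#' `k` because the uniform distribution is stationary.
#'
#' @param x An `srn` or `stochastic_matrix` object.
#' @param k Number of Markov steps, a non-negative integer.
#' @param base Logarithm base; the default natural log reports nats.
#' @return Entropy value in `[0, log(n, base)]`.
#' @export
shannon_entropy <- function(x, k, base = exp(1)) {
  stopifnot(is.numeric(k), length(k) == 1L, k >= 0, k == round(k))
  P <- resolve_matrix(x, "stochastic")
  n <- nrow(P)
  pi_k <- rep(1 / n, n)
  for (i in seq_len(k)) pi_k <- as.numeric(pi_k %*% P)
  nz <- pi_k > 0
  -sum(pi_k[nz] * log(pi_k[nz], base = base))
}

#' Per-sequence descriptor table
#'
#' Builds one SRN per sequence and computes trace (`Tr<k>`) and
#' Markov-Shannon entropy (`Theta<k>`) descriptors for each requested order.
#' Column order is fixed: `sequence_id`, then all traces, then all
#' entropies, in the order given.
#'
#' @param seqs `data.frame` with columns `id`, `residues`
#'   (from [read_fasta()] or [synth_generate()]).
#' @param orders Integer vector of matrix orders; default `c(3, 5)`, the
#'   orders the published model uses.
#' @param include_dummy Passed to [build_srn()].
#' @param matrix_kind Passed to [trace_descriptor()].
#' @param entropies Include `Theta<k>` columns. Default `TRUE`.
#' @return `data.frame` with one row per sequence.
#' @examples
#' descriptor_table(data.frame(id = "p1", residues = "AGAR"))
#' @export
descriptor_table <- function(seqs, orders = c(3L, 5L), include_dummy = TRUE,
                             matrix_kind = "stochastic", entropies = TRUE) {
  stopifnot(is.data.frame(seqs), nrow(seqs) >= 1L,
            all(c("id", "residues") %in% names(seqs)),
            length(orders) >= 1L, all(orders >= 1))
  orders <- sort(as.integer(orders))
  rows <- lapply(seq_len(nrow(seqs)), function(i) {
    res <- tryCatch({
      net <- build_srn(seqs$residues[i], include_dummy = include_dummy)
      pim <- to_stochastic(net)
      M <- if (matrix_kind == "adjacency") net$adjacency else pim$P
      # incremental powers so shared low orders are multiplied once
      tr <- numeric(length(orders))
      Mk <- diag(nrow(M))
      k_now <- 0L
      for (j in seq_along(orders)) {
        while (k_now < orders[j]) {
          Mk <- Mk %*% M
          k_now <- k_now + 1L
        }
        tr[j] <- sum(diag(Mk))
      }
      th <- if (entropies) {
        vapply(orders, function(k) shannon_entropy(pim, k), numeric(1))
      } else NULL
      c(stats::setNames(tr, paste0("Tr", orders)),
        if (entropies) stats::setNames(th, paste0("Theta", orders)))
    }, error = function(e) {
      stop("sequence '", seqs$id[i], "': ", conditionMessage(e), call. = FALSE)
    })
    res
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(data.frame(sequence_id = seqs$id, stringsAsFactors = FALSE), out)
}

#' Write a descriptor table to TSV
#'
#' @param desc Descriptor `data.frame` from [descriptor_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(desc, path) {
  utils::write.table(desc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
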