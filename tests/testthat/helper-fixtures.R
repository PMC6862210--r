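# Shared fixtures built in code at test time.

# Strongly separated study conditions: all subclasses strongly biased with
# spread strengths, realistic protein lengths. Used by the end-to-end
# parameter-recovery checks.
strong_separation_spec <- function(seed = 1L) {
  synth_spec(n_classes = 7L, sequences_per_class = 30L, n_nonenzymes = 60L,
             length_range = c(250L, 350L),
             bias = seq(0.6, 0.9, length.out = 7), seed = seed)
}

# Tiny descriptor table + annotations with hand-set values, for the
# multitask arithmetic tests.
toy_descriptors <- function() {
  list(
    desc = data.frame(
      sequence_id = c("e1", "e2", "e3", "n1", "n2"),
      Tr3 = c(1.0, 3.0, 10.0, 0.5, 0.6),
      Tr5 = c(2.0, 4.0, 12.0, 0.7, 0.8)
    ),
    ann = data.frame(
      sequence_id = c("e1", "e2", "e3", "n1", "n2"),
      class_id = c("1.1", "1.1", "3.4", "non-enzyme", "non-enzyme")
    )
  )
}

# Gaussian pair records with the class signal planted on chosen features.
gaussian_pairs <- function(n_per_class = 100, shift = c(DTr3 = 4),
                           seed = 42) {
  set.seed(seed)
  feats <- c("Tr3_mean", "Tr5_mean", "DTr3", "DTr5")
  X <- matrix(stats::rnorm(2 * n_per_class * 4), ncol = 4,
              dimnames = list(NULL, feats))
  lab <- rep(c(1L, -1L), each = n_per_class)
  for (f in names(shift)) {
    X[lab == 1L, f] <- X[lab == 1L, f] + shift[[f]]
  }
  cbind(data.frame(sequence_id = paste0("s", seq_len(nrow(X))),
                   class_id = "1.1"),
        as.data.frame(X), data.frame(label = lab))
}
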