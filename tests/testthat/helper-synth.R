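# shared fixtures, all built in code

# uniform-background fragments with a fixed S/T centre
random_fragments <- function(n, w = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- 2L * w + 1L
  fm <- matrix(sample(oglcnac:::AA_LETTERS, n * L, replace = TRUE), n, L)
  fm[, w + 1L] <- sample(c("S", "T"), n, replace = TRUE)
  apply(fm, 1L, paste, collapse = "")
}

# two strongly separable group-level motifs (left-flank acidic run vs
# right-flank aromatic run)
separable_motifs <- function() {
  list(motif_spec(data.frame(offset = c(-3, -2, -1), group = "acidic",
                             prob = 1), 0.5),
       motif_spec(data.frame(offset = c(1, 2, 3), group = "aromatic",
                             prob = 1), 0.5))
}

# moderately separable motifs used for the model-ordering comparison
two_motif_dataset <- function(seed, n_pos = 200L, n_neg = 2000L) {
  generate_windows(dataset_spec(
    n_pos = n_pos, n_neg = n_neg,
    motifs = list(
      motif_spec(data.frame(offset = c(-3, -2), group = "hydrophobic",
                            prob = 1), 0.5),
      motif_spec(data.frame(offset = c(1, 2), group = "basic",
                            prob = 1), 0.5)),
    seed = seed))
}

# dependence without marginal concentration: positions i and j share a
# uniformly drawn group per fragment
linked_pair_dataset <- function(seed, n = 400L, offsets = c(-3L, -2L)) {
  generate_windows(dataset_spec(
    n_pos = n, n_neg = 0L,
    motifs = lapply(oglcnac:::GROUP_LEVELS, function(g)
      motif_spec(data.frame(offset = offsets, group = g, prob = 1),
                 weight = 0.2)),
    seed = seed))
}

# small SVM grid keeping unit tests fast; defaults stay the coarse log grid
test_config <- function(seed = 1L, ...) {
  two_layer_config(
    svm_grid = expand.grid(C = 2^c(-1, 3, 7), gamma = 2^c(-7, -3, 1)),
    seed = seed, ...)
}

# independent double-loop evaluation of the dependence statistic
chi_square_oracle <- function(tab) {
  total <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  acc <- 0
  for (m in seq_len(nrow(tab))) {
    for (n in seq_len(ncol(tab))) {
      e <- rs[[m]] * cs[[n]] / total
      if (e > 0) acc <- acc + (tab[m, n] - e)^2 / e
    }
  }
  acc
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
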