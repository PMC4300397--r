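# fixtures shared across test files; all generated in code, seeded

# small genotype matrix with exact allele counts: n_AA / n_AB / n_BB samples
geno_counts <- function(n_AA, n_AB = 0, n_BB = 0, n_loci = 1,
                        locus_names = sprintf("L%02d", seq_len(n_loci))) {
  calls <- c(rep("AA", n_AA), rep("AB", n_AB), rep("BB", n_BB))
  m <- matrix(rep(calls, n_loci), ncol = n_loci,
              dimnames = list(sprintf("S%03d", seq_along(calls)), locus_names))
  m
}

# RIL-style matrix with an exact number of recombinants between two loci
ril_pair <- function(n_lines, n_recomb) {
  gA <- rep("AA", n_lines)
  gB <- gA
  gB[seq_len(n_recomb)] <- "BB"
  cbind(A = gA, B = gB)
}

# binary split-metric genotypes: for each tree edge (split, weight) add
# `weight` loci separating the split; allele-sharing distances are then
# exactly additive on the tree
split_geno <- function(splits, taxa) {
  cols <- list()
  for (s in splits) {
    for (i in seq_len(s$w)) {
      g <- ifelse(taxa %in% s$side, "BB", "AA")
      cols[[length(cols) + 1]] <- g
    }
  }
  m <- do.call(cbind, cols)
  rownames(m) <- taxa
  colnames(m) <- sprintf("L%03d", seq_len(ncol(m)))
  m
}
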