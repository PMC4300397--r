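#!/usr/bin/env Rscript
# Stage 1 -- synthetic hexaploid and reduced-representation substrate.
#
# Builds the three-subgenome genome with a known truth table (allelic SNPs
# between the two parental lines, homeologous variation between subgenomes),
# digests both parents with EcoRI and size-selects 2-4 kb fragments, the
# territory the sequencing libraries will sample.

library(camsnp)

dir.create("results", showWarnings = FALSE)
seed <- 1

truth <- make_hexaploid(n_chromosomes = 2, chrom_length = 50000,
                        homeolog_divergence = 0.03, n_true_snps = 300,
                        seed = seed)
print(truth)

frag_A <- digest_genome(truth$parent_A)
frag_B <- digest_genome(truth$parent_B)
cat(sprintf("selected fragments: parent A %d (%.1f kb), parent B %d (%.1f kb)\n",
            nrow(frag_A), sum(frag_A$length) / 1e3,
            nrow(frag_B), sum(frag_B$length) / 1e3))

write_fasta(setNames(frag_A$seq, frag_A$frag_id), "results/parentA_fragments.fasta")
write.csv(truth$true_snps, "results/true_snps.csv", row.names = FALSE)
write.csv(truth$homeolog_variants, "results/homeolog_variants.csv",
          row.names = FALSE)
saveRDS(truth, "scratch/truth.rds")   # binary intermediate for later stages
saveRDS(list(frag_A = frag_A, frag_B = frag_B), "scratch/fragments.rds")
cat("wrote results/parentA_fragments.fasta, results/true_snps.csv,",
    "results/homeolog_variants.csv\n")
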