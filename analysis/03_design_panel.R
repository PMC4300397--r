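#!/usr/bin/env Rscript
# Stage 3 -- assay panel design.
#
# Takes the zero-variance survivors of the unique-mapping arm through the
# clean-flank rule and the designability surrogate, then assembles three
# provenance tranches: a small 3'-cDNA arm (called at the cDNA thresholds),
# a synteny-spread genomic tranche driven by a homology table, and a
# seeded random draw from the remaining "intergenic" candidates.

library(camsnp)
library(data.table)

truth <- readRDS("scratch/truth.rds")
run_u <- readRDS("scratch/run_unique.rds")
seed <- 1
set.seed(seed)

## genomic candidates: zero-variance + clean flanks + designability
cand <- run_u$candidates[run_u$candidates$fixed_ok == TRUE, ]
contig_len <- setNames(nchar(run_u$contigs), names(run_u$contigs))
variant_pos <- run_u$calls[run_u$calls$alt_frac >= run_u$profile$min_variant_fraction,
                           c("contig", "pos0")]
cand <- flank_filter(cand, contig_len, variant_pos)
funnel <- c(candidates = nrow(run_u$candidates),
            zero_variance = nrow(cand),
            clean_flanks = sum(cand$flank_ok))
cand <- cand[cand$flank_ok == TRUE, ]
cand <- extract_flanks(cand, run_u$contigs)
scores <- vapply(seq_len(nrow(cand)), function(i)
  designability_score(cand$left_flank[i], cand$right_flank[i])$score, numeric(1))
cand$designability <- scores
cand <- cand[scores >= designability_params()$threshold, ]
funnel["designable"] <- nrow(cand)

## synthetic homology table: half the contigs hit a 5-chromosome model genome
ctg <- unique(cand$contig)
hit <- sort(sample(ctg, ceiling(length(ctg) / 2)))
homology <- data.frame(contig = hit,
                       chromosome = sample(1:5, length(hit), TRUE),
                       gene_id = sprintf("MG%05d", seq_along(hit)),
                       gene_pos = sample.int(3000000L, length(hit)))
write.csv(homology, "results/homology_table.csv", row.names = FALSE)

synteny <- spread_select(cand, homology, quota_per_chromosome = 6)
intergenic_pool <- cand[!(cand$contig %in% homology$contig)]
n_inter <- min(10L, nrow(intergenic_pool))
intergenic <- intergenic_pool[sort(sample.int(nrow(intergenic_pool), n_inter))]

## small 3'-cDNA arm at its own thresholds (depth >= 3, variant >= 30%)
tx_meta <- data.table(seq_id = names(truth$parent_A)[1], start0 = 0L)
mk_tx <- function(genome) {
  ids <- names(genome)
  starts <- seq(1000, 40000, by = 4000)
  tx <- unlist(lapply(ids[1:2], function(id)
    setNames(substring(genome[[id]], starts, starts + 799),
             sprintf("%s_tx%04d", id, starts))))
  tx
}
tx_A <- mk_tx(truth$parent_A)
tx_B <- mk_tx(truth$parent_B)
rd_c <- simulate_cdna_reads(tx_B, tail_len = 500, depth = 8,
                            error_rate = 0.001, seed = seed)
rd_a <- simulate_cdna_reads(tx_A, tail_len = 500, depth = 8,
                            error_rate = 0.001, seed = seed + 1)
idx_tx <- index_reference(tx_A, k = 21)
aln_c <- map_reads(setNames(rd_c$seq, rd_c$read_id), idx_tx)
aln_a <- map_reads(setNames(rd_a$seq, rd_a$read_id), idx_tx)
pu_c <- pileup(aln_c); pu_a <- pileup(aln_a)
cdna_calls <- call_variants(pu_c, tx_A, call_profile("cdna"))
cdna_cand <- fixed_allele_filter(cdna_calls[cdna_calls$candidate == TRUE, ],
                                 pu_a, pu_c)
cdna_cand <- cdna_cand[cdna_cand$fixed_ok == TRUE, ]

panel <- assemble_panel(list(
  cdna = cdna_cand[, c("contig", "pos0", "ref", "alt")],
  genomic_synteny = synteny[, c("contig", "pos0", "ref", "alt")],
  genomic_intergenic = intergenic[, c("contig", "pos0", "ref", "alt")]))
cat("panel tranche counts:\n"); print(attr(panel, "counts"))
cat("filter funnel (genomic arm):\n"); print(funnel)

write.csv(panel, "results/assay_panel.csv", row.names = FALSE)
write.csv(data.frame(stage = names(funnel), n = as.integer(funnel)),
          "results/filter_funnel.csv", row.names = FALSE)
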