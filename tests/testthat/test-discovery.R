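# seed index, unique mapping, pileup, threshold calling

test_that("index counts forward seed positions and flags repeats", {
  set.seed(1)
  ctg <- stats::setNames(random_dna(50), "c1")
  idx <- index_reference(ctg, k = 21)
  expect_equal(nrow(idx$lookup), 30) # L - k + 1
  # identical duplicate contigs: at multiplicity 1 every k-mer is repetitive
  dup <- c(c1 = ctg[[1]], c2 = ctg[[1]])
  idx2 <- index_reference(dup, k = 21, max_multiplicity = 1)
  expect_equal(nrow(idx2$lookup), 0)
  expect_equal(length(idx2$repetitive), 30)
  # k larger than every contig: empty index with a warning
  expect_warning(idx3 <- index_reference(c(s = "ACGTACGTACGT"), k = 21),
                 "shorter than k")
  expect_equal(nrow(idx3$lookup), 0)
})

test_that("mapping is exact, mismatch-capped and tie-discarding", {
  set.seed(2)
  ctg <- stats::setNames(random_dna(400), "c1")
  idx <- index_reference(ctg)
  read <- stats::setNames(substring(ctg, 101, 201), "r1")
  aln <- map_reads(read, idx)
  expect_equal(aln$pos0, 100L)
  expect_equal(aln$mm, 0L)
  expect_equal(aln$strand, "+")
  # reverse-complemented read maps to the same locus on the minus strand
  aln_rc <- map_reads(stats::setNames(revcomp(read), "r1rc"), idx)
  expect_equal(aln_rc$pos0, 100L)
  expect_equal(aln_rc$strand, "-")
  # 4 substitutions against a 3-mismatch cap: unmapped
  mut <- strsplit(read, "")[[1]]
  mut[c(30, 40, 50, 60)] <- vapply(mut[c(30, 40, 50, 60)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  expect_equal(nrow(map_reads(stats::setNames(paste(mut, collapse = ""), "r2"),
                              idx)), 0)
  # read matching two identical homeolog copies: tie, discarded when unique_only
  two <- c(h1 = ctg[[1]], h2 = ctg[[1]])
  idx2 <- index_reference(two)
  expect_equal(nrow(map_reads(read, idx2, unique_only = TRUE)), 0)
  kept <- map_reads(read, idx2, unique_only = FALSE)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$contig, "h1") # deterministic tie-break
})

test_that("mapping is strand-symmetric on simulated reads", {
  set.seed(3)
  tr <- make_hexaploid(1, 5000, 0.05, 20, seed = 4)
  frag <- digest_genome(tr$parent_B, min_len = 500, max_len = 4000)
  rd <- simulate_reads(frag, 300, 101, 5, 0, seed = 5)
  reads <- stats::setNames(rd$seq1, paste0(rd$read_id, "/1"))
  idx <- index_reference(stats::setNames(frag$seq, frag$frag_id))
  a1 <- map_reads(reads, idx)
  a2 <- map_reads(stats::setNames(revcomp(reads), names(reads)), idx)
  expect_equal(nrow(a1), nrow(a2))
  m1 <- a1[order(read), .(read, contig, pos0, mm)]
  m2 <- a2[order(read), .(read, contig, pos0, mm)]
  expect_equal(m1, m2)
})

test_that("pileup counts conserve aligned bases and expose disagreements", {
  ctg <- c(c1 = "ACGTACGTACGTACGTACGT")
  aln <- data.table::data.table(
    read = c("a", "b"), contig = "c1", pos0 = c(0L, 4L), strand = "+",
    mm = 0L, qseq = c("ACGTACGTAC", "ACGTACGTAC"))
  pu <- pileup(aln, contig_len = c(c1 = 20L))
  expect_equal(sum(pu$depth), 20)
  expect_true(all(pu$depth[pu$pos0 %in% 4:9] == 2))
  # two overlapping reads disagreeing at one position show both base types
  aln2 <- data.table::data.table(
    read = c("a", "b"), contig = "c1", pos0 = 0L, strand = "+",
    mm = c(0L, 1L), qseq = c("ACGTACGTAC", "ACGTACGTAG"))
  pu2 <- pileup(aln2)
  col <- pu2[pu2$pos0 == 9, ]
  expect_equal(col$depth, 2)
  expect_equal(col$C, 1L)
  expect_equal(col$G, 1L)
  # overrunning alignment is rejected
  aln3 <- data.table::data.table(read = "z", contig = "c1", pos0 = 15L,
                                 strand = "+", mm = 0L, qseq = "ACGTACGTAC")
  expect_error(pileup(aln3, contig_len = c(c1 = 20L)), "overrun")
})

test_that("threshold profiles accept and reject by depth and variant fraction", {
  ref <- c(c1 = paste(rep("A", 50), collapse = ""))
  mk_pileup <- function(pos, nA, nC) data.table::data.table(
    contig = "c1", pos0 = pos, A = nA, C = nC, G = 0L, T = 0L,
    depth = nA + nC)
  # depth 10, alt 4 (40%): genomic candidate
  cv <- call_variants(mk_pileup(5L, 6L, 4L), ref, call_profile("genomic"))
  expect_true(cv$candidate)
  expect_equal(cv$alt, "C")
  # depth 7 fails the genomic depth cut even with a strong variant
  expect_false(call_variants(mk_pileup(5L, 2L, 5L), ref,
                             call_profile("genomic"))$candidate)
  # depth 3, alt 1 (33%): cdna candidate at its 30% rule
  expect_true(call_variants(mk_pileup(5L, 2L, 1L), ref,
                            call_profile("cdna"))$candidate)
  # two alternate bases above the fraction: multi-allelic rejection
  tri <- data.table::data.table(contig = "c1", pos0 = 5L, A = 2L, C = 5L,
                                G = 5L, T = 0L, depth = 12L)
  cv3 <- call_variants(tri, ref, call_profile("genomic"))
  expect_false(cv3$candidate)
  expect_equal(cv3$reason, "multi_allelic")
})

test_that("error-free parent-B reads recover every covered unique true SNP", {
  tr <- make_hexaploid(1, 30000, 0.04, 60, seed = 6)
  run <- snp_discovery_run(tr, min_len = 1000, max_len = 4000, depth = 25,
                           error_rate = 0, seed = 7)
  ev <- evaluate_discovery(run, tr)
  expect_gt(ev$snp$n_assayable, 5)
  expect_equal(ev$snp$retention, 1)
})
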