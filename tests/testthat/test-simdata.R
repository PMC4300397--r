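# synthetic-data generators: genome, digest, reads, RIL, panel, intensities

test_that("zero divergence gives identical subgenomes; zero SNPs identical parents", {
  tr <- make_hexaploid(1, 2000, homeolog_divergence = 0, n_true_snps = 0, seed = 1)
  expect_identical(tr$parent_A[["chr1_s1"]], tr$parent_A[["chr1_s2"]])
  expect_identical(tr$parent_A[["chr1_s2"]], tr$parent_A[["chr1_s3"]])
  expect_identical(tr$parent_A, tr$parent_B)
  expect_equal(nrow(tr$homeolog_variants), 0)
})

test_that("realized pairwise subgenome divergence tracks the target", {
  tr <- make_hexaploid(1, 100000, homeolog_divergence = 0.05, n_true_snps = 0,
                       seed = 2)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    a <- strsplit(tr$parent_A[[sprintf("chr1_s%d", pair[1])]], "")[[1]]
    b <- strsplit(tr$parent_A[[sprintf("chr1_s%d", pair[2])]], "")[[1]]
    expect_lt(abs(mean(a != b) - 0.05), 0.005)
  }
})

test_that("true SNP and homeolog variant position sets are disjoint and biallelic", {
  tr <- make_hexaploid(2, 5000, 0.05, 200, seed = 3)
  snp_key <- paste(tr$true_snps$chrom, tr$true_snps$pos0)
  hv_key <- paste(tr$homeolog_variants$chrom, tr$homeolog_variants$pos0)
  expect_length(intersect(snp_key, hv_key), 0)
  expect_true(all(tr$true_snps$ref != tr$true_snps$alt))
  expect_true(all(strsplit(paste(tr$parent_A, collapse = ""), "")[[1]] %in%
                    c("A", "C", "G", "T")))
  # SNP injected on exactly one subgenome copy: other copies match parent A
  expect_error(make_hexaploid(1, 1000, 0, 1001, seed = 1), "collision|positions")
})

test_that("digest reproduces the worked 22-mer example and tiles exactly", {
  d <- digest_and_select("AAAGAATTCCCCGGAATTCTTT", site = "GAATTC",
                         cut_offset = 1, min_len = 1, max_len = 100)
  expect_equal(d$fragments$start0, c(0, 4, 14))
  expect_equal(d$fragments$end0, c(4, 14, 22))
  # size window 5..12 keeps the fragments of length 10 and 8, drops length 4
  d2 <- digest_and_select("AAAGAATTCCCCGGAATTCTTT", "GAATTC", 1, 5, 12)
  expect_equal(d2$selected$start0, c(4, 14))
  expect_equal(d2$selected$length, c(10, 8))
  # no site: a single fragment spanning the sequence
  d3 <- digest_and_select("ACGTACGT", "TTTTTT", 1, 1, 100)
  expect_equal(nrow(d3$fragments), 1)
  expect_equal(d3$fragments$length, 8)
})

test_that("digest tiling reconstructs random sequences for random sites", {
  set.seed(42)
  for (i in 1:10) {
    s <- random_dna(sample(500:2000, 1))
    site <- random_dna(sample(4:6, 1))
    off <- sample(0:nchar(site), 1)
    d <- digest_and_select(s, site, off, 1, nchar(s))
    pieces <- substring(s, d$fragments$start0 + 1, d$fragments$end0)
    expect_identical(paste(pieces, collapse = ""), s)
  }
})

test_that("error-free reads are exact substrings; coverage near target; seeded determinism", {
  set.seed(7)
  frag <- stats::setNames(random_dna(10000), "f1")
  rd <- simulate_reads(frag, insert_len = 300, read_len = 101, depth = 30,
                       error_rate = 0, seed = 5)
  for (i in head(seq_len(nrow(rd)), 50)) {
    ins <- unname(substring(frag, rd$insert_start0[i] + 1,
                            rd$insert_start0[i] + 300))
    # the 5'-forward mate is seq2 when the pair was strand-flipped
    m1 <- if (rd$flipped[i]) rd$seq2[i] else rd$seq1[i]
    m2 <- if (rd$flipped[i]) rd$seq1[i] else rd$seq2[i]
    expect_identical(m1, substring(ins, 1, 101))
    expect_identical(revcomp(m2), substring(ins, 200, 300))
  }
  cov <- 2 * 101 * nrow(rd) / 10000
  expect_lt(abs(cov - 30) / 30, 0.15)
  rd2 <- simulate_reads(frag, 300, 101, 30, 0, seed = 5)
  expect_identical(rd, rd2)
  rd3 <- simulate_reads(frag, 300, 101, 30, 0, seed = 6)
  expect_false(identical(rd$seq1, rd3$seq1))
  expect_warning(simulate_reads(stats::setNames("ACGT", "tiny"), 300, 101, 10, 0, 1),
                 "shorter than insert")
})

test_that("RIL recombinant fractions follow the selfed-RIL expectation", {
  # unlinked loci on different chromosomes: R -> 0.5
  tm <- data.frame(chrom = c(1, 2), locus = c("a", "b"), cM = c(0, 0))
  g <- simulate_ril(tm, 10000, seed = 1)
  R_unl <- mean(g[, "a"] != g[, "b"])
  expect_lt(abs(R_unl - 0.5), 0.02)
  # 10 cM apart: Haldane r = 0.0906, RIL R = 2r/(1+2r) = 0.1532
  tm2 <- data.frame(chrom = 1, locus = c("a", "b"), cM = c(0, 10))
  g2 <- simulate_ril(tm2, 10000, seed = 2)
  r_h <- 0.5 * (1 - exp(-2 * 10 / 100))
  expect_lt(abs(mean(g2[, "a"] != g2[, "b"]) - 2 * r_h / (1 + 2 * r_h)), 0.01)
  # coincident markers: zero recombinants; full homozygosity
  tm3 <- data.frame(chrom = 1, locus = c("a", "b"), cM = c(5, 5))
  g3 <- simulate_ril(tm3, 500, seed = 3)
  expect_equal(mean(g3[, "a"] != g3[, "b"]), 0)
  expect_true(all(g3 %in% c("AA", "BB")))
})

test_that("RIL allele frequencies stay near one half", {
  tm <- regular_map(2, 10, 10)
  g <- simulate_ril(tm, 1000, seed = 4)
  freq <- colMeans(g == "AA")
  se3 <- 3 * 0.5 / sqrt(1000)
  expect_true(all(abs(freq - 0.5) <= se3 + 0.01))
})

test_that("panel generator hits its differentiation and selfing targets", {
  p <- simulate_panel(100, 500, K = 2, drift_fst = 0.3, selfing_rate = 1,
                      admix_frac = 0, seed = 5)
  expect_equal(sum(p == "AB"), 0)
  lab <- attr(p, "truth")$labels
  p2 <- simulate_panel(100, 500, K = 2, drift_fst = 0.3, selfing_rate = 0.96,
                       admix_frac = 0, seed = 6)
  fs <- f_stats(p2, attr(p2, "truth")$labels)
  expect_lt(abs(fs$F_ST - 0.3), 0.05)
  # monotone in drift_fst
  p_lo <- simulate_panel(100, 500, K = 2, drift_fst = 0.05, selfing_rate = 0.96,
                         admix_frac = 0, seed = 7)
  fs_lo <- f_stats(p_lo, attr(p_lo, "truth")$labels)
  expect_lt(fs_lo$F_ST, fs$F_ST)
  # a 50/50 admixed accession has allele frequency midway between populations
  Q <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  p3 <- simulate_panel(3, 200, K = 2, drift_fst = 0.3, selfing_rate = 0.96,
                       admix_frac = 0, Q = Q, seed = 8)
  tt <- attr(p3, "truth")
  pi3 <- (Q %*% tt$P)[3, ]
  expect_equal(pi3, colMeans(tt$P), tolerance = 1e-12)
})

test_that("cDNA reads are drawn from the 3' transcript tail", {
  set.seed(10)
  tx <- stats::setNames(random_dna(2000), "t1")
  rd <- simulate_cdna_reads(tx, tail_len = 500, read_len = 101, depth = 10,
                            error_rate = 0, seed = 1)
  expect_true(all(rd$start0 >= 1500))                  # inside the 3' window
  expect_true(all(rd$start0 + 101 <= 2000))
  expect_identical(rd$seq[1],
                   unname(substring(tx, rd$start0[1] + 1, rd$start0[1] + 101)))
  expect_identical(simulate_cdna_reads(tx, 500, 101, 10, 0, seed = 1), rd)
})

test_that("intensity generator reproduces the cluster patterns", {
  g <- geno_counts(60, 60, 60, n_loci = 1)
  # failed: every sample below the R threshold
  fi <- simulate_intensities(g, "failed", seed = 1)
  expect_lt(max(fi$x + fi$y), 0.2)
  # noiseless standard: exactly three distinct theta values
  si <- simulate_intensities(g, "standard", noise_sd = 0, seed = 2)
  th <- intensity_polar(si$x, si$y)$theta
  expect_equal(length(unique(round(th, 9))), 3)
  # dominant: het and fluorescing homozygote theta overlap (KS p > 0.05)
  di <- simulate_intensities(g, "dominant", noise_sd = 0.02, seed = 3)
  pol <- intensity_polar(di$x, di$y)
  truth <- attr(di, "truth")$genotypes[, 1]
  ks <- suppressWarnings(stats::ks.test(pol$theta[truth == "AA"],
                                        pol$theta[truth == "AB"]))
  expect_gt(ks$p.value, 0.05)
  # unknown pattern: explicit failure
  expect_error(simulate_intensities(g, "nonsense", seed = 1), "unknown")
  # determinism
  expect_identical(simulate_intensities(g, "standard", seed = 9),
                   simulate_intensities(g, "standard", seed = 9))
})
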