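# zero-variance filter, flank rule, designability surrogate, spread selection

mk_pu <- function(pos, A = 0L, C = 0L, G = 0L, T = 0L) {
  data.table::data.table(contig = "c1", pos0 = pos, A = A, C = C, G = G, T = T,
                         depth = A + C + G + T)
}
cand1 <- data.table::data.table(contig = "c1", pos0 = 10L, ref = "C", alt = "T")

test_that("zero-variance filter demands within-line uniformity on both sides", {
  # A: 10/10 C; B: 8/8 T -> pass
  r <- fixed_allele_filter(cand1, mk_pu(10L, C = 10L), mk_pu(10L, T = 8L))
  expect_true(r$fixed_ok)
  # B mixed 7 T + 1 C (homeolog signature) -> fail
  r2 <- fixed_allele_filter(cand1, mk_pu(10L, C = 10L), mk_pu(10L, T = 7L, C = 1L))
  expect_false(r2$fixed_ok)
  expect_equal(r2$fixed_reason, "mixed_query_line")
  # A mixed 9 C + 1 G -> fail
  r3 <- fixed_allele_filter(cand1, mk_pu(10L, C = 9L, G = 1L), mk_pu(10L, T = 8L))
  expect_equal(r3$fixed_reason, "mixed_ref_line")
  # zero depth in a line gets its own reason code
  r4 <- fixed_allele_filter(cand1, mk_pu(99L, C = 5L), mk_pu(10L, T = 8L))
  expect_equal(r4$fixed_reason, "zero_depth_ref_line")
})

test_that("flank rule enforces 100 clean bases either side, boundary inclusive", {
  cl <- c(c1 = 400L)
  cand <- data.table::data.table(contig = "c1", pos0 = c(150L, 50L, 150L))
  # nearest other variant at distance 110 -> pass
  v1 <- data.frame(contig = "c1", pos0 = c(150L, 260L))
  expect_true(flank_filter(cand[1], cl, v1)$flank_ok)
  # left flank 50 < 100 -> fail
  expect_equal(flank_filter(cand[2], cl, v1)$flank_reason, "short_left_flank")
  # another variant exactly 100 away -> fail (inclusive window)
  v2 <- data.frame(contig = "c1", pos0 = c(150L, 250L))
  expect_equal(flank_filter(cand[3], cl, v2)$flank_reason,
               "secondary_variant_in_flank")
  # 101 away -> pass
  v3 <- data.frame(contig = "c1", pos0 = c(150L, 251L))
  expect_true(flank_filter(cand[3], cl, v3)$flank_ok)
})

test_that("filters compose order-independently", {
  set.seed(8)
  tr <- make_hexaploid(1, 20000, 0.03, 40, seed = 9)
  run <- snp_discovery_run(tr, min_len = 1000, max_len = 4000, depth = 15,
                           error_rate = 0.001, seed = 10)
  cl <- stats::setNames(nchar(run$contigs), names(run$contigs))
  vp <- run$calls[run$calls$alt_frac >= 0.35, c("contig", "pos0")]
  cand <- run$calls[run$calls$candidate == TRUE, ]
  a <- flank_filter(fixed_allele_filter(cand, run$pileup_ref, run$pileup_query),
                    cl, vp)
  b <- fixed_allele_filter(flank_filter(cand, cl, vp),
                           run$pileup_ref, run$pileup_query)
  expect_equal(a$fixed_ok & a$flank_ok, b$fixed_ok & b$flank_ok)
})

test_that("designability surrogate scores and thresholds as declared", {
  clean <- paste(rep("ACGTT", 20), collapse = "") # 100 bp, GC 40%
  s <- designability_score(clean, clean)
  expect_equal(s$score, 1.0)
  expect_true(s$pass)
  # two secondary variants inside the 60 bp window: 1 - 0.6 = 0.4, reject
  s2 <- designability_score(clean, clean, secondary_offsets = c(-10L, 25L))
  expect_equal(s2$score, 0.4)
  expect_false(s2$pass)
  # GC 0.75 plus one ambiguous base: 1 - 0.4 = 0.6, pass (threshold inclusive)
  gc_rich <- paste(rep("GGGC", 25), collapse = "")
  right_amb <- paste0("N", substring(gc_rich, 2))
  s3 <- designability_score(gc_rich, right_amb)
  expect_equal(s3$score, 0.6)
  expect_true(s3$pass)
  # homopolymer of 6 within 20 bp of the SNP
  hp <- paste0(paste(rep("ACGT", 23), collapse = ""), "AAAAAACG")
  expect_equal(designability_score(hp, clean)$penalties[["homopolymer"]], 0.2)
  expect_error(designability_score("ACGT", clean), "exactly 100")
})

test_that("spread selection is the exact max-min optimum", {
  # 10 evenly spaced genes, quota 5: every other candidate
  cand <- data.frame(contig = sprintf("t%02d", 1:10))
  hom <- data.frame(contig = cand$contig, chromosome = 1,
                    gene_id = sprintf("g%d", 1:10), gene_pos = seq(0, 90, 10))
  sel <- spread_select(cand, hom, 5)
  expect_equal(sel$gene_pos, c(0, 20, 40, 60, 80))
  # quota >= candidates: all selected (with a shortfall message)
  expect_message(sel2 <- spread_select(cand, hom, 20), "selecting all")
  expect_equal(nrow(sel2), 10)
  # brute-force oracle on random instances (n <= 12)
  set.seed(11)
  for (i in 1:8) {
    n <- sample(5:12, 1)
    m <- sample(2:(n - 1), 1)
    pos <- sort(sample(0:500, n))
    hom_i <- data.frame(contig = sprintf("c%02d", 1:n), chromosome = 1,
                        gene_id = sprintf("g%d", 1:n), gene_pos = pos)
    sel_i <- spread_select(data.frame(contig = hom_i$contig), hom_i, m)
    got <- min(diff(sort(sel_i$gene_pos)))
    combs <- utils::combn(pos, m)
    best <- max(apply(combs, 2, function(v) min(diff(sort(v)))))
    expect_equal(got, best)
  }
})

test_that("panel assembly preserves tranche provenance and rejects collisions", {
  mk <- function(n, offset) data.frame(contig = sprintf("c%05d", offset + 1:n),
                                       pos0 = 100L)
  panel <- assemble_panel(list(cdna = mk(252, 0), genomic_synteny = mk(288, 1000),
                               genomic_intergenic = mk(228, 5000)))
  cnt <- attr(panel, "counts")
  expect_equal(unname(cnt[["total"]]), 768)
  expect_equal(unname(cnt[["cdna"]]), 252)
  expect_equal(unname(cnt[["genomic_synteny"]]), 288)
  expect_equal(unname(cnt[["genomic_intergenic"]]), 228)
  expect_equal(assemble_panel(list())[, .N], 0)
  expect_error(assemble_panel(list(a = mk(5, 0), b = mk(5, 0))), "duplicate")
})
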