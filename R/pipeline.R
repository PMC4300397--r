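#' Run the reduced-representation SNP discovery pipeline on a synthetic
#' hexaploid
#'
#' Digests both parental genomes, size-selects fragments, simulates
#' paired-end reads for both lines, maps them against parent-A contigs,
#' builds per-line pileups, calls variants in the query line and applies
#' the zero-variance parental allele filter.
#'
#' Two reference modes are supported. The default uses all subgenome
#' contigs with unique-only mapping (the intended marker-development
#' workflow: reads from locally undiverged homeologous copies are dropped
#' as non-unique). `collapsed = TRUE` emulates an assembly that collapsed
#' the subgenomes: only subgenome-1 contigs form the reference, mapping
#' keeps best hits regardless of ties and tolerates enough mismatches for
#' homeologous reads to cross-map, so inter-subgenome variation shows up
#' as within-line mixed pileup columns -- the artifact the zero-variance
#' filter exists to reject.
#'
#' @param truth a [make_hexaploid()] object
#' @param site,cut_offset,min_len,max_len digest parameters
#' @param insert_len,read_len,depth,error_rate read simulation parameters
#' @param profile a [call_profile()]
#' @param collapsed collapse the subgenomes into a one-copy reference?
#' @param max_mismatches mapping mismatch cap (default 3; 10 when
#'   collapsed)
#' @param unique_only drop reads with tied best hits (default: not
#'   collapsed)
#' @param k seed k-mer length
#' @param seed integer seed for read simulation
#' @return list of class `discovery_run`: `contigs`, `contig_meta`,
#'   `pileup_ref`, `pileup_query`, `calls` (all evaluated columns),
#'   `candidates` (with zero-variance flags), `map_stats`, parameters
#' @export
snp_discovery_run <- function(truth, site = "GAATTC", cut_offset = 1L,
                              min_len = 2000L, max_len = 4000L,
                              insert_len = 300L, read_len = 101L, depth = 20,
                              error_rate = 0.001,
                              profile = call_profile("genomic"),
                              collapsed = FALSE,
                              max_mismatches = if (collapsed) 10L else 3L,
                              unique_only = !collapsed, k = 21L, seed = 1) {
  stopifnot(inherits(truth, "hexaploid_truth"))
  frag_A <- digest_genome(truth$parent_A, site, cut_offset, min_len, max_len)
  frag_B <- digest_genome(truth$parent_B, site, cut_offset, min_len, max_len)

  ref_frags <- if (collapsed) frag_A[grepl("_s1$", seq_id)] else frag_A
  contigs <- stats::setNames(ref_frags$seq, ref_frags$frag_id)
  contig_meta <- ref_frags[, .(frag_id, seq_id, start0, end0, length)]

  reads_A <- simulate_reads(frag_A, insert_len, read_len, depth, error_rate,
                            seed = seed + 1L)
  reads_B <- simulate_reads(frag_B, insert_len, read_len, depth, error_rate,
                            seed = seed + 2L)
  as_vec <- function(rd) stats::setNames(
    c(rd$seq1, rd$seq2), c(paste0(rd$read_id, "/1"), paste0(rd$read_id, "/2")))

  index <- index_reference(contigs, k = k)
  aln_A <- map_reads(as_vec(reads_A), index, max_mismatches, unique_only)
  aln_B <- map_reads(as_vec(reads_B), index, max_mismatches, unique_only)
  pu_A <- pileup(aln_A)
  pu_B <- pileup(aln_B)
  calls <- call_variants(pu_B, contigs, profile)
  cand <- calls[calls$candidate == TRUE, ]
  cand <- fixed_allele_filter(cand, pu_A, pu_B)

  structure(list(
    contigs = contigs, contig_meta = contig_meta,
    pileup_ref = pu_A, pileup_query = pu_B,
    calls = calls, candidates = cand,
    map_stats = list(ref_line = attr(aln_A, "stats"),
                     query_line = attr(aln_B, "stats")),
    profile = profile, collapsed = collapsed,
    params = list(site = site, cut_offset = cut_offset, min_len = min_len,
                  max_len = max_len, insert_len = insert_len,
                  read_len = read_len, depth = depth, error_rate = error_rate,
                  max_mismatches = max_mismatches, unique_only = unique_only,
                  k = k, seed = seed)
  ), class = "discovery_run")
}

#' @export
print.discovery_run <- function(x, ...) {
  cat(sprintf(
    "discovery_run (%s reference): %d contig(s), %d evaluated column(s), %d candidate(s), %d passing zero-variance\n",
    if (x$collapsed) "collapsed" else "per-subgenome", length(x$contigs),
    nrow(x$calls), nrow(x$candidates), sum(x$candidates$fixed_ok)))
  invisible(x)
}

# locate genome positions on reference contigs.
# by = "seq_id": exact subgenome sequence match (per-subgenome reference);
# by = "chrom":  subgenome ignored (collapsed reference).
.locate_on_contigs <- function(contig_meta, seq_id, pos0, by = c("seq_id", "chrom")) {
  by <- match.arg(by)
  meta <- data.table::copy(contig_meta)
  q <- data.table::data.table(seq_id = seq_id, pos0 = pos0, qi = seq_along(pos0))
  if (by == "chrom") {
    meta[, chrom_id := sub("_s[0-9]+$", "", seq_id)]
    q[, chrom_id := sub("_s[0-9]+$", "", seq_id)]
    j <- meta[q, on = .(chrom_id, start0 <= pos0, end0 > pos0), nomatch = NULL,
              .(qi = qi, frag_id = frag_id, contig_pos0 = i.pos0 - x.start0)]
  } else {
    j <- meta[q, on = .(seq_id, start0 <= pos0, end0 > pos0), nomatch = NULL,
              .(qi = qi, frag_id = frag_id, contig_pos0 = i.pos0 - x.start0)]
  }
  out <- data.table::data.table(qi = seq_along(pos0))
  merge(out, j, by = "qi", all.x = TRUE, sort = TRUE)
}

#' Score a discovery run against the generating truth
#'
#' Computes, for true allelic SNPs, the retention of the zero-variance
#' filter over the *assayable denominator* -- SNP positions that landed on
#' a reference contig and are covered at the profile's minimum depth in
#' both lines -- and, for homeologous variant positions, the rejection rate
#' among those that surfaced as variant candidates.
#'
#' @param run a [snp_discovery_run()] result
#' @param truth the generating [make_hexaploid()] object
#' @return list: `snp` (per-SNP table + `n_assayable`, `n_retained`,
#'   `retention`), `homeolog` (`n_candidates`, `n_rejected`, `rejection`)
#' @export
evaluate_discovery <- function(run, truth) {
  ts <- truth$true_snps
  loc <- .locate_on_contigs(run$contig_meta, ts$seq_id, ts$pos0,
                            by = if (run$collapsed) "chrom" else "seq_id")
  snp <- data.table::data.table(
    seq_id = ts$seq_id, pos0 = ts$pos0, ref = ts$ref, alt = ts$alt,
    frag_id = loc$frag_id, contig_pos0 = loc$contig_pos0)
  dr <- run$pileup_ref[, .(contig, pos0, depth_ref_line = depth)]
  dq <- run$pileup_query[, .(contig, pos0, depth_query_line = depth)]
  snp <- merge(snp, dr, by.x = c("frag_id", "contig_pos0"),
               by.y = c("contig", "pos0"), all.x = TRUE, sort = FALSE)
  snp <- merge(snp, dq, by.x = c("frag_id", "contig_pos0"),
               by.y = c("contig", "pos0"), all.x = TRUE, sort = FALSE)
  snp[is.na(depth_ref_line), depth_ref_line := 0L]
  snp[is.na(depth_query_line), depth_query_line := 0L]
  md <- run$profile$min_depth
  snp[, assayable := !is.na(frag_id) & depth_ref_line >= md & depth_query_line >= md]
  pass <- run$candidates[run$candidates$fixed_ok == TRUE, c("contig", "pos0", "alt")]
  snp[, retained := FALSE]
  hit <- merge(snp[, .(frag_id, contig_pos0, alt, i = .I)], pass,
               by.x = c("frag_id", "contig_pos0", "alt"),
               by.y = c("contig", "pos0", "alt"))
  snp[hit$i, retained := TRUE]

  hv <- truth$homeolog_variants
  hloc <- .locate_on_contigs(run$contig_meta,
                             paste0("chr", hv$chrom, "_s1"), hv$pos0,
                             by = if (run$collapsed) "chrom" else "seq_id")
  hkeys <- data.table::data.table(frag_id = hloc$frag_id,
                                  contig_pos0 = hloc$contig_pos0)
  hkeys <- hkeys[!is.na(frag_id)]
  cand <- data.table::as.data.table(run$candidates)
  hcand <- merge(cand, unique(hkeys), by.x = c("contig", "pos0"),
                 by.y = c("frag_id", "contig_pos0"))
  n_hc <- nrow(hcand)
  n_rej <- sum(!hcand$fixed_ok)

  list(
    snp = list(table = snp[], n_assayable = sum(snp$assayable),
               n_retained = sum(snp$retained & snp$assayable),
               retention = if (sum(snp$assayable) > 0)
                 sum(snp$retained & snp$assayable) / sum(snp$assayable)
               else NA_real_),
    homeolog = list(n_candidates = n_hc, n_rejected = n_rej,
                    rejection = if (n_hc > 0) n_rej / n_hc else NA_real_)
  )
}

#' Write discovery candidates as a VCF-like tab table
#'
#' Columns: CHROM (contig), POS0, REF, ALT, DEPTH_REF, DEPTH_QUERY,
#' ALT_FRAC, FLAGS.
#'
#' @param candidates candidate table with zero-variance flags (from
#'   [snp_discovery_run()] or [fixed_allele_filter()])
#' @param path output file
#' @export
write_candidates <- function(candidates, path) {
  d <- data.table::as.data.table(candidates)
  out <- data.table::data.table(
    CHROM = d$contig, POS0 = d$pos0, REF = d$ref, ALT = d$alt,
    DEPTH_REF = if ("depth_r" %in% names(d)) d$depth_r else NA_integer_,
    DEPTH_QUERY = if ("depth_q" %in% names(d)) d$depth_q else d$depth,
    ALT_FRAC = round(d$alt_frac, 4),
    FLAGS = if ("fixed_reason" %in% names(d)) d$fixed_reason else "")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
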