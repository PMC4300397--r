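#' Build an exact k-mer seed index over reference contigs
#'
#' Records every position of every k-mer on the forward strand of the
#' contigs (queries are probed in both orientations, which is equivalent to
#' indexing both strands). K-mers occurring at more than `max_multiplicity`
#' positions are marked repetitive and removed from the seed lookup; their
#' loci are still reachable through neighbouring seeds.
#'
#' @param contigs named character vector of reference sequences
#' @param k seed length (>= 11)
#' @param max_multiplicity maximum number of positions a usable seed may
#'   occur at
#' @return object of class `seed_index`
#' @export
index_reference <- function(contigs, k = 21L, max_multiplicity = 8L) {
  stopifnot(k >= 11, length(contigs) > 0, !is.null(names(contigs)))
  lens <- nchar(contigs)
  short <- lens < k
  if (any(short))
    warning(sprintf("%d contig(s) shorter than k = %d excluded from index",
                    sum(short), k))
  keep <- contigs[!short]
  if (length(keep) == 0) {
    dt <- data.table::data.table(kmer = character(0), contig = character(0),
                                 pos0 = integer(0))
  } else {
    dt <- data.table::rbindlist(lapply(names(keep), function(id) {
      L <- nchar(keep[[id]])
      st <- seq_len(L - k + 1L)
      data.table::data.table(kmer = substring(keep[[id]], st, st + k - 1L),
                             contig = id, pos0 = st - 1L)
    }))
  }
  dt[, n_hits := .N, by = kmer]
  repetitive <- unique(dt$kmer[dt$n_hits > max_multiplicity])
  lookup <- dt[n_hits <= max_multiplicity][, n_hits := NULL]
  data.table::setkey(lookup, kmer)
  structure(list(lookup = lookup, k = as.integer(k),
                 contigs = contigs, contig_len = stats::setNames(lens, names(contigs)),
                 repetitive = repetitive,
                 max_multiplicity = as.integer(max_multiplicity)),
            class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("seed_index: %d contig(s), k = %d, %d seed positions, %d repetitive k-mer(s)\n",
              length(x$contigs), x$k, nrow(x$lookup), length(x$repetitive)))
  invisible(x)
}

#' Map reads to a seed index with full-length ungapped verification
#'
#' Each read is probed at three seed offsets (start, middle, end) in both
#' orientations; every seeded locus is verified by full-length comparison
#' allowing at most `max_mismatches` substitutions (no gaps). With
#' `unique_only`, reads whose best mismatch count is achieved at more than
#' one locus are discarded (equal-score ties count as non-unique, so reads
#' from locally identical homeologous copies are dropped). Without it, the
#' single best locus is kept, ties broken deterministically by
#' (contig, position, strand).
#'
#' @param reads named character vector of read sequences
#' @param index a [index_reference()] object
#' @param max_mismatches maximum substitutions tolerated over the read
#' @param unique_only discard reads with tied best-score loci?
#' @return data.table (`read`, `contig`, `pos0`, `strand`, `mm`, `qseq`
#'   where `qseq` is the read oriented to the reference forward strand);
#'   mapping statistics in attribute `"stats"`
#' @export
map_reads <- function(reads, index, max_mismatches = 3L, unique_only = TRUE) {
  stopifnot(inherits(index, "seed_index"), !is.null(names(reads)))
  k <- index$k
  empty <- data.table::data.table(read = character(0), contig = character(0),
                                  pos0 = integer(0), strand = character(0),
                                  mm = integer(0), qseq = character(0))
  if (length(reads) == 0 || nrow(index$lookup) == 0) {
    attr(empty, "stats") <- list(n_reads = length(reads), n_mapped = 0L,
                                 n_nonunique = 0L, n_unmapped = length(reads))
    return(empty)
  }

  rlen <- nchar(reads)
  cand_list <- vector("list", 2)
  oriented <- list("+" = unname(reads), "-" = revcomp(unname(reads)))
  for (oi in 1:2) {
    strand_chr <- names(oriented)[oi]
    q <- oriented[[oi]]
    # three seed offsets per read: start, middle, end
    probe <- data.table::data.table(
      read_i = rep(seq_along(q), 3L),
      off = c(rep(0L, length(q)),
              pmax((rlen - k) %/% 2L, 0L),
              pmax(rlen - k, 0L)))
    probe <- unique(probe)
    probe <- probe[rlen[read_i] >= k]
    probe[, kmer := substring(q[read_i], off + 1L, off + k)]
    hits <- index$lookup[probe, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(hits) == 0) next
    hits[, pos0 := pos0 - off]
    hits <- hits[pos0 >= 0 & pos0 + rlen[read_i] <= index$contig_len[contig]]
    hits <- unique(hits[, .(read_i, contig, pos0)])
    hits[, strand := strand_chr]
    cand_list[[oi]] <- hits
  }
  cand <- data.table::rbindlist(cand_list)
  stats0 <- list(n_reads = length(reads))
  if (nrow(cand) == 0) {
    attr(empty, "stats") <- c(stats0, list(n_mapped = 0L, n_nonunique = 0L,
                                           n_unmapped = length(reads)))
    return(empty)
  }

  qs <- ifelse(cand$strand == "+", oriented[["+"]][cand$read_i],
               oriented[["-"]][cand$read_i])
  ref <- substring(index$contigs[cand$contig], cand$pos0 + 1L,
                   cand$pos0 + rlen[cand$read_i])
  cand[, mm := hamming_pairs(qs, ref)]
  cand <- cand[mm <= max_mismatches]
  if (nrow(cand) == 0) {
    attr(empty, "stats") <- c(stats0, list(n_mapped = 0L, n_nonunique = 0L,
                                           n_unmapped = length(reads)))
    return(empty)
  }
  cand[, best := min(mm), by = read_i]
  cand <- cand[mm == best]
  data.table::setorder(cand, read_i, contig, pos0, strand)
  nloc <- cand[, .(n_loci = data.table::uniqueN(paste(contig, pos0))), by = read_i]
  chosen <- cand[!duplicated(read_i)]
  chosen <- merge(chosen, nloc, by = "read_i", sort = FALSE)
  n_tied <- sum(chosen$n_loci > 1L)
  if (unique_only) chosen <- chosen[n_loci == 1L]

  out <- data.table::data.table(
    read = names(reads)[chosen$read_i], contig = chosen$contig,
    pos0 = chosen$pos0, strand = chosen$strand, mm = chosen$mm,
    qseq = ifelse(chosen$strand == "+", oriented[["+"]][chosen$read_i],
                  oriented[["-"]][chosen$read_i]))
  attr(out, "stats") <- c(stats0, list(
    n_mapped = nrow(out), n_nonunique = n_tied,
    n_unmapped = length(reads) - nrow(out)))
  out
}

#' Per-position base counts from ungapped alignments
#'
#' @param alignments data.table from [map_reads()]
#' @param contig_len named lengths of the reference contigs (used to reject
#'   alignments overrunning a contig end)
#' @return data.table (`contig`, `pos0`, `A`, `C`, `G`, `T`, `depth`);
#'   zero-coverage positions are omitted
#' @export
pileup <- function(alignments, contig_len = NULL) {
  if (nrow(alignments) == 0)
    return(data.table::data.table(contig = character(0), pos0 = integer(0),
                                  A = integer(0), C = integer(0), G = integer(0),
                                  T = integer(0), depth = integer(0)))
  lens <- nchar(alignments$qseq)
  if (!is.null(contig_len)) {
    over <- alignments$pos0 + lens > contig_len[alignments$contig]
    if (any(over)) stop(sprintf("%d alignment(s) overrun contig ends", sum(over)))
  }
  bases <- unlist(strsplit(alignments$qseq, "", fixed = TRUE), use.names = FALSE)
  long <- data.table::data.table(
    contig = rep.int(alignments$contig, lens),
    pos0 = rep.int(alignments$pos0, lens) + (sequence(lens) - 1L),
    base = bases)
  counts <- long[base %in% DNA_BASES, .(count = .N), by = .(contig, pos0, base)]
  wide <- data.table::dcast(counts, contig + pos0 ~ base, value.var = "count",
                            fill = 0L)
  for (b in DNA_BASES) if (!b %in% names(wide)) wide[, (b) := 0L]
  data.table::setcolorder(wide, c("contig", "pos0", DNA_BASES))
  wide[, depth := A + C + G + T]
  data.table::setorder(wide, contig, pos0)
  wide[]
}

#' Variant-calling threshold profiles
#'
#' `genomic`: depth >= 8 and variant fraction >= 0.35 (inclusive), assumed
#' ploidy 3. `cdna`: depth >= 3 and variant fraction >= 0.30, ploidy 3.
#' The ploidy field records the assumed genome copy number; candidate
#' acceptance tolerates exactly one alternate base at or above the variant
#' fraction (columns with two such bases are rejected as multi-allelic).
#'
#' @param name "genomic" or "cdna", or pass explicit values
#' @param min_depth,min_variant_fraction,ploidy override profile fields
#' @return list of class `call_profile`
#' @export
call_profile <- function(name = c("genomic", "cdna"), min_depth = NULL,
                         min_variant_fraction = NULL, ploidy = 3L) {
  name <- match.arg(name)
  def <- switch(name,
                genomic = list(min_depth = 8L, min_variant_fraction = 0.35),
                cdna = list(min_depth = 3L, min_variant_fraction = 0.30))
  p <- list(name = name,
            min_depth = if (is.null(min_depth)) def$min_depth else min_depth,
            min_variant_fraction = if (is.null(min_variant_fraction))
              def$min_variant_fraction else min_variant_fraction,
            ploidy = ploidy)
  stopifnot(p$min_depth >= 1, p$min_variant_fraction > 0,
            p$min_variant_fraction <= 1)
  class(p) <- "call_profile"
  p
}

#' Call variant candidates from a query-line pileup
#'
#' A column is a candidate iff query depth >= `min_depth`, the most frequent
#' non-reference base reaches the profile's variant fraction, and exactly one
#' alternate base does so (single-variant rule; columns where two alternate
#' bases reach it are rejected as multi-allelic).
#'
#' @param pileup_query pileup of the query line (from [pileup()])
#' @param reference named character vector of reference contigs
#' @param profile a [call_profile()]
#' @return data.table of all evaluated columns: `contig`, `pos0`, `ref`,
#'   `alt`, `depth`, `alt_count`, `alt_frac`, `candidate`, `reason`
#' @export
call_variants <- function(pileup_query, reference, profile = call_profile("genomic")) {
  stopifnot(inherits(profile, "call_profile"))
  pu <- data.table::copy(pileup_query)
  if (nrow(pu) == 0) {
    pu[, c("ref", "alt", "alt_count", "alt_frac", "candidate", "reason") :=
         list(character(0), character(0), integer(0), numeric(0), logical(0),
              character(0))]
    return(pu)
  }
  pu[, ref := substring(reference[contig], pos0 + 1L, pos0 + 1L)]
  cnt <- as.matrix(pu[, .SD, .SDcols = DNA_BASES])
  ridx <- match(pu$ref, DNA_BASES)
  alt_cnt <- cnt
  alt_cnt[cbind(seq_len(nrow(cnt)), ridx)] <- -1L # exclude ref from alt choice
  top <- max.col(alt_cnt, ties.method = "first")
  pu[, alt := DNA_BASES[top]]
  pu[, alt_count := alt_cnt[cbind(.I, top)]]
  pu[alt_count < 0L, alt_count := 0L]
  pu[, alt_frac := ifelse(depth > 0, alt_count / depth, 0)]
  frac_all <- sweep(pmax(alt_cnt, 0L), 1, pmax(pu$depth, 1L), "/")
  n_over <- rowSums(frac_all >= profile$min_variant_fraction)
  pu[, reason := "candidate"]
  pu[n_over > 1L, reason := "multi_allelic"]
  pu[alt_frac < profile$min_variant_fraction, reason := "low_fraction"]
  pu[depth < profile$min_depth, reason := "low_depth"]
  pu[, candidate := reason == "candidate"]
  pu[]
}
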