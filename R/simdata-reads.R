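#' Simulate paired-end reads from size-selected fragments
#'
#' Inserts are drawn uniformly from each fragment at the requested mean base
#' coverage; mate 1 reads the insert 5' end on the forward strand, mate 2 the
#' 3' end reverse-complemented. With probability one half the physical strand
#' sequenced first is flipped (the mate sequences are swapped), so read
#' orientation carries no positional information. Substitution errors are
#' i.i.d. per base at `error_rate`. Fragments shorter than the insert are
#' skipped with a warning.
#'
#' @param fragments data.table from [digest_genome()] (columns `frag_id`,
#'   `seq`, and optionally `seq_id`/`start0` for provenance), or a named
#'   character vector of fragment sequences
#' @param insert_len insert size in bp
#' @param read_len read length in bp (<= `insert_len`)
#' @param depth target mean per-base coverage over the fragments
#' @param error_rate per-base substitution probability, `[0, 0.05)`
#' @param seed integer seed; output is bit-reproducible given it
#' @return data.table with one row per pair: `read_id`, `frag_id`,
#'   `insert_start0` (within fragment), `flipped`, `seq1`, `seq2`
#' @export
simulate_reads <- function(fragments, insert_len = 300L, read_len = 101L,
                           depth = 20, error_rate = 0.001, seed = 1) {
  stopifnot(read_len <= insert_len, error_rate >= 0, error_rate < 0.05)
  set.seed(seed)
  if (!is.data.frame(fragments)) {
    stopifnot(!is.null(names(fragments)))
    fragments <- data.table::data.table(frag_id = names(fragments),
                                        seq = unname(fragments))
  }
  lens <- nchar(fragments$seq)
  short <- lens < insert_len
  if (any(short))
    warning(sprintf("%d fragment(s) shorter than insert length skipped",
                    sum(short)))
  frg <- fragments[!short]
  lens <- lens[!short]
  if (nrow(frg) == 0) {
    return(data.table::data.table(read_id = character(0), frag_id = character(0),
                                  insert_start0 = integer(0), flipped = logical(0),
                                  seq1 = character(0), seq2 = character(0)))
  }
  n_pairs <- rpois(nrow(frg), depth * lens / (2 * read_len))
  idx <- rep.int(seq_len(nrow(frg)), n_pairs)
  if (length(idx) == 0) {
    return(data.table::data.table(read_id = character(0), frag_id = character(0),
                                  insert_start0 = integer(0), flipped = logical(0),
                                  seq1 = character(0), seq2 = character(0)))
  }
  span <- lens[idx] - insert_len
  start0 <- floor(runif(length(idx)) * (span + 1)) # 0..span inclusive
  fseq <- frg$seq[idx]
  m1 <- substring(fseq, start0 + 1L, start0 + read_len)
  m2 <- revcomp(substring(fseq, start0 + insert_len - read_len + 1L,
                          start0 + insert_len))
  flip <- runif(length(idx)) < 0.5
  s1 <- ifelse(flip, m2, m1)
  s2 <- ifelse(flip, m1, m2)
  if (error_rate > 0) {
    s1 <- .add_substitution_errors(s1, error_rate)
    s2 <- .add_substitution_errors(s2, error_rate)
  }
  data.table::data.table(
    read_id = sprintf("%s_r%06d", frg$frag_id[idx], sequence(n_pairs)),
    frag_id = frg$frag_id[idx],
    insert_start0 = as.integer(start0), flipped = flip,
    seq1 = s1, seq2 = s2)
}

# i.i.d. substitution errors on a character vector of reads
.add_substitution_errors <- function(seqs, rate) {
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0)
  for (i in hit) {
    ch <- .chars(seqs[i])
    pos <- sample.int(length(ch), n_err[i])
    seqs[i] <- .collapse(.mutate_bases(ch, pos))
  }
  seqs
}

#' Simulate 3'-biased single-end cDNA reads
#'
#' Emulates a 3'-anchored transcript library: single-end reads drawn
#' uniformly from the terminal `tail_len` bases of each supplied transcript
#' sequence. No expression-level model is applied; every transcript gets the
#' same target coverage of its sampled tail.
#'
#' @param transcripts named character vector of transcript sequences
#' @param tail_len length of the 3' window reads are drawn from
#' @inheritParams simulate_reads
#' @return data.table with `read_id`, `transcript`, `start0`
#'   (transcript coordinates), `seq`
#' @export
simulate_cdna_reads <- function(transcripts, tail_len = 500L, read_len = 101L,
                                depth = 10, error_rate = 0.001, seed = 1) {
  stopifnot(!is.null(names(transcripts)), error_rate >= 0, error_rate < 0.05)
  set.seed(seed)
  lens <- nchar(transcripts)
  keep <- lens >= read_len
  if (!all(keep)) warning(sprintf("%d transcript(s) shorter than read length skipped",
                                  sum(!keep)))
  tr <- transcripts[keep]; lens <- lens[keep]
  win <- pmin(lens, tail_len)
  n_reads <- rpois(length(tr), depth * win / read_len)
  idx <- rep.int(seq_along(tr), n_reads)
  if (length(idx) == 0)
    return(data.table::data.table(read_id = character(0), transcript = character(0),
                                  start0 = integer(0), seq = character(0)))
  lo <- lens[idx] - win[idx]                       # window start (0-based)
  span <- win[idx] - read_len
  start0 <- lo + floor(runif(length(idx)) * (pmax(span, 0) + 1))
  s <- substring(tr[idx], start0 + 1L, start0 + read_len)
  if (error_rate > 0) s <- .add_substitution_errors(s, error_rate)
  data.table::data.table(
    read_id = sprintf("%s_c%06d", names(tr)[idx], sequence(n_reads)),
    transcript = names(tr)[idx], start0 = as.integer(start0), seq = s)
}
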