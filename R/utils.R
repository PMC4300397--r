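DNA_BASES <- c("A", "C", "G", "T")

#' Random DNA sequence
#'
#' @param n sequence length in bases
#' @return a single character string of A/C/G/T
#' @export
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement of DNA strings
#'
#' @param x character vector of A/C/G/T sequences
#' @return character vector of reverse complements
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Substitute characters at given positions with a uniformly chosen *different*
# base. `chars` is a character vector of single bases; returns the edited vector.
.mutate_bases <- function(chars, idx) {
  if (length(idx) == 0) return(chars)
  old <- chars[idx]
  # draw an offset 1..3 in base order, cycling past the current base
  ord <- match(old, DNA_BASES)
  shift <- sample.int(3L, length(idx), replace = TRUE)
  chars[idx] <- DNA_BASES[((ord - 1L + shift) %% 4L) + 1L]
  chars
}

# split one string into a character vector of single bases
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.collapse <- function(ch) paste(ch, collapse = "")

# GC fraction of a character string (non-ACGT ignored in denominator)
.gc_frac <- function(s) {
  ch <- .chars(toupper(s))
  acgt <- ch %in% DNA_BASES
  if (!any(acgt)) return(NA_real_)
  mean(ch[acgt] %in% c("G", "C"))
}

# longest homopolymer run length in a string
.max_run <- function(s) {
  if (nchar(s) == 0) return(0L)
  r <- rle(.chars(s))
  max(r$lengths)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Write reads to FASTQ (Phred+33, constant quality)
#'
#' @param seqs named character vector of read sequences
#' @param path output file
#' @param qual single quality character applied to every base (default "I", Q40)
#' @export
write_fastq <- function(seqs, path, qual = "I") {
  s <- Biostrings::DNAStringSet(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep(qual, n), collapse = ""), character(1)))
  names(q) <- names(s)
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(s, Biostrings::PhredQuality(q)), path)
  invisible(path)
}

#' Write a genotype matrix as CSV
#'
#' Samples as rows, loci as columns, calls in \{AA, AB, BB, NA\}.
#'
#' @param geno character matrix of genotype calls
#' @param path output file
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(sample = rownames(geno), geno, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a genotype matrix written by [write_genotypes()]
#'
#' @param path CSV file
#' @return character matrix, samples as rows
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = "NA")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  mode(m) <- "character"
  m
}
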