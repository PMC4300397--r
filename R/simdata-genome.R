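#' Simulate a hexaploid genome with known allelic and homeologous variation
#'
#' Builds, for each pseudo-chromosome, an ancestral sequence and three
#' subgenome copies derived from it by independent substitution at rate
#' `homeolog_divergence / 2` per copy, so that the *pairwise* divergence
#' between any two subgenomes is approximately `homeolog_divergence`.
#' Two parental lines are then created: parent A carries the subgenome
#' sequences unchanged; parent B differs from A at `n_true_snps` true
#' allelic SNPs, each injected on exactly one subgenome copy at a position
#' where all three subgenomes agree (so allelic and homeologous variant
#' position sets are disjoint by construction).
#'
#' @param n_chromosomes number of pseudo-chromosomes
#' @param chrom_length length of each chromosome in bp (>= 1000)
#' @param homeolog_divergence target pairwise divergence between subgenomes,
#'   in `[0, 0.2]`
#' @param n_true_snps number of allelic SNPs between the parents
#' @param seed integer seed; the whole object is reproducible given it
#' @return an object of class `hexaploid_truth`: list with named sequence
#'   vectors `parent_A` and `parent_B` (ids `chr<i>_s<j>`), a `true_snps`
#'   data.frame (`chrom`, `subgenome`, `seq_id`, `pos0`, `ref`, `alt`),
#'   a `homeolog_variants` data.frame (`chrom`, `pos0`, `s1`, `s2`, `s3`),
#'   and the generating parameters.
#' @export
make_hexaploid <- function(n_chromosomes = 2, chrom_length = 50000,
                           homeolog_divergence = 0.03, n_true_snps = 300,
                           seed = 1) {
  stopifnot(chrom_length >= 1000,
            homeolog_divergence >= 0, homeolog_divergence <= 0.2,
            n_true_snps >= 0, n_chromosomes >= 1)
  set.seed(seed)
  q <- homeolog_divergence / 2

  parent_A <- character(0)
  hv_list <- vector("list", n_chromosomes)
  eligible <- vector("list", n_chromosomes) # positions where all subgenomes agree
  sub_chars <- vector("list", n_chromosomes)

  for (ci in seq_len(n_chromosomes)) {
    anc <- .chars(random_dna(chrom_length))
    subs <- vector("list", 3)
    for (s in 1:3) {
      ch <- anc
      idx <- which(runif(chrom_length) < q)
      subs[[s]] <- .mutate_bases(ch, idx)
    }
    sub_chars[[ci]] <- subs
    same <- subs[[1]] == subs[[2]] & subs[[2]] == subs[[3]]
    hv_pos <- which(!same) # 1-based
    hv_list[[ci]] <- data.frame(
      chrom = rep(ci, length(hv_pos)), pos0 = hv_pos - 1L,
      s1 = subs[[1]][hv_pos], s2 = subs[[2]][hv_pos], s3 = subs[[3]][hv_pos],
      stringsAsFactors = FALSE)
    eligible[[ci]] <- which(same)
    for (s in 1:3) parent_A[[sprintf("chr%d_s%d", ci, s)]] <- .collapse(subs[[s]])
  }

  n_elig <- sum(lengths(eligible))
  if (n_true_snps > n_elig)
    stop(sprintf("cannot place %d true SNPs: only %d collision-free positions",
                 n_true_snps, n_elig))

  # sample SNP sites uniformly over all (chrom, pos) with subgenome agreement
  pool <- do.call(rbind, lapply(seq_len(n_chromosomes), function(ci)
    cbind(ci, eligible[[ci]])))
  pick <- pool[sample.int(nrow(pool), n_true_snps), , drop = FALSE]

  parent_B_chars <- lapply(sub_chars, function(subs) lapply(subs, identity))
  if (n_true_snps > 0) {
    sg <- sample.int(3L, n_true_snps, replace = TRUE)
    refs <- character(n_true_snps); alts <- character(n_true_snps)
    for (i in seq_len(n_true_snps)) {
      ci <- pick[i, 1]; p <- pick[i, 2]; s <- sg[i]
      refs[i] <- parent_B_chars[[ci]][[s]][p]
      parent_B_chars[[ci]][[s]] <- .mutate_bases(parent_B_chars[[ci]][[s]], p)
      alts[i] <- parent_B_chars[[ci]][[s]][p]
    }
    true_snps <- data.frame(
      chrom = pick[, 1], subgenome = sg,
      seq_id = sprintf("chr%d_s%d", pick[, 1], sg),
      pos0 = pick[, 2] - 1L, ref = refs, alt = alts, stringsAsFactors = FALSE)
    true_snps <- true_snps[order(true_snps$chrom, true_snps$pos0), ]
    rownames(true_snps) <- NULL
  } else {
    true_snps <- data.frame(chrom = integer(0), subgenome = integer(0),
                            seq_id = character(0), pos0 = integer(0),
                            ref = character(0), alt = character(0))
  }

  parent_B <- character(0)
  for (ci in seq_len(n_chromosomes))
    for (s in 1:3)
      parent_B[[sprintf("chr%d_s%d", ci, s)]] <-
        .collapse(parent_B_chars[[ci]][[s]])

  structure(list(
    parent_A = parent_A, parent_B = parent_B,
    true_snps = true_snps,
    homeolog_variants = do.call(rbind, hv_list),
    n_chromosomes = n_chromosomes, chrom_length = chrom_length,
    homeolog_divergence = homeolog_divergence, seed = seed
  ), class = "hexaploid_truth")
}

#' @export
print.hexaploid_truth <- function(x, ...) {
  cat(sprintf(
    "hexaploid_truth: %d chromosome(s) x 3 subgenomes x %d bp\n  pairwise divergence target %.3f; %d homeolog-variant sites; %d true SNPs\n",
    x$n_chromosomes, x$chrom_length, x$homeolog_divergence,
    nrow(x$homeolog_variants), nrow(x$true_snps)))
  invisible(x)
}

#' Complete restriction digest with size selection
#'
#' Cuts a sequence at every exact occurrence of the recognition site, at
#' `cut_offset` bases into the site (EcoRI `G^AATTC` is `site = "GAATTC"`,
#' `cut_offset = 1`). Fragments are the maximal intervals between successive
#' cut positions; the full tiling is retained alongside the size-selected
#' subset.
#'
#' @param sequence a single DNA string
#' @param site recognition sequence (non-empty)
#' @param cut_offset cut position within the site, `0..nchar(site)`
#' @param min_len,max_len inclusive size-selection bounds
#' @return list with data.frames `fragments` (all, 0-based half-open
#'   `start0`/`end0`) and `selected` (length within bounds), plus the enzyme
#'   parameters
#' @export
digest_and_select <- function(sequence, site = "GAATTC", cut_offset = 1L,
                              min_len = 2000L, max_len = 4000L) {
  stopifnot(nchar(site) > 0, cut_offset >= 0, cut_offset <= nchar(site),
            min_len <= max_len, length(sequence) == 1)
  L <- nchar(sequence)
  m <- Biostrings::matchPattern(Biostrings::DNAString(site),
                                Biostrings::DNAString(sequence))
  cuts <- (Biostrings::start(m) - 1L) + as.integer(cut_offset)
  cuts <- sort(unique(cuts[cuts > 0 & cuts < L]))
  bounds <- c(0L, cuts, L)
  fragments <- data.frame(start0 = bounds[-length(bounds)], end0 = bounds[-1])
  fragments$length <- fragments$end0 - fragments$start0
  selected <- fragments[fragments$length >= min_len & fragments$length <= max_len, ]
  rownames(selected) <- NULL
  list(fragments = fragments, selected = selected,
       site = site, cut_offset = as.integer(cut_offset),
       min_len = min_len, max_len = max_len)
}

#' Digest every sequence of a genome and extract size-selected fragments
#'
#' @param seqs named character vector of sequences
#' @inheritParams digest_and_select
#' @return data.table with one row per selected fragment: `frag_id`,
#'   `seq_id`, `start0`, `end0`, `length`, `seq`
#' @export
digest_genome <- function(seqs, site = "GAATTC", cut_offset = 1L,
                          min_len = 2000L, max_len = 4000L) {
  stopifnot(!is.null(names(seqs)))
  out <- lapply(names(seqs), function(id) {
    d <- digest_and_select(seqs[[id]], site, cut_offset, min_len, max_len)
    sel <- d$selected
    if (nrow(sel) == 0) return(NULL)
    data.table::data.table(
      frag_id = sprintf("%s_f%04d", id, seq_len(nrow(sel))),
      seq_id = id, start0 = sel$start0, end0 = sel$end0, length = sel$length,
      seq = substring(seqs[[id]], sel$start0 + 1L, sel$end0))
  })
  data.table::rbindlist(out)
}
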