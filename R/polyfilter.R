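#' Zero-variance (100%-representation) parental allele filter
#'
#' The core polyploid screen: a candidate passes only if every read of the
#' reference line at its position carries the reference base and every read
#' of the query line carries the alternate base. Any within-line mixture --
#' the signature of collapsed homeologous copies -- fails. Evaluated on raw
#' counts, so sequencing errors trade off sensitivity.
#'
#' @param candidates data.table with `contig`, `pos0`, `ref`, `alt`
#' @param pileup_ref,pileup_query pileups ([pileup()]) of the reference and
#'   query lines
#' @return `candidates` with logical `fixed_ok` and character `fixed_reason`
#'   ("pass", "mixed_ref_line", "mixed_query_line", "zero_depth_ref_line",
#'   "zero_depth_query_line") appended
#' @export
fixed_allele_filter <- function(candidates, pileup_ref, pileup_query) {
  out <- data.table::as.data.table(candidates)
  key <- c("contig", "pos0")
  a <- pileup_ref[, c(key, DNA_BASES, "depth"), with = FALSE]
  data.table::setnames(a, c(DNA_BASES, "depth"), paste0(c(DNA_BASES, "depth"), "_r"))
  b <- pileup_query[, c(key, DNA_BASES, "depth"), with = FALSE]
  data.table::setnames(b, c(DNA_BASES, "depth"), paste0(c(DNA_BASES, "depth"), "_q"))
  out <- merge(out, a, by = key, all.x = TRUE, sort = FALSE)
  out <- merge(out, b, by = key, all.x = TRUE, sort = FALSE)
  for (cl in grep("_r$|_q$", names(out), value = TRUE))
    data.table::set(out, which(is.na(out[[cl]])), cl, 0L)

  cnt_r <- as.matrix(out[, paste0(DNA_BASES, "_r"), with = FALSE])
  cnt_q <- as.matrix(out[, paste0(DNA_BASES, "_q"), with = FALSE])
  ref_n <- cnt_r[cbind(seq_len(nrow(out)), match(out$ref, DNA_BASES))]
  alt_n <- cnt_q[cbind(seq_len(nrow(out)), match(out$alt, DNA_BASES))]

  fr <- rep("pass", nrow(out))
  fr[alt_n != out$depth_q] <- "mixed_query_line"
  fr[ref_n != out$depth_r] <- "mixed_ref_line"
  fr[out$depth_q == 0L] <- "zero_depth_query_line"
  fr[out$depth_r == 0L] <- "zero_depth_ref_line"
  data.table::set(out, j = "fixed_ok", value = fr == "pass")
  data.table::set(out, j = "fixed_reason", value = fr)
  out[, c(paste0(DNA_BASES, "_r"), paste0(DNA_BASES, "_q")) := NULL]
  out[]
}

#' Clean-flank filter
#'
#' A candidate passes iff it has at least `flank_len` bases of contig on
#' each side and no other variant position lies within `flank_len` bases
#' (inclusive window: a variant exactly `flank_len` away fails).
#'
#' @param candidates data.table with `contig`, `pos0`
#' @param contig_len named integer vector of contig lengths
#' @param variant_positions data.frame (`contig`, `pos0`) of *all* variant
#'   columns on the contigs -- candidates and rejected variants alike
#' @param flank_len required clean flank, bp
#' @return `candidates` with logical `flank_ok` and `flank_reason` appended
#' @export
flank_filter <- function(candidates, contig_len, variant_positions,
                         flank_len = 100L) {
  out <- data.table::as.data.table(candidates)
  vp <- data.table::as.data.table(variant_positions)
  n_near <- integer(nrow(out))
  for (ctg in unique(out$contig)) {
    vi <- sort(vp$pos0[vp$contig == ctg])
    ci <- which(out$contig == ctg)
    p <- out$pos0[ci]
    # variants in [p - flank, p + flank], excluding the candidate itself
    lo <- findInterval(p - flank_len - 0.5, vi)
    hi <- findInterval(p + flank_len + 0.5, vi)
    self <- vapply(p, function(pp) sum(vi == pp), integer(1))
    n_near[ci] <- hi - lo - self
  }
  left_ok <- out$pos0 >= flank_len
  right_ok <- (contig_len[out$contig] - out$pos0 - 1L) >= flank_len
  fr <- rep("pass", nrow(out))
  fr[n_near > 0L] <- "secondary_variant_in_flank"
  fr[!right_ok] <- "short_right_flank"
  fr[!left_ok] <- "short_left_flank"
  data.table::set(out, j = "flank_ok", value = fr == "pass")
  data.table::set(out, j = "flank_reason", value = fr)
  out[]
}

#' Default parameters of the designability surrogate
#'
#' Declared penalty weights for the assay designability score; these are
#' constants of this package's surrogate scorer, not a model of any vendor
#' tool. The acceptance threshold of 0.6 (inclusive) follows standard
#' GoldenGate design practice.
#'
#' @return list of weights, windows and the threshold
#' @export
designability_params <- function() {
  list(w_secondary = 0.3, secondary_window = 60L,
       w_gc = 0.2, gc_range = c(0.30, 0.70), gc_window = 60L,
       w_ambiguous = 0.2,
       w_homopolymer = 0.2, homopolymer_min = 6L, homopolymer_window = 20L,
       threshold = 0.6)
}

#' Assay designability score of a candidate's flanks
#'
#' `score = 1 - sum(penalties)`, floored at 0: 0.3 per secondary variant
#' within +/-60 bp of the SNP; 0.2 if GC content of the +/-60 bp window
#' falls outside `[0.30, 0.70]`; 0.2 per ambiguous (non-ACGT) base in the
#' flanks; 0.2 if a homopolymer run of >= 6 bp lies within +/-20 bp.
#' Assays scoring below 0.6 are rejected (threshold inclusive: 0.6 passes).
#'
#' @param left_flank,right_flank flanking sequences, exactly `flank_len` bp
#' @param secondary_offsets integer offsets (relative to the SNP, negative
#'   = left) of other variant positions near the assay
#' @param params see [designability_params()]
#' @param flank_len required flank length
#' @return list(`score`, `pass`, `penalties`)
#' @export
designability_score <- function(left_flank, right_flank,
                                secondary_offsets = integer(0),
                                params = designability_params(),
                                flank_len = 100L) {
  if (nchar(left_flank) != flank_len || nchar(right_flank) != flank_len)
    stop(sprintf("flanks must be exactly %d bp", flank_len))
  w <- params$secondary_window
  pen_sec <- params$w_secondary *
    sum(abs(secondary_offsets) <= w & secondary_offsets != 0)
  gc_win <- paste0(substring(left_flank, flank_len - params$gc_window + 1L, flank_len),
                   substring(right_flank, 1L, params$gc_window))
  gc <- .gc_frac(gc_win)
  pen_gc <- if (!is.na(gc) && (gc < params$gc_range[1] || gc > params$gc_range[2]))
    params$w_gc else 0
  n_ambig <- sum(!(.chars(toupper(paste0(left_flank, right_flank))) %in% DNA_BASES))
  pen_ambig <- params$w_ambiguous * n_ambig
  hp_l <- .max_run(substring(left_flank, flank_len - params$homopolymer_window + 1L,
                             flank_len))
  hp_r <- .max_run(substring(right_flank, 1L, params$homopolymer_window))
  pen_hp <- if (max(hp_l, hp_r) >= params$homopolymer_min) params$w_homopolymer else 0
  penalties <- c(secondary = pen_sec, gc = pen_gc, ambiguous = pen_ambig,
                 homopolymer = pen_hp)
  score <- max(0, 1 - sum(penalties))
  list(score = score, pass = score >= params$threshold, penalties = penalties)
}

# exact max-min selection of m points on a line; returns sorted indices into
# `pos` (ascending). Feasibility by greedy left-to-right scan; optimum gap by
# binary search over realized pairwise gaps; construction greedily picks the
# earliest (lowest-position) feasible points.
.select_maxmin <- function(pos, m) {
  n <- length(pos)
  o <- order(pos)
  p <- pos[o]
  if (m >= n) return(o)
  if (m == 1) return(o[1])
  count_at <- function(g) {
    cnt <- 1L; last <- p[1]
    for (i in 2:n) if (p[i] - last >= g) { cnt <- cnt + 1L; last <- p[i] }
    cnt
  }
  gaps <- sort(unique(as.vector(outer(p, p, "-"))))
  gaps <- gaps[gaps >= 0]
  lo <- 1L; hi <- length(gaps) # gaps[1] == 0 always feasible
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (count_at(gaps[mid]) >= m) lo <- mid else hi <- mid - 1L
  }
  gstar <- gaps[lo]
  sel <- 1L; last <- p[1]
  for (i in 2:n) {
    if (length(sel) == m) break
    if (p[i] - last >= gstar) { sel <- c(sel, i); last <- p[i] }
  }
  o[sel[seq_len(m)]]
}

#' Synteny-spread selection of assay candidates
#'
#' For each model-genome chromosome, selects up to the quota of candidates
#' maximizing the minimum pairwise gene-position gap (exact optimum: binary
#' search over achievable gaps with a greedy feasibility scan). Construction
#' picks the lowest positions compatible with the optimal gap, so the result
#' is deterministic given input order. Candidates without a homology entry
#' are excluded from this tranche.
#'
#' @param candidates data.frame with a `contig` column (one row per
#'   candidate assay)
#' @param homology data.frame (`contig`, `chromosome`, `gene_id`,
#'   `gene_pos`): best-hit homology of each contig to the model genome
#' @param quota_per_chromosome single number, or named vector by chromosome
#' @return subset of `candidates` with homology columns appended
#' @export
spread_select <- function(candidates, homology, quota_per_chromosome) {
  cand <- data.table::as.data.table(candidates)
  cand[, .row__ := .I]
  hom <- data.table::as.data.table(homology)
  stopifnot(!anyDuplicated(hom$contig))
  x <- merge(cand, hom, by = "contig", sort = FALSE)
  picked <- vector("list", length(unique(x$chromosome)))
  chroms <- sort(unique(x$chromosome))
  for (i in seq_along(chroms)) {
    xc <- x[chromosome == chroms[i]]
    data.table::setorder(xc, gene_pos, .row__)
    q <- if (length(quota_per_chromosome) > 1)
      quota_per_chromosome[[as.character(chroms[i])]] else quota_per_chromosome
    if (q > nrow(xc)) {
      message(sprintf("chromosome %s: quota %d exceeds %d candidates; selecting all",
                      chroms[i], q, nrow(xc)))
      picked[[i]] <- xc
    } else {
      idx <- .select_maxmin(xc$gene_pos, q)
      picked[[i]] <- xc[sort(idx)]
    }
  }
  out <- data.table::rbindlist(picked)
  data.table::setorder(out, .row__)
  out[, .row__ := NULL]
  out[]
}

#' Extract fixed-length flanks around candidates
#'
#' @param candidates data.table with `contig`, `pos0`
#' @param contigs named character vector of contig sequences
#' @param flank_len flank length, bp
#' @return `candidates` with `left_flank` and `right_flank` appended (NA
#'   where the contig is too short)
#' @export
extract_flanks <- function(candidates, contigs, flank_len = 100L) {
  out <- data.table::as.data.table(candidates)
  L <- nchar(contigs[out$contig])
  lf <- ifelse(out$pos0 >= flank_len,
               substring(contigs[out$contig], out$pos0 - flank_len + 1L, out$pos0),
               NA_character_)
  rf <- ifelse(L - out$pos0 - 1L >= flank_len,
               substring(contigs[out$contig], out$pos0 + 2L, out$pos0 + 1L + flank_len),
               NA_character_)
  out[, `:=`(left_flank = lf, right_flank = rf)]
  out[]
}

#' Assemble the assay panel from provenance-labelled tranches
#'
#' Concatenates tranche data.frames (e.g. cdna, genomic_synteny,
#' genomic_intergenic), labels each row with its tranche, and rejects any
#' duplicated assay position across tranches.
#'
#' @param tranches named list of data.frames, each with `contig` and `pos0`
#' @return data.table with a `tranche` column; per-tranche counts in
#'   attribute `"counts"`
#' @export
assemble_panel <- function(tranches) {
  stopifnot(is.list(tranches))
  if (length(tranches) == 0) {
    out <- data.table::data.table(contig = character(0), pos0 = integer(0),
                                  tranche = character(0))
    attr(out, "counts") <- c(total = 0L)
    return(out)
  }
  stopifnot(!is.null(names(tranches)))
  lab <- lapply(names(tranches), function(nm) {
    d <- data.table::as.data.table(tranches[[nm]])
    d[, tranche := nm]
    d
  })
  out <- data.table::rbindlist(lab, fill = TRUE)
  key <- paste(out$contig, out$pos0)
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop("duplicate assay positions across tranches: ",
         paste(utils::head(dup, 10), collapse = "; "))
  }
  out[, assay_id := sprintf("ASSAY_%05d", .I)]
  cnt <- c(table(out$tranche), total = nrow(out))
  attr(out, "counts") <- cnt
  out[]
}
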