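#' Two-point linkage analysis for a pair of RIL loci
#'
#' Lines scored at both loci with homozygous calls are informative
#' (heterozygous or missing calls are skipped). `R_obs` is the recombinant
#' fraction among informative lines; the per-meiosis estimate applies the
#' RIL-by-selfing correction \eqn{r = R/(2(1-R))}, clipped to 0..0.5. The
#' LOD is the base-10 binomial likelihood ratio at `R_hat = R_obs` against
#' `R = 0.5`.
#'
#' @param gA,gB character vectors of calls ("AA"/"BB"; others treated
#'   missing)
#' @return list (`n_informative`, `n_recombinant`, `R_obs`, `r`, `LOD`), or
#'   with `reason = "no informative lines"` when undefined
#' @export
two_point <- function(gA, gB) {
  stopifnot(length(gA) == length(gB))
  ok <- gA %in% c("AA", "BB") & gB %in% c("AA", "BB")
  n <- sum(ok)
  if (n == 0)
    return(list(n_informative = 0L, n_recombinant = NA_integer_,
                R_obs = NA_real_, r = NA_real_, LOD = NA_real_,
                reason = "no informative lines"))
  nr <- sum(gA[ok] != gB[ok])
  R <- nr / n
  r <- if (R >= 1) 0.5 else min(max(R / (2 * (1 - R)), 0), 0.5)
  LOD <- .lod_ril(nr, n)
  list(n_informative = n, n_recombinant = nr, R_obs = R, r = r, LOD = LOD)
}

# LOD = nR log10(Rhat/0.5) + nNR log10((1-Rhat)/0.5), Rhat = nR/n,
# with 0 * log10(0) = 0
.lod_ril <- function(nr, n) {
  R <- nr / n
  t1 <- if (nr > 0) nr * log10(R / 0.5) else 0
  t2 <- if (n - nr > 0) (n - nr) * log10((1 - R) / 0.5) else 0
  t1 + t2
}

#' All-pairs two-point statistics for a genotype matrix
#'
#' Vectorised over loci via indicator-matrix products.
#'
#' @param geno samples x loci character matrix ("AA"/"BB"; heterozygous and
#'   missing calls are ignored pairwise)
#' @return list of loci x loci matrices: `n_inf`, `n_rec`, `R`, `r`, `LOD`
#' @export
two_point_matrix <- function(geno) {
  A <- (geno == "AA") + 0
  B <- (geno == "BB") + 0
  A[is.na(A)] <- 0
  B[is.na(B)] <- 0
  n_inf <- t(A) %*% A + t(A) %*% B + t(B) %*% A + t(B) %*% B
  n_rec <- t(A) %*% B + t(B) %*% A
  R <- ifelse(n_inf > 0, n_rec / n_inf, NA_real_)
  r <- ifelse(R >= 1, 0.5, pmin(pmax(R / (2 * (1 - R)), 0), 0.5))
  P1 <- ifelse(n_rec > 0, n_rec * log10(R / 0.5), 0)
  P2 <- ifelse(n_inf - n_rec > 0, (n_inf - n_rec) * log10((1 - R) / 0.5), 0)
  LOD <- P1 + P2
  diag(LOD) <- 0
  list(n_inf = n_inf, n_rec = n_rec, R = R, r = r, LOD = LOD)
}

#' Group loci into linkage groups
#'
#' Connected components of the relation \{LOD >= `lod_min` and r <=
#' `rmax`\}. The r guard protects against spurious transitive joins between
#' unlinked loci: with hundreds of markers the number of unlinked pairs is
#' large enough that LOD alone admits expected false links, so the default
#' caps the admissible recombination estimate at 0.20 (about 22 Kosambi cM)
#' -- configurable where sparser maps are expected.
#'
#' @param tp result of [two_point_matrix()]
#' @param lod_min minimum LOD for linkage (classic default 3.0)
#' @param rmax maximum per-meiosis recombination estimate for linkage
#' @return list with `groups` (list of character vectors, largest first)
#'   and `unlinked` (singleton loci)
#' @export
link_groups <- function(tp, lod_min = 3.0, rmax = 0.20) {
  adj <- (tp$LOD >= lod_min) & !is.na(tp$r) & (tp$r <= rmax)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  loci <- rownames(tp$LOD)
  groups <- split(loci, comp$membership)
  sizes <- lengths(groups)
  groups <- groups[order(-sizes)]
  list(groups = unname(groups[lengths(groups) > 1]),
       unlinked = unlist(groups[lengths(groups) == 1], use.names = FALSE))
}

#' Order the loci of one linkage group
#'
#' Seriation minimising the sum of adjacent recombination estimates:
#' nearest-neighbour chaining started from the most distal pair, followed by
#' 2-opt reversal moves until no improvement. Deterministic given input
#' order (ties resolved by first index).
#'
#' @param loci character vector of group members
#' @param r_mat loci x loci recombination-estimate matrix (from
#'   [two_point_matrix()])
#' @return ordered character vector
#' @export
order_group <- function(loci, r_mat) {
  m <- length(loci)
  if (m <= 2) return(loci)
  r <- r_mat[loci, loci]
  cost <- function(p) sum(r[cbind(p[-length(p)], p[-1])])
  nn_chain <- function(start) {
    path <- start
    free <- setdiff(seq_len(m), start)
    while (length(free)) {
      last <- path[length(path)]
      nxt <- free[which.min(r[last, free])]
      path <- c(path, nxt)
      free <- setdiff(free, nxt)
    }
    path
  }
  two_opt <- function(path) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in 1:(m - 1)) {
        for (j in (i + 1):m) {
          cand <- c(path[seq_len(i - 1)], rev(path[i:j]),
                    if (j < m) path[(j + 1):m] else integer(0))
          if (cost(cand) < cost(path) - 1e-12) {
            path <- cand
            improved <- TRUE
          }
        }
      }
    }
    path
  }
  # terminal loci have the largest summed recombination to the rest; chains
  # started inside a group fold back on themselves, so seed from several
  # end-like loci (plus the most distal pair) and keep the best seriation
  tot <- rowSums(r, na.rm = TRUE)
  far <- which(r == max(r, na.rm = TRUE), arr.ind = TRUE)[1, ]
  starts <- unique(c(order(tot, decreasing = TRUE)[seq_len(min(4L, m))],
                     far[1], far[2]))
  best <- NULL
  for (s in starts) {
    p <- two_opt(nn_chain(s))
    if (is.null(best) || cost(p) < cost(best) - 1e-12) best <- p
  }
  loci[best]
}

#' Kosambi map distance
#'
#' `d = 25 ln((1+2r)/(1-2r))` centiMorgans.
#'
#' @param r recombination fraction(s), `0 <= r < 0.5`
#' @return distance in cM
#' @export
kosambi_cm <- function(r) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 0.5))
    stop("kosambi_cm requires 0 <= r < 0.5")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Segregation-distortion test for one RIL locus
#'
#' One-degree-of-freedom chi-square on AA:BB counts against 1:1
#' (heterozygous and missing calls excluded).
#'
#' @param g character vector of calls
#' @param alpha significance bound for flagging (default 0.01)
#' @param min_informative minimum scored lines; below it the test is
#'   skipped with a warning
#' @return list (`n_AA`, `n_BB`, `chi2`, `p`, `flag`)
#' @export
distortion_test <- function(g, alpha = 0.01, min_informative = 20L) {
  nAA <- sum(g == "AA", na.rm = TRUE)
  nBB <- sum(g == "BB", na.rm = TRUE)
  n <- nAA + nBB
  if (n < min_informative) {
    warning(sprintf("only %d informative lines; distortion test skipped", n))
    return(list(n_AA = nAA, n_BB = nBB, chi2 = NA_real_, p = NA_real_,
                flag = NA))
  }
  chi2 <- (nAA - nBB)^2 / n
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  list(n_AA = nAA, n_BB = nBB, chi2 = chi2, p = p, flag = p < alpha)
}

#' Build a genetic map from a RIL genotype matrix
#'
#' Two-point statistics, LOD grouping, per-group seriation, cumulative
#' Kosambi positions and a segregation-distortion audit.
#'
#' @param geno samples x loci character matrix
#' @param lod_min,rmax grouping thresholds (see [link_groups()])
#' @param alpha distortion significance bound
#' @return object of class `genetic_map`: list with `groups` (each a
#'   data.frame `locus`, `r_adj`, `cM`, `distorted`), `unlinked`, `tp`
#' @export
build_map <- function(geno, lod_min = 3.0, rmax = 0.20, alpha = 0.01) {
  tp <- two_point_matrix(geno)
  lg <- link_groups(tp, lod_min = lod_min, rmax = rmax)
  groups <- lapply(lg$groups, function(loci) {
    ord <- order_group(loci, tp$r)
    r_adj <- c(NA, tp$r[cbind(ord[-length(ord)], ord[-1])])
    r_adj_c <- pmin(r_adj, 0.4999) # guard against degenerate adjacent estimates
    cm <- c(0, cumsum(kosambi_cm(r_adj_c[-1])))
    dist_flag <- vapply(ord, function(l)
      isTRUE(suppressWarnings(distortion_test(geno[, l], alpha = alpha)$flag)),
      logical(1))
    data.frame(locus = ord, r_adj = r_adj, cM = cm, distorted = dist_flag,
               row.names = NULL)
  })
  structure(list(groups = groups, unlinked = lg$unlinked, tp = tp,
                 lod_min = lod_min, rmax = rmax, alpha = alpha),
            class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("genetic_map: %d linkage group(s), %d unlinked locus/loci\n",
              length(x$groups), length(x$unlinked)))
  rep <- map_report(x)
  print(rep, row.names = FALSE)
  invisible(x)
}

#' Linkage-map summary table
#'
#' Per-group and total statistics in the conventional published layout:
#' locus counts (split by marker class when provided), group length (sum of
#' adjacent Kosambi distances, 1 decimal) and average distance between loci
#' computed as length divided by the locus count (2 decimals) -- the
#' convention of the classic map tables this report mirrors.
#'
#' @param map a [build_map()] result, or a list of data.frames with `locus`
#'   and `cM`
#' @param marker_class optional named character vector (locus -> class,
#'   e.g. "SNP"/"SSR")
#' @return data.frame, one row per group plus a total row
#' @export
map_report <- function(map, marker_class = NULL) {
  groups <- if (inherits(map, "genetic_map")) map$groups else map
  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    len <- if (nrow(g) > 1) max(g$cM) - min(g$cM) else 0
    n <- nrow(g)
    cls <- if (!is.null(marker_class))
      table(factor(marker_class[g$locus], levels = unique(marker_class)))
    else NULL
    out <- data.frame(group = sprintf("LG%02d", i), n_loci = n,
                      length_cM = round(len, 1),
                      avg_spacing_cM = if (n > 0) round(len / n, 2) else 0)
    if (!is.null(cls))
      for (cl in names(cls)) out[[paste0("n_", cl)]] <- as.integer(cls[[cl]])
    out
  })
  rep <- do.call(rbind, rows)
  total_len <- sum(rep$length_cM)
  total_n <- sum(rep$n_loci)
  tot <- rep[1, , drop = FALSE]
  tot$group <- "Total"
  tot$n_loci <- total_n
  tot$length_cM <- round(total_len, 1)
  tot$avg_spacing_cM <- if (total_n > 0) round(total_len / total_n, 2) else 0
  for (cl in grep("^n_", names(rep), value = TRUE))
    if (cl != "n_loci") tot[[cl]] <- sum(rep[[cl]])
  rbind(rep, tot)
}
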