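#' Per-locus diversity statistics
#'
#' Allele frequencies from observed allele counts (two characters per
#' genotype string, missing skipped). Gene diversity `He = 1 - sum p_i^2`,
#' polymorphism information content
#' `PIC = He - sum_{i<j} 2 p_i^2 p_j^2`, observed heterozygosity and call
#' rate.
#'
#' @param geno samples x loci character matrix; each call is a 2-character
#'   allele string (e.g. "AA", "AB"), NA = missing
#' @return data.frame with one row per locus: `locus`, `n_called`,
#'   `call_rate`, `n_alleles`, `maf` (major allele frequency), `He`, `PIC`,
#'   `Ho`
#' @export
locus_stats <- function(geno) {
  rows <- lapply(seq_len(ncol(geno)), function(l) {
    g <- geno[, l]
    g <- g[!is.na(g)]
    if (length(g) == 0)
      return(data.frame(locus = colnames(geno)[l], n_called = 0L,
                        call_rate = 0, n_alleles = NA_integer_,
                        maf = NA_real_, He = NA_real_, PIC = NA_real_,
                        Ho = NA_real_))
    a1 <- substr(g, 1, 1)
    a2 <- substr(g, 2, 2)
    p <- table(c(a1, a2)) / (2 * length(g))
    p <- as.numeric(p)
    He <- 1 - sum(p^2)
    pic <- He
    if (length(p) > 1) {
      pp <- outer(p^2, p^2)
      pic <- He - sum(pp[upper.tri(pp)]) * 2
    }
    data.frame(locus = colnames(geno)[l], n_called = length(g),
               call_rate = length(g) / nrow(geno),
               n_alleles = length(p), maf = max(p), He = He, PIC = pic,
               Ho = mean(a1 != a2))
  })
  do.call(rbind, rows)
}

# allele-B dosage matrix (0/1/2) from a biallelic AA/AB/BB matrix;
# non-biallelic loci dropped with a warning
.dosage <- function(geno) {
  ok <- apply(geno, 2, function(g) all(is.na(g) | g %in% c("AA", "AB", "BB")))
  if (!all(ok))
    warning(sprintf("%d non-biallelic locus/loci excluded", sum(!ok)))
  g <- geno[, ok, drop = FALSE]
  d <- matrix(match(g, c("AA", "AB", "BB")) - 1L, nrow(g), ncol(g),
              dimnames = dimnames(g))
  d
}

#' F-statistics: inbreeding coefficient and Weir-Cockerham fixation index
#'
#' `F_IS = 1 - sum(Ho_l) / sum(He_l)` pooled over loci (ratio of sums).
#' With subpopulation labels, `F_ST` is the Weir-Cockerham (1984)
#' variance-components estimator pooled over loci
#' (`sum(a) / sum(a + b + c)`).
#'
#' @param geno samples x loci biallelic matrix ("AA"/"AB"/"BB")
#' @param subpop_labels optional character vector (length = samples) of
#'   subpopulation assignments; required for F_ST
#' @return list (`F_IS`, `F_ST`, `n_loci_used`)
#' @export
f_stats <- function(geno, subpop_labels = NULL) {
  ls <- locus_stats(geno)
  use <- !is.na(ls$He)
  F_IS <- 1 - sum(ls$Ho[use] * ls$n_called[use]) /
    sum(ls$He[use] * ls$n_called[use])

  F_ST <- NA_real_
  if (!is.null(subpop_labels)) {
    stopifnot(length(subpop_labels) == nrow(geno))
    pops <- unique(subpop_labels[!is.na(subpop_labels)])
    if (length(pops) < 2) stop("F_ST requires >= 2 subpopulations")
    d <- .dosage(geno)
    A <- 0; ABC <- 0
    any_poly <- FALSE
    for (l in seq_len(ncol(d))) {
      x <- d[, l]
      ni <- vapply(pops, function(s) sum(!is.na(x[subpop_labels == s])),
                   numeric(1))
      if (any(ni < 1)) next
      pi <- vapply(pops, function(s) mean(x[subpop_labels == s], na.rm = TRUE) / 2,
                   numeric(1))
      hi <- vapply(pops, function(s) mean(x[subpop_labels == s] == 1, na.rm = TRUE),
                   numeric(1))
      r <- length(pops)
      nbar <- mean(ni)
      if (nbar <= 1) next
      nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
      pbar <- sum(ni * pi) / (r * nbar)
      if (pbar <= 0 || pbar >= 1) next
      any_poly <- TRUE
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      a <- nbar / nc *
        (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
      b <- nbar / (nbar - 1) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      A <- A + a
      ABC <- ABC + a + b + cc
    }
    if (!any_poly) stop("F_ST undefined: all loci monomorphic")
    F_ST <- A / ABC
  }
  list(F_IS = F_IS, F_ST = F_ST, n_loci_used = sum(use))
}

#' Two-level analysis of molecular variance (AMOVA)
#'
#' Distances are pairwise squared differences in allele dosage summed over
#' loci (squared Euclidean on the dosage matrix). Sums of squares follow
#' the standard distance-based decomposition; `Phi_ST = sigma2_among /
#' sigma2_total`; significance by permutation of group labels with the
#' plus-one correction.
#'
#' @param geno samples x loci biallelic matrix
#' @param group_labels character vector of group assignments (at least two
#'   groups with at least two members each)
#' @param n_perm number of label permutations
#' @param seed integer seed for the permutations
#' @return list (`SS_among`, `SS_within`, `df_among`, `df_within`,
#'   `sigma2_among`, `sigma2_within`, `phi_st`, `p_value`, `n_perm`)
#' @export
amova <- function(geno, group_labels, n_perm = 1000L, seed = 1) {
  stopifnot(length(group_labels) == nrow(geno))
  tab <- table(group_labels)
  if (length(tab) < 2) stop("AMOVA requires >= 2 groups")
  if (any(tab < 2)) stop("every AMOVA group needs >= 2 members")
  d <- .dosage(geno)
  D <- as.matrix(dist(d))^2
  N <- nrow(D)
  G <- length(tab)

  phi_from_labels <- function(lab) {
    SS_T <- sum(D) / (2 * N)
    SS_W <- 0
    for (g in names(tab)) {
      idx <- which(lab == g)
      SS_W <- SS_W + sum(D[idx, idx]) / (2 * length(idx))
    }
    SS_A <- SS_T - SS_W
    sigma_w <- SS_W / (N - G)
    n0 <- (N - sum(tab^2) / N) / (G - 1)
    sigma_a <- (SS_A / (G - 1) - sigma_w) / n0
    list(SS_A = SS_A, SS_W = SS_W, sigma_a = sigma_a, sigma_w = sigma_w,
         phi = sigma_a / (sigma_a + sigma_w))
  }

  obs <- phi_from_labels(group_labels)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    perm <- sample(group_labels)
    if (phi_from_labels(perm)$phi >= obs$phi - 1e-12) hits <- hits + 1L
  }
  list(SS_among = obs$SS_A, SS_within = obs$SS_W,
       df_among = G - 1, df_within = N - G,
       sigma2_among = obs$sigma_a, sigma2_within = obs$sigma_w,
       phi_st = obs$phi, p_value = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

#' Allele-sharing dissimilarity matrix
#'
#' `d(i, j) = 1 - mean over co-called loci of (shared alleles / 2)`.
#' Pairwise deletion: each pair uses its co-called loci only; a pair with
#' none is an error.
#'
#' @param geno samples x loci biallelic matrix
#' @return a `dist` object
#' @export
allele_sharing_dist <- function(geno) {
  d <- .dosage(geno)
  n <- nrow(d)
  obs <- !is.na(d)
  dz <- d
  dz[!obs] <- 0
  # sum over co-called loci of |gi - gj| / 2, via the identity
  # |gi-gj| for dosages in {0,1,2}: computed per pair below (n is panel-scale)
  out <- matrix(0, n, n, dimnames = list(rownames(geno), rownames(geno)))
  for (i in seq_len(n - 1)) {
    gi <- d[i, ]
    co <- obs[i, ] & obs[(i + 1):n, , drop = FALSE]
    diffs <- abs(sweep(d[(i + 1):n, , drop = FALSE], 2, gi, "-"))
    diffs[!co] <- NA
    nc <- rowSums(co)
    if (any(nc == 0)) {
      j <- which(nc == 0)[1] + i
      stop(sprintf("accessions %s and %s share no co-called loci",
                   rownames(geno)[i], rownames(geno)[j]))
    }
    v <- rowSums(diffs, na.rm = TRUE) / (2 * nc)
    out[i, (i + 1):n] <- v
    out[(i + 1):n, i] <- v
  }
  as.dist(out)
}

#' Unweighted neighbour-joining tree with locus bootstrap
#'
#' Saitou-Nei agglomeration (via \pkg{ape}) on the allele-sharing
#' dissimilarity; support values are the fraction of trees, built from
#' panels resampling loci with replacement, containing each internal
#' bipartition.
#'
#' @param geno samples x loci biallelic matrix (>= 3 accessions)
#' @param bootstrap_n number of locus-resampling replicates (0 = none)
#' @param seed integer seed
#' @return list (`tree` an `ape::phylo`, `support` per internal node as a
#'   fraction of replicates, or NULL, `dist`)
#' @export
nj_tree <- function(geno, bootstrap_n = 1000L, seed = 1) {
  stopifnot(nrow(geno) >= 3)
  dd <- allele_sharing_dist(geno)
  tree <- ape::nj(dd)
  support <- NULL
  if (bootstrap_n > 0) {
    set.seed(seed)
    boots <- vector("list", bootstrap_n)
    for (b in seq_len(bootstrap_n)) {
      idx <- sample.int(ncol(geno), replace = TRUE)
      boots[[b]] <- ape::nj(allele_sharing_dist(geno[, idx, drop = FALSE]))
    }
    pc <- ape::prop.clades(tree, boots, rooted = FALSE)
    pc[is.na(pc)] <- 0
    support <- pc / bootstrap_n
  }
  list(tree = tree, support = support, dist = dd)
}

#' Maximum-likelihood admixture model fitted by EM
#'
#' Model: accession `i` carries ancestry proportions `q_i` over `K`
#' clusters with cluster allele frequencies `p_k`; each of the two allele
#' copies at a locus is drawn from cluster `k` with probability `q_ik` and
#' is the B allele with probability `p_kl`, so `P(B) = sum_k q_ik p_kl`.
#' The E-step computes per-copy cluster responsibilities, the M-step
#' re-estimates `Q` rows and `P` entries; replicates are random restarts
#' and the best log-likelihood fit is returned (log-likelihood omits the
#' genotype binomial coefficient, a model-free constant).
#'
#' @param geno samples x loci biallelic matrix
#' @param K number of ancestral clusters (>= 1, <= accessions)
#' @param n_replicates random restarts
#' @param max_iter EM iteration cap per restart
#' @param tol absolute log-likelihood convergence tolerance
#' @param seed integer seed
#' @return list of class `admixture_fit`: `K`, `Q` (best fit), `P`, `lnL`,
#'   `lnL_replicates`, `n_iter`
#' @export
admixture_fit <- function(geno, K, n_replicates = 10L, max_iter = 500L,
                          tol = 1e-4, seed = 1) {
  d <- .dosage(geno)
  if (K > nrow(d)) stop("K exceeds the number of accessions")
  stopifnot(K >= 1)
  set.seed(seed)
  obs <- !is.na(d)
  g <- d; g[!obs] <- 0
  two_minus_g <- (2 - d); two_minus_g[!obs] <- 0
  n <- nrow(d); L <- ncol(d)
  n_obs2 <- 2 * rowSums(obs)

  lnl_of <- function(PI) sum((g * log(PI) + two_minus_g * log(1 - PI))[obs])

  if (K == 1) {
    p <- colSums(g) / pmax(colSums(obs) * 2, 1)
    p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    PI <- matrix(p, n, L, byrow = TRUE)
    res <- list(K = 1L, Q = matrix(1, n, 1, dimnames = list(rownames(geno), NULL)),
                P = matrix(p, 1, L, dimnames = list(NULL, colnames(d))),
                lnL = lnl_of(PI), lnL_replicates = rep(lnl_of(PI), n_replicates),
                n_iter = 1L)
    class(res) <- "admixture_fit"
    return(res)
  }

  best <- NULL
  lnls <- numeric(n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    Qm <- matrix(stats::rgamma(n * K, 1), n, K)
    Qm <- Qm / rowSums(Qm)
    P <- matrix(runif(K * L, 0.05, 0.95), K, L)
    lnl_prev <- -Inf
    it <- 0L
    repeat {
      it <- it + 1L
      PI <- Qm %*% P
      PI <- pmin(pmax(PI, 1e-9), 1 - 1e-9)
      Qnum <- matrix(0, n, K)
      Pnum <- matrix(0, K, L)
      Pden <- matrix(0, K, L)
      for (k in seq_len(K)) {
        # responsibilities x expected copy counts for cluster k
        EB <- g * (Qm[, k] * sweep(1 / PI, 2, P[k, ], "*"))
        EA <- two_minus_g * (Qm[, k] * sweep(1 / (1 - PI), 2, 1 - P[k, ], "*"))
        Qnum[, k] <- rowSums(EB + EA)
        Pnum[k, ] <- colSums(EB)
        Pden[k, ] <- colSums(EB + EA)
      }
      Qm <- Qnum / pmax(n_obs2, 1)
      Qm <- Qm / rowSums(Qm)
      P <- Pnum / pmax(Pden, 1e-12)
      P <- pmin(pmax(P, 1e-6), 1 - 1e-6)
      PI <- pmin(pmax(Qm %*% P, 1e-9), 1 - 1e-9)
      lnl <- lnl_of(PI)
      if (it >= max_iter || abs(lnl - lnl_prev) < tol) break
      lnl_prev <- lnl
    }
    lnls[rep_i] <- lnl
    if (is.null(best) || lnl > best$lnL)
      best <- list(Q = Qm, P = P, lnL = lnl, n_iter = it)
  }
  rownames(best$Q) <- rownames(geno)
  colnames(best$P) <- colnames(d)
  res <- list(K = as.integer(K), Q = best$Q, P = best$P, lnL = best$lnL,
              lnL_replicates = lnls, n_iter = best$n_iter)
  class(res) <- "admixture_fit"
  res
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K=%d, lnL=%.2f (best of %d replicate(s))\n",
              x$K, x$lnL, length(x$lnL_replicates)))
  invisible(x)
}

#' Align cluster labels of one Q matrix to a reference
#'
#' Greedy column matching by minimal summed absolute difference, the usual
#' label-switching repair across replicates or against truth.
#'
#' @param Q,Q_ref accessions x K ancestry matrices
#' @return `Q` with columns permuted to match `Q_ref`
#' @export
align_q <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, nrow(Q_ref) == nrow(Q))
  cost <- outer(seq_len(K), seq_len(K),
                Vectorize(function(a, b) sum(abs(Q[, a] - Q_ref[, b]))))
  perm <- integer(K)
  free_a <- seq_len(K); free_b <- seq_len(K)
  while (length(free_a)) {
    bestv <- Inf; ba <- free_a[1]; bb <- free_b[1]
    for (a in free_a) for (b in free_b)
      if (cost[a, b] < bestv) { bestv <- cost[a, b]; ba <- a; bb <- b }
    perm[bb] <- ba
    free_a <- setdiff(free_a, ba)
    free_b <- setdiff(free_b, bb)
  }
  Q[, perm, drop = FALSE]
}

#' Fit the admixture model over a range of K
#'
#' @param geno samples x loci biallelic matrix
#' @param k_range integer vector of K values
#' @param n_replicates restarts per K
#' @param seed base seed (each K/replicate derives from it)
#' @param ... passed to [admixture_fit()]
#' @return list: `fits` (per K), `lnL_table` (data.frame `K`, `replicate`,
#'   `lnL`)
#' @export
structure_scan <- function(geno, k_range = 1:5, n_replicates = 10L, seed = 1,
                           ...) {
  fits <- list()
  rows <- list()
  for (K in k_range) {
    f <- admixture_fit(geno, K, n_replicates = n_replicates,
                       seed = seed + 1000L * K, ...)
    fits[[as.character(K)]] <- f
    rows[[as.character(K)]] <- data.frame(K = K,
                                          replicate = seq_along(f$lnL_replicates),
                                          lnL = f$lnL_replicates)
  }
  list(fits = fits, lnL_table = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Evanno delta-K table
#'
#' `L'(K) = Lbar(K) - Lbar(K-1)`; `|L''(K)| = |Lbar(K+1) - 2 Lbar(K) +
#' Lbar(K-1)|`; `deltaK = |L''(K)| / sd(lnL at K)`. Undefined at the range
#' endpoints and where the replicate standard deviation is zero.
#'
#' @param lnl_table data.frame (`K`, `replicate`, `lnL`) with >= 2
#'   replicates per K
#' @return data.frame (`K`, `mean_lnL`, `sd_lnL`, `lppK`, `delta_K`)
#' @export
evanno_delta_k <- function(lnl_table) {
  stopifnot(all(c("K", "lnL") %in% names(lnl_table)))
  agg <- aggregate(lnL ~ K, lnl_table, function(v) c(mean = mean(v), sd = sd(v),
                                                     n = length(v)))
  Ks <- agg$K
  mu <- agg$lnL[, "mean"]
  sdv <- agg$lnL[, "sd"]
  nrep <- agg$lnL[, "n"]
  if (any(nrep < 2)) stop("delta-K requires >= 2 replicates per K")
  m <- length(Ks)
  lpp <- rep(NA_real_, m)
  if (m >= 3)
    for (i in 2:(m - 1)) lpp[i] <- abs(mu[i + 1] - 2 * mu[i] + mu[i - 1])
  dk <- ifelse(!is.na(lpp) & sdv > 0, lpp / sdv, NA_real_)
  data.frame(K = Ks, mean_lnL = mu, sd_lnL = sdv, lppK = lpp, delta_K = dk)
}

#' Assign accessions to populations from ancestry proportions
#'
#' An accession is assigned to its majority cluster only when that
#' cluster's ancestry proportion strictly exceeds the threshold ("higher
#' than" 70% by default); otherwise it is labelled admixed.
#'
#' @param Q accessions x K ancestry matrix
#' @param threshold strict assignment bound on qK
#' @return character vector ("pop_k" or "admixed")
#' @export
assign_populations <- function(Q, threshold = 0.70) {
  top <- apply(Q, 1, which.max)
  qk <- Q[cbind(seq_len(nrow(Q)), top)]
  ifelse(qk > threshold, sprintf("pop_%d", top), "admixed")
}
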