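#' Simulate a structured diversity panel under an admixture model
#'
#' Ancestral allele frequencies for the `K` subpopulations are drawn from a
#' Balding-Nichols model around a uniform ancestral frequency, with the beta
#' dispersion set by `drift_fst` (the expected Weir-Cockerham differentiation
#' between the subpopulations). Each accession has an ancestry vector `q`:
#' a fraction `admix_frac` of accessions draw `q` from a flat Dirichlet, the
#' rest are assigned pure membership in one subpopulation. Genotypes are
#' drawn through the admixture model with near-complete selfing: with
#' probability `selfing_rate` a locus is made fully homozygous (one allele
#' draw duplicated), otherwise two alleles are drawn independently, so
#' observed heterozygosity is `(1 - selfing_rate)` times the outbred
#' expectation and the panel-level inbreeding coefficient equals
#' `selfing_rate`.
#'
#' Defaults mirror a selfing oilseed germplasm collection: 178 accessions,
#' 493 biallelic loci, two subpopulations at differentiation 0.276,
#' inbreeding 0.96, ~13% admixed accessions.
#'
#' @param n_accessions number of accessions (>= K)
#' @param n_loci number of biallelic loci
#' @param K number of ancestral subpopulations
#' @param drift_fst target differentiation between subpopulations, `[0, 1)`
#' @param selfing_rate probability a locus is fully homozygous, `[0, 1]`
#' @param admix_frac fraction of accessions with Dirichlet-drawn ancestry
#' @param Q optional explicit `n_accessions x K` ancestry matrix overriding
#'   the membership draw (rows must sum to 1)
#' @param seed integer seed
#' @return character matrix accessions x loci ("AA"/"AB"/"BB"), with
#'   attribute `"truth"`: list(`Q`, `P` (K x loci allele-B frequencies),
#'   `labels` ("pop_k"/"admixed"), parameters)
#' @export
simulate_panel <- function(n_accessions = 178, n_loci = 493, K = 2,
                           drift_fst = 0.276, selfing_rate = 0.96,
                           admix_frac = 0.13, Q = NULL, seed = 1) {
  stopifnot(K >= 1, n_accessions >= K, drift_fst >= 0, drift_fst < 1,
            selfing_rate >= 0, selfing_rate <= 1)
  set.seed(seed)

  p_anc <- runif(n_loci, 0.1, 0.9)
  if (drift_fst > 0 && K > 1) {
    a <- p_anc * (1 - drift_fst) / drift_fst
    b <- (1 - p_anc) * (1 - drift_fst) / drift_fst
    P <- t(vapply(seq_len(K), function(k) stats::rbeta(n_loci, a, b),
                  numeric(n_loci)))
  } else {
    P <- matrix(rep(p_anc, each = K), K, n_loci)
  }

  if (is.null(Q)) {
    labels <- character(n_accessions)
    Q <- matrix(0, n_accessions, K)
    admixed <- runif(n_accessions) < admix_frac & K > 1
    pure_pop <- rep_len(seq_len(K), n_accessions)[sample.int(n_accessions)]
    for (i in seq_len(n_accessions)) {
      if (admixed[i]) {
        g <- stats::rgamma(K, 1)
        Q[i, ] <- g / sum(g)
        labels[i] <- "admixed"
      } else {
        Q[i, pure_pop[i]] <- 1
        labels[i] <- sprintf("pop_%d", pure_pop[i])
      }
    }
  } else {
    stopifnot(nrow(Q) == n_accessions, ncol(Q) == K,
              all(abs(rowSums(Q) - 1) < 1e-8))
    labels <- ifelse(apply(Q, 1, max) == 1,
                     sprintf("pop_%d", apply(Q, 1, which.max)), "admixed")
  }

  pi_mat <- Q %*% P # per accession/locus allele-B frequency
  u1 <- matrix(runif(n_accessions * n_loci), n_accessions)
  u2 <- matrix(runif(n_accessions * n_loci), n_accessions)
  a1 <- (u1 < pi_mat) + 0L
  a2 <- ifelse(matrix(runif(n_accessions * n_loci), n_accessions) < selfing_rate,
               a1, (u2 < pi_mat) + 0L)
  dose <- a1 + a2
  geno <- matrix(c("AA", "AB", "BB")[dose + 1L], n_accessions, n_loci)
  rownames(geno) <- sprintf("ACC_%03d", seq_len(n_accessions))
  colnames(geno) <- sprintf("L%04d", seq_len(n_loci))
  attr(geno, "truth") <- list(Q = Q, P = P, labels = labels,
                              drift_fst = drift_fst,
                              selfing_rate = selfing_rate, seed = seed)
  geno
}
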