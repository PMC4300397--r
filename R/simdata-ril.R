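#' Simulate a recombinant inbred line (RIL) population by repeated selfing
#'
#' Meiosis is modelled marker-to-marker with independent recombination in
#' each inter-marker interval at the Haldane probability implied by the map
#' distance (the no-interference count-location crossover process restricted
#' to the marker positions). Starting from the F1 between two fully
#' homozygous parents, lines are selfed for `n_generations` (effectively
#' F-infinity); any residual heterozygous interval (probability < 1e-5 at
#' the default) is resolved by a fair coin so that every line is fully
#' homozygous. Under this process the recombinant fraction between adjacent
#' markers converges to the RIL-by-selfing expectation `R = 2r/(1+2r)`.
#'
#' @param true_map data.frame with columns `chrom`, `locus`, `cM` giving
#'   marker positions per chromosome
#' @param n_lines number of RILs (>= 2)
#' @param seed integer seed
#' @param n_generations selfing generations simulated (default 20)
#' @return character matrix `n_lines` x loci with calls "AA"/"BB"; the
#'   generating map is attached as attribute `"true_map"`
#' @export
simulate_ril <- function(true_map, n_lines, seed = 1, n_generations = 20L) {
  stopifnot(all(c("chrom", "locus", "cM") %in% names(true_map)), n_lines >= 2)
  set.seed(seed)
  true_map <- true_map[order(true_map$chrom, true_map$cM), ]
  out <- vector("list", length(unique(true_map$chrom)))
  chroms <- unique(true_map$chrom)

  gamete <- function(H1, H2, r_gap) {
    n <- nrow(H1); m <- ncol(H1)
    phase <- matrix(0L, n, m)
    phase[, 1] <- sample(0:1, n, replace = TRUE)
    if (m > 1) {
      sw <- matrix(rbinom(n * (m - 1), 1L, rep(r_gap, each = n)), n, m - 1)
      for (j in 2:m) phase[, j] <- (phase[, j - 1] + sw[, j - 1]) %% 2L
    }
    ifelse(phase == 0L, H1, H2)
  }

  for (k in seq_along(chroms)) {
    mk <- true_map[true_map$chrom == chroms[k], ]
    m <- nrow(mk)
    d <- diff(mk$cM)
    r_gap <- 0.5 * (1 - exp(-2 * d / 100)) # Haldane, distances in cM
    H1 <- matrix(0L, n_lines, m)           # parent A haplotype
    H2 <- matrix(1L, n_lines, m)           # parent B haplotype
    for (g in seq_len(n_generations)) {
      G1 <- gamete(H1, H2, r_gap)
      G2 <- gamete(H1, H2, r_gap)
      H1 <- G1; H2 <- G2
    }
    het <- H1 != H2
    if (any(het)) {
      coin <- matrix(runif(length(H1)) < 0.5, nrow(H1), ncol(H1))
      H1[het] <- ifelse(coin[het], H1[het], H2[het])
    }
    geno <- matrix(ifelse(H1 == 0L, "AA", "BB"), n_lines, m)
    colnames(geno) <- mk$locus
    out[[k]] <- geno
  }
  res <- do.call(cbind, out)
  rownames(res) <- sprintf("RIL_%04d", seq_len(n_lines))
  attr(res, "true_map") <- true_map
  res
}

#' Regular marker grid for RIL simulations
#'
#' @param n_chromosomes number of chromosomes
#' @param n_loci_per_chrom markers per chromosome
#' @param spacing_cM distance between adjacent markers
#' @return data.frame usable as `true_map` in [simulate_ril()]
#' @export
regular_map <- function(n_chromosomes = 20, n_loci_per_chrom = 30,
                        spacing_cM = 4) {
  do.call(rbind, lapply(seq_len(n_chromosomes), function(ci) {
    data.frame(chrom = ci,
               locus = sprintf("c%02d_m%02d", ci, seq_len(n_loci_per_chrom)),
               cM = (seq_len(n_loci_per_chrom) - 1) * spacing_cM)
  }))
}
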