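INTENSITY_PATTERNS <- c("standard", "diffuse_allele", "low_separation",
                        "dominant", "failed", "monomorphic")

#' Simulate two-channel array intensities for genotyped loci
#'
#' Generates per-sample `(x, y)` channel signals whose polar coordinates
#' `theta = (2/pi) atan(y/x)` and `R = x + y` reproduce the named cluster
#' patterns seen on two-colour genotyping arrays:
#'
#' * `standard`: three tight theta clusters near 0.05 / 0.50 / 0.95;
#' * `diffuse_allele`: as standard, but the low-theta homozygote cluster has
#'   3x the nominal spread (poor hybridisation of one allele);
#' * `low_separation`: cluster theta means 0.40 / 0.50 / 0.60 (adjacent
#'   gaps below 0.15);
#' * `dominant`: only one allele fluoresces -- heterozygotes share the
#'   signalling homozygote's theta distribution (at reduced `R`), while the
#'   other homozygote has `R` below 0.2;
#' * `failed`: all samples below `R = 0.2`;
#' * `monomorphic`: a single cluster regardless of genotype.
#'
#' @param genotypes character matrix samples x loci ("AA"/"AB"/"BB"; NA
#'   yields an `x = y = 0` record)
#' @param pattern one pattern name, or a vector recycled across loci
#' @param noise_sd nominal theta cluster standard deviation
#' @param seed integer seed
#' @return data.table (`locus`, `sample_id`, `x`, `y`); generating
#'   genotypes and per-locus patterns attached as attribute `"truth"`
#' @export
simulate_intensities <- function(genotypes, pattern = "standard",
                                 noise_sd = 0.03, seed = 1) {
  bad <- setdiff(unique(pattern), INTENSITY_PATTERNS)
  if (length(bad))
    stop("unknown intensity pattern(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  n <- nrow(genotypes); L <- ncol(genotypes)
  pat <- rep_len(pattern, L)
  gidx <- function(g) match(g, c("AA", "AB", "BB"))

  res <- vector("list", L)
  for (l in seq_len(L)) {
    g <- gidx(genotypes[, l])
    th <- numeric(n); R <- numeric(n)
    p <- pat[l]
    if (p == "failed") {
      th <- runif(n)
      R <- runif(n, 0.02, 0.15)
    } else if (p == "monomorphic") {
      th <- rnorm(n, 0.05, noise_sd)
      R <- rnorm(n, 1, 0.1)
    } else if (p == "dominant") {
      # alleles: only the A channel fluoresces; AB indistinguishable from AA
      # on theta, the silent homozygote sits below the R failure bound
      th_sig <- abs(rnorm(n, 0.03, noise_sd / 2))
      th <- ifelse(g == 3, rnorm(n, 0.5, 0.12), th_sig)
      R <- ifelse(g == 1, rnorm(n, 1, 0.08),
           ifelse(g == 2, rnorm(n, 0.55, 0.06),
                  pmin(pmax(rnorm(n, 0.08, 0.03), 0.01), 0.19)))
    } else {
      # diffuse_allele: the weakly hybridising allele's homozygote cluster is
      # displaced off the theta rail and spread at 3x the nominal noise
      mus <- switch(p,
                    standard = c(0.05, 0.50, 0.95),
                    diffuse_allele = c(0.05, 0.50, 0.85),
                    low_separation = c(0.40, 0.50, 0.60))
      sds <- rep(noise_sd, 3)
      if (p == "diffuse_allele") sds[3] <- 3 * noise_sd
      th <- rnorm(n, mus[g], sds[g])
      R <- rnorm(n, 1, 0.1)
    }
    th <- pmin(pmax(th, 0), 1)
    R <- pmax(R, 0.01)
    t <- suppressWarnings(tanpi(th / 2)) # tanpi(0.5) is NaN: theta == 1, pure y
    xx <- ifelse(!is.finite(t), 0, R / (1 + t))
    yy <- R - xx
    miss <- is.na(g) & p != "failed" & p != "monomorphic"
    xx[miss] <- 0; yy[miss] <- 0
    res[[l]] <- data.table::data.table(
      locus = colnames(genotypes)[l], sample_id = rownames(genotypes),
      x = xx, y = yy)
  }
  out <- data.table::rbindlist(res)
  attr(out, "truth") <- list(genotypes = genotypes,
                             pattern = stats::setNames(pat, colnames(genotypes)),
                             noise_sd = noise_sd, seed = seed)
  out
}
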