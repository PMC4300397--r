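#' Polar coordinates of two-channel intensities
#'
#' `theta = (2/pi) * atan(y/x)` in `[0, 1]`, `R = x + y`. Records with
#' `x = y = 0` have undefined theta and are returned missing.
#'
#' @param x,y non-negative channel signals (vectors)
#' @return data.frame (`theta`, `R`)
#' @export
intensity_polar <- function(x, y) {
  stopifnot(length(x) == length(y))
  bad <- !is.na(x) & !is.na(y) & x == 0 & y == 0
  theta <- (2 / pi) * atan2(y, x)
  R <- x + y
  theta[bad] <- NA_real_
  R[bad] <- NA_real_
  data.frame(theta = theta, R = R)
}

# deterministic 1-D k-means: quantile initialisation + Lloyd iterations
.kmeans1d <- function(x, k, max_iter = 100L) {
  centers <- unname(quantile(x, probs = (seq_len(k) - 0.5) / k, type = 7))
  centers <- sort(centers)
  assign <- rep(1L, length(x))
  for (it in seq_len(max_iter)) {
    d <- abs(outer(x, centers, "-"))
    new_assign <- max.col(-d, ties.method = "first")
    if (all(new_assign == assign) && it > 1) break
    assign <- new_assign
    for (j in seq_len(k)) {
      xi <- x[assign == j]
      if (length(xi)) centers[j] <- mean(xi)
    }
    o <- order(centers)
    centers <- centers[o]
    assign <- match(assign, o)
  }
  list(centers = centers, assign = assign)
}

# mean silhouette width for a 1-D clustering (O(n^2), n is per-locus samples)
.silhouette1d <- function(x, assign) {
  n <- length(x)
  k <- max(assign)
  if (k < 2) return(NA_real_)
  D <- abs(outer(x, x, "-"))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- assign == assign[i]
    a <- if (sum(own) > 1) sum(D[i, own]) / (sum(own) - 1) else 0
    b <- min(vapply(setdiff(seq_len(k), assign[i]),
                    function(j) mean(D[i, assign == j]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Cluster one locus on theta and classify its pattern
#'
#' If the maximum `R` over samples is below `r_fail` the locus is `failed`
#' and no genotypes can be called. Otherwise theta is clustered for
#' k = 1..`max_k` with a deterministic 1-D k-means; k is selected by mean
#' silhouette (ties to smaller k) among *eligible* k -- a clustering is
#' eligible only if every adjacent cluster-mean gap exceeds 3x the largest
#' within-cluster standard deviation, which separates genuinely monomorphic
#' loci from poorly separated polymorphic ones. Patterns:
#' `monomorphic` (k = 1), `dominant` (one cluster's mean `R` below `r_fail`
#' while the others exceed 0.5), `low_separation` (min adjacent theta gap
#' below `sep_low`), `diffuse_allele` (one cluster's theta spread above 2x
#' the median cluster spread), else `standard`.
#'
#' @param theta,R per-sample polar coordinates (equal length; NA = missing)
#' @param max_k maximum cluster count
#' @param r_fail total-intensity failure bound
#' @param sep_low low-separation bound on adjacent cluster-mean gaps
#' @param min_samples minimum non-missing samples required
#' @return list of class `locus_qc`: `pattern`, `k`, `centers`,
#'   `cluster_sd`, `cluster_R`, `separation`, `assign` (cluster index per
#'   sample, NA where missing), `call_rate`
#' @export
cluster_locus <- function(theta, R, max_k = 3L, r_fail = 0.2, sep_low = 0.15,
                          min_samples = 10L) {
  stopifnot(length(theta) == length(R))
  ok <- !is.na(theta) & !is.na(R)
  qc <- list(pattern = NA_character_, k = NA_integer_, centers = numeric(0),
             cluster_sd = numeric(0), cluster_R = numeric(0),
             separation = NA_real_, assign = rep(NA_integer_, length(theta)),
             call_rate = mean(ok))
  class(qc) <- "locus_qc"
  if (!any(ok) || max(R[ok]) < r_fail) {
    qc$pattern <- "failed"
    return(qc)
  }
  if (sum(ok) < min_samples) {
    qc$pattern <- "insufficient"
    return(qc)
  }
  x <- theta[ok]
  fits <- list(.kmeans1d(x, 1L))
  sil <- c(NA_real_)
  eligible <- c(TRUE)
  for (k in 2:max_k) {
    if (length(unique(x)) < k) { fits[[k]] <- NULL; sil[k] <- NA; eligible[k] <- FALSE; next }
    f <- .kmeans1d(x, k)
    fits[[k]] <- f
    if (any(tabulate(f$assign, k) == 0)) { # Lloyd left a cluster empty
      sil[k] <- NA; eligible[k] <- FALSE; next
    }
    sds <- vapply(seq_len(k), function(j) {
      xi <- x[f$assign == j]
      if (length(xi) > 1) sd(xi) else 0
    }, numeric(1))
    gaps <- diff(f$centers)
    eligible[k] <- length(gaps) > 0 && all(gaps > 0) &&
      min(gaps) > 3 * max(sds)
    sil[k] <- if (eligible[k]) .silhouette1d(x, f$assign) else NA_real_
  }
  k_sel <- 1L
  if (any(eligible[-1] & !is.na(sil[-1]))) {
    cand_k <- which(eligible & !is.na(sil))
    best <- max(sil[cand_k])
    k_sel <- min(cand_k[sil[cand_k] >= best - 1e-9]) # ties -> smaller k
  }
  f <- fits[[k_sel]]
  sds <- vapply(seq_len(k_sel), function(j) {
    xi <- x[f$assign == j]
    if (length(xi) > 1) sd(xi) else 0
  }, numeric(1))
  Rm <- vapply(seq_len(k_sel), function(j) mean(R[ok][f$assign == j]), numeric(1))
  qc$k <- k_sel
  qc$centers <- f$centers
  qc$cluster_sd <- sds
  qc$cluster_R <- Rm
  qc$separation <- if (k_sel > 1) min(diff(f$centers)) else NA_real_
  qc$assign[ok] <- f$assign

  if (k_sel == 1L) {
    qc$pattern <- "monomorphic"
  } else if (any(Rm < r_fail) && all(Rm[Rm >= r_fail] > 0.5)) {
    qc$pattern <- "dominant"
  } else if (qc$separation < sep_low) {
    qc$pattern <- "low_separation"
  } else if (max(sds) > 2 * median(sds) && median(sds) > 0) {
    qc$pattern <- "diffuse_allele"
  } else {
    qc$pattern <- "standard"
  }
  qc
}

#' @export
print.locus_qc <- function(x, ...) {
  cat(sprintf("locus_qc: pattern=%s k=%s centers=[%s] call_rate=%.2f\n",
              x$pattern, x$k, paste(round(x$centers, 3), collapse = ", "),
              x$call_rate))
  invisible(x)
}

#' Call genotypes for one locus from its cluster assignments
#'
#' Clusters are labelled by theta order (low -> AA, middle -> AB, high ->
#' BB; with two clusters, AA and BB). If parent samples are supplied and
#' parent A falls in the high-theta cluster, the homozygote labels are
#' swapped so that parent A's cluster is AA; parents sharing a cluster at a
#' polymorphic locus flag the locus inconsistent (all calls NA). Samples
#' farther than `sd_mult` cluster standard deviations from every cluster
#' mean are set NA. Failed, monomorphic, insufficient and (by default)
#' dominant loci yield no calls.
#'
#' @param qc a [cluster_locus()] result
#' @param theta per-sample theta values (same order as `qc$assign`)
#' @param sample_ids sample names
#' @param parents optional character(2): names of parent A and parent B
#' @param sd_mult distance cut in cluster standard deviations
#' @param call_dominant emit presence/absence-style calls for dominant loci?
#' @return named character vector of calls in AA/AB/BB/NA
#' @export
call_genotypes <- function(qc, theta, sample_ids, parents = NULL, sd_mult = 3,
                           call_dominant = FALSE) {
  stopifnot(inherits(qc, "locus_qc"))
  calls <- rep(NA_character_, length(theta))
  names(calls) <- sample_ids
  if (qc$pattern %in% c("failed", "monomorphic", "insufficient")) return(calls)
  if (qc$pattern == "dominant" && !call_dominant) return(calls)

  k <- qc$k
  labels <- if (k == 3) c("AA", "AB", "BB") else
            if (k == 2) c("AA", "BB") else return(calls)
  if (!is.null(parents)) {
    pa <- qc$assign[match(parents[1], sample_ids)]
    pb <- qc$assign[match(parents[2], sample_ids)]
    if (!is.na(pa) && !is.na(pb) && pa == pb) {
      attr(calls, "inconsistent") <- TRUE
      return(calls)
    }
    if (!is.na(pa) && labels[pa] == "BB") labels <- rev(labels)
  }
  sdf <- pmax(qc$cluster_sd, 1e-9)
  a <- qc$assign
  okc <- !is.na(a)
  within <- abs(theta - qc$centers[a]) <= sd_mult * sdf[a]
  calls[okc & within] <- labels[a[okc & within]]
  if (qc$pattern == "dominant" && call_dominant) {
    # heterozygotes indistinguishable from the fluorescing homozygote
    calls[calls == "AA"] <- "A_"
    calls[calls == "AB"] <- "A_"
  }
  calls
}

#' Call a full intensity table into a genotype matrix with per-locus QC
#'
#' @param intensities data.table (`locus`, `sample_id`, `x`, `y`), e.g. from
#'   [simulate_intensities()]
#' @param parents optional character(2) of parent sample ids
#' @param r_fail,sep_low,max_k,sd_mult see [cluster_locus()] /
#'   [call_genotypes()]
#' @return list: `calls` (samples x loci character matrix), `qc`
#'   (data.frame of per-locus pattern, k, separation, call_rate)
#' @export
call_intensity_matrix <- function(intensities, parents = NULL, r_fail = 0.2,
                                  sep_low = 0.15, max_k = 3L, sd_mult = 3) {
  dt <- data.table::as.data.table(intensities)
  samples <- unique(dt$sample_id)
  loci <- unique(dt$locus)
  calls <- matrix(NA_character_, length(samples), length(loci),
                  dimnames = list(samples, loci))
  qc_rows <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    d <- dt[locus == loci[li]]
    d <- d[match(samples, sample_id)]
    pol <- intensity_polar(d$x, d$y)
    qc <- cluster_locus(pol$theta, pol$R, max_k = max_k, r_fail = r_fail,
                        sep_low = sep_low)
    calls[, li] <- call_genotypes(qc, pol$theta, samples, parents = parents,
                                  sd_mult = sd_mult)
    qc_rows[[li]] <- data.frame(locus = loci[li], pattern = qc$pattern,
                                k = qc$k,
                                separation = qc$separation,
                                call_rate = mean(!is.na(calls[, li])))
  }
  list(calls = calls, qc = do.call(rbind, qc_rows))
}

#' Missingness-based matrix QC
#'
#' Drops samples whose missing fraction exceeds `sample_missing_max`, then
#' loci whose missing fraction (over the retained samples) exceeds
#' `locus_missing_max` -- sample exclusion is applied first, and locus
#' missingness uses the post-exclusion denominator. Uninformative loci
#' (entirely missing or monomorphic among calls) are reported separately
#' but only dropped on request.
#'
#' @param calls samples x loci character matrix
#' @param sample_missing_max,locus_missing_max exclusive missingness bounds
#' @param drop_uninformative also drop loci with < 2 distinct calls?
#' @return list: `calls` (filtered matrix), `excluded_samples`,
#'   `excluded_loci`, `uninformative_loci`
#' @export
qc_matrix <- function(calls, sample_missing_max = 0.20,
                      locus_missing_max = 0.20, drop_uninformative = FALSE) {
  miss_s <- rowMeans(is.na(calls))
  excl_s <- rownames(calls)[miss_s > sample_missing_max]
  m <- calls[!(rownames(calls) %in% excl_s), , drop = FALSE]
  miss_l <- colMeans(is.na(m))
  excl_l <- colnames(m)[miss_l > locus_missing_max]
  m <- m[, !(colnames(m) %in% excl_l), drop = FALSE]
  n_distinct <- apply(m, 2, function(g) length(unique(g[!is.na(g)])))
  uninf <- colnames(m)[n_distinct < 2]
  if (drop_uninformative) m <- m[, !(colnames(m) %in% uninf), drop = FALSE]
  list(calls = m, excluded_samples = excl_s, excluded_loci = excl_l,
       uninformative_loci = uninf)
}
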