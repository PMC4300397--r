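# diversity statistics, F-statistics, AMOVA, NJ tree, admixture EM, delta-K

test_that("locus statistics match formula evaluations", {
  # p = 0.5: He 0.5, PIC 0.375 (the biallelic analytic ceiling)
  s <- locus_stats(geno_counts(10, 0, 10))
  expect_equal(s$He, 0.5)
  expect_equal(s$PIC, 0.375)
  # p = 0.9: He 0.18, PIC 0.1638
  s2 <- locus_stats(geno_counts(9, 0, 1))
  expect_equal(s2$He, 0.18, tolerance = 1e-12)
  expect_equal(s2$PIC, 0.1638, tolerance = 1e-12)
  expect_equal(s2$maf, 0.9)
  # three equifrequent alleles: He 2/3, PIC 16/27
  m <- matrix(c("AA", "BB", "CC"), 3, 1, dimnames = list(NULL, "L1"))
  s3 <- locus_stats(m)
  expect_equal(s3$He, 2 / 3, tolerance = 1e-12)
  expect_equal(s3$PIC, 2 / 3 - 3 * 2 * (1 / 9)^2, tolerance = 1e-12)
  # all-missing locus yields missing stats
  m2 <- matrix(NA_character_, 4, 1, dimnames = list(NULL, "L1"))
  expect_true(is.na(locus_stats(m2)$He))
})

test_that("PIC never exceeds He and both peak at uniform frequencies", {
  for (p in seq(0.05, 0.95, by = 0.05)) {
    nAA <- round(100 * p^2); nBB <- round(100 * (1 - p)^2)
    nAB <- 100 - nAA - nBB
    s <- locus_stats(geno_counts(nAA, nAB, nBB))
    expect_lte(s$PIC, s$He + 1e-12)
  }
  grid <- vapply(seq(0.5, 0.95, by = 0.05), function(p) {
    q <- round(200 * p); locus_stats(geno_counts(q / 2, 0, 100 - q / 2))$He
  }, numeric(1))
  expect_equal(which.max(grid), 1L) # maximal at p = 0.5
})

test_that("F statistics: pooled inbreeding and Weir-Cockerham fixation", {
  # fully homozygous panel at He = 0.5: F_IS = 1
  f <- f_stats(geno_counts(10, 0, 10))
  expect_equal(f$F_IS, 1)
  # Ho = 0.02 at He = 0.5: F_IS = 0.96
  f2 <- f_stats(geno_counts(49, 2, 49))
  ho <- 2 / 100; he <- 1 - (0.5^2 + 0.5^2)
  expect_equal(f2$F_IS, 1 - ho / he, tolerance = 1e-12)
  expect_equal(round(f2$F_IS, 2), 0.96)
  # two subpopulations fixed for alternate alleles: F_ST = 1
  g <- rbind(geno_counts(10), matrix("BB", 10, 1, dimnames = list(
    sprintf("T%02d", 1:10), "L01")))
  f3 <- f_stats(g, rep(c("p1", "p2"), each = 10))
  expect_equal(f3$F_ST, 1)
  expect_error(f_stats(geno_counts(5, 0, 5), rep("p1", 10)), ">= 2 subpopulations")
})

test_that("AMOVA equals the brute-force sums-of-squares decomposition", {
  # 6-accession worked set, 4 loci
  g <- rbind(AA1 = c("AA", "AA", "AB", "AA"), AA2 = c("AA", "AB", "AA", "AA"),
             AA3 = c("AB", "AA", "AA", "BB"), BB1 = c("BB", "BB", "AB", "BB"),
             BB2 = c("BB", "BB", "BB", "AB"), BB3 = c("AB", "BB", "BB", "BB"))
  colnames(g) <- sprintf("L%d", 1:4)
  lab <- rep(c("g1", "g2"), each = 3)
  a <- amova(g, lab, n_perm = 200, seed = 1)
  # oracle: per-locus one-way ANOVA sums of squares on allele dosage
  d <- matrix(match(g, c("AA", "AB", "BB")) - 1, 6, 4)
  SS_T <- sum(scale(d, scale = FALSE)^2)
  SS_W <- sum(vapply(unique(lab), function(l)
    sum(scale(d[lab == l, ], scale = FALSE)^2), numeric(1)))
  expect_equal(a$SS_within, SS_W, tolerance = 1e-9)
  expect_equal(a$SS_among, SS_T - SS_W, tolerance = 1e-9)
  sw <- SS_W / 4; n0 <- (6 - (9 + 9) / 6) / 1
  sa <- ((SS_T - SS_W) / 1 - sw) / n0
  expect_equal(a$phi_st, sa / (sa + sw), tolerance = 1e-9)
})

test_that("AMOVA is maximal on fixed differences and null under shuffled labels", {
  g <- rbind(matrix("AA", 10, 20), matrix("BB", 10, 20))
  rownames(g) <- sprintf("S%02d", 1:20)
  colnames(g) <- sprintf("L%02d", 1:20)
  a <- amova(g, rep(c("x", "y"), each = 10), n_perm = 99, seed = 2)
  expect_equal(a$phi_st, 1)
  expect_equal(a$p_value, 1 / 100)
  # random labels on a panmictic panel: small phi, non-significant
  set.seed(3)
  p <- simulate_panel(40, 100, K = 1, drift_fst = 0, selfing_rate = 0.9,
                      admix_frac = 0, seed = 4)
  a2 <- amova(p, sample(rep(c("x", "y"), each = 20)), n_perm = 199, seed = 5)
  expect_lt(abs(a2$phi_st), 0.05)
  expect_gt(a2$p_value, 0.01)
  expect_error(amova(g, c("x", rep("y", 19)), n_perm = 10), ">= 2 members")
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  taxa <- c("A", "B", "C", "D")
  # tree ((A,B),(C,D)) with edges A:2 B:3 C:4 D:1, internal 2 (100 loci)
  splits <- list(list(side = "A", w = 2), list(side = "B", w = 3),
                 list(side = "C", w = 4), list(side = "D", w = 1),
                 list(side = c("A", "B"), w = 2))
  g <- split_geno(splits, taxa)
  L <- ncol(g)
  res <- nj_tree(g, bootstrap_n = 0)
  tr <- res$tree
  # topology: A+B form a cherry
  pairs <- ape::prop.part(tr)
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")) ||
              ape::is.monophyletic(ape::unroot(tr), c("C", "D")))
  # branch lengths exact on the additive metric (distances in units of 1/L)
  dm <- as.matrix(res$dist) * L
  expect_equal(dm["A", "B"], 5)
  expect_equal(dm["A", "C"], 8)
  expect_equal(dm["C", "D"], 5)
  ed <- ape::dist.nodes(tr)[1:4, 1:4] * L
  dimnames(ed) <- list(tr$tip.label, tr$tip.label)
  expect_equal(ed[taxa, taxa], dm[taxa, taxa], tolerance = 1e-9)
})

test_that("clone groups split with full bootstrap support", {
  g <- rbind(matrix("AA", 3, 40), matrix("BB", 3, 40))
  rownames(g) <- c(paste0("a", 1:3), paste0("b", 1:3))
  colnames(g) <- sprintf("L%02d", 1:40)
  res <- nj_tree(g, bootstrap_n = 100, seed = 6)
  dm <- as.matrix(res$dist)
  expect_equal(dm["a1", "a2"], 0)      # identical accessions: zero distance
  expect_equal(dm["a1", "b1"], 1)
  expect_true(any(res$support == 1))   # the clade split appears in every replicate
  expect_error(nj_tree(g[1:2, , drop = FALSE]), "3")
})

test_that("admixture EM: closed form at K = 1, recovery at K = 2, row symmetry", {
  g <- rbind(geno_counts(4, 2, 4), geno_counts(4, 2, 4))[1:10, , drop = FALSE]
  rownames(g) <- sprintf("S%02d", 1:10)
  f1 <- admixture_fit(g, 1, n_replicates = 2, seed = 1)
  p_pool <- mean(match(g, c("AA", "AB", "BB")) - 1) / 2
  lnl_oracle <- sum((match(g, c("AA", "AB", "BB")) - 1) * log(p_pool) +
                    (2 - (match(g, c("AA", "AB", "BB")) - 1)) * log(1 - p_pool))
  expect_equal(f1$lnL, lnl_oracle, tolerance = 1e-6)
  expect_true(all(f1$Q == 1))
  # two fixed-difference populations: Q recovered within 0.05
  gm <- rbind(matrix("AA", 10, 50), matrix("BB", 10, 50))
  rownames(gm) <- sprintf("A%02d", 1:20); colnames(gm) <- sprintf("L%02d", 1:50)
  f2 <- admixture_fit(gm, 2, n_replicates = 3, seed = 2)
  Qt <- rbind(matrix(c(1, 0), 10, 2, byrow = TRUE),
              matrix(c(0, 1), 10, 2, byrow = TRUE))
  expect_lt(max(abs(align_q(f2$Q, Qt) - Qt)), 0.05)
  expect_equal(unname(rowSums(f2$Q)), rep(1, 20), tolerance = 1e-9)
  # duplicated accession rows get identical ancestry
  gdup <- gm[c(1, 1, 11, 11), , drop = FALSE]
  rownames(gdup) <- sprintf("D%d", 1:4)
  f3 <- admixture_fit(gdup, 2, n_replicates = 2, seed = 3)
  expect_equal(f3$Q[1, ], f3$Q[2, ], tolerance = 1e-6)
  expect_error(admixture_fit(gm[1:3, ], 5), "exceeds")
})

test_that("Evanno delta-K matches its formula and contracts", {
  tab <- data.frame(K = rep(1:3, each = 2), replicate = rep(1:2, 3),
                    lnL = c(-1000.5, -999.5, -900.5, -899.5, -880.5, -879.5))
  ev <- evanno_delta_k(tab)
  # |L''(2)| = |-880 + 1800 - 1000| = 80; sd at K=2 is sd(c(-900.5,-899.5))
  expect_equal(ev$lppK[2], 80)
  expect_equal(ev$delta_K[2], 80 / sd(c(-900.5, -899.5)))
  expect_true(all(is.na(ev$delta_K[c(1, 3)]))) # endpoints undefined
  # linear mean lnL in K: zero second difference everywhere defined
  tab2 <- data.frame(K = rep(1:4, each = 2), replicate = rep(1:2, 4),
                     lnL = rep(c(-100, -90, -80, -70), each = 2) + c(-0.5, 0.5))
  expect_equal(evanno_delta_k(tab2)$delta_K[2:3], c(0, 0))
  # identical replicates: sd 0 -> undefined
  tab3 <- data.frame(K = rep(1:3, each = 2), replicate = rep(1:2, 3),
                     lnL = rep(c(-100, -90, -85), each = 2))
  expect_true(is.na(evanno_delta_k(tab3)$delta_K[2]))
  # single replicate: error
  expect_error(evanno_delta_k(data.frame(K = 1:3, replicate = 1,
                                         lnL = c(-3, -2, -1))), "2 replicates")
})

test_that("population assignment applies the strict 70% ancestry rule", {
  Q <- rbind(c(0.71, 0.29), c(0.60, 0.40), c(0.70, 0.30), c(0.10, 0.90))
  expect_equal(assign_populations(Q),
               c("pop_1", "admixed", "admixed", "pop_2"))
})
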