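test_that("MAF filter is ploidy-aware and strict at the threshold", {
  # 4 diploids; hand-set columns with allele frequencies
  dos <- cbind(c(0L, 0L, 0L, 0L),   # freq 0    -> drop
               c(0L, 1L, 1L, 2L),   # freq 0.5  -> keep
               c(0L, 0L, 0L, 1L),   # freq 1/8  -> keep (0.125 > 0.1)
               c(0L, 0L, 1L, 0L),   # freq 1/8  -> keep
               c(2L, 2L, 2L, 2L),   # freq 1    -> drop
               c(0L, 0L, 0L, 2L))   # freq 0.25 -> keep
  x <- geno_matrix(dos, positions = 1:6 * 100, chrom_length = 1000)
  f <- filter_maf(x, 0.1)
  expect_equal(f$positions, c(200, 300, 400, 600))
  # exactly at the threshold: MAF must be strictly above
  x2 <- geno_matrix(cbind(c(0L, 0L, 0L, 0L, 1L)),
                    positions = 100, chrom_length = 1000)  # freq 0.1
  expect_warning(f2 <- filter_maf(x2, 0.1), "no informative")
  expect_equal(n_snps(f2), 0)
})

test_that("ten-SNP fixture with known frequencies keeps six at MAF 0.1", {
  withr::local_seed(99)
  # six target frequencies above the 0.1 threshold, four below
  freqs <- c(0.02, 0.5, 0.05, 0.3, 0.2, 0.45, 0.25, 0.04, 0.35, 0.06)
  # 200 diploids so realized frequencies stay on the intended side
  dos <- sapply(freqs, function(p) stats::rbinom(200, 2, p))
  x <- geno_matrix(dos, positions = 1:10 * 1000, chrom_length = 1e5)
  alt <- colSums(dos) / 400
  expected_kept <- which(pmin(alt, 1 - alt) > 0.1)
  f <- filter_maf(x, 0.1)
  expect_equal(f$positions, expected_kept * 1000)
  expect_equal(n_snps(f), 6)
})

test_that("PCA separates uniform dosage groups on a rank-1 matrix", {
  x <- rank1_matrix(n_per_group = 2, n_snps = 6)
  p <- run_pca(x)
  expect_equal(length(unique(round(p$scores[, 1], 8))), 3)
  pv <- p$explained_var / sum(p$explained_var)
  expect_equal(pv[1], 1)                      # all variance on PC1
  expect_equal(abs(p$loadings[, 1]), rep(1 / sqrt(6), 6))  # equal loadings
})

test_that("PCA scores reconstruct from centered data times loadings", {
  sim <- simulate_inversion_population(sim_config(seed = 21, n_samples = 12,
                                                  n_snps_inside = 30,
                                                  n_snps_outside = 10))
  x <- sim$matrix
  x$dosage[1, 3] <- NA  # exercise mean imputation
  p <- run_pca(x)
  d <- x$dosage * (2 / x$ploidy)
  d[1, 3] <- mean(d[-1, 3])
  dc <- sweep(d, 2, colMeans(d))
  expect_lt(max(abs(dc %*% p$loadings - p$scores)), 1e-8)
  expect_true(all(diff(p$explained_var) <= 1e-9))
  # orthonormal loadings
  expect_lt(max(abs(crossprod(p$loadings) - diag(ncol(p$loadings)))), 1e-8)
  expect_error(run_pca(geno_matrix(matrix(1L, 3, 3), 1:3 * 10,
                                   chrom_length = 100)),
               "zero variance")
})

test_that("PCA matches brute-force eigen-decomposition on small matrices", {
  withr::local_seed(7)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    m <- sample(2:10, 1)
    dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
    if (all(apply(dos, 2, stats::var) == 0)) next
    x <- geno_matrix(dos, positions = seq_len(m) * 10, chrom_length = 1e4)
    p <- run_pca(x)
    ev <- eigen(stats::cov(dos), symmetric = TRUE)
    keep <- seq_along(p$explained_var)
    expect_equal(p$explained_var, ev$values[keep], tolerance = 1e-8)
    for (j in keep) {
      expect_equal(abs(sum(p$loadings[, j] * ev$vectors[, j])), 1,
                   tolerance = 1e-6)
    }
  }
})

test_that("cluster detection follows the gap criterion deterministically", {
  r1 <- detect_clusters(c(-10, -10, 0, 0, 10, 10))
  expect_equal(r1$cluster_count, 3)
  expect_equal(r1$assignment, c(1, 1, 2, 2, 3, 3))
  expect_equal(detect_clusters(rep(1, 6))$cluster_count, 1)
  r2 <- detect_clusters(c(-5, -5, -5, 5, 5, 5))
  expect_equal(r2$cluster_count, 2)
  expect_equal(r2$assignment, c(1, 1, 1, 2, 2, 2))
  # smooth noise: no cluster evidence
  withr::local_seed(2)
  expect_equal(detect_clusters(stats::rnorm(20))$cluster_count, 1)
  expect_error(detect_clusters(c(1, 2, 3)), "at least 4")
})

test_that("exhaustive check of the gap criterion on the two-cluster vector", {
  pc1 <- c(-5, -5, -5, 5, 5, 5)
  # all 2^6 - 2 non-trivial bipartitions: only the sign split satisfies
  # gap > 2 * max within-range with positive gap
  best <- NULL
  for (mask in 1:(2^6 - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:5)))
    a <- pc1[grp]
    b <- pc1[!grp]
    if (max(a) < min(b)) {
      gap <- min(b) - max(a)
      wr <- max(max(a) - min(a), max(b) - min(b))
      if (gap > 0 && gap > 2 * wr) best <- rbind(best, c(sum(grp), gap))
    }
  }
  expect_equal(nrow(best), 1)
  expect_equal(best[1, 1], 3)  # the 3/3 split
})

test_that("karyotype assignment counts alleles and names the major class", {
  # 19 samples in three clusters sized 7 / 8 / 4 along PC1
  dos <- rbind(matrix(0L, 7, 8), matrix(1L, 8, 8), matrix(2L, 4, 8))
  x <- geno_matrix(dos, positions = 1:8 * 1e5, chrom_length = 1e6)
  p <- run_pca(x)
  cl <- detect_clusters(p$scores[, 1])
  expect_equal(cl$cluster_count, 3)
  cs <- assign_karyotypes(cl, x, p)
  expect_equal(cs$allele_freq_major, (2 * 7 + 8) / (2 * 19))
  tab <- table(cs$calls$karyotype)
  expect_equal(unname(tab[c("HOM_MAJ", "HET", "HOM_MIN")]),
               as.integer(c(7, 8, 4)), ignore_attr = TRUE)
  # HET cluster mean PC1 strictly between the homozygote cluster means
  mns <- tapply(cs$calls$pc1, cs$calls$karyotype, mean)
  expect_true(mns[["HOM_MAJ"]] < mns[["HET"]], mns[["HET"]] < mns[["HOM_MIN"]])
})

test_that("two-cluster case identifies heterokaryotypes by heterozygosity", {
  # 12 HOM_MAJ (dosage 0) + 8 HET (dosage 1)
  dos <- rbind(matrix(0L, 12, 10), matrix(1L, 8, 10))
  x <- geno_matrix(dos, positions = 1:10 * 1e4, chrom_length = 1e6)
  p <- run_pca(x)
  cl <- detect_clusters(p$scores[, 1])
  expect_equal(cl$cluster_count, 2)
  cs <- assign_karyotypes(cl, x, p)
  expect_equal(sum(cs$calls$karyotype == "HET"), 8)
  expect_equal(sum(cs$calls$karyotype == "HOM_MAJ"), 12)
  expect_equal(cs$allele_freq_major, (2 * 12 + 8) / 40)
})

test_that("symmetric three-cluster case breaks the tie toward lower PC1", {
  dos <- rbind(matrix(0L, 5, 6), matrix(1L, 5, 6), matrix(2L, 5, 6))
  x <- geno_matrix(dos, positions = 1:6 * 1e4, chrom_length = 1e6)
  p <- run_pca(x)
  cs <- assign_karyotypes(detect_clusters(p$scores[, 1]), x, p)
  expect_equal(cs$allele_freq_major, 0.5)
  # the lower-PC1 homozygote cluster is named HOM_MAJ
  expect_equal(cs$calls$karyotype[which.min(cs$calls$pc1)], "HOM_MAJ")
})

test_that("exact HWE test matches enumeration and handles edge cases", {
  expect_equal(hwe_exact(25, 50, 25), 1)   # observed table is modal
  expect_equal(hwe_exact(19, 0, 0), 1)     # monomorphic
  # full enumeration oracle for (5, 0, 5)
  n <- 10
  nA <- 10
  h_all <- seq(0, 10, by = 2)
  probs <- sapply(h_all, function(h) {
    naa <- (nA - h) / 2
    nbb <- n - naa - h
    exp(lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
          h * log(2) - (lgamma(2 * n + 1) - lgamma(nA + 1) -
                          lgamma(2 * n - nA + 1)))
  })
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  p_expected <- sum(probs[probs <= probs[1] * (1 + 1e-9)])
  expect_equal(hwe_exact(5, 0, 5), p_expected, tolerance = 1e-12)
  # probabilities sum to 1 across many configurations
  for (cfg in list(c(3, 4, 5), c(10, 2, 1), c(0, 5, 5))) {
    p <- hwe_exact(cfg[1], cfg[2], cfg[3])
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
})

test_that("test_hwe uses diploid karyotyped samples from a callset", {
  dos <- rbind(matrix(0L, 5, 6), matrix(1L, 10, 6), matrix(2L, 5, 6))
  x <- geno_matrix(dos, positions = 1:6 * 1e4, chrom_length = 1e6)
  p <- run_pca(x)
  cs <- assign_karyotypes(detect_clusters(p$scores[, 1]), x, p)
  cs <- test_hwe(cs)
  expect_equal(cs$hwe_p, hwe_exact(5, 10, 5))
})

test_that("breakpoint block spans the top-loading SNPs", {
  # loadings high only at SNPs 10..50 out of 1000
  withr::local_seed(31)
  n <- 21
  m <- 1000
  base <- matrix(stats::rbinom(n * m, 2, 0.5), n, m)
  k <- rep(c(0L, 1L, 2L), each = 7)
  base[, 10:50] <- matrix(k, n, 41)
  x <- geno_matrix(base, positions = seq_len(m) * 1000, chrom_length = 2e6)
  p <- run_pca(x)
  bb <- locate_breakpoint_block(p, top_frac = 0.041)
  expect_equal(bb$block, c(10000, 50000))
  expect_equal(bb$contiguity, 1)
  # uniform loadings: block spans the whole range, degenerate contiguity
  u <- rank1_matrix(2, 10)
  pu <- run_pca(u)
  expect_warning(locate_breakpoint_block(pu, top_frac = 0.005),
                 "falling back")
  bu <- suppressWarnings(locate_breakpoint_block(pu, top_frac = 0.005))
  expect_equal(bu$block, range(u$positions))
})

test_that("projection reproduces training scores and handles missing data", {
  sim <- simulate_inversion_population(sim_config(seed = 13))
  sc <- scan_chromosome(sim$matrix)
  pr <- project_samples(sim$matrix, sc$pca, sc$callset)
  keep <- match(sc$pca$snp_index, sim$matrix$positions)
  expect_lt(max(abs(pr$pc1 - sc$pca$scores[, 1])), 1e-8)
  expect_equal(pr$karyotype, sc$callset$calls$karyotype)

  # all-missing sample is unassigned
  hold <- subset_samples(sim$matrix, 1:2)
  hold$dosage[2, ] <- NA
  pr2 <- project_samples(hold, sc$pca, sc$callset)
  expect_equal(pr2$karyotype[2], "unassigned")
  expect_true(is.na(pr2$pc1[2]))

  # no shared SNPs is an error; few shared SNPs warns
  off <- geno_matrix(matrix(0:1, 2, 2), c(3, 7), chrom_length = 100)
  expect_error(project_samples(off, sc$pca, sc$callset), "no shared")
})

test_that("scan_chromosome reports no inversion for uninformative input", {
  x <- geno_matrix(matrix(0L, 4, 3), 1:3 * 10, chrom_length = 100)
  res <- scan_chromosome(x)
  expect_equal(res$callset$cluster_count, 1)
  expect_true(all(res$callset$calls$karyotype == "unassigned"))
  expect_null(res$pca)
})
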