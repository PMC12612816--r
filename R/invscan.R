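#' Filter SNPs by minor allele frequency
#'
#' Allele frequencies are computed ploidy-aware from non-missing dosages
#' (haploid samples contribute one allele). SNPs with MAF strictly above
#' `maf_min` are retained.
#'
#' @param x a [geno_matrix()].
#' @param maf_min minimum minor allele frequency (exclusive); default 0.1.
#' @return a [geno_matrix()] with the retained SNPs; zero SNPs (with a
#'   warning naming the condition) when none are informative.
#' @export
filter_maf <- function(x, maf_min = 0.1) {
  if (n_snps(x) < 1) stop("no SNPs in input", call. = FALSE)
  alt <- colSums(x$dosage, na.rm = TRUE)
  tot <- colSums((!is.na(x$dosage)) * x$ploidy)
  f <- ifelse(tot > 0, alt / tot, 0)
  maf <- pmin(f, 1 - f)
  keep <- maf > maf_min
  if (!any(keep)) {
    warning("no informative SNPs: all below MAF threshold ", maf_min)
  }
  subset_snps(x, which(keep))
}

#' Principal component analysis of a genotype matrix
#'
#' SVD of the column-centered dosage matrix (no variance scaling). Missing
#' dosages are mean-imputed per SNP; hemizygous (ploidy-1) dosages are
#' doubled to the diploid scale first. Component signs are fixed by forcing
#' the largest-magnitude loading of each component to be positive, so results
#' are fully deterministic.
#'
#' @param x a [geno_matrix()] (>= 2 samples and >= 2 SNPs).
#' @return an object of class `inv_pca` with `scores` (samples x k),
#'   `loadings` (SNPs x k, orthonormal columns), `snp_index` (positions
#'   used), `explained_var` (variance per component, non-increasing),
#'   `center` (per-SNP means used for centering) and `samples`.
#' @export
run_pca <- function(x) {
  if (n_samples(x) < 2 || n_snps(x) < 2) {
    stop("need at least 2 samples and 2 SNPs for PCA", call. = FALSE)
  }
  d <- x$dosage * (2 / x$ploidy)  # hemizygous doubled to diploid scale
  for (j in seq_len(ncol(d))) {
    miss <- is.na(d[, j])
    if (any(miss)) d[miss, j] <- mean(d[!miss, j])
  }
  ctr <- colMeans(d)
  dc <- sweep(d, 2, ctr)
  if (all(abs(dc) < 1e-12)) {
    stop("zero variance: all samples identical after imputation", call. = FALSE)
  }
  sv <- svd(dc)
  k <- sum(sv$d > max(sv$d) * 1e-12)
  k <- max(k, 1L)
  U <- sv$u[, seq_len(k), drop = FALSE]
  V <- sv$v[, seq_len(k), drop = FALSE]
  dvals <- sv$d[seq_len(k)]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(V[, j]))
    if (V[i_max, j] < 0) {
      V[, j] <- -V[, j]
      U[, j] <- -U[, j]
    }
  }
  scores <- U %*% diag(dvals, k)
  rownames(scores) <- x$samples
  structure(list(
    scores = scores, loadings = V, snp_index = x$positions,
    explained_var = dvals^2 / (n_samples(x) - 1), center = ctr,
    samples = x$samples
  ), class = "inv_pca")
}

#' @export
print.inv_pca <- function(x, ...) {
  pv <- x$explained_var / sum(x$explained_var)
  cat(sprintf("<inv_pca> %d samples x %d SNPs; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), nrow(x$loadings), 100 * pv[1],
              if (length(pv) > 1) 100 * pv[2] else 0))
  invisible(x)
}

#' Exact 1-D k-means by dynamic programming over sorted values
#' @return list(assignment, centers, withinss)
#' @noRd
kmeans_1d <- function(x, k) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  sse <- function(i, j) {
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)
  for (j in 1:n) D[1, j] <- sse(1, j)
  if (k > 1) {
    for (q in 2:k) {
      for (j in q:n) {
        for (i in q:j) {
          v <- D[q - 1, i - 1] + sse(i, j)
          if (v < D[q, j] - 1e-12) {
            D[q, j] <- v
            B[q, j] <- i
          }
        }
      }
    }
  }
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  if (k > 1) for (q in k:2) bounds[q] <- B[q, bounds[q + 1]] - 1L
  bounds[1] <- 0L
  assign_sorted <- rep(seq_len(k), diff(bounds))
  assignment <- integer(n)
  assignment[o] <- assign_sorted
  centers <- vapply(seq_len(k), function(q) mean(xs[(bounds[q] + 1):bounds[q + 1]]),
                    0)
  list(assignment = assignment, centers = centers, withinss = D[k, n])
}

#' Detect discrete clusters along PC1
#'
#' Fits exact 1-D k-means for k in 1..3 and accepts a k when the minimum
#' between-cluster gap exceeds `gap_ratio` times the maximum within-cluster
#' range (and is positive). The largest accepted k wins; when no k >= 2 is
#' accepted the result is `cluster_count = 1`, meaning "no inversion
#' evidence". Entirely deterministic.
#'
#' @param pc1 numeric vector of PC1 scores (>= 4 values).
#' @param gap_ratio required ratio of between-cluster gap to within-cluster
#'   range; default 2.
#' @param max_k maximum cluster count considered (default 3).
#' @return list with `cluster_count` and `assignment` (integer labels ordered
#'   by increasing PC1 cluster mean; all 1 when `cluster_count = 1`).
#' @export
detect_clusters <- function(pc1, gap_ratio = 2, max_k = 3) {
  if (length(pc1) < 4) stop("need at least 4 samples", call. = FALSE)
  kmax <- min(max_k, length(unique(pc1)))
  for (k in if (kmax >= 2) seq(kmax, 2) else integer(0)) {
    km <- kmeans_1d(pc1, k)
    rng <- vapply(seq_len(k), function(q) {
      v <- pc1[km$assignment == q]
      max(v) - min(v)
    }, 0)
    lo <- vapply(seq_len(k), function(q) min(pc1[km$assignment == q]), 0)
    hi <- vapply(seq_len(k), function(q) max(pc1[km$assignment == q]), 0)
    ordq <- order(km$centers)
    gaps <- lo[ordq][-1] - hi[ordq][-k]
    if (min(gaps) > 0 && min(gaps) > gap_ratio * max(rng)) {
      relab <- match(km$assignment, ordq)
      return(list(cluster_count = k, assignment = relab))
    }
  }
  list(cluster_count = 1L, assignment = rep(1L, length(pc1)))
}

#' Assign inversion karyotypes from PC1 clusters
#'
#' With three clusters the extremes are the two homozygote classes and the
#' central cluster is heterokaryotypic; with two clusters the cluster with
#' the higher mean heterozygosity at the top-loading SNPs is called
#' heterokaryotypic and the other homozygous for the major allele. Major and
#' minor arrangements are named by the resulting allele frequency (haploid
#' samples contribute one allele; ties resolved toward the lower-PC1
#' cluster).
#'
#' @param clusters result of [detect_clusters()].
#' @param x the [geno_matrix()] used for PCA (after MAF filtering).
#' @param pca the [run_pca()] result.
#' @param het_top_frac fraction of top-|loading| SNPs used to measure
#'   heterozygosity in the 2-cluster case.
#' @return a `karyotype_calls` object: `calls` tibble (`sample`, `pc1`,
#'   `cluster`, `karyotype`), `chrom`, `cluster_count`, `allele_freq_major`,
#'   `hwe_p` (filled by [test_hwe()]), `breakpoint_block` (filled by
#'   [locate_breakpoint_block()]).
#' @export
assign_karyotypes <- function(clusters, x, pca, het_top_frac = 0.05) {
  k <- clusters$cluster_count
  pc1 <- pca$scores[, 1]
  calls <- tibble::tibble(sample = x$samples, sex = x$sex,
                          ploidy = x$ploidy, pc1 = unname(pc1),
                          cluster = clusters$assignment)
  if (k < 2) {
    calls$karyotype <- "unassigned"
    return(new_karyotype_calls(calls, x$chrom, 1L, NA_real_))
  }
  if (k == 3) {
    lab <- c("HOM_A", "HET", "HOM_B")[calls$cluster]
    # haploid samples cannot be heterokaryotypic
    lab[lab == "HET" & calls$ploidy == 1L] <- "unassigned"
    if (any(lab == "unassigned")) {
      warning("haploid sample(s) in the central cluster left unassigned")
    }
  } else {
    # at least 10 SNPs: with few carriers, single high-variance polymorphic
    # sites can outrank the diagnostic sites by chance
    n_top <- min(n_snps(x), max(10L, ceiling(het_top_frac * n_snps(x))))
    top <- order(abs(pca$loadings[, 1]), decreasing = TRUE)[seq_len(n_top)]
    het_rate <- vapply(1:2, function(q) {
      rows <- which(calls$cluster == q & calls$ploidy == 2L)
      if (length(rows) == 0) return(NA_real_)
      mean(x$dosage[rows, top, drop = FALSE] == 1L, na.rm = TRUE)
    }, 0)
    if (any(is.na(het_rate)) || abs(diff(het_rate)) < 1e-6) {
      warning("ambiguous 2-cluster heterozygosity; samples left unassigned")
      calls$karyotype <- "unassigned"
      return(new_karyotype_calls(calls, x$chrom, 2L, NA_real_))
    }
    het_cl <- which.max(het_rate)
    lab <- ifelse(calls$cluster == het_cl, "HET", "HOM_A")
    lab[lab == "HET" & calls$ploidy == 1L] <- "unassigned"
  }
  # allele counting: HOM_X contributes ploidy copies of X, HET one of each
  n_allele <- c(A = 0, B = 0)
  for (i in seq_len(nrow(calls))) {
    n_allele <- n_allele + switch(lab[i],
      HOM_A = c(calls$ploidy[i], 0),
      HOM_B = c(0, calls$ploidy[i]),
      HET = c(1, 1),
      c(0, 0))
  }
  freq_A <- n_allele[["A"]] / sum(n_allele)
  major_is_A <- freq_A >= 0.5  # tie toward the lower-PC1 cluster (A)
  karyotype <- dplyr::case_when(
    lab == "HOM_A" & major_is_A ~ "HOM_MAJ",
    lab == "HOM_A" & !major_is_A ~ "HOM_MIN",
    lab == "HOM_B" & major_is_A ~ "HOM_MIN",
    lab == "HOM_B" & !major_is_A ~ "HOM_MAJ",
    lab == "HET" ~ "HET",
    .default = "unassigned")
  calls$karyotype <- karyotype
  new_karyotype_calls(calls, x$chrom, as.integer(k),
                      max(freq_A, 1 - freq_A))
}

new_karyotype_calls <- function(calls, chrom, cluster_count,
                                allele_freq_major, hwe_p = NA_real_,
                                breakpoint_block = c(NA_real_, NA_real_),
                                block_contiguity = NA_real_) {
  structure(list(calls = calls, chrom = chrom, cluster_count = cluster_count,
                 allele_freq_major = allele_freq_major, hwe_p = hwe_p,
                 breakpoint_block = breakpoint_block,
                 block_contiguity = block_contiguity),
            class = "karyotype_calls")
}

#' @export
print.karyotype_calls <- function(x, ...) {
  cat(sprintf("<karyotype_calls> %s: %d cluster(s)", x$chrom, x$cluster_count))
  if (x$cluster_count >= 2) {
    cat(sprintf(", major-allele freq %.3f, HWE p = %s",
                x$allele_freq_major,
                ifelse(is.na(x$hwe_p), "NA", format(x$hwe_p, digits = 3))))
    if (!is.na(x$breakpoint_block[1])) {
      cat(sprintf("\n  breakpoint block %s-%s (contiguity %.2f)",
                  format(x$breakpoint_block[1], scientific = FALSE),
                  format(x$breakpoint_block[2], scientific = FALSE),
                  x$block_contiguity))
    }
  } else cat(" - no inversion evidence")
  cat("\n")
  print(table(x$calls$karyotype))
  invisible(x)
}

#' Exact conditional Hardy-Weinberg test
#'
#' Enumerates all heterozygote counts compatible with the observed allele
#' counts and sums the probabilities of tables no more probable than the
#' observed one. Monomorphic data give p = 1 by convention.
#'
#' @param n_hom_maj,n_het,n_hom_min diploid genotype counts, or pass a
#'   `karyotype_calls` object to `test_hwe()`.
#' @return exact p-value.
#' @export
hwe_exact <- function(n_hom_maj, n_het, n_hom_min) {
  n <- n_hom_maj + n_het + n_hom_min
  if (n < 2) stop("need at least 2 diploid genotypes", call. = FALSE)
  nA <- 2 * n_hom_maj + n_het
  nB <- 2 * n_hom_min + n_het
  if (nA == 0 || nB == 0) return(1)
  h_all <- seq(nA %% 2, min(nA, nB), by = 2)
  logp <- vapply(h_all, function(h) {
    naa <- (nA - h) / 2
    nbb <- (nB - h) / 2
    lgamma(n + 1) - lgamma(naa + 1) - lgamma(h + 1) - lgamma(nbb + 1) +
      h * log(2) - (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(nB + 1))
  }, 0)
  p_tab <- exp(logp)
  p_obs <- p_tab[match(n_het, h_all)]
  min(1, sum(p_tab[p_tab <= p_obs * (1 + 1e-9)]))
}

#' @rdname hwe_exact
#' @param callset a `karyotype_calls` object; haploid samples are excluded.
#' @return `test_hwe()` returns the callset with `hwe_p` filled in.
#' @export
test_hwe <- function(callset) {
  stopifnot(inherits(callset, "karyotype_calls"))
  d <- dplyr::filter(callset$calls, .data$ploidy == 2L,
                     .data$karyotype != "unassigned")
  if (nrow(d) < 2) {
    warning("fewer than 2 diploid karyotyped samples; HWE not computed")
    return(callset)
  }
  callset$hwe_p <- hwe_exact(sum(d$karyotype == "HOM_MAJ"),
                             sum(d$karyotype == "HET"),
                             sum(d$karyotype == "HOM_MIN"))
  callset
}

#' Locate the breakpoint block from PC1 loadings
#'
#' The SNPs whose absolute PC1 loadings fall in the top `top_frac` fraction
#' form the block; the positions of the first and last such SNP are taken as
#' the breakpoint interval. A contiguity QC number reports the fraction of
#' SNPs inside the interval that are themselves top SNPs (1 = a clean block).
#' When fewer than 2 SNPs make the cut the threshold falls back to the top 5%
#' with a warning.
#'
#' @param pca an `inv_pca`.
#' @param top_frac fraction of SNPs counted as top loadings (default 0.005).
#' @return list with `block` (start, end in bp), `contiguity`, and
#'   `top_index` (SNP indices of the top set).
#' @export
locate_breakpoint_block <- function(pca, top_frac = 0.005) {
  m <- nrow(pca$loadings)
  n_top <- ceiling(top_frac * m)
  if (n_top < 2) {
    warning("top ", top_frac * 100, "% holds fewer than 2 SNPs; ",
            "falling back to top 5%")
    n_top <- min(m, max(5L, ceiling(0.05 * m)))
  }
  al <- abs(pca$loadings[, 1])
  # value threshold at the n_top-th largest |loading|; exact ties (SNPs in
  # complete LD with the karyotype have identical loadings) are all included
  thr <- sort(al, decreasing = TRUE)[n_top]
  top <- which(al >= thr - 1e-12)
  block <- c(pca$snp_index[top[1]], pca$snp_index[top[length(top)]])
  inside <- which(pca$snp_index >= block[1] & pca$snp_index <= block[2])
  list(block = block, contiguity = length(top) / length(inside),
       top_index = top)
}

#' Scan one chromosome for an inversion polymorphism
#'
#' Convenience pipeline: MAF filter, PCA, PC1 cluster detection, karyotype
#' assignment, exact HWE test and breakpoint-block localization.
#'
#' @param x a [geno_matrix()].
#' @param maf_min MAF threshold (default 0.1).
#' @param gap_ratio cluster-gap acceptance ratio (default 2).
#' @param top_frac top-loading fraction for the breakpoint block.
#' @return list with `callset` (a `karyotype_calls`), `pca` (an `inv_pca`)
#'   and `matrix` (the filtered [geno_matrix()]); `pca` is `NULL` when no
#'   informative SNPs remain.
#' @export
scan_chromosome <- function(x, maf_min = 0.1, gap_ratio = 2,
                            top_frac = 0.005) {
  xf <- suppressWarnings(filter_maf(x, maf_min))
  if (n_snps(xf) < 2) {
    calls <- tibble::tibble(sample = x$samples, sex = x$sex,
                            ploidy = x$ploidy, pc1 = NA_real_, cluster = 1L,
                            karyotype = "unassigned")
    return(list(callset = new_karyotype_calls(calls, x$chrom, 1L, NA_real_),
                pca = NULL, matrix = xf))
  }
  pca <- run_pca(xf)
  cl <- detect_clusters(pca$scores[, 1], gap_ratio = gap_ratio)
  cs <- assign_karyotypes(cl, xf, pca)
  if (cs$cluster_count >= 2) {
    cs <- suppressWarnings(test_hwe(cs))
    bb <- suppressWarnings(locate_breakpoint_block(pca, top_frac))
    cs$breakpoint_block <- bb$block
    cs$block_contiguity <- bb$contiguity
  }
  list(callset = cs, pca = pca, matrix = xf)
}

#' Project new samples onto a trained PCA and predict karyotypes
#'
#' New samples are matched to the training SNPs by position, centered with
#' the training means and projected onto the training PC1 loading restricted
#' to the shared SNPs (re-normalized by its squared norm, so a training
#' sample with full overlap reproduces its PC1 score exactly). Each projected
#' sample is assigned the karyotype of the nearest trained cluster mean on
#' PC1; samples with no usable genotype are left unassigned.
#'
#' @param new_matrix a [geno_matrix()] of new samples.
#' @param pca trained `inv_pca`.
#' @param callset trained `karyotype_calls`.
#' @param min_shared warn when fewer shared SNPs than this (default 10).
#' @return tibble with `sample`, `pc1`, `karyotype`, `n_shared`.
#' @export
project_samples <- function(new_matrix, pca, callset, min_shared = 10) {
  shared <- match(pca$snp_index, new_matrix$positions)
  train_idx <- which(!is.na(shared))
  new_idx <- shared[train_idx]
  if (length(train_idx) == 0) stop("no shared SNPs", call. = FALSE)
  if (length(train_idx) < min_shared) {
    warning("only ", length(train_idx), " shared SNP(s); projection may be ",
            "unreliable")
  }
  v <- pca$loadings[train_idx, 1]
  ctr <- pca$center[train_idx]
  d <- new_matrix$dosage[, new_idx, drop = FALSE] * (2 / new_matrix$ploidy)
  cl_means <- dplyr::summarise(
    dplyr::filter(callset$calls, .data$karyotype != "unassigned"),
    mu = mean(.data$pc1), .by = "karyotype")
  score <- rep(NA_real_, n_samples(new_matrix))
  for (i in seq_len(nrow(d))) {
    ok <- !is.na(d[i, ])
    if (!any(ok)) next
    xi <- d[i, ]
    xi[!ok] <- ctr[!ok]  # training-mean imputation
    score[i] <- sum((xi - ctr) * v) / sum(v^2)
  }
  karyotype <- vapply(score, function(s) {
    if (is.na(s) || nrow(cl_means) == 0) return("unassigned")
    cl_means$karyotype[which.min(abs(cl_means$mu - s))]
  }, "")
  tibble::tibble(sample = new_matrix$samples, pc1 = score,
                 karyotype = karyotype, n_shared = length(train_idx))
}
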