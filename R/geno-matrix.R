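#' Genotype matrix container
#'
#' A `geno_matrix` holds per-sample SNP dosages for one chromosome: an
#' `n_samples x n_snps` integer matrix of alternative-allele counts
#' (0/1/2, `NA` for missing) together with sample labels, per-sample sex and
#' ploidy, and 1-based SNP positions. Positions must be strictly increasing;
#' dosages may never exceed a sample's ploidy. Hemizygous samples (e.g.
#' females on an avian Z chromosome) carry ploidy 1 and dosages in {0, 1};
#' doubling of hemizygous dosages happens only inside PCA, never in storage.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; `NA` =
#'   missing call.
#' @param positions integer vector of 1-based SNP positions (bp), strictly
#'   increasing, one per column of `dosage`.
#' @param chrom chromosome label.
#' @param chrom_length chromosome length in bp.
#' @param samples sample labels; defaults to rownames of `dosage` or
#'   `S1..Sn`.
#' @param sex per-sample sex, each `"M"`, `"F"` or `"unknown"`.
#' @param ploidy per-sample ploidy on this chromosome, 1 or 2.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, positions, chrom = "chr1",
                        chrom_length = max(positions),
                        samples = NULL, sex = NULL, ploidy = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(samples)) {
    samples <- rownames(dosage) %||% paste0("S", seq_len(n))
  }
  if (is.null(sex)) sex <- rep("unknown", n)
  if (is.null(ploidy)) ploidy <- rep(2L, n)
  ploidy <- as.integer(ploidy)
  positions <- as.numeric(positions)

  stopifnot(length(samples) == n, length(sex) == n, length(ploidy) == n,
            length(positions) == m)
  if (m > 1 && any(diff(positions) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  if (any(positions < 1) || any(positions > chrom_length)) {
    stop("positions must lie in [1, chrom_length]", call. = FALSE)
  }
  if (!all(sex %in% c("M", "F", "unknown"))) {
    stop("sex must be 'M', 'F' or 'unknown'", call. = FALSE)
  }
  if (!all(ploidy %in% c(1L, 2L))) stop("ploidy must be 1 or 2", call. = FALSE)
  bad <- sweep(dosage, 1, ploidy, ">")
  if (any(bad, na.rm = TRUE)) {
    stop("dosage exceeds ploidy for at least one sample", call. = FALSE)
  }
  if (any(dosage < 0, na.rm = TRUE)) stop("negative dosage", call. = FALSE)

  rownames(dosage) <- samples
  structure(
    list(dosage = dosage, positions = positions, chrom = as.character(chrom),
         chrom_length = as.numeric(chrom_length), samples = samples,
         sex = sex, ploidy = ploidy),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d SNPs on %s (%.3g Mb)\n",
              n_samples(x), n_snps(x), x$chrom, x$chrom_length / 1e6))
  cat(sprintf("  positions %s..%s; ploidy: %s\n",
              format(min(x$positions), big.mark = ","),
              format(max(x$positions), big.mark = ","),
              paste(unique(x$ploidy), collapse = "/")))
  invisible(x)
}

#' @rdname geno_matrix
#' @param x a `geno_matrix`.
#' @export
n_samples <- function(x) nrow(x$dosage)

#' @rdname geno_matrix
#' @export
n_snps <- function(x) ncol(x$dosage)

#' Subset a genotype matrix by SNP index or position window
#'
#' @param x a `geno_matrix`.
#' @param snps integer index into SNP columns, or NULL.
#' @param from,to optional position window (1-based inclusive) applied after
#'   `snps`.
#' @return a `geno_matrix` with the selected SNP columns.
#' @export
subset_snps <- function(x, snps = NULL, from = NULL, to = NULL) {
  idx <- seq_len(n_snps(x))
  if (!is.null(snps)) idx <- idx[snps]
  if (!is.null(from)) idx <- idx[x$positions[idx] >= from]
  if (!is.null(to)) idx <- idx[x$positions[idx] <= to]
  geno_matrix(x$dosage[, idx, drop = FALSE], x$positions[idx], x$chrom,
              x$chrom_length, x$samples, x$sex, x$ploidy)
}

#' Subset a genotype matrix by sample
#'
#' @param x a `geno_matrix`.
#' @param samples sample labels or indices to keep.
#' @return a `geno_matrix` with the selected samples.
#' @export
subset_samples <- function(x, samples) {
  idx <- if (is.character(samples)) match(samples, x$samples) else samples
  if (anyNA(idx)) stop("unknown sample(s)", call. = FALSE)
  geno_matrix(x$dosage[idx, , drop = FALSE], x$positions, x$chrom,
              x$chrom_length, x$samples[idx], x$sex[idx], x$ploidy[idx])
}

#' Tidy a genotype matrix into long format
#'
#' @param x a `geno_matrix`.
#' @param ... unused.
#' @return a tibble with one row per sample-by-SNP call: `sample`, `sex`,
#'   `ploidy`, `chrom`, `pos`, `dosage`.
#' @export
tidy.geno_matrix <- function(x, ...) {
  tibble::tibble(
    sample = rep(x$samples, times = n_snps(x)),
    sex = rep(x$sex, times = n_snps(x)),
    ploidy = rep(x$ploidy, times = n_snps(x)),
    chrom = x$chrom,
    pos = rep(x$positions, each = n_samples(x)),
    dosage = as.integer(x$dosage)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
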