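#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy PCA scores or loadings
#'
#' @param x an `inv_pca`.
#' @param matrix `"scores"` (default) or `"loadings"`.
#' @param ... unused.
#' @return tibble: per sample `PC1..PCk` (scores) or per SNP `pos` plus
#'   `PC1..PCk` (loadings).
#' @export
tidy.inv_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") {
    m <- x$scores
    colnames(m) <- paste0("PC", seq_len(ncol(m)))
    dplyr::bind_cols(tibble::tibble(sample = x$samples), tibble::as_tibble(m))
  } else {
    m <- x$loadings
    colnames(m) <- paste0("PC", seq_len(ncol(m)))
    dplyr::bind_cols(tibble::tibble(pos = x$snp_index), tibble::as_tibble(m))
  }
}

#' @rdname tidy.inv_pca
#' @export
glance.inv_pca <- function(x, ...) {
  pv <- x$explained_var / sum(x$explained_var)
  tibble::tibble(n_samples = nrow(x$scores), n_snps = nrow(x$loadings),
                 pc1_var_frac = pv[1],
                 pc2_var_frac = if (length(pv) > 1) pv[2] else NA_real_)
}

#' Tidy per-sample karyotype calls
#'
#' @param x a `karyotype_calls`.
#' @param ... unused.
#' @return the per-sample calls tibble (`sample`, `sex`, `ploidy`, `pc1`,
#'   `cluster`, `karyotype`); `glance()` gives the per-chromosome summary
#'   (cluster count, major-allele frequency, HWE p, breakpoint block).
#' @export
tidy.karyotype_calls <- function(x, ...) x$calls

#' @rdname tidy.karyotype_calls
#' @export
glance.karyotype_calls <- function(x, ...) {
  tibble::tibble(chrom = x$chrom, cluster_count = x$cluster_count,
                 allele_freq_major = x$allele_freq_major, hwe_p = x$hwe_p,
                 block_start = x$breakpoint_block[1],
                 block_end = x$breakpoint_block[2],
                 block_contiguity = x$block_contiguity)
}

#' Tidy an ancestry verdict
#'
#' @param x an `ancestry_verdict`.
#' @param ... unused.
#' @return the per-statistic evidence tibble; `glance()` gives the verdict.
#' @export
tidy.ancestry_verdict <- function(x, ...) x$evidence

#' @rdname tidy.ancestry_verdict
#' @export
glance.ancestry_verdict <- function(x, ...) {
  tibble::tibble(derived_class = x$derived_class, weak = x$weak)
}

#' Tidy an exceedance-test result
#'
#' @param x an `exceedance_result`.
#' @param ... unused.
#' @return one-row tibble with the p-value, replicate counts and settings.
#' @export
tidy.exceedance_result <- function(x, ...) {
  tibble::tibble(p_value = x$p_value, n_successes = x$n_successes,
                 n_perm = x$n_perm, k = length(x$observed),
                 comparison = x$comparison, seed = x$seed)
}

#' Tidy a linked-read filter report
#'
#' @param x a `filter_report`.
#' @param ... unused.
#' @return all input records with a `status` column (`survivor` or the first
#'   failed criterion); `glance()` gives counts per outcome.
#' @export
tidy.filter_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(dplyr::select(x$survivors, -"locus_id"),
                  status = "survivor"),
    dplyr::rename(x$rejected, status = "criterion"))
}

#' @rdname tidy.filter_report
#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(n_input = nrow(x$survivors) + nrow(x$rejected),
                 n_survivors = nrow(x$survivors),
                 n_rejected = nrow(x$rejected),
                 n_locus_pairs = dplyr::n_distinct(x$survivors$locus_id),
                 relaxed = x$relaxed)
}
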