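#' Neutral site-frequency-spectrum model
#'
#' Under neutrality the expected number of derived alleles at count i out of
#' `two_n` haploid genomes is proportional to 1/i. The model truncates the
#' spectrum at a detection threshold and renormalizes: allele counts with
#' frequency below `detect_min` are unobservable. The folded variant (minor
#' allele frequencies, ancestral state unknown) uses
#' (1/i + 1/(two_n - i)) / (1 + [i == two_n - i]) over minor counts.
#'
#' @param two_n haploid sample size (2N for N diploids); >= 4.
#' @param detect_min minimum detectable allele frequency (fraction);
#'   default `1/two_n`.
#' @param folded use the folded (minor-allele) spectrum.
#' @return an `sfs_model`: `two_n`, `folded`, `detect_min`, `counts`,
#'   `freqs`, `pmf` (sums to 1).
#' @export
neutral_sfs <- function(two_n, detect_min = 1 / two_n, folded = FALSE) {
  stopifnot(two_n >= 4)
  if (detect_min < 1 / two_n || detect_min >= (two_n - 1) / two_n) {
    stop("detect_min must lie in [1/two_n, (two_n-1)/two_n)", call. = FALSE)
  }
  i_min <- ceiling(detect_min * two_n)
  if (folded) {
    i_max <- floor(two_n / 2)
    if (i_min > i_max) stop("empty support for folded spectrum", call. = FALSE)
    counts <- seq(i_min, i_max)
    w <- (1 / counts + 1 / (two_n - counts)) / (1 + (counts == two_n - counts))
  } else {
    counts <- seq(i_min, two_n - 1)
    w <- 1 / counts
  }
  if (length(counts) == 0) stop("empty support", call. = FALSE)
  structure(list(two_n = as.integer(two_n), folded = folded,
                 detect_min = detect_min, counts = as.integer(counts),
                 freqs = counts / two_n, pmf = w / sum(w)),
            class = "sfs_model")
}

#' @export
print.sfs_model <- function(x, ...) {
  cat(sprintf("<sfs_model> %s, 2N = %d, detection >= %.4g, %d frequency classes\n",
              if (x$folded) "folded" else "unfolded", x$two_n, x$detect_min,
              length(x$counts)))
  invisible(x)
}

#' Permutation test for unexpectedly high allele frequencies
#'
#' Per replicate, draws `length(observed)` allele frequencies i.i.d. from the
#' neutral spectrum. Under `sorted_dominance` a replicate succeeds when,
#' after sorting both vectors ascending, every drawn frequency strictly
#' exceeds its paired observed frequency (equivalently: a perfect matching of
#' draws strictly above the observations exists). Under `all_exceed_min` a
#' replicate succeeds when every draw strictly exceeds the smallest observed
#' frequency. The p-value is the success fraction: small p means frequencies
#' as high as those observed are unlikely under neutrality.
#'
#' @param observed numeric vector of observed derived-allele frequencies.
#' @param model an [neutral_sfs()] model.
#' @param n_perm number of permutation replicates (default 1e5).
#' @param comparison `"sorted_dominance"` (default) or `"all_exceed_min"`.
#' @param seed RNG seed.
#' @return an `exceedance_result`: `p_value`, `n_successes`, `n_perm`,
#'   `observed` (sorted), `comparison`, `seed`.
#' @export
exceedance_test <- function(observed, model, n_perm = 1e5,
                            comparison = c("sorted_dominance",
                                           "all_exceed_min"),
                            seed = 1L) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(model, "sfs_model"), length(observed) >= 1,
            all(observed >= 0 & observed <= 1))
  k <- length(observed)
  obs <- sort(observed)
  set.seed(as.integer(seed))
  draws <- matrix(sample(model$freqs, n_perm * k, replace = TRUE,
                         prob = model$pmf), nrow = n_perm)
  if (comparison == "sorted_dominance") {
    # sorted pairwise strict dominance == for each j, at least k-j+1 draws
    # exceed the j-th smallest observed value
    ok <- rep(TRUE, n_perm)
    for (j in seq_len(k)) {
      ok <- ok & (rowSums(draws > obs[j]) >= k - j + 1)
    }
    succ <- sum(ok)
  } else {
    succ <- sum(rowSums(draws > min(obs)) == k)
  }
  structure(list(p_value = succ / n_perm, n_successes = succ, n_perm = n_perm,
                 observed = obs, comparison = comparison,
                 seed = as.integer(seed)), class = "exceedance_result")
}

#' @export
print.exceedance_result <- function(x, ...) {
  cat(sprintf(
    "<exceedance_result> p = %.5f (%d / %d replicates, %s)\n  observed: %s\n",
    x$p_value, x$n_successes, x$n_perm, x$comparison,
    paste(format(x$observed, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Observed derived-allele frequencies of the six zebra finch inversions
#'
#' Derived-arrangement frequencies among 19 wild birds for the six large
#' inversion polymorphisms (chromosomes 5, 11, 13, 26, 27 and Z; for Z the
#' combined derived B+C frequency is 0.5).
#'
#' @return named numeric vector of six frequencies.
#' @export
zebra_finch_derived_freqs <- function() {
  c(chr5 = 0.395, chr11 = 0.605, chr13 = 0.605, chr26 = 0.711,
    chr27 = 0.421, chrZ = 0.500)
}
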