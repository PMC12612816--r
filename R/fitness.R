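#' Z-scale a numeric vector
#'
#' Centers to mean 0 and scales to SD 1 (denominator n-1). Missing values are
#' ignored for the moments and propagated in the output.
#'
#' @param values numeric vector with >= 2 non-missing values.
#' @param trait trait name used in error messages.
#' @return standardized numeric vector.
#' @export
zscale <- function(values, trait = "trait") {
  v <- values[!is.na(values)]
  if (length(v) < 2) stop("fewer than 2 non-missing values for ", trait,
                          call. = FALSE)
  s <- stats::sd(v)
  if (s == 0) stop("zero variance in ", trait, call. = FALSE)
  (values - mean(v)) / s
}

#' Estimate a standardized karyotype contrast on a fitness trait
#'
#' Z-scales the trait, restricts to the ancestral homozygotes (`AA`, the
#' baseline) plus one other genotype class, and fits a linear model of the
#' standardized trait on the class indicator and any covariates. With
#' `random_groups` a random-intercept model is fitted via lme4 (when several
#' grouping factors are supplied, the one with the most levels is used, with
#' a message). Returns the standardized mean difference of the class against
#' `AA`, its SE, a Wald p-value and the sample size.
#'
#' @param data tibble with a `karyotype` column (`AA`/`AD`/`DD`) and either a
#'   column named by `trait`, or long-format `trait`/`value` columns.
#' @param trait trait (column) name.
#' @param contrast `"AD_vs_AA"` or `"DD_vs_AA"`.
#' @param fixed_covariates character vector of covariate column names.
#' @param random_groups character vector of grouping-factor column names
#'   (random intercepts).
#' @return one-row tibble: `trait`, `contrast`, `beta`, `se`, `p`, `n`.
#' @export
fit_contrast <- function(data, trait, contrast = c("AD_vs_AA", "DD_vs_AA"),
                         fixed_covariates = NULL, random_groups = NULL) {
  contrast <- match.arg(contrast)
  cls <- sub("_vs_AA", "", contrast)
  if (all(c("trait", "value") %in% names(data)) && !trait %in% names(data)) {
    d <- dplyr::filter(data, .data$trait == !!trait)
    d$.y <- d$value
  } else {
    d <- data
    d$.y <- d[[trait]]
  }
  d$.y <- zscale(d$.y, trait)
  d <- dplyr::filter(d, .data$karyotype %in% c("AA", cls), !is.na(.data$.y))
  if (length(unique(d$karyotype)) < 2) {
    stop("both genotype classes (AA and ", cls, ") must be present",
         call. = FALSE)
  }
  d$.ind <- as.numeric(d$karyotype == cls)
  rhs <- paste(c(".ind", fixed_covariates), collapse = " + ")

  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), d)
  qr_mm <- qr(mm)
  if (qr_mm$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
    stop("singular design; collinear term(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  if (is.null(random_groups) || length(random_groups) == 0) {
    fit <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = d)
    co <- summary(fit)$coefficients[".ind", ]
    beta <- co[["Estimate"]]
    se <- co[["Std. Error"]]
    p <- co[["Pr(>|t|)"]]
  } else {
    if (length(random_groups) > 1) {
      sizes <- vapply(random_groups, function(g) length(unique(d[[g]])), 0L)
      g <- random_groups[which.max(sizes)]
      message("multiple grouping factors supplied; using '", g,
              "' (largest, ", max(sizes), " levels) for the random intercept")
      random_groups <- g
    }
    fml <- stats::as.formula(paste(".y ~", rhs, "+ (1 |", random_groups, ")"))
    fit <- lme4::lmer(fml, data = d, REML = TRUE)
    co <- summary(fit)$coefficients[".ind", ]
    beta <- co[["Estimate"]]
    se <- co[["Std. Error"]]
    p <- 2 * stats::pnorm(-abs(co[["t value"]]))
  }
  tibble::tibble(trait = trait, contrast = contrast, beta = beta, se = se,
                 p = p, n = nrow(d))
}

#' Meta-summarize standardized effect estimates across traits
#'
#' Weighted least squares of the estimates on the contrast indicators with no
#' intercept and weights 1/SE (the inverse standard error; an inverse-variance
#' option is available). The per-contrast solution equals the weighted mean
#' sum(w b) / sum(w). The 95% CI uses the weighted model's coefficient SE.
#'
#' @param estimates tibble of effect estimates ([fit_contrast()] rows):
#'   columns `contrast`, `beta`, `se`.
#' @param weights `"inv_se"` (default, w = 1/SE) or `"inv_var"` (w = 1/SE^2).
#' @return a `meta_summary` tibble: per contrast `estimate`, `se`, `ci_lo`,
#'   `ci_hi`, `k` (number of pooled estimates).
#' @export
meta_summarize <- function(estimates, weights = c("inv_se", "inv_var")) {
  weights <- match.arg(weights)
  stopifnot(nrow(estimates) >= 1, all(estimates$se > 0))
  w_all <- if (weights == "inv_se") 1 / estimates$se else 1 / estimates$se^2
  # per-contrast weighted LM without intercept; fitted separately per level
  # so a single-contrast input is handled identically
  out <- purrr::map_dfr(unique(estimates$contrast), function(ct) {
    rows <- estimates$contrast == ct
    fit <- stats::lm(beta ~ 1, data = estimates[rows, , drop = FALSE],
                     weights = w_all[rows])
    co <- suppressWarnings(summary(fit)$coefficients)
    tibble::tibble(contrast = ct, estimate = unname(co[1, "Estimate"]),
                   se = unname(co[1, "Std. Error"]), k = sum(rows))
  })
  out$ci_lo <- out$estimate - 1.96 * out$se
  out$ci_hi <- out$estimate + 1.96 * out$se
  class(out) <- c("meta_summary", class(out))
  out
}

#' Rank tag SNPs by linkage with the inversion karyotype
#'
#' r-squared is the squared Pearson correlation between SNP dosage and
#' karyotype dosage (0 = HOM_MAJ, 1 = HET, 2 = HOM_MIN). Ranking: r-squared
#' descending, missing rate ascending, position ascending.
#'
#' @param x a [geno_matrix()].
#' @param callset a `karyotype_calls` (or a named 0/1/2 vector of karyotype
#'   dosages per sample).
#' @param k number of tag SNPs to return (default 1).
#' @return tibble of the top `k` SNPs: `pos`, `snp`, `r2`, `missing_rate`;
#'   empty (with a warning) when no SNP is polymorphic.
#' @export
select_tag_snps <- function(x, callset, k = 1) {
  kd <- if (inherits(callset, "karyotype_calls")) {
    v <- c(HOM_MAJ = 0, HET = 1, HOM_MIN = 2)[callset$calls$karyotype]
    names(v) <- callset$calls$sample
    v
  } else callset
  kd <- kd[x$samples]
  if (all(is.na(kd))) stop("no karyotyped samples", call. = FALSE)
  r2 <- vapply(seq_len(n_snps(x)), function(j) {
    dj <- x$dosage[, j]
    ok <- !is.na(dj) & !is.na(kd)
    if (sum(ok) < 3 || stats::var(dj[ok]) == 0 || stats::var(kd[ok]) == 0) {
      return(NA_real_)
    }
    stats::cor(dj[ok], kd[ok])^2
  }, 0)
  miss <- colMeans(is.na(x$dosage))
  ranked <- tibble::tibble(snp = seq_len(n_snps(x)), pos = x$positions,
                           r2 = r2, missing_rate = miss) |>
    dplyr::filter(!is.na(.data$r2)) |>
    dplyr::arrange(dplyr::desc(.data$r2), .data$missing_rate, .data$pos)
  if (nrow(ranked) == 0) {
    warning("no polymorphic SNP available for tagging")
    return(ranked)
  }
  ranked[seq_len(min(k, nrow(ranked))), ]
}

#' Attenuation of estimated karyotype effects under imperfect tagging
#'
#' For each target r-squared, simulates karyotypes at `derived_freq`, a tag
#' SNP in that LD with the karyotype ([simulate_tag_snp()]), and a fitness
#' trait generated from the true karyotypes ([simulate_fitness_data()]);
#' contrasts are then fitted using the tag-derived genotypes, quantifying how
#' weaker tagging attenuates the estimated effect.
#'
#' @param true_effects list with `b_AD`, `b_DD`.
#' @param r2_grid vector of target r-squared values in `[0, 1]`.
#' @param n individuals per replicate.
#' @param n_reps replicates per grid point.
#' @param derived_freq derived-arrangement frequency.
#' @param seed RNG seed.
#' @return tibble per r-squared: `mean_b_AD`, `mean_b_DD`, `reject_rate_AD`
#'   (share of replicates with p < 0.05 for the AD contrast), `n_reps`.
#' @export
tag_attenuation_sim <- function(true_effects = list(b_AD = 0.094,
                                                    b_DD = 0.010),
                                r2_grid = c(1, 0.8, 0.5, 0.2, 0),
                                n = 5000, n_reps = 50, derived_freq = 0.421,
                                seed = 1L) {
  stopifnot(all(r2_grid >= 0 & r2_grid <= 1))
  set.seed(as.integer(seed))
  seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                             length(r2_grid) * n_reps),
                  nrow = length(r2_grid))
  purrr::map_dfr(seq_along(r2_grid), function(gi) {
    res <- purrr::map_dfr(seq_len(n_reps), function(r) {
      s <- seeds[gi, r]
      set.seed(s)
      kd <- stats::rbinom(n, 2, derived_freq)
      while (length(unique(kd)) < 3) kd <- stats::rbinom(n, 2, derived_freq)
      karyo <- c("AA", "AD", "DD")[kd + 1]
      tag <- simulate_tag_snp(kd, r2_grid[gi], seed = s)
      pheno <- simulate_fitness_data(karyo, effects = true_effects,
                                     n_traits = 1, seed = s)
      pheno$karyotype <- c("AA", "AD", "DD")[tag + 1]
      both <- length(unique(pheno$karyotype)) == 3
      if (!both) return(tibble::tibble(b_AD = NA, b_DD = NA, p_AD = NA))
      ad <- fit_contrast(pheno, "trait01", "AD_vs_AA")
      dd <- fit_contrast(pheno, "trait01", "DD_vs_AA")
      tibble::tibble(b_AD = ad$beta, b_DD = dd$beta, p_AD = ad$p)
    })
    tibble::tibble(r2 = r2_grid[gi],
                   mean_b_AD = mean(res$b_AD, na.rm = TRUE),
                   mean_b_DD = mean(res$b_DD, na.rm = TRUE),
                   reject_rate_AD = mean(res$p_AD < 0.05, na.rm = TRUE),
                   n_reps = sum(!is.na(res$b_AD)))
  })
}

#' Allele frequencies from tag-SNP genotypes
#'
#' Counts alleles ploidy-aware (diploids contribute two, haploids one),
#' excluding missing genotypes.
#'
#' @param tags dosage vector (0/1/2 alt-allele copies; 0/1 for haploids) or
#'   `AA`/`AB`/`BB` strings (plus `A`/`B` for haploids).
#' @param ploidy per-sample ploidy (default 2).
#' @return named numeric vector `c(A = freq_ref, B = freq_alt)`.
#' @export
allele_freq_from_tags <- function(tags, ploidy = NULL) {
  if (is.character(tags) || is.factor(tags)) {
    map <- c(AA = 0, AB = 1, BA = 1, BB = 2, A = 0, B = 1)
    dos <- unname(map[as.character(tags)])
    if (is.null(ploidy)) {
      ploidy <- ifelse(nchar(as.character(tags)) == 1, 1L, 2L)
    }
  } else {
    dos <- as.numeric(tags)
  }
  if (is.null(ploidy)) ploidy <- rep(2L, length(dos))
  ok <- !is.na(dos)
  if (!any(ok)) stop("all tag genotypes missing", call. = FALSE)
  total <- sum(ploidy[ok])
  n_b <- sum(dos[ok])
  c(A = (total - n_b) / total, B = n_b / total)
}
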