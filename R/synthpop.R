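#' Simulation configuration for a planted inversion polymorphism
#'
#' Bundles the parameters of the two-pool haplotype model used by
#' [simulate_inversion_population()]. Haplotypes inside the inversion belong
#' to an ancestral pool (standing diversity `theta`) or a derived pool founded
#' from a single ancestral haplotype `t_div` expected substitutions/site ago;
#' fixed differences between the pools accrue in proportion to `t_div`,
#' derived-pool polymorphism is reduced to `derived_diversity` times the
#' ancestral level, and `gene_flux` swaps alleles between pools with a
#' probability that peaks at the inversion center (eroding LD there).
#'
#' @param n_samples number of individuals (default 20, a typical wild panel).
#' @param n_snps_inside,n_snps_outside SNP counts inside/outside the
#'   inversion (defaults 60/140).
#' @param chrom_length chromosome length in bp.
#' @param bp_left,bp_right inversion breakpoints, 1-based inclusive.
#' @param derived_freq population frequency of the derived arrangement.
#' @param theta relative density of polymorphic sites within the ancestral
#'   pool (per-site scale).
#' @param t_div between-pool divergence in expected substitutions/site;
#'   `t_div = 0` disables class structure entirely (no inversion signal).
#' @param gene_flux per-site, per-haplotype probability scale of allele
#'   exchange between pools (multiplied by a triangular weight peaking at the
#'   inversion center).
#' @param outgroup_div substitutions/site on the outgroup lineage.
#' @param theta_outgroup outgroup's own polymorphism rate (default `theta`).
#' @param founder_bottleneck in `[0, 1]`: probability a derived haplotype
#'   escapes the founder at an ancestral polymorphic site; 0 = single founder.
#' @param derived_diversity relative density of derived-pool private
#'   polymorphic sites (fraction of `theta`).
#' @param p_share probability an ancestral polymorphism is also segregating
#'   in the outgroup (shared ancestral variation).
#' @param sex_linked if `TRUE`, females are hemizygous (ploidy 1).
#' @param prop_female proportion of females when `sex_linked`.
#' @param nested optional list of `c(left, right)` intervals strictly inside
#'   the inversion in which the class roles are reversed (a younger stratum
#'   founded in the other direction), used for strata-scan tests.
#' @param chrom chromosome label.
#' @param seed integer RNG seed; fixed seed gives identical output.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 20, n_snps_inside = 60,
                       n_snps_outside = 60, chrom_length = 20e6,
                       bp_left = 5e6, bp_right = 15e6, derived_freq = 0.4,
                       theta = 0.005, t_div = 0.01, gene_flux = 0.4,
                       outgroup_div = 0.03, theta_outgroup = theta,
                       founder_bottleneck = 0, derived_diversity = 0.3,
                       p_share = 0.5, sex_linked = FALSE, prop_female = 0.5,
                       nested = NULL, chrom = "chr1", seed = 1L) {
  cfg <- as.list(environment())
  rates <- c(derived_freq = derived_freq, theta = theta, t_div = t_div,
             gene_flux = gene_flux, outgroup_div = outgroup_div,
             theta_outgroup = theta_outgroup,
             founder_bottleneck = founder_bottleneck,
             derived_diversity = derived_diversity, p_share = p_share)
  if (any(rates < 0 | rates > 1)) {
    stop("all rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "),
         call. = FALSE)
  }
  stopifnot(bp_left < bp_right, bp_right <= chrom_length, n_samples >= 1)
  if (!is.null(nested)) {
    for (iv in nested) {
      if (!(iv[1] > bp_left && iv[2] < bp_right && iv[1] < iv[2])) {
        stop("nested intervals must lie strictly inside the inversion",
             call. = FALSE)
      }
    }
  }
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

kary_levels <- c("ANC_HOM", "HET", "DER_HOM")

#' Gene-flux weight along the inversion: zero inside a protected zone
#' spanning `protect` of the inversion length at each breakpoint
#' (recombination suppression between arrangements is tightest at the
#' breakpoints), ramping up to 1 at the inversion center, where double
#' crossovers and gene conversion act most freely.
#' @noRd
flux_weight <- function(pos, bp_left, bp_right, protect = 0.1) {
  u <- 2 * abs(pos - (bp_left + bp_right) / 2) / (bp_right - bp_left)
  pmax(0, pmin(1, 1 - u / (1 - 2 * protect)))
}

#' Simulate a SNP genotype matrix with a planted inversion
#'
#' Generates `n_samples` individuals whose haplotypes inside
#' `[bp_left, bp_right]` fall into two non-recombining classes: an ancestral
#' pool carrying standing polymorphism and a derived pool founded from a
#' single ancestral haplotype, separated by fixed differences accumulated
#' over `t_div`. Gene flux mixes alleles between the classes with probability
#' increasing toward the inversion center. Outside the inversion, sites are
#' exchangeable across karyotypes. With `t_div = 0` the two classes are
#' statistically identical and no inversion signal exists.
#'
#' @param config a [sim_config()].
#' @return a list with elements `matrix` (a [geno_matrix()]) and `truth`
#'   (an `inversion_truth` list: `chrom`, `bp_left`, `bp_right`,
#'   `derived_freq` (realized mean dosage/ploidy), `t_div`,
#'   `sample_karyotypes` (named `ANC_HOM`/`HET`/`DER_HOM`), `nested`, and a
#'   `site_info` tibble of generator metadata consumed by
#'   [simulate_outgroup()]).
#' @export
simulate_inversion_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_samples < 4) stop("need n_samples >= 4", call. = FALSE)
  if (config$n_snps_inside < 2) {
    stop("n_snps_inside < 2: no detectable block", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_samples
  L_inv <- config$bp_right - config$bp_left + 1

  sex <- rep("unknown", n)
  ploidy <- rep(2L, n)
  if (config$sex_linked) {
    sex <- ifelse(stats::runif(n) < config$prop_female, "F", "M")
    ploidy <- ifelse(sex == "F", 1L, 2L)
  }
  samples <- sprintf("S%02d", seq_len(n))

  # haplotype classes: 1 = derived, 0 = ancestral
  k_dosage <- stats::rbinom(n, ploidy, config$derived_freq)
  hap_class <- unlist(lapply(seq_len(n), function(i) {
    c(rep(1L, k_dosage[i]), rep(0L, ploidy[i] - k_dosage[i]))
  }))
  hap_sample <- rep(seq_len(n), times = ploidy)
  H <- length(hap_class)

  # positions
  pos_in <- sort(sample(seq(config$bp_left, config$bp_right),
                        config$n_snps_inside))
  out_space <- c(if (config$bp_left > 1) seq_len(config$bp_left - 1),
                 if (config$bp_right < config$chrom_length)
                   seq(config$bp_right + 1, config$chrom_length))
  n_out <- min(config$n_snps_outside, length(out_space))
  pos_out <- if (n_out > 0) sort(sample(out_space, n_out)) else numeric(0)

  # site types inside: fixed difference / ancestral poly / derived-private poly
  w <- c(fix = config$t_div, anc_poly = config$theta,
         der_poly = config$theta * config$derived_diversity)
  if (config$t_div == 0) w <- c(fix = 0, anc_poly = 1, der_poly = 0)
  if (sum(w) == 0) stop("degenerate config: theta and t_div both zero",
                        call. = FALSE)
  type_in <- sample(names(w), config$n_snps_inside, replace = TRUE,
                    prob = w / sum(w))
  in_nested <- rep(FALSE, config$n_snps_inside)
  for (iv in config$nested %||% list()) {
    in_nested <- in_nested | (pos_in >= iv[1] & pos_in <= iv[2])
  }

  hap_alleles <- matrix(0L, H, config$n_snps_inside)
  p_anc <- stats::runif(config$n_snps_inside, 0.15, 0.85)
  founder <- stats::rbinom(config$n_snps_inside, 1, p_anc)
  for (j in seq_len(config$n_snps_inside)) {
    # within a reversed (nested, younger) stratum the class roles swap:
    # the "ancestral" pool is the recently founded one there; with
    # t_div = 0 there is no class structure at all
    der <- if (config$t_div == 0) rep(FALSE, H)
      else if (in_nested[j]) hap_class == 0L else hap_class == 1L
    anc <- !der
    switch(type_in[j],
      fix = {
        hap_alleles[der, j] <- 1L
      },
      anc_poly = {
        hap_alleles[anc, j] <- stats::rbinom(sum(anc), 1, p_anc[j])
        esc <- der & (stats::runif(H) < config$founder_bottleneck)
        hap_alleles[der, j] <- founder[j]
        hap_alleles[esc, j] <- stats::rbinom(sum(esc), 1, p_anc[j])
      },
      der_poly = {
        hap_alleles[der, j] <- stats::rbinom(sum(der), 1, p_anc[j])
      }
    )
  }

  # gene flux: with probability gene_flux * w(position), peaking at the
  # inversion center, a site has been homogenized between the arrangement
  # pools over the inversion's history: its alleles have spread through both
  # classes, so every haplotype draws from the pooled frequency and the
  # class signal at that site is erased
  fluxed <- rep(FALSE, config$n_snps_inside)
  if (config$gene_flux > 0 && config$t_div > 0) {
    wts <- flux_weight(pos_in, config$bp_left, config$bp_right)
    fluxed <- stats::runif(config$n_snps_inside) < config$gene_flux * wts
    for (j in which(fluxed)) {
      p_pool <- switch(type_in[j],
        fix = config$derived_freq,
        anc_poly = p_anc[j],
        der_poly = p_anc[j] * config$derived_freq)
      p_pool <- min(max(p_pool, 0.05), 0.95)
      hap_alleles[, j] <- stats::rbinom(H, 1, p_pool)
    }
  }

  # outside sites: exchangeable across karyotypes
  p_out <- stats::runif(n_out, 0.15, 0.85)
  hap_out <- matrix(stats::rbinom(H * n_out, 1, rep(p_out, each = H)), H)

  ord <- order(c(pos_in, pos_out))
  hap_all <- cbind(hap_alleles, hap_out)[, ord, drop = FALSE]
  site_region <- c(rep("inside", config$n_snps_inside),
                   rep("outside", n_out))[ord]
  site_type <- c(type_in, rep("neutral", n_out))[ord]
  site_fluxed <- c(fluxed, rep(FALSE, n_out))[ord]
  site_p <- c(p_anc, p_out)[ord]
  site_founder <- c(founder, rep(NA_integer_, n_out))[ord]
  site_nested <- c(in_nested, rep(FALSE, n_out))[ord]
  positions <- sort(c(pos_in, pos_out))

  dosage <- rowsum(hap_all, group = hap_sample)
  gm <- geno_matrix(dosage, positions, chrom = config$chrom,
                    chrom_length = config$chrom_length, samples = samples,
                    sex = sex, ploidy = ploidy)

  karyo <- kary_levels[ifelse(ploidy == 2L, k_dosage + 1L,
                              ifelse(k_dosage == 1L, 3L, 1L))]
  names(karyo) <- samples
  truth <- structure(list(
    chrom = config$chrom, chrom_length = config$chrom_length,
    bp_left = config$bp_left, bp_right = config$bp_right,
    derived_freq = mean(k_dosage / ploidy),
    t_div = config$t_div,
    sample_karyotypes = karyo,
    nested = config$nested %||% list(),
    # detectable block: the span of SNPs in complete LD with the arrangement
    diag_span = if (any(type_in == "fix" & !fluxed)) {
      range(pos_in[type_in == "fix" & !fluxed])
    } else c(NA_real_, NA_real_),
    site_info = tibble::tibble(
      pos = positions, region = site_region, type = site_type, p = site_p,
      founder = site_founder, fluxed = site_fluxed, reversed = site_nested)
  ), class = "inversion_truth")
  list(matrix = gm, truth = truth)
}

#' @export
print.inversion_truth <- function(x, ...) {
  cat(sprintf("<inversion_truth> %s:%s-%s, derived freq %.3f, t_div %.3g\n",
              x$chrom, format(x$bp_left, scientific = FALSE),
              format(x$bp_right, scientific = FALSE), x$derived_freq, x$t_div))
  print(table(factor(x$sample_karyotypes, kary_levels)))
  invisible(x)
}

#' Simulate a single outgroup genome at the same SNP sites
#'
#' The outgroup diverged from the root of the ancestral arrangement class:
#' it carries the ancestral allele at between-class fixed differences (so
#' derived homozygotes accumulate fixed differences against it), retains a
#' fraction `p_share` of ancestral-class polymorphisms as heterozygous sites
#' (so ancestral homozygotes share more polymorphism with it), never shares
#' derived-private polymorphism, and picks up substitutions at rate
#' `outgroup_div` plus private heterozygosity at rate `theta_outgroup`.
#'
#' @param config the [sim_config()] used for the focal population.
#' @param truth the `inversion_truth` returned by
#'   [simulate_inversion_population()].
#' @param seed RNG seed; default derives from `config$seed`.
#' @return a single-sample [geno_matrix()] named `"outgroup"`.
#' @export
simulate_outgroup <- function(config, truth, seed = config$seed + 10000L) {
  stopifnot(inherits(truth, "inversion_truth"))
  set.seed(as.integer(seed))
  si <- truth$site_info
  m <- nrow(si)
  flip <- stats::rbinom(m, 1, config$outgroup_div)
  shareable <- si$type %in% c("anc_poly", "neutral")
  shared <- shareable & (stats::runif(m) < config$p_share)
  # ancestral-root allele (0 except at reversed strata fixed differences,
  # where the outgroup matches the nominally "derived" allele)
  a0 <- ifelse(si$type == "fix" & si$reversed, 1L, 0L)
  dos <- ifelse(shared, 1L, 2L * ((a0 + flip) %% 2L))
  own_het <- !shared & (stats::runif(m) < config$theta_outgroup)
  dos[own_het] <- 1L
  geno_matrix(matrix(as.integer(dos), nrow = 1), si$pos, chrom = truth$chrom,
              chrom_length = config$chrom_length, samples = "outgroup",
              sex = "unknown", ploidy = 2L)
}

#' Simulate long-range barcode-interaction calls
#'
#' Every sample whose karyotype differs from the reference arrangement emits
#' interaction records linking both inversion breakpoints (and the
#' breakpoints of any nested inversion in the truth), with endpoint jitter
#' and quality >= 4. Samples matching the reference emit nothing. `noise`
#' adds spurious records that each fail at least one of the downstream filter
#' criteria by construction (short range, quality < 4, or single-sample
#' support at a random locus pair).
#'
#' @param truth an `inversion_truth`.
#' @param reference_karyotype arrangement of the reference assembly,
#'   `"ANC_HOM"` or `"DER_HOM"`.
#' @param samples samples to emit for; default all in the truth.
#' @param noise expected number of spurious records per sample.
#' @param jitter maximal endpoint jitter in bp.
#' @param seed RNG seed.
#' @return tibble with columns `chrom`, `pos1`, `pos2`, `quality`, `sample`,
#'   plus generator labels `truth_label` (`"signal"`/`"noise"`) and `locus`
#'   (`"primary"`/`"nested"`/`"noise"`).
#' @export
simulate_barcode_interactions <- function(truth, reference_karyotype = "ANC_HOM",
                                          samples = names(truth$sample_karyotypes),
                                          noise = 0, jitter = 5000,
                                          seed = 1L) {
  stopifnot(reference_karyotype %in% c("ANC_HOM", "DER_HOM"))
  set.seed(as.integer(seed))
  karyo <- truth$sample_karyotypes[samples]
  carriers <- samples[karyo != reference_karyotype]
  loci <- c(list(primary = c(truth$bp_left, truth$bp_right)),
            stats::setNames(truth$nested,
                            rep("nested", length(truth$nested))))
  rec <- list()
  for (s in carriers) {
    for (k in seq_along(loci)) {
      rec[[length(rec) + 1]] <- tibble::tibble(
        chrom = truth$chrom,
        pos1 = round(loci[[k]][1] + stats::runif(1, -jitter, jitter)),
        pos2 = round(loci[[k]][2] + stats::runif(1, -jitter, jitter)),
        quality = round(stats::runif(1, 4, 60)),
        sample = s, truth_label = "signal", locus = names(loci)[k])
    }
  }
  n_noise <- stats::rpois(1, noise * length(samples))
  if (n_noise > 0) {
    mind <- min_distance_for(truth$chrom_length %||% (truth$bp_right * 2))
    # singleton-mode spurious records are placed on start slots spaced more
    # than twice the default endpoint-merge radius apart, and away from the
    # planted breakpoints, so they can never gain multi-sample support by
    # chance co-clustering with each other or with a true locus pair
    slots <- seq(1e5, truth$bp_right, by = 1.5e5)
    slots <- slots[abs(slots - truth$bp_left) > 1e5]
    for (nst in truth$nested) slots <- slots[abs(slots - nst[1]) > 1e5]
    slots <- sample(slots)
    for (i in seq_len(n_noise)) {
      mode <- sample(c("short", "low_q", "singleton"), 1)
      if (mode == "singleton" && length(slots) == 0) mode <- "low_q"
      p1 <- if (mode == "singleton") {
        s1 <- slots[1]
        slots <- slots[-1]
        round(s1 + stats::runif(1, -2e4, 2e4))
      } else round(stats::runif(1, 1, truth$bp_right))
      rec[[length(rec) + 1]] <- tibble::tibble(
        chrom = truth$chrom,
        pos1 = p1,
        pos2 = p1 + switch(mode,
                           short = round(stats::runif(1, 1000, mind - 1000)),
                           round(stats::runif(1, mind + 1, mind * 3))),
        quality = switch(mode, low_q = sample(0:3, 1),
                         round(stats::runif(1, 4, 60))),
        sample = sample(samples, 1), truth_label = "noise", locus = "noise")
    }
  }
  if (length(rec) == 0) {
    return(tibble::tibble(chrom = character(), pos1 = numeric(),
                          pos2 = numeric(), quality = numeric(),
                          sample = character(), truth_label = character(),
                          locus = character()))
  }
  dplyr::bind_rows(rec)
}

#' Simulate standardized fitness traits with karyotype effects
#'
#' Generates, per trait, `value = b_AD 1[AD] + b_DD 1[DD] + covariates +
#' group random intercept + residual`, with the residual SD chosen so the
#' total variance is ~1 (traits are emitted on a standardized scale).
#'
#' @param karyotypes character vector of `AA`/`AD`/`DD` codes per individual.
#' @param effects list with `b_AD` and `b_DD`, standardized effect sizes of
#'   the heterokaryotype and derived homozygote against the `AA` baseline.
#' @param n_traits number of traits to emit.
#' @param random_effect_sd SD of group random intercepts.
#' @param residual_sd residual SD; default fills variance up to 1.
#' @param covariates named numeric vector of covariate coefficients;
#'   covariate values are drawn standard normal.
#' @param n_groups number of random-effect groups.
#' @param seed RNG seed.
#' @return a tibble in long format: `id`, `karyotype`, `group`, one column
#'   per covariate, `trait`, `value`.
#' @export
simulate_fitness_data <- function(karyotypes, effects = list(b_AD = 0.094,
                                                             b_DD = 0.010),
                                  n_traits = 1, random_effect_sd = 0.2,
                                  residual_sd = NULL, covariates = NULL,
                                  n_groups = 50, seed = 1L) {
  karyotypes <- as.character(karyotypes)
  if (!all(karyotypes %in% c("AA", "AD", "DD"))) {
    stop("karyotypes must be coded AA/AD/DD", call. = FALSE)
  }
  if (length(unique(karyotypes)) < 3) {
    stop("empty karyotype class: need all of AA, AD, DD present",
         call. = FALSE)
  }
  stopifnot(is.finite(effects$b_AD), is.finite(effects$b_DD))
  set.seed(as.integer(seed))
  n <- length(karyotypes)
  gen <- effects$b_AD * (karyotypes == "AD") +
    effects$b_DD * (karyotypes == "DD")
  cov_names <- names(covariates %||% numeric(0))
  X <- matrix(stats::rnorm(n * length(cov_names)), n,
              dimnames = list(NULL, cov_names))
  cov_part <- if (length(cov_names)) drop(X %*% covariates) else 0
  var_sys <- stats::var(gen + cov_part) + random_effect_sd^2
  if (is.null(residual_sd)) residual_sd <- sqrt(max(0.05, 1 - var_sys))
  group <- sample(sprintf("g%03d", seq_len(n_groups)), n, replace = TRUE)

  base <- tibble::tibble(id = sprintf("I%05d", seq_len(n)),
                         karyotype = karyotypes, group = group)
  if (length(cov_names)) base <- dplyr::bind_cols(base, tibble::as_tibble(X))
  purrr::map_dfr(seq_len(n_traits), function(t) {
    u <- stats::rnorm(n_groups, 0, random_effect_sd)
    names(u) <- sprintf("g%03d", seq_len(n_groups))
    dplyr::mutate(base, trait = sprintf("trait%02d", t),
                  value = gen + cov_part + u[group] +
                    stats::rnorm(n, 0, residual_sd))
  })
}

#' Simulate a tag SNP at a controlled r-squared with the karyotype
#'
#' Produces a bi-allelic tag-SNP dosage vector whose squared Pearson
#' correlation with the karyotype dosage is within 0.05 of `r2_target`,
#' resampling until achieved.
#'
#' @param karyotypes `AA`/`AD`/`DD` codes or 0/1/2 dosages.
#' @param r2_target desired squared correlation, in `[0, 1]`.
#' @param seed RNG seed.
#' @param max_iter resampling budget before declaring the target infeasible.
#' @return integer vector of tag dosages (0/1/2) with attribute
#'   `realized_r2`.
#' @export
simulate_tag_snp <- function(karyotypes, r2_target, seed = 1L,
                             max_iter = 2000) {
  if (r2_target < 0 || r2_target > 1) stop("r2_target must be in [0,1]",
                                           call. = FALSE)
  k <- if (is.numeric(karyotypes)) as.integer(karyotypes) else
    c(AA = 0L, AD = 1L, DD = 2L)[as.character(karyotypes)]
  if (any(is.na(k))) stop("karyotypes must be AA/AD/DD or 0/1/2", call. = FALSE)
  if (stats::var(k) == 0) {
    stop("infeasible r2_target: karyotype dosage is constant", call. = FALSE)
  }
  set.seed(as.integer(seed))
  if (r2_target == 1) {
    tag <- k
    attr(tag, "realized_r2") <- 1
    return(tag)
  }
  a <- sqrt(r2_target)
  for (it in seq_len(max_iter)) {
    keep <- stats::runif(length(k)) < a
    tag <- ifelse(keep, k, sample(k))
    r2 <- if (stats::var(tag) == 0) 0 else stats::cor(tag, k)^2
    if (abs(r2 - r2_target) <= 0.05) {
      tag <- as.integer(tag)
      attr(tag, "realized_r2") <- r2
      return(tag)
    }
    # nudge the mixing weight toward the target
    a <- min(1, max(0, a + 0.25 * (sqrt(r2_target) - sqrt(max(r2, 0)))))
  }
  stop("could not achieve r2_target = ", r2_target,
       " within ", max_iter, " resamples (infeasible for these class counts)",
       call. = FALSE)
}

#' Write / read an inversion truth sidecar (YAML-style plain text)
#'
#' @param truth an `inversion_truth`.
#' @param path output path.
#' @return `path` invisibly; `read_truth()` returns the `inversion_truth`.
#' @export
write_truth <- function(truth, path) {
  x <- truth[c("chrom", "chrom_length", "bp_left", "bp_right",
               "derived_freq", "t_div")]
  x$sample_karyotypes <- as.list(truth$sample_karyotypes)
  x$nested <- lapply(truth$nested, as.numeric)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(
    chrom = x$chrom, chrom_length = x$chrom_length,
    bp_left = x$bp_left, bp_right = x$bp_right,
    derived_freq = x$derived_freq, t_div = x$t_div,
    sample_karyotypes = unlist(x$sample_karyotypes),
    nested = x$nested %||% list(), site_info = NULL
  ), class = "inversion_truth")
}
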