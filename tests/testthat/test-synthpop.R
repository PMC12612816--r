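test_that("fixed seed gives identical output; configs are validated", {
  cfg <- sim_config(seed = 1, n_samples = 20, n_snps_inside = 60,
                    derived_freq = 0.4)
  a <- simulate_inversion_population(cfg)
  b <- simulate_inversion_population(cfg)
  expect_identical(a$matrix$dosage, b$matrix$dosage)
  expect_identical(a$matrix$positions, b$matrix$positions)
  expect_identical(a$truth$sample_karyotypes, b$truth$sample_karyotypes)

  expect_error(sim_config(t_div = 1.5), "rates")
  expect_error(sim_config(bp_left = 10, bp_right = 5))
  expect_error(sim_config(nested = list(c(1e6, 6e6))), "nested")
  expect_error(simulate_inversion_population(sim_config(n_snps_inside = 1)),
               "n_snps_inside")
  expect_error(simulate_inversion_population(sim_config(n_samples = 3)),
               "n_samples")
})

test_that("planted truth is internally consistent", {
  sim <- simulate_inversion_population(sim_config(seed = 8))
  tr <- sim$truth
  expect_lt(tr$bp_left, tr$bp_right)
  k <- c(ANC_HOM = 0, HET = 1, DER_HOM = 2)[tr$sample_karyotypes]
  expect_equal(tr$derived_freq,
               mean(k / sim$matrix$ploidy[match(names(tr$sample_karyotypes),
                                                sim$matrix$samples)]))
  inside <- tr$site_info$region == "inside"
  expect_true(all(tr$site_info$pos[inside] >= tr$bp_left &
                    tr$site_info$pos[inside] <= tr$bp_right))
})

test_that("without gene flux (and no standing variation) every inside SNP is
           perfectly correlated with the karyotype", {
  cfg <- sim_config(seed = 5, gene_flux = 0, theta = 0, n_snps_outside = 0)
  sim <- simulate_inversion_population(cfg)
  k <- c(ANC_HOM = 0, HET = 1, DER_HOM = 2)[sim$truth$sample_karyotypes]
  r <- apply(sim$matrix$dosage, 2, function(d) stats::cor(d, k))
  expect_true(all(abs(r) > 1 - 1e-12))
})

test_that("derived-class heterozygosity is below ancestral under the founder
           bottleneck (replicate average)", {
  het <- vapply(1:60, function(s) {
    cfg <- sim_config(seed = s, n_samples = 16, n_snps_inside = 200,
                      n_snps_outside = 0, derived_freq = 0.5, gene_flux = 0)
    sim <- simulate_inversion_population(cfg)
    tk <- sim$truth$sample_karyotypes
    rate <- function(lab) {
      rows <- which(tk == lab)
      if (length(rows) == 0) return(NA_real_)
      mean(sim$matrix$dosage[rows, , drop = FALSE] == 1L)
    }
    c(rate("DER_HOM"), rate("ANC_HOM"))
  }, numeric(2))
  expect_lt(mean(het[1, ], na.rm = TRUE), mean(het[2, ], na.rm = TRUE))
})

test_that("outgroup fixed differences rise with outgroup divergence and
           derived homozygotes share fewer polymorphisms", {
  stats_at <- function(div, s) {
    cfg <- sim_config(seed = s, n_samples = 12, n_snps_inside = 300,
                      n_snps_outside = 0, derived_freq = 0.5,
                      outgroup_div = div, gene_flux = 0, t_div = 0.01)
    sim <- simulate_inversion_population(cfg)
    og <- simulate_outgroup(cfg, sim$truth)
    tk <- sim$truth$sample_karyotypes
    st <- diversity_stats(sim$matrix, og, c(cfg$bp_left, cfg$bp_right))
    st$class <- tk[st$sample]
    c(fixed = mean(st$n_fixed),
      sh_anc = mean(st$n_shared[st$class == "ANC_HOM"]),
      sh_der = mean(st$n_shared[st$class == "DER_HOM"]))
  }
  res <- vapply(1:60, function(s) stats_at(0.01, s), numeric(3))
  res_mid <- vapply(1:60, function(s) stats_at(0.1, s), numeric(3))
  res_hi <- vapply(1:60, function(s) stats_at(0.3, s), numeric(3))
  fixed_means <- c(mean(res[1, ]), mean(res_mid[1, ]), mean(res_hi[1, ]))
  expect_true(all(diff(fixed_means) > 0))
  # shared polymorphism: ancestral homozygotes share more than derived
  expect_gt(mean(res[2, ], na.rm = TRUE), mean(res[3, ], na.rm = TRUE))
})

test_that("zero-divergence, zero-diversity outgroup has no fixed differences", {
  # with no divergence and full retention of the shared ancestral
  # polymorphism, no site can be homozygous for different alleles
  cfg <- sim_config(seed = 2, n_samples = 8, n_snps_inside = 50,
                    n_snps_outside = 10, t_div = 0, outgroup_div = 0,
                    theta_outgroup = 0, p_share = 1)
  sim <- simulate_inversion_population(cfg)
  og <- simulate_outgroup(cfg, sim$truth)
  st <- diversity_stats(sim$matrix, og, c(1, cfg$chrom_length))
  expect_true(all(st$n_fixed == 0))
})

test_that("barcode interactions come only from non-reference carriers and
           span the breakpoints", {
  cfg <- sim_config(seed = 9, derived_freq = 0.4)
  sim <- simulate_inversion_population(cfg)
  tr <- sim$truth
  bc <- simulate_barcode_interactions(tr, "ANC_HOM", noise = 0, seed = 2)
  carriers <- names(tr$sample_karyotypes)[tr$sample_karyotypes != "ANC_HOM"]
  expect_setequal(unique(bc$sample), carriers)
  expect_true(all(abs(bc$pos1 - tr$bp_left) <= 5000))
  expect_true(all(abs(bc$pos2 - tr$bp_right) <= 5000))
  expect_true(all(bc$quality >= 4))

  # all samples matching the reference arrangement: empty output
  ref_all <- tr
  ref_all$sample_karyotypes[] <- "DER_HOM"
  none <- simulate_barcode_interactions(ref_all, "DER_HOM", noise = 0,
                                        seed = 2)
  expect_equal(nrow(none), 0)
})

test_that("spurious barcode records are constructed to fail a filter", {
  for (s in c(7, 8, 9)) {
    cfg <- sim_config(seed = s, chrom_length = 30e6, bp_left = 8e6,
                      bp_right = 24e6)
    sim <- simulate_inversion_population(cfg)
    bc <- simulate_barcode_interactions(sim$truth, "ANC_HOM", noise = 0.5,
                                        seed = s)
    noise <- dplyr::filter(bc, truth_label == "noise")
    if (nrow(noise) == 0) next
    rep <- filter_interactions(bc, gaps = NULL,
                               chrom_length = cfg$chrom_length)
    expect_false(any(rep$survivors$truth_label == "noise"))
  }
})

test_that("fitness simulator recovers null and generating effects", {
  withr::local_seed(42)
  kd <- stats::rbinom(2000, 2, 0.4)
  while (length(unique(kd)) < 3) kd <- stats::rbinom(2000, 2, 0.4)
  karyo <- c("AA", "AD", "DD")[kd + 1]
  # null: contrasts centered on zero
  est0 <- vapply(1:60, function(s) {
    ph <- simulate_fitness_data(karyo, effects = list(b_AD = 0, b_DD = 0),
                                seed = s)
    unlist(fit_contrast(ph, "trait01", "AD_vs_AA")[, c("beta", "se")])
  }, numeric(2))
  expect_lt(abs(mean(est0[1, ])), 2 * stats::sd(est0[1, ]) / sqrt(60))

  # total variance is ~1 on the emitted scale
  ph <- simulate_fitness_data(karyo, effects = list(b_AD = 0.094,
                                                    b_DD = 0.01), seed = 1)
  expect_lt(abs(stats::var(ph$value) - 1), 0.15)

  expect_error(simulate_fitness_data(rep(c("AA", "AD"), 50),
                                     effects = list(b_AD = 0, b_DD = 0)),
               "empty karyotype class")
})

test_that("doubling the residual SD doubles the empirical contrast SE", {
  withr::local_seed(1)
  kd <- stats::rbinom(400, 2, 0.5)
  while (length(unique(kd)) < 3) kd <- stats::rbinom(400, 2, 0.5)
  karyo <- c("AA", "AD", "DD")[kd + 1]
  # the contrast on the raw (unstandardized) scale: Z-scaling would absorb
  # the residual scale by construction
  emp_se <- function(res_sd) {
    est <- vapply(1:200, function(s) {
      ph <- simulate_fitness_data(karyo, effects = list(b_AD = 0, b_DD = 0),
                                  random_effect_sd = 0, residual_sd = res_sd,
                                  seed = s)
      d <- ph[ph$karyotype %in% c("AA", "AD"), ]
      mean(d$value[d$karyotype == "AD"]) - mean(d$value[d$karyotype == "AA"])
    }, 0)
    stats::sd(est)
  }
  ratio <- emp_se(1.0) / emp_se(0.5)
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("tag SNP simulator hits the requested r-squared", {
  withr::local_seed(3)
  kd <- stats::rbinom(1000, 2, 0.45)
  tag1 <- simulate_tag_snp(kd, 1, seed = 1)
  expect_identical(as.integer(tag1), as.integer(kd))
  tag0 <- simulate_tag_snp(kd, 0, seed = 2)
  expect_lt(stats::cor(tag0, kd)^2, 0.05)
  tag8 <- simulate_tag_snp(kd, 0.8, seed = 3)
  r2 <- stats::cor(tag8, kd)^2
  expect_gte(r2, 0.75)
  expect_lte(r2, 0.85)
  expect_error(simulate_tag_snp(rep(2, 10), 0.5), "constant")
})
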