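# shared fixture builders and truth-mapping helpers

# map called karyotypes (HOM_MAJ/HET/HOM_MIN) onto generator truth labels
# (ANC_HOM/HET/DER_HOM) using the realized derived frequency
map_calls_to_truth <- function(karyotype, derived_freq) {
  der_lab <- if (derived_freq <= 0.5) "HOM_MIN" else "HOM_MAJ"
  anc_lab <- setdiff(c("HOM_MAJ", "HOM_MIN"), der_lab)
  dplyr::case_when(karyotype == "HET" ~ "HET",
                   karyotype == der_lab ~ "DER_HOM",
                   karyotype == anc_lab ~ "ANC_HOM",
                   .default = NA_character_)
}

# a small deterministic genotype matrix: three dosage groups constant
# across all SNPs (rank-1 inversion-like structure)
rank1_matrix <- function(n_per_group = 2, n_snps = 6) {
  dos <- rbind(
    matrix(0L, n_per_group, n_snps),
    matrix(1L, n_per_group, n_snps),
    matrix(2L, n_per_group, n_snps))
  geno_matrix(dos, positions = seq(1000, by = 1000, length.out = n_snps),
              chrom = "chrT", chrom_length = 1e6)
}

# plain-text toy VCF with 5 records (one tri-allelic), 3 samples,
# third sample haploid
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr9,length=100000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", sep = "\t"),
    paste("chr9", "100", ".", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1", sep = "\t"),
    paste("chr9", "200", ".", "C", "T", ".", "PASS", ".", "GT",
          "0/1", "1/1", "0", sep = "\t"),
    paste("chr9", "300", ".", "G", "A,T", ".", "PASS", ".", "GT",
          "0/1", "0/2", "1", sep = "\t"),  # tri-allelic: skipped
    paste("chr9", "400", ".", "T", "C", ".", "PASS", ".", "GT",
          "./.", "0/0", "1", sep = "\t"),
    paste("chr9", "500", ".", "G", "C", ".", "PASS", ".", "GT",
          "1|1", "0/1", ".", sep = "\t"))
  writeLines(lines, path)
  path
}

# six-record interaction fixture engineered against the four criteria:
# 2 valid records from 2 samples at one locus pair; 1 short-range;
# 1 low quality; 1 endpoint 5 kb from a gap; 1 well-supported singleton
six_record_fixture <- function() {
  list(
    records = tibble::tibble(
      chrom = "chrF",
      pos1 = c(5.00e6, 5.02e6, 10.0e6, 5.01e6, 8.00e6, 12.0e6),
      pos2 = c(15.0e6, 15.01e6, 10.2e6, 14.99e6, 16.0e6, 18.0e6),
      quality = c(30, 12, 50, 2, 40, 25),
      sample = c("ZF1", "ZF2", "ZF3", "ZF4", "ZF5", "ZF6")),
    gaps = tibble::tibble(chrom = "chrF", start = 8.005e6, end = 8.1e6),
    chrom_length = 40e6)
}

# exact enumeration oracle: probability that k i.i.d. draws from the model,
# sorted ascending, strictly dominate the sorted observed frequencies
enumerate_exceedance <- function(observed, model) {
  k <- length(observed)
  obs <- sort(observed)
  grid <- do.call(expand.grid, rep(list(seq_along(model$freqs)), k))
  p_tot <- 0
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    draw <- sort(model$freqs[idx])
    if (all(draw > obs)) p_tot <- p_tot + prod(model$pmf[idx])
  }
  p_tot
}
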