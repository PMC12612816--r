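#' Read a genotype matrix from VCF
#'
#' Reads bi-allelic SNP records for one chromosome from a VCF v4.2 file and
#' returns dosages coded as the number of alternative alleles (0/1/2 diploid,
#' 0/1 haploid, `NA` missing). Multi-allelic and non-SNP records are skipped
#' with a message reporting how many were dropped. Per-sample ploidy is taken
#' from the GT field (single-allele calls are haploid).
#'
#' @param path path to an (uncompressed or bgzipped) VCF file.
#' @param chrom chromosome to extract; default: the first chromosome seen.
#' @param sex optional named character vector of per-sample sex
#'   (`"M"`/`"F"`/`"unknown"`).
#' @param chrom_length chromosome length in bp; defaults to a contig header
#'   line if present, else the last SNP position.
#' @return a [geno_matrix()], with attributes `ref` and `alt` holding the
#'   per-SNP alleles.
#' @export
read_vcf <- function(path, chrom = NULL, sex = NULL, chrom_length = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) stop("no records in VCF: ", path, call. = FALSE)
  if (is.null(chrom)) chrom <- fix[1, "CHROM"]
  on_chrom <- fix[, "CHROM"] == chrom
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1 & nchar(alt) == 1 &
    !grepl(",", alt, fixed = TRUE)
  keep <- on_chrom & is_snp
  n_skip <- sum(on_chrom & !is_snp)
  if (n_skip > 0) {
    message(sprintf("read_vcf: skipped %d non-bi-allelic-SNP record(s) on %s",
                    n_skip, chrom))
  }
  if (!any(keep)) stop("no usable bi-allelic SNP records on ", chrom, call. = FALSE)

  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  samples <- colnames(gt)
  pos <- as.numeric(fix[keep, "POS"])
  o <- order(pos)
  pos <- pos[o]
  gt <- gt[o, , drop = FALSE]

  parse_gt <- function(g) {
    # returns c(dosage, ploidy); NA dosage for missing
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(c(NA_integer_, NA_integer_))
    al <- strsplit(g, "[/|]")[[1]]
    if (any(al == ".")) return(c(NA_integer_, length(al)))
    c(sum(al == "1"), length(al))
  }
  parsed <- vapply(gt, parse_gt, integer(2))
  dos <- matrix(parsed[1, ], nrow = nrow(gt), ncol = ncol(gt))
  pld <- matrix(parsed[2, ], nrow = nrow(gt), ncol = ncol(gt))
  ploidy <- apply(pld, 2, function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0) 2L else as.integer(max(p))
  })

  if (is.null(chrom_length)) {
    ctg <- grep(sprintf("^##contig=<ID=%s[,>]", chrom), v@meta, value = TRUE)
    len <- regmatches(ctg, regexpr("length=[0-9]+", ctg))
    chrom_length <- if (length(len) >= 1) {
      as.numeric(sub("length=", "", len[[1]]))
    } else max(pos)
  }
  sx <- if (is.null(sex)) rep("unknown", length(samples)) else {
    unname(sex[samples]) -> s
    ifelse(is.na(s), "unknown", s)
  }
  gm <- geno_matrix(t(dos), pos, chrom = chrom, chrom_length = chrom_length,
                    samples = samples, sex = sx, ploidy = ploidy)
  attr(gm, "ref") <- unname(ref[keep][o])
  attr(gm, "alt") <- unname(alt[keep][o])
  gm
}

#' Write a genotype matrix as plain-text VCF v4.2
#'
#' @param x a [geno_matrix()].
#' @param path output path.
#' @param ref,alt per-SNP reference/alternative alleles; default taken from
#'   attributes set by [read_vcf()] or `A`/`T`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, ref = NULL, alt = NULL) {
  ref <- ref %||% attr(x, "ref") %||% rep("A", n_snps(x))
  alt <- alt %||% attr(x, "alt") %||% rep("T", n_snps(x))
  stopifnot(length(ref) == n_snps(x), length(alt) == n_snps(x))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", x$chrom, as.integer(x$chrom_length)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  gt_string <- function(d, p) {
    if (p == 1L) {
      if (is.na(d)) "." else as.character(d)
    } else {
      if (is.na(d)) "./." else c("0/0", "0/1", "1/1")[d + 1L]
    }
  }
  lines <- vapply(seq_len(n_snps(x)), function(j) {
    gts <- vapply(seq_len(n_samples(x)),
                  function(i) gt_string(x$dosage[i, j], x$ploidy[i]), "")
    paste(c(x$chrom, format(x$positions[j], scientific = FALSE), ".",
            ref[j], alt[j], ".", "PASS", ".", "GT", gts), collapse = "\t")
  }, "")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' IUPAC nucleotide ambiguity code for an unordered base pair
#' @noRd
iupac_code <- function(a, b) {
  key <- paste(sort(c(toupper(a), toupper(b))), collapse = "")
  code <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
            AA = "A", CC = "C", GG = "G", TT = "T")[key]
  if (is.na(code)) stop("unknown allele pair: ", key, call. = FALSE)
  unname(code)
}

#' Write per-sample IUPAC consensus sequences over SNP sites
#'
#' Emits one FASTA record per sample covering the SNP positions within
#' `region`: homozygous sites emit the allele, heterozygous sites the IUPAC
#' ambiguity code, missing calls `N`. Only variant positions are written (one
#' character per SNP site; the non-variant sequence backbone is not
#' reconstructed). Lines wrap at 60 columns.
#'
#' @param x a [geno_matrix()].
#' @param ref,alt per-SNP single-base alleles.
#' @param region length-2 numeric `(start, end)` in bp, 1-based inclusive;
#'   default: whole chromosome.
#' @param path optional output file; when `NULL` the FASTA text is returned.
#' @return the FASTA text as a character string (invisibly when written to
#'   `path`).
#' @export
write_iupac_consensus <- function(x, ref = NULL, alt = NULL,
                                  region = c(1, x$chrom_length), path = NULL) {
  ref <- ref %||% attr(x, "ref") %||% rep("A", n_snps(x))
  alt <- alt %||% attr(x, "alt") %||% rep("T", n_snps(x))
  if (any(nchar(c(ref, alt)) != 1)) stop("alleles must be single bases", call. = FALSE)
  if (region[1] > region[2] || region[1] < 1 || region[2] > x$chrom_length) {
    stop("region outside chromosome", call. = FALSE)
  }
  idx <- which(x$positions >= region[1] & x$positions <= region[2])
  recs <- vapply(seq_len(n_samples(x)), function(i) {
    chars <- vapply(idx, function(j) {
      d <- x$dosage[i, j]
      if (is.na(d)) return("N")
      if (x$ploidy[i] == 1L) return(if (d == 1L) alt[j] else ref[j])
      if (d == 0L) ref[j]
      else if (d == 2L) alt[j]
      else tryCatch(iupac_code(ref[j], alt[j]),
                    error = function(e) stop("site at pos ", x$positions[j],
                                             ": ", conditionMessage(e),
                                             call. = FALSE))
    }, "")
    seq <- paste(chars, collapse = "")
    wrapped <- if (nchar(seq)) {
      starts <- seq(1, nchar(seq), by = 60)
      vapply(starts, function(s) substr(seq, s, min(s + 59, nchar(seq))), "")
    } else character(0)
    paste(c(paste0(">", x$samples[i]), wrapped), collapse = "\n")
  }, "")
  fasta <- paste0(paste(recs, collapse = "\n"), "\n")
  if (!is.null(path)) {
    cat(fasta, file = path)
    return(invisible(fasta))
  }
  fasta
}

#' Read long-range barcode-interaction calls
#'
#' Expects a tab-separated file with header columns `chrom`, `pos1`, `pos2`,
#' `quality`, `sample` (Long-Ranger-like large-SV output). Endpoint order is
#' normalized so `pos1 < pos2`.
#'
#' @param path TSV file path.
#' @return a tibble with one interaction per row; empty (with a warning) for
#'   an empty file.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("interactions file not found: ", path, call. = FALSE)
  empty <- tibble::tibble(chrom = character(), pos1 = numeric(),
                          pos2 = numeric(), quality = numeric(),
                          sample = character())
  first <- readLines(path, n = 1L)
  if (length(first) == 0) {
    warning("empty interactions file: ", path)
    return(empty)
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos1", "pos2", "quality", "sample")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("interactions file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(d) == 0) {
    warning("no interaction records in ", path)
    return(empty)
  }
  tibble::as_tibble(d[need]) |>
    dplyr::mutate(lo = pmin(.data$pos1, .data$pos2),
                  hi = pmax(.data$pos1, .data$pos2),
                  pos1 = .data$lo, pos2 = .data$hi) |>
    dplyr::select(-"lo", -"hi")
}

#' Write barcode interactions as TSV
#' @param x tibble with columns `chrom`, `pos1`, `pos2`, `quality`, `sample`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  utils::write.table(
    x[, c("chrom", "pos1", "pos2", "quality", "sample")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read assembly-gap annotations from BED
#'
#' BED intervals are half-open zero-based; they are converted to 1-based
#' inclusive on read, so `chr1 999 2000` becomes `start = 1000, end = 2000`.
#'
#' @param path BED3 file path.
#' @return tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_gaps <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("no gap records in ", path)
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric()))
  }
  parts <- strsplit(lines, "\t| +")
  if (any(lengths(parts) < 3)) {
    stop("BED line with fewer than 3 columns in ", path, call. = FALSE)
  }
  tibble::tibble(
    chrom = vapply(parts, `[[`, "", 1),
    start = as.numeric(vapply(parts, `[[`, "", 2)) + 1,
    end = as.numeric(vapply(parts, `[[`, "", 3))
  )
}

#' Write assembly gaps as BED3 (converting back to half-open zero-based)
#' @param x tibble with 1-based inclusive `chrom`, `start`, `end`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaps <- function(x, path) {
  writeLines(sprintf("%s\t%d\t%d", x$chrom, as.integer(x$start) - 1L,
                     as.integer(x$end)), path)
  invisible(path)
}
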