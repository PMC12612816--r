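#' Breakpoint-flanking regions inside an inversion
#'
#' Default mode returns two equal regions just inside the two breakpoints,
#' each `frac` of the inversion length (combined 2 * `frac`). Single-
#' breakpoint mode returns one fixed-width region adjacent to the chosen
#' breakpoint, as used to export sequence for tree building.
#'
#' @param block numeric `(start, end)` of the inversion, 1-based inclusive.
#' @param frac fraction of the inversion length per flank (default 0.10).
#' @param single `NULL` (both flanks) or `"left"`/`"right"`.
#' @param width region width in bp for single-breakpoint mode
#'   (default 400,000).
#' @return tibble with `region` (`left`/`right`), `start`, `end`.
#' @export
flank_regions <- function(block, frac = 0.10, single = NULL, width = 4e5) {
  stopifnot(block[2] > block[1])
  if (!is.null(single)) {
    single <- match.arg(single, c("left", "right"))
    return(if (single == "left") {
      tibble::tibble(region = "left", start = block[1],
                     end = block[1] + width - 1)
    } else {
      tibble::tibble(region = "right", start = block[2] - width + 1,
                     end = block[2])
    })
  }
  L <- block[2] - block[1] + 1
  w <- floor(frac * L)
  if (w < 1000) warning("flank regions shorter than 1 kb; rates unstable")
  tibble::tibble(region = c("left", "right"),
                 start = c(block[1], block[2] - w + 1),
                 end = c(block[1] + w - 1, block[2]))
}

#' Per-sample diversity statistics against an outgroup
#'
#' For each focal sample, counts within the region: heterozygous sites
#' (`n_het`), sites heterozygous in both the focal sample and the outgroup
#' (`n_shared`, shared polymorphism), and sites where focal and outgroup are
#' homozygous for different alleles (`n_fixed`, fixed differences). Rates are
#' per base pair of region length, not per SNP.
#'
#' @param x a [geno_matrix()] of focal samples.
#' @param outgroup a single-sample [geno_matrix()] at the same positions
#'   (extra positions in either are ignored; `NULL` to skip shared/fixed
#'   counts).
#' @param region numeric `(start, end)`, 1-based inclusive.
#' @return tibble with one row per sample: counts, `length` and `*_rate`
#'   columns.
#' @export
diversity_stats <- function(x, outgroup = NULL, region) {
  stopifnot(region[2] >= region[1])
  len <- region[2] - region[1] + 1
  idx <- which(x$positions >= region[1] & x$positions <= region[2])
  if (length(idx) == 0) {
    warning("no sites overlap region ", region[1], "-", region[2])
  }
  d <- x$dosage[, idx, drop = FALSE]
  og <- NULL
  if (!is.null(outgroup) && length(idx) > 0) {
    m <- match(x$positions[idx], outgroup$positions)
    og <- rep(NA_integer_, length(idx))
    og[!is.na(m)] <- outgroup$dosage[1, m[!is.na(m)]]
  }
  stats <- purrr::map_dfr(seq_len(n_samples(x)), function(i) {
    di <- d[i, ]
    pl <- x$ploidy[i]
    het <- !is.na(di) & pl == 2L & di == 1L
    n_het <- sum(het)
    n_shared <- n_fixed <- 0L
    if (!is.null(og)) {
      ok <- !is.na(di) & !is.na(og)
      n_shared <- sum(ok & het & og == 1L)
      foc_hom_alt <- if (pl == 2L) di == 2L else di == 1L
      foc_hom_ref <- di == 0L
      n_fixed <- sum(ok & ((foc_hom_ref & og == 2L) | (foc_hom_alt & og == 0L)))
    }
    tibble::tibble(sample = x$samples[i], n_het = n_het,
                   n_shared = n_shared, n_fixed = n_fixed)
  })
  dplyr::mutate(stats, chrom = x$chrom, start = region[1], end = region[2],
                length = len, het_rate = .data$n_het / len,
                shared_rate = .data$n_shared / len,
                fixed_rate = .data$n_fixed / len)
}

#' Classify ancestral vs. derived arrangement classes
#'
#' Given per-sample diversity rates for individuals homozygous for either
#' arrangement class, fits an ordinary least-squares contrast per statistic
#' and votes: the derived class is expected to show lower heterozygosity,
#' lower shared polymorphism with the outgroup, and more fixed differences.
#' A verdict requires at least two of the three statistics concordant; a 2-1
#' split is flagged weak; a three-way tie (or all rates identical) is
#' undetermined. When a chromosome-background heterozygosity rate is given
#' and both classes fall below `both_derived_factor` times it, the verdict is
#' `both_derived` (all extant arrangements recently derived).
#'
#' @param stats tibble from [diversity_stats()] with an added `class` column
#'   (two homokaryotype class labels); multiple regions per sample are pooled
#'   by summing counts and lengths.
#' @param background_het_rate optional background (outside-inversion)
#'   heterozygosity rate per bp.
#' @param both_derived_factor threshold factor on the background rate
#'   (default 0.5).
#' @return an `ancestry_verdict`: `derived_class`, `weak`, `evidence` tibble
#'   (per statistic: direction, effect, t, p), `class_rates`.
#' @export
classify_ancestral <- function(stats, background_het_rate = NULL,
                               both_derived_factor = 0.5) {
  stopifnot("class" %in% names(stats))
  classes <- sort(unique(stats$class))
  if (length(classes) != 2) stop("need exactly 2 arrangement classes",
                                 call. = FALSE)
  if (min(table(stats$class[!duplicated(stats$sample)])) < 2) {
    stop("need >= 2 samples per homokaryotype class", call. = FALSE)
  }
  per_sample <- dplyr::summarise(
    stats, dplyr::across(c("n_het", "n_shared", "n_fixed", "length"), sum),
    .by = c("sample", "class")) |>
    dplyr::mutate(het_rate = .data$n_het / .data$length,
                  shared_rate = .data$n_shared / .data$length,
                  fixed_rate = .data$n_fixed / .data$length)

  vote_one <- function(rate, lower_means_derived) {
    fit <- stats::lm(rate ~ factor(per_sample$class, classes))
    co <- suppressWarnings(summary(fit)$coefficients)  # perfect fits are fine
    b <- if (nrow(co) > 1) co[2, 1] else 0  # class2 - class1
    p <- if (nrow(co) > 1 && !is.nan(co[2, 4])) co[2, 4] else NA_real_
    tv <- if (nrow(co) > 1) co[2, 3] else NA_real_
    vote <- if (abs(b) < .Machine$double.eps) NA_character_
      else if ((b < 0) == lower_means_derived) classes[2] else classes[1]
    tibble::tibble(effect = b, t = tv, p = p, derived_vote = vote)
  }
  evidence <- dplyr::bind_rows(
    het = vote_one(per_sample$het_rate, TRUE),
    shared = vote_one(per_sample$shared_rate, TRUE),
    fixed = vote_one(per_sample$fixed_rate, FALSE),
    .id = "statistic")

  class_rates <- dplyr::summarise(
    per_sample, dplyr::across(c("het_rate", "shared_rate", "fixed_rate"),
                              mean), .by = "class")

  votes <- table(factor(evidence$derived_vote, classes))
  derived <- if (!is.null(background_het_rate) &&
                 all(class_rates$het_rate <
                       both_derived_factor * background_het_rate)) {
    "both_derived"
  } else if (max(votes) >= 2) {
    classes[which.max(votes)]
  } else "undetermined"
  structure(list(
    derived_class = derived,
    weak = derived %in% classes && min(votes) > 0,
    evidence = evidence, class_rates = class_rates,
    classes = classes), class = "ancestry_verdict")
}

#' @export
print.ancestry_verdict <- function(x, ...) {
  cat(sprintf("<ancestry_verdict> derived class: %s%s\n", x$derived_class,
              if (isTRUE(x$weak)) " (weak, 2-1 vote)" else ""))
  print(as.data.frame(x$evidence))
  invisible(x)
}

#' Sliding-window scan for evolutionary strata inside an inversion
#'
#' Recomputes the three class contrasts (heterozygosity, shared polymorphism,
#' fixed differences: derived class minus ancestral class) per window and
#' labels each window consistent when the majority of informative contrasts
#' match the global verdict (derived lower het, lower shared, higher fixed).
#' Contiguous runs of opposite windows are reported as candidate strata.
#'
#' @param x [geno_matrix()] of homokaryotype samples.
#' @param outgroup single-sample [geno_matrix()].
#' @param block inversion `(start, end)`.
#' @param classes named vector: arrangement class per sample in `x`.
#' @param derived_class the globally derived class label (e.g. from
#'   [classify_ancestral()]).
#' @param window,step window size and step in bp (defaults 50 kb / 25 kb).
#' @param merge_gap close interior gaps of at most this many windows when
#'   forming candidate strata (default 1).
#' @return tibble per window (`start`, `end`, `n_sites`, the three contrast
#'   values, `consistent`); candidate strata as the `"strata"` attribute
#'   (tibble of `start`, `end`).
#' @export
strata_scan <- function(x, outgroup, block, classes, derived_class,
                        window = 5e4, step = 2.5e4, merge_gap = 1) {
  stopifnot(all(x$samples %in% names(classes)))
  cls <- classes[x$samples]
  other <- setdiff(unique(cls), derived_class)
  if (length(other) != 1) stop("classes must contain the derived class and ",
                               "exactly one other", call. = FALSE)
  starts <- seq(block[1], max(block[1], block[2] - window + 1), by = step)
  if (block[1] + window - 1 > block[2]) starts <- block[1]  # single window
  wins <- purrr::map_dfr(starts, function(s) {
    e <- min(s + window - 1, block[2])
    st <- suppressWarnings(diversity_stats(x, outgroup, c(s, e)))
    st$class <- cls
    mn <- dplyr::summarise(
      st, dplyr::across(c("het_rate", "shared_rate", "fixed_rate"), mean),
      .by = "class")
    d <- function(col) {
      mn[[col]][mn$class == derived_class] - mn[[col]][mn$class == other]
    }
    tibble::tibble(start = s, end = e,
                   n_sites = sum(x$positions >= s & x$positions <= e),
                   d_het = d("het_rate"), d_shared = d("shared_rate"),
                   d_fixed = d("fixed_rate"))
  })
  score <- with(wins, sign(-d_het) + sign(-d_shared) + sign(d_fixed))
  wins$consistent <- dplyr::case_when(score > 0 ~ TRUE, score < 0 ~ FALSE,
                                      .default = NA)
  # candidate strata: contiguous opposite runs, closing interior gaps of at
  # most `merge_gap` windows (single-window flips are sampling noise)
  opp <- !is.na(wins$consistent) & !wins$consistent
  runs <- rle(opp)
  if (length(runs$lengths) > 2) {
    interior <- 2:(length(runs$lengths) - 1)
    close <- interior[!runs$values[interior] &
                        runs$lengths[interior] <= merge_gap]
    if (length(close) > 0) {
      idx <- cumsum(runs$lengths)
      for (ci in close) opp[(idx[ci - 1] + 1):idx[ci]] <- TRUE
      runs <- rle(opp)
    }
  }
  ends <- cumsum(runs$lengths)
  begins <- ends - runs$lengths + 1
  strata <- tibble::tibble(
    start = wins$start[begins[runs$values]],
    end = wins$end[ends[runs$values]])
  attr(wins, "strata") <- strata
  wins
}
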