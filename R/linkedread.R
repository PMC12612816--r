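#' Minimum breakpoint distance for long-range interaction calls
#'
#' Microchromosomes (strictly smaller than 20 Mb) use a 0.4 Mb threshold; all
#' other chromosomes use 3 Mb.
#'
#' @param chrom_length chromosome length in bp (> 0).
#' @return threshold in bp: 400,000 or 3,000,000.
#' @export
min_distance_for <- function(chrom_length) {
  stopifnot(chrom_length > 0)
  ifelse(chrom_length < 20e6, 4e5, 3e6)
}

#' Distance from a position to the nearest gap edge (0 when inside a gap)
#' @noRd
gap_distance <- function(pos, gaps) {
  if (is.null(gaps) || nrow(gaps) == 0) return(rep(Inf, length(pos)))
  vapply(pos, function(p) {
    inside <- p >= gaps$start & p <= gaps$end
    if (any(inside)) return(0)
    min(abs(p - gaps$start), abs(p - gaps$end))
  }, 0)
}

#' Greedy clustering of locus pairs within a merge radius
#' @noRd
cluster_pairs <- function(pos1, pos2, merge_radius) {
  n <- length(pos1)
  id <- integer(n)
  c1 <- c2 <- cn <- numeric(0)
  for (i in order(pos1, pos2)) {
    hit <- which(abs(c1 - pos1[i]) <= merge_radius &
                   abs(c2 - pos2[i]) <= merge_radius)
    if (length(hit) >= 1) {
      h <- hit[1]
      c1[h] <- (c1[h] * cn[h] + pos1[i]) / (cn[h] + 1)
      c2[h] <- (c2[h] * cn[h] + pos2[i]) / (cn[h] + 1)
      cn[h] <- cn[h] + 1
      id[i] <- h
    } else {
      c1 <- c(c1, pos1[i])
      c2 <- c(c2, pos2[i])
      cn <- c(cn, 1)
      id[i] <- length(c1)
    }
  }
  id
}

#' Filter long-range barcode-interaction calls
#'
#' Applies four criteria in fixed order, attributing each rejected record to
#' the first criterion it fails: (i) endpoint distance above the
#' chromosome-size-dependent threshold ([min_distance_for()]); (ii) quality
#' at least `quality_min`; (iii) both endpoints at least `gap_dist` from
#' every assembly gap; (iv) the locus pair (endpoints clustered across
#' samples within `merge_radius`) supported by at least `min_support`
#' distinct samples.
#'
#' @param records tibble of interactions (`chrom`, `pos1`, `pos2`, `quality`,
#'   `sample`), one chromosome.
#' @param gaps tibble of 1-based inclusive gap intervals ([read_gaps()]),
#'   or NULL.
#' @param chrom_length chromosome length in bp.
#' @param quality_min minimum quality (default 4).
#' @param gap_dist minimum distance to a gap in bp (default 10,000).
#' @param min_support minimum number of distinct supporting samples
#'   (default 2).
#' @param merge_radius endpoint clustering radius in bp (default 50,000).
#' @return a `filter_report`: `survivors` (records + `locus_id`),
#'   `rejected` (records + `criterion`), `support_counts` (per locus pair:
#'   mean endpoints and number of distinct samples), `relaxed` (`"none"`).
#' @export
filter_interactions <- function(records, gaps = NULL, chrom_length,
                                quality_min = 4, gap_dist = 10000,
                                min_support = 2, merge_radius = 50000) {
  rec <- tibble::as_tibble(records)
  empty_rep <- structure(list(
    survivors = dplyr::mutate(rec[0, ], locus_id = integer(0)),
    rejected = dplyr::mutate(rec[0, ], criterion = character(0)),
    support_counts = tibble::tibble(locus_id = integer(0), pos1 = numeric(0),
                                    pos2 = numeric(0), n_samples = integer(0)),
    relaxed = "none"), class = "filter_report")
  if (nrow(rec) == 0) return(empty_rep)
  if (length(unique(rec$chrom)) > 1) {
    stop("records must be on a single chromosome", call. = FALSE)
  }
  mind <- min_distance_for(chrom_length)
  crit <- rep(NA_character_, nrow(rec))
  crit[is.na(crit) & !(rec$pos2 - rec$pos1 > mind)] <- "i_distance"
  crit[is.na(crit) & !(rec$quality >= quality_min)] <- "ii_quality"
  if (gap_dist > 0) {
    d1 <- gap_distance(rec$pos1, gaps)
    d2 <- gap_distance(rec$pos2, gaps)
    crit[is.na(crit) & !(d1 >= gap_dist & d2 >= gap_dist)] <- "iii_near_gap"
  }
  pass <- which(is.na(crit))
  locus <- rep(NA_integer_, nrow(rec))
  if (length(pass) > 0) {
    locus[pass] <- cluster_pairs(rec$pos1[pass], rec$pos2[pass], merge_radius)
    supp <- tapply(rec$sample[pass], locus[pass],
                   function(s) length(unique(s)))
    weak <- as.integer(names(supp)[supp < min_support])
    crit[pass][locus[pass] %in% weak] <- "iv_support"
  }
  surv <- which(is.na(crit))
  support_counts <- if (length(pass) > 0) {
    dplyr::summarise(
      tibble::tibble(locus_id = locus[pass], pos1 = rec$pos1[pass],
                     pos2 = rec$pos2[pass], sample = rec$sample[pass]),
      pos1 = mean(.data$pos1), pos2 = mean(.data$pos2),
      n_samples = dplyr::n_distinct(.data$sample), .by = "locus_id")
  } else empty_rep$support_counts
  survivors <- rec[surv, ]
  survivors$locus_id <- locus[surv]  # base assignment: input tibbles may
  rejected <- rec[!is.na(crit), ]    # carry columns with colliding names
  rejected$criterion <- crit[!is.na(crit)]
  structure(list(survivors = survivors, rejected = rejected,
                 support_counts = support_counts,
                 relaxed = "none"), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report%s> %d survivor(s), %d rejected\n",
              if (x$relaxed != "none") paste0(", relaxed: ", x$relaxed) else "",
              nrow(x$survivors), nrow(x$rejected)))
  if (nrow(x$rejected) > 0) print(table(x$rejected$criterion))
  invisible(x)
}

#' Re-run the interaction filter with one criterion relaxed
#'
#' `near_gap_ok` disables the gap-distance criterion (iii); `singleton_ok`
#' disables the multi-sample support criterion (iv). Used to recover nested
#' inversions whose breakpoints sit near assembly gaps or are carried by a
#' single sequenced individual.
#'
#' @inheritParams filter_interactions
#' @param mode `"near_gap_ok"` or `"singleton_ok"`.
#' @return a `filter_report` labeled with the relaxation mode.
#' @export
relaxed_rescan <- function(records, gaps = NULL, chrom_length,
                           mode = c("near_gap_ok", "singleton_ok"),
                           quality_min = 4, gap_dist = 10000,
                           min_support = 2, merge_radius = 50000) {
  mode <- match.arg(mode)
  rep <- filter_interactions(
    records, gaps, chrom_length, quality_min = quality_min,
    gap_dist = if (mode == "near_gap_ok") 0 else gap_dist,
    min_support = if (mode == "singleton_ok") 1 else min_support,
    merge_radius = merge_radius)
  rep$relaxed <- mode
  rep
}

#' Concordance of surviving locus pairs with the PCA breakpoint block
#'
#' A locus pair is concordant when each endpoint lies within `tolerance` of
#' the respective breakpoint-block edge.
#'
#' @param report a `filter_report`.
#' @param breakpoint_block numeric `(start, end)` from
#'   [locate_breakpoint_block()].
#' @param tolerance matching tolerance in bp (default 100,000).
#' @return tibble per locus pair with endpoint distances `d1`, `d2` and
#'   `status` (`concordant`/`discordant`); zero rows (status attribute
#'   `"unmatched"`) when the report has no survivors.
#' @export
concordance <- function(report, breakpoint_block, tolerance = 1e5) {
  sc <- report$support_counts
  sc <- sc[sc$locus_id %in% report$survivors$locus_id, , drop = FALSE]
  out <- dplyr::mutate(
    sc,
    d1 = abs(.data$pos1 - breakpoint_block[1]),
    d2 = abs(.data$pos2 - breakpoint_block[2]),
    status = ifelse(.data$d1 <= tolerance & .data$d2 <= tolerance,
                    "concordant", "discordant"))
  attr(out, "overall") <- if (nrow(out) == 0) "unmatched"
    else if (any(out$status == "concordant")) "concordant" else "discordant"
  out
}

#' Flag nested and overlapping locus pairs relative to the primary inversion
#'
#' The primary pair is the one with the largest span (or supplied). Every
#' other surviving pair is labeled `nested` (strictly inside the primary
#' span), `overlapping` (exactly one endpoint inside) or `independent`.
#'
#' @param report a `filter_report` (or a tibble with `pos1`, `pos2` per
#'   locus pair).
#' @param primary_pair optional numeric `(pos1, pos2)`; default the
#'   largest-span surviving pair.
#' @return tibble of locus pairs with a `relation` column; the primary pair
#'   is labeled `"primary"`.
#' @export
flag_nested <- function(report, primary_pair = NULL) {
  pairs <- if (inherits(report, "filter_report")) {
    sc <- report$support_counts
    sc[sc$locus_id %in% report$survivors$locus_id, , drop = FALSE]
  } else tibble::as_tibble(report)
  if (nrow(pairs) == 0) return(dplyr::mutate(pairs, relation = character(0)))
  if (is.null(primary_pair)) {
    pp <- which.max(pairs$pos2 - pairs$pos1)
    primary_pair <- c(pairs$pos1[pp], pairs$pos2[pp])
  }
  dplyr::mutate(pairs, relation = purrr::map2_chr(
    .data$pos1, .data$pos2, function(a, b) {
      if (isTRUE(all.equal(c(a, b), primary_pair))) return("primary")
      ins <- c(a > primary_pair[1] && a < primary_pair[2],
               b > primary_pair[1] && b < primary_pair[2])
      if (all(ins)) "nested" else if (any(ins)) "overlapping"
      else "independent"
    }))
}
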