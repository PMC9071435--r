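## Profiling statistics computed from a pair-count matrix (or from a model's
## exact expected distribution, which every function here accepts in place of
## counts).
##
## Denominators are always ordered counts. Because every product is counted
## in both orientations, product-level and ordered-event-level fractions are
## identical, and each ordered orientation attributes to its *top* overhang
## (so per-overhang quantities see every product exactly once per
## participating overhang).

GC_BINS <- c(0L, 25L, 50L, 75L, 100L)

#' Normalized ligation frequency per overhang
#'
#' The relative frequency of each overhang appearing across all ligation
#' products, scaled so that uniform usage equals 1: `freq(o) = 256 *`
#' `rowsum(o) / total`. Values sum to 256; the mean over the 256 overhangs
#' is 1.
#'
#' @param M A `pair_counts` matrix, a `pair_expectation`, or a bare 256x256
#'   nonnegative matrix.
#' @return Named numeric vector over the 256 overhangs.
#' @export
normalized_frequency <- function(M) {
  m <- .as_pair_matrix(M)
  tot <- sum(m)
  if (tot <= 0) stop("empty pair-count matrix", call. = FALSE)
  256 * rowSums(m) / tot
}

#' Overall and per-overhang ligation fidelity
#'
#' Fidelity is the fraction of ligation events that are correct
#' (Watson-Crick) rather than mismatch-containing. `overall_fidelity()` is
#' the fraction of all ordered counts that fall in Watson-Crick cells;
#' `per_overhang_fidelity(o)` is counts[o, revcomp(o)] / rowsum(o), reported
#' as NA (undefined, never 0) for overhangs with no events. The overall value
#' equals the event-weighted mean of the per-overhang values.
#'
#' @inheritParams normalized_frequency
#' @return `overall_fidelity()`: a single number in [0, 1].
#'   `per_overhang_fidelity()`: named numeric vector over the 256 overhangs.
#' @export
overall_fidelity <- function(M) {
  m <- .as_pair_matrix(M)
  tot <- sum(m)
  if (tot <= 0) stop("empty pair-count matrix", call. = FALSE)
  sum(m[.pair_tables()$wc_cells]) / tot
}

#' @rdname overall_fidelity
#' @export
per_overhang_fidelity <- function(M) {
  m <- .as_pair_matrix(M)
  if (sum(m) <= 0) stop("empty pair-count matrix", call. = FALSE)
  rs <- rowSums(m)
  wc <- m[.pair_tables()$wc_cells]
  out <- ifelse(rs > 0, wc / rs, NA_real_)
  names(out) <- overhangs()
  out
}

#' GC-stratified summary of a per-overhang statistic
#'
#' Groups a per-overhang value (frequency, fidelity, ...) by overhang GC
#' content. The five bins 0/25/50/75/100% GC contain 16/64/96/64/16 of the
#' 256 overhangs. Undefined values (NA) are excluded from means and medians,
#' never treated as 0.
#'
#' @param values Named numeric vector over four-base overhangs.
#' @return A data.frame with columns `gc_percent`, `n_overhangs`, `n_defined`,
#'   `mean`, `median`.
#' @export
gc_binned_summary <- function(values) {
  if (is.null(names(values)) || length(values) == 0L) {
    stop("values must be a non-empty named vector over overhangs",
         call. = FALSE)
  }
  gc <- gc_percent(names(values))
  out <- lapply(GC_BINS, function(b) {
    v <- values[gc == b]
    data.frame(gc_percent = b,
               n_overhangs = length(v),
               n_defined = sum(!is.na(v)),
               mean = if (any(!is.na(v))) mean(v, na.rm = TRUE) else NA_real_,
               median = if (any(!is.na(v))) stats::median(v, na.rm = TRUE)
                        else NA_real_)
  })
  do.call(rbind, out)
}

#' Rank tests between adjacent GC bins
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) tests of a per-overhang
#' statistic between each pair of adjacent GC-content bins.
#'
#' @param values Named numeric vector over four-base overhangs.
#' @return A data.frame with columns `bin_low`, `bin_high`, `p_value`.
#' @export
gc_bin_tests <- function(values) {
  gc <- gc_percent(names(values))
  out <- lapply(seq_len(length(GC_BINS) - 1L), function(k) {
    a <- values[gc == GC_BINS[k]]
    b <- values[gc == GC_BINS[k + 1L]]
    p <- if (sum(!is.na(a)) > 0 && sum(!is.na(b)) > 0) {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    } else NA_real_
    data.frame(bin_low = GC_BINS[k], bin_high = GC_BINS[k + 1L], p_value = p)
  })
  do.call(rbind, out)
}

#' Positional mismatch spectrum
#'
#' Enumerates every mismatched base pair across all ordered pairs, weighted
#' by counts, and tallies frequency by base-pair label (top:bottom, so both
#' G:T and T:G arise from the two counted orientations) and position class.
#' Edge aggregates positions 1 and 4; middle aggregates positions 2 and 3.
#' Frequencies are normalized within each position class.
#'
#' @inheritParams normalized_frequency
#' @return A data.frame with columns `label`, `position_class`, `weight`
#'   (count-weighted occurrences), `frequency` (within-class). Zero rows for
#'   a Watson-Crick-only matrix.
#' @export
mismatch_spectrum <- function(M) {
  m <- .as_pair_matrix(M)
  if (sum(m) <= 0) stop("empty pair-count matrix", call. = FALSE)
  tb <- .pair_tables()
  pieces <- lapply(seq_len(4L), function(i) {
    lab <- tb$label[[i]]
    idx <- which(!is.na(lab) & m > 0)
    if (!length(idx)) return(NULL)
    w <- rowsum(m[idx], lab[idx])
    data.frame(label = rownames(w), position_class = .position_class(i),
               weight = w[, 1L], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, pieces)
  if (is.null(res) || nrow(res) == 0L) {
    return(data.frame(label = character(0), position_class = character(0),
                      weight = numeric(0), frequency = numeric(0)))
  }
  agg <- stats::aggregate(weight ~ label + position_class, data = res, FUN = sum)
  cls_tot <- stats::ave(agg$weight, agg$position_class, FUN = sum)
  agg$frequency <- agg$weight / cls_tot
  agg <- agg[order(agg$position_class, -agg$weight), ]
  rownames(agg) <- NULL
  agg[, c("label", "position_class", "weight", "frequency")]
}

#' Distribution of mismatches per ligation event
#'
#' Fraction of ordered ligation events carrying 0..4 mismatched junction
#' positions. By the dual-orientation convention this equals the per-product
#' distribution. The zero-mismatch fraction equals [overall_fidelity()].
#'
#' @inheritParams normalized_frequency
#' @return Named numeric vector of length 5 (`"0"`..`"4"`) summing to 1.
#' @export
mismatch_count_distribution <- function(M) {
  m <- .as_pair_matrix(M)
  tot <- sum(m)
  if (tot <= 0) stop("empty pair-count matrix", call. = FALSE)
  tb <- .pair_tables()
  out <- vapply(0:4, function(k) sum(m[tb$mm_count == k]), numeric(1)) / tot
  names(out) <- as.character(0:4)
  out
}

#' Edge involvement among double-mismatch events
#'
#' Among ligation events with exactly two mismatched positions, the fraction
#' whose mismatches include at least one edge position (N1 or N4).
#'
#' @inheritParams normalized_frequency
#' @return A single number in [0, 1], or NA (with a message) if the matrix
#'   contains no two-mismatch events.
#' @export
double_mismatch_edge_fraction <- function(M) {
  m <- .as_pair_matrix(M)
  tb <- .pair_tables()
  two <- tb$mm_count == 2L
  tot <- sum(m[two])
  if (tot <= 0) {
    message("no two-mismatch events; edge fraction undefined")
    return(NA_real_)
  }
  sum(m[two & tb$edge_mm]) / tot
}

#' Mean normalized frequency of pattern-defined overhang groups
#'
#' Summarizes a frequency profile over overhang families defined by patterns
#' with N wildcards (e.g. "TNNA", "CNNG"). With mean-1 normalization, a group
#' mean below 1 reads directly as under-representation relative to the
#' average overhang.
#'
#' @param freqs Named numeric vector over the 256 overhangs (e.g. from
#'   [normalized_frequency()]).
#' @param patterns Character vector of 4-character patterns over
#'   \{A,C,G,T,N\}.
#' @return A data.frame with columns `pattern`, `n`, `mean`.
#' @export
pattern_group_summary <- function(freqs, patterns) {
  stopifnot(!is.null(names(freqs)))
  out <- lapply(patterns, function(p) {
    sel <- matches_pattern(names(freqs), p)
    if (!any(sel)) stop("pattern ", p, " matches no overhang", call. = FALSE)
    data.frame(pattern = p, n = sum(sel), mean = mean(freqs[sel], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Pearson correlation between two per-overhang profiles
#'
#' Product-moment correlation over the 256 paired per-overhang values, the
#' statistic used to compare sequence-bias profiles across replicates and
#' ligases.
#'
#' @param a,b Named numeric vectors over the 256 overhangs.
#' @return Pearson r in [-1, 1]; NA with a warning if either profile has zero
#'   variance.
#' @export
pearson_correlation <- function(a, b) {
  oh <- overhangs()
  stopifnot(!is.null(names(a)), !is.null(names(b)))
  a <- a[oh]
  b <- b[oh]
  if (anyNA(a) || anyNA(b)) {
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]
    b <- b[keep]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(a, b)
}

#' Synthesis-bias correction from the randomized control region
#'
#' The substrate carries an internal randomized control region whose base
#' composition estimates per-position synthesis bias. Expected overhang
#' abundance under that bias is the product of the four per-base frequencies
#' (overhang positions 1-4 mapped to control positions 1-4); the corrected
#' frequency is observed / expected, renormalized to mean 1.
#'
#' @param freqs Named numeric vector over the 256 overhangs.
#' @param control_tally A base x position count matrix (rows A, C, G, T; at
#'   least 4 position columns), e.g. the `control_tally` attribute attached
#'   by [tabulate_pairs()].
#' @return Corrected frequency vector (mean 1). If the tally is missing or
#'   has an all-zero position, the correction is skipped with a warning and
#'   `freqs` is returned unchanged.
#' @export
synthesis_bias_correction <- function(freqs, control_tally) {
  stopifnot(!is.null(names(freqs)))
  if (is.null(control_tally)) {
    warning("no control tallies available; synthesis-bias correction skipped",
            call. = FALSE)
    return(freqs)
  }
  if (!is.matrix(control_tally) || nrow(control_tally) != 4L ||
      ncol(control_tally) < 4L ||
      !all(OH_BASES %in% rownames(control_tally))) {
    stop("control_tally must be a base x position matrix with rows A,C,G,T ",
         "and >= 4 positions", call. = FALSE)
  }
  tally <- control_tally[OH_BASES, 1:4, drop = FALSE]
  cs <- colSums(tally)
  if (any(cs == 0)) {
    warning("control tally has an all-zero position; correction skipped",
            call. = FALSE)
    return(freqs)
  }
  f <- sweep(tally, 2L, cs, "/")
  bm <- do.call(rbind, strsplit(names(freqs), "", fixed = TRUE))
  expected <- vapply(seq_along(freqs), function(k) {
    prod(f[cbind(match(bm[k, ], OH_BASES), 1:4)])
  }, numeric(1))
  corrected <- freqs / (expected / mean(expected))
  corrected / mean(corrected, na.rm = TRUE)
}

#' Ligation yield
#'
#' Yield = 100 x [product] / ([substrate] + [product]). Concentrations may be
#' in any common unit.
#'
#' @param product_conc,substrate_conc Nonnegative concentrations (not both
#'   zero).
#' @return Percent yield.
#' @export
#' @examples
#' yield_percent(50, 50)  # 50
#' yield_percent(3, 1)    # 75
yield_percent <- function(product_conc, substrate_conc) {
  if (any(product_conc < 0) || any(substrate_conc < 0)) {
    stop("concentrations must be nonnegative", call. = FALSE)
  }
  tot <- product_conc + substrate_conc
  if (any(tot == 0)) stop("substrate and product cannot both be zero",
                          call. = FALSE)
  100 * product_conc / tot
}
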