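## The fitted-profile object: every reported statistic computed from one
## pair-count matrix, with print/summary/plot methods.

#' Profile a pair-count matrix
#'
#' Computes the full set of reported statistics from a dual-orientation
#' pair-count matrix (or a model's exact expected distribution): normalized
#' ligation frequency and per-overhang fidelity, overall fidelity,
#' GC-stratified summaries of both, positional mismatch spectra, the
#' per-event mismatch-count distribution, and the edge involvement of double
#' mismatches. Optionally applies the synthesis-bias correction from the
#' randomized control region.
#'
#' @param M A `pair_counts` matrix (from [tabulate_pairs()],
#'   [sample_events()], or [read_counts_csv()]) or a `pair_expectation` from
#'   [expected_profile()].
#' @param correction `"none"` (default, raw frequencies) or
#'   `"control-hexamer"` to divide out per-position synthesis bias estimated
#'   from the control region.
#' @param control_tally Base x position tally for the correction; defaults to
#'   the `control_tally` attribute of `M` when present.
#' @return An object of class `ligation_profile` with elements `frequency`,
#'   `fidelity`, `overall_fidelity`, `gc_frequency`, `gc_fidelity`,
#'   `spectrum`, `mismatch_counts`, `double_mismatch_edge`, `n_ordered`,
#'   `n_products`, `meta`.
#' @export
#' @examples
#' m <- ligase_model_preset("moderate")
#' prof <- ligation_profile(sample_events(m, 5e4, seed = 1))
#' prof
ligation_profile <- function(M, correction = c("none", "control-hexamer"),
                             control_tally = attr(M, "control_tally")) {
  correction <- match.arg(correction)
  m <- .as_pair_matrix(M)
  freq <- normalized_frequency(m)
  if (correction == "control-hexamer") {
    freq <- synthesis_bias_correction(freq, control_tally)
  }
  fid <- per_overhang_fidelity(m)
  two_mm <- sum(m[.pair_tables()$mm_count == 2L]) > 0
  structure(list(
    frequency = freq,
    fidelity = fid,
    overall_fidelity = overall_fidelity(m),
    gc_frequency = gc_binned_summary(freq),
    gc_fidelity = gc_binned_summary(fid),
    spectrum = mismatch_spectrum(m),
    mismatch_counts = mismatch_count_distribution(m),
    double_mismatch_edge = if (two_mm) double_mismatch_edge_fraction(m)
                           else NA_real_,
    n_ordered = sum(m),
    n_products = sum(m) / 2,
    correction = correction,
    meta = list(sample = attr(M, "sample"), ligase = attr(M, "ligase"),
                condition = attr(M, "condition"),
                replicates = attr(M, "replicates"))
  ), class = "ligation_profile")
}

#' @export
print.ligation_profile <- function(x, ...) {
  lig <- x$meta$ligase
  cat("Ligation fidelity/bias profile",
      if (!is.null(lig) && !is.na(lig)) paste0("(", lig, ")"), "\n")
  cat(sprintf("  products: %s (ordered counts: %s)\n",
              format(x$n_products, big.mark = ","),
              format(x$n_ordered, big.mark = ",")))
  cat(sprintf("  overall fidelity: %.1f%% correct ligation events\n",
              100 * x$overall_fidelity))
  mm <- x$mismatch_counts
  cat(sprintf("  mismatch-containing products: %.1f%%", 100 * (1 - mm["0"])))
  if (mm["0"] < 1) {
    cat(sprintf(" (of these, %.1f%% single-mismatch)",
                100 * mm["1"] / (1 - mm["0"])))
  }
  cat("\n")
  invisible(x)
}

#' @export
summary.ligation_profile <- function(object, ...) {
  x <- object
  cat(sprintf("Ligation profile: %s products, overall fidelity %.1f%%\n",
              format(x$n_products, big.mark = ","),
              100 * x$overall_fidelity))
  mm <- x$mismatch_counts
  frac_mm <- 1 - mm["0"]
  cat(sprintf("Mismatch-containing products: %.1f%%\n", 100 * frac_mm))
  if (frac_mm > 0) {
    cat(sprintf("  single-mismatch share of mismatch products: %.1f%%\n",
                100 * mm["1"] / frac_mm))
    cat(sprintf("  double-mismatch share of all products: %.1f%%\n",
                100 * mm["2"]))
    if (!is.na(x$double_mismatch_edge)) {
      cat(sprintf("  double mismatches involving an edge position: %.1f%%\n",
                  100 * x$double_mismatch_edge))
    }
  }
  cat("\nNormalized frequency by GC content:\n")
  print(x$gc_frequency, row.names = FALSE, digits = 3)
  cat("\nFidelity by GC content:\n")
  print(x$gc_fidelity, row.names = FALSE, digits = 3)
  if (nrow(x$spectrum) > 0) {
    cat("\nTop mismatches by position class:\n")
    sp <- x$spectrum
    top <- do.call(rbind, lapply(split(sp, sp$position_class),
                                 function(d) utils::head(d, 3L)))
    print(top, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Plot a ligation profile
#'
#' Strip plots of per-overhang normalized frequency and fidelity grouped by
#' GC content (0% dark red, 25% light red, 50% gray, 75% light blue, 100%
#' dark blue), with per-bin medians marked.
#'
#' @param x A `ligation_profile`.
#' @param which `"frequency"`, `"fidelity"`, or both (default).
#' @param ... Passed to [graphics::stripchart()].
#' @export
plot.ligation_profile <- function(x, which = c("frequency", "fidelity"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  cols <- c("darkred", "salmon", "gray40", "lightblue3", "darkblue")
  op <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(op))
  for (w in which) {
    v <- if (w == "frequency") x$frequency else x$fidelity
    gc <- factor(gc_percent(names(v)), levels = GC_BINS)
    graphics::stripchart(v ~ gc, vertical = TRUE, method = "jitter",
                         jitter = 0.25, pch = 16, cex = 0.5, col = cols,
                         xlab = "GC content (%)",
                         ylab = if (w == "frequency")
                           "normalized ligation frequency" else "fidelity",
                         main = w, ...)
    med <- tapply(v, gc, stats::median, na.rm = TRUE)
    graphics::segments(seq_along(med) - 0.3, med, seq_along(med) + 0.3, med,
                       lwd = 2)
  }
  invisible(x)
}

#' Compare two ligation profiles (e.g. with and without PEG)
#'
#' Paired per-overhang frequency and fidelity deltas (B minus A), per-GC-bin
#' median shifts, and the overall fidelity delta between two conditions.
#'
#' @param a,b `ligation_profile` objects over the same 256 overhangs.
#' @return An object of class `profile_comparison`.
#' @export
compare_profiles <- function(a, b) {
  stopifnot(inherits(a, "ligation_profile"), inherits(b, "ligation_profile"))
  oh <- overhangs()
  dfreq <- b$frequency[oh] - a$frequency[oh]
  dfid <- b$fidelity[oh] - a$fidelity[oh]
  med_shift <- function(va, vb) {
    gb <- gc_binned_summary(vb)
    ga <- gc_binned_summary(va)
    data.frame(gc_percent = ga$gc_percent,
               median_a = ga$median, median_b = gb$median,
               median_shift = gb$median - ga$median)
  }
  structure(list(
    delta_frequency = dfreq,
    delta_fidelity = dfid,
    overall_fidelity_delta = b$overall_fidelity - a$overall_fidelity,
    gc_frequency_shift = med_shift(a$frequency, b$frequency),
    gc_fidelity_shift = med_shift(a$fidelity, b$fidelity),
    meta = list(a = a$meta, b = b$meta)
  ), class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("Condition comparison (B - A)\n")
  cat(sprintf("  overall fidelity delta: %+.1f percentage points\n",
              100 * x$overall_fidelity_delta))
  cat("  per-GC-bin median fidelity shift:\n")
  print(x$gc_fidelity_shift, row.names = FALSE, digits = 3)
  cat("  per-GC-bin median frequency shift:\n")
  print(x$gc_frequency_shift, row.names = FALSE, digits = 3)
  invisible(x)
}
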