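## Initial-velocity estimation for the defined-overhang oligonucleotide
## ligation assay: ordinary least-squares fit of the linear portion of a
## product-formation timecourse, capped at 25% product conversion.

#' Initial velocity from a ligation timecourse
#'
#' Fits fraction product vs time by ordinary least squares over the linear
#' initial regime: points are retained up to (but excluding) the first point
#' whose conversion exceeds `cap`; that point and all later points are
#' dropped. The cap applies to product-conversion fraction, not time.
#'
#' @param time Timepoints in minutes, strictly increasing.
#' @param fraction Fraction product in [0, 1] at each timepoint.
#' @param cap Maximum product conversion included in the fit (default 0.25).
#' @param substrate_conc Optional substrate concentration (nM); when given,
#'   the slope is also reported in nM/min.
#' @return An object of class `initial_velocity`: `slope` (fraction/min),
#'   `stderr` (standard error of the slope; NA when only two points are
#'   retained), `n_points_used`, `points_used` (indices), and optionally
#'   `slope_nM_per_min`.
#' @export
#' @examples
#' v <- initial_velocity(c(0, 1, 2, 3), c(0, 0.10, 0.20, 0.40))
#' v$slope           # 0.10/min; the 0.40 point is excluded (> 25%)
#' v$n_points_used   # 3
initial_velocity <- function(time, fraction, cap = 0.25,
                             substrate_conc = NULL) {
  if (length(time) != length(fraction) || length(time) < 2L) {
    stop("need >= 2 timepoints with matching fractions", call. = FALSE)
  }
  if (any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (any(fraction < 0 | fraction > 1)) {
    stop("fractions must be in [0, 1]", call. = FALSE)
  }
  over <- which(fraction > cap)
  keep <- if (length(over)) seq_len(over[1L] - 1L) else seq_along(time)
  if (length(keep) < 2L) {
    stop("fewer than 2 timepoints at or below the ", 100 * cap,
         "% conversion cap", call. = FALSE)
  }
  fit <- stats::lm(fraction[keep] ~ time[keep])
  # summary.lm warns on exactly collinear points; a zero-residual fit is a
  # legitimate input here
  co <- suppressWarnings(summary(fit)$coefficients)
  slope <- unname(co[2L, 1L])
  se <- unname(co[2L, 2L])
  if (!is.finite(se)) se <- NA_real_   # two retained points: zero df
  if (is.finite(se) && se < sqrt(.Machine$double.eps)) se <- 0
  out <- list(slope = slope, stderr = se, n_points_used = length(keep),
              points_used = keep, cap = cap)
  if (!is.null(substrate_conc)) {
    out$slope_nM_per_min <- slope * substrate_conc
  }
  structure(out, class = "initial_velocity")
}

#' @export
print.initial_velocity <- function(x, ...) {
  cat(sprintf("Initial velocity: %.4g fraction/min (se %s; %d points <= %g%% conversion)\n",
              x$slope,
              if (is.na(x$stderr)) "NA" else sprintf("%.3g", x$stderr),
              x$n_points_used, 100 * x$cap))
  if (!is.null(x$slope_nM_per_min)) {
    cat(sprintf("  = %.4g nM/min\n", x$slope_nM_per_min))
  }
  invisible(x)
}

#' Average replicate initial-velocity fits
#'
#' Arithmetic mean of replicate slopes, with the propagated fit error
#' (quadrature combination of per-fit standard errors, sqrt(sum se^2)/n) and
#' the replicate standard deviation both reported.
#'
#' @param fits A list of `initial_velocity` objects (>= 1).
#' @return A list: `mean_slope`, `reported_error` (propagated fit error),
#'   `replicate_sd`, `n`.
#' @export
average_replicates <- function(fits) {
  if (inherits(fits, "initial_velocity")) fits <- list(fits)
  if (!length(fits)) stop("need at least one fit", call. = FALSE)
  slopes <- vapply(fits, function(f) f$slope, numeric(1))
  ses <- vapply(fits, function(f) f$stderr, numeric(1))
  n <- length(slopes)
  list(mean_slope = mean(slopes),
       reported_error = if (all(is.na(ses))) NA_real_
                        else sqrt(sum(ses^2, na.rm = TRUE)) / n,
       replicate_sd = if (n > 1L) stats::sd(slopes) else NA_real_,
       n = n)
}

#' Per-substrate velocity summary from a timecourse table
#'
#' Fits each (substrate, replicate) timecourse with [initial_velocity()],
#' averages replicates with [average_replicates()], and reports fold ratios
#' of each substrate's mean velocity relative to the fastest substrate.
#'
#' @param timecourses A data.frame with columns `substrate`, `replicate`,
#'   `time_min`, `fraction_product` (e.g. from [read_timecourse_csv()]).
#' @param cap Conversion cap passed to [initial_velocity()].
#' @return A data.frame with one row per substrate: `substrate`,
#'   `mean_slope`, `reported_error`, `replicate_sd`, `n_replicates`,
#'   `fold_vs_fastest`.
#' @export
kinetics_summary <- function(timecourses, cap = 0.25) {
  need <- c("substrate", "replicate", "time_min", "fraction_product")
  if (!all(need %in% names(timecourses))) {
    stop("timecourses must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(timecourses, timecourses$substrate), function(d) {
    fits <- lapply(split(d, d$replicate), function(r) {
      r <- r[order(r$time_min), ]
      initial_velocity(r$time_min, r$fraction_product, cap = cap)
    })
    avg <- average_replicates(fits)
    data.frame(substrate = d$substrate[1L],
               mean_slope = avg$mean_slope,
               reported_error = avg$reported_error,
               replicate_sd = avg$replicate_sd,
               n_replicates = avg$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$fold_vs_fastest <- max(res$mean_slope) / res$mean_slope
  res
}

#' Read a timecourse CSV
#'
#' Expects columns `substrate,replicate,time_min,fraction_product`.
#'
#' @param path File path.
#' @return A data.frame suitable for [kinetics_summary()].
#' @export
read_timecourse_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("substrate", "replicate", "time_min", "fraction_product")
  if (!all(need %in% names(d))) {
    stop("timecourse CSV must have columns ", paste(need, collapse = ","),
         call. = FALSE)
  }
  d
}
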