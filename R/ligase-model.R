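## Parametric generative model of competitive cohesive-end ligation.
##
## The propensity of an ordered overhang pair (a, b) is
##
##   propensity(a, b) = w_a * w_b * exp(alpha * gc_pairs(a, b)) *
##                      prod over mismatched positions of tol(type, class)
##
## where w are per-overhang ligation weights, alpha is a log-scale annealing
## boost per correctly paired G:C position, and tol is a tolerance in [0, 1]
## keyed on the unordered mismatch base-pair type (G:T == T:G) and the
## position class (edge / middle). Watson-Crick positions contribute factor 1;
## a tolerance of 0 forbids the mismatch. The multiset of ligation events in
## a reaction is modelled as a multinomial over annealed pairs with these
## propensities; this is the minimal event-level model of the competitive
## annealing equilibrium that still has closed-form expectations for every
## statistic the package reports.

#' Construct a ligase model
#'
#' @param weights Per-overhang ligation propensities: either a single positive
#'   number (uniform), or a named numeric vector over (a subset of) the 256
#'   overhangs; unnamed overhangs default to 1. All weights must be > 0.
#' @param anneal_coeff Annealing coefficient alpha: log-scale boost per
#'   correctly paired G:C position (default 0 = no GC annealing bias).
#' @param tolerance Mismatch tolerances: a named list or named numeric vector
#'   keyed by unordered mismatch type ("G:T" and "T:G" are the same key).
#'   Each element is either a single number (applied to both position
#'   classes) or a numeric vector with names "edge"/"middle". Unlisted types
#'   default to 0 (mismatch forbidden), so the default model is
#'   Watson-Crick-only.
#' @param name Free-text model name used in printouts and manifests.
#' @return An object of class `ligase_model`.
#' @export
#' @examples
#' # Watson-Crick-only, GC-annealing-biased model:
#' m <- ligase_model(anneal_coeff = 0.5, name = "wc-gc")
#' # G:T-permissive at the edge only:
#' m2 <- ligase_model(tolerance = list("G:T" = c(edge = 0.3, middle = 0)))
ligase_model <- function(weights = 1, anneal_coeff = 0, tolerance = NULL,
                         name = "custom") {
  oh <- overhangs()
  w <- rep(1, length(oh))
  names(w) <- oh
  if (is.numeric(weights) && length(weights) == 1L && is.null(names(weights))) {
    if (!is.finite(weights) || weights <= 0) {
      stop("weights must be positive", call. = FALSE)
    }
    w[] <- weights
  } else {
    if (is.null(names(weights))) {
      stop("weights must be a single number or a named vector", call. = FALSE)
    }
    nm <- .validate_overhang(names(weights))
    if (anyDuplicated(nm)) stop("duplicate overhang in weights", call. = FALSE)
    if (any(!is.finite(weights)) || any(weights <= 0)) {
      stop("all weights must be positive and finite", call. = FALSE)
    }
    w[nm] <- as.numeric(weights)
  }
  if (!is.numeric(anneal_coeff) || length(anneal_coeff) != 1L ||
      !is.finite(anneal_coeff)) {
    stop("anneal_coeff must be a single finite number", call. = FALSE)
  }
  tol <- .parse_tolerance(tolerance)
  structure(
    list(weights = w, anneal_coeff = anneal_coeff, tolerance = tol,
         name = as.character(name)[1L]),
    class = "ligase_model"
  )
}

## Canonicalize a tolerance spec into an 8 x 2 matrix
## (MISMATCH_TYPES x edge/middle), default 0.
.parse_tolerance <- function(tolerance) {
  tol <- matrix(0, nrow = length(MISMATCH_TYPES), ncol = 2L,
                dimnames = list(MISMATCH_TYPES, POSITION_CLASSES))
  if (is.null(tolerance)) return(tol)
  if (is.numeric(tolerance)) tolerance <- as.list(tolerance)
  if (!is.list(tolerance) || is.null(names(tolerance))) {
    stop("tolerance must be a named list or named numeric vector",
         call. = FALSE)
  }
  for (key in names(tolerance)) {
    type <- .canonical_mismatch_type(key)
    val <- tolerance[[key]]
    if (!is.numeric(val) || any(!is.finite(val)) ||
        any(val < 0) || any(val > 1)) {
      stop("tolerance for ", key, " must be in [0, 1]", call. = FALSE)
    }
    if (is.null(names(val))) {
      if (length(val) != 1L) {
        stop("unnamed tolerance for ", key, " must be a single value",
             call. = FALSE)
      }
      tol[type, ] <- val
    } else {
      cls <- match.arg(names(val), POSITION_CLASSES, several.ok = TRUE)
      tol[type, cls] <- val
    }
  }
  tol
}

.canonical_mismatch_type <- function(key) {
  parts <- strsplit(toupper(key), ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !all(parts %in% OH_BASES)) {
    stop("invalid mismatch type '", key, "': use e.g. \"G:T\"", call. = FALSE)
  }
  type <- paste(sort(parts), collapse = ":")
  if (!type %in% MISMATCH_TYPES) {
    stop("'", key, "' is a complementary base pair, not a mismatch type",
         call. = FALSE)
  }
  type
}

#' @export
print.ligase_model <- function(x, ...) {
  cat("Ligase model:", x$name, "\n")
  wr <- range(x$weights)
  cat(sprintf("  weights: %s (range %.3g..%.3g)\n",
              if (wr[1] == wr[2]) "uniform" else "per-overhang",
              wr[1], wr[2]))
  cat(sprintf("  anneal_coeff (alpha): %.3g per matched G:C pair\n",
              x$anneal_coeff))
  nz <- which(x$tolerance > 0, arr.ind = TRUE)
  if (nrow(nz) == 0L) {
    cat("  mismatch tolerance: none (Watson-Crick-only)\n")
  } else {
    cat("  mismatch tolerances:\n")
    for (k in seq_len(nrow(nz))) {
      cat(sprintf("    %s @ %s: %.3g\n",
                  rownames(x$tolerance)[nz[k, 1]],
                  colnames(x$tolerance)[nz[k, 2]],
                  x$tolerance[nz[k, 1], nz[k, 2]]))
    }
  }
  invisible(x)
}

#' Illustrative ligase model presets
#'
#' Ready-made parameter sets spanning the qualitative regimes seen among
#' end-joining ligases: `"uniform"` (no bias, Watson-Crick-only),
#' `"strict-gc"` (strong GC annealing bias, very low mismatch tolerance,
#' qualitatively T7-like), `"moderate"` (mild GC bias, G:T-dominated mismatch
#' tolerance, qualitatively T4-like) and `"permissive"` (no GC bias, high
#' tolerance including purine:purine mismatches, qualitatively hLig3-like).
#' These presets are illustrative parameter regimes only; they are not fitted
#' to any measured ligase.
#'
#' @param name Preset name.
#' @return A `ligase_model`.
#' @export
ligase_model_preset <- function(name = c("uniform", "strict-gc", "moderate",
                                         "permissive")) {
  name <- match.arg(name)
  switch(name,
    "uniform" = ligase_model(name = "uniform"),
    "strict-gc" = ligase_model(
      anneal_coeff = 1.0,
      tolerance = list("G:T" = c(edge = 0.04, middle = 0.01)),
      name = "strict-gc"
    ),
    "moderate" = ligase_model(
      anneal_coeff = 0.35,
      tolerance = list(
        "G:T" = c(edge = 0.25, middle = 0.06),
        "A:C" = c(edge = 0.05, middle = 0.01),
        "C:T" = c(edge = 0.04, middle = 0.01),
        "T:T" = c(edge = 0.05, middle = 0.01),
        "G:G" = c(edge = 0.12, middle = 0.02),
        "C:C" = c(edge = 0.08, middle = 0.02)
      ),
      name = "moderate"
    ),
    "permissive" = ligase_model(
      anneal_coeff = 0.05,
      tolerance = list(
        "G:T" = c(edge = 0.45, middle = 0.15),
        "G:A" = c(edge = 0.35, middle = 0.12),
        "G:G" = c(edge = 0.35, middle = 0.12),
        "C:C" = c(edge = 0.25, middle = 0.08),
        "A:A" = c(edge = 0.10, middle = 0.03),
        "C:T" = c(edge = 0.12, middle = 0.04),
        "A:C" = c(edge = 0.10, middle = 0.03),
        "T:T" = c(edge = 0.10, middle = 0.03)
      ),
      name = "permissive"
    )
  )
}

## Full 256x256 propensity matrix for a model.
.propensity_matrix <- function(model) {
  stopifnot(inherits(model, "ligase_model"))
  tb <- .pair_tables()
  P <- outer(model$weights, model$weights) *
    exp(model$anneal_coeff * tb$gc_pairs)
  for (i in seq_len(4L)) {
    cls <- .position_class(i)
    idx <- which(!tb$match[[i]])
    P[idx] <- P[idx] * model$tolerance[cbind(tb$type[[i]][idx], cls)]
  }
  dimnames(P) <- list(overhangs(), overhangs())
  P
}

#' Ligation propensity of an overhang pair under a model
#'
#' Closed-form pair propensity: `w_top * w_bottom * exp(alpha * gc_pairs) *`
#' product of mismatch tolerances, where `gc_pairs` counts correctly paired
#' G:C positions. Zero iff any mismatched position has tolerance 0. Symmetric
#' in top and bottom.
#'
#' @param model A `ligase_model`.
#' @param top,bottom Character vectors of four-base overhangs (recycled).
#' @return Numeric vector of nonnegative propensities.
#' @export
#' @examples
#' m <- ligase_model(tolerance = list("G:T" = c(edge = 0.2)))
#' pair_propensity(m, "TGGA", "TCCG")  # single edge T:G mismatch -> 0.2
pair_propensity <- function(model, top, bottom) {
  P <- .propensity_matrix(model)
  i <- .oh_index(top)
  j <- .oh_index(bottom)
  n <- max(length(i), length(j))
  unname(P[cbind(rep_len(i, n), rep_len(j, n))])
}

#' Exact expected pair distribution under a ligase model
#'
#' Normalizes the 256x256 propensity matrix to a probability distribution
#' over all 65,536 ordered overhang pairs. The result is symmetric and can be
#' passed to every profiling function in place of a count matrix, yielding
#' the model's closed-form expected statistics (expected overall fidelity,
#' per-overhang fidelity, normalized frequency, mismatch spectra, ...).
#'
#' @param model A `ligase_model`.
#' @return A 256x256 numeric matrix of class `pair_expectation` summing to 1.
#' @export
#' @examples
#' E <- expected_profile(ligase_model())
#' overall_fidelity(E)  # 1: Watson-Crick-only model
expected_profile <- function(model) {
  P <- .propensity_matrix(model)
  s <- sum(P)
  if (s <= 0) {
    stop("model assigns zero propensity to every pair", call. = FALSE)
  }
  structure(P / s, class = "pair_expectation", model = model$name)
}
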