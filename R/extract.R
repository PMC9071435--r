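## Extraction: turn product strand reads into a validated dual-orientation
## pair-count matrix.
##
## Anchors are located by exact substring match (consensus reads are high
## accuracy; a read whose anchors do not match exactly is unusable). An
## optional fuzzy mode allows at most one substitution per anchor. Failures
## are returned and tallied by reason, never silently dropped.

EXTRACT_FAILURE_REASONS <- c("anchor-missing", "wrong-gap-length", "non-ACGT")

## Extract (overhang, control) from one set of strand sequences.
## Returns data.frame(overhang, control, reason) with NA overhang on failure.
.extract_strand <- function(seqs, spec, fuzzy = FALSE) {
  left <- spec$left_const
  ranchor <- .right_anchor(spec)
  n <- length(seqs)
  overhang <- rep(NA_character_, n)
  control <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  lpos <- as.integer(regexpr(left, seqs, fixed = TRUE))
  lend <- lpos + nchar(left)
  rest <- ifelse(lpos > 0L, substr(seqs, lend, nchar(seqs)), "")
  rpos <- as.integer(regexpr(ranchor, rest, fixed = TRUE))

  if (fuzzy) {
    redo <- which(lpos < 0L | rpos < 0L)
    for (k in redo) {
      lp <- .fuzzy_find(seqs[k], left)
      if (is.na(lp)) next
      rem <- substr(seqs[k], lp + nchar(left), nchar(seqs[k]))
      rp <- .fuzzy_find(rem, ranchor)
      if (is.na(rp)) next
      lpos[k] <- lp
      rest[k] <- rem
      rpos[k] <- rp
    }
  }

  miss <- lpos < 0L | rpos < 0L
  reason[miss] <- "anchor-missing"
  gap <- rpos - 1L
  badgap <- !miss & gap != 4L
  reason[badgap] <- "wrong-gap-length"
  ok <- !miss & !badgap
  oh <- toupper(substr(rest, 1L, 4L))
  bad_oh <- ok & grepl("[^ACGT]", oh)
  reason[bad_oh] <- "non-ACGT"
  ok <- ok & !bad_oh
  overhang[ok] <- oh[ok]

  cstart <- 4L + nchar(ranchor) + 1L
  ctrl <- toupper(substr(rest, cstart, cstart + spec$control_len - 1L))
  good_ctrl <- ok & nchar(ctrl) == spec$control_len & !grepl("[^ACGT]", ctrl)
  control[good_ctrl] <- ctrl[good_ctrl]

  data.frame(overhang = overhang, control = control, reason = reason,
             stringsAsFactors = FALSE)
}

## First offset (1-based) at which `pattern` matches `seq` with <= 1
## substitution; exact matches preferred. NA if none.
.fuzzy_find <- function(seq, pattern) {
  s <- utf8ToInt(seq)
  p <- utf8ToInt(pattern)
  L <- length(p)
  nmax <- length(s) - L + 1L
  if (nmax < 1L) return(NA_integer_)
  best <- NA_integer_
  best_mm <- 2L
  for (i in seq_len(nmax)) {
    mm <- sum(s[i:(i + L - 1L)] != p)
    if (mm < best_mm) {
      best <- i
      best_mm <- mm
      if (mm == 0L) break
    }
  }
  if (is.na(best) || best_mm > 1L) NA_integer_ else best
}

#' Parse ligation-product strand reads into overhang-pair observations
#'
#' Locates the constant anchors in each strand by exact match (optionally
#' allowing one substitution per anchor with `fuzzy = TRUE`); the four bases
#' between the anchors are the overhang, and the randomized control region is
#' extracted at its fixed offset when intact. A product fails with reason
#' `anchor-missing`, `wrong-gap-length`, or `non-ACGT` if either strand
#' cannot be parsed; failures are counted and reported, never dropped
#' silently.
#'
#' @param top,bottom Character vectors of product strand sequences (same
#'   length; strands of the same product share an index), or a data.frame
#'   from [emit_reads()] / [read_products_fasta()] passed as `top`.
#' @param spec A [substrate_spec()].
#' @param fuzzy Allow at most one substitution per anchor (off by default).
#' @return A list with `observations` (data.frame: `top`, `bottom`,
#'   `control_top`, `control_bottom`), `failures` (named integer tally by
#'   reason), and `n_input`.
#' @export
parse_products <- function(top, bottom = NULL, spec = substrate_spec(),
                           fuzzy = FALSE) {
  if (is.data.frame(top)) {
    stopifnot(all(c("top", "bottom") %in% names(top)))
    bottom <- top$bottom
    top <- top$top
  }
  stopifnot(length(top) == length(bottom))
  et <- .extract_strand(top, spec, fuzzy = fuzzy)
  eb <- .extract_strand(bottom, spec, fuzzy = fuzzy)
  reason <- ifelse(!is.na(et$reason), et$reason, eb$reason)
  ok <- is.na(reason)
  failures <- table(factor(reason[!ok], levels = EXTRACT_FAILURE_REASONS))
  obs <- data.frame(top = et$overhang[ok], bottom = eb$overhang[ok],
                    control_top = et$control[ok],
                    control_bottom = eb$control[ok],
                    stringsAsFactors = FALSE)
  structure(list(observations = obs,
                 failures = unclass(failures),
                 n_input = length(top)),
            class = "product_parse")
}

#' @export
print.product_parse <- function(x, ...) {
  cat(sprintf("Parsed %d products: %d extracted, %d failed\n",
              x$n_input, nrow(x$observations), sum(x$failures)))
  if (sum(x$failures) > 0) {
    for (r in names(x$failures)) {
      if (x$failures[[r]] > 0) cat(sprintf("  %s: %d\n", r, x$failures[[r]]))
    }
  }
  invisible(x)
}

#' Tabulate overhang-pair observations in both orientations
#'
#' Because strand designation is arbitrary, each observation (top, bottom)
#' increments both counts[top, bottom] and counts[bottom, top]; a palindromic
#' self-ligation therefore adds 2 to its diagonal cell. The resulting matrix
#' is symmetric with total ordered count 2 x number of observations. Control
#' regions, when present, are tallied per position into a base-composition
#' matrix stored as the `control_tally` attribute (used by
#' [synthesis_bias_correction()]).
#'
#' @param observations A data.frame with columns `top` and `bottom` (and
#'   optionally `control_top`, `control_bottom`), or a `product_parse` object.
#' @param ... Metadata passed to [pair_counts()].
#' @return A `pair_counts` matrix.
#' @export
tabulate_pairs <- function(observations, ...) {
  failures <- NULL
  if (inherits(observations, "product_parse")) {
    failures <- observations$failures
    observations <- observations$observations
  }
  oh <- overhangs()
  m <- matrix(0L, 256L, 256L, dimnames = list(oh, oh))
  ctrl <- NULL
  if (nrow(observations) > 0L) {
    i <- .oh_index(observations$top)
    j <- .oh_index(observations$bottom)
    t1 <- table(factor(i, levels = 1:256), factor(j, levels = 1:256))
    m <- m + unclass(t1) + t(unclass(t1))
    storage.mode(m) <- "integer"
    dimnames(m) <- list(oh, oh)
    ctrls <- c(observations$control_top, observations$control_bottom)
    ctrls <- ctrls[!is.na(ctrls)]
    if (length(ctrls)) ctrl <- .tally_controls(ctrls)
  }
  out <- pair_counts(m, ...)
  attr(out, "control_tally") <- ctrl
  attr(out, "failures") <- failures
  out
}

## Base x position tally of control k-mers.
.tally_controls <- function(ctrls) {
  k <- nchar(ctrls[1L])
  m <- matrix(unlist(strsplit(ctrls, "", fixed = TRUE), use.names = FALSE),
              nrow = length(ctrls), ncol = k, byrow = TRUE)
  tally <- vapply(seq_len(k), function(i) {
    tabulate(match(m[, i], OH_BASES), nbins = 4L)
  }, integer(4L))
  dimnames(tally) <- list(OH_BASES, paste0("pos", seq_len(k)))
  tally
}

#' Extract a pair-count matrix from product reads in one step
#'
#' Convenience wrapper: [parse_products()] then [tabulate_pairs()].
#'
#' @inheritParams parse_products
#' @param ... Metadata passed to [pair_counts()].
#' @return A `pair_counts` matrix (with `control_tally` and `failures`
#'   attributes).
#' @export
extract_counts <- function(top, bottom = NULL, spec = substrate_spec(),
                           fuzzy = FALSE, ...) {
  tabulate_pairs(parse_products(top, bottom, spec = spec, fuzzy = fuzzy), ...)
}
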