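## Synthetic-data generator: sample ligation events from a ligase model and
## emit product strand reads with the documented substrate layout.
##
## Each emitted product consists of a top and a bottom strand (each written
## 5'->3' on its own strand). A strand is: left constant anchor | overhang |
## right constant region, where a window of the right constant region is a
## randomized control (default 6 bases) that mimics the substrate's internal
## randomized region used to control for oligonucleotide synthesis bias.

## Fixed default anchors (package constants; structural emulation of the
## assay substrate, not its literal sequence).
DEFAULT_LEFT_CONST <- "GCTGAGGAGTCCGTAGTCGT"
DEFAULT_RIGHT_CONST <- "CATCGGTACCTCAGCTGGAA"

#' Substrate layout specification
#'
#' Describes where the overhang and the randomized synthesis-bias control sit
#' inside an emitted product strand: `left_const | overhang |`
#' `right_const[1..control_offset-1] | control | right_const tail`. The right
#' anchor used for extraction is the part of `right_const` before the control
#' window.
#'
#' @param left_const Constant anchor 5' of the overhang on each strand.
#' @param right_const Constant region 3' of the overhang; the control window
#'   replaces `control_len` of its bases starting at `control_offset`.
#' @param control_len Length of the randomized control region (default 6).
#' @param control_offset 1-based position of the control window within
#'   `right_const` (default 9, leaving an 8-base exact-match right anchor).
#' @return An object of class `substrate_spec`.
#' @export
substrate_spec <- function(left_const = DEFAULT_LEFT_CONST,
                           right_const = DEFAULT_RIGHT_CONST,
                           control_len = 6L, control_offset = 9L) {
  left_const <- .validate_dna(left_const, what = "left_const")
  right_const <- .validate_dna(right_const, what = "right_const")
  stopifnot(length(left_const) == 1L, length(right_const) == 1L)
  control_len <- as.integer(control_len)
  control_offset <- as.integer(control_offset)
  if (nchar(left_const) < 1L || nchar(right_const) < 1L) {
    stop("anchors must be nonempty", call. = FALSE)
  }
  if (grepl(left_const, right_const, fixed = TRUE) ||
      grepl(right_const, left_const, fixed = TRUE)) {
    stop("neither anchor may contain the other as a substring", call. = FALSE)
  }
  if (control_len < 1L) stop("control_len must be >= 1", call. = FALSE)
  if (control_offset < 2L ||
      control_offset + control_len - 1L > nchar(right_const)) {
    stop("control window must lie inside right_const and leave a nonempty ",
         "right anchor (control_offset >= 2)", call. = FALSE)
  }
  structure(
    list(left_const = left_const, right_const = right_const,
         control_len = control_len, control_offset = control_offset),
    class = "substrate_spec"
  )
}

## Exact-match right anchor: the constant prefix before the control window.
.right_anchor <- function(spec) {
  substr(spec$right_const, 1L, spec$control_offset - 1L)
}

.right_tail <- function(spec) {
  substr(spec$right_const, spec$control_offset + spec$control_len,
         nchar(spec$right_const))
}

#' @export
print.substrate_spec <- function(x, ...) {
  cat("Substrate layout: left_const | NNNN | right anchor | control |",
      "tail\n")
  cat("  left_const:  ", x$left_const, "\n")
  cat("  right anchor:", .right_anchor(x), "\n")
  cat(sprintf("  control: %d bases at offset %d of right_const\n",
              x$control_len, x$control_offset))
  invisible(x)
}

#' Sample ligation events from a ligase model
#'
#' Draws `n_events` unordered ligation events from the model's expected pair
#' distribution (a multinomial over annealed overhang pairs) and stores them
#' canonically as a dual-orientation `pair_counts` matrix: each event (a, b)
#' increments counts[a, b] and counts[b, a], and a palindromic self-event
#' adds 2 to its diagonal cell, so the total ordered count is exactly
#' `2 * n_events`.
#'
#' @param model A `ligase_model`.
#' @param n_events Number of ligation events (> 0).
#' @param seed Optional integer seed for reproducible draws.
#' @return A `pair_counts` matrix with `ligase` metadata set to the model
#'   name.
#' @export
#' @examples
#' m <- ligase_model_preset("moderate")
#' counts <- sample_events(m, 1e4, seed = 1)
#' sum(counts)  # 2e4 ordered counts
sample_events <- function(model, n_events, seed = NULL) {
  stopifnot(inherits(model, "ligase_model"))
  if (!is.numeric(n_events) || length(n_events) != 1L || n_events < 1 ||
      n_events != floor(n_events)) {
    stop("n_events must be a positive integer", call. = FALSE)
  }
  E <- unclass(expected_profile(model))
  if (!is.null(seed)) set.seed(seed)
  ut <- which(upper.tri(E, diag = TRUE))
  ij <- arrayInd(ut, dim(E))
  p <- E[ut] * ifelse(ij[, 1L] == ij[, 2L], 1, 2)  # fold ordered -> unordered
  x <- stats::rmultinom(1L, size = n_events, prob = p)[, 1L]
  C <- matrix(0L, 256L, 256L)
  C[ut] <- x
  C <- C + t(C)  # mirrors off-diagonal cells and doubles the diagonal
  pair_counts(C, ligase = model$name, condition = "simulated")
}

#' Synthesis-bias weight vector
#'
#' Per-overhang substrate abundance under independent per-position base
#' composition: weight(o) = prod over positions of `base_freqs[base]`,
#' rescaled to mean 1. Multiply a model's weights by this vector to simulate
#' oligonucleotide synthesis bias in the substrate pool; pair it with the
#' same `control_base_freqs` in [emit_reads()] so the control region carries
#' the matching signal for [synthesis_bias_correction()].
#'
#' @param base_freqs Named numeric vector over A, C, G, T (normalized
#'   internally).
#' @return Named numeric vector over the 256 overhangs, mean 1.
#' @export
synthesis_weights <- function(base_freqs) {
  f <- .normalize_base_freqs(base_freqs)
  oh <- overhangs()
  bm <- do.call(rbind, strsplit(oh, "", fixed = TRUE))
  w <- apply(bm, 1L, function(b) prod(f[b]))
  names(w) <- oh
  w / mean(w)
}

.normalize_base_freqs <- function(base_freqs) {
  if (is.null(base_freqs)) base_freqs <- c(A = 1, C = 1, G = 1, T = 1)
  if (is.null(names(base_freqs)) || !all(OH_BASES %in% names(base_freqs)) ||
      any(base_freqs < 0) || sum(base_freqs) <= 0) {
    stop("base_freqs must be a nonnegative named vector over A, C, G, T",
         call. = FALSE)
  }
  f <- base_freqs[OH_BASES]
  f / sum(f)
}

#' Emit product strand reads for sampled ligation events
#'
#' Writes one record per ligation event: a top strand embedding the top
#' overhang and a bottom strand embedding the bottom overhang, each between
#' the constant anchors of `spec` and each with an independently sampled
#' random control region (default: uniform base composition). Uniform
#' substitution errors are applied per base at `error_rate`. With
#' `error_rate = 0`, extracting the emitted reads reproduces the input
#' count matrix exactly.
#'
#' @param events A `pair_counts` matrix of sampled events (dual-orientation).
#' @param spec A [substrate_spec()].
#' @param error_rate Per-base substitution probability in [0, 1).
#' @param seed Optional integer seed.
#' @param control_base_freqs Optional base composition for the control region
#'   (and nothing else); use with [synthesis_weights()] to emulate synthesis
#'   bias.
#' @return A data.frame with columns `event`, `top`, `bottom` (one row per
#'   ligation product; strands written 5'->3').
#' @export
emit_reads <- function(events, spec = substrate_spec(), error_rate = 0,
                       seed = NULL, control_base_freqs = NULL) {
  stopifnot(inherits(spec, "substrate_spec"))
  if (!is.numeric(error_rate) || length(error_rate) != 1L ||
      error_rate < 0 || error_rate >= 1) {
    stop("error_rate must be in [0, 1)", call. = FALSE)
  }
  M <- .as_pair_matrix(events)
  if (!isTRUE(all.equal(M, t(M), check.attributes = FALSE))) {
    stop("events matrix must be symmetric (dual-orientation counts)",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  ut <- which(upper.tri(M, diag = TRUE))
  ij <- arrayInd(ut, dim(M))
  n_ev <- M[ut]
  diag_cell <- ij[, 1L] == ij[, 2L]
  if (any(n_ev[diag_cell] %% 2 != 0)) {
    stop("diagonal cells must be even (palindromic events count twice)",
         call. = FALSE)
  }
  n_ev[diag_cell] <- n_ev[diag_cell] / 2
  keep <- n_ev > 0
  ij <- ij[keep, , drop = FALSE]
  n_ev <- n_ev[keep]
  oh <- overhangs()
  tops <- rep(oh[ij[, 1L]], n_ev)
  bottoms <- rep(oh[ij[, 2L]], n_ev)
  n <- length(tops)
  f <- .normalize_base_freqs(control_base_freqs)

  build <- function(ohs) {
    ctrl <- .random_kmers(n, spec$control_len, f)
    paste0(spec$left_const, ohs, .right_anchor(spec), ctrl, .right_tail(spec))
  }
  top_seq <- build(tops)
  bottom_seq <- build(bottoms)
  if (error_rate > 0) {
    top_seq <- .substitution_errors(top_seq, error_rate)
    bottom_seq <- .substitution_errors(bottom_seq, error_rate)
  }
  data.frame(event = seq_len(n), top = top_seq, bottom = bottom_seq,
             stringsAsFactors = FALSE)
}

.random_kmers <- function(n, k, base_freqs) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(OH_BASES, n * k, replace = TRUE, prob = base_freqs),
              nrow = n, ncol = k)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

## Uniform per-base substitutions: each base is replaced, with probability
## `rate`, by one of the three other bases chosen uniformly.
.substitution_errors <- function(seqs, rate) {
  if (length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1L])
  stopifnot(all(nchar(seqs) == L))
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  hit <- which(stats::runif(length(m)) < rate)
  if (length(hit)) {
    shift <- sample(3L, length(hit), replace = TRUE)
    old <- match(m[hit], OH_BASES)
    m[hit] <- OH_BASES[((old - 1L + shift) %% 4L) + 1L]
  }
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Write / read product strand reads as FASTA
#'
#' Two records per ligation product, with ids `<event>#top` and
#' `<event>#bottom`. `read_products_fasta()` re-pairs records by id suffix
#' and also accepts FASTQ (`format = "fastq"`).
#'
#' @param products A data.frame from [emit_reads()].
#' @param path File path.
#' @param format `"fasta"` (default) or `"fastq"` for reading.
#' @return `read_products_fasta()`: a data.frame with columns `event`, `top`,
#'   `bottom`.
#' @export
write_products_fasta <- function(products, path) {
  stopifnot(all(c("event", "top", "bottom") %in% names(products)))
  n <- nrow(products)
  seqs <- character(2L * n)
  ids <- character(2L * n)
  seqs[seq(1L, by = 2L, length.out = n)] <- products$top
  seqs[seq(2L, by = 2L, length.out = n)] <- products$bottom
  ids[seq(1L, by = 2L, length.out = n)] <- paste0(products$event, "#top")
  ids[seq(2L, by = 2L, length.out = n)] <- paste0(products$event, "#bottom")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_products_fasta
#' @export
read_products_fasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  ids <- names(x)
  seqs <- as.character(x)
  is_top <- grepl("#top$", ids)
  is_bottom <- grepl("#bottom$", ids)
  if (!all(is_top | is_bottom)) {
    stop("every record id must end in #top or #bottom", call. = FALSE)
  }
  ev_top <- sub("#top$", "", ids[is_top])
  ev_bottom <- sub("#bottom$", "", ids[is_bottom])
  common <- intersect(ev_top, ev_bottom)
  if (length(common) < sum(is_top) || length(common) < sum(is_bottom)) {
    warning("unpaired records dropped", call. = FALSE)
  }
  data.frame(event = common,
             top = seqs[is_top][match(common, ev_top)],
             bottom = seqs[is_bottom][match(common, ev_bottom)],
             stringsAsFactors = FALSE)
}

#' Simulate a pair-count matrix from a ligase model
#'
#' Method for [stats::simulate()]: draws `nsim` independent event samples of
#' `n_events` each and returns a list of `pair_counts` matrices.
#'
#' @param object A `ligase_model`.
#' @param nsim Number of independent samples.
#' @param seed Optional integer seed (consecutive seeds are used per sample).
#' @param n_events Events per sample.
#' @param ... Unused.
#' @return A list of `pair_counts` matrices (length `nsim`).
#' @export
simulate.ligase_model <- function(object, nsim = 1, seed = NULL,
                                  n_events = 1e5, ...) {
  lapply(seq_len(nsim), function(k) {
    s <- if (is.null(seed)) NULL else seed + k - 1L
    sample_events(object, n_events, seed = s)
  })
}
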