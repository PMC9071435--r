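## Sequence algebra for four-base 5' overhangs.
##
## All sequences are written 5'->3' on their own strand. In an annealed pair
## of overhangs (top, bottom), top position i opposes bottom position 5-i,
## so the Watson-Crick partner of an overhang is its reverse complement.
## Positions are 1-based within the overhang (N1..N4); positions 1 and 4 are
## the "edge" of the junction, positions 2 and 3 the "middle".

OH_BASES <- c("A", "C", "G", "T")
OH_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
OH_EDGE_POSITIONS <- c(1L, 4L)

## The 8 non-complementary unordered base-pair types (mismatch types).
MISMATCH_TYPES <- c("A:A", "A:C", "A:G", "C:C", "C:T", "G:G", "G:T", "T:T")
POSITION_CLASSES <- c("edge", "middle")

#' All four-base overhangs
#'
#' @return Character vector of the 256 possible four-base 5' overhangs over
#'   \{A,C,G,T\}, in alphabetical order. This ordering indexes every
#'   pair-count matrix in the package.
#' @export
#' @examples
#' length(overhangs())
#' head(overhangs())
overhangs <- function() {
  if (is.null(.ligfid_cache$overhangs)) {
    g <- expand.grid(OH_BASES, OH_BASES, OH_BASES, OH_BASES,
                     stringsAsFactors = FALSE)
    .ligfid_cache$overhangs <- sort(do.call(paste0, g))
  }
  .ligfid_cache$overhangs
}

## Normalize and validate DNA strings of a fixed length (NA allowed length).
## Lowercase is accepted with a warning; anything outside ACGT is an error.
.validate_dna <- function(x, len = NA_integer_, what = "sequence") {
  if (!is.character(x) || length(x) == 0L || anyNA(x)) {
    stop("invalid ", what, ": must be a non-missing character vector",
         call. = FALSE)
  }
  if (any(grepl("[acgt]", x))) {
    warning("lowercase bases in ", what, " normalized to uppercase",
            call. = FALSE)
    x <- toupper(x)
  }
  if (!is.na(len) && any(nchar(x) != len)) {
    bad <- x[nchar(x) != len][1L]
    stop("invalid ", what, " '", bad, "': length must be ", len,
         call. = FALSE)
  }
  if (any(grepl("[^ACGT]", x))) {
    bad <- x[grepl("[^ACGT]", x)][1L]
    stop("invalid ", what, " '", bad,
         "': only A, C, G, T are allowed (no U or IUPAC ambiguity codes)",
         call. = FALSE)
  }
  x
}

.validate_overhang <- function(x) .validate_dna(x, 4L, "overhang")

.oh_index <- function(x) match(.validate_overhang(x), overhangs())

#' Reverse complement of a DNA sequence
#'
#' The Watson-Crick partner of a 5' overhang: the strand, read 5'->3', that
#' pairs it at every position. Applying it twice returns the input.
#'
#' @param x Character vector of DNA sequences (ACGT only; lowercase is
#'   normalized with a warning).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AGCG")  # "CGCT"
#' revcomp(c("GTGA", "AAAA"))
revcomp <- function(x) {
  x <- .validate_dna(x, what = "sequence")
  comp <- chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Is an overhang palindromic?
#'
#' A palindromic overhang equals its own reverse complement and therefore
#' ligates correctly to itself (e.g. ACGT). Exactly 16 of the 256 four-base
#' overhangs are palindromic.
#'
#' @param x Character vector of four-base overhangs.
#' @return Logical vector.
#' @export
is_palindromic <- function(x) {
  x <- .validate_overhang(x)
  x == revcomp(x)
}

#' Watson-Crick test for an annealed overhang pair
#'
#' A pair (top, bottom), each read 5'->3' on its own strand, is Watson-Crick
#' iff bottom equals the reverse complement of top (equivalently, every
#' junction position forms a complementary base pair). The test is symmetric
#' in top and bottom.
#'
#' @param top,bottom Character vectors of four-base overhangs (recycled to a
#'   common length).
#' @return Logical vector.
#' @export
#' @examples
#' is_watson_crick("CTAT", "ATAG")  # TRUE
#' is_watson_crick("AAAA", "AAAA")  # FALSE: the partner of AAAA is TTTT
is_watson_crick <- function(top, bottom) {
  top <- .validate_overhang(top)
  bottom <- .validate_overhang(bottom)
  revcomp(top) == bottom
}

#' Enumerate mismatched base pairs at a ligation junction
#'
#' For an annealed pair (top, bottom), lists every junction position where
#' the opposing bases are not complementary. Top position i opposes bottom
#' position 5-i; records are labeled by the top-strand position, its class
#' (edge: positions 1 and 4; middle: positions 2 and 3), and the base pair
#' written top_base:bottom_base.
#'
#' @param top,bottom Single four-base overhangs.
#' @return A data.frame with columns `position` (1..4 on the top strand),
#'   `position_class` ("edge"/"middle"), `top_base`, `bottom_base`. Zero rows
#'   iff the pair is Watson-Crick.
#' @export
#' @examples
#' overhang_mismatches("TGGA", "TCCG")  # one edge T:G mismatch at position 1
#' overhang_mismatches("CTAT", "ATAG")  # Watson-Crick: no rows
overhang_mismatches <- function(top, bottom) {
  top <- .validate_overhang(top)
  bottom <- .validate_overhang(bottom)
  stopifnot(length(top) == 1L, length(bottom) == 1L)
  tb <- strsplit(top, "", fixed = TRUE)[[1L]]
  bb <- strsplit(bottom, "", fixed = TRUE)[[1L]]
  opp <- bb[5L - seq_len(4L)]
  mism <- unname(OH_COMPLEMENT[tb]) != opp
  pos <- which(mism)
  data.frame(
    position = pos,
    position_class = ifelse(pos %in% OH_EDGE_POSITIONS, "edge", "middle"),
    top_base = tb[pos],
    bottom_base = opp[pos],
    stringsAsFactors = FALSE
  )
}

#' GC content of an overhang
#'
#' @param x Character vector of four-base overhangs.
#' @return `gc_count`: integer number of G or C bases (0..4).
#'   `gc_percent`: the same expressed as a percentage (0, 25, 50, 75, 100).
#' @export
#' @examples
#' gc_count("CGGC")    # 4
#' gc_percent("GTGA")  # 50
gc_count <- function(x) {
  x <- .validate_overhang(x)
  vapply(strsplit(x, "", fixed = TRUE),
         function(ch) sum(ch %in% c("G", "C")),
         integer(1))
}

#' @rdname gc_count
#' @export
gc_percent <- function(x) 25L * gc_count(x)

#' Match overhangs against a pattern with N wildcards
#'
#' Positionwise equality against a 4-character pattern over \{A,C,G,T,N\},
#' with N matching any base. Used for pattern families such as TNNA or CNNG.
#'
#' @param x Character vector of four-base overhangs.
#' @param pattern A single 4-character pattern.
#' @return Logical vector.
#' @export
#' @examples
#' matches_pattern("TGGA", "TNNA")  # TRUE
#' matches_pattern("AGGT", "TNNA")  # FALSE
matches_pattern <- function(x, pattern) {
  x <- .validate_overhang(x)
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("pattern must be a single 4-character string", call. = FALSE)
  }
  pattern <- toupper(pattern)
  if (nchar(pattern) != 4L || grepl("[^ACGTN]", pattern)) {
    stop("invalid pattern '", pattern,
         "': must be 4 characters over A, C, G, T, N", call. = FALSE)
  }
  re <- paste0("^", gsub("N", "[ACGT]", pattern), "$")
  grepl(re, x)
}
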