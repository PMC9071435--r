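# Independent oracles used across the suite. These deliberately take a
# different route than the package: Watson-Crick partners come from
# Biostrings::reverseComplement, and pair geometry is derived by comparing
# the bottom strand against that partner (bottom position k <-> top position
# 5-k), rather than by per-position complement tables.

oracle_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Mismatch records for one ordered pair, by brute-force comparison of the
# bottom strand with the top strand's Watson-Crick partner.
oracle_mismatches <- function(top, bottom) {
  rc <- oracle_revcomp(top)
  bb <- strsplit(bottom, "")[[1]]
  rr <- strsplit(rc, "")[[1]]
  k <- which(bb != rr)           # bottom positions differing from the partner
  pos <- 5L - k                  # corresponding top positions
  o <- order(pos)
  data.frame(
    position = pos[o],
    position_class = ifelse(pos[o] %in% c(1L, 4L), "edge", "middle"),
    top_base = vapply(pos[o], function(i) substr(top, i, i), character(1)),
    bottom_base = bb[k][o],
    stringsAsFactors = FALSE
  )
}

# Vectorized mismatch-count matrix over all 65,536 ordered pairs (rows = top).
oracle_mm_count_matrix <- function() {
  oh <- overhangs()
  rc <- oracle_revcomp(oh)
  cnt <- matrix(0L, 256L, 256L)
  for (k in 1:4) {
    bk <- substr(oh, k, k)       # bottom base at position k (per column)
    rk <- substr(rc, k, k)       # partner base at position k (per row)
    cnt <- cnt + outer(rk, bk, "!=")
  }
  dimnames(cnt) <- list(oh, oh)
  cnt
}

# Independent propensity matrix for a ligase model, built from the partner
# comparison above instead of the package's pair tables.
oracle_propensity_matrix <- function(model) {
  oh <- overhangs()
  rc <- oracle_revcomp(oh)
  top <- rep(oh, times = 256L)      # varies within a column (row index)
  bottom <- rep(oh, each = 256L)
  rc_top <- rep(rc, times = 256L)
  p <- unname(model$weights[top] * model$weights[bottom])
  gcp <- integer(length(top))
  tolp <- rep(1, length(top))
  for (k in 1:4) {
    bb <- substr(bottom, k, k)
    rr <- substr(rc_top, k, k)
    matched <- bb == rr
    pos <- 5L - k
    cls <- if (pos %in% c(1L, 4L)) "edge" else "middle"
    tb <- substr(top, pos, pos)
    gcp <- gcp + (matched & tb %in% c("G", "C"))
    mm <- which(!matched)
    if (length(mm)) {
      type <- paste(pmin(tb[mm], bb[mm]), pmax(tb[mm], bb[mm]), sep = ":")
      tolp[mm] <- tolp[mm] * model$tolerance[cbind(type, cls)]
    }
  }
  P <- matrix(p * exp(model$anneal_coeff * gcp) * tolp, 256L, 256L,
              dimnames = list(oh, oh))
  P
}

# Build a dual-orientation count matrix from a list of (top, bottom, count)
# products, applying the both-orientations convention directly.
counts_from_products <- function(...) {
  prods <- list(...)
  oh <- overhangs()
  m <- matrix(0L, 256L, 256L, dimnames = list(oh, oh))
  for (p in prods) {
    i <- match(p[[1]], oh)
    j <- match(p[[2]], oh)
    n <- if (length(p) >= 3) as.integer(p[[3]]) else 1L
    m[i, j] <- m[i, j] + n
    m[j, i] <- m[j, i] + n
  }
  pair_counts(m)
}

# Uniform tolerance spec over all 8 mismatch types.
uniform_tolerance <- function(value) {
  stats::setNames(as.list(rep(value, 8)),
                  c("A:A", "A:C", "A:G", "C:C", "C:T", "G:G", "G:T", "T:T"))
}
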