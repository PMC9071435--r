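## Precomputed 256x256 lookup tables over all ordered overhang pairs.
##
## Row index = top overhang, column index = bottom overhang (alphabetical
## order, see overhangs()). Built lazily once per session; every table is
## symmetric in the sense induced by swapping strands (position i <-> 5-i).

.ligfid_cache <- new.env(parent = emptyenv())

.pair_tables <- function() {
  if (!is.null(.ligfid_cache$tables)) return(.ligfid_cache$tables)
  oh <- overhangs()
  n <- length(oh)
  bm <- do.call(rbind, strsplit(oh, "", fixed = TRUE))  # 256 x 4 base matrix

  match_pos <- vector("list", 4L)   # logical: complementary at position i
  label_pos <- vector("list", 4L)   # "top:bottom" where mismatched, else NA
  type_pos <- vector("list", 4L)    # unordered mismatch type, else NA
  mm_count <- matrix(0L, n, n)
  gc_pairs <- matrix(0L, n, n)      # correctly paired G:C positions

  for (i in seq_len(4L)) {
    top <- matrix(bm[, i], n, n)
    bot <- matrix(bm[, 5L - i], n, n, byrow = TRUE)
    m <- matrix(unname(OH_COMPLEMENT[top]) == bot, n, n)
    lab <- matrix(NA_character_, n, n)
    lab[!m] <- paste(top[!m], bot[!m], sep = ":")
    ty <- matrix(NA_character_, n, n)
    ty[!m] <- paste(pmin(top[!m], bot[!m]), pmax(top[!m], bot[!m]), sep = ":")
    match_pos[[i]] <- m
    label_pos[[i]] <- lab
    type_pos[[i]] <- ty
    mm_count <- mm_count + (!m)
    gc_pairs <- gc_pairs + (m & (top == "G" | top == "C"))
  }

  storage.mode(mm_count) <- "integer"
  storage.mode(gc_pairs) <- "integer"
  rc_index <- match(revcomp(oh), oh)

  .ligfid_cache$tables <- list(
    match = match_pos,
    label = label_pos,
    type = type_pos,
    mm_count = mm_count,
    gc_pairs = gc_pairs,
    edge_mm = !match_pos[[1L]] | !match_pos[[4L]],
    rc_index = rc_index,
    wc_cells = cbind(seq_len(n), rc_index)
  )
  .ligfid_cache$tables
}

.position_class <- function(i) {
  ifelse(i %in% OH_EDGE_POSITIONS, "edge", "middle")
}
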