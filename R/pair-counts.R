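## The pair-count matrix: the assay's central data structure.
##
## A 256x256 nonnegative integer matrix indexed by (top overhang, bottom
## overhang). Because strand designation in a ligation product is arbitrary,
## every product is counted in both orientations (top-to-bottom and
## bottom-to-top), so a valid matrix is symmetric and its total ordered count
## is even: 2 x number of products. A palindromic self-ligation contributes 2
## to its diagonal cell, keeping that convention exact.

#' Construct a pair-count matrix
#'
#' @param counts A 256x256 nonnegative numeric matrix. If it carries overhang
#'   dimnames they are used to reorder rows/columns into the canonical
#'   alphabetical order; otherwise canonical order is assumed.
#' @param sample,ligase,condition Free-text metadata.
#' @param replicates Character vector of contributing replicate ids.
#' @return An object of class `pair_counts`.
#' @export
pair_counts <- function(counts, sample = NA_character_, ligase = NA_character_,
                        condition = NA_character_, replicates = character()) {
  oh <- overhangs()
  if (!is.matrix(counts) || !identical(dim(counts), c(256L, 256L))) {
    stop("counts must be a 256x256 matrix", call. = FALSE)
  }
  if (!is.numeric(counts) || anyNA(counts) || any(counts < 0)) {
    stop("counts must be nonnegative and non-missing", call. = FALSE)
  }
  if (!is.null(dimnames(counts))) {
    rn <- .validate_overhang(rownames(counts))
    cn <- .validate_overhang(colnames(counts))
    if (anyDuplicated(rn) || anyDuplicated(cn)) {
      stop("duplicated overhang in dimnames", call. = FALSE)
    }
    counts <- counts[match(oh, rn), match(oh, cn)]
  }
  dimnames(counts) <- list(oh, oh)
  structure(counts, class = "pair_counts",
            sample = as.character(sample)[1L],
            ligase = as.character(ligase)[1L],
            condition = as.character(condition)[1L],
            replicates = as.character(replicates))
}

#' @export
print.pair_counts <- function(x, ...) {
  tot <- sum(x)
  cat("Overhang pair-count matrix (256 x 256)\n")
  meta <- c(sample = attr(x, "sample"), ligase = attr(x, "ligase"),
            condition = attr(x, "condition"))
  meta <- meta[!is.na(meta)]
  if (length(meta)) {
    cat(" ", paste(names(meta), meta, sep = ": ", collapse = "; "), "\n")
  }
  if (length(attr(x, "replicates"))) {
    cat("  replicates:", paste(attr(x, "replicates"), collapse = ", "), "\n")
  }
  cat(sprintf("  ordered counts: %s (%s products)\n",
              format(tot, big.mark = ","), format(tot / 2, big.mark = ",")))
  cat(sprintf("  symmetric: %s\n", is_symmetric_counts(x)))
  invisible(x)
}

#' Test the dual-orientation symmetry invariant
#'
#' @param x A `pair_counts` matrix (or plain 256x256 matrix).
#' @return TRUE iff counts[a, b] == counts[b, a] for all a, b.
#' @export
is_symmetric_counts <- function(x) {
  m <- unclass(x)
  isTRUE(all.equal(m, t(m), check.attributes = FALSE))
}

## Accept pair_counts, pair_expectation, or a bare matrix; return the
## numeric matrix in canonical order.
.as_pair_matrix <- function(x) {
  if (inherits(x, "pair_counts") || inherits(x, "pair_expectation")) {
    return(unclass(x))
  }
  if (is.matrix(x) && identical(dim(x), c(256L, 256L)) && is.numeric(x)) {
    return(unclass(pair_counts(x)))
  }
  stop("expected a pair_counts / pair_expectation / 256x256 matrix",
       call. = FALSE)
}

#' Combine replicate pair-count matrices
#'
#' Elementwise sum of replicate matrices for the same ligase and condition;
#' data from replicates are combined before any statistic is computed.
#' Metadata must agree across replicates unless `override = TRUE`.
#'
#' @param matrices A list of `pair_counts` matrices (or a single matrix).
#' @param override Allow combining despite mismatched ligase/condition
#'   metadata.
#' @return A `pair_counts` matrix whose `replicates` attribute records the
#'   contributing replicate ids.
#' @export
combine_replicates <- function(matrices, override = FALSE) {
  if (inherits(matrices, "pair_counts")) matrices <- list(matrices)
  if (!is.list(matrices) || length(matrices) == 0L) {
    stop("matrices must be a non-empty list of pair_counts", call. = FALSE)
  }
  ms <- lapply(matrices, .as_pair_matrix)
  lig <- vapply(matrices, function(m) as.character(attr(m, "ligase"))[1L],
                character(1))
  cond <- vapply(matrices, function(m) as.character(attr(m, "condition"))[1L],
                 character(1))
  same <- function(v) length(unique(v[!is.na(v)])) <= 1L
  if (!override && (!same(lig) || !same(cond))) {
    stop("replicates disagree on ligase/condition metadata; ",
         "use override = TRUE to combine anyway", call. = FALSE)
  }
  total <- Reduce(`+`, ms)
  reps <- unlist(lapply(seq_along(matrices), function(k) {
    r <- attr(matrices[[k]], "replicates")
    if (is.null(r) || length(r) == 0L) paste0("rep", k) else r
  }))
  pair_counts(total,
              sample = attr(matrices[[1L]], "sample"),
              ligase = lig[!is.na(lig)][1L] %||% NA_character_,
              condition = cond[!is.na(cond)][1L] %||% NA_character_,
              replicates = reps)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a[1L])) b else a

#' Read / write overhang pair-count CSV tables
#'
#' `read_counts_csv()` accepts either the long form (columns
#' `top_overhang,bottom_overhang,count`, header optional, omitted pairs are 0)
#' or the wide form (256x256 with overhang row and column names); the layout
#' is autodetected. Non-symmetric input is accepted with a warning; pass
#' `symmetrize = TRUE` to add the transposed counts (treating the input as
#' single-orientation product counts). `write_counts_csv()` writes the long
#' form with all nonzero cells; write then read round-trips losslessly.
#'
#' @param path File path.
#' @param symmetrize Add the transpose on read (explicit request only).
#' @param ... Metadata passed to [pair_counts()] (`sample`, `ligase`,
#'   `condition`, `replicates`).
#' @return `read_counts_csv()`: a `pair_counts` matrix.
#' @export
read_counts_csv <- function(path, symmetrize = FALSE, ...) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  nfield <- length(strsplit(first, ",", fixed = TRUE)[[1L]])
  m <- if (nfield > 4L) .read_counts_wide(path) else .read_counts_long(path)
  if (!isTRUE(all.equal(m, t(m), check.attributes = FALSE))) {
    if (symmetrize) {
      m <- m + t(m)
    } else {
      warning("count table is not symmetric (single-orientation counts?); ",
              "pass symmetrize = TRUE to fold in the opposite orientation",
              call. = FALSE)
    }
  }
  pair_counts(m, ...)
}

.read_counts_long <- function(path) {
  raw <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         strip.white = TRUE)
  if (ncol(raw) != 3L) {
    stop("long-form counts CSV must have 3 columns ",
         "(top_overhang,bottom_overhang,count); got ", ncol(raw),
         call. = FALSE)
  }
  offset <- 0L
  if (suppressWarnings(is.na(as.numeric(raw[1L, 3L]))) ||
      toupper(raw[1L, 1L]) == "TOP_OVERHANG") {
    raw <- raw[-1L, , drop = FALSE]  # header line
    offset <- 1L
  }
  oh <- overhangs()
  m <- matrix(0, 256L, 256L, dimnames = list(oh, oh))
  if (nrow(raw) == 0L) return(m)
  top <- toupper(raw[[1L]])
  bottom <- toupper(raw[[2L]])
  cnt <- suppressWarnings(as.numeric(raw[[3L]]))
  bad <- !(top %in% oh) | !(bottom %in% oh) | is.na(cnt) | cnt < 0 |
    cnt != floor(cnt)
  if (any(bad)) {
    row <- which(bad)[1L]
    stop("malformed counts CSV at data row ", row + offset, ": '",
         paste(raw[row, ], collapse = ","), "'", call. = FALSE)
  }
  i <- match(top, oh)
  j <- match(bottom, oh)
  for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + cnt[k]
  m
}

.read_counts_wide <- function(path) {
  raw <- utils::read.csv(path, header = TRUE, row.names = 1L,
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(dim(raw), c(256L, 256L))) {
    stop("wide-form counts CSV must be 256x256 with overhang row/col names",
         call. = FALSE)
  }
  m <- as.matrix(raw)
  if (anyNA(suppressWarnings(as.numeric(m)))) {
    stop("wide-form counts CSV contains non-numeric cells", call. = FALSE)
  }
  storage.mode(m) <- "numeric"
  rownames(m) <- toupper(rownames(raw))
  colnames(m) <- toupper(colnames(raw))
  m
}

#' @rdname read_counts_csv
#' @param x A `pair_counts` matrix to write.
#' @export
write_counts_csv <- function(x, path) {
  m <- .as_pair_matrix(x)
  nz <- which(m != 0, arr.ind = TRUE)
  nz <- nz[order(nz[, 1L], nz[, 2L]), , drop = FALSE]
  oh <- overhangs()
  df <- data.frame(top_overhang = oh[nz[, 1L]],
                   bottom_overhang = oh[nz[, 2L]],
                   count = m[nz],
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
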