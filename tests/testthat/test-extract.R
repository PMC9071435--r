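# Extraction: anchored overhang parsing, dual-orientation tabulation,
# replicate combination, and CSV round trips.

test_that("round trip through emit_reads at zero error recovers each event", {
  spec <- substrate_spec()
  ev <- counts_from_products(list("GTGA", "TCAC", 1))
  reads <- emit_reads(ev, spec, error_rate = 0, seed = 2)
  parsed <- parse_products(reads, spec = spec)
  expect_equal(sum(parsed$failures), 0L)
  expect_equal(parsed$observations$top, "GTGA")
  expect_equal(parsed$observations$bottom, "TCAC")
  expect_equal(nchar(parsed$observations$control_top), 6L)
})

test_that("parse failures carry the right reason codes", {
  spec <- substrate_spec()
  ra <- substr(spec$right_const, 1, spec$control_offset - 1)
  tail <- substr(spec$right_const, spec$control_offset + spec$control_len,
                 nchar(spec$right_const))
  good <- paste0(spec$left_const, "CTAT", ra, "AAAAAA", tail)
  gap5 <- paste0(spec$left_const, "CTATA", ra, "AAAAAA", tail)
  # substitution inside the left anchor
  broken_anchor <- good
  substr(broken_anchor, 3, 3) <- if (substr(good, 3, 3) == "A") "C" else "A"

  p <- parse_products(c(good, gap5, broken_anchor),
                      c(good, good, good), spec = spec)
  expect_equal(nrow(p$observations), 1L)
  expect_equal(p$failures[["wrong-gap-length"]], 1L)
  expect_equal(p$failures[["anchor-missing"]], 1L)

  # fuzzy mode (<= 1 substitution per anchor) rescues the broken anchor
  pf <- parse_products(broken_anchor, good, spec = spec, fuzzy = TRUE)
  expect_equal(sum(pf$failures), 0L)
  expect_equal(pf$observations$top, "CTAT")
})

test_that("extraction failure rate is 0 at zero error and nondecreasing in error rate", {
  m <- ligase_model_preset("moderate")
  counts <- sample_events(m, 400, seed = 31)
  spec <- substrate_spec()
  fail_frac <- vapply(c(0, 0.05, 0.3), function(er) {
    reads <- emit_reads(counts, spec, error_rate = er, seed = 32)
    p <- parse_products(reads, spec = spec)
    sum(p$failures) / p$n_input
  }, numeric(1))
  expect_equal(fail_frac[1], 0)
  expect_true(all(diff(fail_frac) >= 0))
  expect_gt(fail_frac[3], 0)
})

test_that("tabulation counts both orientations and palindromes twice", {
  obs <- data.frame(top = "CTAT", bottom = "ATAG",
                    control_top = NA_character_,
                    control_bottom = NA_character_,
                    stringsAsFactors = FALSE)
  m <- tabulate_pairs(obs)
  expect_equal(m["CTAT", "ATAG"], 1)
  expect_equal(m["ATAG", "CTAT"], 1)
  expect_equal(sum(m), 2)

  pal <- data.frame(top = "ACGT", bottom = "ACGT")
  mp <- tabulate_pairs(pal)
  expect_equal(mp["ACGT", "ACGT"], 2)
  expect_equal(sum(mp), 2)

  empty <- tabulate_pairs(data.frame(top = character(0),
                                     bottom = character(0)))
  expect_equal(sum(empty), 0)
})

test_that("tabulated matrices satisfy symmetry and parity on random inputs", {
  set.seed(13)
  oh <- overhangs()
  for (k in 1:5) {
    n <- sample(50:200, 1)
    obs <- data.frame(top = sample(oh, n, replace = TRUE),
                      bottom = sample(oh, n, replace = TRUE))
    m <- tabulate_pairs(obs)
    expect_true(is_symmetric_counts(m))
    expect_equal(sum(m), 2 * n)
    expect_equal(sum(m) %% 2, 0)
  }
})

test_that("combine_replicates sums counts and enforces matching metadata", {
  m1 <- counts_from_products(list("CTAT", "ATAG", 5), list("GTGA", "TCAC", 3))
  m <- pair_counts(unclass(m1), ligase = "L1", condition = "std",
                   replicates = "r1")
  m2 <- pair_counts(unclass(m1), ligase = "L1", condition = "std",
                    replicates = "r2")
  comb <- combine_replicates(list(m, m2))
  expect_equal(unclass(comb), unclass(m) * 2L, ignore_attr = TRUE)
  expect_equal(attr(comb, "replicates"), c("r1", "r2"))
  # single matrix is the identity
  expect_equal(unclass(combine_replicates(list(m))), unclass(m),
               ignore_attr = TRUE)
  # metadata mismatch errors unless overridden
  m3 <- pair_counts(unclass(m1), ligase = "L2")
  expect_error(combine_replicates(list(m, m3)), "metadata")
  expect_silent(combine_replicates(list(m, m3), override = TRUE))
})

test_that("counts CSV round trips losslessly in long form", {
  counts <- sample_events(ligase_model_preset("permissive"), 2000, seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts_csv(counts, path)
  back <- read_counts_csv(path)
  expect_equal(unclass(back), unclass(counts), ignore_attr = TRUE)
})

test_that("long-form rows populate single cells and bad rows are rejected by number", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("top_overhang,bottom_overhang,count", "CTAT,ATAG,5"), path)
  m <- suppressWarnings(read_counts_csv(path))
  expect_equal(m["CTAT", "ATAG"], 5)
  expect_equal(sum(m), 5)

  writeLines(c("top_overhang,bottom_overhang,count", "CTA,ATAG,5"), path)
  expect_error(read_counts_csv(path), "row 2")
  writeLines(c("CTAT,ATAG,-3"), path)
  expect_error(read_counts_csv(path), "row 1")
})

test_that("non-symmetric input is flagged and symmetrized only on request", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("top_overhang,bottom_overhang,count", "CTAT,ATAG,5"), path)
  expect_warning(m <- read_counts_csv(path), "not symmetric")
  expect_false(is_symmetric_counts(m))
  m2 <- read_counts_csv(path, symmetrize = TRUE)
  expect_true(is_symmetric_counts(m2))
  expect_equal(m2["ATAG", "CTAT"], 5)
})

test_that("wide-form CSV is autodetected", {
  counts <- sample_events(ligase_model(), 500, seed = 43)
  path <- withr::local_tempfile(fileext = ".csv")
  m <- unclass(counts)
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  back <- read_counts_csv(path)
  expect_equal(unclass(back), m, ignore_attr = TRUE)
})

test_that("control regions are tallied per position for bias correction", {
  obs <- data.frame(top = c("CTAT", "GTGA"), bottom = c("ATAG", "TCAC"),
                    control_top = c("AAAAAA", "CCCCCC"),
                    control_bottom = c("GGGGGG", NA),
                    stringsAsFactors = FALSE)
  m <- tabulate_pairs(obs)
  tally <- attr(m, "control_tally")
  expect_equal(dim(tally), c(4L, 6L))
  expect_equal(unname(colSums(tally)), rep(3L, 6L))  # 3 intact controls
  expect_equal(unname(tally["A", ]), rep(1L, 6L))
})
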