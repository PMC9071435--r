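# Profiling statistics: bias, fidelity, GC stratification, mismatch spectra,
# pattern groups, correlation, synthesis-bias correction, yield.

test_that("normalized frequency is mean-1 scaled and sums to 256", {
  # uniform WC-only expectation: every overhang at exactly 1.0
  f <- normalized_frequency(expected_profile(ligase_model()))
  expect_equal(unname(f), rep(1, 256))
  # a matrix with only (CTAT, ATAG) events: each carries half the ordered
  # counts, x256
  m <- counts_from_products(list("CTAT", "ATAG", 7))
  f2 <- normalized_frequency(m)
  expect_equal(f2[["CTAT"]], 128)
  expect_equal(f2[["ATAG"]], 128)
  expect_equal(sum(f2), 256)
  expect_equal(sum(f2 == 0), 254L)
  expect_error(normalized_frequency(matrix(0, 256, 256)), "empty")
})

test_that("fidelity counts Watson-Crick events over all events", {
  # 3 WC events + 1 single-mismatch event
  m <- counts_from_products(list("CTAT", "ATAG", 2), list("GTGA", "TCAC", 1),
                            list("TGGA", "TCCG", 1))
  expect_equal(overall_fidelity(m), 0.75)
  fid <- per_overhang_fidelity(m)
  expect_equal(fid[["CTAT"]], 1)
  expect_equal(fid[["TGGA"]], 0)  # its only partner is a mismatch
  expect_true(is.na(fid[["AAAA"]]))  # no events: undefined, not 0
  # overall equals the event-weighted mean of per-overhang fidelity
  rs <- rowSums(unclass(m))
  expect_equal(overall_fidelity(m),
               sum(fid * rs, na.rm = TRUE) / sum(rs))
  # WC-only matrix has fidelity 1 everywhere it is defined
  wc <- counts_from_products(list("CTAT", "ATAG", 4), list("ACGT", "ACGT", 1))
  expect_equal(overall_fidelity(wc), 1)
  expect_true(all(per_overhang_fidelity(wc) %in% c(1, NA)))
})

test_that("palindromic overhang fidelity counts the diagonal as correct", {
  m <- counts_from_products(list("ACGT", "ACGT", 3))
  expect_equal(per_overhang_fidelity(m)[["ACGT"]], 1)
  expect_equal(overall_fidelity(m), 1)
})

test_that("GC bins have populations 16/64/96/64/16 and summarize values", {
  oh <- overhangs()
  const <- stats::setNames(rep(1, 256), oh)
  s <- gc_binned_summary(const)
  expect_equal(s$gc_percent, c(0, 25, 50, 75, 100))
  expect_equal(s$n_overhangs, c(16, 64, 96, 64, 16))
  expect_equal(s$mean, rep(1, 5))
  # cross-check bin populations by direct enumeration
  expect_equal(as.vector(table(gc_count(oh))),
               choose(4, 0:4) * 2^(0:4) * 2^(4 - (0:4)))
  # NA values are excluded from means, never counted as zero
  v <- const
  v[gc_percent(oh) == 0][1:8] <- NA
  s2 <- gc_binned_summary(v)
  expect_equal(s2$n_defined[1], 8)
  expect_equal(s2$mean[1], 1)
})

test_that("mismatch spectrum tallies labels by position class", {
  # WC-only matrix: empty spectrum, all mass at 0 mismatches
  wc <- counts_from_products(list("CTAT", "ATAG", 5))
  expect_equal(nrow(mismatch_spectrum(wc)), 0L)
  expect_equal(unname(mismatch_count_distribution(wc)),
               c(1, 0, 0, 0, 0))
  # only (TGGA, TCCG) events: a single edge mismatch seen as T:G in one
  # orientation and G:T in the other
  m <- counts_from_products(list("TGGA", "TCCG", 4))
  sp <- mismatch_spectrum(m)
  expect_setequal(sp$label, c("T:G", "G:T"))
  expect_true(all(sp$position_class == "edge"))
  expect_equal(sum(sp$frequency), 1)
  expect_equal(sp$frequency, c(0.5, 0.5))
  d <- mismatch_count_distribution(m)
  expect_equal(unname(d), c(0, 1, 0, 0, 0))
})

test_that("spectrum and count distribution agree with the brute-force oracle on random matrices", {
  set.seed(99)
  oh <- overhangs()
  mm_oracle <- oracle_mm_count_matrix()
  for (k in 1:3) {
    obs <- data.frame(top = sample(oh, 500, replace = TRUE),
                      bottom = sample(oh, 500, replace = TRUE))
    m <- tabulate_pairs(obs)
    d <- mismatch_count_distribution(m)
    d_oracle <- vapply(0:4, function(j) sum(unclass(m)[mm_oracle == j]),
                       numeric(1)) / sum(m)
    expect_equal(unname(d), d_oracle)
    expect_equal(overall_fidelity(m), d[["0"]])
    expect_equal(sum(d), 1)
    # spectrum weights total the count-weighted mismatch positions
    sp <- mismatch_spectrum(m)
    expect_equal(sum(sp$weight), sum(unclass(m) * mm_oracle))
  }
})

test_that("double-mismatch edge fraction distinguishes edge and middle pairs", {
  # mismatches at middle positions 2 and 3 only
  mid <- counts_from_products(list("AGGA", "TGGT", 3))
  expect_equal(overhang_mismatches("AGGA", "TGGT")$position, c(2L, 3L))
  expect_equal(double_mismatch_edge_fraction(mid), 0)
  # mismatches at positions 1 and 2
  edge <- counts_from_products(list("GGGA", "TCGG", 2))
  expect_equal(overhang_mismatches("GGGA", "TCGG")$position, c(1L, 2L))
  expect_equal(double_mismatch_edge_fraction(edge), 1)
  # undefined when no two-mismatch events exist
  wc <- counts_from_products(list("CTAT", "ATAG", 1))
  expect_message(out <- double_mismatch_edge_fraction(wc), "undefined")
  expect_true(is.na(out))
})

test_that("pattern group summaries report group mean and size", {
  f <- normalized_frequency(expected_profile(ligase_model()))
  s <- pattern_group_summary(f, c("NNNN", "TNNA", "CNNG"))
  expect_equal(s$n, c(256, 16, 16))
  expect_equal(s$mean, rep(1, 3))  # uniform profile: all group means 1
  expect_error(pattern_group_summary(f, "NNNU"), "pattern")
  # a TNNA-depleted profile shows a group mean below 1
  w <- stats::setNames(rep(1, 256), overhangs())
  w[matches_pattern(names(w), "TNNA")] <- 0.2
  fd <- normalized_frequency(expected_profile(ligase_model(weights = w)))
  expect_lt(pattern_group_summary(fd, "TNNA")$mean, 1)
})

test_that("Pearson correlation behaves at the extremes and across replicates", {
  f <- normalized_frequency(expected_profile(
    ligase_model(anneal_coeff = 0.3)))
  expect_equal(pearson_correlation(f, f), 1)
  neg <- 2 * mean(f) - f  # reflection about the mean
  expect_equal(pearson_correlation(f, neg), -1)
  const <- stats::setNames(rep(1, 256), overhangs())
  expect_warning(r <- pearson_correlation(f, const), "zero variance")
  expect_true(is.na(r))
  # two independent large samples from one model correlate near 1
  m <- ligase_model_preset("moderate")
  f1 <- normalized_frequency(sample_events(m, 1e6, seed = 51))
  f2 <- normalized_frequency(sample_events(m, 1e6, seed = 52))
  expect_gt(pearson_correlation(f1, f2), 0.99)
})

test_that("synthesis-bias correction divides out control-region composition", {
  f <- stats::setNames(rep(1, 256), overhangs())
  # uniform control tallies: identity
  tally <- matrix(25L, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(synthesis_bias_correction(f, tally), f)
  # exact closed form: a fully permissive uniform ligase on a skewed
  # substrate pool has raw frequency proportional to the pool abundance;
  # dividing it out flattens the profile
  skew <- c(A = 0.4, C = 0.2, G = 0.2, T = 0.2)
  model <- ligase_model(weights = synthesis_weights(skew),
                        tolerance = uniform_tolerance(1))
  raw <- normalized_frequency(expected_profile(model))
  expect_gt(raw[["AAAA"]], raw[["CCCC"]])
  tally_skew <- matrix(round(1e6 * skew), 4, 6,
                       dimnames = list(names(skew), NULL))
  corrected <- synthesis_bias_correction(raw, tally_skew)
  expect_equal(unname(corrected), rep(1, 256), tolerance = 1e-6)
  # all-zero position: skipped with a warning
  tally0 <- tally
  tally0[, 2] <- 0L
  expect_warning(out <- synthesis_bias_correction(f, tally0), "skipped")
  expect_equal(out, f)
  expect_warning(synthesis_bias_correction(f, NULL), "skipped")
})

test_that("sampled reads on a skewed pool are flattened by the control correction", {
  skew <- c(A = 0.4, C = 0.2, G = 0.2, T = 0.2)
  model <- ligase_model(weights = synthesis_weights(skew),
                        tolerance = uniform_tolerance(1))
  counts <- sample_events(model, 40000, seed = 61)
  reads <- emit_reads(counts, substrate_spec(), error_rate = 0, seed = 62,
                      control_base_freqs = skew)
  m <- extract_counts(reads)
  raw <- ligation_profile(m)$frequency
  corr <- ligation_profile(m, correction = "control-hexamer")$frequency
  # raw profile is A-enriched; corrected profile has no A-vs-C gradient
  a_mean <- function(v) mean(v[matches_pattern(names(v), "ANNN")])
  c_mean <- function(v) mean(v[matches_pattern(names(v), "CNNN")])
  expect_gt(a_mean(raw) / c_mean(raw), 1.5)
  expect_lt(abs(a_mean(corr) / c_mean(corr) - 1), 0.1)
})

test_that("yield follows product / (substrate + product)", {
  expect_equal(yield_percent(50, 50), 50)
  expect_equal(yield_percent(0, 10), 0)
  expect_equal(yield_percent(3, 1), 75)
  expect_error(yield_percent(0, 0), "both")
  expect_error(yield_percent(-1, 2), "nonnegative")
})

test_that("statistics are invariant under count scaling and strand relabeling", {
  m <- sample_events(ligase_model_preset("permissive"), 20000, seed = 71)
  m5 <- pair_counts(unclass(m) * 5L)
  mt <- pair_counts(t(unclass(m)))
  for (variant in list(m5, mt)) {
    expect_equal(normalized_frequency(variant), normalized_frequency(m))
    expect_equal(overall_fidelity(variant), overall_fidelity(m))
    expect_equal(per_overhang_fidelity(variant), per_overhang_fidelity(m))
    expect_equal(mismatch_count_distribution(variant),
                 mismatch_count_distribution(m))
    expect_equal(mismatch_spectrum(variant)$frequency,
                 mismatch_spectrum(m)$frequency)
  }
})

test_that("profile object ties the pieces together and compares conditions", {
  m <- ligase_model_preset("moderate")
  counts <- sample_events(m, 30000, seed = 81)
  prof <- ligation_profile(counts)
  expect_s3_class(prof, "ligation_profile")
  expect_equal(prof$overall_fidelity, overall_fidelity(counts))
  expect_equal(prof$mismatch_counts[["0"]], prof$overall_fidelity)
  expect_equal(prof$n_products, 30000)
  expect_output(print(prof), "overall fidelity")
  expect_output(summary(prof), "GC content")
  # identical inputs give all-zero deltas
  cmp <- compare_profiles(prof, prof)
  expect_equal(unname(cmp$delta_frequency), rep(0, 256))
  expect_equal(cmp$overall_fidelity_delta, 0)
  # a more permissive condition lowers overall fidelity
  prof2 <- ligation_profile(sample_events(ligase_model_preset("permissive"),
                                          30000, seed = 82))
  cmp2 <- compare_profiles(prof, prof2)
  expect_lt(cmp2$overall_fidelity_delta, 0)
})

test_that("adjacent GC bins are compared with a rank test", {
  E <- expected_profile(ligase_model(anneal_coeff = 0.5))
  res <- gc_bin_tests(normalized_frequency(E))
  expect_equal(nrow(res), 4L)
  expect_true(all(res$p_value < 0.001))  # strongly separated bins
})
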