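test_that("aggregation counts keys and tallies QC separately", {
  ref <- synthetic_reference()
  arm5 <- substr(ref$precursor_seq, 13, 34)
  asg <- match_reads(rep(arm5, 3), ref)
  prof <- aggregate_assignments(asg, "s1")
  expect_equal(nrow(prof), 1)
  expect_equal(prof$count, 3)
  expect_equal(attr(prof, "total_counted"), 3)

  empty <- aggregate_assignments(match_reads(character(0), ref), "s0")
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "total_counted"), 0)

  twin <- mirna_reference("syn-mir-2",
                          paste0("GGTACC", arm5, "CGAAGGTTCCAA"),
                          data.frame(arm_name = "syn-mir-2-5p", start = 6,
                                     end = 28))
  asg2 <- match_reads(c(rep(substr(ref$precursor_seq, 51, 72), 2), arm5),
                      list(ref, twin))
  prof2 <- aggregate_assignments(asg2, "s2")
  expect_equal(attr(prof2, "total_counted"), 2)           # ambiguous excluded
  expect_equal(unname(attr(prof2, "qc")["ambiguous"]), 1L)
  prof2w <- aggregate_assignments(asg2, "s2", include_ambiguous = TRUE)
  expect_equal(attr(prof2w, "total_counted"), 3)          # 2 + 2 * 1/2
  expect_equal(sort(prof2w$count[prof2w$tail == "" & prof2w$delta3 == 0 &
                                   prof2w$offset5 == 0]), c(0.5, 0.5, 2))
})

test_that("cpm normalises to a million and is linear in the denominator", {
  prof <- profile_from_counts(0, 1, 3)
  v <- cpm(prof)
  expect_equal(sort(v), c(250000, 750000))
  expect_equal(sum(cpm(profile_from_counts(7, 13, 5))), 1e6)
  v10 <- cpm(prof, "supplied", library_size = 10 * attr(prof, "total_counted"))
  expect_equal(v10, v / 10)
  expect_error(cpm(prof, "supplied", library_size = 0), "positive")
})

test_that("adenylation and degradation ratios follow the species definition", {
  prof <- profile_from_counts(20, 40, 10)
  rr <- tailing_ratios(prof, "syn-mir-1", "syn-mir-1-5p")
  expect_equal(rr$substrate_count, 40)
  expect_equal(rr$tailed_count, 10)
  expect_equal(rr$trimmed_count, 20)
  expect_ratio(rr, 0.25, 0.5)
  # substrate only: defined, both zero
  expect_ratio(tailing_ratios(profile_from_counts(0, 40, 0),
                              "syn-mir-1", "syn-mir-1-5p"), 0, 0)
  # zero substrate: undefined (NA), never zero, with warning
  expect_warning(
    rr0 <- tailing_ratios(profile_from_counts(5, 0, 0),
                          "syn-mir-1", "syn-mir-1-5p"),
    "undefined")
  expect_true(is.na(rr0$adenylation_ratio) && is.na(rr0$degradation_ratio))
})

test_that("ratios are invariant under count rescaling (raw counts vs cpm)", {
  base <- tailing_ratios(profile_from_counts(20, 40, 10),
                         "syn-mir-1", "syn-mir-1-5p")
  for (c_scale in c(3, 17)) {
    scaled <- tailing_ratios(
      profile_from_counts(20 * c_scale, 40 * c_scale, 10 * c_scale),
      "syn-mir-1", "syn-mir-1-5p")
    expect_ratio(scaled, base$adenylation_ratio, base$degradation_ratio)
  }
})

test_that("adding one species moves exactly one ratio, monotonically", {
  r0 <- tailing_ratios(profile_from_counts(20, 40, 10),
                       "syn-mir-1", "syn-mir-1-5p")
  r_tail <- tailing_ratios(profile_from_counts(20, 40, 25),
                           "syn-mir-1", "syn-mir-1-5p")
  expect_gt(r_tail$adenylation_ratio, r0$adenylation_ratio)
  expect_equal(r_tail$degradation_ratio, r0$degradation_ratio)
  r_can <- tailing_ratios(profile_from_counts(35, 40, 10),
                          "syn-mir-1", "syn-mir-1-5p")
  expect_gt(r_can$degradation_ratio, r0$degradation_ratio)
  expect_equal(r_can$adenylation_ratio, r0$adenylation_ratio)
})

test_that("longer tails stay out of the adenylation numerator", {
  ref <- synthetic_reference()
  substrate <- reconstruct_read(ref, "syn-mir-1-5p", 0L, 1L)
  reads <- c(rep(substrate, 10), rep(paste0(substrate, "A"), 4),
             rep(paste0(substrate, "AA"), 6))
  prof <- aggregate_assignments(match_reads(reads, ref), "s")
  rr <- tailing_ratios(prof, "syn-mir-1", "syn-mir-1-5p")
  expect_equal(rr$tailed_count, 4)
  expect_equal(rr$adenylation_ratio, 0.4)
  expect_equal(sum(prof$count[prof$tail == "AA"]), 6)    # reported separately
})

test_that("region counting uses majority overlap with a 5'-most tie-break", {
  seq50 <- strrep("ACGTG", 10)
  ctx3 <- substr(strrep("ACGTG", 11), 43, 52)
  ref <- mirna_reference("p", seq50,
                         data.frame(arm_name = c("p-5p", "p-3p"),
                                    start = c(0, 26), end = c(16, 42),
                                    template_context = c("", ctx3)))
  rg <- derive_regions(ref)
  # [14,34): 2 bases in 5p, 10 in loop [16,26), 8 in 3p -> loop
  rc <- region_counts(data.frame(start = 14, end = 34), rg)
  expect_equal(rc$loop, 1)
  # entirely inside the loop
  expect_equal(region_counts(data.frame(start = 17, end = 25), rg)$loop, 1)
  # 5 bases in 5p [11,16) and 5 in loop [16,21): tie -> 5'-most region
  expect_equal(region_counts(data.frame(start = 11, end = 21), rg)$mature_5p, 1)
  # no overlap at all
  expect_equal(region_counts(data.frame(start = 60, end = 70), rg)$outside, 1)
})

test_that("majority overlap matches an arithmetic oracle and conserves reads", {
  seq50 <- strrep("ACGTG", 10)
  ctx3 <- substr(strrep("ACGTG", 11), 43, 52)
  ref <- mirna_reference("p", seq50,
                         data.frame(arm_name = c("p-5p", "p-3p"),
                                    start = c(2, 26), end = c(18, 42),
                                    template_context = c("", ctx3)))
  rg <- derive_regions(ref)
  set.seed(11)
  ints <- data.frame(start = sample(0:45, 60, replace = TRUE))
  ints$end <- pmin(50, ints$start + sample(8:24, 60, replace = TRUE))
  rc <- region_counts(ints, rg)
  counted <- sum(rc[, !(names(rc) %in% c("sample_id", "precursor_id"))])
  expect_equal(counted, nrow(ints))
  # independent oracle: per-read max overlap, first (5'-most) region on ties
  regions <- rg$regions
  oracle <- vapply(seq_len(nrow(ints)), function(i) {
    ov <- vapply(regions, function(r)
      max(0, min(ints$end[i], r["end"]) - max(ints$start[i], r["start"])), 0)
    if (max(ov) <= 0) "outside" else names(regions)[which.max(ov)]
  }, "")
  for (nm in names(regions))
    expect_equal(rc[[nm]], sum(oracle == nm), info = nm)
})

test_that("exact-match location places background fragments", {
  ref <- synthetic_reference()
  rg <- derive_regions(ref)$regions
  loop_frag <- substr(ref$precursor_seq, rg$loop["start"] + 1, rg$loop["end"])
  loc <- locate_reads(c(loop_frag, "AAAAAAAAAAAAAAAA"), ref)
  expect_equal(nrow(loc), 1)
  expect_equal(loc$start, unname(rg$loop["start"]))
  expect_equal(attr(loc, "n_unlocated"), 1L)
})
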