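test_that("TSV-annotated references load with correct coordinates and context", {
  ref <- toy_ref()
  files <- write_ref_files(ref)
  refs <- load_reference(files$fasta, files$tsv, dialect = "tsv")
  expect_length(refs, 1)
  arm <- refs[["toy-1"]]$arms[["miR-T-5p"]]
  expect_equal(arm$canonical_length, 16L)
  expect_true(startsWith(arm$template_context, "CGATCGATT"))
  # template context starts at the base immediately 3' of the arm end
  expect_equal(substr(arm$template_context, 1, 1),
               substr(refs[["toy-1"]]$precursor_seq, arm$end + 1, arm$end + 1))
})

test_that("RNA input is normalised to the internal DNA alphabet", {
  ref <- mirna_reference("r", "AAGGCCUUAAGGCCUUCGAUCGAUU",
                         data.frame(arm_name = "r-5p", start = 0, end = 16,
                                    template_context = "CGAUCGAUUA"))
  expect_false(grepl("U", ref$precursor_seq))
  expect_equal(as_rna(ref$precursor_seq), "AAGGCCUUAAGGCCUUCGAUCGAUU")
})

test_that("annotation errors are hard errors naming the problem", {
  ref <- toy_ref()
  files <- write_ref_files(ref)
  # arm outside precursor bounds
  tsv <- file.path(dirname(files$tsv), "bad.tsv")
  writeLines(c("precursor_id\tarm_name\tstart\tend",
               "toy-1\tmiR-T-5p\t10\t40"), tsv)
  expect_error(load_reference(files$fasta, tsv), "outside precursor")
  # annotated precursor missing from FASTA
  writeLines(c("precursor_id\tarm_name\tstart\tend",
               "ghost-1\tghost-5p\t0\t16"), tsv)
  expect_error(load_reference(files$fasta, tsv), "ghost-1")
  # duplicate arm names
  writeLines(c("precursor_id\tarm_name\tstart\tend\ttemplate_context",
               "toy-1\tmiR-T-5p\t0\t16\tCGATCGATTA",
               "toy-1\tmiR-T-5p\t1\t17\tGATCGATTAA"), tsv)
  expect_error(load_reference(files$fasta, tsv), "duplicate")
  # insufficient template context at the precursor boundary
  writeLines(c("precursor_id\tarm_name\tstart\tend",
               "toy-1\tmiR-T-5p\t0\t16"), tsv)
  expect_error(load_reference(files$fasta, tsv), "template context")
})

test_that("GFF3 coordinates convert to precursor-relative on both strands", {
  dir <- withr::local_tempdir()
  ref <- synthetic_reference()
  fasta <- file.path(dir, "pre.fa")
  writeLines(c(">syn-mir-1", ref$precursor_seq), fasta)
  # plus strand: precursor at genomic 1001..1084; 5p arm [12,34) -> 1013..1034
  gff <- file.path(dir, "plus.gff3")
  writeLines(c("##gff-version 3",
    paste("chr1", ".", "miRNA_primary_transcript", 1001, 1084, ".", "+", ".",
          "ID=MI001;Name=syn-mir-1", sep = "\t"),
    paste("chr1", ".", "miRNA", 1013, 1034, ".", "+", ".",
          "ID=MIMAT001;Name=syn-mir-1-5p;Derives_from=MI001", sep = "\t"),
    paste("chr1", ".", "miRNA", 1051, 1072, ".", "+", ".",
          "ID=MIMAT002;Name=syn-mir-1-3p;Derives_from=MI001", sep = "\t")), gff)
  refs <- load_reference(fasta, gff, dialect = "gff3")
  expect_equal(refs[["syn-mir-1"]]$arms[["syn-mir-1-5p"]]$start, 12L)
  expect_equal(refs[["syn-mir-1"]]$arms[["syn-mir-1-5p"]]$end, 34L)
  # minus strand: same precursor-relative intervals from flipped genomic ones
  gffm <- file.path(dir, "minus.gff3")
  writeLines(c("##gff-version 3",
    paste("chr1", ".", "miRNA_primary_transcript", 2001, 2084, ".", "-", ".",
          "ID=MI002;Name=syn-mir-1", sep = "\t"),
    paste("chr1", ".", "miRNA", 2051, 2072, ".", "-", ".",
          "ID=MIMAT003;Name=syn-mir-1-5p;Derives_from=MI002", sep = "\t"),
    paste("chr1", ".", "miRNA", 2013, 2034, ".", "-", ".",
          "ID=MIMAT004;Name=syn-mir-1-3p;Derives_from=MI002", sep = "\t")), gffm)
  refsm <- load_reference(fasta, gffm, dialect = "gff3")
  expect_equal(refsm[["syn-mir-1"]]$arms[["syn-mir-1-5p"]]$start, 12L)
  expect_equal(refsm[["syn-mir-1"]]$arms[["syn-mir-1-5p"]]$end, 34L)
  expect_equal(refsm[["syn-mir-1"]]$arms[["syn-mir-1-3p"]]$start, 50L)
})

test_that("references round-trip through the TSV dialect", {
  for (ref in list(toy_ref(), synthetic_reference())) {
    files <- write_ref_files(ref)
    back <- load_reference(files$fasta, files$tsv)[[ref$precursor_id]]
    expect_equal(back, ref)
  }
})

test_that("derive_regions splits precursors as expected, any arm may be absent", {
  seq40 <- strrep("ACGT", 10)
  ref <- mirna_reference("p", seq40,
                         data.frame(arm_name = c("p-5p", "p-3p"),
                                    start = c(0, 20), end = c(16, 36),
                                    template_context = c("", "ACGTACGTAC")))
  rg <- derive_regions(ref)$regions
  expect_equal(unname(rg$loop), c(16L, 20L))
  expect_equal(unname(rg$upstream_of_5p), c(0L, 0L))
  expect_equal(unname(rg$downstream_of_3p), c(36L, 40L))

  seq60 <- strrep("ACGTT", 12)
  ref5 <- mirna_reference("q", seq60,
                          data.frame(arm_name = "q-5p", start = 4, end = 26))
  rg5 <- derive_regions(ref5)$regions
  expect_equal(unname(rg5$upstream_of_5p), c(0L, 4L))
  expect_equal(diff(rg5$loop), c(end = 0L))
  expect_equal(diff(rg5$mature_3p), c(end = 0L))
  expect_equal(unname(rg5$downstream_of_3p), c(26L, 60L))
})

test_that("overlapping arms are a hard error", {
  seq40 <- strrep("ACGT", 10)
  ref <- mirna_reference("p", seq40,
                         data.frame(arm_name = c("p-5p", "p-3p"),
                                    start = c(0, 15), end = c(20, 35),
                                    template_context = c("", "TACGTACGTA")))
  expect_error(derive_regions(ref), "overlapping")
})

test_that("regions partition the precursor exactly", {
  for (i in 1:5) {
    ref <- random_reference(i)
    rg <- derive_regions(ref)$regions
    covered <- integer(0)
    for (r in rg)
      if (r["end"] > r["start"]) covered <- c(covered, r["start"]:(r["end"] - 1))
    expect_false(anyDuplicated(covered) > 0)
    expect_setequal(covered, 0:(nchar(ref$precursor_seq) - 1))
  }
})
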