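# Shared fixtures: toy references built in code, random reference/read
# generators, and the brute-force 3' decomposition oracle.

# 25-nt toy precursor with a 16-nt 5p arm at [0,16); downstream template
# begins CGATCGATT. Supplied context extends 1 nt past the precursor end.
toy_ref <- function() {
  mirna_reference("toy-1", "AAGGCCTTAAGGCCTTCGATCGATT",
                  data.frame(arm_name = "miR-T-5p", start = 0L, end = 16L,
                             template_context = "CGATCGATTA",
                             stringsAsFactors = FALSE))
}

toy_arm_seq <- function() substr("AAGGCCTTAAGGCCTTCGATCGATT", 1, 16)

# Write a reference as FASTA + TSV files; returns the two paths.
write_ref_files <- function(ref, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  fasta <- file.path(dir, "pre.fa")
  writeLines(c(paste0(">", ref$precursor_id), ref$precursor_seq), fasta)
  tsv <- file.path(dir, "arms.tsv")
  write_reference_tsv(list(ref), tsv)
  list(fasta = fasta, tsv = tsv)
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# Deterministic random single-arm reference (seeded by index).
random_reference <- function(i) {
  set.seed(1000 + i)
  plen <- sample(60:100, 1)
  clen <- sample(16:26, 1)
  start <- sample(3:8, 1)
  mirna_reference(sprintf("rand-%d", i), rand_seq(plen),
                  data.frame(arm_name = sprintf("rand-%d-5p", i),
                             start = start, end = start + clen,
                             stringsAsFactors = FALSE))
}

# Independent oracle: enumerate every split of the read into (templated
# prefix, tail), keep splits whose prefix matches the template exactly, and
# choose the maximal templated prefix.
brute_decompose <- function(read_seq, ref, arm, offset5 = 0L) {
  if (is.character(arm)) arm <- ref$arms[[arm]]
  tmpl <- paste0(ref$precursor_seq,
                 substring(arm$template_context,
                           nchar(ref$precursor_seq) - arm$end + 1L))
  p <- arm$start + offset5
  best <- -1L
  for (tl in 0:nchar(read_seq)) {
    if (p + tl > nchar(tmpl)) break
    if (substr(read_seq, 1L, tl) == substr(tmpl, p + 1L, p + tl)) best <- tl
  }
  list(delta3_templated = offset5 + best - arm$canonical_length,
       tail = substr(read_seq, best + 1L, nchar(read_seq)))
}

# Random isomiR read from an arm: random 5' offset, 3' trim/extension, tail.
random_isomir_read <- function(ref, arm_name = names(ref$arms)[1]) {
  arm <- ref$arms[[arm_name]]
  off <- sample(-2:2, 1)
  d3 <- sample(-5:3, 1)
  tail_len <- sample(0:3, 1)
  tail <- if (tail_len) rand_seq(tail_len) else ""
  core <- arm$canonical_length - off + d3
  if (arm$start + off < 0 || core < 1) return(NULL)
  tmpl_len <- nchar(ref$precursor_seq) +
    max(0L, nchar(arm$template_context) - (nchar(ref$precursor_seq) - arm$end))
  if (arm$start + off + core > tmpl_len) return(NULL)
  list(seq = paste0(reconstruct_read(ref, arm, off, d3), tail), offset5 = off)
}

expect_ratio <- function(rr, aden, degr, tol = 1e-12) {
  testthat::expect_equal(rr$adenylation_ratio, aden, tolerance = tol)
  testthat::expect_equal(rr$degradation_ratio, degr, tolerance = tol)
}

# Simulate one sample and push it through match -> aggregate -> ratios.
estimate_arm_ratios <- function(scn, seed) {
  s <- simulate_sample(scn, seed)
  prof <- aggregate_assignments(match_reads(s$reads, scn$reference),
                                sample_id = as.character(seed))
  suppressWarnings(
    tailing_ratios(prof, scn$reference$precursor_id, scn$arm_name,
                   substrate_delta3 = scn$substrate_delta3,
                   tail_nt = scn$tail_nt))
}

# Profile built directly from species read counts on the synthetic reference.
profile_from_counts <- function(n_canonical, n_substrate, n_tailed,
                                sample_id = "s", ref = synthetic_reference()) {
  arm <- ref$arms[[1]]
  canon <- substr(ref$precursor_seq, arm$start + 1, arm$end)
  substrate <- reconstruct_read(ref, arm, 0L, 1L)
  reads <- c(rep(canon, n_canonical), rep(substrate, n_substrate),
             rep(paste0(substrate, "A"), n_tailed))
  aggregate_assignments(match_reads(reads, ref), sample_id = sample_id)
}
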