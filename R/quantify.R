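# Quantification: per-sample isomiR profiles, cpm, adenylation/degradation
# ratios, and precursor-region counts (the processing proxy).

#' Aggregate read assignments into a per-sample isomiR profile
#'
#' Counts assigned reads per isomiR key. Ambiguous and unassigned reads are
#' tallied in a QC sidecar, not in the profile; optionally, multi-arm
#' ambiguous reads can be included with fractional weight 1/n over their
#' candidate arms.
#'
#' @param assignments a `read_assignments` data.frame from [match_reads()].
#' @param sample_id sample identifier.
#' @param include_ambiguous include ambiguous reads at weight
#'   1/n_candidate_arms (default `FALSE`: excluded).
#' @return an `isomir_profile`: data.frame with columns `precursor_id`,
#'   `arm_name`, `offset5`, `delta3`, `tail`, `count`, plus attributes
#'   `sample_id`, `total_counted`, `qc` (named vector of
#'   assigned/ambiguous/unassigned/invalid read tallies).
#' @export
aggregate_assignments <- function(assignments, sample_id = "sample",
                                  include_ambiguous = FALSE) {
  stopifnot(inherits(assignments, "read_assignments"))
  qc <- c(assigned = sum(assignments$status == "assigned"),
          ambiguous = sum(assignments$status == "ambiguous"),
          unassigned = sum(assignments$status == "unassigned"),
          invalid = sum(assignments$reason %in% "invalid_characters"))
  a <- assignments[assignments$status == "assigned", , drop = FALSE]
  if (nrow(a)) {
    key <- paste(a$precursor_id, a$arm_name, a$offset5, a$delta3_templated,
                 a$tail, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    prof <- data.frame(
      precursor_id = vapply(parts, `[`, "", 1L),
      arm_name = vapply(parts, `[`, "", 2L),
      offset5 = as.integer(vapply(parts, `[`, "", 3L)),
      delta3 = as.integer(vapply(parts, `[`, "", 4L)),
      tail = vapply(parts, function(p) if (length(p) >= 5L) p[5L] else "", ""),
      count = as.numeric(tab), stringsAsFactors = FALSE)
  } else {
    prof <- data.frame(precursor_id = character(), arm_name = character(),
                       offset5 = integer(), delta3 = integer(),
                       tail = character(), count = numeric(),
                       stringsAsFactors = FALSE)
  }
  if (include_ambiguous) {
    amb <- attr(assignments, "ambiguous_candidates")
    if (!is.null(amb) && nrow(amb)) {
      add <- data.frame(precursor_id = amb$precursor_id,
                        arm_name = amb$arm_name, offset5 = amb$offset5,
                        delta3 = amb$delta3_templated, tail = amb$tail,
                        count = amb$n_reads / amb$n_candidate_arms,
                        stringsAsFactors = FALSE)
      prof <- merge_profile_rows(rbind(prof, add))
    }
  }
  prof <- prof[order(prof$precursor_id, prof$arm_name, prof$offset5,
                     prof$delta3, prof$tail), , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, sample_id = sample_id, total_counted = sum(prof$count),
            qc = qc, class = c("isomir_profile", "data.frame"))
}

merge_profile_rows <- function(prof) {
  key <- paste(prof$precursor_id, prof$arm_name, prof$offset5, prof$delta3,
               prof$tail, sep = "\r")
  cnt <- tapply(prof$count, key, sum)
  keep <- prof[!duplicated(key), , drop = FALSE]
  keep$count <- as.numeric(cnt[paste(keep$precursor_id, keep$arm_name,
                                     keep$offset5, keep$delta3, keep$tail,
                                     sep = "\r")])
  keep
}

#' @export
print.isomir_profile <- function(x, ...) {
  cat(sprintf("<isomir_profile> sample %s: %d keys, %.6g reads counted\n",
              attr(x, "sample_id"), nrow(x), attr(x, "total_counted")))
  qc <- attr(x, "qc")
  cat(sprintf("  QC: %s\n", paste(names(qc), qc, sep = "=", collapse = " ")))
  print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Counts-per-million normalisation of an isomiR profile
#'
#' `cpm = count * 1e6 / denominator`. With `denominator = "counted"` the
#' denominator is the profile's total counted reads, so the cpm values sum to
#' one million; a supplied library size (e.g. all genome-mapped reads) can be
#' used instead.
#'
#' @param profile an `isomir_profile`.
#' @param denominator `"counted"` or `"supplied"`.
#' @param library_size library size when `denominator = "supplied"`.
#' @return numeric vector of cpm values aligned with the profile rows.
#' @export
cpm <- function(profile, denominator = c("counted", "supplied"),
                library_size = NULL) {
  denominator <- match.arg(denominator)
  d <- if (denominator == "counted") attr(profile, "total_counted")
       else as.numeric(library_size)
  if (is.null(d) || is.na(d) || d <= 0)
    stopf("cpm denominator must be a positive number (got %s)", format(d))
  profile$count * 1e6 / d
}

#' Adenylation and degradation ratios for one arm
#'
#' Implements the tailing-and-trimming ratio pair for a mature arm, using
#' only reads with canonical 5' ends (`offset5 = 0`), since the underlying
#' 22/23/24-mer species are length-defined from a fixed 5' end:
#'
#' * substrate: the templated-extension species (`delta3 = substrate_delta3`,
#'   no tail) — the miR-21-5p "+C" 23-mer analogue;
#' * tailed: substrate plus one non-templated `tail_nt` — the "+CA" 24-mer;
#' * trimmed: the canonical-length species (`delta3 = 0`, no tail) — the
#'   22-mer.
#'
#' `adenylation_ratio = tailed/substrate`;
#' `degradation_ratio = trimmed/substrate`. With zero substrate both ratios
#' are undefined and returned as `NA` (never 0); longer tails are excluded
#' from the numerator and reported separately in the profile. Both ratios are
#' invariant under rescaling of all counts, so raw counts and cpm give
#' identical ratios.
#'
#' @param profile an `isomir_profile`.
#' @param precursor_id,arm_name which arm to summarise.
#' @param substrate_delta3 templated extension of the substrate (nt, default
#'   +1, the "+C" species).
#' @param tail_nt the non-templated nucleotide of the tailed species
#'   (default `"A"`, adenylation).
#' @return a one-row data.frame of class `ratio_result`: counts of the three
#'   species and the two ratios.
#' @export
tailing_ratios <- function(profile, precursor_id, arm_name,
                           substrate_delta3 = 1L, tail_nt = "A") {
  p <- profile[profile$precursor_id == precursor_id &
               profile$arm_name == arm_name & profile$offset5 == 0L, ,
               drop = FALSE]
  pick <- function(delta3, tail) {
    i <- p$delta3 == delta3 & p$tail == tail
    if (any(i)) sum(p$count[i]) else 0
  }
  substrate <- pick(substrate_delta3, "")
  tailed <- pick(substrate_delta3, tail_nt)
  trimmed <- pick(0L, "")
  if (substrate > 0) {
    aden <- tailed / substrate
    degr <- trimmed / substrate
  } else {
    warnf("substrate species absent for %s/%s: ratios undefined",
          precursor_id, arm_name)
    aden <- NA_real_; degr <- NA_real_
  }
  structure(data.frame(sample_id = attr(profile, "sample_id") %||% NA_character_,
                       precursor_id = precursor_id, arm_name = arm_name,
                       substrate_count = substrate, tailed_count = tailed,
                       trimmed_count = trimmed, adenylation_ratio = aden,
                       degradation_ratio = degr, stringsAsFactors = FALSE),
            class = c("ratio_result", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count precursor-located reads per analysis region
#'
#' Each located read contributes 1 to the region holding the majority of its
#' bases; ties go to the 5'-most tied region. Reads overlapping no region are
#' counted in an `outside` bucket, so region counts plus `outside` equal the
#' number of located reads.
#'
#' @param intervals data.frame with 0-based half-open `start`, `end` columns
#'   (one row per located read on the precursor).
#' @param regions a [derive_regions()] result.
#' @param sample_id sample label carried into the output.
#' @return a `region_profile`: one-row data.frame with a count per region
#'   plus `outside`.
#' @export
region_counts <- function(intervals, regions, sample_id = "sample") {
  stopifnot(inherits(regions, "precursor_regions"))
  rg <- regions$regions
  nms <- names(rg)
  counts <- stats::setNames(numeric(length(nms) + 1L), c(nms, "outside"))
  if (nrow(intervals)) {
    ov <- sapply(nms, function(nm) {
      pmax(0L, pmin(intervals$end, rg[[nm]]["end"]) -
                 pmax(intervals$start, rg[[nm]]["start"]))
    })
    ov <- matrix(ov, nrow = nrow(intervals),
                 dimnames = list(NULL, nms))
    best <- apply(ov, 1L, function(o) {
      if (max(o) <= 0) return("outside")
      nms[which(o == max(o))[1L]]        # regions ordered 5'->3': first = 5'-most
    })
    tab <- table(best)
    counts[names(tab)] <- as.numeric(tab)
  }
  structure(data.frame(sample_id = sample_id,
                       precursor_id = regions$precursor_id,
                       as.list(counts), stringsAsFactors = FALSE),
            class = c("region_profile", "data.frame"))
}

#' Locate reads on a precursor by exact match
#'
#' Finds, for each read, the unique exact-match interval on the precursor
#' sequence (used to place background fragments — loop, 3p, flanks — for
#' region counting when no alignment is supplied). Reads matching nowhere or
#' in several places are dropped with a count returned in the attribute
#' `n_unlocated`.
#'
#' @param reads character vector of read sequences.
#' @param ref a [mirna_reference()].
#' @return data.frame of `start`, `end` (0-based half-open) per located read.
#' @export
locate_reads <- function(reads, ref) {
  reads <- toupper(chartr("U", "T", as.character(reads)))
  useq <- unique(reads[nzchar(reads) & !grepl("[^ACGT]", reads)])
  subj <- Biostrings::DNAString(ref$precursor_seq)
  loc <- lapply(useq, function(s) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(s), subj)
    if (length(m) == 1L) c(Biostrings::start(m) - 1L, Biostrings::end(m)) else NULL
  })
  names(loc) <- useq
  located <- !vapply(loc, is.null, TRUE)
  idx <- match(reads, useq)
  keep <- !is.na(idx)
  keep[keep] <- located[idx[keep]]
  ints <- if (any(keep)) {
    do.call(rbind, lapply(loc[idx[keep]], function(x)
      data.frame(start = x[1], end = x[2])))
  } else data.frame(start = integer(), end = integer())
  rownames(ints) <- NULL
  structure(ints, n_unlocated = sum(!keep))
}

#' Write an isomiR profile (with cpm), ratio table or region table as TSV
#'
#' @param x the object to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  df <- as.data.frame(x)
  if (inherits(x, "isomir_profile")) {
    df$cpm <- cpm(x)
    df <- cbind(sample_id = attr(x, "sample_id"), df)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
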