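# isomiR core: anchor reads to a mature arm and decompose the 3' end into
# templated extension, non-templated tail, and trimming.
#
# An isomiR key is (precursor_id, arm_name, offset5, delta3_templated, tail):
#   offset5         read 5' start minus arm start (signed; -3 = three extra
#                   upstream templated nucleotides)
#   delta3_templated signed templated 3' delta (negative = trimmed below the
#                   canonical end, positive = templated extension)
#   tail            non-templated 3' nucleotides (possibly empty)
# Identity: nchar(read) = canonical_length - offset5 + delta3_templated + nchar(tail).

#' Greedy 3' decomposition of a matched read
#'
#' Given a read whose 5' portion is anchored at `offset5` relative to the
#' arm's 5' start, walks 3'-wards along the precursor (and the arm's template
#' context past the precursor boundary) for as long as read and template
#' agree; everything that remains is the non-templated tail. A 3' nucleotide
#' that matches the template is therefore always called templated, never tail
#' (greedy templated-first rule): the 23-mer "+C" of miR-21-5p is a templated
#' extension, the final A of the 24-mer "+CA" is a tail. If the read stops
#' short of the canonical 3' end with no tail, `delta3_templated` is negative
#' (trimming).
#'
#' @param read_seq read sequence (ACGT/U).
#' @param ref a [mirna_reference()].
#' @param arm arm name or one of `ref$arms`.
#' @param offset5 signed 5' offset at which the read is anchored.
#' @return list with `delta3_templated` (integer) and `tail` (string).
#' @export
decompose_3prime <- function(read_seq, ref, arm, offset5 = 0L) {
  if (is.character(arm)) arm <- ref$arms[[arm]]
  read_seq <- normalize_seq(read_seq, "read")
  tmpl <- extended_template(ref, arm)
  p <- arm$start + as.integer(offset5)            # 0-based start on template
  stopifnot(p >= 0L, p < nchar(tmpl))
  m <- common_prefix_len(read_seq, substr(tmpl, p + 1L, nchar(tmpl)))
  list(delta3_templated = as.integer(offset5) + m - arm$canonical_length,
       tail = substr(read_seq, m + 1L, nchar(read_seq)))
}

#' Rebuild a read from its isomiR key
#'
#' Inverse of the decomposition: the arm sequence shifted by `offset5`,
#' extended or trimmed by `delta3_templated` templated nucleotides, with the
#' tail appended. Used by the invariant tests.
#'
#' @param ref a [mirna_reference()]; @param arm arm name or arm object.
#' @param offset5,delta3_templated,tail key components.
#' @return the read sequence.
#' @export
reconstruct_read <- function(ref, arm, offset5, delta3_templated, tail = "") {
  if (is.character(arm)) arm <- ref$arms[[arm]]
  tmpl <- extended_template(ref, arm)
  p <- arm$start + as.integer(offset5)
  m <- arm$canonical_length - as.integer(offset5) + as.integer(delta3_templated)
  paste0(substr(tmpl, p + 1L, p + m), if (nzchar(tail)) normalize_seq(tail) else "")
}

#' Classify an isomiR key into the field's isoform vocabulary
#'
#' * `canonical`: exact canonical-length arm sequence.
#' * `templated_extended`: 3' extension matching the template (the "+C"
#'   23-mer species).
#' * `nt_tailed`: any non-templated tail (the "+CA" 24-mer species).
#' * `trimmed`: 3' end short of the canonical end, no tail.
#' * `tailed_and_shifted`: any 5'-shifted read, regardless of 3' state.
#'
#' @param offset5,delta3_templated,tail key components (vectorised).
#' @return character vector of classes.
#' @export
classify_key <- function(offset5, delta3_templated, tail = "") {
  n <- max(length(offset5), length(delta3_templated), length(tail))
  offset5 <- rep_len(as.integer(offset5), n)
  delta3 <- rep_len(as.integer(delta3_templated), n)
  tail <- rep_len(as.character(tail), n)
  out <- character(n)
  out[offset5 != 0L] <- "tailed_and_shifted"
  z <- offset5 == 0L
  out[z & nzchar(tail)] <- "nt_tailed"
  out[z & !nzchar(tail) & delta3 > 0L] <- "templated_extended"
  out[z & !nzchar(tail) & delta3 < 0L] <- "trimmed"
  out[z & !nzchar(tail) & delta3 == 0L] <- "canonical"
  out
}

#' Assign reads to mature arms and decompose their 3' ends
#'
#' For each read, every arm of every reference is a candidate if the read
#' aligns ungapped and mismatch-free over its templated portion, starting
#' within `±max_offset5` of the arm's 5' start, with at least
#' `min_core_match` templated nucleotides. Exactly one candidate arm →
#' `assigned`; several arms → `ambiguous`; none → `unassigned`. Within one
#' arm, if several 5' offsets admit a match, the decomposition with the
#' longest templated portion wins (tie: smallest `|offset5|`, then the more
#' negative offset); offsets never make a read ambiguous, only distinct arms
#' do. Reads with non-ACGT/U characters are recorded as `unassigned` with a
#' reason, never an error.
#'
#' @param reads character vector of adapter-free read sequences (or a named
#'   vector; names become read ids).
#' @param refs a [mirna_reference()] or list of them.
#' @param max_offset5 5' offset window (nt), default ±2.
#' @param min_core_match minimum templated match length (nt), default 14.
#' @return a data.frame of class `read_assignments` with one row per read:
#'   `read_id`, `precursor_id`, `arm_name`, `offset5`, `delta3_templated`,
#'   `tail`, `status`, `n_candidate_arms`, `reason`. Ambiguous reads carry the
#'   full candidate set in `attr(, "ambiguous_candidates")`.
#' @export
match_reads <- function(reads, refs, max_offset5 = 2L, min_core_match = 14L) {
  if (inherits(refs, "mirna_reference")) refs <- list(refs)
  ids <- if (!is.null(names(reads))) names(reads)
         else sprintf("read%d", seq_along(reads))
  reads <- toupper(chartr("U", "T", as.character(reads)))
  n <- length(reads)
  if (n == 0L) {
    res <- data.frame(read_id = character(), precursor_id = character(),
                      arm_name = character(), offset5 = integer(),
                      delta3_templated = integer(), tail = character(),
                      status = character(), n_candidate_arms = integer(),
                      reason = character(), stringsAsFactors = FALSE)
    return(structure(res, class = c("read_assignments", "data.frame")))
  }
  valid <- !is.na(reads) & nzchar(reads) & !grepl("[^ACGT]", reads)
  res <- data.frame(read_id = ids, precursor_id = NA_character_,
                    arm_name = NA_character_, offset5 = NA_integer_,
                    delta3_templated = NA_integer_, tail = NA_character_,
                    status = "unassigned", n_candidate_arms = 0L,
                    reason = NA_character_, stringsAsFactors = FALSE)
  res$reason[!valid] <- "invalid_characters"
  if (!any(valid)) return(structure(res, class = c("read_assignments", "data.frame")))

  # Match unique sequences once; expand back to reads at the end.
  useq <- unique(reads[valid])
  cand <- vector("list", length(useq))   # per unique seq: candidate rows
  ulen <- nchar(useq)
  for (ref in refs) {
    for (arm in ref$arms) {
      tmpl <- extended_template(ref, arm)
      best_m <- integer(length(useq)); best_o <- integer(length(useq))
      best_m[] <- -1L
      for (o in seq.int(-max_offset5, max_offset5)) {
        p <- arm$start + o
        if (p < 0L || p >= nchar(tmpl)) next
        m <- common_prefix_len(useq, substr(tmpl, p + 1L, nchar(tmpl)))
        ok <- m >= min_core_match &
          (o + m - arm$canonical_length) >= -(arm$canonical_length - 1L)
        better <- ok & (m > best_m |
                        (m == best_m & abs(o) < abs(best_o)) |
                        (m == best_m & abs(o) == abs(best_o) & o < best_o))
        best_m[better] <- m[better]; best_o[better] <- o
      }
      hit <- which(best_m >= 0L)
      for (i in hit) {
        cand[[i]] <- c(cand[[i]], list(list(
          precursor_id = ref$precursor_id, arm_name = arm$name,
          offset5 = best_o[i],
          delta3_templated = best_o[i] + best_m[i] - arm$canonical_length,
          tail = substr(useq[i], best_m[i] + 1L, ulen[i]))))
      }
    }
  }
  ncand <- vapply(cand, length, 0L)
  idx <- match(reads[valid], useq)
  vi <- which(valid)
  res$n_candidate_arms[vi] <- ncand[idx]
  one <- ncand == 1L
  if (any(one)) {
    rows <- do.call(rbind, lapply(which(one), function(i) {
      k <- cand[[i]][[1]]
      data.frame(u = i, precursor_id = k$precursor_id, arm_name = k$arm_name,
                 offset5 = k$offset5, delta3_templated = k$delta3_templated,
                 tail = k$tail, stringsAsFactors = FALSE)
    }))
    map <- match(idx, rows$u)
    hitv <- !is.na(map)
    res$status[vi[hitv]] <- "assigned"
    for (col in c("precursor_id", "arm_name", "offset5", "delta3_templated", "tail"))
      res[[col]][vi[hitv]] <- rows[[col]][map[hitv]]
  }
  multi <- ncand > 1L
  res$status[vi[multi[idx]]] <- "ambiguous"
  res$reason[res$status == "ambiguous"] <- "multiple_arms"
  res$reason[res$status == "unassigned" & is.na(res$reason)] <- "no_match"
  amb <- NULL
  if (any(multi)) {
    amb <- do.call(rbind, lapply(which(multi), function(i) {
      do.call(rbind, lapply(cand[[i]], function(k)
        data.frame(seq = useq[i], precursor_id = k$precursor_id,
                   arm_name = k$arm_name, offset5 = k$offset5,
                   delta3_templated = k$delta3_templated, tail = k$tail,
                   n_candidate_arms = length(cand[[i]]),
                   stringsAsFactors = FALSE)))
    }))
    amb$n_reads <- as.integer(table(reads[valid])[amb$seq])
  }
  structure(res, ambiguous_candidates = amb,
            class = c("read_assignments", "data.frame"))
}

#' Assign a single read
#'
#' Convenience wrapper around [match_reads()] for one read.
#'
#' @inheritParams match_reads
#' @param read_seq a single read sequence.
#' @return a one-row `read_assignments` data.frame.
#' @export
match_read <- function(read_seq, refs, max_offset5 = 2L, min_core_match = 14L) {
  match_reads(read_seq, refs, max_offset5 = max_offset5,
              min_core_match = min_core_match)
}
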