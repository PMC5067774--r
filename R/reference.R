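# Reference module: precursor sequences + mature-arm annotation in
# precursor-relative coordinates, with 3' template context per arm.
#
# All internal coordinates are 0-based half-open and precursor-relative;
# genome strand is resolved at load time only (minus-strand GFF3 records are
# mapped into precursor orientation). Internal alphabet is DNA (ACGT); U is
# accepted on input.

#' Construct a miRNA precursor reference
#'
#' The coordinate authority for all downstream read decomposition: a precursor
#' sequence, its mature arms as 0-based half-open precursor-relative
#' intervals, and, per arm, at least 10 nt of template context immediately 3'
#' of the mature end. Context is taken from the precursor itself when the arm
#' ends inside it, and must be supplied explicitly for arms ending at (or
#' near) the precursor boundary — genomic flank handling is deliberately not
#' guessed.
#'
#' @param precursor_id identifier string.
#' @param precursor_seq precursor sequence (DNA or RNA alphabet).
#' @param arms a data.frame with columns `arm_name`, `start`, `end` and
#'   optionally `template_context`.
#' @param min_context minimum template context length per arm (nt).
#' @return an object of class `mirna_reference`.
#' @export
mirna_reference <- function(precursor_id, precursor_seq, arms,
                            min_context = 10L) {
  precursor_seq <- normalize_seq(precursor_seq,
                                 sprintf("precursor %s", precursor_id))
  plen <- nchar(precursor_seq)
  stopifnot(is.data.frame(arms),
            all(c("arm_name", "start", "end") %in% names(arms)))
  if (anyDuplicated(arms$arm_name))
    stopf("duplicate arm names for precursor %s", precursor_id)
  arm_list <- vector("list", nrow(arms))
  for (i in seq_len(nrow(arms))) {
    a <- arms[i, ]
    start <- as.integer(a$start); end <- as.integer(a$end)
    if (is.na(start) || is.na(end) || start < 0L || end > plen || start >= end)
      stopf("arm %s interval [%s,%s) outside precursor %s (length %d)",
            a$arm_name, a$start, a$end, precursor_id, plen)
    clen <- end - start
    if (clen < 16L || clen > 30L)
      stopf("arm %s canonical length %d outside 16-30 nt", a$arm_name, clen)
    internal_ctx <- if (end < plen) substr(precursor_seq, end + 1L, plen) else ""
    supplied <- if ("template_context" %in% names(a) &&
                    !is.na(a$template_context) && nzchar(a$template_context))
      normalize_seq(a$template_context,
                    sprintf("template context of %s", a$arm_name)) else ""
    # The precursor is authoritative where it covers the context; a supplied
    # context may only extend it past the precursor boundary.
    if (nzchar(supplied)) {
      ov <- min(nchar(supplied), nchar(internal_ctx))
      if (ov > 0L && substr(supplied, 1L, ov) != substr(internal_ctx, 1L, ov))
        stopf("supplied template context for %s disagrees with precursor %s",
              a$arm_name, precursor_id)
      ctx <- if (nchar(supplied) >= nchar(internal_ctx)) supplied else internal_ctx
    } else ctx <- internal_ctx
    if (nchar(ctx) < min_context)
      stopf("arm %s of %s has %d nt of template context (< %d); supply it explicitly for boundary arms",
            a$arm_name, precursor_id, nchar(ctx), min_context)
    arm_list[[i]] <- list(name = as.character(a$arm_name), start = start,
                          end = end, canonical_length = clen,
                          template_context = ctx)
  }
  names(arm_list) <- vapply(arm_list, `[[`, "", "name")
  is5 <- grepl("5p$", names(arm_list)); is3 <- grepl("3p$", names(arm_list))
  if (any(is5) && any(is3)) {
    if (arm_list[[which(is5)[1]]]$start >= arm_list[[which(is3)[1]]]$start)
      stopf("5p arm must start before 3p arm in precursor %s", precursor_id)
  }
  structure(list(precursor_id = precursor_id, precursor_seq = precursor_seq,
                 arms = arm_list),
            class = "mirna_reference")
}

#' @export
print.mirna_reference <- function(x, ...) {
  cat(sprintf("<mirna_reference> %s (%d nt)\n", x$precursor_id,
              nchar(x$precursor_seq)))
  for (a in x$arms)
    cat(sprintf("  arm %-16s [%d,%d) %d nt, context %s...\n", a$name,
                a$start, a$end, a$canonical_length,
                substr(a$template_context, 1L, 6L)))
  invisible(x)
}

# Precursor sequence extended past its 3' boundary by an arm's supplied
# context, so greedy templated matching can run off the precursor end.
extended_template <- function(ref, arm) {
  plen <- nchar(ref$precursor_seq)
  beyond <- if (arm$end < plen) {
    internal <- plen - arm$end
    if (nchar(arm$template_context) > internal)
      substr(arm$template_context, internal + 1L, nchar(arm$template_context))
    else ""
  } else arm$template_context
  paste0(ref$precursor_seq, beyond)
}

arm_seq <- function(ref, arm) substr(ref$precursor_seq, arm$start + 1L, arm$end)

#' Load miRNA references from FASTA plus annotation
#'
#' Reads precursor sequences from a FASTA file and mature-arm intervals from
#' either a miRBase-dialect GFF3 (features `miRNA_primary_transcript` and
#' `miRNA`, genomic 1-based inclusive coordinates, minus-strand records mapped
#' into precursor orientation) or a simple TSV with columns `precursor_id`,
#' `arm_name`, `start`, `end` (0-based half-open, precursor-relative) and
#' optional `template_context`.
#'
#' @param precursor_fasta path to precursor FASTA.
#' @param annotation path to GFF3 or TSV annotation.
#' @param dialect `"gff3"` or `"tsv"`.
#' @return a named list of [mirna_reference()] objects.
#' @export
load_reference <- function(precursor_fasta, annotation,
                           dialect = c("tsv", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(precursor_fasta)) stopf("missing FASTA: %s", precursor_fasta)
  if (!file.exists(annotation)) stopf("missing annotation: %s", annotation)
  seqs <- Biostrings::readDNAStringSet(precursor_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- if (dialect == "tsv") read_arm_tsv(annotation) else read_arm_gff3(annotation)
  refs <- list()
  for (pid in unique(ann$precursor_id)) {
    if (!pid %in% names(seqs))
      stopf("annotated precursor %s missing from FASTA", pid)
    refs[[pid]] <- mirna_reference(pid, as.character(seqs[[pid]]),
                                   ann[ann$precursor_id == pid, , drop = FALSE])
  }
  refs
}

read_arm_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("precursor_id", "arm_name", "start", "end")
  if (!all(need %in% names(tab)))
    stopf("annotation TSV needs columns %s", paste(need, collapse = ", "))
  tab
}

# miRBase-dialect GFF3: genomic coordinates; each miRNA feature is located
# inside its miRNA_primary_transcript and converted to precursor-relative
# 0-based half-open coordinates (strand-aware).
read_arm_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  pre <- gr[type == "miRNA_primary_transcript"]
  mat <- gr[type == "miRNA"]
  if (length(pre) == 0L || length(mat) == 0L)
    stopf("GFF3 %s lacks miRNA_primary_transcript/miRNA features", path)
  pre_name <- if (!is.null(pre$Name)) as.character(pre$Name) else as.character(pre$ID)
  out <- vector("list", length(mat))
  for (i in seq_along(mat)) {
    m <- mat[i]
    parent <- if (!is.null(m$Derives_from) && !is.na(m$Derives_from[1]))
      as.character(m$Derives_from[1]) else NA_character_
    j <- if (!is.na(parent)) {
      match(parent, as.character(pre$ID))
    } else {
      which(as.logical(GenomicRanges::seqnames(pre) == GenomicRanges::seqnames(m)) &
            GenomicRanges::start(pre) <= GenomicRanges::start(m) &
            GenomicRanges::end(pre) >= GenomicRanges::end(m))[1]
    }
    if (is.na(j)) stopf("miRNA feature %s has no containing precursor",
                        as.character(m$Name))
    strand <- as.character(GenomicRanges::strand(pre[j]))
    if (strand == "-") {
      start0 <- GenomicRanges::end(pre[j]) - GenomicRanges::end(m)
      end0 <- GenomicRanges::end(pre[j]) - GenomicRanges::start(m) + 1L
    } else {
      start0 <- GenomicRanges::start(m) - GenomicRanges::start(pre[j])
      end0 <- GenomicRanges::end(m) - GenomicRanges::start(pre[j]) + 1L
    }
    out[[i]] <- data.frame(precursor_id = pre_name[j],
                           arm_name = as.character(m$Name),
                           start = start0, end = end0,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write references back to the TSV annotation dialect
#'
#' @param refs list of [mirna_reference()] objects.
#' @param path output TSV path.
#' @return `path`, invisibly. Reloading the TSV (with the same FASTA)
#'   reproduces the references exactly.
#' @export
write_reference_tsv <- function(refs, path) {
  rows <- do.call(rbind, lapply(refs, function(r) {
    do.call(rbind, lapply(r$arms, function(a) {
      plen <- nchar(r$precursor_seq)
      beyond <- if (a$end < plen && nchar(a$template_context) <= plen - a$end)
        "" else a$template_context
      data.frame(precursor_id = r$precursor_id, arm_name = a$name,
                 start = a$start, end = a$end, template_context = beyond,
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Partition a precursor into analysis regions
#'
#' Splits a precursor into the five sub-regions used as the miRNA-processing
#' proxy: fragments upstream of the 5p arm, the mature 5p arm, the pre-miRNA
#' loop (the gap between the arms), the mature 3p arm, and fragments
#' downstream of 3p. Any region may be empty (zero width).
#'
#' @param ref a [mirna_reference()].
#' @return an object of class `precursor_regions`: a named list of
#'   `c(start, end)` 0-based half-open intervals.
#' @export
derive_regions <- function(ref) {
  stopifnot(inherits(ref, "mirna_reference"), length(ref$arms) >= 1L)
  plen <- nchar(ref$precursor_seq)
  i5 <- grep("5p$", names(ref$arms)); i3 <- grep("3p$", names(ref$arms))
  a5 <- if (length(i5)) ref$arms[[i5[1]]] else NULL
  a3 <- if (length(i3)) ref$arms[[i3[1]]] else NULL
  if (is.null(a5) && is.null(a3)) a5 <- ref$arms[[1]]
  if (!is.null(a5) && !is.null(a3) && a5$end > a3$start)
    stopf("overlapping arms in precursor %s", ref$precursor_id)
  iv <- function(s, e) c(start = as.integer(s), end = as.integer(max(s, e)))
  regions <- list(
    upstream_of_5p = if (!is.null(a5)) iv(0L, a5$start)
                     else iv(0L, a3$start),
    mature_5p      = if (!is.null(a5)) iv(a5$start, a5$end) else iv(0L, 0L),
    loop           = if (!is.null(a5) && !is.null(a3)) iv(a5$end, a3$start)
                     else iv(0L, 0L),
    mature_3p      = if (!is.null(a3)) iv(a3$start, a3$end) else iv(0L, 0L),
    downstream_of_3p = if (!is.null(a3)) iv(a3$end, plen)
                       else if (!is.null(a5)) iv(a5$end, plen) else iv(0L, 0L)
  )
  if (is.null(a3) && !is.null(a5)) regions$loop <- iv(a5$end, a5$end)
  structure(list(precursor_id = ref$precursor_id, plen = plen,
                 regions = regions),
            class = "precursor_regions")
}

#' @export
print.precursor_regions <- function(x, ...) {
  cat(sprintf("<precursor_regions> %s (%d nt)\n", x$precursor_id, x$plen))
  for (nm in names(x$regions)) {
    r <- x$regions[[nm]]
    cat(sprintf("  %-17s [%d,%d)\n", nm, r["start"], r["end"]))
  }
  invisible(x)
}
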