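# End-to-end pipeline: FASTQ/SAM in, isomiR/ratio/region/QC tables out, plus
# a run manifest; and the two-group comparison stage on top.

#' Build and validate a pipeline run configuration
#'
#' @param reference either a list of [mirna_reference()] objects or a list
#'   `list(fasta =, annotation =, dialect =)` of annotation paths.
#' @param samples data.frame with columns `sample_id`, `path` and optional
#'   `format` (`"fastq"`/`"sam"`, default fastq), or a named character vector
#'   of FASTQ paths.
#' @param metadata optional metadata data.frame (`sample_id`, `group`) or TSV
#'   path, needed by [run_compare()].
#' @param out_dir optional output directory for TSV/JSON results.
#' @param max_offset5,min_core_match matcher settings (see [match_reads()]).
#' @param substrate_delta3,tail_nt ratio settings (see [tailing_ratios()]).
#' @param contrast character of length 2, the group contrast for
#'   [run_compare()].
#' @param adjust `"none"` or `"benjamini_hochberg"`.
#' @param max_skip_frac maximum tolerated fraction of per-sample rejected
#'   (unparseable) reads before a hard error (default 0.1).
#' @return a validated `run_config` list.
#' @export
run_config <- function(reference, samples, metadata = NULL, out_dir = NULL,
                       max_offset5 = 2L, min_core_match = 14L,
                       substrate_delta3 = 1L, tail_nt = "A",
                       contrast = NULL, adjust = "none",
                       max_skip_frac = 0.1) {
  if (is.character(samples))
    samples <- data.frame(sample_id = names(samples) %||%
                            sprintf("sample%d", seq_along(samples)),
                          path = unname(samples), stringsAsFactors = FALSE)
  if (!"format" %in% names(samples))
    samples$format <- rep("fastq", nrow(samples))
  for (p in samples$path)
    if (!file.exists(p)) stopf("sample file missing: %s", p)
  if (is.list(reference) && !inherits(reference[[1]], "mirna_reference")) {
    for (p in c(reference$fasta, reference$annotation))
      if (!file.exists(p)) stopf("reference file missing: %s", p)
  }
  if (is.character(metadata)) {
    if (!file.exists(metadata)) stopf("metadata file missing: %s", metadata)
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  structure(list(reference = reference, samples = samples,
                 metadata = metadata, out_dir = out_dir,
                 max_offset5 = max_offset5, min_core_match = min_core_match,
                 substrate_delta3 = substrate_delta3, tail_nt = tail_nt,
                 contrast = contrast, adjust = adjust,
                 max_skip_frac = max_skip_frac),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' A single-file description of a run: top-level keys mirror the
#' [run_config()] arguments (`reference:` with `fasta`/`annotation`/`dialect`,
#' `samples:` either a path to a sample-sheet TSV or an inline list of
#' `sample_id`/`path`/`format` records, plus matcher/ratio/stats settings).
#' Arguments passed through `...` override the file's values.
#'
#' @param path YAML file.
#' @param ... overrides forwarded to [run_config()].
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stopf("missing config file: %s", path)
  y <- yaml::read_yaml(path)
  if (is.character(y$samples) && length(y$samples) == 1L &&
      file.exists(y$samples) && grepl("\\.tsv$", y$samples))
    y$samples <- utils::read.delim(y$samples, stringsAsFactors = FALSE)
  else if (is.list(y$samples) && !is.data.frame(y$samples))
    y$samples <- do.call(rbind, lapply(y$samples, as.data.frame))
  if (!is.null(y$contrast)) y$contrast <- as.character(y$contrast)
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y[intersect(names(y), names(formals(run_config)))])
}

resolve_reference <- function(reference) {
  if (is.list(reference) && length(reference) &&
      inherits(reference[[1]], "mirna_reference")) return(reference)
  if (inherits(reference, "mirna_reference")) return(list(reference))
  load_reference(reference$fasta, reference$annotation,
                 dialect = reference$dialect %||% "tsv")
}

#' Read small RNA reads from FASTQ or SAM
#'
#' FASTQ is parsed with Biostrings; SAM via Rsamtools (converted in a
#' temporary directory). Only read id and sequence are used — decomposition
#' is always recomputed locally against the precursor, never taken from the
#' alignment.
#'
#' @param path input file. @param format `"fastq"` or `"sam"`.
#' @return named character vector of read sequences.
#' @export
read_reads <- function(path, format = c("fastq", "sam")) {
  format <- match.arg(format)
  if (format == "fastq") {
    if (file.size(path) == 0L) return(stats::setNames(character(0), character(0)))
    x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                  error = function(e)
                    stopf("malformed FASTQ %s: %s", path, conditionMessage(e)))
    stats::setNames(as.character(x), names(x))
  } else {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    res <- Rsamtools::scanBam(bam,
      param = Rsamtools::ScanBamParam(what = c("qname", "seq")))[[1]]
    stats::setNames(as.character(res$seq), res$qname)
  }
}

#' Quantify isomiRs, ratios and regions for every sample of a run
#'
#' For each sample: read → match to arms → aggregate into an isomiR profile
#' → tailing ratios per arm → region counts (assigned reads via their
#' templated footprint, unassigned reads located by exact precursor match).
#' Reads that fail to parse as nucleotide sequences are skipped and counted;
#' a sample with more than `max_skip_frac` such reads is a hard error.
#' Results are deterministic for fixed inputs; with `out_dir` set, combined
#' TSV tables (`isomirs.tsv`, `ratios.tsv`, `regions.tsv`, `qc.tsv`) and a
#' run manifest (`manifest.json`: package version, config hash, input
#' checksums, per-sample read counters) are written.
#'
#' @param config a [run_config()].
#' @return list with `profiles`, `ratios`, `regions`, `qc`, `manifest`.
#' @export
run_quantify <- function(config) {
  stopifnot(inherits(config, "run_config"))
  refs <- resolve_reference(config$reference)
  names(refs) <- vapply(refs, function(r) r$precursor_id, "")
  regions <- lapply(refs, derive_regions)
  profiles <- list(); ratio_rows <- list(); region_rows <- list()
  qc_rows <- list()
  for (i in seq_len(nrow(config$samples))) {
    sid <- config$samples$sample_id[i]
    reads <- read_reads(config$samples$path[i], config$samples$format[i])
    asg <- match_reads(reads, refs, max_offset5 = config$max_offset5,
                       min_core_match = config$min_core_match)
    n_bad <- sum(asg$reason %in% "invalid_characters")
    if (length(reads) && n_bad / length(reads) > config$max_skip_frac)
      stopf("sample %s: %d/%d reads rejected (limit %.0f%%)", sid, n_bad,
            length(reads), 100 * config$max_skip_frac)
    if (n_bad > 0)
      warnf("sample %s: skipped %d unparseable read(s)", sid, n_bad)
    prof <- aggregate_assignments(asg, sample_id = sid)
    profiles[[sid]] <- prof
    for (ref in refs) {
      for (arm in ref$arms) {
        rr <- suppressWarnings(
          tailing_ratios(prof, ref$precursor_id, arm$name,
                         substrate_delta3 = config$substrate_delta3,
                         tail_nt = config$tail_nt))
        ratio_rows[[length(ratio_rows) + 1L]] <- rr
      }
      region_rows[[length(region_rows) + 1L]] <-
        region_counts(sample_intervals(asg, reads, ref),
                      regions[[ref$precursor_id]], sample_id = sid)
    }
    qc <- attr(prof, "qc")
    qc_rows[[sid]] <- data.frame(sample_id = sid, reads_in = length(reads),
                                 t(qc), stringsAsFactors = FALSE)
  }
  ratios <- do.call(rbind, ratio_rows)
  regions_tab <- do.call(rbind, region_rows)
  qc_tab <- do.call(rbind, qc_rows)
  rownames(ratios) <- rownames(regions_tab) <- rownames(qc_tab) <- NULL
  manifest <- build_manifest(config, qc_tab)
  if (!is.null(config$out_dir)) {
    iso <- do.call(rbind, lapply(profiles, function(p) {
      d <- as.data.frame(p)
      d <- cbind(sample_id = rep(attr(p, "sample_id"), nrow(d)), d)
      d$cpm <- if (nrow(d)) cpm(p) else numeric(0)
      d
    }))
    wt <- function(d, f) utils::write.table(
      d, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(iso, "isomirs.tsv"); wt(ratios, "ratios.tsv")
    wt(regions_tab, "regions.tsv"); wt(qc_tab, "qc.tsv")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(profiles = profiles, ratios = ratios, regions = regions_tab,
       qc = qc_tab, manifest = manifest)
}

# Precursor intervals for region counting: assigned reads contribute their
# templated footprint; other reads are placed by unique exact match.
sample_intervals <- function(asg, reads, ref) {
  a <- asg[asg$status == "assigned" & asg$precursor_id == ref$precursor_id, ,
           drop = FALSE]
  ints <- NULL
  if (nrow(a)) {
    arm_start <- vapply(a$arm_name, function(n) ref$arms[[n]]$start, 0L)
    arm_len <- vapply(a$arm_name, function(n) ref$arms[[n]]$canonical_length, 0L)
    start <- arm_start + a$offset5
    end <- pmin(start + arm_len - a$offset5 + a$delta3_templated,
                nchar(ref$precursor_seq))
    ints <- data.frame(start = start, end = end)
  }
  other <- asg$status != "assigned" & !(asg$reason %in% "invalid_characters")
  if (any(other)) {
    loc <- locate_reads(reads[other], ref)
    if (nrow(loc)) ints <- rbind(ints, loc[, c("start", "end")])
  }
  if (is.null(ints)) data.frame(start = integer(), end = integer()) else ints
}

build_manifest <- function(config, qc_tab) {
  cfg <- config[setdiff(names(config), c("reference", "metadata"))]
  tmp <- tempfile(); on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE), tmp)
  inputs <- config$samples$path
  list(package = "isomirTT",
       version = as.character(utils::packageVersion("isomirTT")),
       timestamp = format(Sys.time(), tz = "UTC"),
       config_hash = unname(tools::md5sum(tmp)),
       input_checksums = as.list(stats::setNames(
         unname(tools::md5sum(inputs)), basename(inputs))),
       reads = as.list(stats::setNames(qc_tab$reads_in, qc_tab$sample_id)))
}

#' Compare quantified metrics between two groups
#'
#' Runs [compare_groups()] on the ratio table of a [run_quantify()] result
#' (or a ratios TSV previously written by it) for both tailing metrics, using
#' the run's metadata and contrast. Groups with fewer than two usable samples
#' yield a skipped row with a reason rather than an error. With `out_dir`
#' set, writes `comparisons.tsv`.
#'
#' @param config a [run_config()] with `metadata` and `contrast` set.
#' @param quantified a [run_quantify()] result; if `NULL`, `ratios.tsv` is
#'   read from `config$out_dir`.
#' @return a `group_comparison` data.frame (one row per arm and metric).
#' @export
run_compare <- function(config, quantified = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$metadata) || is.null(config$contrast))
    stopf("run_compare needs metadata and a contrast in the config")
  ratios <- if (!is.null(quantified)) quantified$ratios
    else utils::read.delim(file.path(config$out_dir, "ratios.tsv"),
                           stringsAsFactors = FALSE)
  out <- NULL
  for (metric in c("adenylation_ratio", "degradation_ratio")) {
    cmp <- compare_groups(ratios, config$metadata, metric,
                          contrast = config$contrast,
                          adjust = config$adjust)
    out <- rbind(out, cmp)
  }
  rownames(out) <- NULL
  if (!is.null(config$out_dir))
    utils::write.table(out, file.path(config$out_dir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  structure(out, class = c("group_comparison", "data.frame"))
}
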