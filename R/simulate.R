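# Kinetic simulator of the tailing-and-trimming pathway.
#
# Minimal three-species linear chain, a modelling choice (not a literature
# claim): the Dicer product with a templated 3' extension (the "+C" substrate)
# is produced at rate alpha; a non-canonical poly(A) polymerase (PAPD5)
# adenylates it at rate a_rate; the poly(A)-specific ribonuclease (PARN)
# trims the tailed species back to canonical length at rate t_rate (a single
# jump removing tail plus templated extension); every species decays at the
# basal rate delta. At steady state:
#
#   S_sub  = alpha / (a_rate + delta)
#   S_tail = a_rate * S_sub / (t_rate + delta)
#   S_trim = t_rate * S_tail / delta
#
# so adenylation_ratio = S_tail/S_sub = a/(t+delta) and
# degradation_ratio = S_trim/S_sub = (t/delta) * a/(t+delta), both free of
# alpha. Total mature-arm mass is alpha/delta regardless of a and t, which is
# what makes the precursor-region processing proxy clean: tailing/trimming
# redistributes 5p species without touching loop/3p/flank background.

#' A synthetic miRNA precursor for simulation and testing
#'
#' A fully synthetic 84-nt hairpin-style precursor (not any real miRNA): a
#' 22-nt 5p arm whose downstream template begins with C then G — so "+C" is a
#' templated extension and a subsequent A is necessarily a non-templated
#' tail, mirroring the miR-21-5p "+C"/"+CA" species structure — plus a 16-nt
#' loop, a 22-nt 3p arm and 12-nt flanks for region-proxy tests.
#'
#' @return a [mirna_reference()].
#' @export
synthetic_reference <- function() {
  up   <- "TGTCGGGTAGCT"
  arm5 <- "ACGATCTAGCAGGCTTAGCAAT"
  loop <- "CGTTAACGGCATTGCA"
  arm3 <- "GGCAATCCGTAGCTAGACCTTA"
  down <- "CAGTGGATCGTA"
  pre <- paste0(up, arm5, loop, arm3, down)
  arms <- data.frame(
    arm_name = c("syn-mir-1-5p", "syn-mir-1-3p"),
    start = c(nchar(up), nchar(up) + nchar(arm5) + nchar(loop)),
    end = c(nchar(up) + nchar(arm5),
            nchar(up) + nchar(arm5) + nchar(loop) + nchar(arm3)),
    template_context = c("", "CAGTGGATCG"),
    stringsAsFactors = FALSE)
  mirna_reference("syn-mir-1", pre, arms)
}

#' Define a tailing-and-trimming simulation scenario
#'
#' Rates are first-order (per unit time, arbitrary units); only their ratios
#' matter for the steady-state composition that reads are drawn from.
#'
#' @param reference a [mirna_reference()] (default [synthetic_reference()]).
#' @param arm_name the mature arm subject to tailing-and-trimming (default
#'   the reference's 5p arm).
#' @param alpha production rate of the substrate species.
#' @param a_rate adenylation rate (substrate → tailed), the PAPD5 arm.
#' @param t_rate trimming rate (tailed → canonical), the PARN arm.
#' @param delta basal decay rate of every species.
#' @param seq_error per-base substitution probability (0–0.05).
#' @param depth reads per sample.
#' @param n_samples samples per group.
#' @param bg_level steady-state abundance of each background fragment (loop,
#'   mature 3p, upstream flank, downstream flank), in the same abundance
#'   units as the mature-arm species; the background is constant across
#'   groups by construction.
#' @param substrate_delta3,tail_nt the substrate/tail definition (defaults:
#'   +1 templated nucleotide, single-A tail).
#' @param group_effects named list: group label → named numeric of
#'   multiplicative factors on `a_rate`, `t_rate` and/or `alpha` (e.g.
#'   `list(control = c(), aso = c(a_rate = 1.5, t_rate = 1.5))`). `NULL`
#'   means one unperturbed group `"control"`.
#' @param seed root seed; per-sample seeds are derived with [derive_seed()].
#' @return a `sim_scenario` list.
#' @export
sim_scenario <- function(reference = synthetic_reference(),
                         arm_name = NULL,
                         alpha = 100, a_rate = 0.2, t_rate = 0.3,
                         delta = 0.1, seq_error = 0.001, depth = 1e5,
                         n_samples = 3L, bg_level = 60,
                         substrate_delta3 = 1L, tail_nt = "A",
                         group_effects = NULL, seed = 1L) {
  if (is.null(arm_name))
    arm_name <- names(reference$arms)[grep("5p$", names(reference$arms))[1]]
  stopifnot(alpha > 0, a_rate > 0, t_rate > 0, delta > 0,
            seq_error >= 0, seq_error <= 0.05, depth >= 1,
            arm_name %in% names(reference$arms))
  if (is.null(group_effects)) group_effects <- list(control = c())
  structure(list(reference = reference, arm_name = arm_name, alpha = alpha,
                 a_rate = a_rate, t_rate = t_rate, delta = delta,
                 seq_error = seq_error, depth = as.integer(depth),
                 n_samples = as.integer(n_samples), bg_level = bg_level,
                 substrate_delta3 = as.integer(substrate_delta3),
                 tail_nt = tail_nt, group_effects = group_effects,
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "<sim_scenario> %s/%s alpha=%g a=%g t=%g delta=%g err=%g depth=%d n=%d groups=%s\n",
    x$reference$precursor_id, x$arm_name, x$alpha, x$a_rate, x$t_rate,
    x$delta, x$seq_error, x$depth, x$n_samples,
    paste(names(x$group_effects), collapse = ",")))
  invisible(x)
}

apply_effects <- function(scn, effects) {
  for (nm in names(effects)) {
    stopifnot(nm %in% c("a_rate", "t_rate", "alpha", "delta"))
    scn[[nm]] <- scn[[nm]] * effects[[nm]]
  }
  scn
}

#' Closed-form steady state of the tailing-and-trimming chain
#'
#' Solves the three linear balance equations of the kinetic model: substrate
#' produced at `alpha` and leaving at `a_rate + delta`; tailed species fed by
#' adenylation and leaving at `t_rate + delta`; canonical (trimmed) species
#' fed by trimming and leaving at `delta`.
#'
#' @param scn a [sim_scenario()].
#' @return a `sim_truth` list: `S_sub`, `S_tail`, `S_trim` abundances,
#'   `adenylation_ratio` (= a/(t+delta)) and `degradation_ratio`
#'   (= (t/delta)·a/(t+delta)); both ratios are independent of `alpha`.
#' @export
steady_state <- function(scn) {
  S_sub <- scn$alpha / (scn$a_rate + scn$delta)
  S_tail <- scn$a_rate * S_sub / (scn$t_rate + scn$delta)
  S_trim <- scn$t_rate * S_tail / scn$delta
  structure(list(S_sub = S_sub, S_tail = S_tail, S_trim = S_trim,
                 adenylation_ratio = S_tail / S_sub,
                 degradation_ratio = S_trim / S_sub),
            class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("<sim_truth> S_sub=%.4g S_tail=%.4g S_trim=%.4g aden=%.4g degr=%.4g\n",
              x$S_sub, x$S_tail, x$S_trim, x$adenylation_ratio,
              x$degradation_ratio))
  invisible(x)
}

# Species table: sequence and steady-state abundance of every simulated
# species (three mature-arm species + constant background fragments).
sim_species <- function(scn) {
  ref <- scn$reference
  arm <- ref$arms[[scn$arm_name]]
  canon <- arm_seq(ref, arm)
  substrate <- reconstruct_read(ref, arm, 0L, scn$substrate_delta3)
  tailed <- paste0(substrate, scn$tail_nt)
  ss <- steady_state(scn)
  regions <- derive_regions(ref)$regions
  bg_names <- c("loop", "mature_3p", "upstream_of_5p", "downstream_of_3p")
  bg <- lapply(bg_names, function(nm) {
    r <- regions[[nm]]
    if (r["end"] > r["start"])
      substr(ref$precursor_seq, r["start"] + 1L, r["end"]) else NA_character_
  })
  names(bg) <- paste0("bg_", bg_names)
  keep <- !vapply(bg, is.na, TRUE)
  data.frame(
    species = c("substrate", "tailed", "trimmed", names(bg)[keep]),
    seq = c(substrate, tailed, canon, unlist(bg[keep])),
    abundance = c(ss$S_sub, ss$S_tail, ss$S_trim,
                  rep(scn$bg_level, sum(keep))),
    stringsAsFactors = FALSE)
}

# Per-base substitution noise, applied in place on a character vector.
inject_errors <- function(reads, p) {
  if (p <= 0 || !length(reads)) return(reads)
  L <- nchar(reads)
  total <- sum(L)
  k <- stats::rbinom(1L, total, p)
  if (k == 0L) return(reads)
  pos <- sample.int(total, k)
  cum <- cumsum(L)
  ri <- findInterval(pos - 1L, cum) + 1L        # read index
  bi <- pos - c(0L, cum)[ri]                    # base index within read
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(k)) {
    old <- substr(reads[ri[j]], bi[j], bi[j])
    substr(reads[ri[j]], bi[j], bi[j]) <- sample(setdiff(bases, old), 1L)
  }
  reads
}

#' Simulate one small RNA-seq sample
#'
#' Draws `depth` reads multinomially from the steady-state species
#' proportions (substrate, tailed, trimmed, plus the constant background of
#' loop/3p/flank fragments), applies per-base substitution noise, and
#' optionally writes adapter-free 4-line FASTQ (constant quality). Output is
#' deterministic for a fixed `sample_seed`.
#'
#' @param scn a [sim_scenario()] (group effects already applied if any).
#' @param sample_seed integer seed for this sample.
#' @param fastq optional path; when given, reads are written as FASTQ.
#' @param sample_id read-id prefix / sample label.
#' @return list with `reads` (character vector), `species_counts` (true drawn
#'   counts per species), `truth` (the [steady_state()] record) and
#'   `fastq` (path or `NA`).
#' @export
simulate_sample <- function(scn, sample_seed = scn$seed, fastq = NULL,
                            sample_id = "sim") {
  sp <- sim_species(scn)
  reads <- with_seed(sample_seed, {
    counts <- as.vector(stats::rmultinom(1L, scn$depth,
                                         sp$abundance / sum(sp$abundance)))
    r <- rep(sp$seq, counts)
    r <- r[sample.int(length(r))]
    list(reads = inject_errors(r, scn$seq_error), counts = counts)
  })
  names(reads$counts) <- sp$species
  out <- list(reads = reads$reads, species_counts = reads$counts,
              truth = steady_state(scn), fastq = NA_character_)
  if (!is.null(fastq)) {
    write_fastq(reads$reads, fastq,
                ids = sprintf("%s_%06d", sample_id, seq_along(reads$reads)))
    out$fastq <- fastq
  }
  out
}

#' Write reads as 4-line FASTQ with constant quality
#'
#' @param reads character vector of sequences.
#' @param path output path.
#' @param ids read identifiers (default `read1..n`).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = sprintf("read%d", seq_along(reads))) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- ids
  q <- Biostrings::BStringSet(strrep("I", nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Simulate a multi-group experiment
#'
#' Applies each group's rate effects to the scenario, simulates `n_samples`
#' FASTQ samples per group with deterministically derived seeds, and emits a
#' sample sheet consumable by the pipeline plus the per-group closed-form
#' truth. With `out_dir` set, FASTQ files, a metadata TSV (`sample_id`,
#' `group`, `fastq`) and a truth JSON are written.
#'
#' @param scn a [sim_scenario()]; groups come from `scn$group_effects`.
#' @param out_dir optional output directory (created if absent).
#' @return list: `samples` (list of [simulate_sample()] results, named by
#'   sample id), `metadata` (data.frame), `truth` (per-group `sim_truth`),
#'   `scenarios` (per-group effective scenario).
#' @export
simulate_experiment <- function(scn, out_dir = NULL) {
  groups <- names(scn$group_effects)
  stopifnot(length(groups) >= 1L)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  samples <- list(); meta <- NULL
  truth <- list(); scens <- list()
  k <- 0L
  for (g in groups) {
    gs <- apply_effects(scn, scn$group_effects[[g]])
    scens[[g]] <- gs
    truth[[g]] <- steady_state(gs)
    for (i in seq_len(scn$n_samples)) {
      k <- k + 1L
      sid <- sprintf("%s_%d", g, i)
      fq <- if (!is.null(out_dir)) file.path(out_dir, paste0(sid, ".fastq"))
            else NULL
      samples[[sid]] <- simulate_sample(gs, derive_seed(scn$seed, k),
                                        fastq = fq, sample_id = sid)
      meta <- rbind(meta, data.frame(sample_id = sid, group = g,
                                     fastq = samples[[sid]]$fastq,
                                     stringsAsFactors = FALSE))
    }
  }
  if (!is.null(out_dir)) {
    utils::write.table(meta, file.path(out_dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(lapply(truth, unclass),
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(samples = samples, metadata = meta, truth = truth, scenarios = scens)
}
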