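# Group comparison of per-sample metrics (ratios, cpm, region cpm) with the
# classical two-sample pooled-variance (Student's) t-test.

#' Two-sample Student's t-test
#'
#' Classical pooled-variance two-sample t-test with a two-sided p-value
#' (Welch's unequal-variance test available behind `var_equal = FALSE`).
#' Non-finite values are dropped. Degenerate inputs (zero pooled variance)
#' are flagged rather than raised: `t` and `p` come back `NA` with
#' `degenerate = TRUE`. Groups with fewer than two finite values yield a
#' skipped result with a reason.
#'
#' @param values_a,values_b numeric vectors.
#' @param var_equal pooled variance (Student's, default) or Welch.
#' @return list with `t`, `p`, `df`, `n_a`, `n_b`, `mean_a`, `mean_b`,
#'   `degenerate`, `reason`.
#' @export
student_t <- function(values_a, values_b, var_equal = TRUE) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  out <- list(t = NA_real_, p = NA_real_, df = NA_real_,
              n_a = length(a), n_b = length(b),
              mean_a = if (length(a)) mean(a) else NA_real_,
              mean_b = if (length(b)) mean(b) else NA_real_,
              degenerate = FALSE, reason = NA_character_)
  if (length(a) < 2L || length(b) < 2L) {
    out$reason <- "insufficient_n"
    return(out)
  }
  fit <- tryCatch(stats::t.test(a, b, var.equal = var_equal),
                  error = function(e) NULL)
  if (is.null(fit)) {            # "data are essentially constant"
    out$degenerate <- TRUE
    out$reason <- "zero_variance"
    return(out)
  }
  out$t <- unname(fit$statistic)
  out$p <- fit$p.value
  out$df <- unname(fit$parameter)
  out
}

#' Compare a per-sample metric between two groups
#'
#' Generalises the tumour-subtype and ASO-vs-control comparisons: one
#' Student's t-test per (precursor, arm) on a per-sample metric table,
#' contrasting two metadata group labels. Missing (NA) metric values —
#' e.g. undefined ratios at zero substrate — are dropped per sample, never
#' treated as zero. Optional Benjamini-Hochberg adjustment across the tested
#' features.
#'
#' @param metric_table data.frame with columns `sample_id`, `precursor_id`,
#'   `arm_name`, and the metric column named by `metric` (the ratio tables
#'   from [tailing_ratios()] row-bound across samples work directly).
#' @param metadata data.frame with columns `sample_id`, `group`.
#' @param metric name of the metric column (e.g. `"adenylation_ratio"`).
#' @param contrast character of length 2: `c(group_a, group_b)`; the t
#'   statistic is for a − b.
#' @param adjust `"none"` (default, raw p-values) or `"benjamini_hochberg"`.
#' @return data.frame of class `group_comparison`: one row per
#'   (precursor, arm) with means, t, p, n, and `p_adj` when requested.
#' @export
compare_groups <- function(metric_table, metadata, metric,
                           contrast,
                           adjust = c("none", "benjamini_hochberg")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c("sample_id", "group") %in% names(metadata)),
            metric %in% names(metric_table), length(contrast) == 2L)
  missing_lab <- setdiff(contrast, unique(metadata$group))
  if (length(missing_lab))
    stopf("contrast label(s) absent from metadata: %s",
          paste(missing_lab, collapse = ", "))
  grp <- metadata$group[match(metric_table$sample_id, metadata$sample_id)]
  if (anyNA(grp))
    stopf("samples missing from metadata: %s",
          paste(unique(metric_table$sample_id[is.na(grp)]), collapse = ", "))
  feat <- unique(metric_table[, c("precursor_id", "arm_name"), drop = FALSE])
  rows <- lapply(seq_len(nrow(feat)), function(i) {
    sel <- metric_table$precursor_id == feat$precursor_id[i] &
      metric_table$arm_name == feat$arm_name[i]
    va <- metric_table[[metric]][sel & grp == contrast[1]]
    vb <- metric_table[[metric]][sel & grp == contrast[2]]
    st <- student_t(va, vb)
    data.frame(precursor_id = feat$precursor_id[i],
               arm_name = feat$arm_name[i], metric = metric,
               group_a = contrast[1], group_b = contrast[2],
               n_a = st$n_a, n_b = st$n_b, mean_a = st$mean_a,
               mean_b = st$mean_b, t = st$t, p = st$p,
               degenerate = st$degenerate, reason = st$reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (adjust == "benjamini_hochberg")
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  structure(out, class = c("group_comparison", "data.frame"))
}

#' Build a metric table of per-key cpm across samples
#'
#' For comparing the expression of a single isomiR species (e.g. substrate
#' cpm) between groups with [compare_groups()].
#'
#' @param profiles list of `isomir_profile` objects.
#' @param precursor_id,arm_name,offset5,delta3,tail the isomiR key.
#' @return data.frame `sample_id`, `precursor_id`, `arm_name`, `cpm`.
#' @export
key_cpm_table <- function(profiles, precursor_id, arm_name,
                          offset5 = 0L, delta3 = 1L, tail = "") {
  do.call(rbind, lapply(profiles, function(p) {
    v <- cpm(p)
    sel <- p$precursor_id == precursor_id & p$arm_name == arm_name &
      p$offset5 == offset5 & p$delta3 == delta3 & p$tail == tail
    data.frame(sample_id = attr(p, "sample_id"),
               precursor_id = precursor_id, arm_name = arm_name,
               cpm = if (any(sel)) sum(v[sel]) else 0,
               stringsAsFactors = FALSE)
  }))
}
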