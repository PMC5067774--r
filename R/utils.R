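# Internal helpers shared across modules.

#' Normalise a nucleotide string to the internal DNA alphabet
#'
#' Sequences are stored internally in the DNA alphabet (ACGT); `U` is accepted
#' on input and mapped to `T`. Use [as_rna()] to emit RNA on request.
#'
#' @param x character vector of sequences.
#' @param what label used in error messages.
#' @return upper-case DNA-alphabet character vector.
#' @keywords internal
normalize_seq <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%s contains non-ACGT/U characters: %s",
                 what, paste(utils::head(x[bad], 3), collapse = ", ")),
         call. = FALSE)
  }
  x
}

#' Emit a sequence in the RNA alphabet
#' @param x character vector of DNA-alphabet sequences.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", toupper(x))

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Derive a per-sample seed from a root seed
#'
#' One root seed governs a whole simulated experiment; per-sample seeds are
#' derived deterministically from `(root, index)` so any sample can be
#' regenerated in isolation. Values stay below 2^31.
#'
#' @param root integer root seed.
#' @param index non-negative integer (sample index).
#' @return integer seed.
#' @export
derive_seed <- function(root, index) {
  m <- 2147483647
  as.integer((((as.numeric(root) %% m) * 48271) %% m + 1009 * as.numeric(index)) %% m)
}

# Vectorised longest common prefix length between each read and one template.
common_prefix_len <- function(reads, template) {
  n <- length(reads)
  if (n == 0L) return(integer(0))
  maxk <- min(max(nchar(reads)), nchar(template))
  m <- integer(n)
  alive <- rep(TRUE, n)
  for (k in seq_len(maxk)) {
    tk <- substr(template, k, k)
    alive[alive] <- substr(reads[alive], k, k) == tk
    if (!any(alive)) break
    m[alive] <- k
  }
  m
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
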