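# Internal helpers shared across modules. Intervals are 1-based closed
# (the IRanges convention); conversion from other conventions happens only
# at format boundaries (BLAST tabular input, FASTA description output).

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to RNA alphabet
#'
#' Uppercases and converts T to U. Characters outside A/C/G/U/N are
#' rejected.
#'
#' @param x character vector of sequences.
#' @return character vector in RNA alphabet.
#' @export
to_rna <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside A/C/G/U/T/N: ",
         paste(utils::head(which(bad), 3L), collapse = ", "))
  }
  x
}

#' Reverse complement of an RNA or DNA string
#'
#' @param x character vector of sequences (RNA alphabet after [to_rna()]).
#' @return character vector of reverse complements, in RNA alphabet.
#' @export
rev_comp <- function(x) {
  x <- to_rna(x)
  vapply(x, function(s) {
    chartr("ACGUN", "UGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a base seed (kept below 2^31).
child_seed <- function(seed, k) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
}

stopifnot_scalar_seq <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop("expected a single non-empty sequence string")
  }
}

# interval helpers (1-based closed, stored as c(start, end))
iv_len <- function(iv) iv[2] - iv[1] + 1L
iv_contains <- function(outer, inner) outer[1] <= inner[1] && inner[2] <= outer[2]
iv_overlaps <- function(a, b) a[1] <= b[2] && b[1] <= a[2]
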