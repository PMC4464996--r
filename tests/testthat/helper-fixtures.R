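# Shared fixtures. The heavier objects (reference descriptor table and the
# cutoffs derived from it) are built once per test run and memoised here.

fixture_env <- new.env(parent = emptyenv())

# cutoffs derived from a moderate reference population; unit tests use
# this, the acceptance test derives its own from 1000 precursors
fixture_cutoffs <- function() {
  if (is.null(fixture_env$cutoffs)) {
    ref <- make_reference_set(300, seed = 11)
    fixture_env$cutoffs <- derive_cutoffs(descriptor_table(ref))
  }
  fixture_env$cutoffs
}

fixture_catalog <- function() {
  if (is.null(fixture_env$catalog)) {
    fams <- list(
      MIRX = vapply(make_family(3, "UUG", seed = 5), `[[`, character(1),
                    "seq"),
      MIRY = vapply(make_family(3, "AUG", seed = 6), `[[`, character(1),
                    "seq"))
    fixture_env$catalog <- build_catalog(fams)
  }
  fixture_env$catalog
}

# window row (the precursor itself) for criteria checks
as_window <- function(p) {
  data.frame(seq = p$seq, mature_start = p$mature_span[1],
             mature_end = p$mature_span[2], length = nchar(p$seq),
             start = 1L, subject_id = "fixture", end = nchar(p$seq),
             strand = "+", stringsAsFactors = FALSE)
}

# strong-stem fixture for the duplex-mismatch ablation: 24-nt mature,
# deep GC-rich stem, five star substitutions on a spacing-3 grid with a
# sixth site left free
ablation_spec <- function(seed = 1L, motif = "UUG") {
  hairpin_spec(seed = seed, mature_len = 24L, pad_len = 12L,
               gc_bias = 0.65, stem_mismatches = 5L,
               sub_sites = c(4L, 7L, 10L, 13L, 16L),
               signature_motif = motif)
}

# add one more pair-breaking substitution at star position `site`
add_star_mismatch <- function(p, site = 19L) {
  chars <- strsplit(p$seq, "")[[1]]
  ml <- p$spec$mature_len
  f <- ml - site + 1L
  m <- chars[p$mature_span[1] - 1L + f]
  repl <- switch(m, A = "C", C = "A", G = "A", U = "C")
  chars[p$star_span[1] - 1L + site] <- repl
  paste(chars, collapse = "")
}

# replace every occurrence of the signature motif with a neutral A/C
# pattern; returns NULL if an occurrence touches the folded stem (scrub
# would then perturb the structure, not just the signature)
scrub_motif <- function(p) {
  chars <- strsplit(p$seq, "")[[1]]
  k <- nchar(p$motif)
  body <- c(p$mature_span[1] - p$spec$pad_len - 3L,
            p$star_span[2] + p$spec$pad_len + 3L)
  repeat {
    occ <- count_motif(paste(chars, collapse = ""), p$motif)
    if (occ == 0) break
    n <- length(chars)
    starts <- which(vapply(1:(n - k + 1), function(s) {
      paste(chars[s:(s + k - 1)], collapse = "") == p$motif
    }, logical(1)))
    s <- starts[1]
    if (s + k - 1L >= body[1] && s <= body[2]) return(NULL)
    chars[s:(s + k - 1)] <- rep(c("A", "C"), length.out = k)
  }
  paste(chars, collapse = "")
}

write_temp_fasta <- function(records, ext = ".fa") {
  path <- tempfile(fileext = ext)
  write_fasta(records, path)
  path
}
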