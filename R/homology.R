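# Homology scanning of subject sequences against known mature miRNAs,
# candidate-window enumeration, and protein-coding exclusion.
#
# The scan is a full-query-coverage ungapped model: every subject placement
# of a mature query (either strand) with at most `max_mismatches`
# substitutions and at least one exact `word_size` seed is a hit. With the
# published settings (word size 7, mismatch < 4, e-value 1000) the e-value
# threshold is non-restrictive, so no alignment statistics are computed;
# externally computed tabular hits can be ingested via [read_blast_tab()].

# longest run of TRUE in a logical vector
longest_true_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Scan subjects for homologs of mature miRNA queries
#'
#' @param queries named character vector of mature miRNA sequences
#'   (U-space; names are query ids).
#' @param subjects named character vector of subject (EST/GSS) sequences;
#'   DNA or RNA alphabet, compared in U-space.
#' @param word_size minimum exact seed length.
#' @param max_mismatches maximum substitutions over the full query.
#' @return data.frame of hits: `query_id`, `subject_id`, `sstart`, `send`
#'   (1-based closed on the forward subject), `strand`, `mismatches`,
#'   `query_coverage` (always 1 under this model). Queries shorter than
#'   `word_size` are skipped with a warning.
#' @export
scan_homologs <- function(queries, subjects, word_size = 7L,
                          max_mismatches = 3L) {
  stopifnot(!is.null(names(queries)), !is.null(names(subjects)))
  queries <- to_rna(queries)
  subjects_u <- to_rna(subjects)
  short <- nchar(queries) < word_size
  if (any(short)) {
    warning("skipping ", sum(short), " query(ies) shorter than word size: ",
            paste(utils::head(names(queries)[short], 3L), collapse = ", "))
    queries <- queries[!short]
  }
  if (length(queries) == 0 || length(subjects) == 0) {
    return(empty_hits())
  }
  subj_dna <- Biostrings::DNAStringSet(chartr("U", "T", subjects_u))
  rows <- list()
  for (qi in seq_along(queries)) {
    qseq <- queries[qi]
    qlen <- nchar(qseq)
    for (str in c("+", "-")) {
      pat <- if (str == "+") qseq else rev_comp(qseq)
      pat_dna <- Biostrings::DNAString(chartr("U", "T", pat))
      mt <- Biostrings::vmatchPattern(pat_dna, subj_dna,
                                      max.mismatch = max_mismatches)
      for (si in seq_along(subj_dna)) {
        ir <- mt[[si]]
        if (length(ir) == 0) next
        sseq <- subjects_u[si]
        for (h in seq_along(ir)) {
      s <- IRanges::start(ir)[h]; e <- IRanges::end(ir)[h]
      if (s < 1 || e > nchar(sseq)) next  # out-of-range soft matches
      frag <- substring(sseq, s, e)
      qcmp <- if (str == "+") qseq else rev_comp(qseq)
      fv <- strsplit(frag, "")[[1]]
      qv <- strsplit(qcmp, "")[[1]]
      match_vec <- fv == qv
      mm <- sum(!match_vec)
      if (mm > max_mismatches) next
      if (longest_true_run(match_vec) < word_size) next
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = names(queries)[qi], subject_id = names(subjects)[si],
        sstart = s, send = e, strand = str, mismatches = mm,
        query_coverage = 1, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_hits())
  hits <- do.call(rbind, rows)
  key <- paste(hits$query_id, hits$subject_id, hits$sstart, hits$send,
               hits$strand)
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits <- hits[order(hits$subject_id, hits$sstart, hits$query_id,
                     hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             sstart = integer(), send = integer(), strand = character(),
             mismatches = integer(), query_coverage = numeric(),
             stringsAsFactors = FALSE)
}

#' Enumerate candidate precursor windows around a hit
#'
#' All subject windows of each length in `[min_len, max_len]` (stepped by
#' `stride` in both length and offset) that contain the full hit span and
#' lie within the subject. The mature span is recomputed in window
#' coordinates; for minus-strand hits the window sequence is the reverse
#' complement of the subject slice and coordinates refer to that
#' orientation.
#'
#' @param subject_seq the full subject sequence (U-space or DNA).
#' @param hit one row of the [scan_homologs()] data.frame.
#' @param min_len,max_len window length range (nt).
#' @param stride step in window length and offset (1 = exhaustive).
#' @return data.frame of windows: `subject_id`, `start`, `end` (subject
#'   coordinates, 1-based closed, forward strand), `strand`, `length`,
#'   `seq` (window RNA, hit orientation), `mature_start`, `mature_end`
#'   (window coordinates).
#' @export
enumerate_windows <- function(subject_seq, hit, min_len = 55L,
                              max_len = 505L, stride = 1L) {
  subject_seq <- to_rna(subject_seq)
  n <- nchar(subject_seq)
  hs <- hit$sstart; he <- hit$send
  stopifnot(hs >= 1, he <= n, hs <= he)
  hit_len <- he - hs + 1L
  out <- list()
  if (n < min_len || hit_len > max_len) return(empty_windows())
  for (len in seq(min_len, min(max_len, n), by = stride)) {
    if (len < hit_len) next
    s_lo <- max(1L, he - len + 1L)
    s_hi <- min(hs, n - len + 1L)
    if (s_hi < s_lo) next
    for (s in seq(s_lo, s_hi, by = stride)) {
      e <- s + len - 1L
      frag <- substring(subject_seq, s, e)
      if (hit$strand == "+") {
        wseq <- frag
        ms <- hs - s + 1L
        me <- he - s + 1L
      } else {
        wseq <- rev_comp(frag)
        ms <- e - he + 1L
        me <- e - hs + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        subject_id = hit$subject_id, start = s, end = e,
        strand = hit$strand, length = len, seq = wseq,
        mature_start = ms, mature_end = me, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(empty_windows())
  win <- do.call(rbind, out)
  rownames(win) <- NULL
  win
}

empty_windows <- function() {
  data.frame(subject_id = character(), start = integer(), end = integer(),
             strand = character(), length = integer(), seq = character(),
             mature_start = integer(), mature_end = integer(),
             stringsAsFactors = FALSE)
}

# --- protein-coding exclusion -------------------------------------------

# Translate all six reading frames of an RNA sequence into amino-acid
# strings (stops as '*').
translate_frames <- function(seq) {
  seq <- to_rna(seq)
  dna <- chartr("U", "T", seq)
  strands <- c(dna, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(dna))))
  out <- character(0)
  for (s in strands) {
    for (off in 0:2) {
      sub <- substring(s, off + 1, nchar(s) - (nchar(s) - off) %% 3)
      if (nchar(sub) < 3) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(sub), if.fuzzy.codon = "X")))
      out <- c(out, aa)
    }
  }
  out
}

# Does any ungapped local alignment of `aa` against `protein` reach
# `min_identity_pct` identity over at least `min_aln_aa` residues?
has_protein_similarity <- function(aa, protein, min_identity_pct = 80,
                                   min_aln_aa = 20L) {
  la <- nchar(aa); lp <- nchar(protein)
  if (la < min_aln_aa || lp < min_aln_aa) return(FALSE)
  av <- strsplit(aa, "")[[1]]
  pv <- strsplit(protein, "")[[1]]
  for (d in (-(lp - min_aln_aa)):(la - min_aln_aa)) {
    ai <- max(1L, 1L + d):min(la, lp + d)
    pi_ <- ai - d
    m <- av[ai] == pv[pi_]
    L <- length(m)
    if (L < min_aln_aa) next
    cs <- c(0, cumsum(m))
    for (st in 1:(L - min_aln_aa + 1L)) {
      for (en in (st + min_aln_aa - 1L):L) {
        matches <- cs[en + 1L] - cs[st]
        if (matches / (en - st + 1L) * 100 >= min_identity_pct) return(TRUE)
      }
    }
  }
  FALSE
}

#' Remove candidate windows with protein-coding similarity
#'
#' A candidate is rejected if any of its six reading-frame translations
#' contains an ungapped local alignment to any supplied protein with at
#' least `min_identity_pct` identity over at least `min_aln_aa` aligned
#' residues (the screening analogue of an ungapped BLASTX at an 80%
#' identity cutoff). Alternatively, pass `hits` (a [read_blast_tab()]
#' data.frame of externally computed translated-search hits) to reject the
#' candidates named there at or above the identity threshold.
#'
#' @param candidates data.frame with columns `seq` and (for the `hits`
#'   route) an id column `candidate_id`, or a character vector of
#'   sequences.
#' @param proteins character vector of protein sequences (amino acids).
#' @param min_identity_pct identity threshold (percent).
#' @param min_aln_aa minimum aligned residues.
#' @param hits optional precomputed tabular hits; rows with
#'   `pident >= min_identity_pct` and `aln_len >= min_aln_aa` reject the
#'   matching `query_id`.
#' @return list with `kept` and `rejected` (same type as `candidates`).
#' @export
coding_filter <- function(candidates, proteins = NULL, min_identity_pct = 80,
                          min_aln_aa = 20L, hits = NULL) {
  seqs <- if (is.data.frame(candidates)) candidates$seq else candidates
  if (!is.null(hits)) {
    bad_ids <- unique(hits$query_id[hits$pident >= min_identity_pct &
                                      hits$aln_len >= min_aln_aa])
    ids <- if (is.data.frame(candidates)) candidates$candidate_id else
      names(candidates)
    reject <- ids %in% bad_ids
  } else {
    if (is.null(proteins) || length(proteins) == 0) {
      stop("coding_filter needs either proteins or precomputed hits")
    }
    proteins <- toupper(proteins)
    reject <- vapply(seqs, function(s) {
      frames <- translate_frames(s)
      any(vapply(frames, function(aa) {
        any(vapply(proteins, has_protein_similarity, logical(1), aa = aa,
                   min_identity_pct = min_identity_pct,
                   min_aln_aa = min_aln_aa))
      }, logical(1)))
    }, logical(1), USE.NAMES = FALSE)
  }
  if (is.data.frame(candidates)) {
    list(kept = candidates[!reject, , drop = FALSE],
         rejected = candidates[reject, , drop = FALSE])
  } else {
    list(kept = candidates[!reject], rejected = candidates[reject])
  }
}
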