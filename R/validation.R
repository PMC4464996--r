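# Validation statistics: confusion-matrix metrics, matching predictions
# against small-RNA reads and known miRNA sets, TPM, and relative qRT-PCR
# expression.

#' Confusion-matrix metrics
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN). A metric with a zero denominator is reported as `NA`
#' (undefined), never 0.
#'
#' @param tp,tn,fp,fn non-negative counts.
#' @return named numeric vector `sensitivity`, `specificity`, `ppv`,
#'   `npv`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  c(sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    ppv = safe(tp, tp + fp),
    npv = safe(tn, tn + fn))
}

# Hamming distance for equal-length strings, Inf otherwise
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(Inf)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Match predicted matures against a collapsed read library
#'
#' A read supports a prediction when its full length matches the mature
#' sequence with at most `max_mismatches` substitutions (exact identity by
#' default). Counts of all supporting reads are summed; a prediction is
#' confirmed when its read count is at least 1.
#'
#' @param matures character vector of predicted mature sequences (named or
#'   not).
#' @param reads data.frame from [read_collapsed_reads()] (columns `seq`,
#'   `count`), already length-filtered.
#' @param max_mismatches allowed substitutions for a supporting read.
#' @return data.frame with columns `mature_seq`, `read_count`,
#'   `confirmed`.
#' @export
match_reads <- function(matures, reads, max_mismatches = 0L) {
  counts <- vapply(matures, function(m) {
    if (max_mismatches == 0L) {
      sum(reads$count[reads$seq == m])
    } else {
      ok <- vapply(reads$seq, function(r) {
        hamming(r, m) <= max_mismatches
      }, logical(1))
      sum(reads$count[ok])
    }
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(mature_seq = unname(matures), read_count = counts,
             confirmed = counts >= 1, stringsAsFactors = FALSE)
}

#' Transcripts per million
#'
#' @param read_count supporting-read count for one miRNA.
#' @param total_reads library total (cleaned reads).
#' @return `read_count / total_reads * 1e6`.
#' @export
tpm <- function(read_count, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  read_count / total_reads * 1e6
}

#' Relative expression from qRT-PCR cycle thresholds
#'
#' `2^-(CT_miRNA - CT_reference)`, the standard 2^-dCT quantity against a
#' reference gene (e.g. U6 snRNA).
#'
#' @param ct_mirna,ct_reference finite CT values.
#' @return relative expression (positive).
#' @export
relative_expression <- function(ct_mirna, ct_reference) {
  stopifnot(is.finite(ct_mirna), is.finite(ct_reference))
  2^-(ct_mirna - ct_reference)
}

# do two matures match, allowing up to `slack` nt of 5'/3' end offset
mature_match <- function(a, b, slack = 0L) {
  if (a == b) return(TRUE)
  if (slack == 0L) return(FALSE)
  la <- nchar(a); lb <- nchar(b)
  for (off in (-slack):slack) {
    # align a[i] with b[i - off]; overlap must cover all but <= slack at
    # each end of both sequences
    s_a <- max(1L, 1L + off); e_a <- min(la, lb + off)
    if (e_a < s_a) next
    s_b <- s_a - off; e_b <- e_a - off
    if (s_a - 1L > slack || la - e_a > slack) next
    if (s_b - 1L > slack || lb - e_b > slack) next
    if (substring(a, s_a, e_a) == substring(b, s_b, e_b)) return(TRUE)
  }
  FALSE
}

#' Score predictions against a known miRNA set
#'
#' A prediction counts as known when its mature sequence matches a known
#' mature exactly (or within `end_slack` nt of 5'/3' offset). TP =
#' predictions matching a known; FP = predictions matching none; FN =
#' knowns never matched; TN = members of the candidate universe that are
#' neither predicted nor known.
#'
#' @param predictions character vector of predicted mature sequences.
#' @param known character vector of known mature sequences.
#' @param universe character vector of candidate sequences the classifier
#'   decided over (needed for TN/specificity/NPV; the negative universe is
#'   caller-defined).
#' @param end_slack allowed end offset (nt) for a match.
#' @return list with `counts` (tp/tn/fp/fn) and `metrics`
#'   ([confusion_metrics()] of those counts).
#' @export
evaluate_against_known <- function(predictions, known,
                                   universe = character(0),
                                   end_slack = 0L) {
  pred_known <- vapply(predictions, function(p) {
    any(vapply(known, mature_match, logical(1), a = p, slack = end_slack))
  }, logical(1))
  known_found <- vapply(known, function(k) {
    any(vapply(predictions, mature_match, logical(1), a = k,
               slack = end_slack))
  }, logical(1))
  tp <- sum(pred_known)
  fp <- sum(!pred_known)
  fn <- sum(!known_found)
  tn <- if (length(universe)) {
    sum(vapply(universe, function(u) {
      !any(vapply(c(predictions, known), mature_match, logical(1), a = u,
                  slack = end_slack))
    }, logical(1)))
  } else 0L
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  list(counts = counts,
       metrics = confusion_metrics(tp, tn, fp, fn))
}

#' Per-prediction expression validation report
#'
#' @param predictions data.frame with columns `name` and `mature_seq`
#'   (e.g. `pipeline_result$predictions`).
#' @param reads collapsed read library ([read_collapsed_reads()]).
#' @param total_reads TPM denominator; defaults to the sum of the library
#'   counts (cleaned-read total).
#' @param max_mismatches see [match_reads()].
#' @return data.frame `name`, `mature_seq`, `read_count`, `tpm`,
#'   `confirmed`.
#' @export
validation_report <- function(predictions, reads,
                              total_reads = sum(reads$count),
                              max_mismatches = 0L) {
  m <- match_reads(predictions$mature_seq, reads,
                   max_mismatches = max_mismatches)
  data.frame(name = predictions$name, mature_seq = m$mature_seq,
             read_count = m$read_count, tpm = tpm(m$read_count, total_reads),
             confirmed = m$confirmed, stringsAsFactors = FALSE)
}
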