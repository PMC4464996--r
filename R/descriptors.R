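# Per-sequence folding descriptors and 99%-probability cutoff ranges.
#
# For a precursor of length L with minimum folding energy MFE and ensemble
# pair probabilities p_ij:
#   AMFE = -MFE / L * 100            (MFE per 100 nt)
#   MFEI = AMFE / (G+C)%             (GC on the percent scale, e.g. 50)
#   NQ   = -(1/L) sum_{i<j} p_ij log2(p_ij)   (normalized Shannon entropy)
#   ND   =  (1/L) sum_{i<j} p_ij (1 - p_ij)   (normalized base-pair distance)
#   Npb  = pairs in the MFE structure / L      (in [0, 0.5])

#' Compute folding descriptors for one sequence
#'
#' @param profile a [fold_profile()] result (carries the sequence, MFE
#'   structure and pair probabilities).
#' @return object of class `descriptor_set`: named list with `L`,
#'   `au_pct`, `gc_pct`, `mfe`, `amfe`, `mfei`, `nq`, `nd`, `npb`. `mfei`
#'   is `NA` when GC% is zero (reported as missing; such a candidate fails
#'   the MFEI criterion).
#' @export
compute_descriptors <- function(profile) {
  seq <- profile$seq
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  au <- sum(chars %in% c("A", "U"))
  gc <- sum(chars %in% c("G", "C"))
  au_pct <- au / L * 100
  gc_pct <- gc / L * 100
  amfe <- -profile$mfe / L * 100
  mfei <- if (gc_pct > 0) amfe / gc_pct else NA_real_
  p <- profile$pair_prob$p
  nq <- if (length(p)) -sum(p * log2(p)) / L else 0
  nd <- if (length(p)) sum(p * (1 - p)) / L else 0
  npb <- sum(strsplit(profile$structure, "")[[1]] == "(") / L
  structure(list(L = L, au_pct = au_pct, gc_pct = gc_pct, mfe = profile$mfe,
                 amfe = amfe, mfei = mfei, nq = nq, nd = nd, npb = npb),
            class = "descriptor_set")
}

#' Descriptor table for a set of sequences
#'
#' @param seqs character vector of sequences (named or not).
#' @param backend folding backend, see [builtin_backend()].
#' @return data.frame, one row per sequence, columns `id` plus the
#'   `descriptor_set` fields.
#' @export
descriptor_table <- function(seqs, backend = builtin_backend()) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rows <- lapply(seqs, function(s) {
    d <- compute_descriptors(fold_profile(s, backend))
    as.data.frame(unclass(d))
  })
  out <- cbind(data.frame(id = ids, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Derive descriptor cutoffs from a reference precursor set
#'
#' Computes the 99% (by default) probability acceptance ranges from the
#' empirical distribution of descriptors over a reference set of known
#' precursors. Two-sided quantities (length, AU%) get the central
#' `coverage` interval; one-sided quantities get the single quantile that
#' leaves `1 - coverage` in the rejected tail (lower quantile for MFEI and
#' Npb, upper quantile for NQ and ND). Quantiles use linear interpolation
#' of order statistics (R type 7).
#'
#' @param table data.frame of descriptors as from [descriptor_table()]
#'   (columns `L`, `au_pct`, `mfei`, `nq`, `nd`, `npb`).
#' @param coverage probability mass to accept, in (0, 1).
#' @return object of class `cutoff_set`: list with `length` and `au_pct`
#'   closed intervals, `mfei_min`, `nq_max`, `nd_max`, `npb_min`,
#'   `coverage`.
#' @export
derive_cutoffs <- function(table, coverage = 0.99) {
  stopifnot(coverage > 0, coverage < 1)
  if (nrow(table) < 2) stop("need at least 2 reference rows to derive cutoffs")
  a <- (1 - coverage) / 2
  q <- function(x, p) unname(quantile(x, p, type = 7, na.rm = TRUE))
  new_cutoff_set(
    length = c(q(table$L, a), q(table$L, 1 - a)),
    au_pct = c(q(table$au_pct, a), q(table$au_pct, 1 - a)),
    mfei_min = q(table$mfei, 1 - coverage),
    nq_max = q(table$nq, coverage),
    nd_max = q(table$nd, coverage),
    npb_min = q(table$npb, 1 - coverage),
    coverage = coverage)
}

new_cutoff_set <- function(length, au_pct, mfei_min, nq_max, nd_max,
                           npb_min, coverage = 0.99) {
  stopifnot(length[1] <= length[2], au_pct[1] <= au_pct[2])
  structure(list(length = length, au_pct = au_pct, mfei_min = mfei_min,
                 nq_max = nq_max, nd_max = nd_max, npb_min = npb_min,
                 coverage = coverage),
            class = "cutoff_set")
}

#' Published Viridiplantae precursor cutoffs
#'
#' The cutoff set derived from the 99% probability ranges of the 6088
#' Viridiplantae precursors in miRBase 20 (folded with a thermodynamic
#' folder): length 55-505 nt, AU 22-77% (the stricter published range;
#' `au = "results"` selects the alternative 27-77%), MFEI >= 0.41,
#' NQ <= 0.45, ND <= 0.15, Npb >= 0.25. These values are only meaningful
#' with a comparable thermodynamic backend; with the built-in energy model
#' cutoffs must be re-derived via [derive_cutoffs()].
#'
#' @param au which published AU range to use: `"methods"` (22-77, default)
#'   or `"results"` (27-77).
#' @return a `cutoff_set`.
#' @export
viridiplantae_cutoffs <- function(au = c("methods", "results")) {
  au <- match.arg(au)
  new_cutoff_set(length = c(55, 505),
                 au_pct = if (au == "methods") c(22, 77) else c(27, 77),
                 mfei_min = 0.41, nq_max = 0.45, nd_max = 0.15,
                 npb_min = 0.25, coverage = 0.99)
}

#' Check descriptors against a cutoff set
#'
#' Boundary values pass: comparisons are >= / <= exactly as the cutoffs
#' are stated.
#'
#' @param d a `descriptor_set`.
#' @param c a `cutoff_set`.
#' @return named logical vector with elements `length_ok`, `mfei_ok`
#'   (MFEI criterion), `au_ok` (AU-range criterion), `nq_ok`, `nd_ok`,
#'   `npb_ok` and `folding_ok` (the combined NQ/ND/Npb criterion).
#' @export
check_descriptors <- function(d, c) {
  mfei_ok <- !is.na(d$mfei) && d$mfei >= c$mfei_min
  out <- c(length_ok = d$L >= c$length[1] && d$L <= c$length[2],
           mfei_ok = mfei_ok,
           au_ok = d$au_pct >= c$au_pct[1] && d$au_pct <= c$au_pct[2],
           nq_ok = d$nq <= c$nq_max,
           nd_ok = d$nd <= c$nd_max,
           npb_ok = d$npb >= c$npb_min)
  c(out, folding_ok = unname(out["nq_ok"] && out["nd_ok"] && out["npb_ok"]))
}

#' Serialize a cutoff set to JSON
#'
#' @param cutoffs a `cutoff_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cutoffs <- function(cutoffs, path) {
  jsonlite::write_json(unclass(cutoffs), path, auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

#' Read a cutoff set from JSON
#'
#' @param path file written by [write_cutoffs()].
#' @return a `cutoff_set`.
#' @export
read_cutoffs <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_cutoff_set(length = x$length, au_pct = x$au_pct,
                 mfei_min = x$mfei_min, nq_max = x$nq_max,
                 nd_max = x$nd_max, npb_min = x$npb_min,
                 coverage = x$coverage)
}
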