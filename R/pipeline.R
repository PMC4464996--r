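# End-to-end prediction: seven-criterion filtering of candidate windows,
# best-window selection per hit, mature extraction, naming, and the
# orchestrated homology -> windows -> coding filter -> criteria ->
# selection -> naming pipeline.
#
# The seven criteria for a candidate window:
#   c1  folds into a stem-loop with MFE < 0 and MFEI >= cutoff (0.41 for
#       the published thermodynamic-backend cutoffs)
#   c2  mature sits on one arm of the hairpin, not in a terminal loop
#   c3  fewer than 6 mismatches between mature and star
#   c4  no loop or break in the star (star pairs only back into the mature)
#   c5  AU content within the cutoff range
#   c6  NQ, ND within their upper cutoffs and Npb above its lower cutoff
#   c7  the query family has an SSR signature and the window carries it at
#       R >= 2.5

#' Apply the seven precursor criteria to one candidate window
#'
#' @param window one row of an [enumerate_windows()] data.frame (needs
#'   `seq`, `mature_start`, `mature_end`).
#' @param cutoffs a `cutoff_set` (see [derive_cutoffs()]).
#' @param catalog an `ssr_catalog` (see [build_catalog()]).
#' @param family family id of the query miRNA that produced the hit.
#' @param backend folding backend.
#' @param min_r minimum signature density R in the window.
#' @param max_duplex_mismatches mature/star mismatch bound (exclusive).
#' @param profile optional precomputed `folding_profile` for `window$seq`.
#' @return object of class `criteria_report`: named logical vector
#'   `c1`..`c7` plus `overall`, with the window's `descriptor_set` and
#'   `duplex_report` attached as attributes.
#' @export
apply_criteria <- function(window, cutoffs, catalog, family,
                           backend = builtin_backend(), min_r = 2.5,
                           max_duplex_mismatches = 6L, profile = NULL) {
  if (is.null(profile)) profile <- fold_profile(window$seq, backend)
  d <- compute_descriptors(profile)
  chk <- check_descriptors(d, cutoffs)
  dup <- analyze_duplex(profile, c(window$mature_start, window$mature_end))
  motif <- catalog_motif(catalog, family)
  c7 <- !is.na(motif) && r_value(window$seq, motif) >= min_r
  rep <- c(c1 = unname(profile$mfe < 0 && chk["mfei_ok"]),
           c2 = dup$same_arm && !dup$overlaps_loop,
           c3 = dup$mismatches < max_duplex_mismatches,
           c4 = dup$star_contiguous,
           c5 = unname(chk["au_ok"]),
           c6 = unname(chk["folding_ok"]),
           c7 = c7)
  rep <- c(rep, overall = all(rep))
  structure(rep, descriptors = d, duplex = dup, motif = motif,
            class = "criteria_report")
}

#' Select the best passing window for one hit
#'
#' Lexicographic maximization over windows that pass all seven criteria:
#' highest MFEI first, then highest signature density R, then the shorter
#' window, then the smaller start (for determinism).
#'
#' @param windows data.frame of passing windows carrying columns `mfei`,
#'   `r_signature`, `length`, `start`.
#' @return the single best row, or `NULL` for empty input.
#' @export
select_best <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0) return(NULL)
  ord <- order(-windows$mfei, -windows$r_signature, windows$length,
               windows$start)
  windows[ord[1], , drop = FALSE]
}

#' Extract the mature miRNA from a window
#'
#' The mature is the window subsequence aligned to the query (the hit
#' span), in U-space; its length always equals the hit length.
#'
#' @param window one row of an [enumerate_windows()] data.frame.
#' @return list with `mature_seq` and `mature_span` (window coordinates).
#' @export
extract_mature <- function(window) {
  list(mature_seq = substring(window$seq, window$mature_start,
                              window$mature_end),
       mature_span = c(window$mature_start, window$mature_end))
}

# base-26 letter suffix: 1 -> a, 26 -> z, 27 -> aa
variant_suffix <- function(i) {
  s <- ""
  while (i > 0) {
    i <- i - 1L
    s <- paste0(letters[i %% 26L + 1L], s)
    i <- i %/% 26L
  }
  s
}

#' Assign miRBase-style names to predictions
#'
#' Within each family, distinct mature sequences get suffix letters a, b,
#' c, ... (aa after z) in deterministic sorted-sequence order. Identical
#' mature sequences collapse to a single prediction; provenance ids are
#' concatenated.
#'
#' @param predictions data.frame with columns `family`, `mature_seq` and
#'   optionally `provenance`.
#' @param species_prefix e.g. `"pvu"`.
#' @return the deduplicated data.frame with a `name` column added.
#' @export
name_predictions <- function(predictions, species_prefix) {
  if (nrow(predictions) == 0) {
    predictions$name <- character(0)
    return(predictions)
  }
  key <- paste(predictions$family, predictions$mature_seq)
  if (!is.null(predictions$provenance)) {
    prov <- tapply(predictions$provenance, key,
                   function(x) paste(unique(x), collapse = ";"))
  }
  first <- !duplicated(key)
  out <- predictions[first, , drop = FALSE]
  if (!is.null(predictions$provenance)) {
    out$provenance <- as.character(prov[paste(out$family, out$mature_seq)])
  }
  out <- out[order(out$family, out$mature_seq), , drop = FALSE]
  idx <- stats::ave(seq_len(nrow(out)), out$family, FUN = seq_along)
  digits <- sub("^MIR", "", out$family)
  out$name <- paste0(species_prefix, "-miR", digits,
                     vapply(idx, variant_suffix, character(1)))
  rownames(out) <- NULL
  out
}

#' Target-prediction parameter profile for a mature miRNA length
#'
#' Returns the psRNATarget submission parameters adjusted to the miRNA
#' length: complementarity-scoring length (hpsize) equal to the miRNA
#' length, the central-mismatch range for translational inhibition per
#' published mapping, maximum expectation 2.0, maximum unpairing energy
#' (UPE) 25 kcal, and target-site flanks of 17 nt upstream / 13 nt
#' downstream.
#'
#' @param mirna_len mature miRNA length, 14-24 nt.
#' @return list with `mirna_len`, `hpsize`, `central_mismatch`
#'   (inclusive range), `max_expectation`, `max_upe`, `flank_up`,
#'   `flank_down`.
#' @export
psrnatarget_params <- function(mirna_len) {
  if (!(mirna_len %in% 14:24)) {
    stop("miRNA length must be within 14-24 nt, got ", mirna_len)
  }
  central <- list(`14` = c(6, 8), `15` = c(7, 8), `16` = c(7, 9),
                  `17` = c(8, 9), `18` = c(8, 10), `19` = c(9, 10),
                  `20` = c(9, 11), `21` = c(10, 11), `22` = c(10, 12),
                  `23` = c(11, 12), `24` = c(11, 13))
  list(mirna_len = mirna_len, hpsize = mirna_len,
       central_mismatch = central[[as.character(mirna_len)]],
       max_expectation = 2.0, max_upe = 25, flank_up = 17L,
       flank_down = 13L)
}

#' Pipeline configuration
#'
#' @param queries named character vector of known mature miRNA sequences
#'   (names parseable by [parse_mirna_name()]; they define the family of
#'   each hit).
#' @param subjects named character vector of subject EST/GSS sequences.
#' @param cutoffs a `cutoff_set`.
#' @param catalog an `ssr_catalog`.
#' @param proteins optional protein sequences for coding exclusion.
#' @param species_prefix prefix for assigned names.
#' @param word_size,max_mismatches homology-scan settings.
#' @param min_len,max_len,stride window-enumeration settings; by default
#'   the window length range is taken from `cutoffs$length` intersected
#'   with the published 55-505 extraction range.
#' @param backend folding backend.
#' @param min_r minimum in-window signature density R.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(queries, subjects, cutoffs, catalog,
                            proteins = NULL, species_prefix = "pvu",
                            word_size = 7L, max_mismatches = 3L,
                            min_len = NULL, max_len = NULL, stride = 1L,
                            backend = builtin_backend(), min_r = 2.5) {
  if (length(queries) == 0) stop("no queries supplied")
  if (is.null(min_len)) min_len <- max(55, floor(cutoffs$length[1]))
  if (is.null(max_len)) max_len <- min(505, ceiling(cutoffs$length[2]))
  structure(list(queries = queries, subjects = subjects, cutoffs = cutoffs,
                 catalog = catalog, proteins = proteins,
                 species_prefix = species_prefix, word_size = word_size,
                 max_mismatches = max_mismatches, min_len = min_len,
                 max_len = max_len, stride = stride, backend = backend,
                 min_r = min_r),
            class = "pipeline_config")
}

#' Run the full prediction pipeline
#'
#' Homology scan, window enumeration, protein-coding exclusion,
#' seven-criterion filtering, per-hit best-window selection (maximum MFEI,
#' then maximum R), mature extraction, naming and deduplication. Windows
#' for each hit are examined in best-first (MFEI, R) order so the selected
#' window is the lexicographic optimum among all passing windows without
#' evaluating ensemble descriptors for every candidate.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `predictions` (named,
#'   deduplicated matures with precursor provenance), `precursors`
#'   (per-hit selected precursor windows), and `report` (stage counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  qfam <- parse_mirna_name(names(config$queries))
  hits <- scan_homologs(config$queries, config$subjects,
                        word_size = config$word_size,
                        max_mismatches = config$max_mismatches)
  n_windows <- 0L
  n_coding <- 0L
  precursors <- list()
  if (nrow(hits) > 0) {
    for (hk in seq_len(nrow(hits))) {
      hit <- hits[hk, , drop = FALSE]
      family <- qfam$family[match(hit$query_id, qfam$name)]
      subject_seq <- config$subjects[[hit$subject_id]]
      win <- enumerate_windows(subject_seq, hit, min_len = config$min_len,
                               max_len = config$max_len,
                               stride = config$stride)
      if (nrow(win) == 0) next
      win <- win[!duplicated(win$seq), , drop = FALSE]
      n_windows <- n_windows + nrow(win)
      sel <- best_passing_window(win, config, family)
      n_coding <- n_coding + sel$n_coding
      if (is.null(sel$best)) next
      best <- sel$best
      best$query_id <- hit$query_id
      best$family <- family
      best$hit_mismatches <- hit$mismatches
      precursors[[length(precursors) + 1L]] <- best
    }
  }
  precursors <- if (length(precursors)) do.call(rbind, precursors) else NULL
  if (!is.null(precursors)) {
    # one precursor per hit; drop duplicated precursor sequences
    precursors <- precursors[!duplicated(paste(precursors$seq,
                                               precursors$family)), ,
                             drop = FALSE]
    rownames(precursors) <- NULL
    mat <- lapply(seq_len(nrow(precursors)), function(k) {
      extract_mature(precursors[k, , drop = FALSE])
    })
    pred <- data.frame(
      family = precursors$family,
      mature_seq = vapply(mat, `[[`, character(1), "mature_seq"),
      mature_len = vapply(mat, function(m) iv_len(m$mature_span), numeric(1)),
      mfei = precursors$mfei,
      r_signature = precursors$r_signature,
      provenance = paste0(precursors$subject_id, ":", precursors$start, "-",
                          precursors$end, ":", precursors$strand),
      stringsAsFactors = FALSE)
    predictions <- name_predictions(pred, config$species_prefix)
  } else {
    predictions <- data.frame(family = character(), mature_seq = character(),
                              mature_len = numeric(), mfei = numeric(),
                              r_signature = numeric(),
                              provenance = character(), name = character(),
                              stringsAsFactors = FALSE)
  }
  report <- data.frame(
    stage = c("subjects", "hits", "candidate_windows",
              "windows_rejected_coding", "predicted_precursors",
              "predicted_matures"),
    count = c(length(config$subjects), nrow(hits), n_windows, n_coding,
              if (is.null(precursors)) 0L else nrow(precursors),
              nrow(predictions)),
    stringsAsFactors = FALSE)
  structure(list(predictions = predictions, precursors = precursors,
                 report = report),
            class = "pipeline_result")
}

# Examine windows in best-first (MFEI, R, length, start) order computed
# from the cheap MFE stage; the first window that passes the coding screen
# and all seven criteria is the selection optimum.
best_passing_window <- function(win, config, family) {
  mfei <- numeric(nrow(win))
  motif <- catalog_motif(config$catalog, family)
  rvals <- numeric(nrow(win))
  mfe_fold <- backend_mfe(config$backend)
  for (k in seq_len(nrow(win))) {
    m <- mfe_fold(win$seq[k])
    d_gc <- compute_gc_pct(win$seq[k])
    amfe <- -m$mfe / win$length[k] * 100
    mfei[k] <- if (d_gc > 0) amfe / d_gc else NA_real_
    rvals[k] <- if (is.na(motif)) 0 else r_value(win$seq[k], motif)
  }
  ord <- order(-ifelse(is.na(mfei), -Inf, mfei), -rvals, win$length,
               win$start)
  n_coding <- 0L
  for (k in ord) {
    w <- win[k, , drop = FALSE]
    if (!is.null(config$proteins)) {
      cf <- coding_filter(w$seq, config$proteins)
      if (length(cf$rejected) > 0) {
        n_coding <- n_coding + 1L
        next
      }
    }
    profile <- fold_profile(w$seq, config$backend)
    rep <- apply_criteria(w, config$cutoffs, config$catalog, family,
                          backend = config$backend, min_r = config$min_r,
                          profile = profile)
    if (rep["overall"]) {
      d <- attr(rep, "descriptors")
      w$mfei <- d$mfei
      w$r_signature <- if (is.na(motif)) 0 else r_value(w$seq, motif)
      w$structure <- profile$structure
      w$mfe <- profile$mfe
      return(list(best = w, n_coding = n_coding))
    }
  }
  list(best = NULL, n_coding = n_coding)
}

compute_gc_pct <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sum(chars %in% c("G", "C")) / length(chars) * 100
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", nrow(x$predictions), "predicted mature miRNA(s)\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits `predictions.tsv`, `precursors.fasta`, `matures.fasta` and
#' `report.tsv`. FASTA descriptions carry subject coordinates as
#' `subject:start-end:strand` (1-based closed).
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$predictions, file.path(dir, "predictions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$report, file.path(dir, "report.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(result$precursors) && nrow(result$precursors) > 0) {
    pre <- result$precursors
    write_fasta(data.frame(
      id = paste0("pre", seq_len(nrow(pre))),
      description = paste0(pre$subject_id, ":", pre$start, "-", pre$end,
                           ":", pre$strand),
      seq = pre$seq, stringsAsFactors = FALSE),
      file.path(dir, "precursors.fasta"))
  }
  if (nrow(result$predictions) > 0) {
    write_fasta(data.frame(id = result$predictions$name,
                           description = result$predictions$provenance,
                           seq = result$predictions$mature_seq,
                           stringsAsFactors = FALSE),
                file.path(dir, "matures.fasta"))
  }
  invisible(dir)
}
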