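# RNA secondary-structure engine: MFE folding, ensemble base-pair
# probabilities and mature/star duplex analysis.
#
# The built-in engine uses a simplified base-pair energy model (fixed
# per-pair energies, minimum hairpin loop of 3) solved exactly by dynamic
# programming; ensemble pair probabilities come from an inside-outside
# partition-function recursion over the same model. A pluggable backend
# interface lets a full thermodynamic folder (e.g. RNAfold) stand in;
# descriptor cutoffs must then be re-derived for that backend.

#' Folding parameters for the built-in energy model
#'
#' @param e_gc,e_au,e_gu stacking-free energy per G:C, A:U and G:U pair
#'   (kcal/mol, negative). G:U wobble counts as a pair.
#' @param minloop minimum number of unpaired bases in a hairpin loop.
#' @param rt thermal energy RT (kcal/mol) for Boltzmann weighting.
#' @return list of class `folding_params`.
#' @export
folding_params <- function(e_gc = -3.0, e_au = -2.0, e_gu = -1.0,
                           minloop = 3L, rt = 0.616) {
  stopifnot(e_gc < 0, e_au < 0, e_gu < 0, minloop >= 0, rt > 0)
  structure(list(e_gc = e_gc, e_au = e_au, e_gu = e_gu,
                 minloop = as.integer(minloop), rt = rt),
            class = "folding_params")
}

#' Minimum free energy structure of an RNA sequence
#'
#' @param seq RNA sequence over A/C/G/U.
#' @param params a [folding_params()] object.
#' @return list with `structure` (dot-bracket), `mfe` (kcal/mol, <= 0) and
#'   `n_pairs`. Energy ties are broken toward fewer pairs, then toward a
#'   deterministic earliest-partner traceback.
#' @export
fold_mfe <- function(seq, params = folding_params()) {
  stopifnot_scalar_seq(seq)
  .fold_mfe_cpp(seq, params$e_gc, params$e_au, params$e_gu, params$minloop)
}

#' Ensemble base-pair probabilities
#'
#' Boltzmann-weighted probability that bases i and j pair, over all
#' secondary structures of the model, computed by an exact
#' partition-function recursion (McCaskill-style) on the built-in energy
#' model.
#'
#' @inheritParams fold_mfe
#' @param prob_min drop pairs with probability below this value from the
#'   sparse result.
#' @return data.frame with columns `i`, `j` (1-based, i < j) and `p`.
#' @export
pair_probabilities <- function(seq, params = folding_params(),
                               prob_min = 1e-12) {
  stopifnot_scalar_seq(seq)
  .pair_prob_cpp(seq, params$e_gc, params$e_au, params$e_gu,
                 params$minloop, params$rt, prob_min)
}

#' Built-in folding backend
#'
#' A backend is a function taking a sequence and returning a list with
#' `structure`, `mfe` and `pair_prob` (data.frame i, j, p). Swapping
#' backends changes numeric values only, never the contract.
#'
#' @param params a [folding_params()] object.
#' @return backend function.
#' @export
builtin_backend <- function(params = folding_params()) {
  force(params)
  f <- function(seq) {
    m <- fold_mfe(seq, params)
    list(structure = m$structure, mfe = m$mfe,
         pair_prob = pair_probabilities(seq, params))
  }
  # cheap MFE-only path used by the pipeline to pre-rank windows before
  # the ensemble computation; must agree with the full call on mfe
  attr(f, "mfe_only") <- function(seq) fold_mfe(seq, params)
  f
}

# MFE-only view of a backend (falls back to the full call).
backend_mfe <- function(backend) {
  f <- attr(backend, "mfe_only")
  if (is.null(f)) {
    function(seq) {
      r <- backend(seq)
      list(structure = r$structure, mfe = r$mfe)
    }
  } else {
    f
  }
}

#' RNAfold (ViennaRNA) folding backend
#'
#' Runs the external `RNAfold -p` binary and parses the MFE structure and
#' the base-pair probability dot plot. Requires ViennaRNA on the PATH.
#' Descriptor cutoffs derived under the built-in model do not transfer to
#' this backend and must be re-derived.
#'
#' @param rnafold path to the RNAfold executable.
#' @return backend function (same contract as [builtin_backend()]).
#' @export
vienna_backend <- function(rnafold = "RNAfold") {
  force(rnafold)
  function(seq) {
    stopifnot_scalar_seq(seq)
    dir <- tempfile("rnafold")
    dir.create(dir)
    oldwd <- setwd(dir)
    on.exit({
      setwd(oldwd)
      unlink(dir, recursive = TRUE)
    })
    input <- file.path(dir, "in.fa")
    writeLines(c(">q", seq), input)
    out <- suppressWarnings(system2(
      rnafold, c("-p", "--noPS", "--infile", input),
      stdout = TRUE, stderr = FALSE))
    mfe_line <- grep("^[().]+\\s+\\(", out, value = TRUE)[1]
    if (is.na(mfe_line)) stop("could not parse RNAfold output")
    structure_db <- sub("\\s.*$", "", mfe_line)
    mfe <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", mfe_line))
    ps <- list.files(dir, pattern = "_dp\\.ps$", full.names = TRUE)
    pp <- data.frame(i = integer(), j = integer(), p = numeric())
    if (length(ps) >= 1) {
      lines <- readLines(ps[1])
      ub <- grep("ubox$", lines, value = TRUE)
      ub <- ub[grepl("^[0-9]+ [0-9]+ [0-9.eE+-]+ ubox$", ub)]
      if (length(ub)) {
        m <- do.call(rbind, strsplit(ub, " "))
        pp <- data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
                         p = as.numeric(m[, 3])^2)
      }
      file.remove(ps)
    }
    list(structure = structure_db, mfe = mfe, pair_prob = pp)
  }
}

#' Fold a sequence into a folding profile
#'
#' @param seq RNA sequence.
#' @param backend a backend function ([builtin_backend()] by default).
#' @return object of class `folding_profile`: list with `seq`,
#'   `structure`, `mfe`, `pair_prob`.
#' @export
fold_profile <- function(seq, backend = builtin_backend()) {
  seq <- to_rna(seq)
  res <- backend(seq)
  stopifnot(nchar(res$structure) == nchar(seq))
  structure(list(seq = seq, structure = res$structure, mfe = res$mfe,
                 pair_prob = res$pair_prob),
            class = "folding_profile")
}

#' @export
print.folding_profile <- function(x, ...) {
  cat("folding_profile:", nchar(x$seq), "nt, MFE", x$mfe, "kcal/mol\n")
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Partner table from a dot-bracket structure
#'
#' @param structure dot-bracket string.
#' @return integer vector; `pt[i]` is the partner of position i, 0 if
#'   unpaired.
#' @export
pair_table <- function(structure) {
  chars <- strsplit(structure, "")[[1]]
  pt <- integer(length(chars))
  stack <- integer(0)
  for (i in seq_along(chars)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (length(stack) == 0) stop("unbalanced brackets at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced brackets: unmatched '('")
  pt
}

# 1-based closed spans of hairpin (terminal) loops: maximal unpaired runs
# directly closed by a pair.
hairpin_loops <- function(pt) {
  n <- length(pt)
  loops <- list()
  for (i in seq_len(n)) {
    j <- pt[i]
    if (j > i + 1 && all(pt[(i + 1):(j - 1)] == 0L)) {
      loops[[length(loops) + 1L]] <- c(i + 1L, j - 1L)
    }
  }
  loops
}

#' Analyze the mature/star duplex of a precursor structure
#'
#' Given a folding profile and the mature miRNA span on the precursor,
#' locates the star span (partners of the paired mature positions) and
#' reports the duplex statistics used by the hairpin criteria: number of
#' mature-star pairs, mismatches (mature length minus pairs), whether all
#' partners fall on one arm, whether the star pairs only back into the
#' mature (no loop or break in the star), and whether the mature overlaps
#' a terminal loop.
#'
#' @param profile a `folding_profile`.
#' @param mature_span integer vector `c(start, end)`, 1-based closed, on
#'   the precursor.
#' @return list of class `duplex_report` with fields `mature_span`,
#'   `star_span` (NULL if no mature position pairs), `n_pairs`,
#'   `mismatches`, `same_arm`, `star_contiguous`, `overlaps_loop`.
#' @export
analyze_duplex <- function(profile, mature_span) {
  if (length(mature_span) != 2L || mature_span[2] < mature_span[1]) {
    stop("mature_span must be c(start, end) with start <= end")
  }
  n <- nchar(profile$seq)
  if (mature_span[1] < 1 || mature_span[2] > n) {
    stop("mature_span outside precursor bounds")
  }
  pt <- pair_table(profile$structure)
  mpos <- mature_span[1]:mature_span[2]
  partners <- pt[mpos]
  paired <- partners[partners > 0L]
  n_pairs <- length(paired)
  mismatches <- length(mpos) - n_pairs
  if (n_pairs == 0L) {
    star_span <- NULL
    same_arm <- FALSE
    star_contiguous <- FALSE
  } else {
    star_span <- c(min(paired), max(paired))
    same_arm <- all(paired < mature_span[1]) || all(paired > mature_span[2])
    spos <- star_span[1]:star_span[2]
    sp <- pt[spos]
    outside <- sp > 0L & (sp < mature_span[1] | sp > mature_span[2])
    star_contiguous <- !any(outside)
  }
  loops <- hairpin_loops(pt)
  overlaps_loop <- any(vapply(loops, function(lp) iv_overlaps(lp, mature_span),
                              logical(1)))
  structure(list(mature_span = mature_span, star_span = star_span,
                 n_pairs = n_pairs, mismatches = mismatches,
                 same_arm = same_arm, star_contiguous = star_contiguous,
                 overlaps_loop = overlaps_loop),
            class = "duplex_report")
}
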