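# Simple sequence repeat (SSR) signatures of miRNA families.
#
# A family's SSR signature is the k-mer (k = 3 by default) present in
# every member whose family-averaged density R = occurrences / L * 100 is
# maximal; in single-member families it is simply the member's max-R
# k-mer. Counting is overlapping exact occurrence counting; an optional
# tandem-only mode restricts counts to motifs inside perfect tandem runs
# of at least two units.

#' Count (overlapping) occurrences of a motif in a sequence
#'
#' @param seq RNA sequence.
#' @param motif motif over A/C/G/U.
#' @param tandem_only count only occurrences inside perfect tandem runs of
#'   two or more motif units.
#' @return integer count of matching start positions.
#' @export
count_motif <- function(seq, motif, tandem_only = FALSE) {
  seq <- to_rna(seq)
  if (grepl("[^ACGU]", motif)) stop("motif must be over A/C/G/U: ", motif)
  k <- nchar(motif)
  n <- nchar(seq)
  if (k > n) stop("motif longer than sequence")
  starts <- 1:(n - k + 1)
  hit <- substring(seq, starts, starts + k - 1) == motif
  if (!tandem_only) return(sum(hit))
  # an occurrence is tandem if preceded or followed by another at +/- k
  idx <- which(hit)
  in_run <- (idx - k) %in% idx | (idx + k) %in% idx
  sum(in_run)
}

#' SSR density R: motif occurrences per 100 nucleotides
#'
#' @inheritParams count_motif
#' @return `count / L * 100`.
#' @export
r_value <- function(seq, motif, tandem_only = FALSE) {
  count_motif(seq, motif, tandem_only) / nchar(seq) * 100
}

all_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (k > n) return(character(0))
  starts <- 1:(n - k + 1)
  kmers <- substring(seq, starts, starts + k - 1)
  unique(kmers[!grepl("[^ACGU]", kmers)])
}

#' Conserved SSR signature of one miRNA family
#'
#' For a multi-member family, candidate motifs are those occurring at
#' least once in every member; the winner maximizes the family-averaged R
#' (ties broken lexicographically). For a single-member family the motif
#' with the maximum R in that sequence wins. When `enforce_min = TRUE`, a
#' signature is returned only if its average R meets `min_avg_r`.
#'
#' @param members character vector of member precursor sequences.
#' @param window motif length k.
#' @param min_avg_r minimum family-averaged R for a valid signature.
#' @param enforce_min drop signatures below `min_avg_r`.
#' @param tandem_only see [count_motif()].
#' @return list with `motif`, `avg_r`, `n_members`, or `NULL` when no
#'   motif qualifies.
#' @export
family_signature <- function(members, window = 3L, min_avg_r = 2.5,
                             enforce_min = TRUE, tandem_only = FALSE) {
  if (length(members) == 0) stop("family has no members")
  members <- to_rna(members)
  kmer_sets <- lapply(members, all_kmers, k = window)
  shared <- Reduce(intersect, kmer_sets)
  if (tandem_only) {
    shared <- shared[vapply(shared, function(m) {
      all(vapply(members, count_motif, integer(1), motif = m,
                 tandem_only = TRUE) >= 1L)
    }, logical(1))]
  }
  if (length(shared) == 0) return(NULL)
  avg_r <- vapply(shared, function(m) {
    mean(vapply(members, r_value, numeric(1), motif = m,
                tandem_only = tandem_only))
  }, numeric(1))
  ord <- order(-avg_r, shared)
  best <- ord[1]
  if (enforce_min && avg_r[best] < min_avg_r) return(NULL)
  list(motif = shared[best], avg_r = unname(avg_r[best]),
       n_members = length(members))
}

#' Build the SSR signature catalog over miRNA families
#'
#' @param families named list: family id -> character vector of member
#'   precursor sequences.
#' @param window motif length (3, the published choice, by default).
#' @param min_avg_r minimum family-averaged R.
#' @param enforce_min drop families whose best shared motif falls below
#'   `min_avg_r`.
#' @param tandem_only see [count_motif()].
#' @return object of class `ssr_catalog`: data.frame with columns
#'   `family`, `motif`, `avg_r`, `n_members` (families without a
#'   qualifying signature get `NA` motif), with attributes `window` and
#'   `min_avg_r`.
#' @export
build_catalog <- function(families, window = 3L, min_avg_r = 2.5,
                          enforce_min = TRUE, tandem_only = FALSE) {
  rows <- lapply(names(families), function(fam) {
    sig <- family_signature(families[[fam]], window, min_avg_r,
                            enforce_min, tandem_only)
    if (is.null(sig)) {
      data.frame(family = fam, motif = NA_character_, avg_r = NA_real_,
                 n_members = length(families[[fam]]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(family = fam, motif = sig$motif, avg_r = sig$avg_r,
                 n_members = sig$n_members, stringsAsFactors = FALSE)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(), motif = character(),
               avg_r = numeric(), n_members = integer(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, window = window, min_avg_r = min_avg_r,
            class = c("ssr_catalog", "data.frame"))
}

#' Look up the signature motif of a family in a catalog
#'
#' @param catalog an `ssr_catalog`.
#' @param family family id.
#' @return motif string, or `NA` if the family is absent or signature-less.
#' @export
catalog_motif <- function(catalog, family) {
  i <- match(family, catalog$family)
  if (is.na(i)) NA_character_ else catalog$motif[i]
}

#' Distribution of signatures across families
#'
#' @param catalog an `ssr_catalog`.
#' @return data.frame with columns `motif` and `pct_families`, the
#'   percentage of signature-bearing families carrying each motif
#'   (percentages sum to 100).
#' @export
signature_distribution <- function(catalog) {
  assigned <- catalog$motif[!is.na(catalog$motif)]
  if (length(assigned) == 0) {
    return(data.frame(motif = character(), pct_families = numeric(),
                      stringsAsFactors = FALSE))
  }
  tab <- table(assigned)
  out <- data.frame(motif = names(tab),
                    pct_families = as.numeric(tab) / length(assigned) * 100,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$pct_families, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an SSR catalog as TSV
#'
#' @param catalog an `ssr_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write.table(as.data.frame(catalog), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
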