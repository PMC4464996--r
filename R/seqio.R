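# Sequence input/output and miRBase-style name handling.

#' Read a FASTA file into a sequence table
#'
#' Reads FASTA records into a data frame with columns `id`, `description`
#' and `seq`. Sequences are uppercased; with `rna = TRUE` (default) T is
#' converted to U on ingest. Optionally collapses records with identical
#' sequences, keeping the first id (redundancy removal as applied to
#' precursor and EST/GSS datasets before prediction).
#'
#' @param path path to a FASTA file.
#' @param dedup collapse records with identical sequences (keep first).
#' @param rna convert T to U (RNA-role input). Set `FALSE` to keep DNA as
#'   given; comparisons elsewhere are always done in U-space.
#' @return data.frame with columns `id`, `description`, `seq`; zero rows
#'   for an empty file.
#' @export
read_fasta <- function(path, dedup = FALSE, rna = TRUE) {
  if (file.exists(path) && file.size(path) == 0) {
    return(data.frame(id = character(), description = character(),
                      seq = character(), stringsAsFactors = FALSE))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  seq <- toupper(as.character(set))
  if (rna) seq <- to_rna(seq)
  if (any(!nzchar(seq))) {
    stop("empty sequence for record(s): ",
         paste(utils::head(id[!nzchar(seq)], 3L), collapse = ", "))
  }
  df <- data.frame(id = id, description = desc, seq = seq,
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  if (dedup) df <- df[!duplicated(df$seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a sequence table to FASTA
#'
#' @param records data.frame with columns `id`, `seq` and optionally
#'   `description`.
#' @param path output path.
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_len(nrow(records))) {
    hdr <- records$id[k]
    if (!is.null(records$description) && nzchar(records$description[k])) {
      hdr <- paste(hdr, records$description[k])
    }
    writeLines(paste0(">", hdr), con)
    s <- records$seq[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a miRBase-style miRNA name
#'
#' Splits names of the form `<prefix>-miR<digits><suffix>` (or `MIR`,
#' `mir`) into species prefix, canonical family (`MIR<digits>`) and
#' variant suffix. Formatting the parts with [format_mirna_name()]
#' round-trips the original name.
#'
#' @param name character vector of miRNA names, e.g. `"pvu-miR399a"`.
#' @return data.frame with columns `name`, `species_prefix`, `family`,
#'   `variant` and `tag` (the literal miR/MIR token, kept for
#'   round-tripping).
#' @export
parse_mirna_name <- function(name) {
  m <- regexec("^([A-Za-z0-9]+)-(miR|MIR|mir)([0-9]+)(.*)$", name)
  parts <- regmatches(name, m)
  bad <- vapply(parts, length, integer(1)) != 5L
  if (any(bad)) {
    stop("unparseable miRNA name(s): ",
         paste(utils::head(name[bad], 5L), collapse = ", "))
  }
  data.frame(
    name = name,
    species_prefix = vapply(parts, `[`, character(1), 2L),
    family = paste0("MIR", vapply(parts, `[`, character(1), 4L)),
    variant = vapply(parts, `[`, character(1), 5L),
    tag = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE)
}

#' Format miRNA name parts back into a name
#'
#' @param parsed data.frame as returned by [parse_mirna_name()].
#' @return character vector of names.
#' @export
format_mirna_name <- function(parsed) {
  paste0(parsed$species_prefix, "-", parsed$tag,
         sub("^MIR", "", parsed$family), parsed$variant)
}

#' Read a small-RNA read library as collapsed reads
#'
#' Accepts either collapsed FASTA with counts encoded in headers
#' (`<id>_x<count>`, the common collapser convention) or plain FASTQ, in
#' which case identical reads are accumulated by exact sequence. Reads
#' shorter than `min_len` nucleotides are removed (default 14).
#'
#' @param path FASTA or FASTQ file of reads.
#' @param min_len minimum retained read length (nt).
#' @param format `"auto"` (by extension/first character), `"fasta"` or
#'   `"fastq"`.
#' @return data.frame with columns `seq` (RNA alphabet) and `count`,
#'   one row per distinct sequence.
#' @export
read_collapsed_reads <- function(path, min_len = 14L, format = "auto") {
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "@")) "fastq" else "fasta"
  }
  if (format == "fastq") {
    set <- Biostrings::readBStringSet(path, format = "fastq")
    seq <- to_rna(as.character(set))
    count <- rep(1, length(seq))
  } else {
    recs <- read_fasta(path, rna = TRUE)
    seq <- recs$seq
    m <- regmatches(recs$id, regexec("_x([0-9]+)$", recs$id))
    count <- vapply(m, function(p) {
      if (length(p) == 2L) as.numeric(p[2]) else NA_real_
    }, numeric(1))
    if (anyNA(count)) {
      warning(sum(is.na(count)),
              " read header(s) without a parseable _x<count>; counted as 1")
      count[is.na(count)] <- 1
    }
  }
  keep <- nchar(seq) >= min_len
  seq <- seq[keep]
  count <- count[keep]
  agg <- tapply(count, seq, sum)
  out <- data.frame(seq = names(agg), count = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read BLAST 12-column tabular hits
#'
#' Parses the standard `-outfmt 6` layout (qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore).
#' Subject coordinates are converted to 1-based closed intervals with
#' `start <= end`; the strand is inferred from the original coordinate
#' order (sstart > send means minus).
#'
#' @param path tab-separated hit file.
#' @return data.frame of hits with columns `query_id`, `subject_id`,
#'   `pident`, `aln_len`, `mismatches`, `gapopen`, `qstart`, `qend`,
#'   `sstart`, `send`, `strand`, `evalue`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      pident = numeric(), aln_len = integer(),
                      mismatches = integer(), gapopen = integer(),
                      qstart = integer(), qend = integer(),
                      sstart = integer(), send = integer(),
                      strand = character(), evalue = numeric(),
                      bitscore = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, integer(1))
  if (any(nf != 12L)) {
    stop("expected 12 tab-separated columns; line ",
         which(nf != 12L)[1], " has ", nf[nf != 12L][1])
  }
  m <- do.call(rbind, fields)
  sstart <- as.integer(m[, 9]); send <- as.integer(m[, 10])
  minus <- sstart > send
  data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    pident = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = ifelse(minus, send, sstart),
    send = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
}
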