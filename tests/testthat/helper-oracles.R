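# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals: structures
# are enumerated recursively, energies summed per pair, probabilities
# accumulated by exhaustive Boltzmann weighting, and homology hits found
# by naive all-offsets Hamming scanning.

oracle_pairable <- function(a, b) {
  paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
}

# all secondary structures of chars[i..j] as k x 2 matrices of pairs
oracle_structures <- function(chars, i, j, minloop = 3) {
  if (j - i < minloop + 1) return(list(matrix(integer(0), ncol = 2)))
  res <- oracle_structures(chars, i + 1, j, minloop)
  for (k in (i + minloop + 1):j) {
    if (!oracle_pairable(chars[i], chars[k])) next
    left <- oracle_structures(chars, i + 1, k - 1, minloop)
    right <- if (k + 1 <= j) oracle_structures(chars, k + 1, j, minloop)
    else list(matrix(integer(0), ncol = 2))
    for (a in left) {
      for (b in right) {
        res[[length(res) + 1]] <- rbind(matrix(c(i, k), ncol = 2), a, b)
      }
    }
  }
  res
}

oracle_energy <- function(pairs, chars, e = c(GC = -3, AU = -2, GU = -1)) {
  if (nrow(pairs) == 0) return(0)
  sum(apply(pairs, 1, function(p) {
    pr <- paste0(chars[p[1]], chars[p[2]])
    if (pr %in% c("GC", "CG")) e[["GC"]]
    else if (pr %in% c("AU", "UA")) e[["AU"]]
    else e[["GU"]]
  }))
}

# exhaustive MFE and Boltzmann pair-probability matrix
oracle_fold <- function(seq, rt = 0.616) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  ss <- oracle_structures(chars, 1, n)
  en <- vapply(ss, oracle_energy, numeric(1), chars = chars)
  w <- exp(-en / rt)
  z <- sum(w)
  p <- matrix(0, n, n)
  for (k in seq_along(ss)) {
    s <- ss[[k]]
    if (nrow(s)) {
      for (r in seq_len(nrow(s))) {
        p[s[r, 1], s[r, 2]] <- p[s[r, 1], s[r, 2]] + w[k]
      }
    }
  }
  list(mfe = min(en), pair_prob = p / z,
       max_pairs = max(vapply(ss, nrow, integer(1))))
}

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# naive full-coverage ungapped homology scan (both strands)
oracle_scan <- function(query, subject, word_size = 7, max_mismatches = 3) {
  qlen <- nchar(query)
  n <- nchar(subject)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") query else rev_comp(query)
    pv <- strsplit(pat, "")[[1]]
    if (qlen > n) next
    for (s in 1:(n - qlen + 1)) {
      fv <- strsplit(substring(subject, s, s + qlen - 1), "")[[1]]
      m <- fv == pv
      if (sum(!m) > max_mismatches) next
      r <- rle(m)
      if (!any(r$lengths[r$values] >= word_size)) next
      hits[[length(hits) + 1]] <- data.frame(
        sstart = s, send = s + qlen - 1, strand = strand,
        mismatches = sum(!m), stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(sstart = integer(), send = integer(),
                      strand = character(), mismatches = integer()))
  }
  do.call(rbind, hits)
}

# closed-form window count: sum over lengths of valid offsets
oracle_window_count <- function(n, hs, he, min_len, max_len, stride = 1) {
  total <- 0
  for (len in seq(min_len, min(max_len, n), by = stride)) {
    if (len < he - hs + 1) next
    lo <- max(1, he - len + 1)
    hi <- min(hs, n - len + 1)
    if (hi >= lo) total <- total + length(seq(lo, hi, by = stride))
  }
  total
}

dinuc_counts <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  table(paste0(chars[-length(chars)], chars[-1]))
}
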