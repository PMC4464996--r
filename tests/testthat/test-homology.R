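test_that("exact and mismatched copies are found with the seed condition", {
  set.seed(12)
  query <- c(q1 = random_rna(21))
  flank5 <- random_rna(150)
  flank3 <- random_rna(129)
  subject <- c(s1 = paste0(flank5, query[[1]], flank3))
  hits <- scan_homologs(query, subject)
  exact <- hits[hits$mismatches == 0, ]
  expect_gte(nrow(exact), 1L)
  expect_true(any(exact$sstart == 151 & exact$send == 171 &
                    exact$strand == "+"))

  # three substitutions confined to the last three positions keep an
  # exact 7-mer seed and stay under the mismatch cap
  qv <- strsplit(query[[1]], "")[[1]]
  qv[19:21] <- chartr("ACGU", "CAUG", qv[19:21])
  sub3 <- c(s1 = paste0(flank5, paste(qv, collapse = ""), flank3))
  hits3 <- scan_homologs(query, sub3)
  expect_true(any(hits3$mismatches == 3 & hits3$sstart == 151))

  # four substitutions exceed the cap: no hit at that placement
  qv[15] <- chartr("ACGU", "CAUG", qv[15])
  sub4 <- c(s1 = paste0(flank5, paste(qv, collapse = ""), flank3))
  hits4 <- scan_homologs(query, sub4)
  expect_false(any(hits4$sstart == 151 & hits4$strand == "+"))
})

test_that("minus-strand homologs are reported on forward coordinates", {
  set.seed(13)
  query <- c(q1 = random_rna(21))
  subject <- c(s1 = paste0(random_rna(100), rev_comp(query[[1]]),
                           random_rna(80)))
  hits <- scan_homologs(query, subject)
  minus <- hits[hits$strand == "-", ]
  expect_true(any(minus$sstart == 101 & minus$send == 121 &
                    minus$mismatches == 0))
})

test_that("the scan agrees with a brute-force Hamming oracle", {
  set.seed(14)
  for (trial in 1:8) {
    query <- c(q = random_rna(sample(18:23, 1)))
    subject <- c(s = random_rna(300))
    # plant a mutated copy to make non-trivial hits likely
    pos <- sample(50:250, 1)
    qv <- strsplit(query[[1]], "")[[1]]
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      at <- sample(seq_along(qv), nmut)
      qv[at] <- chartr("ACGU", "CAUG", qv[at])
    }
    sv <- strsplit(subject[[1]], "")[[1]]
    sv[pos:(pos + length(qv) - 1)] <- qv
    subject <- c(s = paste(sv, collapse = ""))

    got <- scan_homologs(query, subject)
    want <- oracle_scan(query[[1]], subject[[1]])
    key <- function(d) sort(paste(d$sstart, d$send, d$strand,
                                  d$mismatches))
    expect_equal(key(got), key(want), info = paste("trial", trial))
  }
})

test_that("short queries are skipped with a warning", {
  expect_warning(
    hits <- scan_homologs(c(tiny = "ACGUA"), c(s = random_rna(100))),
    "shorter than word size")
  expect_equal(nrow(hits), 0L)
})

test_that("window enumeration matches the closed-form count", {
  # subject 600, hit [301, 321], single length 55: 35 placements
  hit <- data.frame(subject_id = "s", sstart = 301L, send = 321L,
                    strand = "+", stringsAsFactors = FALSE)
  subject <- random_rna(600)
  win <- enumerate_windows(subject, hit, min_len = 55, max_len = 55)
  expect_equal(nrow(win), 35L)
  expect_true(all(win$start <= 301 & win$end >= 321))
  expect_true(all(substring(subject, win$start, win$end) == win$seq))
  expect_equal(unique(substring(win$seq, win$mature_start,
                                win$mature_end)),
               substring(subject, 301, 321))

  # short subject: only the feasible lengths remain
  hit2 <- data.frame(subject_id = "s", sstart = 21L, send = 41L,
                     strand = "+", stringsAsFactors = FALSE)
  win2 <- enumerate_windows(random_rna(60), hit2, min_len = 55,
                            max_len = 505)
  expect_equal(sum(win2$length == 55), 6L)

  # random geometries against the offset-count oracle
  set.seed(15)
  for (trial in 1:10) {
    n <- sample(80:400, 1)
    hs <- sample(10:(n - 30), 1)
    he <- hs + 20
    stride <- sample(1:4, 1)
    win <- enumerate_windows(random_rna(n),
                             data.frame(subject_id = "s", sstart = hs,
                                        send = he, strand = "+"),
                             min_len = 55, max_len = 120, stride = stride)
    expect_equal(nrow(win),
                 oracle_window_count(n, hs, he, 55, 120, stride))
    if (nrow(win)) {
      expect_true(all(win$start <= hs & win$end >= he))
    }
  }

  # hit longer than the maximum window: nothing to enumerate
  hit3 <- data.frame(subject_id = "s", sstart = 1L, send = 80L,
                     strand = "+", stringsAsFactors = FALSE)
  expect_equal(nrow(enumerate_windows(random_rna(200), hit3,
                                      min_len = 55, max_len = 60)), 0L)
})

test_that("minus-strand windows carry the reverse-complement sequence", {
  set.seed(16)
  subject <- random_rna(200)
  hit <- data.frame(subject_id = "s", sstart = 90L, send = 110L,
                    strand = "-", stringsAsFactors = FALSE)
  win <- enumerate_windows(subject, hit, min_len = 60, max_len = 60,
                           stride = 7)
  expect_gt(nrow(win), 0)
  for (k in seq_len(nrow(win))) {
    expect_equal(win$seq[k],
                 rev_comp(substring(subject, win$start[k], win$end[k])))
    expect_equal(substring(win$seq[k], win$mature_start[k],
                           win$mature_end[k]),
                 rev_comp(substring(subject, 90, 110)))
  }
})

test_that("the coding filter rejects translated protein matches", {
  set.seed(17)
  protein <- paste(sample(c("M", "K", "L", "S", "T", "V", "D", "E", "F",
                            "G"), 60, replace = TRUE), collapse = "")
  decoys <- make_decoys(5, kind = "coding", seed = 3, proteins = protein,
                        lengths = 150)
  clean <- make_decoys(5, kind = "random", seed = 4, lengths = 150)
  res <- coding_filter(c(decoys, clean), proteins = protein)
  expect_equal(sort(names(res$rejected)), sort(names(decoys)))
  expect_equal(sort(names(res$kept)), sort(names(clean)))
})

test_that("identity below threshold is kept", {
  # a candidate whose best translated identity is 75% over 20 aa
  aa <- strsplit(paste(rep(c("M", "K", "L", "S"), 5), collapse = ""),
                 "")[[1]]
  protein <- paste(aa, collapse = "")
  mutated <- aa
  mutated[seq(1, 20, by = 4)] <- "W"  # 15/20 = 75% identity
  codons <- c(M = "AUG", K = "AAA", L = "CUU", S = "UCU", W = "UGG")
  cds <- paste(codons[mutated], collapse = "")
  res <- coding_filter(c(cand = cds), proteins = protein)
  expect_equal(names(res$kept), "cand")

  exact <- paste(codons[aa], collapse = "")
  res2 <- coding_filter(c(cand = exact), proteins = protein)
  expect_equal(names(res2$rejected), "cand")
})

test_that("precomputed tabular hits can drive the coding filter", {
  hits <- data.frame(query_id = c("w1", "w2"), pident = c(92, 60),
                     aln_len = c(30L, 30L), stringsAsFactors = FALSE)
  cands <- c(w1 = "ACGUACGU", w2 = "ACGUACGU", w3 = "ACGUACGU")
  res <- coding_filter(cands, hits = hits)
  expect_equal(names(res$rejected), "w1")
  expect_equal(names(res$kept), c("w2", "w3"))
})
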