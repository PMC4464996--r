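# Seeded generators for every input the pipeline consumes, with ground
# truth: planted hairpin precursors, miRNA families sharing an SSR motif,
# EST-like embeddings, decoys and read libraries.
#
# Precursor layout (5'->3'), with all-GC clamp helices clo/cli:
#   tail5 | clo | pad | mature | cli | loop | rc(cli) | star | rc(pad) | rc(clo) | tail3
# where star is the reverse complement of the mature with
# `stem_mismatches` pair-breaking substitutions planted in its middle
# third. Fixed all-GC clamp helices close both ends of the stem: any
# competing pairing between the unpaired regions (tails, loop) and the
# stem interior would have to cross a clamp pair and can never win under
# the built-in energy model, so the designed stem is the MFE structure
# and the duplex mismatch count equals `stem_mismatches` exactly. The
# loop is drawn from {A, C} (self-unpairable) and the star substitutions
# from {A, C} as well. Signature motif copies are inserted in the tails,
# outside the duplex.

# all-GC clamp helices closing the stem ends; composition is sampled per
# precursor (mixed G/C, no homopolymer) so no clamp 3-mer is shared
# systematically across family members
CLAMP_LEN <- 3L
CLAMP_CHOICES <- c("GGC", "GCG", "CGG", "GCC", "CCG", "CGC")

sample_bases <- function(n, gc_bias = 0.5) {
  p_gc <- gc_bias / 2
  p_au <- (1 - gc_bias) / 2
  sample(RNA_BASES, n, replace = TRUE, prob = c(p_au, p_gc, p_gc, p_au))
}

comp_base <- function(b) chartr("ACGU", "UGCA", b)

#' Specification of a synthetic hairpin precursor
#'
#' @param mature_len mature miRNA length (nt).
#' @param stem_mismatches substitutions planted in the star (the resulting
#'   mature/star duplex mismatch count); must be below 6 for a
#'   criterion-passing precursor but larger values are allowed for
#'   negative fixtures.
#' @param loop_len terminal loop length (nt).
#' @param pad_len extra stem length between the tails and the mature.
#' @param flank_len unpaired tail length on each side of the stem.
#' @param gc_bias GC fraction used when sampling stem bases.
#' @param signature_motif SSR motif planted in the tails (NULL = none).
#' @param signature_copies number of non-overlapping motif insertions.
#' @param mature_seq fix the mature sequence instead of sampling it.
#' @param sub_sites fix the star substitution sites (positions 1..
#'   `mature_len` along the star, counted from its 5' end) instead of
#'   sampling them; length must equal `stem_mismatches`.
#' @param seed RNG seed for this precursor.
#' @return list of class `hairpin_spec`.
#' @export
hairpin_spec <- function(mature_len = 21L, stem_mismatches = 2L,
                         loop_len = 8L, pad_len = 5L, flank_len = 12L,
                         gc_bias = 0.5, signature_motif = NULL,
                         signature_copies = 4L, mature_seq = NULL,
                         sub_sites = NULL, seed = 1L) {
  if (!is.null(sub_sites) && length(sub_sites) != stem_mismatches) {
    stop("sub_sites must have length stem_mismatches")
  }
  spec <- list(mature_len = as.integer(mature_len),
               stem_mismatches = as.integer(stem_mismatches),
               loop_len = as.integer(loop_len),
               pad_len = as.integer(pad_len),
               flank_len = as.integer(flank_len), gc_bias = gc_bias,
               signature_motif = signature_motif,
               signature_copies = as.integer(signature_copies),
               mature_seq = mature_seq,
               sub_sites = if (is.null(sub_sites)) NULL else
                 as.integer(sub_sites),
               seed = seed)
  L <- 2L * (CLAMP_LEN + spec$pad_len + spec$mature_len) + spec$loop_len +
    2L * spec$flank_len
  if (L < 55L || L > 505L) {
    stop("precursor length ", L, " outside the 55-505 nt range")
  }
  structure(spec, class = "hairpin_spec")
}

#' Generate one synthetic precursor with ground truth
#'
#' Deterministic under `spec$seed`. The random parts (pads, tails, loop,
#' substitution sites) are rejection-sampled from seeds derived from
#' `spec$seed` until the built-in folder's MFE structure realizes the
#' designed duplex exactly, so the returned truth record is guaranteed
#' consistent with [analyze_duplex()] under default folding parameters.
#'
#' @param spec a [hairpin_spec()].
#' @param max_attempts rejection-sampling attempts before giving up.
#' @return list with `seq`, `mature_span`, `star_span`, `loop_span`
#'   (1-based closed precursor coordinates), `sub_positions` (star
#'   substitution sites), `motif`, `motif_starts`, and `spec`.
#' @export
make_precursor <- function(spec, max_attempts = 25L) {
  stopifnot(inherits(spec, "hairpin_spec"))
  k <- if (is.null(spec$signature_motif)) 0L else nchar(spec$signature_motif)
  if (k > 0 && spec$signature_copies * k > 2L * spec$flank_len) {
    stop("signature copies exceed tail capacity")
  }
  # The clamp construction makes the designed stem optimal, but with a
  # self-similar mature the model can hold equal-energy shifted registers;
  # rejection-sample the random parts (deterministically, from child
  # seeds) until the folded MFE structure realizes the designed duplex.
  for (attempt in seq_len(max_attempts)) {
    cand <- build_precursor_once(spec, k,
                                 child_seed(spec$seed, attempt - 1L))
    if (precursor_realized(cand, spec)) return(cand)
  }
  stop("could not realize the designed duplex for this spec/seed")
}

# fold the candidate and confirm the designed duplex is the MFE structure
precursor_realized <- function(cand, spec) {
  m <- fold_mfe(cand$seq)
  profile <- structure(list(seq = cand$seq, structure = m$structure,
                            mfe = m$mfe, pair_prob = NULL),
                       class = "folding_profile")
  d <- analyze_duplex(profile, cand$mature_span)
  isTRUE(d$mismatches == spec$stem_mismatches && d$same_arm &&
           d$star_contiguous && !d$overlaps_loop &&
           (is.null(d$star_span) ||
              (d$star_span[1] >= cand$star_span[1] &&
                 d$star_span[2] <= cand$star_span[2])))
}

build_precursor_once <- function(spec, k, seed) {
  with_seed(seed, {
    clamp_outer <- sample(CLAMP_CHOICES, 1L)
    clamp_inner <- sample(CLAMP_CHOICES, 1L)
    mature <- if (is.null(spec$mature_seq)) {
      paste(sample_bases(spec$mature_len, spec$gc_bias), collapse = "")
    } else {
      to_rna(spec$mature_seq)
    }
    pad <- paste(sample_bases(spec$pad_len, spec$gc_bias), collapse = "")
    loop <- paste(sample(c("A", "C"), spec$loop_len, replace = TRUE),
                  collapse = "")
    tails <- lapply(1:2, function(i) {
      sample(RNA_BASES, spec$flank_len, replace = TRUE)
    })
    # plant motif copies at non-overlapping tail positions
    motif_sites <- list()
    if (k > 0 && spec$signature_copies > 0) {
      slots <- data.frame(
        tail = rep(1:2, each = max(0L, spec$flank_len - k + 1L)),
        off = rep(seq_len(max(0L, spec$flank_len - k + 1L)), times = 2L))
      slots <- slots[sample(nrow(slots)), , drop = FALSE]
      used <- list(`1` = integer(0), `2` = integer(0))
      placed <- 0L
      for (r in seq_len(nrow(slots))) {
        if (placed == spec$signature_copies) break
        t <- slots$tail[r]; o <- slots$off[r]
        span <- o:(o + k - 1L)
        if (any(span %in% used[[as.character(t)]])) next
        tails[[t]][span] <- strsplit(spec$signature_motif, "")[[1]]
        used[[as.character(t)]] <- c(used[[as.character(t)]], span)
        motif_sites[[length(motif_sites) + 1L]] <- c(t, o)
        placed <- placed + 1L
      }
      if (placed < spec$signature_copies) {
        stop("could not place all signature copies in the tails")
      }
    }
    tail5 <- paste(tails[[1]], collapse = "")
    tail3 <- paste(tails[[2]], collapse = "")

    star_chars <- strsplit(rev_comp(mature), "")[[1]]
    mature_chars <- strsplit(mature, "")[[1]]
    # star position i (1..mature_len) faces mature position mature_len-i+1
    sub_rel <- integer(0)
    if (spec$stem_mismatches > 0) {
      # keep >= 3 designed pairs at each stem end (crossing protection)
      # and >= 1 pair between substitutions (no register slips)
      ml <- spec$mature_len
      if (!is.null(spec$sub_sites)) {
        sub_rel <- sort(spec$sub_sites)
      } else {
        eligible <- 4:(ml - 3L)
        if (length(eligible) < 2L * spec$stem_mismatches - 1L) {
          stop("mature too short for ", spec$stem_mismatches, " mismatches")
        }
        repeat {
          sub_rel <- sort(sample(eligible, spec$stem_mismatches))
          if (spec$stem_mismatches == 1L || min(diff(sub_rel)) >= 2L) break
        }
      }
      for (i in sub_rel) {
        # replacement from {A, C} must not pair the facing mature base
        # (A pairs U, C pairs G); prefer also not pairing its neighbors
        f <- ml - i + 1L
        m <- mature_chars[f]
        base_ok <- switch(m, A = c("A", "C"), C = c("A", "C"), G = "A",
                          U = "C")
        nbhd <- mature_chars[setdiff(max(1L, f - 1L):min(ml, f + 1L), f)]
        pref <- base_ok
        if ("U" %in% nbhd) pref <- setdiff(pref, "A")
        if ("G" %in% nbhd) pref <- setdiff(pref, "C")
        if (length(pref) == 0) pref <- base_ok
        star_chars[i] <- if (length(pref) == 1L) pref else sample(pref, 1L)
      }
    }
    star <- paste(star_chars, collapse = "")

    seq <- paste0(tail5, clamp_outer, pad, mature, clamp_inner, loop,
                  rev_comp(clamp_inner), star, rev_comp(pad),
                  rev_comp(clamp_outer), tail3)
    fl <- spec$flank_len; pl <- spec$pad_len; ml <- spec$mature_len
    ll <- spec$loop_len; cl <- CLAMP_LEN
    mature_span <- c(fl + cl + pl + 1L, fl + cl + pl + ml)
    loop_span <- c(mature_span[2] + cl + 1L, mature_span[2] + cl + ll)
    star_span <- c(loop_span[2] + cl + 1L, loop_span[2] + cl + ml)
    motif_starts <- vapply(motif_sites, function(ms) {
      if (ms[1] == 1L) ms[2] else
        fl + 2L * (2L * cl + pl + ml) + ll + ms[2]
    }, integer(1))
    list(seq = seq, mature_span = mature_span, star_span = star_span,
         loop_span = loop_span,
         sub_positions = star_span[1] - 1L + sub_rel,
         motif = spec$signature_motif,
         motif_starts = sort(motif_starts), spec = spec)
  })
}

#' Generate a synthetic miRNA family sharing an SSR motif
#'
#' All members carry `shared_motif` at a per-member density R of at least
#' 2.5 (by planted copies); members are otherwise randomized.
#'
#' @param n_members family size.
#' @param shared_motif the planted trinucleotide signature.
#' @param seed base seed; member k uses a derived child seed.
#' @param base_spec template [hairpin_spec()]; its motif/seed fields are
#'   overridden.
#' @return list of [make_precursor()] truth records, named by member.
#' @export
make_family <- function(n_members, shared_motif, seed = 1L,
                        base_spec = hairpin_spec()) {
  stopifnot(n_members >= 1)
  lapply(setNames(seq_len(n_members), letters[seq_len(n_members)]),
         function(k) {
           sp <- base_spec
           sp$signature_motif <- shared_motif
           sp$seed <- child_seed(seed, k)
           make_precursor(sp)
         })
}

#' Embed a precursor in an EST-like subject
#'
#' @param precursor precursor sequence (or a [make_precursor()] record).
#' @param flank_len random flank length added on each side.
#' @param seed RNG seed.
#' @param strand `"+"` embeds the precursor as is; `"-"` embeds its
#'   reverse complement (the hairpin then lies on the minus strand of the
#'   subject).
#' @return list with `seq` (subject, RNA alphabet), `precursor_span`,
#'   `mature_span` (subject coordinates of the mature, forward strand),
#'   `strand`.
#' @export
embed_in_est <- function(precursor, flank_len = 60L, seed = 1L,
                         strand = "+") {
  truth <- if (is.list(precursor)) precursor else NULL
  pseq <- if (is.list(precursor)) precursor$seq else to_rna(precursor)
  L <- nchar(pseq)
  with_seed(seed, {
    f5 <- paste(sample_bases(flank_len), collapse = "")
    f3 <- paste(sample_bases(flank_len), collapse = "")
    body <- if (strand == "+") pseq else rev_comp(pseq)
    seq <- paste0(f5, body, f3)
    precursor_span <- c(flank_len + 1L, flank_len + L)
    mature_span <- NULL
    if (!is.null(truth)) {
      ms <- truth$mature_span
      mature_span <- if (strand == "+") {
        flank_len + ms
      } else {
        c(flank_len + L - ms[2] + 1L, flank_len + L - ms[1] + 1L)
      }
    }
    list(seq = seq, precursor_span = precursor_span,
         mature_span = mature_span, strand = strand)
  })
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erikson shuffle: produces a random sequence with exactly the
#' same dinucleotide counts (and first/last base) as the input. Uses the
#' current RNG state; wrap in a seed for reproducibility.
#'
#' @param seq sequence to shuffle.
#' @param max_tries arborescence sampling attempts.
#' @return shuffled sequence.
#' @export
dinucleotide_shuffle <- function(seq, max_tries = 200L) {
  chars <- strsplit(to_rna(seq), "")[[1]]
  n <- length(chars)
  if (n < 3) return(seq)
  first <- chars[1]; last <- chars[n]
  edges <- split(chars[-1], chars[-n])  # from -> multiset of to
  verts <- sort(unique(chars))
  for (v in setdiff(verts, names(edges))) edges[[v]] <- character(0)
  for (try in seq_len(max_tries)) {
    # choose a last-edge for every vertex except `last`; they must form an
    # arborescence toward `last`
    last_edge <- list()
    ok <- TRUE
    for (v in verts) {
      if (v == last) next
      last_edge[[v]] <- sample(edges[[v]], 1L)
    }
    for (v in verts) {
      if (v == last) next
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || is.null(last_edge[[cur]])) {
          ok <- FALSE
          break
        }
        seen <- c(seen, cur)
        cur <- last_edge[[cur]]
      }
      if (!ok) break
    }
    if (!ok) next
    # order each adjacency list randomly, forced last edge at the end
    ordered <- list()
    for (v in verts) {
      e <- edges[[v]]
      if (v != last) {
        le <- last_edge[[v]]
        i <- match(le, e)
        e <- e[-i]
        ordered[[v]] <- c(if (length(e)) sample(e) else character(0), le)
      } else {
        ordered[[v]] <- if (length(e)) sample(e) else character(0)
      }
    }
    # walk the Eulerian path
    out <- character(n)
    out[1] <- first
    ptr <- setNames(rep(1L, length(verts)), verts)
    cur <- first
    feasible <- TRUE
    for (i in 2:n) {
      nxt_list <- ordered[[cur]]
      if (ptr[cur] > length(nxt_list)) {
        feasible <- FALSE
        break
      }
      nxt <- nxt_list[ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    if (feasible) return(paste(out, collapse = ""))
  }
  stop("dinucleotide shuffle failed to find an Eulerian path")
}

#' Generate decoy subject sequences
#'
#' @param n number of decoys.
#' @param kind `"shuffled"` (dinucleotide shuffles of `templates`),
#'   `"random"` (iid), or `"coding"` (random sequences embedding an exact
#'   reverse-translated stretch of a supplied protein; these must be
#'   removed by [coding_filter()]).
#' @param seed RNG seed.
#' @param templates sequences to shuffle (recycled) for
#'   `kind = "shuffled"`.
#' @param lengths decoy lengths for `"random"`/`"coding"` (recycled).
#' @param proteins protein sequences for `"coding"`.
#' @param embed_aa embedded coding stretch length (aa) for `"coding"`.
#' @return named character vector of decoy sequences.
#' @export
make_decoys <- function(n, kind = c("shuffled", "random", "coding"),
                        seed = 1L, templates = NULL, lengths = 200L,
                        proteins = NULL, embed_aa = 30L) {
  kind <- match.arg(kind)
  if (n == 0) return(setNames(character(0), character(0)))
  with_seed(seed, {
    out <- character(n)
    if (kind == "shuffled") {
      if (is.null(templates) || length(templates) == 0) {
        stop("shuffled decoys need template sequences")
      }
      tpl <- rep_len(to_rna(templates), n)
      out <- vapply(tpl, dinucleotide_shuffle, character(1),
                    USE.NAMES = FALSE)
    } else if (kind == "random") {
      len <- rep_len(lengths, n)
      out <- vapply(len, function(L) {
        paste(sample_bases(L), collapse = "")
      }, character(1))
    } else {
      if (is.null(proteins) || length(proteins) == 0) {
        stop("coding decoys need protein sequences")
      }
      len <- rep_len(lengths, n)
      codons <- codon_table()
      for (i in seq_len(n)) {
        L <- len[i]
        prot <- proteins[[((i - 1L) %% length(proteins)) + 1L]]
        aa_len <- min(embed_aa, nchar(prot))
        start_aa <- sample(nchar(prot) - aa_len + 1L, 1L)
        aa <- strsplit(substring(prot, start_aa, start_aa + aa_len - 1L),
                       "")[[1]]
        cds <- paste(vapply(aa, function(a) {
          opts <- codons[[a]]
          if (is.null(opts)) "GCU" else sample(opts, 1L)
        }, character(1)), collapse = "")
        pad_n <- max(0L, L - nchar(cds))
        left <- sample(0:pad_n, 1L)
        out[i] <- paste0(paste(sample_bases(left), collapse = ""), cds,
                         paste(sample_bases(pad_n - left), collapse = ""))
      }
    }
    names(out) <- sprintf("decoy_%s_%03d", kind, seq_len(n))
    out
  })
}

# amino acid -> RNA codons (standard code)
codon_table <- function() {
  codons <- as.character(Biostrings::GENETIC_CODE)
  rna <- chartr("T", "U", names(Biostrings::GENETIC_CODE))
  split(rna, codons)
}

#' Generate a reference precursor population for cutoff derivation
#'
#' Draws `n` hairpin precursors with varied stem lengths, loop sizes, GC
#' bias and duplex mismatches (0-5, the full range compatible with the
#' fewer-than-6 duplex criterion), emulating the spread of a curated
#' precursor database under the built-in folding model.
#'
#' @param n population size.
#' @param seed base seed.
#' @return character vector of precursor sequences.
#' @export
make_reference_set <- function(n = 1000L, seed = 1L) {
  with_seed(seed, {
    specs <- data.frame(
      mature_len = sample(20:22, n, replace = TRUE),
      pad_len = sample(3:8, n, replace = TRUE),
      loop_len = sample(6:10, n, replace = TRUE),
      flank_len = sample(8:16, n, replace = TRUE),
      gc_bias = runif(n, 0.35, 0.65),
      stem_mismatches = sample(0:5, n, replace = TRUE),
      seed = sample.int(2^30, n))
    vapply(seq_len(n), function(k) {
      motif <- paste(sample(RNA_BASES, 3, replace = TRUE), collapse = "")
      # a rare spec draw (weak stem plus many mismatches) may not be
      # realizable; redraw its seed deterministically until it is
      for (redraw in 0:9) {
        sp <- hairpin_spec(mature_len = specs$mature_len[k],
                           stem_mismatches = specs$stem_mismatches[k],
                           loop_len = specs$loop_len[k],
                           pad_len = specs$pad_len[k],
                           flank_len = specs$flank_len[k],
                           gc_bias = specs$gc_bias[k],
                           signature_motif = motif, signature_copies = 3L,
                           seed = child_seed(specs$seed[k], redraw))
        p <- tryCatch(make_precursor(sp), error = function(e) NULL)
        if (!is.null(p)) return(p$seq)
      }
      stop("unrealizable reference spec at index ", k)
    }, character(1))
  })
}

#' Generate a complete synthetic prediction corpus with ground truth
#'
#' Builds `n_planted` miRNA families (each with `members_per_family` known
#' precursors for the SSR catalog plus one planted precursor embedded in
#' an EST-like subject) and `n_decoys` decoy subjects (dinucleotide
#' shuffles of the planted subjects). Queries are the known mature
#' sequences of each family; every planted precursor carries its family's
#' mature exactly, so ground-truth recovery is well defined.
#'
#' @param n_planted number of planted families/subjects.
#' @param n_decoys number of decoy subjects.
#' @param members_per_family known members per family (catalog input).
#' @param est_flank EST flank length around each planted precursor.
#' @param minus_every embed every k-th planted precursor on the minus
#'   strand.
#' @param seed base seed.
#' @param base_spec template [hairpin_spec()] for all precursors.
#' @return list with `queries` (named matures), `subjects` (named,
#'   planted + decoys), `families` (family -> member sequences, catalog
#'   input), `truth` (data.frame: subject_id, family, mature_seq, spans,
#'   strand), `planted_ids`, `decoy_ids`.
#' @export
make_corpus <- function(n_planted = 20L, n_decoys = 200L,
                        members_per_family = 3L, est_flank = 60L,
                        minus_every = 5L, seed = 1L,
                        base_spec = hairpin_spec()) {
  fam_ids <- paste0("MIR", 100L + seq_len(n_planted))
  queries <- character(0)
  subjects <- character(0)
  families <- list()
  truth <- list()
  # family motifs are AU-rich trinucleotides (at least two of A/U), the
  # composition dominating real plant SSR signatures; this also keeps the
  # planted signal well separated from incidental GC-rich stem 3-mers
  motif_pool <- apply(expand.grid(RNA_BASES, RNA_BASES, RNA_BASES), 1,
                      paste, collapse = "")
  au_count <- vapply(strsplit(motif_pool, ""), function(ch) {
    sum(ch %in% c("A", "U"))
  }, integer(1))
  motif_pool <- motif_pool[au_count >= 2L]
  for (f in seq_len(n_planted)) {
    fseed <- child_seed(seed, f)
    motif <- with_seed(child_seed(fseed, 777), sample(motif_pool, 1L))
    # the corpus construction guarantees that the planted motif IS the
    # family's SSR signature (the ground truth assumes criterion c7 is
    # checkable against it); redraw the family if an incidental shared
    # 3-mer outcompetes the planted one
    fam <- NULL
    for (redraw in 0:19) {
      cand <- make_family(members_per_family, motif,
                          seed = child_seed(fseed, redraw),
                          base_spec = base_spec)
      sig <- family_signature(vapply(cand, `[[`, character(1), "seq"))
      if (!is.null(sig) && sig$motif == motif) {
        fam <- cand
        break
      }
    }
    if (is.null(fam)) stop("could not realize family signature for ",
                           fam_ids[f])
    families[[fam_ids[f]]] <- vapply(fam, `[[`, character(1), "seq")
    mature <- substring(fam[["a"]]$seq, fam[["a"]]$mature_span[1],
                        fam[["a"]]$mature_span[2])
    qname <- paste0("syn-miR", sub("^MIR", "", fam_ids[f]), "a")
    queries[qname] <- mature
    psp <- base_spec
    psp$signature_motif <- motif
    psp$mature_seq <- mature
    psp$seed <- child_seed(fseed, 999)
    planted <- make_precursor(psp)
    strand <- if (f %% minus_every == 0L) "-" else "+"
    emb <- embed_in_est(planted, flank_len = est_flank,
                        seed = child_seed(fseed, 555), strand = strand)
    sid <- sprintf("planted_%03d", f)
    subjects[sid] <- emb$seq
    truth[[f]] <- data.frame(
      subject_id = sid, family = fam_ids[f], mature_seq = mature,
      precursor_start = emb$precursor_span[1],
      precursor_end = emb$precursor_span[2],
      mature_start = emb$mature_span[1], mature_end = emb$mature_span[2],
      strand = strand, stringsAsFactors = FALSE)
  }
  decoys <- make_decoys(n_decoys, kind = "shuffled",
                        seed = child_seed(seed, 31337),
                        templates = unname(subjects))
  list(queries = queries, subjects = c(subjects, decoys),
       families = families,
       truth = do.call(rbind, truth),
       planted_ids = names(subjects), decoy_ids = names(decoys))
}

#' Generate a collapsed read library supporting a set of matures
#'
#' @param matures character vector of mature sequences to support.
#' @param counts read counts per mature (recycled).
#' @param n_noise number of random unrelated reads (count 1 each).
#' @param read_len length of noise reads.
#' @param seed RNG seed.
#' @return data.frame with columns `seq`, `count`.
#' @export
make_reads <- function(matures, counts = 10L, n_noise = 50L,
                       read_len = 21L, seed = 1L) {
  with_seed(seed, {
    noise <- vapply(seq_len(n_noise), function(i) {
      paste(sample_bases(read_len), collapse = "")
    }, character(1))
    df <- rbind(
      data.frame(seq = unname(matures),
                 count = rep_len(counts, length(matures)),
                 stringsAsFactors = FALSE),
      data.frame(seq = noise, count = 1L, stringsAsFactors = FALSE))
    agg <- tapply(df$count, df$seq, sum)
    out <- data.frame(seq = names(agg), count = as.numeric(agg),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
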