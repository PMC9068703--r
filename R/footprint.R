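# Phylogenetic footprinting: conserved palindromic motif discovery in
# orthologous upstream regions, PWM construction and log-odds scanning.
#
# The motif model is deliberately simple and transparent: a star multiple
# alignment anchors orthologous promoters, gap-free windows are ranked by
# conservation weighted by palindromicity (LysR-family operators are
# approximate palindromes bound by homodimers), and the winning window's
# per-sequence sites feed a position weight matrix.

IUPAC_LETTERS <- names(Biostrings::IUPAC_CODE_MAP)

#' Reverse complement of a DNA string
#'
#' Watson-Crick complement, reversed. Accepts the full IUPAC alphabet,
#' case-insensitively; output is uppercase.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  up <- toupper(seq)
  bad <- !grepl(paste0("^[", paste(IUPAC_LETTERS, collapse = ""), "]*$"), up)
  if (any(bad)) {
    stop("non-IUPAC character in sequence: '", seq[bad][1L], "'")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
}

#' Palindromicity of a DNA site
#'
#' Fraction of positions at which the site agrees with its own reverse
#' complement; `N` matches anything. A perfect palindrome scores 1. The
#' score is symmetric: a site and its reverse complement score identically.
#'
#' @param site DNA string (non-empty).
#' @return Numeric in `[0, 1]`.
#' @export
palindrome_score <- function(site) {
  stopifnot(nzchar(site))
  a <- strsplit(toupper(site), "")[[1L]]
  b <- strsplit(reverse_complement(site), "")[[1L]]
  mean(a == b | a == "N" | b == "N")
}

# Substitution matrix shared by all DNA alignments in the package.
dna_submat <- function(match = 2, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match = match,
                                           mismatch = mismatch,
                                           baseOnly = FALSE)
}

nw_align <- function(a, b, match = 2, mismatch = -1, gap = -1,
                     gap_open = -8, score_only = FALSE) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = dna_submat(match, mismatch),
    gapOpening = -gap_open, gapExtension = -gap,
    scoreOnly = score_only
  )
}

# vectorized: align many patterns against one subject in a single call
nw_align_many <- function(patterns, subject, match = 2, mismatch = -1,
                          gap = -1, gap_open = -8, score_only = FALSE) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global",
    substitutionMatrix = dna_submat(match, mismatch),
    gapOpening = -gap_open, gapExtension = -gap,
    scoreOnly = score_only
  )
}

# Gap counts before each center residue (and after the last) in an aligned
# center string; used to merge pairwise alignments on center coordinates.
gap_profile <- function(aligned_center) {
  chars <- strsplit(aligned_center, "")[[1L]]
  n_res <- sum(chars != "-")
  prof <- integer(n_res + 1L)
  slot <- 1L
  run <- 0L
  for (ch in chars) {
    if (ch == "-") {
      run <- run + 1L
    } else {
      prof[slot] <- run
      slot <- slot + 1L
      run <- 0L
    }
  }
  prof[n_res + 1L] <- run
  prof
}

# Re-pad one aligned row so its center-gap profile matches the master
# profile (extra gaps are appended on the left edge of each run; the choice
# within a run is arbitrary but must be deterministic).
expand_row <- function(aligned_center, aligned_other, master) {
  own <- gap_profile(aligned_center)
  extra <- master - own
  c_chars <- strsplit(aligned_center, "")[[1L]]
  o_chars <- strsplit(aligned_other, "")[[1L]]
  out <- character(0L)
  slot <- 1L
  pending <- TRUE
  i <- 1L
  while (i <= length(c_chars)) {
    if (pending) {
      out <- c(out, rep("-", extra[slot]))
      pending <- FALSE
    }
    if (c_chars[i] != "-") {
      slot <- slot + 1L
      pending <- TRUE
    }
    out <- c(out, o_chars[i])
    i <- i + 1L
  }
  if (pending) out <- c(out, rep("-", extra[slot]))
  paste(out, collapse = "")
}

#' Star multiple alignment of promoter sequences
#'
#' The center sequence is the one maximizing the summed pairwise global
#' (Needleman-Wunsch) alignment scores against all others; every other
#' sequence is aligned to the center pairwise and the alignments are merged
#' on center coordinates ("once a gap, always a gap"). Deterministic given
#' the scoring parameters; ties in center choice break by input order.
#'
#' @param seqs Named character vector of >= 2 DNA sequences.
#' @param match,mismatch Substitution scores (defaults +2/-1).
#' @param gap,gap_open Affine gap scores: per-residue extension and opening
#'   (defaults -1 and -8; opening gaps is expensive because short
#'   intergenic orthologs diverge almost exclusively by substitution, so
#'   cheap gaps mostly model alignment noise).
#' @param center Optional name or index of the center sequence; when `NULL`
#'   it is chosen by the summed-score rule.
#' @return List of class `star_alignment`: `rows` (named character vector of
#'   equal-length gapped strings), `center` (name of the center sequence),
#'   and the scoring parameters.
#' @export
star_align <- function(seqs, match = 2, mismatch = -1, gap = -1,
                       gap_open = -8, center = NULL) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (any(!nzchar(seqs))) stop("empty sequence in input")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  n <- length(seqs)
  if (is.null(center)) {
    # pairwise global scores are symmetric: upper triangle suffices
    score_sum <- numeric(n)
    for (i in seq_len(n - 1L)) {
      rest <- seq(i + 1L, n)
      s <- nw_align_many(seqs[rest], seqs[[i]], match, mismatch, gap,
                         gap_open, score_only = TRUE)
      score_sum[i] <- score_sum[i] + sum(s)
      score_sum[rest] <- score_sum[rest] + s
    }
    center_idx <- which.max(score_sum)
  } else {
    center_idx <- if (is.character(center)) match(center, names(seqs)) else
      as.integer(center)
    stopifnot(!is.na(center_idx), center_idx >= 1L, center_idx <= n)
  }
  center <- seqs[[center_idx]]

  aligned_centers <- character(n)
  aligned_others <- character(n)
  others <- setdiff(seq_len(n), center_idx)
  aln <- nw_align_many(seqs[others], center, match, mismatch, gap,
                       gap_open)
  # pattern = other sequence, subject = center
  aligned_others[others] <-
    as.character(Biostrings::alignedPattern(aln))
  aligned_centers[others] <-
    as.character(Biostrings::alignedSubject(aln))
  profiles <- lapply(seq_len(n), function(i) {
    if (i == center_idx) gap_profile(gsub("-", "", center)) * 0L else
      gap_profile(aligned_centers[i])
  })
  master <- Reduce(pmax, profiles)

  rows <- character(n)
  center_plain <- center
  for (i in seq_len(n)) {
    if (i == center_idx) {
      rows[i] <- expand_row(center_plain, center_plain, master)
    } else {
      rows[i] <- expand_row(aligned_centers[i], aligned_others[i], master)
    }
  }
  names(rows) <- names(seqs)
  structure(
    list(rows = rows, center = names(seqs)[center_idx],
         match = match, mismatch = mismatch, gap = gap,
         gap_open = gap_open),
    class = "star_alignment"
  )
}

alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(unname(alignment$rows), ""))
}

majority_consensus <- function(mat_window) {
  apply(mat_window, 2L, function(col) {
    col <- col[col != "-"]
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1L]
  })
}

#' Rank conserved gap-free windows of an alignment
#'
#' Every window of the requested width that is gap-free in all rows is
#' scored by conservation (mean per-column majority-base frequency);
#' windows at or above `min_identity` are ranked by
#' `conservation * (0.5 + 0.5 * palindromicity)` of the majority-base
#' consensus, so an imperfect palindrome is down-weighted but never
#' excluded. Ties break leftmost.
#'
#' @param alignment A `star_alignment`.
#' @param width Window width in bp.
#' @param min_identity Minimum mean conservation to report (default 0.7).
#' @return `data.frame` with `start` (1-based alignment column),
#'   `conservation`, `palindromicity`, `rank_score`, `consensus`, sorted
#'   best-first. Zero rows when no window qualifies.
#' @export
conserved_windows <- function(alignment, width, min_identity = 0.7) {
  mat <- alignment_matrix(alignment)
  L <- ncol(mat)
  if (width > L) stop("width exceeds alignment length")
  gap_free_col <- colSums(mat == "-") == 0L
  col_cons <- vapply(seq_len(L), function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) return(0)
    max(table(col)) / nrow(mat)
  }, numeric(1L))

  starts <- seq_len(L - width + 1L)
  ok <- vapply(starts, function(s) all(gap_free_col[s:(s + width - 1L)]),
               logical(1L))
  starts <- starts[ok]
  if (length(starts) == 0L) {
    return(data.frame(start = integer(0L), conservation = numeric(0L),
                      palindromicity = numeric(0L), rank_score = numeric(0L),
                      consensus = character(0L), stringsAsFactors = FALSE))
  }
  res <- lapply(starts, function(s) {
    cols <- s:(s + width - 1L)
    cons <- mean(col_cons[cols])
    cs <- paste(majority_consensus(mat[, cols, drop = FALSE]), collapse = "")
    pal <- palindrome_score(cs)
    data.frame(start = s, conservation = cons, palindromicity = pal,
               rank_score = cons * (0.5 + 0.5 * pal), consensus = cs,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res <- res[res$conservation >= min_identity, , drop = FALSE]
  res <- res[order(-res$rank_score, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a position weight matrix from aligned binding sites
#'
#' `pwm[b, j] = (count + pseudocount) / (n + 4 * pseudocount)`. `N` in a
#' site contributes 1/4 to each base count. Also computes the IUPAC
#' consensus, per-column information content and the palindromicity of the
#' majority consensus.
#'
#' @param sites Character vector of equal-width sites, or a `data.frame`
#'   with columns `sequence`, `source`, `offset`, `strand` (provenance is
#'   carried into the motif).
#' @param pseudocount Added to every base count (default 0.5).
#' @param major,minor Consensus thresholds, see [consensus_from_pwm()].
#' @return Object of class `motif`.
#' @export
build_pwm <- function(sites, pseudocount = 0.5, major = 0.75, minor = 0.25) {
  if (is.data.frame(sites)) {
    site_df <- sites
    seqs <- toupper(sites$sequence)
  } else {
    seqs <- toupper(sites)
    site_df <- data.frame(sequence = seqs,
                          source = paste0("site", seq_along(seqs)),
                          offset = NA_integer_,
                          strand = "+",
                          stringsAsFactors = FALSE)
  }
  if (length(seqs) < 1L) stop("need at least one site")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("sites have unequal widths: ",
                            paste(w, collapse = ", "))
  chars <- do.call(rbind, strsplit(seqs, ""))
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0, nrow = 4L, ncol = w, dimnames = list(bases, NULL))
  for (b in bases) counts[b, ] <- colSums(chars == b)
  counts <- counts + matrix(colSums(chars == "N") / 4, nrow = 4L,
                            ncol = w, byrow = TRUE)
  pwm <- sweep(counts + pseudocount, 2L,
               colSums(counts) + 4 * pseudocount, "/")
  maj <- bases[apply(pwm, 2L, which.max)]
  structure(
    list(sites = site_df,
         width = w,
         pwm = pwm,
         consensus = consensus_from_pwm(pwm, major = major, minor = minor),
         info_content = information_content(pwm),
         palindromicity = palindrome_score(paste(maj, collapse = ""))),
    class = "motif"
  )
}

#' @export
print.motif <- function(x, ...) {
  cat("<motif> width", x$width, "consensus", x$consensus,
      sprintf("palindromicity %.2f", x$palindromicity), "\n")
  cat("  sites:", nrow(x$sites), " total IC:",
      sprintf("%.1f bits", sum(x$info_content)), "\n")
  invisible(x)
}

#' IUPAC consensus of a PWM
#'
#' Per column: the single base if its frequency reaches `major`; otherwise
#' the bases at or above `minor` are collected and encoded as the matching
#' two-base IUPAC letter. Three or more qualifying bases — or none — give
#' `N`: with near-uniform columns a three-base degenerate letter carries no
#' usable constraint at these matrix sizes.
#'
#' @param pwm 4 x width matrix with rownames `A`, `C`, `G`, `T`, columns
#'   summing to 1.
#' @param major Frequency for a unique base call (default 0.75).
#' @param minor Inclusion frequency for degenerate calls (default 0.25).
#' @return IUPAC consensus string.
#' @export
consensus_from_pwm <- function(pwm, major = 0.75, minor = 0.25) {
  code_for <- function(bases) {
    hits <- vapply(Biostrings::IUPAC_CODE_MAP, function(expansion) {
      setequal(strsplit(expansion, "")[[1L]], bases)
    }, logical(1L))
    names(Biostrings::IUPAC_CODE_MAP)[hits][1L]
  }
  letters <- apply(pwm, 2L, function(col) {
    top <- names(col)[which.max(col)]
    if (col[top] >= major) return(top)
    qual <- names(col)[col >= minor]
    if (length(qual) == 1L) return(qual)
    if (length(qual) == 2L) return(code_for(qual))
    "N"
  })
  paste(letters, collapse = "")
}

#' Per-column information content of a PWM (bits)
#'
#' `2 + sum_b p log2 p`, with `0 log 0 = 0`; ranges from 0 (uniform) to 2
#' (fixed base). These are the column heights of a sequence logo.
#'
#' @param pwm 4 x width probability matrix.
#' @return Numeric vector, one value per column.
#' @export
information_content <- function(pwm) {
  apply(pwm, 2L, function(col) {
    terms <- ifelse(col > 0, col * log2(col), 0)
    2 + sum(terms)
  })
}

#' Number of positions of a sequence not covered by an IUPAC consensus
#'
#' A position matches when the sequence base is in the expansion of the
#' consensus letter (so `N` matches anything). Used to compare a recovered
#' consensus to a known implanted site.
#'
#' @param consensus IUPAC string.
#' @param seq DNA string of the same length.
#' @return Integer count of mismatching positions.
#' @export
consensus_mismatches <- function(consensus, seq) {
  a <- strsplit(toupper(consensus), "")[[1L]]
  b <- strsplit(toupper(seq), "")[[1L]]
  stopifnot(length(a) == length(b))
  ok <- mapply(function(code, base) {
    grepl(base, Biostrings::IUPAC_CODE_MAP[[code]], fixed = TRUE) ||
      base == "N"
  }, a, b)
  sum(!ok)
}

# Log-odds lookup matrix against a background, with an all-zero N row so
# ambiguous reference bases score neutrally.
log_odds_matrix <- function(pwm, background = rep(0.25, 4)) {
  lo <- log2(sweep(pwm, 1L, background, "/"))
  rbind(lo, N = 0)
}

scan_one_strand <- function(lo, chars, width) {
  L <- length(chars)
  n_win <- L - width + 1L
  if (n_win < 1L) return(numeric(0L))
  scores <- numeric(n_win)
  row_idx <- match(chars, rownames(lo))
  row_idx[is.na(row_idx)] <- which(rownames(lo) == "N")
  for (j in seq_len(width)) {
    scores <- scores + lo[cbind(row_idx[j:(j + n_win - 1L)], j)]
  }
  scores
}

#' Scan a sequence with a motif PWM
#'
#' Log-odds scores against a background (uniform by default) at every
#' offset on both strands; hits at or above `threshold` are returned sorted
#' by offset, `+` strand first on ties. Offsets are 0-based on the forward
#' strand of `seq`; minus-strand hits report the reverse complement of the
#' window as their site sequence.
#'
#' @param motif A `motif`.
#' @param seq DNA string, length >= motif width.
#' @param threshold Minimum log-odds score.
#' @param background Base frequencies `A`, `C`, `G`, `T` (default uniform).
#' @param source Id recorded for the scanned sequence.
#' @return `data.frame` with `source`, `offset`, `strand`, `score`,
#'   `sequence`.
#' @export
scan_sequence <- function(motif, seq, threshold,
                          background = rep(0.25, 4), source = "seq") {
  up <- toupper(seq)
  w <- motif$width
  if (nchar(up) < w) stop("sequence shorter than motif width")
  lo <- log_odds_matrix(motif$pwm, background)
  fwd_chars <- strsplit(up, "")[[1L]]
  rev_chars <- strsplit(reverse_complement(up), "")[[1L]]
  fwd <- scan_one_strand(lo, fwd_chars, w)
  rev <- scan_one_strand(lo, rev_chars, w)
  L <- nchar(up)
  # small tolerance so a threshold set to the exact maximum score still
  # admits the maximal site despite summation-order rounding
  f_idx <- which(fwd >= threshold - 1e-9)
  r_idx <- which(rev >= threshold - 1e-9)
  hits <- rbind(
    data.frame(offset = f_idx - 1L, strand = rep("+", length(f_idx)),
               score = fwd[f_idx], stringsAsFactors = FALSE),
    data.frame(offset = L - w - (r_idx - 1L),
               strand = rep("-", length(r_idx)),
               score = rev[r_idx], stringsAsFactors = FALSE)
  )
  if (nrow(hits) == 0L) {
    return(data.frame(source = character(0L), offset = integer(0L),
                      strand = character(0L), score = numeric(0L),
                      sequence = character(0L), stringsAsFactors = FALSE))
  }
  win <- substring(up, hits$offset + 1L, hits$offset + w)
  hits$sequence <- ifelse(hits$strand == "+", win, reverse_complement(win))
  hits <- data.frame(source = source, hits, stringsAsFactors = FALSE)
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Maximum attainable log-odds score of a motif
#' @param motif A `motif`.
#' @param background Background base frequencies.
#' @return Numeric scalar.
#' @export
max_score <- function(motif, background = rep(0.25, 4)) {
  lo <- log2(sweep(motif$pwm, 1L, background, "/"))
  sum(apply(lo, 2L, max))
}

#' Discover a conserved motif in orthologous upstream regions
#'
#' The phylogenetic footprinting pipeline: orient every sequence against a
#' center (each non-center sequence enters in whichever strand aligns
#' better), build a star alignment, rank conserved gap-free windows with
#' [conserved_windows()], take the top window, extract the per-sequence
#' sites with provenance, and build a PWM. The result is invariant to the
#' input order of the sequences and to reverse-complementing any input
#' (the affected site is simply reported on the other strand).
#'
#' @param upstream_set Named character vector of orthologous upstream
#'   sequences (>= 2).
#' @param width Motif width in bp (default 15, the canonical width of the
#'   palindromic LysR operator studied here).
#' @param min_identity Passed to [conserved_windows()].
#' @param match,mismatch,gap Alignment scores, see [star_align()].
#' @return A `motif` whose `sites` table records, per input sequence, the
#'   chosen site, its 0-based offset in the original sequence and the
#'   strand it was found on. `NULL`-like empty motif errors are avoided: if
#'   no conserved window exists the function errors.
#' @export
discover_motif <- function(upstream_set, width = 15L, min_identity = 0.6,
                           match = 2, mismatch = -1, gap = -1,
                           gap_open = -8) {
  if (length(upstream_set) < 2L) stop("need at least 2 sequences")
  if (is.null(names(upstream_set))) {
    names(upstream_set) <- paste0("seq", seq_along(upstream_set))
  }
  seqs <- toupper(upstream_set)

  # canonical processing order: independent of the caller's ordering
  ord <- order(names(seqs))
  seqs <- seqs[ord]

  # strand-canonical form of each sequence, so a flipped input is restored
  canon <- vapply(seqs, function(s) {
    rc <- reverse_complement(s)
    if (s <= rc) s else rc
  }, character(1L))
  was_flipped <- canon != seqs

  n <- length(canon)
  canon_rc <- reverse_complement(canon)
  # orientation-aware pairwise scores for center selection; scores are
  # order- and strand-symmetric, so one triangle with both orientations
  # of one side suffices
  best_sum <- numeric(n)
  for (i in seq_len(n - 1L)) {
    rest <- seq(i + 1L, n)
    s_f <- nw_align_many(canon[rest], canon[[i]], match, mismatch, gap,
                         gap_open, score_only = TRUE)
    s_r <- nw_align_many(canon_rc[rest], canon[[i]], match, mismatch,
                         gap, gap_open, score_only = TRUE)
    s <- pmax(s_f, s_r)
    best_sum[i] <- best_sum[i] + sum(s)
    best_sum[rest] <- best_sum[rest] + s
  }
  center_idx <- which.max(best_sum)

  oriented <- canon
  flipped_vs_canon <- logical(n)
  others <- setdiff(seq_len(n), center_idx)
  s_f <- nw_align_many(canon[others], canon[[center_idx]],
                       match, mismatch, gap, gap_open, score_only = TRUE)
  s_r <- nw_align_many(canon_rc[others], canon[[center_idx]],
                       match, mismatch, gap, gap_open, score_only = TRUE)
  flip <- others[s_r > s_f]
  oriented[flip] <- canon_rc[flip]
  flipped_vs_canon[flip] <- TRUE

  aln <- star_align(oriented, match = match, mismatch = mismatch,
                    gap = gap, gap_open = gap_open, center = center_idx)
  wins <- conserved_windows(aln, width = width, min_identity = min_identity)
  if (nrow(wins) == 0L) {
    stop("no conserved gap-free window of width ", width,
         " at identity >= ", min_identity)
  }
  top <- wins[1L, ]

  mat <- alignment_matrix(aln)
  cols <- top$start:(top$start + width - 1L)
  site_seq <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
  # offset of the site within each oriented sequence
  offset_oriented <- apply(mat[, seq_len(top$start - 1L), drop = FALSE], 1L,
                           function(r) sum(r != "-"))
  # map back to the orientation the caller supplied
  net_flip <- xor(was_flipped, flipped_vs_canon)
  lens <- nchar(seqs)
  site_out <- ifelse(net_flip, reverse_complement(site_seq), site_seq)
  # report the site as observed in the oriented (motif) frame, with the
  # strand and offset referring to the caller's sequence
  offset_caller <- ifelse(net_flip, lens - (offset_oriented + width),
                          offset_oriented)
  sites <- data.frame(
    sequence = site_seq,
    source = names(seqs),
    offset = as.integer(offset_caller),
    strand = ifelse(net_flip, "-", "+"),
    stringsAsFactors = FALSE
  )
  motif <- build_pwm(sites)
  motif$window <- top
  motif$alignment <- aln
  # keep site_out so callers can confirm the caller-frame sequences
  motif$sites$sequence_caller_frame <- site_out
  motif
}

#' Serialize a motif to MEME minimal format plus a JSON sidecar
#'
#' @param motif A `motif`.
#' @param path Output file stem; writes `<path>.meme` and `<path>.json`.
#' @export
write_motif <- function(motif, path) {
  meme <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    "A 0.25 C 0.25 G 0.25 T 0.25", "",
    sprintf("MOTIF %s", motif$consensus),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            motif$width, nrow(motif$sites)),
    apply(motif$pwm, 2L, function(col) {
      sprintf(" %8.6f %8.6f %8.6f %8.6f", col[1], col[2], col[3], col[4])
    })
  )
  writeLines(meme, paste0(path, ".meme"))
  sidecar <- list(
    consensus = motif$consensus,
    width = motif$width,
    palindromicity = motif$palindromicity,
    info_content = motif$info_content,
    sites = motif$sites[, c("sequence", "source", "offset", "strand")]
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(motif)
}
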