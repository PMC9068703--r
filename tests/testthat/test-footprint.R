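# Motif primitives: reverse complement, palindromicity, star alignment,
# conserved windows, PWM construction and log-odds scanning.

test_that("reverse complement maps the printed ptrR site onto the sad site", {
  sites <- ptrr_sites()
  ptrR <- sites$site[sites$gene == "ptrR"]
  sad <- sites$site[sites$gene == "sad"]
  expect_identical(reverse_complement(ptrR), toupper(sad))
  expect_identical(reverse_complement("A"), "T")
  expect_error(reverse_complement("ACGQ"), "non-IUPAC")
})

test_that("reverse complement is an involution on random 1000-mers", {
  for (seed in 1:5) {
    s <- random_seq(1000L, seed = seed)
    expect_identical(reverse_complement(reverse_complement(s)), s)
  }
})

test_that("palindrome score: worked example, perfect palindrome, symmetry", {
  expect_equal(palindrome_score("TTCACGAATCGAGAA"), 12 / 15)
  expect_equal(palindrome_score("ACGT"), 1)
  expect_equal(palindrome_score("NNNN"), 1)
  for (seed in 1:10) {
    s <- random_seq(16L, seed = seed)
    expect_equal(palindrome_score(s),
                 palindrome_score(reverse_complement(s)))
  }
})

test_that("star alignment of identical sequences is gap-free and fully conserved", {
  s <- random_seq(60L, seed = 4L)
  al <- star_align(stats::setNames(rep(s, 4L), paste0("s", 1:4)))
  expect_false(any(grepl("-", al$rows)))
  cw <- conserved_windows(al, 15L)
  expect_true(all(cw$conservation == 1))
})

test_that("two-sequence star alignment equals plain pairwise alignment", {
  a <- "ACGTACGGTACGGATT"
  b <- "ACGTACGTACGAT"
  al <- star_align(c(x = a, y = b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -1, baseOnly = FALSE),
    gapOpening = 8, gapExtension = 1)
  expect_identical(unname(al$rows[["x"]]),
                   as.character(Biostrings::alignedPattern(aln)))
  expect_identical(unname(al$rows[["y"]]),
                   as.character(Biostrings::alignedSubject(aln)))
  expect_error(star_align(c(x = "ACGT", y = "")), "empty")
})

test_that("star alignment rows degap to their inputs with equal widths", {
  withr::with_seed(21L, {
    for (trial in 1:10) {
      n <- sample(3:6, 1L)
      seqs <- stats::setNames(
        vapply(seq_len(n),
               function(i) random_seq(sample(40:80, 1L)), character(1L)),
        paste0("s", seq_len(n)))
      al <- star_align(seqs)
      expect_length(unique(nchar(al$rows)), 1L)
      expect_identical(gsub("-", "", al$rows), seqs[names(al$rows)])
    }
  })
})

test_that("a fully conserved perfect palindrome ranks first among windows", {
  pal <- "TTCACGCGTGAA"  # 12-bp perfect palindrome
  flank_l <- random_seq(30L, seed = 5L)
  flank_r <- random_seq(30L, seed = 6L)
  s <- paste0(flank_l, pal, flank_r)
  al <- star_align(stats::setNames(rep(s, 5L), paste0("s", 1:5)))
  cw <- conserved_windows(al, nchar(pal))
  expect_equal(cw$start[1L], 31L)
  expect_equal(cw$palindromicity[1L], 1)
})

test_that("min_identity = 1 on a diverged alignment yields no windows", {
  withr::with_seed(31L, {
    seqs <- vapply(1:4, function(i) random_seq(60L), character(1L))
    names(seqs) <- paste0("s", 1:4)
    al <- star_align(seqs)
    cw <- conserved_windows(al, 10L, min_identity = 1)
    expect_equal(nrow(cw), 0L)
  })
})

test_that("PWM columns normalize, IC is bounded, worked consensus matches", {
  m <- build_pwm(c("TTCACGAATCGAGAA", "TTCACAAATAGAGAA", "TTCACTAATTGAGAA"),
                 pseudocount = 0)
  expect_equal(unname(colSums(m$pwm)), rep(1, 15L), tolerance = 1e-9)
  expect_true(all(m$info_content >= 0 & m$info_content <= 2))
  expect_identical(m$consensus, "TTCACNAATNGAGAA")
  # single site, no pseudocount: every column fully informative
  m1 <- build_pwm("TTCACGAATCGAGAA", pseudocount = 0)
  expect_equal(unname(m1$info_content), rep(2, 15L))
  # uniform column: zero bits
  expect_equal(information_content(matrix(0.25, 4L, 1L,
                                          dimnames = list(c("A", "C",
                                                            "G", "T")))),
               0)
  expect_error(build_pwm(c("ACGT", "ACG")), "width")
})

test_that("two-base degenerate columns get IUPAC codes", {
  m <- build_pwm(c("AC", "AG"), pseudocount = 0)
  expect_identical(m$consensus, "AS")  # S = C/G
})

test_that("scanning the consensus sequence at max score gives one + hit at 0", {
  m <- build_pwm(c("TTCACGAATCGAGAA", "TTCACGAATCGAGAA"))
  hits <- scan_sequence(m, "TTCACGAATCGAGAA", threshold = max_score(m))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 0L)
  expect_equal(hits$strand, "+")
})

test_that("a planted sad site is recovered on the minus strand by a ptrR-built PWM", {
  group1 <- c("TTCACGAATCGAGAA", "TTCACAAATAGAGAA", "TTCACTAATTGAGAA")
  m <- build_pwm(group1)
  sad <- "TTCTCGATTCGTGAA"  # revcomp of the ptrR site
  seq <- paste0(random_seq(40L, seed = 7L), sad, random_seq(40L, seed = 8L))
  hits <- scan_sequence(m, seq, threshold = 0.8 * max_score(m))
  expect_true(any(hits$strand == "-" & hits$offset == 40L))
})

test_that("hits on a sequence and its reverse complement are mirror images", {
  m <- build_pwm(c("TTCACGAATCGAGAA", "TTCACAAATAGAGAA"))
  s <- paste0(random_seq(25L, seed = 9L), "TTCACGAATCGAGAA",
              random_seq(25L, seed = 10L))
  thr <- 0.5 * max_score(m)
  fwd <- scan_sequence(m, s, thr)
  rev <- scan_sequence(m, reverse_complement(s), thr)
  L <- nchar(s)
  mirrored <- data.frame(offset = L - m$width - rev$offset,
                         strand = ifelse(rev$strand == "+", "-", "+"),
                         score = rev$score)
  mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
  expect_equal(fwd$offset, mirrored$offset)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$score, mirrored$score, tolerance = 1e-9)
})

test_that("discovery on identical motif-bearing promoters returns the implant exactly", {
  core <- "TTCACGAATCGAGAA"
  s <- paste0(random_seq(50L, seed = 11L), core, random_seq(50L, seed = 12L))
  proms <- stats::setNames(rep(s, 6L), sprintf("p%02d", 1:6))
  m <- discover_motif(proms)
  expect_true(m$consensus == core ||
                m$consensus == reverse_complement(core))
})

test_that("discovery is invariant to input order and to strand-flipping inputs", {
  sp <- synthetic_spec(seed = 13L, motif = "TTCACGAATCGAGAA",
                       n_promoters = 8L)
  proms <- make_ortholog_promoters(sp)$sequences
  m1 <- discover_motif(proms)
  m2 <- discover_motif(rev(proms))
  expect_identical(m1$consensus, m2$consensus)
  expect_identical(m1$sites$sequence, m2$sites$sequence)
  flipped <- proms
  flipped[[3L]] <- reverse_complement(flipped[[3L]])
  m3 <- discover_motif(flipped)
  expect_identical(m1$consensus, m3$consensus)
  # the flipped input's site is reported on the other strand at the
  # mirrored offset
  i <- match(names(proms)[3L], m1$sites$source)
  j <- match(names(proms)[3L], m3$sites$source)
  expect_false(m1$sites$strand[i] == m3$sites$strand[j])
  expect_equal(m3$sites$offset[j],
               nchar(proms[[3L]]) - m1$sites$offset[i] - m1$width)
})

test_that("motif serialization writes MEME matrix plus JSON sidecar", {
  m <- build_pwm(c("TTCACGAATCGAGAA", "TTCACAAATAGAGAA"))
  stem <- tempfile()
  write_motif(m, stem)
  meme <- readLines(paste0(stem, ".meme"))
  expect_true(any(grepl("^letter-probability matrix", meme)))
  side <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(side$width, 15L)
})
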