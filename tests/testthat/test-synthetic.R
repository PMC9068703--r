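# Synthetic-data generators: determinism, planted ground truth, and the
# distributional properties downstream stages rely on.

test_that("the same seed reproduces byte-identical FASTA and GFF output", {
  sp <- synthetic_spec(seed = 51L, n_genomes = 2L)
  g1 <- make_genomes(sp)$genomes[[1L]]
  g2 <- make_genomes(sp)$genomes[[1L]]
  d <- tempfile(); dir.create(d)
  f1 <- file.path(d, c("a.gff3", "a.fa"))
  f2 <- file.path(d, c("b.gff3", "b.fa"))
  write_gff(g1, f1[1L], f1[2L])
  write_gff(g2, f2[1L], f2[2L])
  expect_identical(readLines(f1[1L]), readLines(f2[1L]))
  expect_identical(readLines(f1[2L]), readLines(f2[2L]))
})

test_that("promoters carry the exact motif when conservation is perfect", {
  sp <- synthetic_spec(seed = 52L, motif = "TTCACGAATCGAGAA",
                       motif_conservation = 1, background_divergence = 0)
  pr <- make_ortholog_promoters(sp)
  for (i in seq_along(pr$sequences)) {
    s <- pr$sequences[[i]]
    tr <- pr$truth[i, ]
    window <- substr(s, tr$offset + 1L, tr$offset + 15L)
    if (tr$strand == "-") window <- reverse_complement(window)
    expect_identical(window, pr$implant)
  }
})

test_that("ground-truth offsets always locate the (possibly mutated) implant", {
  sp <- synthetic_spec(seed = 53L, motif = "TTCACGAATCGAGAA")
  pr <- make_ortholog_promoters(sp)
  mism <- vapply(seq_along(pr$sequences), function(i) {
    s <- pr$sequences[[i]]
    tr <- pr$truth[i, ]
    window <- substr(s, tr$offset + 1L, tr$offset + 15L)
    if (tr$strand == "-") window <- reverse_complement(window)
    sum(strsplit(window, "")[[1L]] != strsplit(pr$implant, "")[[1L]])
  }, numeric(1L))
  # 0.95 per-position conservation: mismatch count is small per site
  expect_true(all(mism <= 5))
  expect_lt(mean(mism), 15 * 0.05 * 3)
})

test_that("conserved_fraction drives the planted adjacency labels binomially", {
  sp <- synthetic_spec(seed = 54L, n_genomes = 20L,
                       conserved_fraction = 0.5)
  gd <- make_genomes(sp)
  n_cons <- sum(gd$truth$conserved)
  # 99.9% binomial band around 10/20
  expect_gte(n_cons, qbinom(0.0005, 20L, 0.5))
  expect_lte(n_cons, qbinom(0.9995, 20L, 0.5))
})

test_that("genome layouts are valid and carry the planted sites in sequence", {
  sp <- synthetic_spec(seed = 55L, motif_conservation = 1)
  gd <- make_genomes(sp)
  for (gi in seq_along(gd$genomes)) {
    gn <- gd$genomes[[gi]]
    expect_true(all(gn$genes$end <= nchar(gn$contigs[gn$genes$contig])))
    sites <- gd$truth$sites[gd$truth$sites$genome_id == gn$genome_id, ]
    for (j in seq_len(nrow(sites))) {
      written <- substr(gn$contigs[["chr"]], sites$start[j] + 1L,
                        sites$end[j])
      expect_identical(written, gd$truth$implant)
    }
  }
})

test_that("count means track the planted effects and dispersion shapes variance", {
  sp <- synthetic_spec(seed = 56L, n_genes_counts = 400L,
                       planted_regulon = c(gene_0001 = 3))
  cm <- make_counts(sp)
  expect_equal(dim(cm$counts), c(400L, 10L))
  expect_equal(unname(cm$effects["gene_0001"]), 3)
  expect_true(all(cm$effects[-1L] == 0))
  # Poisson limit: zero dispersion gives variance ~ mean
  sp0 <- synthetic_spec(seed = 57L, nb_dispersion = 0,
                        n_genes_counts = 2000L, mean_count = 50)
  cm0 <- make_counts(sp0)
  m <- rowMeans(cm0$counts[, 1:5])
  v <- apply(cm0$counts[, 1:5], 1L, var)
  # pooled variance-to-mean ratio near 1 (per-gene ratios average out)
  expect_equal(mean(v / pmax(m, 1)), 1, tolerance = 0.1)
  # positive dispersion: clearly overdispersed at high means
  sp1 <- synthetic_spec(seed = 58L, nb_dispersion = 0.3,
                        n_genes_counts = 2000L, mean_count = 50)
  cm1 <- make_counts(sp1)
  m1 <- rowMeans(cm1$counts[, 1:5])
  v1 <- apply(cm1$counts[, 1:5], 1L, var)
  expect_gt(mean(v1 / pmax(m1, 1)), 2)
})

test_that("generators leave the global RNG state untouched", {
  set.seed(123L)
  before <- .Random.seed
  invisible(make_ortholog_promoters(synthetic_spec(seed = 59L,
                                                   n_promoters = 3L)))
  expect_identical(.Random.seed, before)
})
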