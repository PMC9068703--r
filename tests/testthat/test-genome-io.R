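# Genome model, coordinate conventions and format round trips.

test_that("GFF 1-based inclusive coordinates become 0-based half-open", {
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(
    "##gff-version 3",
    "chr\ttest\tgene\t1\t9\t.\t+\t.\tID=gA;locus_tag=gA;Name=alpha",
    "chr\ttest\tgene\t15\t20\t.\t-\t.\tID=gB;locus_tag=gB"
  ), gff)
  writeLines(c(">chr", strrep("ACGT", 10L)), fa)
  g <- read_gff(gff, fa)
  expect_equal(g$genes$start, c(0L, 14L))
  expect_equal(g$genes$end, c(9L, 20L))
  expect_equal(g$genes$name, c("alpha", ""))
})

test_that("malformed coordinates and missing contigs are hard errors", {
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr", strrep("ACGT", 10L)), fa)
  writeLines(c("##gff-version 3",
               "chr\ttest\tgene\t1\tnine\t.\t+\t.\tID=gA"), gff)
  expect_error(read_gff(gff, fa), "line 2")
  writeLines(c("##gff-version 3",
               "plasmid\ttest\tgene\t1\t9\t.\t+\t.\tID=gA"), gff)
  expect_error(read_gff(gff, fa), "plasmid")
})

test_that("a synthetic genome round-trips losslessly through GFF3+FASTA", {
  sp <- synthetic_spec(seed = 3L, n_genomes = 2L)
  gn <- make_genomes(sp)$genomes[[1L]]
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  write_gff(gn, gff, fa)
  back <- read_gff(gff, fa, genome_id = gn$genome_id)
  expect_equal(back$genes[, c("locus_tag", "start", "end", "strand",
                              "feature_kind")],
               gn$genes[, c("locus_tag", "start", "end", "strand",
                            "feature_kind")])
  expect_equal(back$contigs, gn$contigs)
})

test_that("an ncRNA feature named fnrS is annotatable and retrievable", {
  g <- toy_genome()
  gff <- tempfile(fileext = ".gff3")
  fa <- tempfile(fileext = ".fa")
  write_gff(g, gff, fa)
  back <- read_gff(gff, fa)
  hit <- find_gene(back, "fnrS")
  expect_equal(hit$feature_kind, "ncrna")
  expect_equal(hit$locus_tag, "b4699")
})

test_that("divergent pair upstream regions are reverse complements over the shared intergenic span", {
  g <- toy_genome()
  up_ptrR <- upstream_region(find_gene(g, "ptrR"), g)
  up_sad <- upstream_region(find_gene(g, "sad"), g)
  # shared intergenic [1900, 2100): both truncated to 200 bp by the other gene
  expect_equal(c(up_ptrR$start, up_ptrR$end), c(1900L, 2100L))
  expect_equal(c(up_sad$start, up_sad$end), c(1900L, 2100L))
  expect_identical(up_ptrR$sequence, reverse_complement(up_sad$sequence))
})

test_that("upstream regions respect max_len, gene bodies and contig edges", {
  g <- toy_genome()
  up <- upstream_region(find_gene(g, "sad"), g, max_len = 50L)
  expect_equal(nchar(up$sequence), 50L)
  expect_equal(c(up$start, up$end), c(2050L, 2100L))
  # waa2 has only the 20-bp operon gap upstream
  up2 <- upstream_region(find_gene(g, "waa2"), g)
  expect_equal(nchar(up2$sequence), 20L)
  # gene flush at position 0 has no upstream space
  g0 <- annotated_genome("edge", c(c1 = strrep("ACGT", 30L)),
                         data.frame(locus_tag = "e1", name = "",
                                    contig = "c1", start = 0L, end = 30L,
                                    strand = "+", feature_kind = "cds"))
  expect_identical(upstream_region(g0$genes[1L, ], g0)$sequence, "")
})

test_that("extracted upstream sequence re-locates by exact string search", {
  sp <- synthetic_spec(seed = 8L, n_genomes = 1L)
  gn <- make_genomes(sp)$genomes[[1L]]
  gene <- gn$genes[gn$genes$name == "target", , drop = FALSE]
  up <- upstream_region(gene, gn)
  pos <- as.integer(regexpr(
    if (gene$strand == "+") up$sequence else
      reverse_complement(up$sequence),
    gn$contigs[[gene$contig]], fixed = TRUE)) - 1L
  expect_equal(pos, up$start)
})

test_that("DEG TSV loader parses fixtures, preserves order, flags bad rows", {
  t3 <- deg_table(3L)
  expect_equal(nrow(t3), 16L)
  expect_equal(t3$locus_tag[1L], "b3584")  # input order preserved
  expect_equal(t3$log2fc[t3$gene == "yiaT"], 2.8)
  empty <- tempfile(fileext = ".tsv")
  writeLines("locus_tag\tgene\tbase_mean\tlog2fc\tpvalue", empty)
  expect_equal(nrow(read_deg_tsv(empty)), 0L)
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("locus_tag\tgene\tbase_mean\tlog2fc\tpvalue",
               "b0001\tx\t10\ttwo\t0.01"), bad)
  expect_error(read_deg_tsv(bad), "row 1")
})

test_that("BED round trip preserves 0-based half-open intervals", {
  peaks <- data.frame(contig = "chr", start = c(0L, 150L),
                      end = c(50L, 210L), score = c(1.5, 0))
  bed <- tempfile(fileext = ".bed")
  write_bed(peaks, bed)
  back <- read_bed(bed)
  expect_equal(back$start, peaks$start)
  expect_equal(back$end, peaks$end)
  expect_equal(back$score, peaks$score)
})
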