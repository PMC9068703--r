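# Toy genome builders used across the suite. Coordinates are 0-based
# half-open; the divergent ptrR/sad pair shares a 200-bp intergenic region
# and an 8-gene waa-style operon sits downstream.

toy_contig <- function(len = 12000L, seed = 99L) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), len,
                                      replace = TRUE), collapse = ""))
}

# layout (all on "chr"):
#   decoyA [100, 700) +
#   ptrR   [1000, 1900) -   \ divergent pair, shared intergenic
#   sad    [2100, 3000) +   / [1900, 2100)
#   waa operon: 8 genes +, 600 bp each, 20 bp gaps, lead at 3500
#   decoyB [9500, 10100) -
#   fnrS   [10500, 10600) +  (ncRNA)
toy_genome <- function(seed = 99L) {
  waa_starts <- 3500L + (0:7) * 620L
  genes <- data.frame(
    locus_tag = c("b0001", "b1526", "b1525", sprintf("waa%d", 1:8),
                  "b0002", "b4699"),
    name = c("decoyA", "ptrR", "sad", sprintf("waa%d", 1:8),
             "decoyB", "fnrS"),
    contig = "chr",
    start = c(100L, 1000L, 2100L, waa_starts, 9500L, 10500L),
    end = c(700L, 1900L, 3000L, waa_starts + 600L, 10100L, 10600L),
    strand = c("+", "-", "+", rep("+", 8L), "-", "+"),
    feature_kind = c(rep("cds", 12L), "ncrna"),
    stringsAsFactors = FALSE
  )
  annotated_genome("toy", c(chr = toy_contig(seed = seed)), genes)
}

random_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n,
                                  replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
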