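# regulonscout

Inference of regulons for poorly characterized bacterial LysR-type
transcription factors (LTFs), for microbial genomicists who have binding
intervals, knockout expression tables and a handful of related genomes —
but no characterized function for the regulator.

LTFs bind roughly palindromic ~15-bp operators as homodimers, usually in
the promoter of an adjacent (often divergently transcribed) gene, and
that arrangement is conserved across related genomes. `regulonscout`
combines four evidence streams into one scored hypothesis per TF:

1. **Phylogenetic footprinting** — a star multiple alignment of
   orthologous upstream regions; gap-free windows ranked by
   `conservation × (0.5 + 0.5 × palindromicity)`; the winning window's
   sites give a position weight matrix with
   `pwm[b,j] = (n_bj + pc) / (n + 4·pc)`, IUPAC consensus, and
   per-column information content `2 + Σ_b p log2 p` bits, scanned as
   log-odds `Σ_j log2(p_bj / q_b)` on both strands.
2. **ChIP peak assignment** — a peak whose midpoint lies within the
   promoter window upstream of a gene start (and not inside a gene body)
   targets that gene; one intergenic peak may legitimately hit both
   genes of a divergent pair; operon heads propagate to all members.
3. **Conserved neighborhoods** — support of each ortholog group within
   *k* genes of the TF across the genome panel.
4. **Knockout expression** — targets up in the deletion strain
   (log2FC ≥ +1) were repressed, targets down (≤ −1) were activated;
   a simplified score-type negative-binomial test (median-of-ratios
   normalization, common method-of-moments dispersion) handles
   synthetic counts, while published tables are consumed as-is.

Scores are additive over the four streams (unit weights); binding
evidence makes a target "direct", and binding at the TF's own promoter
flags autoregulation.

## Worked example

The classic configuration: a TF divergently opposed to its target across
a shared intergenic region, a ChIP peak between them, and the knockout
table of the adjacent genes.

```r
library(regulonscout)

sites <- ptrr_sites()
reverse_complement(sites$site[sites$gene == "ptrR"])
#> [1] "TTCTCGATTCGTGAA"            # identical to the printed sad site:
                                   # one palindromic operator, two strands
palindrome_score("TTCACGAATCGAGAA")
#> [1] 0.8

build_pwm(c("TTCACGAATCGAGAA", "TTCACAAATAGAGAA", "TTCACTAATTGAGAA"),
          pseudocount = 0)$consensus
#> [1] "TTCACNAATNGAGAA"

# divergent ptrR/sad toy genome + one intergenic peak + published table
genes <- data.frame(
  locus_tag = c("b1526", "b1525", "b1527"),
  name = c("ptrR", "sad", "yneK"), contig = "chr",
  start = c(1000L, 2100L, 3200L), end = c(1900L, 3000L, 3800L),
  strand = c("-", "+", "+"), feature_kind = "cds")
toy <- annotated_genome("toy", c(chr = strrep("ACGT", 1000L)), genes)
ap <- assign_peak_targets(data.frame(contig = "chr", start = 1975L,
                                     end = 2025L), toy)
ev <- build_evidence_table("b1526", deg_table(5L), ap)
regulon_report("b1526", ev, ap)
#> <regulon_hypothesis> b1526
#>   DEGs: 2  binding sites (ChIP/predicted): 1 / 0  autoregulation: TRUE
#>  target score      mode direct deg_log2fc
#>   b1525     2 repressor   TRUE       1.32
#>   b1527     1 repressor  FALSE       2.78
```

The sad gene rises 1.32 log2 units when the regulator is deleted and
carries the binding peak: a direct repressor call, with autoregulation
because the shared peak also sits in the TF's own promoter.

The numbered scripts under `analysis/` run the full workflow on
generated data — `01_simulate.R` (genomes, promoters, peaks, counts),
`02_footprint.R` (motif discovery), `03_peaks_context.R` (assignment,
operons, conserved clusters), `04_deg.R` (table extremes, test
calibration), `05_integrate.R` (the scored regulon reports) — writing
their tables under `results/`. The methods vignette
(`vignettes/regulon-inference.Rmd`) documents the models, defaults and
their rationale.

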