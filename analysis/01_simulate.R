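#!/usr/bin/env Rscript
# Generate the synthetic study dataset every later step consumes:
# a panel of annotated genomes with a divergent TF-target pair and a
# waa-style operon, orthologous promoters around a conserved palindromic
# site, jittered ChIP peaks, and knockout-vs-WT NB counts.

suppressPackageStartupMessages(library(regulonscout))
dir.create("results/synthetic", recursive = TRUE, showWarnings = FALSE)

spec <- synthetic_spec(seed = 20260922L)

gd <- make_genomes(spec)
for (gn in gd$genomes) {
  write_gff(gn,
            file.path("results/synthetic", paste0(gn$genome_id, ".gff3")),
            file.path("results/synthetic", paste0(gn$genome_id, ".fa")))
}
write.table(gd$orthologs, "results/synthetic/orthologs.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

ref <- gd$genomes[[1L]]
sites <- gd$truth$sites[gd$truth$sites$genome_id == ref$genome_id, ]
peaks <- make_peaks(sites, spec, genome = ref)
write_bed(peaks, "results/synthetic/peaks.bed")

proms <- make_ortholog_promoters(spec)
writeLines(unlist(lapply(names(proms$sequences), function(id) {
  c(paste0(">", id), proms$sequences[[id]])
})), "results/synthetic/promoters.fa")

eff_role <- gd$truth$regulon
role <- ref$genes$name
eff <- setNames(ifelse(role %in% names(eff_role), eff_role[role], 0),
                ref$genes$locus_tag)
cm <- make_counts(spec, gene_ids = ref$genes$locus_tag,
                  effects = eff[eff != 0])
write.table(data.frame(locus_tag = rownames(cm$counts), cm$counts),
            "results/synthetic/counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

jsonlite::write_json(
  list(seed = spec$seed,
       implant = gd$truth$implant,
       regulon = as.list(gd$truth$regulon),
       conserved_genomes = sum(gd$truth$conserved),
       promoter_truth = proms$truth,
       sites = gd$truth$sites),
  "results/synthetic/truth.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat("Simulated", length(gd$genomes), "genomes,",
    nrow(peaks), "peaks,", length(proms$sequences), "promoters,",
    nrow(cm$counts), "genes x", ncol(cm$counts), "samples\n")
cat("Implanted operator:", gd$truth$implant, "\n")
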