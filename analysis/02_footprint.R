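#!/usr/bin/env Rscript
# Phylogenetic footprinting: the printed-site worked example (the ptrR and
# sad sites are one palindromic operator read from opposite strands) and
# de novo recovery of the implanted operator from synthetic orthologous
# promoters.

suppressPackageStartupMessages(library(regulonscout))
dir.create("results", showWarnings = FALSE)

sites <- ptrr_sites()
cat("Predicted PtrR operator sites:\n")
print(sites)
ptrR <- toupper(sites$site[sites$gene == "ptrR"])
sad <- toupper(sites$site[sites$gene == "sad"])
cat("\nreverse_complement(ptrR site) == sad site:",
    identical(reverse_complement(ptrR), sad), "\n")
cat("palindrome score of the ptrR site:",
    round(palindrome_score(ptrR), 3), "\n")
cat("palindrome score of the fnrS site:",
    round(palindrome_score(sites$site[sites$gene == "fnrS"]), 3), "\n")

# a three-site PWM reproduces the N positions of the group-1 consensus
m3 <- build_pwm(c("TTCACGAATCGAGAA", "TTCACAAATAGAGAA", "TTCACTAATTGAGAA"),
                pseudocount = 0)
cat("\nthree-site consensus:", m3$consensus, "\n")

# de novo discovery on the simulated ortholog set
spec <- synthetic_spec(seed = 20260922L)
proms <- make_ortholog_promoters(spec)
motif <- discover_motif(proms$sequences)
cat("\nimplanted: ", proms$implant, "\n")
cat("recovered: ", motif$consensus,
    sprintf(" (palindromicity %.2f, total IC %.1f bits)\n",
            motif$palindromicity, sum(motif$info_content)))
cat("mismatches vs implant (either strand):",
    min(consensus_mismatches(motif$consensus, proms$implant),
        consensus_mismatches(motif$consensus,
                             reverse_complement(proms$implant))), "\n")
write_motif(motif, "results/discovered_motif")
cat("wrote results/discovered_motif.{meme,json}\n")
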