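---
title: "Inferring LysR-type regulons from binding, conservation and knockout expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring LysR-type regulons from binding, conservation and knockout expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscout)
```

## The problem

LysR-type transcription factors (LTFs) are the largest family of bacterial
regulators, yet many members even in *Escherichia coli* have no known
function. Four observations make them tractable by desk analysis:

* LTFs bind DNA as homodimers at roughly palindromic ~15-bp operators
  inside ~50-bp protected promoter regions;
* they typically regulate genes adjacent to their own locus, often a
  divergently transcribed neighbor sharing one intergenic region, so a
  single binding event can control both genes;
* that gene neighborhood is conserved across related genomes, and so is
  the operator, which phylogenetic footprinting can recover from an
  alignment of orthologous upstream regions;
* deleting the regulator moves its targets' transcript levels, with the
  sign of the change identifying the mode: a target that rises in the
  knockout was repressed, one that falls was activated.

`regulonscout` operationalizes this reasoning as four evidence streams —
ChIP binding intervals, predicted operator sites, knockout
differential-expression tables, and conserved gene neighborhoods — that
are combined into a per-target evidence table with an additive confidence
score, an activator/repressor call, a direct/indirect flag, and an
autoregulation flag. A synthetic-data module generates inputs with the
statistical structure each stage assumes, so the whole pipeline is
testable end to end without any downloads.

## Coordinate and data conventions

All internal coordinates are 0-based half-open; GFF3 (1-based inclusive)
is converted on read and write, BED is consumed natively. Genes are
sorted by (contig, start, locus tag) and every iteration order in the
package is deterministic, so identical inputs give byte-identical
outputs. Differential-expression tables use a fixed five-column TSV
dialect (`locus_tag`, `gene`, `base_mean`, `log2fc`, `pvalue`); the five
published knockout tables that anchor the worked examples ship as
fixtures in this dialect (one of them prints no p-values, which the
loader represents as `NA`). Mixed-case emphasis in printed binding sites
is preserved for display only; all sequence operations are
case-insensitive.

## Phylogenetic footprinting

The footprinting pipeline is `star_align` →
`conserved_windows` → site extraction → `build_pwm`, wrapped by
`discover_motif()`.

**Star alignment.** The center sequence maximizes the summed pairwise
global alignment scores; all other sequences are aligned to it pairwise
and merged on center coordinates ("once a gap, always a gap"). Before
alignment each input is reduced to a strand-canonical form and then
oriented to the center by whichever strand aligns better, which makes
discovery invariant both to input order and to reverse-complementing any
input — necessary because promoter fragments have no canonical strand.

**Alignment scores.** Match +2, mismatch −1, affine gaps (opening −8,
extension −1 per residue). The gap model matters more than it may seem:
orthologous intergenic regions of closely related genomes diverge almost
entirely by substitution, so at the divergence levels of interest
(~50% pairwise identity) cheap gaps mostly model alignment noise. With
linear gap −2 the aligner freely inserts spurious interior gap pairs,
and because a candidate window must be gap-free in *every* row, a single
noisy row destroys or shifts the conserved window; at the package's
default study conditions this lost the implanted operator in roughly a
third of simulations. The affine penalty removes essentially all
spurious gaps while still allowing genuine indels, and recovery becomes
near-perfect. The scores are arguments to every alignment function for
callers who need different regimes.

**Window ranking.** Each gap-free window of the motif width (default 15
bp, the canonical LysR operator width) is scored by conservation — the
mean per-column majority-base frequency — and candidates above a minimum
identity are ranked by `conservation × (0.5 + 0.5 × palindromicity)` of
the majority consensus. Palindromicity (the fraction of positions at
which a site matches its own reverse complement, `N` matching anything)
enters with a floor of 0.5 so an imperfect palindrome is down-weighted
but never excluded: real LysR sites include clearly non-palindromic
operators, e.g. the predicted site at the small-RNA gene *fnrS* scores
only 0.4.

**PWM, consensus, information content.** `pwm[b,j] = (count +
pseudocount) / (n + 4·pseudocount)` with default pseudocount 0.5
(0 reproduces textbook single-site behavior). Consensus letters use
major/minor thresholds 0.75/0.25: one base at or above the major
threshold is called directly; two qualifying bases give the two-base
IUPAC code; three or more qualifying bases — or none — give `N`, because
a three-base degenerate letter carries no usable constraint at these
matrix sizes. This rule reproduces the printed group-1 operator
consensus, including its two `N` positions, from the three-site worked
example. Information content per column is `2 + Σ p log2 p` bits, the
sequence-logo column height. Scanning scores log-odds against a uniform
background on both strands (a GC-aware background can be supplied);
ambiguous reference bases score zero, and a site and its reverse
complement score identically on opposite strands to within rounding.

## Peak assignment and genomic context

A peak's summit is proxied by its interval midpoint, since upstream peak
callers rarely agree on a summit convention. A gene is a candidate
target when the midpoint falls within the promoter window (default 300
bp, generously containing the ~50-bp protected regions) upstream of its
start on its coding strand and not inside any gene body. Two qualifying
genes in divergent orientation are both reported (`divergent_pair`) —
the configuration in which one LysR binding event regulates both genes;
tandem ambiguity resolves to the nearer downstream start; a midpoint
inside a gene body is `intragenic`; anything else is `unassigned`.
Binding at an operon head propagates to all operon members.

Operons are maximal runs of same-strand adjacent genes with intergenic
gaps of at most 50 bp (a deliberately simple distance rule; the default
is conservative for enterobacterial genomes). Conserved neighborhoods
take an explicit ortholog map — orthology inference is out of scope —
and report, for each ortholog group seen within *k* genes (default 5) of
the anchor TF, the fraction of anchor-containing genomes in which that
adjacency holds, keeping groups at support ≥ 0.6 by default.

## The knockout differential-expression stand-in

Published tables are consumed as-is and never recomputed. For synthetic
counts the package provides a deliberately transparent negative-binomial
test: median-of-ratios size factors; `log2fc = log2((mean_KO + c) /
(mean_WT + c))` with pseudocount `c = 1` normalized count; and a
two-sided score-type test of equal NB means. The dispersion is a single
common value estimated by method of moments — the pooled within-condition
variance against `μ + αμ²`, averaged over genes with pooled mean above 5,
where low counts would contribute only noise. The test statistic
evaluates the variance at the pooled mean (the score form): evaluating
it at the two observed means (the Wald form) lets the larger observed
mean inflate its own variance, which we found measurably conservative.
With the dispersion pooled across thousands of genes the variance is
essentially known, so the reference is normal. Under the null the test
rejects at the nominal rate to within binomial error; a −4.3 log2
knockout effect on a well-expressed gene — the scale of the strongest
single-gene effects in the worked tables — is recovered to a few tenths
of a log2 unit with five replicates at dispersion 0.1. Benjamini–
Hochberg adjustment is available but off by default, since the published
tables carry raw p-values.

## Evidence integration

The target universe is the union of genes named by any evidence stream.
Targets inside a multi-gene operon are keyed by the operon and
represented by the member with the largest |log2fc| — arguments about
operon regulation usually rest on the strongest member. The additive
score `w_chip·peak + w_site·site + w_deg·[|log2fc| ≥ 1 ∧ p ≤ 0.05] +
w_ctx·conserved` (unit weights) is deliberately not a probabilistic
fusion: it is transparent, monotone in each stream, and easy to audit.
Mode calls use the knockout sign convention with the same unit
fold-change gate; the |log2fc| ≥ 1 default reflects that the smallest
effect printed in the worked tables is 1.2. "Direct" requires binding
evidence; expression plus conservation alone yields an indirect call,
mirroring cases where a conserved, differentially expressed cluster has
no detected peak. The TF's own knockout fold change is excluded from
target statistics — it measures the deletion, not regulation — but
binding at the TF's own promoter sets the autoregulation flag, a common
LysR property.

## What the synthetic data emulates — and what it does not

`synthetic_spec()` pins the study conditions: 12 genomes of 30 genes; a
divergent TF–target pair across a 300-bp intergenic region; an 8-gene
same-strand operon with 20-bp gaps; 20 orthologous 200-bp promoters with
a 15-bp implanted operator at 0.95 per-position conservation over a
background diverged at 0.3 substitutions per site; NB counts with
dispersion 0.1, typical mean 100 (log-normal spread; planted-effect
genes sit at the typical mean, as regulon targets in the worked tables
are well-expressed); 50-bp peaks with 10-bp positional jitter; five
replicates per condition. Promoter divergence is substitution-only, so
the operator offset is conserved up to strand; each ortholog is emitted
on a random strand. Decoy ortholog groups are shuffled across genome
layouts so any conserved adjacency among them is incidental, and decoy
peaks are planted inside gene bodies.

Passing tests on these data show that each stage recovers planted
structure under its own model assumptions. They do not show robustness
to what real data add: indels and rearrangements in promoters, uneven
phylogenetic relatedness (the generator's genomes are independent given
the ancestor, real ortholog sets are tree-correlated), GC-skewed
backgrounds, peak-caller artifacts, library-composition effects beyond
median-of-ratios, or operon boundaries that violate a fixed gap rule.

## Numerical choices and degenerate inputs

Ties in window ranking break leftmost, then + strand first; ties in
extreme fold changes break by locus tag. Scanning admits scores within
1e-9 of the threshold so a threshold set to the exact maximum is
attainable despite summation-order rounding. All-zero genes report
log2fc 0 and p 1; a gene flush against the contig edge yields an empty
upstream region rather than an error; an empty evidence table produces a
valid zero-target report. Every generator draws from its own seeded RNG
stream scoped with `withr::with_seed`, leaving the global RNG state
untouched; identical specs give byte-identical FASTA/GFF/JSON output.

The analysis scripts and the test suite run the generator at modest
sizes (a dozen genomes, 2,000-gene count matrices, 50 footprinting
replicates), which keeps every stage's statistical checks sharp while a
full run completes in minutes on one core.

## Known limitations

Star alignment is a heuristic multiple alignment; a center sequence that
aligns poorly to everything degrades window detection. The common-
dispersion NB test is not a substitute for DESeq2/edgeR-class inference
on real RNA-seq, and is exercised only on synthetic counts. Peak
assignment trusts the midpoint; asymmetric protected regions will bias
target distances. The additive score treats evidence streams as
exchangeable and independent, which is a reporting convenience, not a
statistical model. Orthology is consumed, never inferred. Logo rendering
is limited to computing per-column information content; no graphics are
produced.
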