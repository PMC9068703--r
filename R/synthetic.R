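# Synthetic data with the statistical structure the analysis assumes:
# orthologous promoters diverged from a common ancestor around a conserved
# palindromic site, multi-genome gene layouts with a conserved divergent
# TF-target pair and a same-strand operon, negative-binomial knockout
# counts with planted regulon effects, and jittered binding peaks.
#
# Every generator is a pure function of (spec, seed): the RNG state is
# scoped with withr::with_seed and never leaks.

#' Specification for synthetic study data
#'
#' Defaults describe the study conditions the package emulates: a 15-bp
#' palindromic operator conserved across enterobacterial promoters, ~50-bp
#' binding regions, knockout effect sizes on the scale of the worked
#' differential-expression tables, and a dozen related genomes.
#'
#' @param seed Integer seed; all generators derive their streams from it.
#' @param n_genomes Number of genomes for neighborhood analysis.
#' @param n_genes_per_genome Genes per genome (>= 12).
#' @param motif IUPAC motif to implant (default the 15-bp group-1
#'   consensus; `N` positions are concretized once per dataset).
#' @param motif_conservation Per-position retention probability of the
#'   implanted site in each ortholog (default 0.95).
#' @param background_divergence Per-site substitution probability of
#'   non-motif positions relative to the ancestral sequence (default 0.3).
#' @param planted_regulon Named numeric of log2 knockout effects; `NULL`
#'   uses the layout defaults (divergent target up +2.8, operon members
#'   down -2.8, the regulator itself -6.2 as the deletion artifact).
#' @param n_replicates RNA-seq replicates per condition (default 5).
#' @param nb_dispersion Negative-binomial dispersion (default 0.1).
#' @param mean_count Typical baseline mean count (default 100).
#' @param peak_jitter_sd SD in bp of peak-center positional noise
#'   (default 10).
#' @param n_promoters Orthologous promoter sequences to emit (default 20).
#' @param promoter_len Promoter length in bp (default 200).
#' @param conserved_fraction Probability that a genome retains the
#'   TF-target adjacency (default 1).
#' @param n_decoy_peaks Decoy peaks placed inside gene bodies (default 5).
#' @param n_genes_counts Genes in a standalone count matrix (default 2000).
#' @return List of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           n_genomes = 12L,
                           n_genes_per_genome = 30L,
                           motif = "TTCACNAATNGAGAA",
                           motif_conservation = 0.95,
                           background_divergence = 0.3,
                           planted_regulon = NULL,
                           n_replicates = 5L,
                           nb_dispersion = 0.1,
                           mean_count = 100,
                           peak_jitter_sd = 10,
                           n_promoters = 20L,
                           promoter_len = 200L,
                           conserved_fraction = 1,
                           n_decoy_peaks = 5L,
                           n_genes_counts = 2000L) {
  stopifnot(n_replicates >= 2L, nb_dispersion >= 0,
            motif_conservation >= 0, motif_conservation <= 1,
            background_divergence >= 0, background_divergence <= 1,
            conserved_fraction >= 0, conserved_fraction <= 1,
            n_genes_per_genome >= 12L)
  structure(
    list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
         n_genes_per_genome = as.integer(n_genes_per_genome),
         motif = toupper(motif),
         motif_conservation = motif_conservation,
         background_divergence = background_divergence,
         planted_regulon = planted_regulon,
         n_replicates = as.integer(n_replicates),
         nb_dispersion = nb_dispersion,
         mean_count = mean_count,
         peak_jitter_sd = peak_jitter_sd,
         n_promoters = as.integer(n_promoters),
         promoter_len = as.integer(promoter_len),
         conserved_fraction = conserved_fraction,
         n_decoy_peaks = as.integer(n_decoy_peaks),
         n_genes_counts = as.integer(n_genes_counts)),
    class = "synthetic_spec"
  )
}

sub_seed <- function(spec, k) {
  as.integer((as.numeric(spec$seed) * 7919 + k) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute each position with probability p (to one of the 3 other bases)
mutate_seq <- function(chars, p) {
  hit <- stats::runif(length(chars)) < p
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1L))
  }
  chars
}

concretize_motif <- function(motif) {
  chars <- strsplit(motif, "")[[1L]]
  vapply(chars, function(ch) {
    if (ch %in% c("A", "C", "G", "T")) return(ch)
    sample(strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1L]], 1L)
  }, character(1L), USE.NAMES = FALSE)
}

#' Generate orthologous promoter sequences around a conserved site
#'
#' An ancestral promoter (with the concretized motif at one position) is
#' diverged independently into each ortholog: background positions are
#' substituted at `background_divergence`, motif positions at
#' `1 - motif_conservation`. The divergence model is substitution-only
#' (no indels), so the site offset is positionally conserved; each
#' ortholog is emitted on a random strand, which is what varies the
#' recorded ground-truth offsets.
#' Ground truth (offset and strand of the implanted site per sequence) is
#' returned alongside.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `sequences` (named character), `truth` (`data.frame` with
#'   `id`, `offset` 0-based, `strand`), `implant` (the concrete motif
#'   instance), `spec`.
#' @export
make_ortholog_promoters <- function(spec) {
  withr::with_seed(sub_seed(spec, 1L), {
    w <- nchar(spec$motif)
    L <- spec$promoter_len
    implant <- concretize_motif(spec$motif)
    anc <- strsplit(random_dna(L), "")[[1L]]
    offset_anc <- sample(seq(20L, L - 20L - w), 1L)
    anc[(offset_anc + 1L):(offset_anc + w)] <- implant
    is_motif <- rep(FALSE, L)
    is_motif[(offset_anc + 1L):(offset_anc + w)] <- TRUE

    ids <- sprintf("prom_%02d", seq_len(spec$n_promoters))
    seqs <- character(spec$n_promoters)
    offs <- integer(spec$n_promoters)
    strands <- character(spec$n_promoters)
    for (i in seq_len(spec$n_promoters)) {
      chars <- anc
      chars[!is_motif] <- mutate_seq(chars[!is_motif],
                                     spec$background_divergence)
      chars[is_motif] <- mutate_seq(chars[is_motif],
                                    1 - spec$motif_conservation)
      off <- offset_anc
      strand <- sample(c("+", "-"), 1L)
      seq <- paste(chars, collapse = "")
      if (strand == "-") {
        seq <- reverse_complement(seq)
        off <- L - off - w
      }
      seqs[i] <- seq
      offs[i] <- off
      strands[i] <- strand
    }
    list(sequences = stats::setNames(seqs, ids),
         truth = data.frame(id = ids, offset = offs, strand = strands,
                            stringsAsFactors = FALSE),
         implant = paste(implant, collapse = ""),
         spec = spec)
  })
}

# Fixed gene-slot layout shared by all synthetic genomes. The TF sits
# divergently against its target across a 300-bp intergenic region (the
# classic LysR arrangement); an 8-gene same-strand operon sits well away
# from the TF; the remaining slots are decoys whose ortholog groups are
# shuffled per genome so none of them is a conserved neighbor by design.
GENE_LEN <- 900L
TF_INTERGENIC <- 300L
DEFAULT_GAP <- 150L
OPERON_GAP <- 20L

layout_slots <- function(n_genes) {
  n_decoys <- n_genes - 10L
  pre <- 6L
  post <- n_decoys - 6L - 6L  # 6 decoys between pair and operon
  roles <- c(rep("decoy", pre), "tf", "target", rep("decoy", 6L),
             paste0("op", 1:8), rep("decoy", post))
  strands <- c(rep("+", pre), "-", "+", rep("+", 6L), rep("+", 8L),
               rep("+", post))
  gaps <- c(rep(DEFAULT_GAP, pre), DEFAULT_GAP, TF_INTERGENIC,
            rep(DEFAULT_GAP, 6L), DEFAULT_GAP, rep(OPERON_GAP, 7L),
            rep(DEFAULT_GAP, post))
  data.frame(role = roles, strand = strands, gap_before = gaps,
             stringsAsFactors = FALSE)
}

#' Generate a panel of annotated genomes with conserved context
#'
#' Every genome carries a TF gene divergently opposed to a target gene
#' across a shared intergenic region, an 8-gene same-strand operon, and
#' decoy genes. The TF-target adjacency is retained with probability
#' `conserved_fraction` per genome; otherwise the target slot holds an
#' unrelated transporter-like ortholog group (`mfs`), mimicking the two
#' genomic-context groups seen across real enterobacteria. Decoy ortholog
#' groups are shuffled across slots per genome. A concrete instance of the
#' motif is written into the TF-target intergenic region and upstream of
#' the operon lead gene; these are the ground-truth binding sites.
#'
#' @param spec A `synthetic_spec`.
#' @return List: `genomes` (list of `annotated_genome`), `orthologs`
#'   (`data.frame` `genome_id`, `locus_tag`, `group_id`), `truth` (list
#'   with `sites` per genome, `conserved` logical per genome, `implant`,
#'   `regulon` of planted log2 effects keyed by reference-genome gene
#'   name).
#' @export
make_genomes <- function(spec) {
  withr::with_seed(sub_seed(spec, 2L), {
    slots <- layout_slots(spec$n_genes_per_genome)
    n_decoys <- sum(slots$role == "decoy")
    implant <- concretize_motif(spec$motif)
    w <- length(implant)
    conserved <- stats::runif(spec$n_genomes) < spec$conserved_fraction

    genomes <- vector("list", spec$n_genomes)
    ortho <- list()
    sites <- list()
    for (gi in seq_len(spec$n_genomes)) {
      gid <- sprintf("gn%02d", gi)
      decoy_groups <- sample(sprintf("dec%02d", seq_len(n_decoys)))
      group <- character(nrow(slots))
      di <- 0L
      for (si in seq_len(nrow(slots))) {
        role <- slots$role[si]
        if (role == "decoy") {
          di <- di + 1L
          group[si] <- decoy_groups[di]
        } else if (role == "target" && !conserved[gi]) {
          group[si] <- "mfs"
        } else {
          group[si] <- role
        }
      }
      starts <- integer(nrow(slots))
      pos <- 0L
      for (si in seq_len(nrow(slots))) {
        pos <- pos + slots$gap_before[si]
        starts[si] <- pos
        pos <- pos + GENE_LEN
      }
      ends <- starts + GENE_LEN
      ctg_len <- pos + DEFAULT_GAP
      chars <- strsplit(random_dna(ctg_len), "")[[1L]]

      plant <- function(center) {
        s0 <- center - w %/% 2L
        inst <- mutate_seq(implant, 1 - spec$motif_conservation)
        chars[(s0 + 1L):(s0 + w)] <<- inst
        c(start = s0, end = s0 + w)
      }
      tf_i <- which(slots$role == "tf")
      tgt_i <- which(slots$role == "target")
      op1_i <- which(slots$role == "op1")
      site1 <- plant((ends[tf_i] + starts[tgt_i]) %/% 2L)
      site2 <- plant(starts[op1_i] - 60L)

      locus <- sprintf("%s_g%03d", gid, seq_len(nrow(slots)))
      genes <- data.frame(
        locus_tag = locus,
        name = group,
        contig = "chr",
        start = starts, end = ends,
        strand = slots$strand,
        feature_kind = "cds",
        stringsAsFactors = FALSE
      )
      genomes[[gi]] <- annotated_genome(
        gid, c(chr = paste(chars, collapse = "")), genes)
      ortho[[gi]] <- data.frame(genome_id = gid, locus_tag = locus,
                                group_id = group, stringsAsFactors = FALSE)
      sites[[gi]] <- data.frame(
        genome_id = gid, contig = "chr",
        start = c(site1["start"], site2["start"]),
        end = c(site1["end"], site2["end"]),
        target = c(locus[tgt_i], locus[op1_i]),
        site_for = c("target", "op1"),
        stringsAsFactors = FALSE
      )
    }
    regulon <- spec$planted_regulon
    if (is.null(regulon)) {
      regulon <- c(target = 2.8,
                   stats::setNames(rep(-2.8, 8L), paste0("op", 1:8)),
                   tf = -6.2)
    }
    list(genomes = genomes,
         orthologs = do.call(rbind, ortho),
         truth = list(sites = do.call(rbind, sites),
                      conserved = conserved,
                      implant = paste(implant, collapse = ""),
                      regulon = regulon))
  })
}

#' Simulate a knockout-vs-wild-type count matrix
#'
#' Counts are negative binomial with mean
#' `baseline * 2^(effect * condition)` and dispersion `nb_dispersion`
#' (Poisson when the dispersion is 0). Baselines are log-normal around
#' `mean_count`, mimicking the wide dynamic range of real base means.
#' Genes without a planted effect have effect 0.
#'
#' @param spec A `synthetic_spec`.
#' @param gene_ids Gene identifiers; `NULL` gives `n_genes_counts` generic
#'   genes. Planted effects are matched to these ids by name.
#' @param effects Named log2 effects overriding `spec$planted_regulon`.
#' @return List: `counts` (genes x samples, wild type then knockout),
#'   `condition` (factor `WT`/`KO` per column), `effects` (per-gene truth).
#' @export
make_counts <- function(spec, gene_ids = NULL, effects = NULL) {
  withr::with_seed(sub_seed(spec, 3L), {
    if (is.null(gene_ids)) {
      gene_ids <- sprintf("gene_%04d", seq_len(spec$n_genes_counts))
    }
    if (is.null(effects)) {
      effects <- spec$planted_regulon
      if (is.null(effects)) effects <- numeric(0L)
    }
    eff <- stats::setNames(rep(0, length(gene_ids)), gene_ids)
    shared <- intersect(names(effects), gene_ids)
    eff[shared] <- effects[shared]

    n <- spec$n_replicates
    baseline <- stats::rlnorm(length(gene_ids),
                              meanlog = log(spec$mean_count), sdlog = 1)
    # regulon targets in knockout tables are well-expressed genes; pin
    # planted-effect genes at the typical baseline so effect recovery is
    # a property of the test, not of a lucky baseline draw
    baseline[eff != 0] <- spec$mean_count
    draw <- function(mu) {
      if (spec$nb_dispersion == 0) {
        stats::rpois(length(mu), lambda = mu)
      } else {
        stats::rnbinom(length(mu), mu = mu, size = 1 / spec$nb_dispersion)
      }
    }
    wt <- vapply(seq_len(n), function(i) draw(baseline),
                 numeric(length(gene_ids)))
    ko <- vapply(seq_len(n), function(i) draw(baseline * 2^eff),
                 numeric(length(gene_ids)))
    counts <- cbind(wt, ko)
    dimnames(counts) <- list(gene_ids,
                             c(sprintf("WT_%d", seq_len(n)),
                               sprintf("KO_%d", seq_len(n))))
    list(counts = counts,
         condition = factor(rep(c("WT", "KO"), each = n),
                            levels = c("WT", "KO")),
         effects = eff)
  })
}

#' Simulate ChIP peaks around true binding sites
#'
#' One 50-bp interval per true site, its center jittered by
#' `N(0, peak_jitter_sd)`; optional decoy peaks are centered inside random
#' gene bodies of the supplied genome.
#'
#' @param true_sites `data.frame` with `contig`, `start`, `end` (one row
#'   per site; e.g. the per-genome rows of `make_genomes()` truth).
#' @param spec A `synthetic_spec`.
#' @param genome Optional `annotated_genome` used to place decoy peaks.
#' @return `data.frame` `contig`, `start`, `end`, `score`, `is_decoy`.
#' @export
make_peaks <- function(true_sites, spec, genome = NULL) {
  withr::with_seed(sub_seed(spec, 4L), {
    center <- (true_sites$start + true_sites$end) %/% 2L
    jitter <- if (spec$peak_jitter_sd > 0) {
      as.integer(round(stats::rnorm(length(center),
                                    sd = spec$peak_jitter_sd)))
    } else {
      integer(length(center))
    }
    center <- center + jitter
    peaks <- data.frame(contig = true_sites$contig,
                        start = center - 25L, end = center + 25L,
                        score = 1, is_decoy = FALSE,
                        stringsAsFactors = FALSE)
    if (!is.null(genome) && spec$n_decoy_peaks > 0L) {
      g <- genome$genes
      pick <- sample(nrow(g), min(spec$n_decoy_peaks, nrow(g)))
      dc <- (g$start[pick] + g$end[pick]) %/% 2L
      peaks <- rbind(peaks,
                     data.frame(contig = g$contig[pick],
                                start = dc - 25L, end = dc + 25L,
                                score = 0.5, is_decoy = TRUE,
                                stringsAsFactors = FALSE))
    }
    peaks$start <- pmax(peaks$start, 0L)
    rownames(peaks) <- NULL
    peaks
  })
}
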