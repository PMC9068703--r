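# End-to-end synthetic pipeline: one call runs every stage on generated
# data and returns the regulon report plus recovery metrics against the
# planted truth.

#' Run the full inference pipeline on synthetic data
#'
#' Generates a genome panel, ChIP peaks, knockout counts and orthologous
#' promoters from one `synthetic_spec`; then runs peak assignment, operon
#' grouping, motif discovery plus upstream scanning, the NB
#' differential-expression test, conserved-neighborhood analysis and
#' evidence integration for the planted TF. Fully deterministic given the
#' spec (same spec in, byte-identical JSON out).
#'
#' @param spec A `synthetic_spec`.
#' @param promoter_window Peak-assignment window in bp (default 300).
#' @param scan_threshold_frac Scanning threshold as a fraction of the
#'   motif's maximum log-odds score (default 0.7, tolerating the one or
#'   two substitutions a 95%-conserved 15-mer typically carries).
#' @return List: `spec`, `report` (`regulon_hypothesis`), `json` (its
#'   canonical serialization), `evidence`, `motif`, `assigned_peaks`,
#'   `de`, `clusters`, `metrics` (list with `peak_recall`, `auprc`),
#'   `truth`.
#' @export
run_all <- function(spec, promoter_window = 300L,
                    scan_threshold_frac = 0.7) {
  gd <- make_genomes(spec)
  ref <- gd$genomes[[1L]]
  tf_locus <- ref$genes$locus_tag[ref$genes$name == "tf"]

  truth_sites <- gd$truth$sites[gd$truth$sites$genome_id == ref$genome_id, ,
                                drop = FALSE]
  peaks <- make_peaks(truth_sites, spec, genome = ref)
  assigned <- assign_peak_targets(peaks, ref,
                                  promoter_window = promoter_window)
  operons <- group_operons(ref)

  proms <- make_ortholog_promoters(spec)
  motif <- discover_motif(proms$sequences)
  threshold <- scan_threshold_frac * max_score(motif)
  site_hits <- do.call(rbind, lapply(seq_len(nrow(ref$genes)), function(i) {
    gene <- ref$genes[i, , drop = FALSE]
    reg <- upstream_region(gene, ref)
    if (nchar(reg$sequence) < motif$width) return(NULL)
    hits <- scan_sequence(motif, reg$sequence, threshold,
                          source = gene$locus_tag)
    if (nrow(hits) == 0L) return(NULL)
    data.frame(locus_tag = gene$locus_tag, hits, stringsAsFactors = FALSE)
  }))

  # planted knockout effects, keyed by ortholog role in the layout
  eff_role <- gd$truth$regulon
  role <- ref$genes$name
  eff_locus <- stats::setNames(
    ifelse(role %in% names(eff_role), eff_role[role], 0),
    ref$genes$locus_tag)
  eff_locus <- eff_locus[eff_locus != 0]
  cm <- make_counts(spec, gene_ids = ref$genes$locus_tag,
                    effects = eff_locus)
  n <- spec$n_replicates
  de <- nb_de_test(cm$counts[, seq_len(n), drop = FALSE],
                   cm$counts[, n + seq_len(n), drop = FALSE])

  clusters <- conserved_neighbors("tf", gd$genomes, gd$orthologs)
  conserved_loci <- ref$genes$locus_tag[ref$genes$name %in%
                                          clusters$group_id]

  evidence <- build_evidence_table(tf_locus, de, assigned, site_hits,
                                   conserved_loci, operons)
  report <- regulon_report(tf_locus, evidence, assigned, site_hits,
                           narrative = sprintf(
                             "synthetic run, seed %d", spec$seed))

  # recovery metrics against the planted truth
  planted <- ref$genes$locus_tag[role %in%
                                   setdiff(names(eff_role), "tf")]
  promoter_rows <- assigned[assigned$relation %in%
                              c("upstream_sense", "divergent_pair"), ,
                            drop = FALSE]
  recovered <- vapply(seq_len(nrow(truth_sites)), function(i) {
    truth_sites$target[i] %in% promoter_rows$locus_tag
  }, logical(1L))
  row_true <- vapply(seq_len(nrow(evidence)), function(i) {
    members <- strsplit(evidence$members[i], ",")[[1L]]
    any(members %in% planted)
  }, logical(1L))
  metrics <- list(
    peak_recall = mean(recovered),
    auprc = auprc(evidence$score, row_true)
  )
  list(spec = spec, report = report, json = regulon_json(report),
       evidence = evidence, motif = motif, assigned_peaks = assigned,
       de = de, clusters = clusters, metrics = metrics,
       truth = gd$truth)
}
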