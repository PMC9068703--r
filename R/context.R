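# Genomic context: operon grouping within a genome and conserved
# TF-neighborhood detection across genomes via an explicit ortholog map.

#' Group genes into operons
#'
#' Maximal runs of same-strand adjacent genes whose intergenic gaps are at
#' most `max_gap`; singletons become one-member operons. Members are
#' reported in transcription order (the head of a minus-strand operon is
#' its rightmost gene). The partition covers every gene exactly once and
#' is invariant to the input order of the gene table.
#'
#' @param genome An `annotated_genome`.
#' @param max_gap Maximum intergenic gap in bp (default 50).
#' @return `data.frame` with `operon_id`, `contig`, `strand`, `locus_tag`,
#'   `position` (1 = transcription start) and `n_members`.
#' @export
group_operons <- function(genome, max_gap = 50L) {
  g <- genome$genes  # already sorted by (contig, start)
  if (nrow(g) == 0L) {
    return(data.frame(operon_id = character(0L), contig = character(0L),
                      strand = character(0L), locus_tag = character(0L),
                      position = integer(0L), n_members = integer(0L)))
  }
  new_run <- c(TRUE, g$contig[-1L] != g$contig[-nrow(g)] |
                 g$strand[-1L] != g$strand[-nrow(g)] |
                 g$start[-1L] - g$end[-nrow(g)] > max_gap)
  run <- cumsum(new_run)
  out <- lapply(split(seq_len(nrow(g)), run), function(idx) {
    members <- g[idx, , drop = FALSE]
    if (members$strand[1L] == "-") {
      members <- members[rev(seq_len(nrow(members))), , drop = FALSE]
    }
    data.frame(operon_id = paste0("operon_", members$locus_tag[1L]),
               contig = members$contig[1L],
               strand = members$strand[1L],
               locus_tag = members$locus_tag,
               position = seq_len(nrow(members)),
               n_members = nrow(members),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Conserved gene neighborhoods around an anchor ortholog group
#'
#' For each ortholog group observed within `k` genes of the anchor (gene
#' order on the same contig) in at least one genome, computes its support:
#' the fraction of anchor-containing genomes in which the group lies
#' within `k` genes of the anchor. Groups at or above `min_support` are
#' returned ranked by support, then mean gene distance, then group id.
#' LysR-family regulators typically sit adjacent to their regulated
#' cluster, which is what this detects.
#'
#' @param anchor_group Ortholog group id of the TF.
#' @param genomes List of `annotated_genome`.
#' @param ortholog_map `data.frame` with `genome_id`, `locus_tag`,
#'   `group_id`.
#' @param k Neighborhood radius in genes (default 5).
#' @param min_support Minimum support to report (default 0.6).
#' @return `data.frame` with `group_id`, `support`, `mean_distance`,
#'   `n_genomes`, `genomes` (comma-collapsed ids). Empty when the anchor
#'   is absent everywhere.
#' @export
conserved_neighbors <- function(anchor_group, genomes, ortholog_map,
                                k = 5L, min_support = 0.6) {
  empty <- data.frame(group_id = character(0L), support = numeric(0L),
                      mean_distance = numeric(0L), n_genomes = integer(0L),
                      genomes = character(0L), stringsAsFactors = FALSE)
  per_genome <- list()
  n_with_anchor <- 0L
  for (gn in genomes) {
    om <- ortholog_map[ortholog_map$genome_id == gn$genome_id, ,
                       drop = FALSE]
    g <- gn$genes
    g$group_id <- om$group_id[match(g$locus_tag, om$locus_tag)]
    anchor_rows <- which(g$group_id %in% anchor_group)
    if (length(anchor_rows) == 0L) next
    n_with_anchor <- n_with_anchor + 1L
    a <- anchor_rows[1L]
    same_ctg <- which(g$contig == g$contig[a])
    dist <- abs(seq_along(same_ctg) - match(a, same_ctg))
    keep <- dist <= k
    found <- data.frame(group_id = g$group_id[same_ctg[keep]],
                        distance = dist[keep],
                        stringsAsFactors = FALSE)
    found <- found[!is.na(found$group_id), , drop = FALSE]
    found <- found[order(found$distance), , drop = FALSE]
    found <- found[!duplicated(found$group_id), , drop = FALSE]
    per_genome[[gn$genome_id]] <- found
  }
  if (n_with_anchor == 0L) return(empty)
  all_groups <- sort(unique(unlist(lapply(per_genome,
                                          function(x) x$group_id))))
  rows <- lapply(all_groups, function(grp) {
    obs <- vapply(per_genome, function(x) grp %in% x$group_id, logical(1L))
    dists <- vapply(per_genome[obs], function(x) {
      x$distance[x$group_id == grp]
    }, numeric(1L))
    data.frame(group_id = grp,
               support = sum(obs) / n_with_anchor,
               mean_distance = mean(dists),
               n_genomes = sum(obs),
               genomes = paste(names(per_genome)[obs], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$support >= min_support, , drop = FALSE]
  out <- out[order(-out$support, out$mean_distance, out$group_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Percent identity of two sequences under global alignment
#'
#' Needleman-Wunsch global alignment; identity is matches over alignment
#' columns (gaps included) times 100. DNA uses the same scoring as
#' [star_align()]; protein uses BLOSUM62 with affine gaps.
#'
#' @param a,b Sequences (character strings).
#' @param type `"dna"` or `"protein"`.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (type == "dna") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
      type = "global", substitutionMatrix = dna_submat(),
      gapOpening = 8, gapExtension = 1)
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1)
  }
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  100 * sum(p == s & p != "-") / length(p)
}
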