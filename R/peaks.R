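# ChIP peak-to-target assignment. A peak's summit is proxied by its
# interval midpoint; a gene is a candidate target when the midpoint lies
# within the promoter window upstream of its start on its coding strand
# and not inside another gene body. One shared intergenic peak may hit two
# divergently transcribed genes at once.

#' Assign ChIP peaks to candidate target genes
#'
#' For each peak, candidates are genes whose promoter window (upstream of
#' the start on the coding strand) contains the peak midpoint, provided
#' the midpoint is not inside any gene body. Two qualifying genes in
#' divergent orientation are both returned with relation `divergent_pair`;
#' tandem ambiguity resolves to the nearer downstream start; a midpoint
#' inside a gene body with no qualifying promoter gives that gene with
#' relation `intragenic`; otherwise the peak row carries relation
#' `unassigned`. The result is deterministic and independent of peak input
#' order.
#'
#' @param peaks `data.frame` with `contig`, `start`, `end` (0-based
#'   half-open) and optionally `score`.
#' @param genome An `annotated_genome`.
#' @param promoter_window Promoter window in bp (default 300, matching the
#'   upstream-region default).
#' @return `data.frame`, one row per (peak, target): `peak_id`, `contig`,
#'   `start`, `end`, `score`, `midpoint`, `locus_tag`, `relation`.
#' @export
assign_peak_targets <- function(peaks, genome, promoter_window = 300L) {
  stopifnot(promoter_window >= 1L)
  missing_ctg <- setdiff(unique(peaks$contig), names(genome$contigs))
  if (length(missing_ctg) > 0L) {
    stop("peak contig '", missing_ctg[1L], "' absent from genome ",
         genome$genome_id)
  }
  score <- if ("score" %in% names(peaks)) peaks$score else rep(0, nrow(peaks))
  p <- data.frame(contig = peaks$contig, start = as.integer(peaks$start),
                  end = as.integer(peaks$end), score = score,
                  stringsAsFactors = FALSE)
  p <- p[order(p$contig, p$start, p$end), , drop = FALSE]
  p$peak_id <- sprintf("pk_%04d", seq_len(nrow(p)))
  p$midpoint <- (p$start + p$end) %/% 2L
  g <- genome$genes

  one_peak <- function(i) {
    m <- p$midpoint[i]
    ctg <- p$contig[i]
    gc <- g[g$contig == ctg, , drop = FALSE]
    inside <- gc[gc$start <= m & m < gc$end, , drop = FALSE]
    base <- p[i, c("peak_id", "contig", "start", "end", "score", "midpoint")]
    row_for <- function(locus, relation) {
      cbind(base, data.frame(locus_tag = locus, relation = relation,
                             stringsAsFactors = FALSE), row.names = NULL)
    }
    if (nrow(inside) == 0L) {
      plus <- gc[gc$strand == "+" & m >= gc$start - promoter_window &
                   m < gc$start, , drop = FALSE]
      minus <- gc[gc$strand == "-" & m >= gc$end &
                    m < gc$end + promoter_window, , drop = FALSE]
      nearest <- function(cand) {
        if (nrow(cand) == 0L) return(NULL)
        d <- ifelse(cand$strand == "+", cand$start - m, m - cand$end)
        cand[order(d, cand$locus_tag)[1L], , drop = FALSE]
      }
      np <- nearest(plus)
      nm <- nearest(minus)
      if (!is.null(np) && !is.null(nm)) {
        # shared intergenic region of a divergent pair: minus gene left,
        # plus gene right, peak between them
        return(rbind(row_for(nm$locus_tag, "divergent_pair"),
                     row_for(np$locus_tag, "divergent_pair")))
      }
      if (!is.null(np)) return(row_for(np$locus_tag, "upstream_sense"))
      if (!is.null(nm)) return(row_for(nm$locus_tag, "upstream_sense"))
      return(row_for(NA_character_, "unassigned"))
    }
    host <- inside[order(inside$start, inside$locus_tag)[1L], , drop = FALSE]
    row_for(host$locus_tag, "intragenic")
  }
  out <- do.call(rbind, lapply(seq_len(nrow(p)), one_peak))
  rownames(out) <- NULL
  out
}

#' Expand targets through operon membership
#'
#' A target that is the transcriptionally first gene of an operon expands
#' to the full operon (all members tagged with the operon id); targets
#' inside an operon but not at its head, and targets outside any operon,
#' pass through unchanged.
#'
#' @param targets Character vector of locus tags.
#' @param operons Operon table from [group_operons()].
#' @return `data.frame` with `locus_tag`, `operon_id` (`NA` outside
#'   operons), `via` (the original target that pulled the gene in).
#' @export
propagate_to_operon <- function(targets, operons) {
  targets <- unique(targets[!is.na(targets)])
  if (length(targets) == 0L) {
    return(data.frame(locus_tag = character(0L),
                      operon_id = character(0L),
                      via = character(0L), stringsAsFactors = FALSE))
  }
  rows <- lapply(targets, function(t) {
    hit <- operons[operons$locus_tag == t, , drop = FALSE]
    if (nrow(hit) == 1L && hit$position == 1L && hit$n_members > 1L) {
      members <- operons[operons$operon_id == hit$operon_id, , drop = FALSE]
      members <- members[order(members$position), , drop = FALSE]
      data.frame(locus_tag = members$locus_tag,
                 operon_id = hit$operon_id, via = t,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(locus_tag = t,
                 operon_id = if (nrow(hit) == 1L) hit$operon_id else
                   NA_character_,
                 via = t, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$locus_tag), , drop = FALSE]
  out <- out[order(out$locus_tag), , drop = FALSE]
  rownames(out) <- NULL
  out
}
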