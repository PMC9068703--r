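# Evidence integration: combine binding, expression and conservation into
# a per-TF regulon hypothesis with activator/repressor calls and a
# transparent additive confidence score.

#' Activator/repressor call from a knockout log2 fold change
#'
#' If deleting the regulator raises a target (`log2fc >= +min_abs_lfc` in
#' knockout vs wild type) the regulator was holding it down: repressor.
#' If the target falls (`<= -min_abs_lfc`) the regulator was driving it:
#' activator. In between: unknown. Vectorized.
#'
#' @param deg_log2fc Knockout-vs-wild-type log2 fold change(s).
#' @param min_abs_lfc Magnitude needed for a call (default 1).
#' @return Character vector: `"repressor"`, `"activator"` or `"unknown"`.
#' @export
classify_mode <- function(deg_log2fc, min_abs_lfc = 1) {
  out <- rep("unknown", length(deg_log2fc))
  out[!is.na(deg_log2fc) & deg_log2fc >= min_abs_lfc] <- "repressor"
  out[!is.na(deg_log2fc) & deg_log2fc <= -min_abs_lfc] <- "activator"
  out
}

#' Additive evidence score for a target
#'
#' `w_chip * has_chip_peak + w_site * has_predicted_site + w_deg *
#' [|log2fc| >= lfc_threshold and p <= p_max] + w_ctx * conserved_neighbor`,
#' all weights 1 by default. Monotone in every evidence flag.
#'
#' @param rows Evidence `data.frame` (see [build_evidence_table()]).
#' @param weights Named numeric: `chip`, `site`, `deg`, `context`.
#' @param lfc_threshold,p_max DEG significance gates (defaults 1, 0.05).
#' @return Numeric score per row.
#' @export
score_target <- function(rows,
                         weights = c(chip = 1, site = 1, deg = 1,
                                     context = 1),
                         lfc_threshold = 1, p_max = 0.05) {
  deg_ok <- !is.na(rows$deg_log2fc) & !is.na(rows$deg_p) &
    abs(rows$deg_log2fc) >= lfc_threshold & rows$deg_p <= p_max
  weights[["chip"]] * as.numeric(rows$has_chip_peak) +
    weights[["site"]] * as.numeric(rows$has_predicted_site) +
    weights[["deg"]] * as.numeric(deg_ok) +
    weights[["context"]] * as.numeric(rows$conserved_neighbor)
}

#' Assemble the per-target evidence table for one TF
#'
#' The target universe is the union of genes named by any evidence stream:
#' promoter-level ChIP peak assignments, predicted binding-site hits,
#' filtered knockout DEGs, and conserved-neighborhood members. Targets
#' inside a multi-gene operon are keyed by the operon and represented by
#' the member with the largest |log2fc| (regulation arguments usually rest
#' on the strongest member). The TF's own gene is excluded from DEG-based
#' evidence - its knockout fold change reflects the deletion itself, not
#' regulation - but binding at its own promoter is kept and later flagged
#' as autoregulation.
#'
#' @param tf Locus tag of the TF.
#' @param degs DEG `data.frame` (unfiltered; filtering applied here).
#' @param annotated_peaks Output of [assign_peak_targets()] (or `NULL`).
#' @param site_hits `data.frame` with a `locus_tag` column naming genes
#'   with a predicted binding site (or `NULL`).
#' @param conserved Character vector of locus tags in conserved clusters
#'   with the TF, optionally named by distance (or `NULL`).
#' @param operons Output of [group_operons()] (or `NULL`).
#' @param min_abs_lfc,max_p DEG gates (defaults 1, 0.05).
#' @return Evidence `data.frame`, one row per target (gene or operon),
#'   ordered by score then target id, with attribute `n_degs` = number of
#'   DEG-supported target genes before operon expansion.
#' @export
build_evidence_table <- function(tf, degs, annotated_peaks = NULL,
                                 site_hits = NULL, conserved = NULL,
                                 operons = NULL,
                                 min_abs_lfc = 1, max_p = 0.05) {
  peak_loci <- character(0L)
  if (!is.null(annotated_peaks) && nrow(annotated_peaks) > 0L) {
    promoter <- annotated_peaks$relation %in%
      c("upstream_sense", "divergent_pair")
    peak_loci <- unique(annotated_peaks$locus_tag[promoter])
  }
  site_loci <- if (!is.null(site_hits) && nrow(site_hits) > 0L) {
    unique(site_hits$locus_tag)
  } else character(0L)
  deg_f <- filter_degs(degs, min_abs_lfc = min_abs_lfc, max_p = max_p)
  deg_f <- deg_f[deg_f$locus_tag != tf, , drop = FALSE]
  deg_loci <- unique(deg_f$locus_tag)
  ctx_loci <- setdiff(unique(conserved), tf)

  universe <- setdiff(unique(c(peak_loci, site_loci, deg_loci, ctx_loci)),
                      c(NA_character_, tf))
  if (length(universe) == 0L) {
    out <- data.frame(target = character(0L), members = character(0L),
                      has_chip_peak = logical(0L),
                      has_predicted_site = logical(0L),
                      deg_log2fc = numeric(0L), deg_p = numeric(0L),
                      conserved_neighbor = logical(0L),
                      score = numeric(0L), mode = character(0L),
                      direct = logical(0L), stringsAsFactors = FALSE)
    attr(out, "n_degs") <- 0L
    return(out)
  }

  # binding evidence propagates from an operon head to the whole operon
  if (!is.null(operons)) {
    peak_exp <- propagate_to_operon(peak_loci, operons)$locus_tag
    site_exp <- propagate_to_operon(site_loci, operons)$locus_tag
  } else {
    peak_exp <- peak_loci
    site_exp <- site_loci
  }
  universe <- setdiff(unique(c(universe, peak_exp, site_exp)), tf)

  key_of <- function(locus) {
    if (is.null(operons)) return(locus)
    hit <- operons[match(locus, operons$locus_tag), , drop = FALSE]
    ifelse(!is.na(hit$operon_id) & hit$n_members > 1L, hit$operon_id, locus)
  }
  keys <- key_of(universe)
  deg_lfc <- deg_f$log2fc[match(universe, deg_f$locus_tag)]
  deg_p <- deg_f$pvalue[match(universe, deg_f$locus_tag)]

  rows <- lapply(split(seq_along(universe), keys), function(idx) {
    loci <- universe[idx]
    lfcs <- deg_lfc[idx]
    ps <- deg_p[idx]
    rep_i <- if (all(is.na(lfcs))) 1L else which.max(abs(lfcs))
    data.frame(
      target = keys[idx][1L],
      members = paste(sort(loci), collapse = ","),
      has_chip_peak = any(loci %in% peak_exp),
      has_predicted_site = any(loci %in% site_exp),
      deg_log2fc = lfcs[rep_i],
      deg_p = ps[rep_i],
      conserved_neighbor = any(loci %in% ctx_loci),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$score <- score_target(out, lfc_threshold = min_abs_lfc, p_max = max_p)
  out$mode <- classify_mode(out$deg_log2fc, min_abs_lfc = min_abs_lfc)
  out$direct <- out$has_chip_peak | out$has_predicted_site
  out <- out[order(-out$score, out$target), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_degs") <- length(deg_loci)
  out
}

#' Build a regulon hypothesis report for one TF
#'
#' Wraps the evidence table with the summary counts a regulon table
#' reports: number of DEGs (before operon expansion), number of binding
#' sites (ChIP peaks at promoters plus predicted sites), per-target mode
#' and direct/indirect calls, and an autoregulation flag set when binding
#' evidence maps to the TF's own promoter.
#'
#' @param tf TF locus tag (or name).
#' @param evidence Output of [build_evidence_table()].
#' @param annotated_peaks Output of [assign_peak_targets()], used for the
#'   binding-site count and the autoregulation flag (or `NULL`).
#' @param site_hits Predicted-site table with `locus_tag` (or `NULL`).
#' @param narrative Optional character tags describing the hypothesis.
#' @return List of class `regulon_hypothesis`.
#' @export
regulon_report <- function(tf, evidence, annotated_peaks = NULL,
                           site_hits = NULL, narrative = character(0L)) {
  promoter_peaks <- 0L
  autoreg <- FALSE
  if (!is.null(annotated_peaks) && nrow(annotated_peaks) > 0L) {
    promoter <- annotated_peaks$relation %in%
      c("upstream_sense", "divergent_pair")
    promoter_peaks <- length(unique(annotated_peaks$peak_id[promoter]))
    autoreg <- tf %in% annotated_peaks$locus_tag[promoter]
  }
  n_sites_pred <- if (!is.null(site_hits)) {
    length(unique(site_hits$locus_tag))
  } else 0L
  if (!is.null(site_hits)) autoreg <- autoreg || tf %in% site_hits$locus_tag
  structure(
    list(tf = tf,
         n_degs = as.integer(attr(evidence, "n_degs")),
         n_binding_sites = list(chip = promoter_peaks,
                                predicted = n_sites_pred),
         autoregulation = autoreg,
         targets = evidence,
         narrative = as.character(narrative)),
    class = "regulon_hypothesis"
  )
}

#' @export
print.regulon_hypothesis <- function(x, ...) {
  cat("<regulon_hypothesis>", x$tf, "\n")
  cat("  DEGs:", x$n_degs,
      " binding sites (ChIP/predicted):", x$n_binding_sites$chip, "/",
      x$n_binding_sites$predicted,
      " autoregulation:", x$autoregulation, "\n")
  tt <- x$targets
  if (nrow(tt) > 0L) {
    show <- utils::head(tt[, c("target", "score", "mode", "direct",
                               "deg_log2fc")], 10L)
    print(show, row.names = FALSE)
    if (nrow(tt) > 10L) cat("  ...", nrow(tt) - 10L, "more target(s)\n")
  } else {
    cat("  (no targets)\n")
  }
  invisible(x)
}

#' Serialize a regulon hypothesis to canonical JSON
#'
#' Byte-stable for identical inputs: fixed key order, fixed numeric
#' formatting.
#'
#' @param report A `regulon_hypothesis`.
#' @return Single JSON string.
#' @export
regulon_json <- function(report) {
  tt <- report$targets
  payload <- list(
    tf = report$tf,
    n_degs = report$n_degs,
    n_binding_sites = report$n_binding_sites,
    autoregulation = report$autoregulation,
    targets = lapply(seq_len(nrow(tt)), function(i) {
      list(target = tt$target[i],
           members = tt$members[i],
           has_chip_peak = tt$has_chip_peak[i],
           has_predicted_site = tt$has_predicted_site[i],
           deg_log2fc = if (is.na(tt$deg_log2fc[i])) NULL else
             round(tt$deg_log2fc[i], 6L),
           deg_p = if (is.na(tt$deg_p[i])) NULL else
             signif(tt$deg_p[i], 6L),
           conserved_neighbor = tt$conserved_neighbor[i],
           score = tt$score[i],
           mode = tt$mode[i],
           direct = tt$direct[i])
    }),
    narrative = report$narrative
  )
  as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"))
}

#' Area under the precision-recall curve
#'
#' Tie-aware step interpolation: thresholds sweep the distinct score
#' values from high to low; AUPRC is the sum of precision times recall
#' gained at each step (average precision with ties grouped).
#'
#' @param scores Numeric scores, larger = more confident.
#' @param labels Logical truth per score.
#' @return AUPRC in `[0, 1]`; `NA` if no positive labels.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos_total <- sum(labels)
  if (pos_total == 0L) return(NA_real_)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel])
    precision <- tp / sum(sel)
    recall <- tp / pos_total
    area <- area + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  area
}
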