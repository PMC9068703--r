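# Differential-expression evidence: filtering, extremes, and a simplified
# negative-binomial test used on synthetic counts. Published knockout DEG
# tables are consumed as-is (see read_deg_tsv and deg_table).

#' Filter differential-expression records
#'
#' Keeps records with `|log2fc| >= min_abs_lfc` and `pvalue <= max_p`;
#' input order is preserved. Records without a printed p-value (`NA`) are
#' dropped whenever a p-value cutoff below 1 is in force. The defaults
#' (unit fold change, p 0.05) match the smallest effect printed in the
#' worked tables (|log2fc| 1.2).
#'
#' @param records DEG `data.frame` (see [read_deg_tsv()]).
#' @param min_abs_lfc Minimum absolute log2 fold change (default 1).
#' @param max_p Maximum p-value (default 0.05).
#' @return Filtered `data.frame`.
#' @export
filter_degs <- function(records, min_abs_lfc = 1, max_p = 0.05) {
  stopifnot(min_abs_lfc >= 0, max_p >= 0)
  keep_lfc <- abs(records$log2fc) >= min_abs_lfc
  keep_p <- if (max_p >= 1) rep(TRUE, nrow(records)) else
    !is.na(records$pvalue) & records$pvalue <= max_p
  out <- records[keep_lfc & keep_p, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Most extreme differential-expression record
#'
#' @param records Non-empty DEG `data.frame`.
#' @param direction `"most_down"` (minimal log2fc) or `"most_up"`
#'   (maximal). Ties break by locus tag.
#' @return One-row `data.frame`.
#' @export
extreme_deg <- function(records, direction = c("most_down", "most_up")) {
  direction <- match.arg(direction)
  if (nrow(records) == 0L) stop("empty DEG table")
  key <- if (direction == "most_down") records$log2fc else -records$log2fc
  ord <- order(key, records$locus_tag)
  out <- records[ord[1L], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median-of-ratios size factors
#'
#' Per sample: median ratio of its counts to the per-gene geometric mean
#' across all samples (genes with any zero are excluded from the
#' reference).
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @return Numeric vector of size factors, one per sample.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) return(rep(1, ncol(counts)))
  apply(counts, 2L, function(col) {
    exp(stats::median(log(col[use]) - log_geo[use]))
  })
}

#' Simplified negative-binomial differential-expression test
#'
#' A transparent stand-in for a full RNA-seq differential-expression
#' analysis, intended for synthetic counts. Counts are normalized by
#' median-of-ratios size factors; the log2 fold change is
#' `log2((mean_B + c) / (mean_A + c))` with pseudocount `c`; the p-value
#' comes from a two-sided score-type test of equal means whose variance is
#' the negative-binomial `mu + alpha mu^2`, evaluated at the pooled mean,
#' with a common (across genes) method-of-moments dispersion `alpha`.
#' Swapping the two conditions negates every log2 fold change and
#' leaves p-values unchanged. All-zero genes report log2fc 0 and p 1.
#'
#' @param counts_a,counts_b Genes x replicates count matrices (wild type
#'   and knockout, say), same genes in the same order; >= 2 replicates
#'   each.
#' @param sf Size factors for `cbind(counts_a, counts_b)`; computed with
#'   [size_factors()] when `NULL`.
#' @param pseudocount Added to both means inside the log ratio (default 1
#'   normalized count).
#' @param adjust If `TRUE`, append a Benjamini-Hochberg adjusted p-value
#'   column `padj`.
#' @return DEG `data.frame`: `locus_tag`, `gene`, `base_mean`, `log2fc`,
#'   `pvalue` (and optionally `padj`).
#' @export
nb_de_test <- function(counts_a, counts_b, sf = NULL, pseudocount = 1,
                       adjust = FALSE) {
  stopifnot(nrow(counts_a) == nrow(counts_b),
            ncol(counts_a) >= 2L, ncol(counts_b) >= 2L)
  if (any(counts_a < 0) || any(counts_b < 0)) stop("negative counts")
  all_counts <- cbind(counts_a, counts_b)
  if (is.null(sf)) sf <- size_factors(all_counts)
  na <- ncol(counts_a)
  nb <- ncol(counts_b)
  norm <- sweep(all_counts, 2L, sf, "/")
  a <- norm[, seq_len(na), drop = FALSE]
  b <- norm[, na + seq_len(nb), drop = FALSE]

  mu_a <- rowMeans(a)
  mu_b <- rowMeans(b)
  base_mean <- rowMeans(norm)
  lfc <- log2((mu_b + pseudocount) / (mu_a + pseudocount))

  # common method-of-moments dispersion: per-gene pooled within-condition
  # variance against the NB mean-variance relation, averaged over
  # well-expressed genes (low-count genes carry almost no information
  # about alpha and only add noise)
  var_a <- apply(a, 1L, stats::var)
  var_b <- apply(b, 1L, stats::var)
  s2 <- ((na - 1L) * var_a + (nb - 1L) * var_b) / (na + nb - 2L)
  mu_pool <- (na * mu_a + nb * mu_b) / (na + nb)
  ok <- mu_pool > 5
  alpha <- if (any(ok)) {
    max(0, mean((s2[ok] - mu_pool[ok]) / mu_pool[ok]^2))
  } else 0

  # score-type statistic: under the null both conditions share one mean,
  # so the variance is evaluated at the pooled mean (avoids the Wald
  # artifact where the larger observed mean inflates its own variance);
  # with the dispersion pooled across thousands of genes the variance is
  # essentially known, hence a normal reference
  v_pool <- (mu_pool + alpha * mu_pool^2) * (1 / na + 1 / nb)
  stat <- ifelse(v_pool > 0, (mu_b - mu_a) / sqrt(v_pool), 0)
  pval <- 2 * stats::pnorm(-abs(stat))

  zero <- mu_a == 0 & mu_b == 0
  lfc[zero] <- 0
  pval[zero] <- 1

  ids <- rownames(all_counts)
  if (is.null(ids)) ids <- sprintf("gene_%04d", seq_len(nrow(all_counts)))
  out <- data.frame(locus_tag = ids, gene = ids,
                    base_mean = base_mean, log2fc = lfc, pvalue = pval,
                    stringsAsFactors = FALSE)
  if (adjust) out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}
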