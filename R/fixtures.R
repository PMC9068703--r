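# Accessors for the worked-example fixtures shipped with the package:
# the five published knockout differential-expression tables and the
# three predicted PtrR operator sites.

#' Published knockout differential-expression tables
#'
#' The five printed DEG tables from the LysR-family study the package's
#' worked examples follow, transcribed as TSV fixtures:
#'
#' 1. *ybdO* (CitR) knockout, M9 glucose + threonine.
#' 2. *ygfI* (DhfA) knockout, M9 glucose + threonine (no p-values were
#'    printed for this table; `pvalue` is `NA`).
#' 3. *yiaU* (LpsR) knockout, M9 + threonine.
#' 4. *ptrR* (YneJ) knockout, glutamate/putrescine nitrogen sources.
#' 5. *ptrR* knockout, glutamate nitrogen source (adjacent genes only).
#'
#' @param i Table number, 1-5.
#' @return DEG `data.frame` (see [read_deg_tsv()]).
#' @export
deg_table <- function(i) {
  stopifnot(i %in% 1:5)
  path <- system.file("extdata", sprintf("deg_table%d.tsv", i),
                      package = "regulonscout", mustWork = TRUE)
  read_deg_tsv(path)
}

#' Predicted PtrR operator sites
#'
#' The three predicted 15-bp PtrR binding sites (at the *ptrR*, *sad* and
#' *fnrS* promoters), with the published mixed-case emphasis preserved for
#' display; all sequence operations are case-insensitive. The *ptrR* and
#' *sad* sites are exact reverse complements - one palindromic operator in
#' the shared intergenic region read from either strand.
#'
#' @return `data.frame` with `gene` and `site`.
#' @export
ptrr_sites <- function() {
  path <- system.file("extdata", "ptrr_predicted_sites.tsv",
                      package = "regulonscout", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Per-TF study summary
#'
#' Published summary counts for the seven regulators (number of DEGs and
#' of ChIP-detected/predicted binding sites) plus their predicted roles.
#' Reported for provenance in regulon reports; the DEG counts come from
#' the study's full supplementary tables, so they exceed what the printed
#' per-table fixtures can reproduce.
#'
#' @return `data.frame` with `tf`, `renamed`, `n_degs`, `sites_chip`,
#'   `sites_predicted`, `predicted_role`.
#' @export
tf_summary <- function() {
  path <- system.file("extdata", "tf_summary.tsv",
                      package = "regulonscout", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
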