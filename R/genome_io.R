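# Genome model and format I/O.
#
# Internal coordinates are 0-based half-open throughout; GFF3 (1-based
# inclusive) is converted on read/write, BED is consumed as-is.

#' Construct an annotated genome
#'
#' An annotated genome bundles contig sequences with a gene table. Gene
#' coordinates are 0-based half-open on the forward strand; the gene table is
#' kept sorted by (contig, start, locus_tag) so all downstream iteration
#' orders are deterministic.
#'
#' @param genome_id Single string identifying the genome.
#' @param contigs Named character vector of DNA sequences (alphabet `ACGTN`).
#' @param genes `data.frame` with columns `locus_tag`, `name`, `contig`,
#'   `start`, `end`, `strand` (`"+"`/`"-"`) and `feature_kind`
#'   (`"cds"`/`"ncrna"`).
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, contigs, genes) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  stopifnot(is.character(contigs), !is.null(names(contigs)))
  required <- c("locus_tag", "name", "contig", "start", "end", "strand",
                "feature_kind")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L) {
    stop("gene table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  genes <- genes[, required]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (any(genes$start < 0L) || any(genes$start >= genes$end)) {
    bad <- genes$locus_tag[genes$start < 0L | genes$start >= genes$end][1L]
    stop("invalid coordinates for gene ", bad,
         " (need 0 <= start < end, 0-based half-open)")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  if (!all(genes$feature_kind %in% c("cds", "ncrna"))) {
    stop("feature_kind must be 'cds' or 'ncrna'")
  }
  if (anyDuplicated(genes$locus_tag)) {
    stop("duplicated locus_tag: ",
         genes$locus_tag[duplicated(genes$locus_tag)][1L])
  }
  unknown <- setdiff(genes$contig, names(contigs))
  if (length(unknown) > 0L) {
    stop("gene(s) reference unknown contig(s): ",
         paste(unknown, collapse = ", "))
  }
  too_long <- genes$end > nchar(contigs)[match(genes$contig, names(contigs))]
  if (any(too_long)) {
    stop("gene ", genes$locus_tag[too_long][1L], " extends past its contig")
  }
  ord <- order(genes$contig, genes$start, genes$locus_tag)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  structure(
    list(genome_id = genome_id,
         contigs = vapply(contigs, toupper, character(1L)),
         genes = genes),
    class = "annotated_genome"
  )
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome>", x$genome_id, "\n")
  cat("  contigs:", length(x$contigs), "(",
      sum(nchar(x$contigs)), "bp )\n")
  cat("  genes:  ", nrow(x$genes), "\n")
  invisible(x)
}

#' Look up a gene by locus tag or name
#'
#' @param genome An `annotated_genome`.
#' @param id Locus tag or gene name.
#' @return One-row `data.frame` (the gene), or an error if not found.
#' @export
find_gene <- function(genome, id) {
  g <- genome$genes
  hit <- g[g$locus_tag == id | g$name == id, , drop = FALSE]
  if (nrow(hit) == 0L) {
    stop("no gene with locus_tag or name '", id, "' in ", genome$genome_id)
  }
  hit[1L, , drop = FALSE]
}

# Pre-scan a GFF3 file so coordinate errors can be reported with a line
# number (rtracklayer's message would not carry one).
check_gff_coordinates <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 8L) {
      stop("malformed GFF line ", i, " in ", path, ": fewer than 8 fields")
    }
    coords <- suppressWarnings(as.integer(fields[4:5]))
    if (anyNA(coords)) {
      stop("malformed coordinate at line ", i, " of ", path, ": '",
           fields[4L], "'/'", fields[5L], "'")
    }
  }
  invisible(TRUE)
}

#' Read a genome from GFF3 + FASTA
#'
#' Features of type `gene`/`CDS` become `cds` genes and `ncRNA` features
#' become `ncrna` genes; other feature types are ignored. The locus tag is
#' taken from the `locus_tag` attribute, falling back to `ID`; the gene name
#' from `Name`, falling back to `gene` (empty when neither is present).
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open.
#'
#' @param path GFF3 file.
#' @param fasta_path FASTA file whose ids match the GFF seqids.
#' @param genome_id Genome identifier; defaults to the GFF file stem.
#' @return An `annotated_genome`.
#' @export
read_gff <- function(path, fasta_path,
                     genome_id = sub("\\.gff3?$", "", basename(path))) {
  check_gff_coordinates(path)
  contig_set <- Biostrings::readDNAStringSet(fasta_path)
  names(contig_set) <- sub("\\s.*$", "", names(contig_set))
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  kind <- rep(NA_character_, length(gr))
  kind[tolower(as.character(md$type)) %in% c("gene", "cds")] <- "cds"
  kind[tolower(as.character(md$type)) %in% c("ncrna", "ncrna_gene")] <- "ncrna"
  keep <- !is.na(kind)
  gr <- gr[keep]
  md <- md[keep, , drop = FALSE]
  kind <- kind[keep]

  pick <- function(col) {
    if (col %in% names(md)) as.character(md[[col]]) else
      rep(NA_character_, length(gr))
  }
  locus <- pick("locus_tag")
  id <- pick("ID")
  locus <- ifelse(is.na(locus) | locus == "", id, locus)
  if (anyNA(locus)) {
    stop("feature without locus_tag or ID attribute in ", path)
  }
  nm <- pick("Name")
  gene_attr <- pick("gene")
  nm <- ifelse(is.na(nm) | nm == "", gene_attr, nm)
  nm[is.na(nm)] <- ""

  contig <- as.character(GenomicRanges::seqnames(gr))
  missing_ctg <- setdiff(contig, names(contig_set))
  if (length(missing_ctg) > 0L) {
    off <- locus[contig %in% missing_ctg][1L]
    stop("feature ", off, " references contig '",
         contig[contig %in% missing_ctg][1L],
         "' absent from ", fasta_path)
  }
  genes <- data.frame(
    locus_tag = locus,
    name = nm,
    contig = contig,
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_kind = kind,
    stringsAsFactors = FALSE
  )
  annotated_genome(genome_id,
                   stats::setNames(as.character(contig_set),
                                   names(contig_set)),
                   genes)
}

#' Write a genome as GFF3 + FASTA
#'
#' Inverse of [read_gff()]: deterministic output, suitable for byte-level
#' round-trip checks.
#'
#' @param genome An `annotated_genome`.
#' @param gff_path,fasta_path Output files.
#' @export
write_gff <- function(genome, gff_path, fasta_path) {
  g <- genome$genes
  gr <- GenomicRanges::GRanges(
    seqnames = g$contig,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand
  )
  S4Vectors::mcols(gr)$type <- ifelse(g$feature_kind == "ncrna",
                                      "ncRNA", "gene")
  S4Vectors::mcols(gr)$ID <- g$locus_tag
  S4Vectors::mcols(gr)$locus_tag <- g$locus_tag
  S4Vectors::mcols(gr)$Name <- ifelse(g$name == "", NA_character_, g$name)
  rtracklayer::export(gr, gff_path, format = "gff3")
  seqs <- Biostrings::DNAStringSet(genome$contigs)
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  invisible(genome)
}

#' Extract the upstream (promoter-side) region of a gene
#'
#' Returns the sequence immediately 5' of the gene on its coding strand,
#' truncated at the nearer of `max_len` and the boundary of the closest
#' other annotated gene. For a divergently transcribed pair the two upstream
#' regions cover the same intergenic interval on opposite strands. A gene
#' flush against the contig edge yields an empty region.
#'
#' @param gene One-row gene `data.frame` (e.g. from [find_gene()]).
#' @param genome The `annotated_genome` the gene belongs to.
#' @param max_len Maximum region length in bp (default 300; generously
#'   contains the ~50-bp protected regions seen in ChIP-exo footprints).
#' @return A list of class `region` with `contig`, `start`, `end`, `strand`
#'   and `sequence` (coding-strand orientation, 5' to 3' toward the gene).
#' @export
upstream_region <- function(gene, genome, max_len = 300L) {
  stopifnot(max_len >= 1L)
  g <- genome$genes
  others <- g[g$locus_tag != gene$locus_tag & g$contig == gene$contig, ,
              drop = FALSE]
  ctg_len <- nchar(genome$contigs[[gene$contig]])
  if (gene$strand == "+") {
    s0 <- max(gene$start - max_len, 0L)
    e0 <- gene$start
    blocking <- others[others$end > s0 & others$start < e0, , drop = FALSE]
    if (nrow(blocking) > 0L) {
      s0 <- max(s0, min(blocking$end, e0))
    }
  } else {
    s0 <- gene$end
    e0 <- min(gene$end + max_len, ctg_len)
    blocking <- others[others$start < e0 & others$end > s0, , drop = FALSE]
    if (nrow(blocking) > 0L) {
      e0 <- min(e0, max(blocking$start, s0))
    }
  }
  seq <- if (e0 > s0) {
    substr(genome$contigs[[gene$contig]], s0 + 1L, e0)
  } else {
    s0 <- e0 <- if (gene$strand == "+") gene$start else gene$end
    ""
  }
  if (gene$strand == "-" && nzchar(seq)) {
    seq <- reverse_complement(seq)
  }
  structure(
    list(contig = gene$contig, start = s0, end = e0,
         strand = gene$strand, sequence = seq),
    class = "region"
  )
}

#' Read a differential-expression table
#'
#' Expects a TSV with header columns `locus_tag`, `gene`, `base_mean`,
#' `log2fc`, `pvalue` (knockout vs wild type). Missing p-values (`NA`) are
#' allowed; some published tables print none. Row order is preserved.
#'
#' @param path TSV file.
#' @return `data.frame` with the five columns, numeric fields parsed.
#' @export
read_deg_tsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  required <- c("locus_tag", "gene", "base_mean", "log2fc", "pvalue")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("DEG table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, required]
  num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & !is.na(x) & x != "" & toupper(x) != "NA")
    if (length(bad) > 0L) {
      stop("non-numeric ", col, " at row ", bad[1L], " of ", path, ": '",
           x[bad[1L]], "'")
    }
    out
  }
  df$base_mean <- num(df$base_mean, "base_mean")
  df$log2fc <- num(df$log2fc, "log2fc")
  df$pvalue <- num(df$pvalue, "pvalue")
  if (any(df$log2fc %in% NA)) {
    stop("missing log2fc at row ", which(is.na(df$log2fc))[1L], " of ", path)
  }
  rownames(df) <- NULL
  df
}

#' Read ChIP peaks from a BED file
#'
#' BED3+ (0-based half-open); the optional 5th column becomes the peak
#' score (0 when absent).
#'
#' @param path BED file.
#' @return `data.frame` with `contig`, `start`, `end`, `score`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) score <- rep(0, length(gr))
  score[is.na(score)] <- 0
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
}

#' Write peaks as BED
#' @param peaks `data.frame` with `contig`, `start`, `end` and optionally
#'   `score` (0-based half-open).
#' @param path Output file.
#' @export
write_bed <- function(peaks, path) {
  score <- if ("score" %in% names(peaks)) peaks$score else rep(0, nrow(peaks))
  lines <- sprintf("%s\t%d\t%d\tpeak_%04d\t%s", peaks$contig,
                   as.integer(peaks$start), as.integer(peaks$end),
                   seq_len(nrow(peaks)), format(score, trim = TRUE))
  writeLines(lines, path)
  invisible(peaks)
}
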