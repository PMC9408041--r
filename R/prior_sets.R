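# Construction of prior SNP sets from QTL and gene interval tables:
# keep short QTLs, pair genes with QTL traits within a window, keep genes
# recurrent across traits, then collect SNPs within a window of those genes.
# Interval joins run on IRanges/GenomicRanges; coordinates are held 0-based
# half-open internally and converted at the boundary.

.intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end))
}

#' Read an interval table
#'
#' Tab- or whitespace-delimited columns `chrom start end name [trait]` with
#' a header row. Input coordinates are 1-based inclusive by default;
#' BED-style 0-based half-open input is accepted via `zero_based = TRUE`.
#' Internally intervals are 0-based half-open.
#'
#' @param file Path.
#' @param zero_based Set `TRUE` for BED-style input coordinates.
#' @return data.frame with columns chrom, start, end, name and optionally
#'   trait (0-based half-open).
#' @export
read_intervals <- function(file, zero_based = FALSE) {
  tab <- utils::read.table(file, header = TRUE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "name")
  if (!all(need %in% names(tab))) {
    stop("interval table needs columns: ", paste(need, collapse = ", "))
  }
  if (!zero_based) tab$start <- tab$start - 1L
  validate_intervals(tab)
  tab
}

validate_intervals <- function(x) {
  if (nrow(x) && any(x$start >= x$end)) stop("intervals must satisfy start < end")
  if (nrow(x) && any(!nzchar(x$chrom))) stop("empty chromosome label")
  invisible(x)
}

#' Keep QTL intervals shorter than a length cutoff
#'
#' Retention is strict: an interval of exactly `max_len` is dropped.
#'
#' @param qtls Interval data.frame (0-based half-open).
#' @param max_len Length cutoff in bp (default 40 kb).
#' @return The retained rows.
#' @export
filter_qtl_by_length <- function(qtls, max_len = 40000) {
  validate_intervals(qtls)
  qtls[(qtls$end - qtls$start) < max_len, , drop = FALSE]
}

#' Pair genes with QTL traits within a distance window
#'
#' A gene is associated with the trait of a QTL when the gap between them is
#' at most `window` bp on the same chromosome (0 for overlapping intervals;
#' the bound is inclusive). Duplicate (gene, trait) pairs are collapsed.
#'
#' @param genes Interval data.frame with gene IDs in `name`.
#' @param qtls Interval data.frame with a `trait` column.
#' @param window Window in bp (default 50 kb).
#' @return data.frame with columns `gene`, `trait` (deduplicated).
#' @export
genes_near_qtl <- function(genes, qtls, window = 50000) {
  validate_intervals(genes)
  validate_intervals(qtls)
  if (!"trait" %in% names(qtls)) stop("QTL table needs a 'trait' column")
  if (!nrow(genes) || !nrow(qtls)) {
    return(data.frame(gene = character(0), trait = character(0)))
  }
  hits <- GenomicRanges::findOverlaps(.intervals_to_granges(genes),
                                      .intervals_to_granges(qtls),
                                      maxgap = window)
  out <- unique(data.frame(
    gene = genes$name[S4Vectors::queryHits(hits)],
    trait = qtls$trait[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Genes recurrent across traits
#'
#' @param table data.frame of (gene, trait) pairs as from
#'   [genes_near_qtl()]; duplicates are collapsed before counting.
#' @param min_traits Minimum number of distinct traits (default 4).
#' @return Character vector of gene IDs.
#' @export
recurrent_genes <- function(table, min_traits = 4L) {
  tab <- unique(table[, c("gene", "trait")])
  counts <- table(tab$gene)
  sort(names(counts)[counts >= min_traits])
}

#' SNPs within a window of gene intervals
#'
#' A SNP is retained when its position lies within `window` bp of any gene
#' interval (inclusive; 0 for positions inside the gene).
#'
#' @param snps data.frame with columns `id`, `chrom`, `pos` (1-based
#'   position), e.g. the `snps` element of a `genotype_matrix`.
#' @param genes Interval data.frame (0-based half-open).
#' @param window Window in bp (default 10 kb).
#' @return Character vector of SNP IDs (sorted, unique).
#' @export
snps_near_genes <- function(snps, genes, window = 10000) {
  validate_intervals(genes)
  if (!nrow(genes) || !nrow(snps)) return(character(0))
  snp_gr <- GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L))
  hits <- GenomicRanges::findOverlaps(snp_gr, .intervals_to_granges(genes),
                                      maxgap = window)
  sort(unique(snps$id[S4Vectors::queryHits(hits)]))
}

#' Full prior-set construction chain
#'
#' Runs the filter chain: drop long QTLs, pair genes with QTL traits within
#' `gene_window`, keep genes recurrent in at least `min_traits` traits, then
#' collect SNPs within `snp_window` of those genes.
#'
#' @param snps SNP data.frame (`id`, `chrom`, `pos`).
#' @param genes Gene interval data.frame.
#' @param qtls QTL interval data.frame with `trait`.
#' @param max_qtl_len QTL length cutoff (strict; default 40 kb).
#' @param gene_window Gene-to-QTL window (default 50 kb).
#' @param min_traits Trait-recurrence cutoff (default 4).
#' @param snp_window SNP-to-gene window (default 10 kb).
#' @return List: `snp_set` (character IDs), `genes` (retained gene IDs),
#'   `gene_trait` (the intermediate pair table).
#' @export
build_prior_set <- function(snps, genes, qtls, max_qtl_len = 40000,
                            gene_window = 50000, min_traits = 4L,
                            snp_window = 10000) {
  q <- filter_qtl_by_length(qtls, max_qtl_len)
  gt <- genes_near_qtl(genes, q, gene_window)
  gsel <- recurrent_genes(gt, min_traits)
  gint <- genes[genes$name %in% gsel, , drop = FALSE]
  list(snp_set = snps_near_genes(snps, gint, snp_window),
       genes = gsel, gene_trait = gt)
}
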