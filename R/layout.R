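#' Genome layout: chromosome sizes, exclusions and annotation intervals
#'
#' Container for everything positional that is not a measurement: chromosome
#' lengths, excluded (centromere-like) regions, CpG islands, island shores,
#' promoters, genes and optional gene sets. All interval slots are `GRanges`
#' carrying seqlengths; on disk they are BED (0-based half-open).
#'
#' @param chrom_lengths named numeric/integer vector of chromosome lengths.
#' @param excluded `GRanges` of regions removed from all analyses.
#' @param cgis,genes `GRanges`; genes must carry a `name` column (gene ids).
#' @param shores `GRanges`, or NULL to derive 2-kb CGI flanks.
#' @param promoters `GRanges`, or NULL to derive TSS +/- 1 kb from genes.
#' @param gene_sets named list of character vectors of gene ids (e.g. TSG
#'   lists); membership is validated against `genes$name`.
#' @param shore_bp,promoter_bp widths used when deriving shores/promoters.
#' @return A `GenomeLayout` object.
#' @export
genome_layout <- function(chrom_lengths,
                          excluded = NULL,
                          cgis = NULL,
                          shores = NULL,
                          promoters = NULL,
                          genes = NULL,
                          gene_sets = list(),
                          shore_bp = 2000,
                          promoter_bp = 1000) {
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0))
  chrom_lengths <- setNames(as.numeric(chrom_lengths), names(chrom_lengths))
  fix <- function(gr) {
    if (is.null(gr)) return(.empty_gr(chrom_lengths))
    stopifnot(is(gr, "GRanges"))
    if (!all(as.character(GenomeInfoDb::seqnames(gr)) %in%
             names(chrom_lengths)))
      stop("intervals on chromosomes absent from the layout")
    GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
    GenomeInfoDb::seqlengths(gr) <- chrom_lengths
    if (length(gr) &&
        any(GenomicRanges::end(gr) >
            chrom_lengths[as.character(GenomeInfoDb::seqnames(gr))]))
      stop("intervals exceed chromosome bounds")
    sort(gr, ignore.strand = TRUE)
  }
  cgis <- fix(cgis)
  genes <- fix(genes)
  if (is.null(shores) && length(cgis)) {
    # flanks may poke past chromosome ends; trimmed silently by design
    shores <- suppressWarnings({
      left <- GenomicRanges::flank(cgis, shore_bp, start = TRUE)
      right <- GenomicRanges::flank(cgis, shore_bp, start = FALSE)
      GenomicRanges::setdiff(
        GenomicRanges::reduce(GenomicRanges::trim(c(left, right))),
        cgis, ignore.strand = TRUE)
    })
  }
  if (is.null(promoters) && length(genes)) {
    promoters <- suppressWarnings({
      tss <- GenomicRanges::resize(genes, width = 1, fix = "start")
      GenomicRanges::reduce(GenomicRanges::trim(
        GenomicRanges::resize(tss, width = 2 * promoter_bp + 1,
                              fix = "center")), ignore.strand = TRUE)
    })
  }
  if (length(gene_sets)) {
    stopifnot(!is.null(names(gene_sets)))
    miss <- setdiff(unlist(gene_sets), genes$name)
    if (length(miss))
      stop("gene-set members absent from gene annotation: ",
           paste(head(miss, 5), collapse = ", "))
  }
  obj <- list(chrom_lengths = chrom_lengths,
              excluded = fix(excluded),
              cgis = cgis,
              shores = fix(shores),
              promoters = fix(promoters),
              genes = genes,
              gene_sets = gene_sets)
  class(obj) <- "GenomeLayout"
  obj
}

#' @export
print.GenomeLayout <- function(x, ...) {
  cat("GenomeLayout:", length(x$chrom_lengths), "chromosomes,",
      format(sum(x$chrom_lengths), big.mark = ","), "bp\n")
  cat("  excluded:", length(x$excluded), " CGIs:", length(x$cgis),
      " shores:", length(x$shores), " promoters:", length(x$promoters),
      " genes:", length(x$genes), "\n")
  if (length(x$gene_sets))
    cat("  gene sets:", paste(names(x$gene_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Non-excluded portion of the genome
#'
#' @param layout a `GenomeLayout`.
#' @return `GRanges` covering every chromosome minus excluded regions.
#' @export
non_excluded_regions <- function(layout) {
  whole <- gr_from_bed0(data.frame(chrom = names(layout$chrom_lengths),
                                   start = 0,
                                   end = layout$chrom_lengths),
                        layout$chrom_lengths)
  GenomicRanges::setdiff(whole, layout$excluded, ignore.strand = TRUE)
}
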