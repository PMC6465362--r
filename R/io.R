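# On-disk formats. Conventions enforced here and nowhere else:
# all text coordinates are 0-based half-open (BED); in memory intervals are
# GRanges (1-based closed) and CpG positions are 0-based integer columns.

#' Read a per-sample methylome table
#'
#' Supported formats: `methcounts` — six tab-separated columns (chrom,
#' 0-based position, strand, context tag, methylation fraction, coverage);
#' `bedgraph` — four columns (chrom, start, end, fraction), a fraction-only
#' track read back at nominal coverage 1. Methylated counts are
#' reconstructed as `M = round(fraction * coverage)`. A `soloWCGW` context
#' tag sets the solo-WCGW flag.
#'
#' @param path input file.
#' @param format `"methcounts"` or `"bedgraph"`.
#' @param min_coverage drop records with coverage below this (default 0:
#'   keep everything, including uncovered CpGs).
#' @param sample_id sample identifier; defaults to the file base name.
#' @return A `SampleMethylome`.
#' @export
read_methylome <- function(path, format = c("methcounts", "bedgraph"),
                           min_coverage = 0,
                           sample_id = sub("\\.[^.]*$", "", basename(path))) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    warning("empty methylome file: ", path)
    return(sample_methylome(sample_id, data.table(
      chrom = character(), pos = integer(), M = integer(), T = integer())))
  }
  if (format == "methcounts") {
    dt <- tryCatch(
      fread(path, header = FALSE, sep = "\t",
            col.names = c("chrom", "pos", "strand", "context",
                          "fraction", "coverage"),
            colClasses = list(character = c(1, 3, 4))),
      error = function(e) stop("malformed methcounts file ", path, ": ",
                               conditionMessage(e)))
    bad <- which(!is.finite(dt$fraction) | dt$fraction < 0 | dt$fraction > 1 |
                   !is.finite(dt$coverage) | dt$coverage < 0)
    if (length(bad))
      stop("malformed methcounts record at line ", bad[1], " of ", path)
    rec <- data.table(chrom = dt$chrom, pos = as.integer(dt$pos),
                      strand = dt$strand,
                      M = as.integer(round(dt$fraction * dt$coverage)),
                      T = as.integer(dt$coverage),
                      is_solo_wcgw = grepl("soloWCGW", dt$context,
                                           fixed = TRUE))
  } else {
    dt <- tryCatch(
      fread(path, header = FALSE, sep = "\t",
            col.names = c("chrom", "start", "end", "fraction"),
            colClasses = list(character = 1), skip = "chr"),
      error = function(e) stop("malformed bedGraph file ", path, ": ",
                               conditionMessage(e)))
    if (nrow(dt) && (any(dt$fraction < 0) || any(dt$fraction > 1)))
      stop("bedGraph fractions outside [0,1] in ", path)
    rec <- data.table(chrom = dt$chrom, pos = as.integer(dt$start),
                      strand = "+",
                      M = as.integer(round(dt$fraction)), T = 1L,
                      is_solo_wcgw = NA)
  }
  if (nrow(rec) && is.unsorted(order(rec$chrom, rec$pos))) {
    # sortedness is restored silently below; flag it for the caller
    warning("unsorted input in ", path, "; records re-sorted")
  }
  if (min_coverage > 0) rec <- rec[rec$T >= min_coverage, ]
  sample_methylome(sample_id, rec)
}

#' Write a methylome as methcounts-style TSV (or bedGraph)
#'
#' Fractions are rendered with six decimals; uncovered CpGs are written with
#' fraction 0 and coverage 0.
#'
#' @param methylome a `SampleMethylome`.
#' @param path output file.
#' @param format `"methcounts"` or `"bedgraph"` (fraction track, covered
#'   CpGs only).
#' @return `path`, invisibly.
#' @export
write_methylome <- function(methylome, path,
                            format = c("methcounts", "bedgraph")) {
  format <- match.arg(format)
  r <- methylome$records
  frac <- ifelse(r$T > 0, r$M / pmax(1L, r$T), 0)
  if (format == "methcounts") {
    out <- data.table(
      chrom = r$chrom, pos = r$pos, strand = r$strand,
      context = ifelse(!is.na(r$is_solo_wcgw) & r$is_solo_wcgw,
                       "CpG:soloWCGW", "CpG"),
      fraction = sprintf("%.6f", frac), coverage = r$T)
  } else {
    keep <- r$T > 0
    out <- data.table(chrom = r$chrom[keep], start = r$pos[keep],
                      end = r$pos[keep] + 1L,
                      fraction = sprintf("%.6f", frac[keep]))
  }
  fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genomic intervals from BED3/BED6
#'
#' Coordinates on disk are 0-based half-open and are returned as `GRanges`
#' (1-based closed) with identical genomic footprint.
#'
#' @param path BED file.
#' @param strict reject overlapping intervals (`TRUE`) or merge them
#'   (`FALSE`).
#' @param chrom_lengths optional named vector to attach as seqlengths.
#' @return A `GRanges`, sorted.
#' @export
read_intervals <- function(path, strict = TRUE, chrom_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) return(.empty_gr(chrom_lengths))
  dt <- fread(path, header = FALSE, sep = "\t",
              colClasses = list(character = 1))
  setnames(dt, seq_len(ncol(dt)),
           c("chrom", "start", "end", "name", "score", "strand")[
             seq_len(ncol(dt))])
  bad <- which(dt$start >= dt$end)
  if (length(bad))
    stop(sprintf("invalid interval (start >= end) at %s:%d-%d",
                 dt$chrom[bad[1]], dt$start[bad[1]], dt$end[bad[1]]))
  gr <- gr_from_bed0(dt, chrom_lengths)
  gr <- sort(gr, ignore.strand = TRUE)
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  if (length(red) < length(gr) &&
      sum(GenomicRanges::width(red)) <
        sum(GenomicRanges::width(gr))) {
    if (strict) stop("overlapping intervals in ", path,
                     " (strict = TRUE); use strict = FALSE to merge")
    gr <- red
  }
  gr
}

#' Write intervals as BED
#'
#' @param gr a `GRanges`; a `name` column yields BED4+, a `score` column
#'   BED5/BED6.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(gr, path) {
  df <- bed0_from_gr(gr)
  if ("score" %in% names(df) && !"name" %in% names(df))
    df$name <- rep(".", nrow(df))
  df <- df[, intersect(c("chrom", "start", "end", "name", "score"),
                       names(df)), with = FALSE]
  fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fill CpG annotation flags from a layout
#'
#' Sets `in_cgi`, `in_shore` and `in_promoter` by interval membership
#' (half-open convention: a CpG at an interval's end coordinate is outside).
#' The sequence-derived `is_solo_wcgw` flag is left untouched.
#'
#' @param methylome a `SampleMethylome`.
#' @param layout a `GenomeLayout`.
#' @return The annotated `SampleMethylome`.
#' @export
annotate_cpgs <- function(methylome, layout) {
  r <- methylome$records
  if (nrow(r) == 0) return(methylome)
  unknown <- setdiff(unique(r$chrom), names(layout$chrom_lengths))
  if (length(unknown))
    stop("CpGs on chromosomes absent from layout: ",
         paste(unknown, collapse = ", "))
  gr <- gr_from_bed0(data.table(chrom = r$chrom, start = r$pos,
                                end = r$pos + 1), layout$chrom_lengths)
  r$in_cgi <- GenomicRanges::countOverlaps(gr, layout$cgis,
                                           ignore.strand = TRUE) > 0
  r$in_shore <- GenomicRanges::countOverlaps(gr, layout$shores,
                                             ignore.strand = TRUE) > 0
  r$in_promoter <- GenomicRanges::countOverlaps(gr, layout$promoters,
                                                ignore.strand = TRUE) > 0
  methylome$records <- r
  methylome
}

#' Write / read a cohort sample sheet
#'
#' @param sheet data.frame with at least a `sample_id` column.
#' @param path TSV file.
#' @return `path` / a data.table.
#' @export
write_sample_sheet <- function(sheet, path) {
  fwrite(as.data.table(sheet), path, sep = "\t")
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  dt <- fread(path, sep = "\t")
  if (!"sample_id" %in% names(dt))
    stop("sample sheet lacks a sample_id column: ", path)
  dt
}

#' Write a synthetic cohort to a directory
#'
#' Emits one methcounts TSV per sample, per-sample planted PMD BED6 files
#' (name = domain id), the permissive-domain BED, CGI/gene/excluded BEDs,
#' the sample sheet, and a JSON ground-truth file (CGI states, gene labels,
#' per-sample truth).
#'
#' @param cohort a `SyntheticCohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in cohort$samples)
    write_methylome(s, file.path(dir, paste0(s$sample_id, ".methcounts.tsv")))
  for (sid in names(cohort$pmds))
    write_intervals(cohort$pmds[[sid]],
                    file.path(dir, paste0(sid, ".planted_pmds.bed")))
  write_intervals(cohort$truth$domains, file.path(dir, "permissive.bed"))
  cg <- cohort$layout$cgis
  if (length(cg)) write_intervals(cg, file.path(dir, "cgis.bed"))
  if (length(cohort$layout$genes))
    write_intervals(cohort$layout$genes, file.path(dir, "genes.bed"))
  if (length(cohort$layout$excluded))
    write_intervals(cohort$layout$excluded, file.path(dir, "excluded.bed"))
  write_sample_sheet(cohort$sample_sheet, file.path(dir, "samples.tsv"))
  jsonlite::write_json(list(
    chrom_lengths = as.list(cohort$layout$chrom_lengths),
    cgi_states = cohort$truth$cgi_states,
    gene_truth = cohort$truth$gene_truth,
    sample_truth = cohort$truth$sample_truth), file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
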