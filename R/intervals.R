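#' Construct a set of genomic intervals
#'
#' Builds a [GenomicRanges::GRanges] from chromosome / start / end vectors.
#' All coordinates in this package are 1-based and inclusive (the
#' R/Bioconductor convention); BED files are converted at the I/O boundary
#' (see [read_bed6()] / [write_bed6()]).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive, `start <= end`.
#' @param strand Strand (`"+"`, `"-"` or `"*"`); recycled.
#' @param sizes Optional named integer vector of chromosome lengths. When
#'   given, every interval is checked against its chromosome bound.
#' @return A `GRanges`.
#' @export
g_intervals <- function(chrom, start, end, strand = "*", sizes = NULL) {
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    stopifnot(all(start >= 1L), all(end >= start))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  }
  if (!is.null(sizes)) check_chrom_bounds(gr, sizes)
  gr
}

check_chrom_bounds <- function(gr, sizes) {
  chr <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- setdiff(unique(chr), names(sizes))
  if (length(unknown) > 0L) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  over <- BiocGenerics::end(gr) > unname(sizes[chr])
  if (any(over)) {
    stop("interval exceeds chromosome length on: ",
         paste(unique(chr[over]), collapse = ", "))
  }
  invisible(gr)
}

#' Merge overlapping or book-ended intervals
#'
#' Returns the sorted, disjoint union of the input intervals. Merging is
#' unstranded and book-ended (touching) intervals are merged: control
#' coverage is a property of genomic position, and a zero-length gap is not
#' a distinct uncovered region.
#'
#' @param intervals A `GRanges`.
#' @param sizes Optional chromosome sizes for bounds checking.
#' @return Sorted, disjoint, unstranded `GRanges` covering the same bases.
#' @export
merge_intervals <- function(intervals, sizes = NULL) {
  if (!is.null(sizes)) check_chrom_bounds(intervals, sizes)
  if (length(intervals) == 0L) return(GenomicRanges::GRanges())
  intervals <- unstranded(intervals)
  # deterministic chromosome order regardless of input seqlevels order
  GenomeInfoDb::seqlevels(intervals) <-
    sort(GenomeInfoDb::seqlevels(intervals))
  GenomicRanges::reduce(GenomicRanges::sort(intervals), min.gapwidth = 1L)
}

unstranded <- function(gr) {
  BiocGenerics::strand(gr) <- "*"
  gr
}

#' Complement a covered interval set within chromosome bounds
#'
#' Computes, per chromosome, the regions not covered by `covered`. The union
#' of `covered` and the result tiles each chromosome in `sizes` exactly.
#' Chromosomes absent from `covered` are returned whole.
#'
#' @param covered A `GRanges` (merged or not; it is merged internally).
#' @param sizes Named integer vector of chromosome lengths.
#' @return Sorted, disjoint `GRanges` of uncovered regions.
#' @export
invert_intervals <- function(covered, sizes) {
  stopifnot(length(sizes) > 0L, all(sizes > 0L), !is.null(names(sizes)))
  covered <- merge_intervals(covered, sizes = sizes)
  sizes <- sizes[sort(names(sizes))]
  GenomeInfoDb::seqlevels(covered) <- names(sizes)
  GenomeInfoDb::seqlengths(covered) <- unname(sizes)
  gaps <- GenomicRanges::gaps(covered)
  # gaps() emits per-strand entries; keep the unstranded complement only
  gaps <- gaps[BiocGenerics::strand(gaps) == "*"]
  GenomicRanges::sort(gaps)
}

#' Clip blocks against a set of regions
#'
#' Intersects each block with each region, returning every maximal
#' sub-interval of a block lying inside a single region, together with the
#' index of the region it fell in. Ordering is deterministic:
#' (chromosome, start, region index).
#'
#' @param blocks,regions `GRanges`.
#' @return A `GRanges` with metadata columns `region_id` (index into
#'   `regions`) and `block_id` (index into `blocks`).
#' @export
intersect_blocks <- function(blocks, regions) {
  hits <- GenomicRanges::findOverlaps(unstranded(blocks), unstranded(regions))
  if (length(hits) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out)$region_id <- integer(0)
    S4Vectors::mcols(out)$block_id <- integer(0)
    return(out)
  }
  b <- blocks[S4Vectors::queryHits(hits)]
  r <- regions[S4Vectors::subjectHits(hits)]
  out <- GenomicRanges::pintersect(unstranded(b), unstranded(r))
  S4Vectors::mcols(out) <- NULL
  S4Vectors::mcols(out)$region_id <- S4Vectors::subjectHits(hits)
  S4Vectors::mcols(out)$block_id <- S4Vectors::queryHits(hits)
  ord <- order(as.character(GenomeInfoDb::seqnames(out)),
               BiocGenerics::start(out),
               S4Vectors::mcols(out)$region_id)
  out[ord]
}

#' Read a BED6 file
#'
#' Plain tab-separated BED6: chrom, start (0-based), end (exclusive), name,
#' score, strand. In capture BED files the name column carries the region
#' category and the score column the control maximum TPM, which may be
#' fractional -- hence a permissive numeric score.
#'
#' @param path File path.
#' @return `GRanges` (1-based inclusive) with `name` and `score` columns.
#' @export
read_bed6 <- function(path) {
  if (file.size(path) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$name <- character(0)
    S4Vectors::mcols(gr)$score <- numeric(0)
    return(gr)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = ifelse(df$strand %in% c("+", "-"),
                                               df$strand, "*"))
  S4Vectors::mcols(gr)$name <- df$name
  S4Vectors::mcols(gr)$score <- df$score
  gr
}

#' Write a BED6 file
#'
#' @param gr `GRanges`; optional `name` / `score` metadata columns are used
#'   for the corresponding BED columns (defaults `"."` and `0`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(gr, path) {
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) mc$name else rep(".", length(gr))
  score <- if ("score" %in% names(mc)) mc$score else rep(0, length(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[strand == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   as.character(GenomeInfoDb::seqnames(gr)),
                   BiocGenerics::start(gr) - 1L,
                   BiocGenerics::end(gr),
                   name, format_num(score), strand)
  writeLines(lines, path)
  invisible(path)
}

# compact, locale-stable numeric formatting for text outputs
format_num <- function(x) {
  out <- formatC(x, format = "fg", digits = 15)
  trimws(out)
}
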