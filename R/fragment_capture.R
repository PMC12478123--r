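#' Capture tumor transcript fragments falling in capture regions
#'
#' Intersects every tumor transcript's exon chain with the capture regions.
#' Clipped pieces from consecutive exons of the same transcript falling in
#' the same capture region are kept together as one junction-spanning
#' fragment with multiple blocks; pieces of one transcript in different
#' capture regions stay separate fragments.
#'
#' @param tumor A [transcript_set()].
#' @param capture Capture `GRanges` from [derive_capture_bed()] /
#'   [read_capture_bed()].
#' @return Tibble with one row per fragment: `fragment_id`,
#'   `transcript_id`, `category`, `region_id`, `nt_length`, `chrom`,
#'   `strand`, and a `blocks` list-column of data frames
#'   (`start`, `end`, ascending genomic order).
#' @export
capture_fragments <- function(tumor, capture) {
  ex <- tumor$exons
  if (nrow(ex) == 0L || length(capture) == 0L) return(empty_fragments())
  blocks <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  clips <- intersect_blocks(blocks, capture)
  if (length(clips) == 0L) return(empty_fragments())
  df <- tibble::tibble(
    transcript_id = ex$transcript_id[S4Vectors::mcols(clips)$block_id],
    exon_rank = ex$exon_rank[S4Vectors::mcols(clips)$block_id],
    region_id = S4Vectors::mcols(clips)$region_id,
    chrom = as.character(GenomeInfoDb::seqnames(clips)),
    start = BiocGenerics::start(clips),
    end = BiocGenerics::end(clips))
  strand_of <- stats::setNames(tumor$transcripts$strand,
                               tumor$transcripts$transcript_id)
  df <- dplyr::arrange(df, .data$transcript_id, .data$region_id, .data$start)
  grp <- dplyr::group_by(df, .data$transcript_id, .data$region_id)
  frags <- dplyr::summarise(
    grp,
    chrom = .data$chrom[1],
    nt_length = sum(.data$end - .data$start + 1L),
    blocks = list(data.frame(start = .data$start, end = .data$end)),
    .groups = "drop")
  frags$category <- S4Vectors::mcols(capture)$category[frags$region_id]
  frags$strand <- unname(strand_of[frags$transcript_id])
  frags <- dplyr::arrange(frags, .data$chrom,
                          vapply(frags$blocks, function(b) b$start[1], 0),
                          .data$region_id)
  frags$fragment_id <- sprintf("frag_%04d", seq_len(nrow(frags)))
  dplyr::select(frags, "fragment_id", "transcript_id", "category",
                "region_id", "chrom", "strand", "nt_length", "blocks")
}

empty_fragments <- function() {
  tibble::tibble(fragment_id = character(0), transcript_id = character(0),
                 category = character(0), region_id = integer(0),
                 chrom = character(0), strand = character(0),
                 nt_length = integer(0), blocks = list())
}

#' Filter captured fragments on length, expression and coverage
#'
#' A fragment is kept when its total length reaches `min_len` nucleotides
#' (default 24, i.e. longer than 23) and its source transcript clears the
#' category-specific expression gates: novel fragments need transcript TPM
#' >= `novel_tpm` and mean coverage >= `novel_cov`; differential fragments
#' need TPM >= `diff_tpm` and mean coverage >= `diff_cov`.
#'
#' @param fragments Output of [capture_fragments()].
#' @param tumor The [transcript_set()] the fragments came from.
#' @param min_len Minimum fragment length in nucleotides.
#' @param novel_tpm,novel_cov Gates for novel (intronic/intergenic)
#'   fragments.
#' @param diff_tpm,diff_cov Gates for differential fragments.
#' @return The kept subset of `fragments`.
#' @export
filter_fragments <- function(fragments, tumor, min_len = 24,
                             novel_tpm = 1.0, novel_cov = 4.0,
                             diff_tpm = 10.0, diff_cov = 16.0) {
  if (nrow(fragments) == 0L) return(fragments)
  unknown <- setdiff(fragments$transcript_id, tumor$transcripts$transcript_id)
  if (length(unknown) > 0L) {
    stop("fragments reference unknown transcript(s): ",
         paste(unknown, collapse = ", "))
  }
  tx <- tumor$transcripts
  idx <- match(fragments$transcript_id, tx$transcript_id)
  tpm <- tx$tpm[idx]
  cov <- tx$mean_cov[idx]
  novel <- fragments$category %in% c("novel_intronic", "novel_intergenic")
  keep <- fragments$nt_length >= min_len &
    ((novel & tpm >= novel_tpm & cov >= novel_cov) |
       (!novel & tpm >= diff_tpm & cov >= diff_cov))
  fragments[keep, ]
}

#' Write fragments as BED12-like records for inspection
#'
#' @param fragments Output of [capture_fragments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  lines <- vapply(seq_len(nrow(fragments)), function(i) {
    b <- fragments$blocks[[i]]
    chrom_start <- b$start[1] - 1L
    sprintf("%s\t%d\t%d\t%s|%s\t0\t%s\t%d\t%s\t%s",
            fragments$chrom[i], chrom_start, max(b$end),
            fragments$fragment_id[i], fragments$category[i],
            fragments$strand[i], nrow(b),
            paste(b$end - b$start + 1L, collapse = ","),
            paste(b$start - 1L - chrom_start, collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
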