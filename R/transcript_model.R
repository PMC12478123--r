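#' Transcript sets
#'
#' A `transcript_set` is the package's container for assembled transcript
#' models: a list of two tibbles.
#'
#' * `transcripts`: one row per transcript -- `transcript_id`, `locus_id`,
#'   `sample_id`, `chrom`, `strand`, `tpm`, `mean_cov`, `n_exons`, and
#'   `ref_gene_id` (reference gene the assembler matched, `NA` for fully
#'   novel structures).
#' * `exons`: one row per exon -- `transcript_id`, `exon_rank` (1 = 5'-most
#'   genomic... exons are stored in ascending genomic order), `chrom`,
#'   `start`, `end` (1-based inclusive), `strand`, `cov` (per-exon read
#'   coverage).
#'
#' @param transcripts,exons Tibbles as described above.
#' @return An object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons) {
  stopifnot(all(c("transcript_id", "locus_id", "strand", "tpm", "mean_cov")
                %in% names(transcripts)),
            all(c("transcript_id", "chrom", "start", "end", "cov")
                %in% names(exons)))
  exons <- dplyr::arrange(exons, .data$transcript_id, .data$start)
  exons <- dplyr::mutate(dplyr::group_by(exons, .data$transcript_id),
                         exon_rank = dplyr::row_number())
  exons <- dplyr::ungroup(exons)
  bad <- dplyr::filter(dplyr::group_by(exons, .data$transcript_id),
                       any(.data$start[-1] <= .data$end[-length(.data$end)] &
                             length(.data$start) > 1))
  if (nrow(bad) > 0L) {
    stop("overlapping exons within transcript(s): ",
         paste(unique(bad$transcript_id), collapse = ", "))
  }
  structure(list(transcripts = tibble::as_tibble(transcripts),
                 exons = tibble::as_tibble(exons)),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("<transcript_set> %d transcripts, %d exons, %d loci\n",
              nrow(x$transcripts), nrow(x$exons),
              length(unique(x$transcripts$locus_id))))
  invisible(x)
}

#' Read assembled or reference transcript models from GTF
#'
#' Supports two dialects. `"stringtie"` expects `TPM` and `cov` attributes
#' (transcript-level TPM and mean coverage, per-exon `cov`), as emitted by
#' reference-guided assembly; `"gencode"` expects plain annotation
#' (`gene_id`/`transcript_id`), with expression fields set to zero.
#'
#' The locus grouping key is the assembler gene id (`gene_id` attribute;
#' equivalently the transcript id minus its last dot-suffix, e.g.
#' `"STRG.1.1"` -> `"STRG.1"`) for the stringtie dialect and `gene_id` for
#' gencode. When `sample_id` is given it is appended to each transcript id
#' with an underscore so transcripts from different samples stay distinct
#' after concatenation.
#'
#' @param path GTF file path.
#' @param dialect `"stringtie"` or `"gencode"`.
#' @param sample_id Optional sample name appended to transcript ids.
#' @return A [transcript_set()].
#' @export
read_transcript_gtf <- function(path, dialect = c("stringtie", "gencode"),
                                sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) {
                   stop("malformed GTF '", path, "': ", conditionMessage(e))
                 })
  mc <- S4Vectors::mcols(gr)
  if (!all(c("type", "transcript_id") %in% names(mc))) {
    stop("GTF '", path, "' lacks type/transcript_id attributes")
  }
  ex <- gr[mc$type == "exon"]
  tx <- gr[mc$type == "transcript"]
  if (length(tx) == 0L) {
    # annotation without explicit transcript features: synthesize from exons
    tx_ids <- unique(S4Vectors::mcols(ex)$transcript_id)
  } else {
    tx_ids <- S4Vectors::mcols(tx)$transcript_id
  }
  missing_ex <- setdiff(tx_ids, S4Vectors::mcols(ex)$transcript_id)
  if (length(missing_ex) > 0L) {
    stop("transcript(s) with no exons in '", path, "': ",
         paste(missing_ex, collapse = ", "))
  }
  num_attr <- function(obj, key) {
    v <- S4Vectors::mcols(obj)[[key]]
    if (is.null(v)) return(rep(0, length(obj)))
    v <- suppressWarnings(as.numeric(v))
    v[is.na(v)] <- 0
    v
  }
  chr_attr <- function(obj, key, default = NA_character_) {
    v <- S4Vectors::mcols(obj)[[key]]
    if (is.null(v)) rep(default, length(obj)) else as.character(v)
  }

  exons <- tibble::tibble(
    transcript_id = chr_attr(ex, "transcript_id"),
    chrom = as.character(GenomeInfoDb::seqnames(ex)),
    start = BiocGenerics::start(ex),
    end = BiocGenerics::end(ex),
    strand = as.character(BiocGenerics::strand(ex)),
    cov = num_attr(ex, "cov"))

  if (length(tx) > 0L) {
    transcripts <- tibble::tibble(
      transcript_id = chr_attr(tx, "transcript_id"),
      locus_id = chr_attr(tx, "gene_id"),
      chrom = as.character(GenomeInfoDb::seqnames(tx)),
      strand = as.character(BiocGenerics::strand(tx)),
      tpm = num_attr(tx, "TPM"),
      mean_cov = num_attr(tx, "cov"),
      ref_gene_id = chr_attr(tx, "ref_gene_id"))
  } else {
    transcripts <- dplyr::summarise(
      dplyr::group_by(exons, .data$transcript_id),
      chrom = .data$chrom[1], strand = .data$strand[1], .groups = "drop")
    first_ex <- ex[!duplicated(S4Vectors::mcols(ex)$transcript_id)]
    lk <- tibble::tibble(transcript_id = chr_attr(first_ex, "transcript_id"),
                         locus_id = chr_attr(first_ex, "gene_id"),
                         ref_gene_id = chr_attr(first_ex, "ref_gene_id"))
    transcripts <- dplyr::left_join(transcripts, lk, by = "transcript_id")
    transcripts$tpm <- 0
    transcripts$mean_cov <- 0
  }
  no_gene <- is.na(transcripts$locus_id)
  if (any(no_gene)) {
    transcripts$locus_id[no_gene] <-
      sub("\\.[^.]+$", "", transcripts$transcript_id[no_gene])
  }
  if (!is.null(sample_id)) {
    old <- transcripts$transcript_id
    new <- paste0(old, "_", sample_id)
    transcripts$transcript_id <- new
    exons$transcript_id <- new[match(exons$transcript_id, old)]
    transcripts$sample_id <- sample_id
  } else {
    transcripts$sample_id <- NA_character_
  }
  n_ex <- table(exons$transcript_id)
  transcripts$n_exons <- as.integer(n_ex[transcripts$transcript_id])
  transcript_set(transcripts, exons)
}

#' Write a transcript set as a StringTie-dialect GTF
#'
#' @param ts A [transcript_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_gtf <- function(ts, path) {
  lines <- character(0)
  tx <- ts$transcripts
  for (i in seq_len(nrow(tx))) {
    t <- tx[i, ]
    e <- ts$exons[ts$exons$transcript_id == t$transcript_id, ]
    ref <- if (!is.na(t$ref_gene_id))
      sprintf(' ref_gene_id "%s";', t$ref_gene_id) else ""
    lines <- c(lines, sprintf(
      '%s\ttsacapture\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; cov "%s"; TPM "%s";%s',
      t$chrom, min(e$start), max(e$end), t$strand, t$locus_id,
      t$transcript_id, format_num(t$mean_cov), format_num(t$tpm), ref))
    for (j in seq_len(nrow(e))) {
      lines <- c(lines, sprintf(
        '%s\ttsacapture\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_number "%d"; cov "%s";',
        e$chrom[j], e$start[j], e$end[j], t$strand, t$locus_id,
        t$transcript_id, j, format_num(e$cov[j])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Per-transcript isoform metrics
#'
#' Computes, per locus, `isoform_count` (number of isoforms sharing the
#' locus id), `tpm_iso_perc` (a transcript's TPM as a percentage of the
#' summed TPM of all isoforms at its locus; 0 and flagged when the locus sum
#' is zero), and per-exon `exon_cov_ratio` (mean transcript coverage divided
#' by the exon's own coverage; `Inf` marks an uncovered exon).
#'
#' @param ts A [transcript_set()].
#' @return `ts` with columns `isoform_count`, `tpm_iso_perc`,
#'   `zero_tpm_locus` added to `$transcripts` and `exon_cov_ratio` added to
#'   `$exons`.
#' @export
compute_metrics <- function(ts) {
  tx <- dplyr::group_by(ts$transcripts, .data$locus_id)
  tx <- dplyr::mutate(tx,
    isoform_count = dplyr::n(),
    locus_tpm = sum(.data$tpm),
    zero_tpm_locus = .data$locus_tpm == 0,
    tpm_iso_perc = ifelse(.data$locus_tpm > 0,
                          100 * .data$tpm / .data$locus_tpm, 0))
  tx <- dplyr::select(dplyr::ungroup(tx), -"locus_tpm")
  mean_cov <- stats::setNames(tx$mean_cov, tx$transcript_id)
  ex <- dplyr::mutate(ts$exons,
    exon_cov_ratio = ifelse(.data$cov > 0,
                            unname(mean_cov[.data$transcript_id]) / .data$cov,
                            Inf))
  out <- ts
  out$transcripts <- tx
  out$exons <- ex
  out
}

#' Exons of one transcript, in transcription (5' to 3') order
#'
#' @param ts A [transcript_set()].
#' @param transcript_id Transcript to extract.
#' @return Tibble of exon rows; reversed genomic order on the minus strand.
#' @export
transcript_exons <- function(ts, transcript_id) {
  e <- ts$exons[ts$exons$transcript_id == transcript_id, ]
  if (nrow(e) == 0L) stop("unknown transcript: ", transcript_id)
  if (e$strand[1] == "-") e <- e[rev(seq_len(nrow(e))), ]
  e
}

#' Combine transcript sets
#'
#' @param sets List of [transcript_set()] objects.
#' @return A single `transcript_set`.
#' @export
concat_transcript_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  transcript_set(dplyr::bind_rows(lapply(sets, `[[`, "transcripts")),
                 dplyr::bind_rows(lapply(sets, `[[`, "exons")))
}
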