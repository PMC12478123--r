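#' Chop a translated region into sliding-window peptides
#'
#' Emits every window of exactly `peptide_len` consecutive amino acids
#' (step 1) of a region peptide, tracking for each window its underlying
#' nucleotide sequence (cDNA orientation) and genomic blocks, split at exon
#' junctions, recovered through the cDNA positional map.
#'
#' @param region Result of [translate_fragment()].
#' @param translated Result of [translate_full()] for the transcript.
#' @param cdna Result of [spliced_cdna()] for the transcript.
#' @param peptide_len Window length in amino acids.
#' @return Tibble: `peptide`, `protein_start`, `ref_nt`, `blocks`
#'   (list-column of `start`/`end` data frames), `n_blocks`. Zero rows when
#'   the region is shorter than `peptide_len`.
#' @export
chop_peptides <- function(region, translated, cdna, peptide_len = 9L) {
  empty <- tibble::tibble(peptide = character(0), protein_start = integer(0),
                          ref_nt = character(0), blocks = list(),
                          n_blocks = integer(0))
  if (is.null(region$aa_seq)) return(empty)
  len <- nchar(region$aa_seq)
  if (len < peptide_len) return(empty)
  n_win <- len - peptide_len + 1L
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    p0 <- region$protein_start + w - 1L
    cd_from <- translated$orf_start + 3L * (p0 - 1L)
    cd_to <- cd_from + 3L * peptide_len - 1L
    gpos <- cdna$map[cd_from:cd_to]
    rows[[w]] <- tibble::tibble(
      peptide = substr(region$aa_seq, w, w + peptide_len - 1L),
      protein_start = p0,
      ref_nt = substr(cdna$seq, cd_from, cd_to),
      blocks = list(blocks_from_positions(gpos)))
  }
  out <- dplyr::bind_rows(rows)
  out$n_blocks <- vapply(out$blocks, nrow, 0L)
  out
}

#' Read alignments for read-support checks
#'
#' Accepts either a plain read-placement table (tab-separated with header:
#' `read_id`, `chrom`, `blocks` as `start-end;start-end` 1-based inclusive,
#' `seq` as the reference-space aligned bases concatenated across blocks in
#' ascending genomic order, `mapq`, `flag`) or a SAM/BAM file (SAM is
#' converted on the fly; spliced alignments contribute one block per
#' aligned segment).
#'
#' @param path Alignment file (`.tsv`/`.txt`, `.sam`, `.bam`).
#' @return Tibble: `read_id`, `chrom`, `mapq`, `flag`, `blocks`
#'   (list-column), `seq`.
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt")) return(read_alignment_table(path))
  if (ext %in% c("sam", "bam")) return(read_alignment_sam(path))
  stop("unsupported alignment format: .", ext)
}

read_alignment_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character",
                                         "character", "character",
                                         "integer", "integer"))
  blocks <- lapply(strsplit(df$blocks, ";", fixed = TRUE), function(bb) {
    se <- do.call(rbind, strsplit(bb, "-", fixed = TRUE))
    data.frame(start = as.integer(se[, 1]), end = as.integer(se[, 2]))
  })
  tibble::tibble(read_id = df$read_id, chrom = df$chrom, mapq = df$mapq,
                 flag = df$flag, blocks = blocks, seq = toupper(df$seq))
}

read_alignment_sam <- function(path) {
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "mapq", "flag", "seq"))
  ga <- GenomicAlignments::readGAlignments(path, param = param, use.names = FALSE)
  mc <- S4Vectors::mcols(ga)
  # lay query bases into reference space (deletions become '-'), then take
  # one piece per aligned block
  ref_seq <- GenomicAlignments::sequenceLayer(mc$seq,
                                              GenomicAlignments::cigar(ga),
                                              from = "query", to = "reference")
  grl <- GenomicAlignments::grglist(ga, drop.D.ranges = FALSE)
  starts <- BiocGenerics::start(ga)
  blocks <- vector("list", length(ga))
  seqs <- character(length(ga))
  for (i in seq_along(ga)) {
    b <- grl[[i]]
    off_from <- BiocGenerics::start(b) - starts[i] + 1L
    off_to <- BiocGenerics::end(b) - starts[i] + 1L
    pieces <- substring(as.character(ref_seq[[i]]), off_from, off_to)
    blocks[[i]] <- data.frame(start = BiocGenerics::start(b),
                              end = BiocGenerics::end(b))
    seqs[i] <- toupper(paste(pieces, collapse = ""))
  }
  tibble::tibble(read_id = as.character(mc$qname),
                 chrom = as.character(GenomeInfoDb::seqnames(ga)),
                 mapq = as.integer(mc$mapq), flag = as.integer(mc$flag),
                 blocks = blocks, seq = seqs)
}

is_high_quality <- function(reads, min_mapq = 20L) {
  flag <- reads$flag
  !bitwAnd(flag, 4L) & !bitwAnd(flag, 256L) & !bitwAnd(flag, 1024L) &
    !is.na(reads$mapq) & reads$mapq >= min_mapq
}

read_covered_positions <- function(read_blocks) {
  as.integer(unlist(Map(seq, read_blocks$start, read_blocks$end)))
}

#' Count high-quality reads fully spanning a peptide region
#'
#' A read supports a peptide only when its aligned segments cover every
#' base of every peptide block (spliced peptides therefore require reads
#' spliced compatibly). High quality means primary, non-duplicate, mapped,
#' with mapping quality at least `min_mapq`. The reported count is capped
#' at `cap` reads; the uncapped count and the indices of the spanning reads
#' are returned for downstream SNP consensus.
#'
#' @param peptide_blocks Data frame of `start`/`end` peptide blocks.
#' @param chrom Chromosome of the peptide.
#' @param reads Alignment tibble from [read_alignments()].
#' @param min_mapq Mapping-quality cut for high-quality reads.
#' @param cap Cap for the reported read count.
#' @return List: `bam_reads` (capped), `n_spanning`, `spanning_idx`.
#' @export
read_support <- function(peptide_blocks, chrom, reads,
                         min_mapq = 20L, cap = 100L) {
  pep_pos <- unlist(Map(seq, peptide_blocks$start, peptide_blocks$end))
  cand <- which(reads$chrom == chrom & is_high_quality(reads, min_mapq))
  spanning <- cand[vapply(cand, function(i) {
    all(pep_pos %in% read_covered_positions(reads$blocks[[i]]))
  }, logical(1))]
  list(bam_reads = min(length(spanning), cap),
       n_spanning = length(spanning),
       spanning_idx = spanning)
}

# Per-position base counts (A/C/G/T) across the given reads at the given
# genomic positions. '-' and 'N' bases are ignored.
pileup_counts <- function(positions, reads, idx) {
  counts <- matrix(0L, nrow = length(positions), ncol = 4,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in idx) {
    rpos <- read_covered_positions(reads$blocks[[i]])
    hit <- match(positions, rpos)
    ok <- !is.na(hit)
    if (!any(ok)) next
    bases <- substring(reads$seq[i], hit[ok], hit[ok])
    keep <- bases %in% c("A", "C", "G", "T")
    if (!any(keep)) next
    rows <- which(ok)[keep]
    cols <- match(bases[keep], c("A", "C", "G", "T"))
    for (k in seq_along(rows)) {
      counts[rows[k], cols[k]] <- counts[rows[k], cols[k]] + 1L
    }
  }
  counts
}

#' Incorporate majority-supported SNPs into a peptide
#'
#' For every base of the peptide's genomic blocks, the base supported by a
#' strict majority of the fully-spanning high-quality reads replaces the
#' reference base; ties (no strict majority) keep the reference. The
#' corrected nucleotide sequence is re-translated in the peptide's frame so
#' the substitution is reflected at the amino-acid level.
#'
#' @param peptide_blocks Data frame of `start`/`end` blocks.
#' @param chrom,strand Location of the peptide.
#' @param ref_nt Reference nucleotide sequence (cDNA orientation).
#' @param reads Alignment tibble.
#' @param spanning_idx Indices of spanning reads (from [read_support()]).
#' @return List: `corrected_nt`, `corrected_peptide`, `snp_changed`.
#' @export
apply_majority_snps <- function(peptide_blocks, chrom, strand, ref_nt,
                                reads, spanning_idx) {
  positions <- unlist(Map(seq, peptide_blocks$start, peptide_blocks$end))
  genomic_ref <- if (strand == "-") revcomp(ref_nt) else toupper(ref_nt)
  if (nchar(genomic_ref) != length(positions)) {
    stop("ref_nt length does not match peptide blocks")
  }
  base_vec <- strsplit(genomic_ref, "")[[1]]
  if (length(spanning_idx) > 0L) {
    counts <- pileup_counts(positions, reads, spanning_idx)
    tot <- rowSums(counts)
    for (p in seq_along(positions)) {
      if (tot[p] == 0L) next
      best <- which.max(counts[p, ])
      if (counts[p, best] * 2L > tot[p]) {
        base_vec[p] <- c("A", "C", "G", "T")[best]
      }
    }
  }
  corrected_genomic <- paste(base_vec, collapse = "")
  corrected_nt <- if (strand == "-") revcomp(corrected_genomic)
                  else corrected_genomic
  list(corrected_nt = corrected_nt,
       corrected_peptide = sub("\\*.*$", "", translate_nt(corrected_nt, 0L)),
       snp_changed = !identical(corrected_nt, toupper(ref_nt)))
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Build the reference-proteome k-mer library
#'
#' All windows of `peptide_len` consecutive residues over every reference
#' protein; windows containing non-standard residues are excluded.
#'
#' @param proteome A [read_proteome()] tibble, a character vector of
#'   protein sequences, or a FASTA path.
#' @param peptide_len Window length.
#' @return Character vector (set) of k-mers, with attribute `peptide_len`.
#' @export
build_proteome_kmers <- function(proteome, peptide_len) {
  stopifnot(peptide_len >= 1L)
  if (is.character(proteome) && length(proteome) == 1L &&
      file.exists(proteome)) {
    proteome <- read_proteome(proteome)
  }
  seqs <- if (is.data.frame(proteome)) proteome$seq else as.character(proteome)
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < peptide_len) return(character(0))
    substring(s, seq_len(n - peptide_len + 1L),
              seq_len(n - peptide_len + 1L) + peptide_len - 1L)
  }), use.names = FALSE)
  kmers <- unique(kmers[!grepl("[^ACDEFGHIKLMNPQRSTVWY]", kmers)])
  attr(kmers, "peptide_len") <- as.integer(peptide_len)
  kmers
}

#' Remove novel candidates matching the reference proteome
#'
#' Only candidates of the novel categories (intronic/intergenic) are
#' filtered against the self-peptide library; differential candidates
#' derive from annotated regions and pass regardless. The SNP-corrected
#' sequence is the one looked up.
#'
#' @param candidates Candidate tibble (columns `peptide_corrected`,
#'   `category`, `length`).
#' @param proteome_kmers Output of [build_proteome_kmers()] for the same
#'   peptide length.
#' @return The kept subset.
#' @export
filter_self_peptides <- function(candidates, proteome_kmers) {
  if (nrow(candidates) == 0L) return(candidates)
  L <- attr(proteome_kmers, "peptide_len")
  if (!is.null(L) && any(candidates$length != L)) {
    stop("proteome k-mer set was built for length ", L,
         " but candidates have other lengths")
  }
  novel <- candidates$category %in% c("novel_intronic", "novel_intergenic")
  drop <- novel & candidates$peptide_corrected %in% proteome_kmers
  candidates[!drop, ]
}

#' Deterministic binding-rank stub
#'
#' A seeded hash of (peptide, allele) mapped to a percentile rank in
#' `[0, 5]`. Deterministic across sessions and platforms; intended for
#' tests and for fixture bundles, where it plays the role of the binding
#' ground truth. Real predictions should come from a precomputed rank table
#' (see [rank_provider_tsv()]).
#'
#' @param seed Integer folded into the hash.
#' @return Function `(peptides, alleles) ->` tibble
#'   (`peptide`, `allele`, `rank_pct`).
#' @export
rank_provider_stub <- function(seed = 0L) {
  force(seed)
  function(peptides, alleles) {
    grid <- expand.grid(peptide = unique(peptides), allele = alleles,
                        stringsAsFactors = FALSE)
    grid$rank_pct <- vapply(paste0(grid$peptide, "|", grid$allele),
                            string_hash_unit, 0, seed = seed) * 5
    tibble::as_tibble(grid)
  }
}

# stable polynomial string hash onto [0, 1)
string_hash_unit <- function(s, seed = 0L) {
  h <- (as.numeric(seed) %% 1048573) + 7
  for (code in utf8ToInt(s)) {
    h <- (h * 131 + code) %% 1048573
  }
  h / 1048573
}

#' Binding ranks from a precomputed table
#'
#' Reads a tab-separated file with columns `peptide`, `allele`, `rank`
#' (percentile rank), as produced by external peptide-MHC predictors run
#' offline.
#'
#' @param path Rank TSV path.
#' @return Function `(peptides, alleles) ->` tibble; missing combinations
#'   are simply absent and will be caught by [classify_binders()].
#' @export
rank_provider_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           col.names = c("peptide", "allele", "rank_pct"),
                           colClasses = c("character", "character", "numeric"))
  tab <- tibble::as_tibble(tab)
  function(peptides, alleles) {
    dplyr::filter(tab, .data$peptide %in% peptides,
                  .data$allele %in% alleles)
  }
}

#' Label HLA binders and drop non-binding candidates
#'
#' Peptides with a percentile rank below `wb_rank` are weak binders (WB),
#' below `sb_rank` strong binders (SB). Only binding peptides are kept: a
#' candidate with no SB or WB label for any allele is removed. The result
#' is in long format, one row per (candidate, binding allele).
#'
#' @param candidates Candidate tibble (must carry `peptide_corrected`).
#' @param ranks Tibble (`peptide`, `allele`, `rank_pct`) covering every
#'   candidate sequence for every allele.
#' @param alleles HLA alleles requested; a missing rank for any
#'   (candidate, allele) pair is an error.
#' @param sb_rank,wb_rank Strong / weak binder rank cuts.
#' @return Long-format candidate tibble with `allele`, `rank_pct`,
#'   `binder_label` columns.
#' @export
classify_binders <- function(candidates, ranks, alleles,
                             sb_rank = 0.5, wb_rank = 2.0) {
  if (nrow(candidates) == 0L) {
    out <- candidates
    out$allele <- character(0)
    out$rank_pct <- numeric(0)
    out$binder_label <- character(0)
    return(out)
  }
  need <- expand.grid(peptide = unique(candidates$peptide_corrected),
                      allele = alleles, stringsAsFactors = FALSE)
  have <- paste0(ranks$peptide, "|", ranks$allele)
  missing <- !(paste0(need$peptide, "|", need$allele) %in% have)
  if (any(missing)) {
    stop("missing binding rank for ",
         paste(utils::head(paste(need$peptide[missing], need$allele[missing]),
                           5), collapse = "; "))
  }
  ranks <- dplyr::filter(ranks, .data$allele %in% alleles)
  long <- dplyr::inner_join(candidates, ranks,
                            by = c(peptide_corrected = "peptide"),
                            relationship = "many-to-many")
  long$binder_label <- ifelse(long$rank_pct < sb_rank, "SB",
                              ifelse(long$rank_pct < wb_rank, "WB", "none"))
  dplyr::filter(long, .data$binder_label != "none")
}

#' Flag candidates overlapping known endogenous retrovirus regions
#'
#' The flag is purely an annotation: a candidate's category is never
#' changed by ERV overlap. One overlapping base suffices.
#'
#' @param candidates Candidate tibble with `chrom` and `blocks`.
#' @param erv `GRanges` of ERV regions (e.g. from [read_bed6()]).
#' @return `candidates` with a logical `erv` column.
#' @export
annotate_erv <- function(candidates, erv) {
  if (nrow(candidates) == 0L) {
    candidates$erv <- logical(0)
    return(candidates)
  }
  candidates$erv <- vapply(seq_len(nrow(candidates)), function(i) {
    b <- candidates$blocks[[i]]
    gr <- GenomicRanges::GRanges(candidates$chrom[i],
                                 IRanges::IRanges(b$start, b$end))
    length(GenomicRanges::findOverlaps(gr, unstranded(erv))) > 0L
  }, logical(1))
  candidates
}

#' Select top candidates under a prioritization preset
#'
#' `organoid`: novel candidates (intronic/intergenic) with
#' `TPM_iso_perc >= 50`, `TPM > 3`, `BAM_reads > 5`,
#' `Exon_cov_ratio >= 0.8`, then one candidate per transcript with the
#' strongest binding (lowest percentile rank). `glioblastoma`: strong
#' binders only (`rank < 0.5`) with `TPM_iso_perc == 100`,
#' `Exon_cov_ratio >= 0.8`, `TPM >= 1`, `BAM_reads >= 5`, then one per
#' transcript by lowest rank. `custom` applies no threshold filter, only
#' the per-transcript best-rank reduction.
#'
#' @param rows Long-format output rows (see [assemble_output()] /
#'   [classify_binders()]).
#' @param preset `"organoid"`, `"glioblastoma"` or `"custom"`.
#' @return Filtered rows ranked by ascending `rank_pct`.
#' @export
select_top_candidates <- function(rows,
                                  preset = c("organoid", "glioblastoma",
                                             "custom")) {
  preset <- match.arg(preset)
  keep <- switch(preset,
    organoid = rows$category %in% c("novel_intronic", "novel_intergenic") &
      rows$tpm_iso_perc >= 50 & rows$tpm > 3 & rows$bam_reads > 5 &
      rows$exon_cov_ratio >= 0.8,
    glioblastoma = rows$rank_pct < 0.5 & rows$tpm_iso_perc == 100 &
      rows$exon_cov_ratio >= 0.8 & rows$tpm >= 1 & rows$bam_reads >= 5,
    custom = rep(TRUE, nrow(rows)))
  out <- rows[keep, ]
  if (nrow(out) == 0L) return(out)
  out <- dplyr::slice_min(dplyr::group_by(out, .data$transcript_id),
                          .data$rank_pct, n = 1L, with_ties = FALSE)
  dplyr::arrange(dplyr::ungroup(out), .data$rank_pct)
}

#' Assemble the final output table
#'
#' Consolidates annotated candidates into the fixed-order long-format
#' result: one row per (peptide, binding allele), stably sorted by
#' (chromosome, first block start, peptide sequence, allele).
#'
#' @param long Long-format candidate tibble after all annotation stages.
#' @return Tibble with columns `sample_id`, `peptide`, `length`,
#'   `category`, `erv`, `chrom`, `blocks` (comma-joined `start-end` pairs,
#'   1-based inclusive), `strand`, `transcript_id`, `locus_id`, `TPM`,
#'   `TPM_iso_perc`, `Exon_cov_ratio`, `BAM_reads`, `REF_NT`,
#'   `corrected_NT`, `snp_changed`, `allele`, `rank_pct`, `binder_label`.
#' @export
assemble_output <- function(long) {
  if (nrow(long) == 0L) {
    return(tibble::tibble(
      sample_id = character(0), peptide = character(0), length = integer(0),
      category = character(0), erv = logical(0), chrom = character(0),
      blocks = character(0), strand = character(0),
      transcript_id = character(0), locus_id = character(0),
      TPM = numeric(0), TPM_iso_perc = numeric(0),
      Exon_cov_ratio = numeric(0), BAM_reads = integer(0),
      REF_NT = character(0), corrected_NT = character(0),
      snp_changed = logical(0), allele = character(0),
      rank_pct = numeric(0), binder_label = character(0)))
  }
  first_start <- vapply(long$blocks, function(b) b$start[1], 0)
  out <- tibble::tibble(
    sample_id = long$sample_id,
    peptide = long$peptide_corrected,
    length = long$length,
    category = long$category,
    erv = long$erv,
    chrom = long$chrom,
    blocks = vapply(long$blocks, function(b)
      paste(sprintf("%d-%d", b$start, b$end), collapse = ","), ""),
    strand = long$strand,
    transcript_id = long$transcript_id,
    locus_id = long$locus_id,
    TPM = long$tpm,
    TPM_iso_perc = long$tpm_iso_perc,
    Exon_cov_ratio = long$exon_cov_ratio,
    BAM_reads = long$bam_reads,
    REF_NT = long$ref_nt,
    corrected_NT = long$corrected_nt,
    snp_changed = long$snp_changed,
    allele = long$allele,
    rank_pct = long$rank_pct,
    binder_label = long$binder_label)
  out[order(out$chrom, first_start, out$peptide, out$allele), ]
}

#' Write the final table as TSV
#'
#' @param output Tibble from [assemble_output()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_output_tsv <- function(output, path) {
  utils::write.table(output, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
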