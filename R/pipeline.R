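#' Default pipeline configuration
#'
#' All tunable thresholds with their documented defaults: fragments must be
#' at least `min_len` = 24 nt (longer than 23); novel fragments need
#' transcript TPM >= 1 and coverage >= 4, differential ones >= 10 and
#' >= 16; capture-BED sparsity is strict (< 1 TPM, < 4 coverage); the
#' tumor-specificity gate on control expression is inclusive
#' (`control_max_tpm` <= 1); fragment/protein overlap needs >= 8 amino
#' acids; peptides are 9-mers by default (8-11 for class I, 15 for class
#' II); peptides need >= 2 high-quality fully-spanning reads, reported
#' counts capped at 100; strong/weak binder rank cuts are 0.5 and 2;
#' high-quality reads are primary, non-duplicate, mapping quality >= 20.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(min_len = 24, novel_tpm = 1, novel_cov = 4,
       diff_tpm = 10, diff_cov = 16,
       tpm_cut = 1, cov_cut = 4, control_max_tpm = 1,
       min_overlap_aa = 8, peptide_len = 9,
       min_bam_reads = 2, max_bam_reads = 100,
       sb_rank = 0.5, wb_rank = 2, min_mapq = 20,
       preset = "custom", seed = 1)
}

#' Load a pipeline configuration
#'
#' Precedence: explicit overrides > YAML file values > documented defaults.
#' Unknown keys and non-positive thresholds are errors. The effective
#' configuration is echoed to the log.
#'
#' @param path Optional YAML file.
#' @param overrides Named list of values taking precedence over the file.
#' @param quiet Suppress the configuration echo.
#' @return Named list (complete configuration).
#' @export
load_config <- function(path = NULL, overrides = list(), quiet = FALSE) {
  cfg <- default_config()
  apply_values <- function(cfg, values, origin) {
    unknown <- setdiff(names(values), names(cfg))
    if (length(unknown) > 0L) {
      stop("unknown configuration key(s) in ", origin, ": ",
           paste(unknown, collapse = ", "),
           "; valid keys: ", paste(names(cfg), collapse = ", "))
    }
    cfg[names(values)] <- values
    cfg
  }
  if (!is.null(path)) cfg <- apply_values(cfg, yaml::read_yaml(path), path)
  cfg <- apply_values(cfg, overrides, "overrides")
  num_keys <- setdiff(names(cfg), c("preset", "seed"))
  bad <- num_keys[!vapply(cfg[num_keys],
                          function(v) is.numeric(v) && v > 0, logical(1))]
  if (length(bad) > 0L) {
    stop("configuration thresholds must be positive: ",
         paste(bad, collapse = ", "))
  }
  if (!cfg$peptide_len %in% 8:15) {
    stop("peptide_len must be in 8..15 (class I: 8-11, class II: 15)")
  }
  if (!quiet) {
    message("effective configuration: ",
            paste(names(cfg), unlist(cfg), sep = "=", collapse = " "))
  }
  cfg
}

#' Gene spans from a reference annotation
#'
#' @param annotation A [transcript_set()] read with dialect `"gencode"`, or
#'   a GTF path.
#' @return `GRanges` of per-gene spans (min exon start to max exon end).
#' @export
gene_spans <- function(annotation) {
  if (is.character(annotation)) {
    annotation <- read_transcript_gtf(annotation, dialect = "gencode")
  }
  ex <- dplyr::left_join(
    annotation$exons,
    dplyr::select(annotation$transcripts, "transcript_id", "locus_id"),
    by = "transcript_id")
  spans <- dplyr::summarise(dplyr::group_by(ex, .data$locus_id, .data$chrom),
                            start = min(.data$start), end = max(.data$end),
                            .groups = "drop")
  gr <- GenomicRanges::GRanges(spans$chrom,
                               IRanges::IRanges(spans$start, spans$end))
  S4Vectors::mcols(gr)$gene_id <- spans$locus_id
  GenomicRanges::sort(gr)
}

#' Build the control database and capture BED from files
#'
#' @param control_gtfs Character vector of control GTF paths (StringTie
#'   dialect).
#' @param annotation_gtf Reference annotation GTF path.
#' @param sizes Named chromosome sizes (e.g. [genome_sizes()]).
#' @param out_bed Optional path; when given the capture BED is written.
#' @param tpm_cut,cov_cut Sparsity thresholds for differential regions.
#' @return Capture `GRanges` (invisibly when written to file).
#' @export
run_build_ref <- function(control_gtfs, annotation_gtf, sizes,
                          out_bed = NULL, tpm_cut = 1.0, cov_cut = 4.0) {
  db <- build_control_db(control_gtfs)
  capture <- derive_capture_bed(db, gene_spans(annotation_gtf), sizes,
                                tpm_cut = tpm_cut, cov_cut = cov_cut)
  message(sprintf("capture BED: %d regions (%d novel, %d differential)",
                  length(capture),
                  sum(S4Vectors::mcols(capture)$category != "differential"),
                  sum(S4Vectors::mcols(capture)$category == "differential")))
  if (!is.null(out_bed)) {
    write_capture_bed(capture, out_bed)
    return(invisible(capture))
  }
  capture
}

#' Core prediction over in-memory objects
#'
#' Executes capture -> fragment filter -> translation -> peptide windows ->
#' read support and SNP consensus -> self-peptide filter -> binder
#' classification -> ERV annotation -> output assembly, logging per-stage
#' counts.
#'
#' @param tumor A [transcript_set()] of the tumor sample.
#' @param capture Capture `GRanges`.
#' @param genome `DNAStringSet`.
#' @param proteome [read_proteome()] tibble or `NULL` (disables
#'   reference-guided frame selection and self-peptide filtering).
#' @param reads Alignment tibble from [read_alignments()] or `NULL`
#'   (disables read-support filtering and SNP consensus).
#' @param erv ERV `GRanges` or `NULL`.
#' @param alleles Character vector of HLA alleles.
#' @param rank_fn Rank provider, e.g. [rank_provider_stub()].
#' @param config Configuration list from [load_config()].
#' @param quiet Suppress per-stage log messages.
#' @return List: `table` ([assemble_output()] tibble), `candidates`
#'   (pre-assembly long tibble), `stage_counts` (named integer vector).
#' @export
predict_core <- function(tumor, capture, genome, proteome = NULL,
                         reads = NULL, erv = NULL,
                         alleles = c("HLA-A*02:01"),
                         rank_fn = rank_provider_stub(),
                         config = default_config(), quiet = FALSE) {
  log_n <- integer(0)
  say <- function(stage, n) {
    log_n[[stage]] <<- n
    if (!quiet) message(sprintf("[%s] %d", stage, n))
  }
  ts <- compute_metrics(tumor)
  say("transcripts", nrow(ts$transcripts))

  frags <- capture_fragments(ts, capture)
  say("fragments_captured", nrow(frags))
  frags <- filter_fragments(frags, ts, min_len = config$min_len,
                            novel_tpm = config$novel_tpm,
                            novel_cov = config$novel_cov,
                            diff_tpm = config$diff_tpm,
                            diff_cov = config$diff_cov)
  say("fragments_kept", nrow(frags))

  cands <- translate_and_chop(ts, frags, genome, proteome, config)
  say("peptide_windows", nrow(cands))

  if (!is.null(reads) && nrow(cands) > 0L) {
    supp <- lapply(seq_len(nrow(cands)), function(i)
      read_support(cands$blocks[[i]], cands$chrom[i], reads,
                   min_mapq = config$min_mapq, cap = config$max_bam_reads))
    cands$bam_reads <- vapply(supp, function(s) as.integer(s$bam_reads), 0L)
    keep <- vapply(supp, function(s) s$n_spanning, 0L) >= config$min_bam_reads
    cands <- cands[keep, ]
    supp <- supp[keep]
    say("read_supported", nrow(cands))
    if (nrow(cands) > 0L) {
      snp <- lapply(seq_len(nrow(cands)), function(i)
        apply_majority_snps(cands$blocks[[i]], cands$chrom[i],
                            cands$strand[i], cands$ref_nt[i],
                            reads, supp[[i]]$spanning_idx))
      cands$corrected_nt <- vapply(snp, `[[`, "", "corrected_nt")
      cands$peptide_corrected <- vapply(snp, `[[`, "", "corrected_peptide")
      cands$snp_changed <- vapply(snp, `[[`, TRUE, "snp_changed")
      # a consensus edit may introduce a stop codon; such windows are no
      # longer full-length peptides
      cands <- cands[nchar(cands$peptide_corrected) == cands$length, ]
    }
  } else {
    cands$bam_reads <- rep(NA_integer_, nrow(cands))
    cands$corrected_nt <- cands$ref_nt
    cands$peptide_corrected <- cands$peptide
    cands$snp_changed <- rep(FALSE, nrow(cands))
  }

  if (!is.null(proteome) && nrow(cands) > 0L) {
    kmers <- build_proteome_kmers(proteome, config$peptide_len)
    cands <- filter_self_peptides(cands, kmers)
  }
  say("non_self", nrow(cands))

  if (nrow(cands) > 0L) {
    ranks <- rank_fn(cands$peptide_corrected, alleles)
    cands <- classify_binders(cands, ranks, alleles,
                              sb_rank = config$sb_rank,
                              wb_rank = config$wb_rank)
  } else {
    cands <- classify_binders(cands, tibble::tibble(peptide = character(0),
                                                    allele = character(0),
                                                    rank_pct = numeric(0)),
                              alleles)
  }
  say("binders", length(unique(cands$peptide_corrected)))

  if (!is.null(erv)) {
    cands <- annotate_erv(cands, erv)
  } else {
    cands$erv <- rep(FALSE, nrow(cands))
  }
  tab <- assemble_output(cands)
  say("output_rows", nrow(tab))
  list(table = tab, candidates = cands, stage_counts = log_n)
}

# translation + sliding windows for every kept fragment
translate_and_chop <- function(ts, frags, genome, proteome, config) {
  empty <- tibble::tibble(
    peptide = character(0), length = integer(0), protein_start = integer(0),
    ref_nt = character(0), blocks = list(), n_blocks = integer(0),
    category = character(0), transcript_id = character(0),
    locus_id = character(0), sample_id = character(0), chrom = character(0),
    strand = character(0), tpm = numeric(0), tpm_iso_perc = numeric(0),
    exon_cov_ratio = numeric(0), translation_method = character(0),
    fragment_id = character(0))
  if (nrow(frags) == 0L) return(empty)
  tx <- ts$transcripts
  out <- list()
  for (tid in unique(frags$transcript_id)) {
    cdna <- spliced_cdna(ts, tid, genome)
    trow <- tx[tx$transcript_id == tid, ]
    ref_seq <- NULL
    ref_id <- NA_character_
    if (!is.null(proteome) && !is.na(trow$ref_gene_id)) {
      hit <- which(proteome$gene_id == trow$ref_gene_id)
      if (length(hit) > 0L) {
        ref_seq <- proteome$seq[hit[1]]
        ref_id <- proteome$protein_id[hit[1]]
      }
    }
    translated <- translate_full(cdna$seq, ref_seq, ref_id)
    tfrags <- frags[frags$transcript_id == tid, ]
    for (i in seq_len(nrow(tfrags))) {
      region <- translate_fragment(tfrags[i, ], translated, cdna,
                                   min_overlap_aa = config$min_overlap_aa,
                                   peptide_len = config$peptide_len)
      if (is.null(region$aa_seq)) next
      peps <- chop_peptides(region, translated, cdna,
                            peptide_len = config$peptide_len)
      if (nrow(peps) == 0L) next
      peps$length <- nchar(peps$peptide)
      peps$category <- tfrags$category[i]
      peps$transcript_id <- tid
      peps$locus_id <- trow$locus_id
      peps$sample_id <- trow$sample_id
      peps$chrom <- cdna$chrom
      peps$strand <- cdna$strand
      peps$tpm <- trow$tpm
      peps$tpm_iso_perc <- trow$tpm_iso_perc
      peps$exon_cov_ratio <- vapply(peps$blocks, function(b)
        peptide_exon_cov_ratio(ts, tid, b), 0)
      peps$translation_method <- translated$method
      peps$fragment_id <- tfrags$fragment_id[i]
      out[[length(out) + 1L]] <- peps
    }
  }
  if (length(out) == 0L) return(empty)
  dplyr::bind_rows(out)
}

# minimum exon_cov_ratio over the exons a peptide's blocks overlap; the
# conservative choice for junction-spanning peptides
peptide_exon_cov_ratio <- function(ts, transcript_id, blocks) {
  e <- ts$exons[ts$exons$transcript_id == transcript_id, ]
  hit <- vapply(seq_len(nrow(e)), function(i)
    any(blocks$start <= e$end[i] & blocks$end >= e$start[i]), logical(1))
  if (!any(hit)) return(NA_real_)
  min(e$exon_cov_ratio[hit])
}

#' Run the prediction pipeline from files
#'
#' Thin file-level wrapper around [predict_core()]: reads the tumor GTF,
#' capture BED, genome, proteome, ERV BED and alignments, runs the
#' pipeline, and writes the final TSV. An empty final set is a success
#' and produces a header-only file.
#'
#' @param gtf Tumor StringTie-dialect GTF.
#' @param genome Genome FASTA.
#' @param capture_bed Capture BED path.
#' @param proteome Reference proteome FASTA (optional).
#' @param erv_bed ERV BED path (optional).
#' @param alignments Alignment file (optional; TSV table, SAM or BAM).
#' @param alleles Character vector of HLA alleles, or a file with one
#'   allele per line.
#' @param rank_source `"stub"` or the path of a precomputed rank TSV.
#' @param out Output TSV path (optional).
#' @param sample_id Sample name recorded in the output.
#' @param config Configuration list.
#' @param quiet Suppress log messages.
#' @return The [predict_core()] result list, invisibly when `out` is given.
#' @export
run_predict <- function(gtf, genome, capture_bed, proteome = NULL,
                        erv_bed = NULL, alignments = NULL,
                        alleles = c("HLA-A*02:01"), rank_source = "stub",
                        out = NULL, sample_id = "sample",
                        config = default_config(), quiet = FALSE) {
  for (arg in c("gtf", "genome", "capture_bed")) {
    val <- get(arg)
    if (is.null(val) || !file.exists(val)) {
      stop("required input --", gsub("_", "-", arg),
           " missing or not found: ", if (is.null(val)) "<unset>" else val)
    }
  }
  tumor <- read_transcript_gtf(gtf, dialect = "stringtie",
                               sample_id = sample_id)
  capture <- read_capture_bed(capture_bed)
  gen <- read_genome(genome)
  prot <- if (!is.null(proteome)) read_proteome(proteome) else NULL
  erv <- if (!is.null(erv_bed)) read_bed6(erv_bed) else NULL
  reads <- if (!is.null(alignments)) read_alignments(alignments) else NULL
  if (length(alleles) == 1L && file.exists(alleles)) {
    alleles <- readLines(alleles)
    alleles <- alleles[nzchar(alleles)]
  }
  rank_fn <- if (identical(rank_source, "stub")) rank_provider_stub()
             else rank_provider_tsv(rank_source)
  res <- predict_core(tumor, capture, gen, prot, reads, erv,
                      alleles = alleles, rank_fn = rank_fn,
                      config = config, quiet = quiet)
  if (!is.null(out)) {
    write_output_tsv(res$table, out)
    return(invisible(res))
  }
  res
}

#' Quantify cassette-exon inclusion from assembled transcripts
#'
#' For every event, classifies the isoforms of each condition's replicates,
#' averages the inclusion fraction across replicates, and reports the
#' between-condition delta.
#'
#' @param events Event table (path or tibble from
#'   [read_cassette_events()]).
#' @param sets_a,sets_b Lists of [transcript_set()] replicates (or GTF
#'   paths) for the two conditions; `sets_b` may be `NULL` for a
#'   single-condition report.
#' @param out Optional output TSV path.
#' @return Tibble: per-event inclusion/exclusion/other percentages per
#'   condition and `dtpm_iso_perc` (condition A minus condition B).
#' @export
run_exon_inclusion <- function(events, sets_a, sets_b = NULL, out = NULL) {
  if (is.character(events)) events <- read_cassette_events(events)
  as_sets <- function(x) {
    if (is.character(x)) lapply(x, read_transcript_gtf, dialect = "stringtie")
    else x
  }
  sets_a <- as_sets(sets_a)
  sets_b <- if (!is.null(sets_b)) as_sets(sets_b)
  rows <- lapply(seq_len(nrow(events)), function(k) {
    ev <- events[k, ]
    a <- event_inclusion_summary(ev, sets_a)
    row <- tibble::tibble(event_id = ev$event_id, chrom = ev$chrom,
                          inclusion_pct_a = a$inclusion_pct,
                          exclusion_pct_a = a$exclusion_pct,
                          other_pct_a = a$other_pct)
    if (!is.null(sets_b)) {
      b <- event_inclusion_summary(ev, sets_b)
      row$inclusion_pct_b <- b$inclusion_pct
      row$exclusion_pct_b <- b$exclusion_pct
      row$other_pct_b <- b$other_pct
      row$dtpm_iso_perc <- delta_inclusion(a$inclusion_pct, b$inclusion_pct)
    }
    row
  })
  res <- dplyr::bind_rows(rows)
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    return(invisible(res))
  }
  res
}
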