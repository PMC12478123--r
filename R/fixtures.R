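#' Specification for a synthetic fixture bundle
#'
#' Describes a deterministic toy study: a single-chromosome genome with a
#' reference gene, planted tumor-specific features (one per class), healthy
#' controls that exclude the planted novel regions and express the
#' differential region below the sparsity thresholds, and full-length
#' spliced reads over every tumor transcript. The defaults are the study
#' conditions used throughout the test suite.
#'
#' Planted features: `intronic` (an intron-retention transcript of the
#' reference gene), `intergenic` (a two-exon transcript outside any gene,
#' Kozak-initiated), `differential` (a minus-strand transcript over a
#' sparsely-expressed control region, methionine-initiated), `erv` (an
#' intergenic transcript overlapping an ERV region), `snp` (an intergenic
#' transcript whose reads carry an alternative base at a fixed fraction),
#' `cassette` (a three-exon reference gene with inclusion/exclusion tumor
#' isoforms at a known inclusion fraction).
#'
#' @param seed Integer seed; the whole bundle is a pure function of the
#'   spec.
#' @param chrom_len Chromosome length (default 10 kb).
#' @param peptide_len Peptide window length.
#' @param n_controls Number of control samples (2-6).
#' @param n_decoys Number of decoy tumor transcripts, each covered by
#'   three of the pool controls (used for saturation studies; 0 disables).
#' @param read_depth Full-length reads generated per tumor transcript.
#' @param snp_alt_fraction Fraction of reads carrying the planted SNP.
#' @param cassette_psi True inclusion fraction of the cassette event.
#' @param features Character vector choosing which features to plant.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, chrom_len = 10000L, peptide_len = 9L,
                         n_controls = 2L, n_decoys = 0L, read_depth = 20L,
                         snp_alt_fraction = 0.7, cassette_psi = 0.6,
                         features = c("intronic", "intergenic",
                                      "differential", "erv", "snp",
                                      "cassette")) {
  stopifnot(chrom_len >= 10000L, n_controls >= 1L, n_controls <= 6L,
            n_decoys >= 0L, n_decoys <= 6L,
            snp_alt_fraction > 0, snp_alt_fraction < 1)
  structure(list(seed = as.integer(seed), chrom_len = as.integer(chrom_len),
                 peptide_len = as.integer(peptide_len),
                 n_controls = as.integer(n_controls),
                 n_decoys = as.integer(n_decoys),
                 read_depth = as.integer(read_depth),
                 snp_alt_fraction = snp_alt_fraction,
                 cassette_psi = cassette_psi, features = features),
            class = "fixture_spec")
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# sample a synonymous codon for each residue (standard code, no stops)
backtranslate <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  paste(vapply(strsplit(aa, "")[[1]], function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, ""), collapse = "")
}

# random DNA guaranteed not to contain an ATG
dna_no_atg <- function(n) {
  repeat {
    s <- random_dna(n)
    if (!grepl("ATG", s, fixed = TRUE)) return(s)
  }
}

# one designed single-ORF cDNA: UTR + ATG-initiated CDS + stop.
# init = "kozak" forces Kozak context at the start codon; "met" forbids a
# Kozak context anywhere so the closest-Met rule applies.
design_orf_cdna <- function(utr_len, n_aa, init = c("kozak", "met")) {
  init <- match.arg(init)
  repeat {
    aa_body <- random_aa(n_aa - 2L)
    if (init == "kozak") {
      aa2 <- "A"                                   # GCx: +4 position is G
      utr <- paste0(dna_no_atg(utr_len - 3L), "ACC")
      cds <- paste0("ATG", "GCC", backtranslate(aa_body))
    } else {
      aa2 <- "L"
      utr <- paste0(dna_no_atg(utr_len - 3L), "TCC")
      cds <- paste0("ATG", "CTG", backtranslate(aa_body))
    }
    protein <- paste0("M", aa2, aa_body)
    cdna <- paste0(utr, cds, "TAA")
    koz <- kozak_atg_positions(cdna)
    first_atg <- regexpr("ATG", cdna, fixed = TRUE)[1]
    ok <- if (init == "kozak") {
      length(koz) > 0L && koz[1] == utr_len + 1L
    } else {
      length(koz) == 0L && first_atg == utr_len + 1L
    }
    if (ok) return(list(cdna = cdna, protein = protein, utr_len = utr_len,
                        orf_start = utr_len + 1L))
  }
}

sliding_windows <- function(protein, from, to, L) {
  if (to - from + 1L < L) return(character(0))
  starts <- from:(to - L + 1L)
  substring(protein, starts, starts + L - 1L)
}

#' Generate a synthetic fixture bundle
#'
#' Writes a complete input set for the pipeline -- genome FASTA, reference
#' annotation GTF and proteome FASTA, control GTFs, tumor GTF with TPM and
#' coverage attributes, read alignments (both a placement table and a SAM
#' file), ERV BED, cassette-event table, HLA allele list -- together with a
#' truth manifest listing every peptide the pipeline is expected to report
#' (after self-peptide and binder filtering under the deterministic rank
#' stub), with its category and SNP-corrected sequence. The bundle is a
#' pure function of the spec: repeated calls produce identical bytes.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List: `paths` (named file paths), `truth` (tibble: `peptide`,
#'   `category`, `transcript_id`, `snp_changed`, `erv`, `min_rank`),
#'   `alleles`, `spec`, and the in-memory `tumor`, `controls`, `genome`
#'   objects.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- spec$peptide_len
  feats <- spec$features
  withr::with_seed(spec$seed, {
    genome_chars <- strsplit(random_dna(spec$chrom_len), "")[[1]]
    plant <- function(at, seq) {
      stopifnot(at + nchar(seq) - 1L <= spec$chrom_len)
      genome_chars[at:(at + nchar(seq) - 1L)] <<- strsplit(seq, "")[[1]]
    }

    ref_tx <- list(); ref_ex <- list()       # reference annotation
    proteins <- list()                       # proteome entries
    tum_tx <- list(); tum_ex <- list()       # tumor assembly
    ctrl_core_ex <- list()                   # exons present in all controls
    truth <- list()
    erv_regions <- NULL
    events <- NULL
    snp_site <- NULL

    add_tumor <- function(tid, locus, chrom, strand, tpm, cov, exons,
                          ref_gene = NA_character_) {
      tum_tx[[length(tum_tx) + 1L]] <<- tibble::tibble(
        transcript_id = tid, locus_id = locus, sample_id = "tumor",
        chrom = chrom, strand = strand, tpm = tpm, mean_cov = cov,
        n_exons = nrow(exons), ref_gene_id = ref_gene)
      tum_ex[[length(tum_ex) + 1L]] <<- tibble::tibble(
        transcript_id = tid, chrom = chrom, start = exons$start,
        end = exons$end, strand = strand, cov = cov)
    }
    add_truth <- function(peptides, category, tid, snp_changed = FALSE,
                          erv = FALSE) {
      if (length(peptides) == 0L) return(invisible(NULL))
      truth[[length(truth) + 1L]] <<- tibble::tibble(
        peptide = peptides, category = category, transcript_id = tid,
        snp_changed = snp_changed, erv = erv)
    }

    ## -- intron retention in reference gene G1 ------------------------
    if ("intronic" %in% feats) {
      ref_aa <- paste0("M", random_aa(39L))            # 40-aa protein
      cds <- backtranslate(ref_aa)
      repeat {                                         # 12-aa intron,
        intron_aa <- random_aa(12L)                    # no spurious match
        if (substr(intron_aa, 1L, 1L) != substr(ref_aa, 21L, 21L) &&
            substr(intron_aa, 12L, 12L) != substr(ref_aa, 20L, 20L)) break
      }
      intron_nt <- backtranslate(intron_aa)
      exon1 <- substr(cds, 1L, 60L)
      exon2 <- paste0(substr(cds, 61L, 120L), "TAA")
      plant(1001L, paste0(exon1, intron_nt, exon2))
      ref_tx[[length(ref_tx) + 1L]] <- list(
        gene = "G1", tx = "REF_T1", chrom = "chr1", strand = "+",
        exons = data.frame(start = c(1001L, 1097L), end = c(1060L, 1159L)))
      proteins[[length(proteins) + 1L]] <- list(id = "P1", gene = "G1",
                                                tx = "REF_T1", seq = ref_aa)
      ctrl_core_ex[[length(ctrl_core_ex) + 1L]] <- list(
        locus = "CTRL_G1", chrom = "chr1", strand = "+", tpm_base = 5,
        cov = 10, exons = data.frame(start = c(1001L, 1097L),
                                     end = c(1060L, 1159L)))
      add_tumor("STRG.1.1", "STRG.1", "chr1", "+", 5, 10,
                data.frame(start = 1001L, end = 1159L), ref_gene = "G1")
      tumor_protein <- paste0(substr(ref_aa, 1L, 20L), intron_aa,
                              substr(ref_aa, 21L, 40L))
      win <- sliding_windows(tumor_protein, max(1L, 21L - (L - 1L)),
                             min(nchar(tumor_protein), 32L + (L - 1L)), L)
      add_truth(win, "novel_intronic", "STRG.1.1_tumor")
    }

    ## -- intergenic two-exon transcript -------------------------------
    if ("intergenic" %in% feats) {
      d <- design_orf_cdna(20L, 30L, "kozak")
      # split the 113-nt cDNA after base 60; 200-nt genomic intron
      plant(2501L, substr(d$cdna, 1L, 60L))
      plant(2761L, substr(d$cdna, 61L, nchar(d$cdna)))
      add_tumor("STRG.2.1", "STRG.2", "chr1", "+", 8, 12,
                data.frame(start = c(2501L, 2761L),
                           end = c(2560L, 2761L + (nchar(d$cdna) - 61L))))
      add_truth(sliding_windows(d$protein, 1L, nchar(d$protein), L),
                "novel_intergenic", "STRG.2.1_tumor")
    }

    ## -- differential, minus strand, Met-initiated --------------------
    if ("differential" %in% feats) {
      d <- design_orf_cdna(15L, 25L, "met")
      gseq <- revcomp(d$cdna)
      plant(4001L, gseq)
      span <- data.frame(start = 4001L, end = 4000L + nchar(gseq))
      ctrl_core_ex[[length(ctrl_core_ex) + 1L]] <- list(
        locus = "CTRL_DIFF", chrom = "chr1", strand = "-", tpm_base = 0.3,
        cov = 2, exons = span)
      add_tumor("STRG.3.1", "STRG.3", "chr1", "-", 50, 20, span)
      add_truth(sliding_windows(d$protein, 1L, nchar(d$protein), L),
                "differential", "STRG.3.1_tumor")
    }

    ## -- ERV-overlapping intergenic transcript ------------------------
    if ("erv" %in% feats) {
      d <- design_orf_cdna(12L, 20L, "kozak")
      plant(5501L, d$cdna)
      span <- data.frame(start = 5501L, end = 5500L + nchar(d$cdna))
      add_tumor("STRG.5.1", "STRG.5", "chr1", "+", 6, 10, span)
      erv_regions <- data.frame(start = 5520L, end = 5620L)
      add_truth(sliding_windows(d$protein, 1L, nchar(d$protein), L),
                "novel_intergenic", "STRG.5.1_tumor", erv = TRUE)
    }

    ## -- heterozygous-looking SNP transcript --------------------------
    alt_protein <- NULL
    if ("snp" %in% feats) {
      d <- design_orf_cdna(15L, 22L, "kozak")
      plant(7001L, d$cdna)
      span <- data.frame(start = 7001L, end = 7000L + nchar(d$cdna))
      add_tumor("STRG.6.1", "STRG.6", "chr1", "+", 4, 9, span)
      # SNP in the middle base of codon 10 of the ORF
      snp_cdna_pos <- d$orf_start + 9L * 3L + 1L
      ref_codon <- substr(d$cdna, snp_cdna_pos - 1L, snp_cdna_pos + 1L)
      alt_base <- NULL
      for (b in c("A", "C", "G", "T")) {
        codon <- ref_codon
        substr(codon, 2L, 2L) <- b
        aa <- Biostrings::GENETIC_CODE[[codon]]
        if (b != substr(ref_codon, 2L, 2L) && aa != "*" &&
            aa != Biostrings::GENETIC_CODE[[ref_codon]]) {
          alt_base <- b
          alt_aa <- aa
          break
        }
      }
      snp_site <- list(genomic_pos = 7000L + snp_cdna_pos,
                       alt_base = alt_base)
      alt_protein <- d$protein
      substr(alt_protein, 10L, 10L) <- alt_aa
      n_aa <- nchar(d$protein)
      win_starts <- 1L:(n_aa - L + 1L)
      covers_snp <- win_starts <= 10L & (win_starts + L - 1L) >= 10L
      add_truth(substring(d$protein, win_starts[!covers_snp],
                          win_starts[!covers_snp] + L - 1L),
                "novel_intergenic", "STRG.6.1_tumor", snp_changed = FALSE)
      add_truth(substring(alt_protein, win_starts[covers_snp],
                          win_starts[covers_snp] + L - 1L),
                "novel_intergenic", "STRG.6.1_tumor", snp_changed = TRUE)
    }

    ## -- cassette-exon event in reference gene G2 ----------------------
    if ("cassette" %in% feats) {
      ex3 <- data.frame(start = c(8001L, 8201L, 8401L),
                        end = c(8060L, 8260L, 8460L))
      ref_tx[[length(ref_tx) + 1L]] <- list(
        gene = "G2", tx = "REF_T2", chrom = "chr1", strand = "+",
        exons = ex3)
      ctrl_core_ex[[length(ctrl_core_ex) + 1L]] <- list(
        locus = "CTRL_G2", chrom = "chr1", strand = "+", tpm_base = 5,
        cov = 10, exons = ex3)
      psi <- spec$cassette_psi
      add_tumor("STRG.4.1", "STRG.4", "chr1", "+", 20 * psi, 10, ex3)
      add_tumor("STRG.4.2", "STRG.4", "chr1", "+", 20 * (1 - psi), 10,
                ex3[c(1L, 3L), ])
      events <- tibble::tibble(event_id = "cassette_01", chrom = "chr1",
                               pre_start = 8001L, pre_end = 8060L,
                               target_start = 8201L, target_end = 8260L,
                               post_start = 8401L, post_end = 8460L,
                               strand = "+")
    }

    ## -- decoy transcripts for saturation studies ----------------------
    decoy_cover <- vector("list", spec$n_controls)
    for (d_i in seq_len(spec$n_decoys)) {
      d <- design_orf_cdna(12L, 20L, "kozak")
      at <- 8600L + 200L * (d_i - 1L)
      plant(at, d$cdna)
      span <- data.frame(start = at, end = at + nchar(d$cdna) - 1L)
      add_tumor(sprintf("STRG.9%d.1", d_i), sprintf("STRG.9%d", d_i),
                "chr1", "+", 5, 10, span)
      covering <- unique((d_i - 1L + 0:2) %% spec$n_controls + 1L)
      for (ci in covering) {
        decoy_cover[[ci]] <- c(decoy_cover[[ci]], list(list(
          locus = sprintf("CTRL_DEC%d", d_i), chrom = "chr1", strand = "+",
          tpm_base = 5, cov = 10, exons = span)))
      }
    }

    ## decoy proteome entries so the self-filter has a real library
    for (k in 1:3) {
      proteins[[length(proteins) + 1L]] <- list(
        id = sprintf("PD%d", k), gene = sprintf("GD%d", k),
        tx = sprintf("REF_D%d", k), seq = random_aa(50L))
    }

    genome_seq <- paste(genome_chars, collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(genome_seq, "chr1"))
    tumor <- transcript_set(dplyr::bind_rows(tum_tx),
                            dplyr::bind_rows(tum_ex))

    ## -- control transcript sets ---------------------------------------
    controls <- lapply(seq_len(spec$n_controls), function(ci) {
      entries <- c(ctrl_core_ex, decoy_cover[[ci]])
      tx <- list(); exl <- list()
      for (j in seq_along(entries)) {
        en <- entries[[j]]
        tid <- sprintf("%s.c%d", en$locus, ci)
        tx[[j]] <- tibble::tibble(
          transcript_id = tid, locus_id = en$locus,
          sample_id = sprintf("ctrl%02d", ci), chrom = en$chrom,
          strand = en$strand, tpm = en$tpm_base + 0.05 * ci,
          mean_cov = en$cov, n_exons = nrow(en$exons),
          ref_gene_id = NA_character_)
        exl[[j]] <- tibble::tibble(
          transcript_id = tid, chrom = en$chrom, start = en$exons$start,
          end = en$exons$end, strand = en$strand, cov = en$cov)
      }
      transcript_set(dplyr::bind_rows(tx), dplyr::bind_rows(exl))
    })

    ## -- reads: full-length spliced reads per tumor transcript ---------
    reads <- list()
    for (i in seq_len(nrow(tumor$transcripts))) {
      tid <- tumor$transcripts$transcript_id[i]
      ex <- tumor$exons[tumor$exons$transcript_id == tid, ]
      ref_pieces <- substring(genome_seq, ex$start, ex$end)
      n_alt <- 0L
      if (!is.null(snp_site) && any(ex$start <= snp_site$genomic_pos &
                                    ex$end >= snp_site$genomic_pos)) {
        n_alt <- round(spec$read_depth * spec$snp_alt_fraction)
      }
      for (r in seq_len(spec$read_depth)) {
        pieces <- ref_pieces
        if (r <= n_alt) {
          k <- which(ex$start <= snp_site$genomic_pos &
                       ex$end >= snp_site$genomic_pos)
          off <- snp_site$genomic_pos - ex$start[k] + 1L
          substr(pieces[k], off, off) <- snp_site$alt_base
        }
        reads[[length(reads) + 1L]] <- tibble::tibble(
          read_id = sprintf("%s_r%03d", tid, r), chrom = ex$chrom[1],
          blocks = paste(sprintf("%d-%d", ex$start, ex$end),
                         collapse = ";"),
          seq = paste(pieces, collapse = ""), mapq = 60L, flag = 0L)
      }
    }
    reads <- dplyr::bind_rows(reads)

    ## -- truth post-processing: self-filter + binder stub ---------------
    proteome_tbl <- tibble::tibble(
      protein_id = vapply(proteins, `[[`, "", "id"),
      gene_id = vapply(proteins, `[[`, "", "gene"),
      transcript_id = vapply(proteins, `[[`, "", "tx"),
      seq = vapply(proteins, `[[`, "", "seq"))
    truth <- if (length(truth) > 0L) dplyr::bind_rows(truth) else
      tibble::tibble(peptide = character(0), category = character(0),
                     transcript_id = character(0), snp_changed = logical(0),
                     erv = logical(0))
    kmers <- build_proteome_kmers(proteome_tbl, L)
    novel <- truth$category %in% c("novel_intronic", "novel_intergenic")
    truth <- truth[!(novel & truth$peptide %in% kmers), ]
    alleles <- c("HLA-A*02:01", "HLA-B*07:02")
    if (nrow(truth) > 0L) {
      ranks <- rank_provider_stub()(truth$peptide, alleles)
      min_rank <- dplyr::summarise(dplyr::group_by(ranks, .data$peptide),
                                   min_rank = min(.data$rank_pct))
      truth <- dplyr::left_join(truth, min_rank, by = "peptide")
      truth <- truth[truth$min_rank < 2, ]
    } else {
      truth$min_rank <- numeric(0)
    }

    ## -- write the bundle ------------------------------------------------
    p <- function(f) file.path(dir, f)
    Biostrings::writeXStringSet(genome, p("genome.fa"))
    write_reference_gtf(ref_tx, p("reference.gtf"))
    writeLines(sprintf(">%s gene:%s transcript:%s\n%s",
                       proteome_tbl$protein_id, proteome_tbl$gene_id,
                       proteome_tbl$transcript_id, proteome_tbl$seq),
               p("proteome.fa"))
    ctrl_paths <- vapply(seq_along(controls), function(ci) {
      path <- p(sprintf("control_%02d.gtf", ci))
      write_transcript_gtf(controls[[ci]], path)
      path
    }, "")
    write_transcript_gtf(tumor, p("tumor.gtf"))
    utils::write.table(reads, p("reads.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_fixture_sam(reads, genome_sizes(genome), p("reads.sam"))
    if (!is.null(erv_regions)) {
      erv_gr <- g_intervals("chr1", erv_regions$start, erv_regions$end)
      S4Vectors::mcols(erv_gr)$name <- sprintf("ERV%04d",
                                               seq_len(length(erv_gr)))
      S4Vectors::mcols(erv_gr)$score <- 0
      write_bed6(erv_gr, p("erv.bed"))
    } else {
      writeLines(character(0), p("erv.bed"))
    }
    if (!is.null(events)) {
      utils::write.table(events, p("events.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    writeLines(alleles, p("alleles.txt"))
    utils::write.table(truth, p("truth_peptides.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

    list(paths = list(genome = p("genome.fa"),
                      reference_gtf = p("reference.gtf"),
                      proteome = p("proteome.fa"),
                      controls = ctrl_paths,
                      tumor_gtf = p("tumor.gtf"),
                      reads_tsv = p("reads.tsv"),
                      reads_sam = p("reads.sam"),
                      erv_bed = p("erv.bed"),
                      events = if (!is.null(events)) p("events.tsv"),
                      alleles = p("alleles.txt"),
                      truth = p("truth_peptides.tsv")),
         truth = truth, alleles = alleles, spec = spec,
         tumor = tumor, controls = controls, genome = genome,
         snp_site = snp_site)
  })
}

write_reference_gtf <- function(ref_tx, path) {
  lines <- character(0)
  for (g in ref_tx) {
    lines <- c(lines, sprintf(
      '%s\tref\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      g$chrom, min(g$exons$start), max(g$exons$end), g$strand, g$gene, g$tx))
    for (j in seq_len(nrow(g$exons))) {
      lines <- c(lines, sprintf(
        '%s\tref\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
        g$chrom, g$exons$start[j], g$exons$end[j], g$strand, g$gene, g$tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# plain-text SAM with spliced (M/N) cigars matching the placement table
write_fixture_sam <- function(reads, sizes, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sizes), unname(sizes)))
  body <- vapply(seq_len(nrow(reads)), function(i) {
    b <- strsplit(reads$blocks[i], ";", fixed = TRUE)[[1]]
    se <- do.call(rbind, lapply(strsplit(b, "-", fixed = TRUE), as.integer))
    widths <- se[, 2] - se[, 1] + 1L
    cig <- character(0)
    for (k in seq_along(widths)) {
      cig <- c(cig, sprintf("%dM", widths[k]))
      if (k < length(widths)) {
        cig <- c(cig, sprintf("%dN", se[k + 1L, 1] - se[k, 2] - 1L))
      }
    }
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
            reads$read_id[i], reads$flag[i], reads$chrom[i], se[1, 1],
            reads$mapq[i], paste(cig, collapse = ""), reads$seq[i],
            strrep("I", nchar(reads$seq[i])))
  }, "")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' The packaged confirmation-cascade worked example
#'
#' Loads the packaged 23-row table of published non-canonical
#' tumor-specific antigen calls with their per-stage evaluation fields
#' (region reconstructed, control expression, class, tumor expression,
#' reading-frame / ORF correctness, HLA match). Dashes in the printed
#' table are encoded as `NA`.
#'
#' @param path Defaults to the packaged fixture.
#' @return Tibble with one row per peptide call.
#' @export
read_table2 <- function(path = system.file("extdata", "table2_nctsa.tsv",
                                           package = "tsacapture")) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = "-",
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Sequential confirmation cascade over evaluated peptide calls
#'
#' Applies the decision gates in order: (1) region reconstructed by
#' assembly; (2) maximum control expression at most `control_max_tpm`
#' (a missing value passes -- novel calls have no control expression by
#' construction); (3) a transcript class assigned; (4) tumor expression --
#' differential calls need minimum TPM strictly greater than
#' `diff_min_tpm`, novel calls at least `novel_min_tpm`; (5) correct
#' reading frame; (6) correct ORF; (7) HLA type match. A row is confirmed
#' when it passes all gates; otherwise its first failing gate is recorded.
#'
#' @param rows Tibble from [read_table2()] (columns `region_reconstructed`,
#'   `max_tpm_control`, `nr_class`, `min_tpm_diff`, `min_tpm_novel`,
#'   `correct_rf`, `correct_orf`, `hla_match`).
#' @param diff_min_tpm,novel_min_tpm,control_max_tpm Gate thresholds.
#' @return `rows` with `confirmed` (logical) and `failed_gate` (integer,
#'   `NA` when confirmed) columns.
#' @export
table2_cascade <- function(rows, diff_min_tpm = 10.0, novel_min_tpm = 1.0,
                           control_max_tpm = 1.0) {
  yes <- function(x) !is.na(x) & tolower(x) == "yes"
  gate <- rep(NA_integer_, nrow(rows))
  fail_at <- function(cond, g) {
    gate <<- ifelse(is.na(gate) & !cond, g, gate)
  }
  fail_at(yes(rows$region_reconstructed), 1L)
  fail_at(is.na(rows$max_tpm_control) |
            rows$max_tpm_control <= control_max_tpm, 2L)
  fail_at(!is.na(rows$nr_class), 3L)
  expr_ok <- ifelse(rows$nr_class %in% "differential",
                    !is.na(rows$min_tpm_diff) &
                      rows$min_tpm_diff > diff_min_tpm,
                    !is.na(rows$min_tpm_novel) &
                      rows$min_tpm_novel >= novel_min_tpm)
  fail_at(expr_ok, 4L)
  fail_at(yes(rows$correct_rf), 5L)
  fail_at(yes(rows$correct_orf), 6L)
  fail_at(yes(rows$hla_match), 7L)
  rows$failed_gate <- gate
  rows$confirmed <- is.na(gate)
  rows
}
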