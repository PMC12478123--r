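make_reads <- function(n, start, end, chrom = "chr1", seq = NULL,
                       mapq = 60L, flag = 0L) {
  seq <- seq %||% strrep("A", end - start + 1)
  tibble::tibble(read_id = sprintf("r%03d", seq_len(n)), chrom = chrom,
                 mapq = mapq, flag = flag,
                 blocks = replicate(n, data.frame(start = start, end = end),
                                    simplify = FALSE),
                 seq = rep(seq, n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sliding windows count and track junction-split blocks", {
  # 10-aa region, 9-mers -> 2 windows; 8-aa region -> 0
  region <- list(aa_seq = strrep("A", 10), protein_start = 1L)
  cdna <- list(seq = strrep("GCT", 12), map = 1:36, chrom = "chr1",
               strand = "+")
  translated <- list(orf_start = 1L)
  expect_equal(nrow(chop_peptides(region, translated, cdna, 9)), 2L)
  region8 <- list(aa_seq = strrep("A", 8), protein_start = 1L)
  expect_equal(nrow(chop_peptides(region8, translated, cdna, 9)), 0L)

  # junction: cDNA maps to two genomic runs; windows crossing it split
  map2 <- c(101:130, 501:530)
  cdna2 <- list(seq = strrep("GCT", 20), map = map2, chrom = "chr1",
                strand = "+")
  region2 <- list(aa_seq = strrep("A", 20), protein_start = 1L)
  peps <- chop_peptides(region2, translated, cdna2, 9)
  expect_equal(nrow(peps), 12L)
  spanning <- peps[peps$n_blocks == 2, ]
  expect_true(nrow(spanning) > 0)
  for (i in seq_len(nrow(spanning))) {
    b <- spanning$blocks[[i]]
    expect_equal(sum(b$end - b$start + 1L), 27L)
  }
})

test_that("read support counts only fully-spanning high-quality reads, capped", {
  pep <- data.frame(start = 111L, end = 137L)
  full <- make_reads(3, 101, 150)
  partial <- make_reads(1, 101, 120)
  partial$read_id <- "partial"
  rs <- read_support(pep, "chr1", dplyr::bind_rows(full, partial))
  expect_equal(rs$bam_reads, 3L)

  one <- read_support(pep, "chr1", make_reads(1, 101, 150))
  expect_equal(one$n_spanning, 1L)   # below the >=2 pipeline cut

  many <- read_support(pep, "chr1", make_reads(250, 101, 150))
  expect_equal(many$bam_reads, 100L)
  expect_equal(many$n_spanning, 250L)

  # low mapq, secondary and duplicate reads are not high-quality
  lowq <- make_reads(3, 101, 150, mapq = 5L)
  expect_equal(read_support(pep, "chr1", lowq)$n_spanning, 0L)
  dup <- make_reads(3, 101, 150, flag = 1024L)
  expect_equal(read_support(pep, "chr1", dup)$n_spanning, 0L)

  # spliced peptide: read must cover both blocks
  pep2 <- data.frame(start = c(111L, 201L), end = c(120L, 210L))
  spliced <- tibble::tibble(read_id = "s1", chrom = "chr1", mapq = 60L,
                            flag = 0L,
                            blocks = list(data.frame(start = c(105L, 195L),
                                                     end = c(125L, 215L))),
                            seq = strrep("A", 42))
  unspliced <- make_reads(1, 105, 215)
  expect_equal(read_support(pep2, "chr1", spliced)$n_spanning, 1L)
  expect_equal(read_support(pep2, "chr1", unspliced)$n_spanning, 1L)
})

test_that("majority-vote SNP correction is strict and re-translates", {
  pep <- data.frame(start = 101L, end = 109L)
  ref_nt <- "GCTGGTCAT"   # A G H
  mk <- function(n, base_at_5) {
    s <- ref_nt
    substr(s, 5, 5) <- base_at_5
    make_reads(n, 101, 109, seq = s)
  }
  # 7 alt vs 3 ref: alt wins, GGT -> GAT changes Gly to Asp
  reads <- dplyr::bind_rows(mk(7, "A"), mk(3, "G"))
  reads$read_id <- sprintf("r%02d", 1:10)
  res <- apply_majority_snps(pep, "chr1", "+", ref_nt, reads, 1:10)
  expect_equal(res$corrected_nt, "GCTGATCAT")
  expect_equal(res$corrected_peptide, "ADH")
  expect_true(res$snp_changed)

  # all reads match the reference
  res2 <- apply_majority_snps(pep, "chr1", "+", ref_nt, mk(5, "G"), 1:5)
  expect_false(res2$snp_changed)
  expect_equal(res2$corrected_nt, ref_nt)

  # 5/5 tie: no strict majority, reference kept
  tie <- dplyr::bind_rows(mk(5, "A"), mk(5, "G"))
  tie$read_id <- sprintf("r%02d", 1:10)
  res3 <- apply_majority_snps(pep, "chr1", "+", ref_nt, tie, 1:10)
  expect_false(res3$snp_changed)

  # minus strand: pileup is in genome space, correction lands in cDNA space
  ref_minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ref_nt)))
  res4 <- apply_majority_snps(pep, "chr1", "-", ref_minus, reads, 1:10)
  expect_equal(res4$corrected_nt, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("GCTGATCAT"))))
})

test_that("proteome k-mer library and self-filter follow the category rule", {
  kmers <- build_proteome_kmers(c("MKLV"), 3)
  expect_setequal(as.character(kmers), c("MKL", "KLV"))
  expect_length(build_proteome_kmers(c("MK"), 3), 0L)
  # shared windows collapse; non-standard residues excluded
  k2 <- build_proteome_kmers(c("MKLV", "AKLV", "AXLV"), 3)
  expect_equal(sum(as.character(k2) == "KLV"), 1L)
  expect_false(any(grepl("X", k2)))

  cands <- tibble::tibble(
    peptide_corrected = c("MKL", "QQQ", "MKL"),
    category = c("novel_intronic", "novel_intergenic", "differential"),
    length = 3L)
  kept <- filter_self_peptides(cands, kmers)
  # novel self-peptide removed; novel non-self and differential self kept
  expect_equal(kept$peptide_corrected, c("QQQ", "MKL"))
  expect_equal(kept$category[2], "differential")
  expect_error(filter_self_peptides(dplyr::mutate(cands, length = 9L),
                                    kmers), "length")
})

test_that("binder thresholds are exact and non-binders are removed", {
  cands <- tibble::tibble(peptide_corrected = c("PEPA", "PEPB", "PEPC",
                                                "PEPD", "PEPE"),
                          category = "novel_intronic", length = 4L)
  ranks <- tibble::tibble(
    peptide = rep(cands$peptide_corrected, each = 1),
    allele = "HLA-A*02:01",
    rank_pct = c(0.4, 0.49, 0.5, 1.99, 2.0))
  out <- classify_binders(cands, ranks, "HLA-A*02:01")
  lab <- stats::setNames(out$binder_label, out$peptide_corrected)
  expect_equal(unname(lab["PEPA"]), "SB")
  expect_equal(unname(lab["PEPB"]), "SB")
  expect_equal(unname(lab["PEPC"]), "WB")
  expect_equal(unname(lab["PEPD"]), "WB")
  expect_false("PEPE" %in% out$peptide_corrected)

  # all alleles above the weak cut -> candidate removed entirely
  ranks2 <- tibble::tibble(peptide = rep("PEPA", 2),
                           allele = c("A1", "A2"), rank_pct = c(2.5, 3.0))
  out2 <- classify_binders(cands[1, ], ranks2, c("A1", "A2"))
  expect_equal(nrow(out2), 0L)
  expect_error(classify_binders(cands[1, ], ranks2[1, ], c("A1", "A2")),
               "missing")
})

test_that("rank providers are deterministic and bounded", {
  stub <- rank_provider_stub()
  r1 <- stub(c("AAAA", "BBBB"), c("HLA-A*02:01", "HLA-B*07:02"))
  r2 <- stub(c("AAAA", "BBBB"), c("HLA-A*02:01", "HLA-B*07:02"))
  expect_identical(r1, r2)
  expect_true(all(r1$rank_pct >= 0 & r1$rank_pct <= 5))
  expect_equal(nrow(r1), 4L)

  path <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\tallele\trank", "AAAA\tA1\t0.3"), path)
  tsv <- rank_provider_tsv(path)
  expect_equal(tsv("AAAA", "A1")$rank_pct, 0.3)
})

test_that("ERV annotation needs one overlapping base and never changes category", {
  cands <- tibble::tibble(
    peptide_corrected = c("P1", "P2", "P3"),
    category = c("novel_intergenic", "differential", "novel_intronic"),
    chrom = "chr1",
    blocks = list(data.frame(start = 101L, end = 127L),
                  data.frame(start = 900L, end = 926L),
                  data.frame(start = 94L, end = 120L)))
  erv <- gi("chr1", 121, 500)
  out <- annotate_erv(cands, erv)
  expect_equal(out$erv, c(TRUE, FALSE, FALSE))  # P3 ends at 120: touching
  expect_equal(out$category, cands$category)
  out2 <- annotate_erv(cands, gi("chr1", 120, 500))
  expect_true(out2$erv[3])
})

test_that("prioritization presets apply their thresholds and keep one per transcript", {
  rows <- tibble::tibble(
    peptide_corrected = sprintf("P%d", 1:5),
    category = c("novel_intergenic", "novel_intronic", "novel_intergenic",
                 "differential", "novel_intergenic"),
    transcript_id = c("T1", "T1", "T2", "T3", "T4"),
    tpm_iso_perc = c(60, 60, 100, 100, 40),
    tpm = c(4, 4, 5, 8, 10),
    bam_reads = c(6L, 6L, 10L, 10L, 10L),
    exon_cov_ratio = c(0.9, 0.9, 1, 1, 1),
    rank_pct = c(0.4, 0.3, 0.45, 0.2, 0.1))
  top <- select_top_candidates(rows, "organoid")
  # differential excluded; low iso-perc excluded; T1 keeps only rank 0.3
  expect_setequal(top$transcript_id, c("T1", "T2"))
  expect_equal(top$rank_pct[top$transcript_id == "T1"], 0.3)
  # strict TPM > 3
  rows2 <- dplyr::mutate(rows[3, ], tpm = 3.0)
  expect_equal(nrow(select_top_candidates(rows2, "organoid")), 0L)
  # glioblastoma: strong binders with full clonality only
  gbm <- select_top_candidates(rows, "glioblastoma")
  expect_setequal(gbm$transcript_id, c("T2", "T3"))
  expect_error(select_top_candidates(rows, "nope"))
})

test_that("output assembly emits the fixed column order, long format, stable sort", {
  cands <- tibble::tibble(
    sample_id = "s", peptide_corrected = c("PEPA", "PEPA"), length = 4L,
    category = "novel_intergenic", erv = FALSE, chrom = "chr1",
    blocks = list(data.frame(start = 101L, end = 112L),
                  data.frame(start = 101L, end = 112L)),
    strand = "+", transcript_id = "T1", locus_id = "L1", tpm = 5,
    tpm_iso_perc = 100, exon_cov_ratio = 1, bam_reads = 9L,
    ref_nt = "GCTGCTGCTGCT", corrected_nt = "GCTGCTGCTGCT",
    snp_changed = FALSE, allele = c("A1", "A2"), rank_pct = c(0.4, 1.2),
    binder_label = c("SB", "WB"))
  out <- assemble_output(cands)
  expect_equal(names(out),
               c("sample_id", "peptide", "length", "category", "erv",
                 "chrom", "blocks", "strand", "transcript_id", "locus_id",
                 "TPM", "TPM_iso_perc", "Exon_cov_ratio", "BAM_reads",
                 "REF_NT", "corrected_NT", "snp_changed", "allele",
                 "rank_pct", "binder_label"))
  expect_equal(nrow(out), 2L)   # one row per binding allele
  expect_equal(out$blocks, rep("101-112", 2))

  empty <- assemble_output(cands[0, ])
  expect_equal(nrow(empty), 0L)
  path <- tempfile(fileext = ".tsv")
  write_output_tsv(empty, path)
  expect_equal(length(readLines(path)), 1L)   # header only
})
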