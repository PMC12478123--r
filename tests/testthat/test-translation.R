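mini_ts <- function(starts, ends, strand = "+", tid = "T1") {
  tx <- tibble::tibble(transcript_id = tid, locus_id = "L1",
                       sample_id = NA_character_, chrom = "chr1",
                       strand = strand, tpm = 1, mean_cov = 1,
                       n_exons = length(starts),
                       ref_gene_id = NA_character_)
  ex <- tibble::tibble(transcript_id = tid, chrom = "chr1", start = starts,
                       end = ends, strand = strand, cov = 1)
  transcript_set(tx, ex)
}
dna <- function(s) Biostrings::DNAStringSet(stats::setNames(s, "chr1"))

test_that("spliced cDNA concatenates exons and reverse-complements minus strand", {
  g <- dna("ATGCCCGGGTTT")
  cd <- spliced_cdna(mini_ts(c(1, 7), c(3, 9)), "T1", g)
  expect_equal(cd$seq, "ATGGGG")
  expect_equal(cd$map, c(1:3, 7:9))

  cdm <- spliced_cdna(mini_ts(1, 6, strand = "-"), "T1", dna("ATGCCC"))
  expect_equal(cdm$seq, "GGGCAT")
  expect_equal(cdm$map, 6:1)

  # map is a bijection back to the genomic base at every offset
  gchars <- strsplit("ATGCCCGGGTTT", "")[[1]]
  cd2 <- spliced_cdna(mini_ts(c(2, 8), c(5, 11), strand = "-"), "T1", g)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_equal(strsplit(cd2$seq, "")[[1]],
               unname(comp[gchars[cd2$map]]))
  expect_error(spliced_cdna(mini_ts(10, 20), "T1", dna("ATGCCC")), "bounds")
})

test_that("three-frame translation follows the standard code with N and stop rules", {
  expect_equal(translate_nt("ATGAAATAG", 0), "MK*")
  expect_equal(translate_nt("ATGAAA", 1), "*")    # TGA in frame 1
  expect_equal(translate_nt("ATGNNN", 0), "MX")
  expect_equal(translate_nt("CTGAAA", 0), "LK")   # CTG is Leu mid-sequence
  expect_equal(translate_nt("AT", 0), "")
  expect_error(translate_nt("ATGQ", 0), "ACGTN")
})

test_that("ORF selection without a reference uses Kozak then closest Met", {
  t1 <- translate_full("ATGGCCTAA")
  expect_equal(t1$protein, "MA")
  expect_equal(t1$method, "met")
  expect_equal(t1$orf_start, 1L)

  # first ATG lacks Kozak context, the second (GCCACCATGG) has it
  seq <- paste0("AAAATGTTT", "GCCACCATGGCTTAA")
  t2 <- translate_full(seq)
  expect_equal(t2$method, "kozak")
  expect_equal(t2$orf_start, 16L)
  expect_equal(t2$protein, "MA")
  expect_equal(t2$frame, (16L - 1L) %% 3L)

  # no ATG at all: untranslatable, flagged
  t3 <- translate_full("CCCGGGCCCGGG")
  expect_equal(t3$protein, "")
  expect_equal(t3$method, "none")
})

test_that("reference-guided frame choice matches a brute-force three-frame oracle", {
  set.seed(5)
  for (case in 1:12) {
    ref <- paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L"),
                        12, replace = TRUE), collapse = "")
    frame <- sample(0:2, 1)
    # plant the reference segment in the chosen frame of a random backbone
    lead_codons <- sample(c("GCT", "GAA", "TTT"), 4, replace = TRUE)
    cdna <- paste0(strrep("C", frame), paste(lead_codons, collapse = ""),
                   local({
                     code <- Biostrings::GENETIC_CODE
                     by_aa <- split(names(code), unname(code))
                     paste(vapply(strsplit(ref, "")[[1]], function(a)
                       by_aa[[a]][1], ""), collapse = "")
                   }),
                   "TAAGGG")
    tr <- translate_full(cdna, reference_protein = ref,
                         reference_protein_id = "R1")
    expect_equal(tr$method, "reference")
    # oracle: score each frame by independent LCS enumeration
    scores <- vapply(0:2, function(f)
      lcs_oracle(translate_nt(cdna, f), ref), 0L)
    expect_equal(tr$frame, which.max(scores) - 1L)
    expect_equal(tr$match_len, max(scores))
    # protein is stop-free and is reproduced by direct translation
    expect_false(grepl("*", tr$protein, fixed = TRUE))
    redo <- translate_nt(substr(cdna, tr$orf_start, nchar(cdna)), 0)
    expect_equal(sub("\\*.*$", "", redo), tr$protein)
    expect_equal((tr$orf_start - 1L) %% 3L, tr$frame)
  }
})

test_that("a transcript carrying its reference CDS reproduces the reference protein", {
  ref <- "MKLVNDAQRS"
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  cds <- paste(vapply(strsplit(ref, "")[[1]], function(a) by_aa[[a]][1], ""),
               collapse = "")
  tr <- translate_full(paste0(cds, "TAA"), reference_protein = ref)
  expect_equal(tr$protein, ref)
  expect_equal(tr$match_len, nchar(ref))
  expect_equal(tr$frame, 0L)
})

test_that("fragment placement requires the minimum overlap and extends for junction peptides", {
  # genome: 15-nt lead-in + 60-nt ORF (20 codons) + stop
  set.seed(31)
  aa <- paste(sample(c("G", "A", "V", "L", "I", "P", "F", "W", "S", "T"),
                     19, replace = TRUE), collapse = "")
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  cds <- paste0("ATG", paste(vapply(strsplit(aa, "")[[1]], function(a)
    by_aa[[a]][1], ""), collapse = ""))
  gseq <- paste0("CCTTTCCTTTCCTTT", cds, "TAA")
  ts <- mini_ts(1, nchar(gseq))
  g <- dna(gseq)
  cd <- spliced_cdna(ts, "T1", g)
  tr <- translate_full(cd$seq)
  expect_equal(tr$protein, paste0("M", aa))

  # 30-nt in-frame fragment inside the ORF (codons 4..13) -> 10-aa match
  frag <- list(blocks = data.frame(start = 16 + 9, end = 16 + 38))
  rp <- translate_fragment(frag, tr, cd, min_overlap_aa = 8, peptide_len = 9)
  expect_equal(rp$match_end - rp$match_start + 1L, 10L)
  expect_equal(rp$match_start, 4L)
  # extension: 8 aa each side, clipped to the 20-aa protein
  expect_equal(rp$protein_start, 1L)
  expect_equal(rp$protein_end, 20L)
  expect_true(rp$extended)
  expect_equal(rp$aa_seq, tr$protein)

  # 23-nt fragment gives at most 7 aa in any frame: below the minimum
  frag23 <- list(blocks = data.frame(start = 16 + 9, end = 16 + 31))
  expect_null(translate_fragment(frag23, tr, cd, 8, 9)$aa_seq)

  # fragment upstream of the ORF never matches the protein
  fragup <- list(blocks = data.frame(start = 1, end = 12))
  expect_null(translate_fragment(fragup, tr, cd, 8, 9)$aa_seq)
})

test_that("region peptides round-trip from genome through the recorded blocks", {
  out <- run_fixture_predict(fixture_spec(seed = 13))
  tab <- out$res$table
  genome <- out$fx$genome
  for (i in seq_len(min(nrow(tab), 25))) {
    blocks <- do.call(rbind, lapply(strsplit(strsplit(tab$blocks[i], ",")[[1]],
                                             "-"), as.integer))
    nt <- paste(substring(as.character(genome[["chr1"]]),
                          blocks[, 1], blocks[, 2]), collapse = "")
    if (tab$strand[i] == "-") {
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    }
    expect_equal(nt, tab$REF_NT[i])
    if (!tab$snp_changed[i]) {
      expect_equal(translate_nt(nt, 0), tab$peptide[i])
    }
  }
})
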