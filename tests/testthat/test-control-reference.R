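mini_control <- function(starts, ends, tpm, cov, ids = NULL) {
  n <- length(starts)
  ids <- ids %||% sprintf("C.%d.1", seq_len(n))
  tx <- tibble::tibble(transcript_id = ids,
                       locus_id = sub("\\.[^.]+$", "", ids),
                       sample_id = NA_character_, chrom = "chr1",
                       strand = "+", tpm = tpm, mean_cov = cov,
                       n_exons = 1L, ref_gene_id = NA_character_)
  ex <- tibble::tibble(transcript_id = ids, chrom = "chr1", start = starts,
                       end = ends, strand = "+", cov = cov)
  transcript_set(tx, ex)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("control database carries the max TPM/coverage over merged exons", {
  db <- build_control_db(list(mini_control(101, 200, tpm = 0.5, cov = 3),
                              mini_control(151, 250, tpm = 2.0, cov = 1)))
  expect_length(db, 1L)
  expect_same_bases(db, data.frame(chrom = "chr1", start = 101L, end = 250L))
  expect_equal(S4Vectors::mcols(db)$max_tpm, 2.0)
  expect_equal(S4Vectors::mcols(db)$max_cov, 3)

  # disjoint exons keep their own statistics
  db2 <- build_control_db(list(mini_control(c(101, 501), c(200, 600),
                                            tpm = c(1, 9), cov = c(2, 8),
                                            ids = c("C.1.1", "C.2.1"))))
  expect_equal(S4Vectors::mcols(db2)$max_tpm, c(1, 9))

  # book-ended exons from three samples collapse into one region
  db3 <- build_control_db(list(mini_control(101, 200, 1, 5),
                               mini_control(201, 300, 2, 7),
                               mini_control(301, 400, 3, 6)))
  expect_length(db3, 1L)
  expect_equal(S4Vectors::mcols(db3)$max_cov, 7)
  expect_error(build_control_db(list()), "control")
})

test_that("capture BED splits novel regions at gene boundaries and applies strict sparsity", {
  sizes <- c(chr1 = 1000L)
  db <- build_control_db(list(mini_control(c(101, 301), c(200, 400),
                                           tpm = c(5, 5), cov = c(10, 10),
                                           ids = c("C.1.1", "C.2.1"))))
  spans <- gi("chr1", 51, 500)
  cap <- derive_capture_bed(db, spans, sizes)
  df <- gr_to_df(cap)
  df$category <- S4Vectors::mcols(cap)$category
  expect_equal(df[df$category == "novel_intronic",
                  c("start", "end")],
               data.frame(start = c(51L, 201L, 401L),
                          end = c(100L, 300L, 500L)),
               ignore_attr = TRUE)
  expect_equal(df[df$category == "novel_intergenic",
                  c("start", "end")],
               data.frame(start = c(1L, 501L), end = c(50L, 1000L)),
               ignore_attr = TRUE)
  # no control exon is sparse here
  expect_false(any(df$category == "differential"))
  # per-base check: novel bases are exactly the control complement
  novel <- cap[S4Vectors::mcols(cap)$category != "differential"]
  expect_equal(base_mask(novel, sizes)$chr1, !base_mask(db, sizes)$chr1)

  # sparsity boundaries are strict
  db_sparse <- build_control_db(list(mini_control(c(101, 301, 501),
                                                  c(200, 400, 600),
                                                  tpm = c(0.5, 1.0, 0.5),
                                                  cov = c(3, 3, 4),
                                                  ids = c("C.1.1", "C.2.1",
                                                          "C.3.1"))))
  cap2 <- derive_capture_bed(db_sparse, spans, sizes)
  diff <- cap2[S4Vectors::mcols(cap2)$category == "differential"]
  expect_same_bases(diff, data.frame(chrom = "chr1", start = 101L,
                                     end = 200L))
  expect_equal(S4Vectors::mcols(diff)$control_max_tpm, 0.5)
})

test_that("capture BED file round trip preserves categories and control TPM", {
  sizes <- c(chr1 = 1000L)
  db <- build_control_db(list(mini_control(c(101, 301), c(200, 400),
                                           tpm = c(0.5, 5), cov = c(2, 9),
                                           ids = c("C.1.1", "C.2.1"))))
  cap <- derive_capture_bed(db, gi("chr1", 51, 500), sizes)
  path <- tempfile(fileext = ".bed")
  write_capture_bed(cap, path)
  back <- read_capture_bed(path)
  expect_equal(gr_to_df(back), gr_to_df(cap))
  expect_equal(S4Vectors::mcols(back)$category,
               S4Vectors::mcols(cap)$category)
  expect_equal(S4Vectors::mcols(back)$control_max_tpm,
               S4Vectors::mcols(cap)$control_max_tpm)
})

test_that("saturation statistics behave as defined", {
  expect_equal(jaccard_similarity(list(c("A", "B", "C"), c("A", "B", "D"))),
               0.5)
  expect_equal(jaccard_similarity(list(c("A", "B"), c("A", "B"))), 1.0)
  expect_equal(jaccard_similarity(list("A", "B")), 0.0)
  expect_equal(jaccard_similarity(list(character(0), character(0))), 1.0)
  expect_error(jaccard_similarity(list("A")), "2 sets")

  expect_equal(removed_self_peptide_pct(100, 57), 43)
  expect_equal(removed_self_peptide_pct(100, 100), 0)
  expect_equal(removed_self_peptide_pct(100, 0), 100)
  expect_error(removed_self_peptide_pct(0, 0), "positive")

  expect_equal(coefficient_of_variation(c(10, 10, 10)), 0)
  expect_equal(coefficient_of_variation(c(8, 12)), 100 * 2 * sqrt(2) / 10)
  expect_error(coefficient_of_variation(10), "2 values")
  expect_error(coefficient_of_variation(c(-5, 5)), "mean")
})

test_that("saturation runs are seeded, nested and deterministic", {
  pool <- as.list(letters[1:6])
  # toy predictor: a 'control' removes its own peptide from a fixed set
  predict_fn <- function(subset) setdiff(LETTERS[1:6],
                                         toupper(unlist(subset)))
  s1 <- saturation_run(pool, c(2, 4), 3, seed = 11, predict_fn)
  s2 <- saturation_run(pool, c(2, 4), 3, seed = 11, predict_fn)
  expect_identical(s1$runs$peptides, s2$runs$peptides)
  expect_equal(nrow(s1$runs), 6L)
  # nested prefixes: larger subsets predict subsets of the smaller run
  for (r in 1:3) {
    small <- s1$runs$peptides[[which(s1$runs$replicate == r &
                                       s1$runs$n_controls == 2)]]
    large <- s1$runs$peptides[[which(s1$runs$replicate == r &
                                       s1$runs$n_controls == 4)]]
    expect_true(all(large %in% small))
  }
  expect_error(saturation_run(pool, 7, 2, 1, predict_fn), "pool")
})
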