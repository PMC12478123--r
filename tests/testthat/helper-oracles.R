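# Brute-force per-base oracles, independent of the interval implementation:
# intervals are expanded to logical coverage masks over toy chromosomes.

gi <- function(chrom, start, end, strand = "*") {
  tsacapture::g_intervals(chrom, start, end, strand)
}

# logical coverage mask per chromosome
base_mask <- function(gr, sizes) {
  masks <- lapply(sizes, function(n) logical(n))
  if (length(gr) == 0L) return(masks)
  chroms <- as.character(GenomeInfoDb::seqnames(gr))
  for (i in seq_along(gr)) {
    masks[[chroms[i]]][BiocGenerics::start(gr)[i]:BiocGenerics::end(gr)[i]] <- TRUE
  }
  masks
}

mask_to_intervals <- function(masks) {
  out <- list()
  for (chrom in names(masks)) {
    m <- masks[[chrom]]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep)) {
      out[[chrom]] <- data.frame(chrom = chrom, start = starts[keep],
                                 end = ends[keep])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
             start = BiocGenerics::start(gr),
             end = BiocGenerics::end(gr))
}

expect_same_bases <- function(gr, expected_df) {
  df <- gr_to_df(gr)
  rownames(df) <- NULL
  rownames(expected_df) <- NULL
  expect_equal(df, expected_df)
}

random_intervals <- function(n, sizes) {
  chrom <- sample(names(sizes), n, replace = TRUE)
  start <- vapply(chrom, function(c) sample.int(sizes[[c]] - 10L, 1L), 0L)
  width <- sample.int(200L, n, replace = TRUE)
  end <- pmin(start + width, unname(sizes[chrom]))
  gi(chrom, start, end)
}

# independent longest-common-substring oracle: enumerate all substrings of
# the shorter string and test containment in the longer one
lcs_oracle <- function(a, b) {
  if (nchar(a) == 0L || nchar(b) == 0L) return(0L)
  short <- if (nchar(a) <= nchar(b)) a else b
  long <- if (nchar(a) <= nchar(b)) b else a
  for (len in seq(nchar(short), 1L)) {
    for (s in seq_len(nchar(short) - len + 1L)) {
      if (grepl(substr(short, s, s + len - 1L), long, fixed = TRUE)) {
        return(len)
      }
    }
  }
  0L
}

# one full fixture -> prediction cycle, shared by several tests
run_fixture_predict <- function(spec, dir = tempfile("fxp")) {
  fx <- tsacapture::generate_fixture(spec, dir = dir)
  capture <- suppressMessages(tsacapture::run_build_ref(
    fx$paths$controls, fx$paths$reference_gtf,
    tsacapture::genome_sizes(fx$genome)))
  cb <- file.path(dir, "capture.bed")
  tsacapture::write_capture_bed(capture, cb)
  res <- tsacapture::run_predict(
    fx$paths$tumor_gtf, fx$paths$genome, cb,
    proteome = fx$paths$proteome, erv_bed = fx$paths$erv_bed,
    alignments = fx$paths$reads_tsv, alleles = fx$paths$alleles,
    sample_id = "tumor", quiet = TRUE)
  list(fx = fx, capture = capture, res = res)
}
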