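#' Build a control database from healthy-tissue transcript models
#'
#' Concatenates the control assemblies, merges overlapping (and book-ended)
#' exon regions across all samples, and records on every merged region the
#' maximum transcript TPM and maximum exon coverage among the exons merged
#' into it.
#'
#' @param controls A list of [transcript_set()] objects or a character
#'   vector of StringTie-dialect GTF paths.
#' @return `GRanges` of disjoint control regions with metadata columns
#'   `max_tpm` and `max_cov`.
#' @export
build_control_db <- function(controls) {
  if (is.character(controls)) {
    controls <- lapply(controls, read_transcript_gtf, dialect = "stringtie")
  }
  if (length(controls) == 0L) stop("at least one control GTF is required")
  # transcript ids may repeat across control samples; qualify them so the
  # concatenated set stays well-formed
  controls <- lapply(seq_along(controls), function(i) {
    ts <- controls[[i]]
    pre <- sprintf("ctl%02d:", i)
    ts$transcripts$transcript_id <- paste0(pre, ts$transcripts$transcript_id)
    ts$exons$transcript_id <- paste0(pre, ts$exons$transcript_id)
    ts
  })
  all_ts <- concat_transcript_sets(controls)
  ex <- dplyr::left_join(
    all_ts$exons,
    dplyr::select(all_ts$transcripts, "transcript_id", "tpm"),
    by = "transcript_id")
  gr <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  merged <- merge_intervals(gr)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  max_tpm <- rep(0, length(merged))
  max_cov <- rep(0, length(merged))
  for (k in seq_along(hits)) {
    j <- S4Vectors::subjectHits(hits)[k]
    i <- S4Vectors::queryHits(hits)[k]
    max_tpm[j] <- max(max_tpm[j], ex$tpm[i])
    max_cov[j] <- max(max_cov[j], ex$cov[i])
  }
  S4Vectors::mcols(merged)$max_tpm <- max_tpm
  S4Vectors::mcols(merged)$max_cov <- max_cov
  merged
}

#' Derive the capture BED from a control database
#'
#' The capture regions are the union of two parts. *Novel* regions are the
#' per-chromosome complement of the control regions -- genomic positions
#' with zero control coverage -- labelled `novel_intronic` where they
#' overlap an annotated gene span and `novel_intergenic` elsewhere; regions
#' straddling a gene boundary are split at the boundary so each piece is
#' purely one category. *Differential* regions are control regions sparsely
#' covered in the controls: maximum TPM strictly below `tpm_cut` and
#' maximum coverage strictly below `cov_cut`.
#'
#' @param control_db Output of [build_control_db()].
#' @param gene_spans `GRanges` of gene-level spans from the reference
#'   annotation.
#' @param sizes Named integer vector of chromosome lengths.
#' @param tpm_cut,cov_cut Sparsity thresholds (strict `<`); defaults 1 TPM
#'   and 4 reads.
#' @return `GRanges` with metadata columns `category` (one of
#'   `novel_intronic`, `novel_intergenic`, `differential`),
#'   `control_max_tpm` and `control_max_cov` (zero for novel regions).
#' @export
derive_capture_bed <- function(control_db, gene_spans, sizes,
                               tpm_cut = 1.0, cov_cut = 4.0) {
  novel <- invert_intervals(control_db, sizes)
  gene_spans <- merge_intervals(gene_spans, sizes = sizes)
  if (length(gene_spans) > 0L && length(novel) > 0L) {
    intronic <- GenomicRanges::intersect(novel, gene_spans)
    intergenic <- GenomicRanges::setdiff(novel, gene_spans)
  } else {
    intronic <- GenomicRanges::GRanges()
    intergenic <- novel
  }
  lab <- function(gr, category) {
    if (length(gr) > 0L) {
      S4Vectors::mcols(gr)$category <- category
      S4Vectors::mcols(gr)$control_max_tpm <- 0
      S4Vectors::mcols(gr)$control_max_cov <- 0
    } else {
      S4Vectors::mcols(gr)$category <- character(0)
      S4Vectors::mcols(gr)$control_max_tpm <- numeric(0)
      S4Vectors::mcols(gr)$control_max_cov <- numeric(0)
    }
    gr
  }
  intronic <- lab(intronic, "novel_intronic")
  intergenic <- lab(intergenic, "novel_intergenic")
  sparse <- control_db[S4Vectors::mcols(control_db)$max_tpm < tpm_cut &
                         S4Vectors::mcols(control_db)$max_cov < cov_cut]
  diff <- GenomicRanges::granges(sparse)
  S4Vectors::mcols(diff)$category <- rep("differential", length(diff))
  S4Vectors::mcols(diff)$control_max_tpm <- S4Vectors::mcols(sparse)$max_tpm
  S4Vectors::mcols(diff)$control_max_cov <- S4Vectors::mcols(sparse)$max_cov
  out <- c(intronic, intergenic, diff)
  GenomicRanges::sort(out)
}

#' Write / read a capture BED
#'
#' BED6 encoding: the name column carries the region category and the score
#' column the control maximum TPM (0 for novel regions).
#'
#' @param capture `GRanges` from [derive_capture_bed()].
#' @param path File path.
#' @return `read_capture_bed` returns the capture `GRanges`.
#' @export
write_capture_bed <- function(capture, path) {
  gr <- GenomicRanges::granges(capture)
  S4Vectors::mcols(gr)$name <- S4Vectors::mcols(capture)$category
  S4Vectors::mcols(gr)$score <- S4Vectors::mcols(capture)$control_max_tpm
  write_bed6(gr, path)
}

#' @rdname write_capture_bed
#' @export
read_capture_bed <- function(path) {
  gr <- read_bed6(path)
  cat_ok <- c("novel_intronic", "novel_intergenic", "differential")
  bad <- setdiff(unique(S4Vectors::mcols(gr)$name), cat_ok)
  if (length(bad) > 0L) stop("unknown capture categories: ",
                             paste(bad, collapse = ", "))
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$category <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(out)$control_max_tpm <- S4Vectors::mcols(gr)$score
  S4Vectors::mcols(out)$control_max_cov <- NA_real_
  out
}

#' Jaccard similarity of replicate peptide sets
#'
#' The ratio between the number of peptides shared by all replicates and the
#' number of unique peptides across all replicates. Defined as 1 when every
#' set is empty (degenerate but fully concordant).
#'
#' @param sets List (length >= 2) of character vectors.
#' @return Fraction in `[0, 1]`.
#' @export
jaccard_similarity <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets")
  sets <- lapply(sets, unique)
  uni <- unique(unlist(sets, use.names = FALSE))
  if (length(uni) == 0L) return(1.0)
  inter <- Reduce(intersect, sets)
  length(inter) / length(uni)
}

#' Percentage of removed self-peptides relative to a reference count
#'
#' `100 * (x_ref - x_i) / x_ref`: the proportion of putative self-peptides
#' at the reference filter size that a larger filter removed.
#'
#' @param x_ref Reference count (> 0).
#' @param x_i Count at the filter size of interest.
#' @return Percentage.
#' @export
removed_self_peptide_pct <- function(x_ref, x_i) {
  if (x_ref <= 0) stop("reference count must be positive")
  100 * (x_ref - x_i) / x_ref
}

#' Coefficient of variation, in percent
#'
#' @param values Numeric vector, length >= 2, non-zero mean.
#' @return `100 * sd(values) / mean(values)` (sample standard deviation).
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero; CV undefined")
  100 * stats::sd(values) / m
}

#' Saturation analysis over control-database size
#'
#' Runs `predict_fn` on growing control subsets sampled from a pool,
#' repeating each size over several replicates, and summarizes prediction
#' robustness. Sampling is nested within each replicate: a replicate draws
#' one seeded permutation of the pool and each step uses its prefix, so a
#' larger subset always contains the smaller one and novel predictions are
#' non-increasing along a replicate chain.
#'
#' @param pool List of controls (passed by subset to `predict_fn`).
#' @param step_sizes Integer vector of control-subset sizes (each <= pool).
#' @param replicates Number of replicates per step.
#' @param seed Master seed; per-replicate permutation seeds are derived from
#'   it and recorded in the output.
#' @param predict_fn Function taking a list (subset of `pool`) and returning
#'   a character vector of predicted peptides.
#' @return List with `runs` (tibble: `n_controls`, `replicate`,
#'   `replicate_seed`, `n_peptides`, `peptides` list-column) and `summary`
#'   (tibble: per-step mean count, CV, Jaccard).
#' @export
saturation_run <- function(pool, step_sizes, replicates, seed, predict_fn) {
  if (any(step_sizes > length(pool))) {
    stop("step size exceeds control pool (", length(pool), ")")
  }
  step_sizes <- sort(step_sizes)
  rep_seeds <- seed + seq_len(replicates)
  rows <- list()
  for (r in seq_len(replicates)) {
    perm <- withr::with_seed(rep_seeds[r], sample.int(length(pool)))
    for (n in step_sizes) {
      peps <- sort(unique(predict_fn(pool[perm[seq_len(n)]])))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_controls = n, replicate = r, replicate_seed = rep_seeds[r],
        n_peptides = length(peps), peptides = list(peps))
    }
  }
  runs <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(runs, .data$n_controls),
    mean_n = mean(.data$n_peptides),
    cv_pct = if (dplyr::n() >= 2 && mean(.data$n_peptides) > 0)
      coefficient_of_variation(.data$n_peptides) else NA_real_,
    jaccard = if (dplyr::n() >= 2)
      jaccard_similarity(.data$peptides) else NA_real_,
    .groups = "drop")
  list(runs = runs, summary = summary)
}
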