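#' Read a cassette-exon event table
#'
#' BED-like TSV with header columns: `chrom`, `pre_start`, `pre_end`,
#' `target_start`, `target_end`, `post_start`, `post_end`, `strand`
#' (coordinates 1-based inclusive), one row per event.
#'
#' @param path Event table path.
#' @return Tibble with an added `event_id` column.
#' @export
read_cassette_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pre_start", "pre_end", "target_start", "target_end",
            "post_start", "post_end", "strand")
  if (!all(need %in% names(df))) {
    stop("event table must have columns: ", paste(need, collapse = ", "))
  }
  df <- tibble::as_tibble(df)
  if (!"event_id" %in% names(df)) {
    df$event_id <- sprintf("event_%03d", seq_len(nrow(df)))
  }
  df
}

#' Classify transcripts of a cassette-exon event
#'
#' *Inclusion* transcripts contain the pre, target and post exons as three
#' consecutive exons, junction-exact at the boundaries shared with the
#' event: the pre exon's 3' boundary, both target boundaries, and the post
#' exon's 5' boundary must match; outer transcript ends may differ, since
#' assembly trims ends while junctions are read-supported. *Exclusion*
#' transcripts splice the pre exon directly to the post exon across the
#' same two junctions. Every other isoform overlapping the pre-to-post
#' span is counted as *other*.
#'
#' @param event One event row (list or single-row tibble).
#' @param ts A [transcript_set()].
#' @return List of character vectors: `inclusion`, `exclusion`, `other`
#'   (transcript ids).
#' @export
classify_event_transcripts <- function(event, ts) {
  span_lo <- min(event$pre_start)
  span_hi <- max(event$post_end)
  ex <- ts$exons[ts$exons$chrom == event$chrom, ]
  overlapping <- unique(ex$transcript_id[ex$start <= span_hi &
                                           ex$end >= span_lo])
  inclusion <- character(0)
  exclusion <- character(0)
  for (tid in overlapping) {
    e <- ex[ex$transcript_id == tid, ]
    e <- e[order(e$start), ]
    n <- nrow(e)
    is_incl <- FALSE
    is_excl <- FALSE
    if (n >= 3L) {
      for (i in seq_len(n - 2L)) {
        if (e$end[i] == event$pre_end &&
            e$start[i + 1L] == event$target_start &&
            e$end[i + 1L] == event$target_end &&
            e$start[i + 2L] == event$post_start) {
          is_incl <- TRUE
          break
        }
      }
    }
    if (!is_incl && n >= 2L) {
      for (i in seq_len(n - 1L)) {
        if (e$end[i] == event$pre_end &&
            e$start[i + 1L] == event$post_start) {
          is_excl <- TRUE
          break
        }
      }
    }
    if (is_incl) inclusion <- c(inclusion, tid)
    else if (is_excl) exclusion <- c(exclusion, tid)
  }
  list(inclusion = inclusion, exclusion = exclusion,
       other = setdiff(overlapping, c(inclusion, exclusion)))
}

#' Isoform-fraction quantification of cassette-exon inclusion
#'
#' Sums transcript TPM within the inclusion, exclusion and other sets and
#' converts each to a percentage of the three-set total -- the isoform
#' expression fraction used as a percent-spliced-in surrogate. When several
#' isoforms include (or exclude) the exon their fractions are summed.
#'
#' @param event One event row.
#' @param ts A [transcript_set()] for one sample/replicate.
#' @return Tibble row: `inclusion_pct`, `exclusion_pct`, `other_pct`,
#'   `n_inclusion`, `n_exclusion`, `n_other`, `total_tpm`. Percentages are
#'   `NA` when no overlapping transcript expresses (total TPM zero).
#' @export
inclusion_fraction <- function(event, ts) {
  cls <- classify_event_transcripts(event, ts)
  tpm_of <- stats::setNames(ts$transcripts$tpm, ts$transcripts$transcript_id)
  s <- vapply(cls, function(ids) sum(tpm_of[ids], na.rm = TRUE), 0)
  total <- sum(s)
  pct <- if (total > 0) 100 * s / total else rep(NA_real_, 3)
  tibble::tibble(inclusion_pct = pct[[1]], exclusion_pct = pct[[2]],
                 other_pct = pct[[3]],
                 n_inclusion = length(cls$inclusion),
                 n_exclusion = length(cls$exclusion),
                 n_other = length(cls$other),
                 total_tpm = total)
}

#' Mean inclusion fraction across replicates
#'
#' @param event One event row.
#' @param replicate_sets List of [transcript_set()] objects (replicates of
#'   one condition).
#' @return Tibble row of replicate means (`NA` replicates are dropped; all
#'   `NA` yields `NA`).
#' @export
event_inclusion_summary <- function(event, replicate_sets) {
  per_rep <- dplyr::bind_rows(lapply(replicate_sets, inclusion_fraction,
                                     event = event))
  dplyr::summarise(per_rep,
                   inclusion_pct = mean(.data$inclusion_pct, na.rm = TRUE),
                   exclusion_pct = mean(.data$exclusion_pct, na.rm = TRUE),
                   other_pct = mean(.data$other_pct, na.rm = TRUE),
                   n_replicates = sum(!is.na(per_rep$inclusion_pct)))
}

#' Between-condition difference of inclusion fractions
#'
#' The delta isoform-fraction, computed in concordance with delta-PSI
#' conventions: first condition minus second. `NA` inputs propagate.
#'
#' @param incl_a,incl_b Mean inclusion percentages of the two conditions.
#' @return `incl_a - incl_b`.
#' @export
delta_inclusion <- function(incl_a, incl_b) {
  incl_a - incl_b
}

#' Simulate cassette-exon events with known inclusion levels
#'
#' Generates `n_events` three-exon loci, each with an inclusion isoform
#' (pre + target + post), an exclusion isoform (pre + post) and a
#' non-participating "other" isoform, and draws per-replicate TPMs so that
#' the expected inclusion fraction among inclusion+exclusion+other equals a
#' known value. TPM noise is multiplicative log-normal with standard
#' deviation `noise_sd` on the log scale (about `100 * noise_sd` percent).
#'
#' @param n_events Number of events.
#' @param seed RNG seed.
#' @param noise_sd Multiplicative noise level (default 0.1, i.e. 10%).
#' @param n_replicates Replicates per condition.
#' @param total_tpm Expected per-event total TPM across the three isoform
#'   classes.
#' @param other_frac Expected fraction of locus expression carried by the
#'   "other" isoform.
#' @return List: `events` (tibble with `true_psi_a`, `true_psi_b`),
#'   `sets_a`, `sets_b` (lists of [transcript_set()] replicates).
#' @export
simulate_cassette_events <- function(n_events = 50L, seed = 1L,
                                     noise_sd = 0.1, n_replicates = 3L,
                                     total_tpm = 100, other_frac = 0) {
  withr::with_seed(seed, {
    exon_w <- 100L
    gap <- 200L
    pitch <- 2000L
    events <- tibble::tibble(
      event_id = sprintf("sim_%03d", seq_len(n_events)),
      chrom = "chrSim",
      pre_start = (seq_len(n_events) - 1L) * pitch + 1L)
    events$pre_end <- events$pre_start + exon_w - 1L
    events$target_start <- events$pre_end + gap + 1L
    events$target_end <- events$target_start + exon_w - 1L
    events$post_start <- events$target_end + gap + 1L
    events$post_end <- events$post_start + exon_w - 1L
    events$strand <- "+"
    events$true_psi_a <- stats::runif(n_events, 0.05, 0.95)
    events$true_psi_b <- stats::runif(n_events, 0.05, 0.95)
    build_rep <- function(psi_col, rep_id) {
      tx <- list(); exl <- list()
      for (k in seq_len(n_events)) {
        ev <- events[k, ]
        noise <- exp(stats::rnorm(3, 0, noise_sd))
        coding_tpm <- total_tpm * (1 - other_frac)
        tpms <- c(inc = coding_tpm * ev[[psi_col]] * noise[1],
                  exc = coding_tpm * (1 - ev[[psi_col]]) * noise[2],
                  oth = total_tpm * other_frac * noise[3])
        ids <- paste0(ev$event_id, "_", c("inc", "exc", "oth"), "_", rep_id)
        tx[[k]] <- tibble::tibble(
          transcript_id = ids, locus_id = ev$event_id,
          sample_id = rep_id, chrom = ev$chrom, strand = "+",
          tpm = as.numeric(tpms), mean_cov = 10, n_exons = c(3L, 2L, 1L),
          ref_gene_id = NA_character_)
        exl[[k]] <- tibble::tibble(
          transcript_id = c(rep(ids[1], 3), rep(ids[2], 2), ids[3]),
          chrom = ev$chrom,
          start = c(ev$pre_start, ev$target_start, ev$post_start,
                    ev$pre_start, ev$post_start,
                    ev$pre_start + 10L),
          end = c(ev$pre_end, ev$target_end, ev$post_end,
                  ev$pre_end, ev$post_end,
                  ev$pre_start + 39L),
          strand = "+", cov = 10)
      }
      transcript_set(dplyr::bind_rows(tx), dplyr::bind_rows(exl))
    }
    sets_a <- lapply(seq_len(n_replicates), function(r)
      build_rep("true_psi_a", sprintf("a%d", r)))
    sets_b <- lapply(seq_len(n_replicates), function(r)
      build_rep("true_psi_b", sprintf("b%d", r)))
    list(events = events, sets_a = sets_a, sets_b = sets_b)
  })
}
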