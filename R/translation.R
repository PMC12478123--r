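#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return Named `DNAStringSet`; names truncated to the first header token.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Chromosome sizes of a genome
#'
#' @param genome `DNAStringSet` from [read_genome()].
#' @return Named integer vector of lengths.
#' @export
genome_sizes <- function(genome) {
  stats::setNames(BiocGenerics::width(genome), names(genome))
}

#' Read a reference proteome FASTA
#'
#' Headers are expected to carry `gene:<id>` and/or `transcript:<id>`
#' tokens (GENCODE-style pipe-delimited headers are also recognized), which
#' provide the transcript/gene-to-protein mapping used for reference-guided
#' frame selection.
#'
#' @param path FASTA path.
#' @return Tibble with `protein_id`, `gene_id`, `transcript_id`, `seq`.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  hdr <- names(aa)
  tok <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, ":[^ |]+"), hdr))
    out <- rep(NA_character_, length(hdr))
    out[grepl(paste0(key, ":"), hdr)] <- sub(paste0(key, ":"), "", m)
    out
  }
  tibble::tibble(protein_id = sub("[ |].*$", "", hdr),
                 gene_id = tok("gene"),
                 transcript_id = tok("transcript"),
                 seq = as.character(aa))
}

#' Spliced cDNA of a transcript
#'
#' Concatenates the exon sequences in transcription order (5' to 3';
#' reverse-complemented on the minus strand), returning the sequence
#' together with a positional map from each cDNA offset to its genomic
#' coordinate -- the bijection used later to place peptides back on the
#' genome.
#'
#' @param ts A [transcript_set()].
#' @param transcript_id Transcript to splice.
#' @param genome `DNAStringSet`.
#' @return List: `seq` (character), `map` (integer vector, `map[i]` is the
#'   genomic position of cDNA base `i`), `chrom`, `strand`.
#' @export
spliced_cdna <- function(ts, transcript_id, genome) {
  ex <- transcript_exons(ts, transcript_id)
  chrom <- ex$chrom[1]
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (any(ex$end > length(genome[[chrom]]))) {
    stop("exon out of chromosome bounds for ", transcript_id)
  }
  pieces <- character(nrow(ex))
  maps <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    s <- Biostrings::subseq(genome[[chrom]], ex$start[i], ex$end[i])
    if (ex$strand[1] == "-") {
      s <- Biostrings::reverseComplement(s)
      maps[[i]] <- seq(ex$end[i], ex$start[i])
    } else {
      maps[[i]] <- seq(ex$start[i], ex$end[i])
    }
    pieces[i] <- toupper(as.character(s))
  }
  list(seq = paste(pieces, collapse = ""),
       map = as.integer(unlist(maps)),
       chrom = chrom,
       strand = if (ex$strand[1] == "-") "-" else "+")
}

#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code; codons containing `N` become `X`; stop codons are
#' rendered as `*`. Trailing bases short of a codon are dropped.
#'
#' @param seq Nucleotide string (`ACGTN`).
#' @param frame 0, 1 or 2 (offset into `seq`).
#' @return Amino-acid string (possibly empty).
#' @export
translate_nt <- function(seq, frame = 0L) {
  stopifnot(frame %in% 0:2)
  check_nt(seq)
  n <- nchar(seq) - frame
  n <- n - n %% 3L
  if (n < 3L) return("")
  sub <- substr(seq, frame + 1L, frame + n)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

check_nt <- function(seq) {
  if (grepl("[^ACGTNacgtn]", seq)) {
    stop("sequence contains non-ACGTN characters")
  }
  invisible(seq)
}

# Longest common substring of two strings.
# Returns length and 1-based start offsets; among equal-length matches the
# one starting earliest in `a` wins (5'-most match).
longest_common_substring <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(list(len = 0L, start_a = NA, start_b = NA))
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  prev <- integer(nb)
  best <- list(len = 0L, start_a = NA_integer_, start_b = NA_integer_)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    hit <- av[i] == bv
    cur[hit] <- c(0L, prev)[which(hit)] + 1L
    mx <- max(cur)
    if (mx > best$len) {
      j <- which.max(cur)
      best <- list(len = mx, start_a = i - mx + 1L, start_b = j - mx + 1L)
    }
    prev <- cur
  }
  best
}

# Positions (1-based) of ATG codons in Kozak context: purine at -3 and G at
# +4 relative to the A of the ATG (the gccRccATGG consensus core).
kozak_atg_positions <- function(seq) {
  atg <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  atg <- atg[atg > 0]
  if (length(atg) == 0L) return(integer(0))
  n <- nchar(seq)
  ok <- vapply(atg, function(i) {
    i >= 4L && (i + 3L) <= n &&
      substr(seq, i - 3L, i - 3L) %in% c("A", "G") &&
      substr(seq, i + 3L, i + 3L) == "G"
  }, logical(1))
  atg[ok]
}

#' Translate a full transcript, selecting the reading frame
#'
#' With a reference protein: the cDNA is translated in all three reading
#' frames (stop codons act as segment separators) and each frame is scored
#' by the length of its longest exact amino-acid match with the reference
#' protein. The highest-scoring frame wins (ties break to the lowest frame
#' index, then to the 5'-most match); the open reading frame is the
#' stop-free segment containing the match, i.e. the matched region trimmed
#' at its first stop codon.
#'
#' Without a reference protein the most likely open reading frame is chosen
#' from the 5'-most ATG in Kozak context, falling back to the 5'-most ATG
#' (closest methionine to the 5' end), translated up to the first stop. A
#' transcript with no ATG at all is untranslatable and returns an empty
#' protein flagged `method = "none"`.
#'
#' @param cdna Spliced cDNA sequence (character).
#' @param reference_protein Optional reference amino-acid sequence.
#' @param reference_protein_id Optional identifier recorded in the result.
#' @return List: `protein` (no stop symbol), `frame` (0/1/2), `orf_start`
#'   (1-based cDNA position of the first translated base), `method`
#'   (`reference`, `kozak`, `met` or `none`), `match_len`,
#'   `reference_protein_id`.
#' @export
translate_full <- function(cdna, reference_protein = NULL,
                           reference_protein_id = NA_character_) {
  check_nt(cdna)
  if (nchar(cdna) < 3L) stop("cDNA shorter than one codon")
  cdna <- toupper(cdna)
  if (!is.null(reference_protein) && nchar(reference_protein) > 0L) {
    best <- NULL
    for (f in 0:2) {
      pep <- translate_nt(cdna, f)
      m <- longest_common_substring(pep, reference_protein)
      if (is.null(best) || m$len > best$m$len) {
        best <- list(f = f, pep = pep, m = m)
      }
    }
    if (best$m$len > 0L) {
      pep <- best$pep
      stops <- c(0L, which(strsplit(pep, "")[[1]] == "*"), nchar(pep) + 1L)
      seg_start <- max(stops[stops < best$m$start_a]) + 1L
      seg_end <- min(stops[stops >= best$m$start_a + best$m$len]) - 1L
      protein <- substr(pep, seg_start, seg_end)
      return(list(protein = protein, frame = best$f,
                  orf_start = best$f + 1L + 3L * (seg_start - 1L),
                  method = "reference", match_len = best$m$len,
                  reference_protein_id = reference_protein_id))
    }
    # no amino-acid overlap with the reference: fall through to the
    # annotation-free heuristics
  }
  koz <- kozak_atg_positions(cdna)
  if (length(koz) > 0L) {
    start <- koz[1]
    method <- "kozak"
  } else {
    atg <- gregexpr("ATG", cdna, fixed = TRUE)[[1]]
    atg <- atg[atg > 0]
    if (length(atg) == 0L) {
      return(list(protein = "", frame = NA_integer_, orf_start = NA_integer_,
                  method = "none", match_len = 0L,
                  reference_protein_id = NA_character_))
    }
    start <- atg[1]
    method <- "met"
  }
  pep <- translate_nt(substr(cdna, start, nchar(cdna)), 0L)
  protein <- sub("\\*.*$", "", pep)
  list(protein = protein, frame = (start - 1L) %% 3L, orf_start = start,
       method = method, match_len = nchar(protein),
       reference_protein_id = NA_character_)
}

# Group sorted genomic positions into maximal runs of consecutive bases.
blocks_from_positions <- function(positions) {
  positions <- sort(unique(positions))
  if (length(positions) == 0L) return(data.frame(start = integer(0),
                                                 end = integer(0)))
  brk <- c(0L, which(diff(positions) != 1L), length(positions))
  data.frame(start = positions[brk[-length(brk)] + 1L],
             end = positions[brk[-1]])
}

#' Locate a captured fragment within the translated transcript
#'
#' The fragment's nucleotide sequence (spliced across its blocks,
#' strand-aware) is translated in all three frames and each frame's peptide
#' is matched against the transcript's full protein. The frame with the
#' longest exact match of at least `min_overlap_aa` amino acids wins (ties
#' break to the lowest frame). The matched protein window is then extended
#' by `peptide_len - 1` amino acids on each side (clipped to the protein)
#' so that every peptide of that length overlapping the fragment --
#' including junction-spanning ones -- can be generated from it. Stop
#' codons in the fragment's frame bound the match, so only the stop-free
#' portion is used.
#'
#' @param fragment One row of [capture_fragments()] output (list or
#'   single-row tibble with a `blocks` data frame).
#' @param translated Result of [translate_full()] for the source
#'   transcript.
#' @param cdna Result of [spliced_cdna()] for the source transcript.
#' @param min_overlap_aa Minimum fragment/protein overlap (amino acids).
#' @param peptide_len Peptide length used downstream (extension width).
#' @return List (`aa_seq`, `protein_start`, `protein_end`, `match_start`,
#'   `match_end`, `frame`, `extended`, `genomic_blocks`); when no frame
#'   qualifies, `aa_seq` is `NULL` and `reason` records why.
#' @export
translate_fragment <- function(fragment, translated, cdna,
                               min_overlap_aa = 8L, peptide_len = 9L) {
  if (is.null(translated$protein) || nchar(translated$protein) == 0L) {
    return(failed_region("untranslated_transcript"))
  }
  blocks <- fragment$blocks
  if (is.data.frame(blocks)) b <- blocks else b <- blocks[[1]]
  frag_pos <- unlist(Map(seq, b$start, b$end))
  idx <- which(cdna$map %in% frag_pos)
  if (length(idx) < 3L) return(failed_region("fragment_too_short"))
  frag_nt <- paste(strsplit(cdna$seq, "")[[1]][idx], collapse = "")
  best <- NULL
  for (f in 0:2) {
    pep <- translate_nt(frag_nt, f)
    if (nchar(pep) == 0L) next
    m <- longest_common_substring(pep, translated$protein)
    if (is.null(best) || m$len > best$m$len) best <- list(f = f, m = m)
  }
  if (is.null(best) || best$m$len < min_overlap_aa) {
    return(failed_region("no_frame_overlap"))
  }
  ps <- best$m$start_b
  pe <- best$m$start_b + best$m$len - 1L
  ps2 <- max(1L, ps - (peptide_len - 1L))
  pe2 <- min(nchar(translated$protein), pe + (peptide_len - 1L))
  cd_from <- translated$orf_start + 3L * (ps2 - 1L)
  cd_to <- translated$orf_start + 3L * pe2 - 1L
  gpos <- cdna$map[cd_from:cd_to]
  list(aa_seq = substr(translated$protein, ps2, pe2),
       protein_start = ps2, protein_end = pe2,
       match_start = ps, match_end = pe,
       frame = best$f,
       extended = (ps2 < ps) || (pe2 > pe),
       genomic_blocks = blocks_from_positions(gpos))
}

failed_region <- function(reason) {
  list(aa_seq = NULL, reason = reason)
}
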