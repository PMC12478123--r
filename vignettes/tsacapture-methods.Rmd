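---
title: "Capture-based prediction of non-canonical tumor-specific antigens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Capture-based prediction of non-canonical tumor-specific antigens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsacapture)
```

## The problem

Tumors present peptides on HLA molecules that do not come from coding
mutations: retained introns, transcription of intergenic loci, endogenous
retroviral (ERV) sequences, and isoforms expressed far above their level in
healthy tissue. These non-canonical tumor-specific antigens (ncTSAs) widen
the pool of immunotherapy targets, particularly for low-mutational-burden
tumors, but predicting them from RNA-seq alone requires a dedicated
filtering and translation strategy: the space of assembled tumor
transcripts is enormous, most of it is shared with healthy tissue, and
novel sequence has no annotated reading frame.

`tsacapture` implements that strategy as a library. It starts from
reference-guided transcript assemblies (StringTie-dialect GTF with `TPM`
and `cov` attributes) of a tumor sample and of a panel of healthy
controls, and ends at a table of candidate peptides with genomic
coordinates, expression and read-support metadata, HLA-binding labels, and
ERV annotation. Alignment and assembly themselves, HLA typing, and the
peptide-MHC predictor are outside the package: binding ranks enter through
a provider interface (a precomputed rank table, or a deterministic stub
for testing).

## The capture database

Control assemblies are concatenated and their exons merged (unstranded,
book-ended intervals merge — coverage is a property of genomic position,
and a zero-width gap is not a distinct uncovered region). Each merged
control region records the maximum transcript TPM and maximum exon
coverage over everything merged into it. The capture regions are then:

* **novel** — the per-chromosome complement of the control regions, i.e.
  positions with zero control coverage, labelled *intronic* where they
  overlap an annotated gene span and *intergenic* elsewhere. Regions
  straddling a gene boundary are split at the boundary so every region is
  purely one category (the field's tools label by position without
  defining partial overlap; splitting is the unambiguous choice).
* **differential** — control regions sparsely covered in health:
  maximum TPM strictly below 1 and maximum coverage strictly below 4
  (both configurable). Strictness follows the stated defaults of the
  sparsity rule; note this is deliberately distinct from the *inclusive*
  "control expression at most 1 TPM" gate used by the confirmation
  cascade (`table2_cascade()`), so the two thresholds are separate
  configuration keys.

Tumor exon chains intersected with these regions give *fragments*; clips
from consecutive exons of one transcript falling in the same region stay
together as one junction-spanning fragment. Fragments are kept when they
are at least 24 nt long (longer than 23) and their transcript clears the
expression gates: TPM ≥ 1 and coverage ≥ 4 for novel fragments, TPM ≥ 10
and coverage ≥ 16 for differential ones. "Covered by ≥ N reads" is read as
the transcript's mean coverage because the filter is applied per
transcript; per-peptide read counting happens later and separately.

## Per-transcript metrics

For every locus (assembler gene id; equivalently the transcript id minus
its last dot-suffix), `compute_metrics()` reports:

* `isoform_count` — number of isoforms at the locus;
* `TPM_iso_perc` — the transcript's TPM as a percentage of the locus TPM
  sum. A high value marks a clonal, dominant aberrant isoform, and doubles
  as a percent-spliced-in surrogate;
* `Exon_cov_ratio` — mean transcript coverage divided by each exon's own
  coverage; exons covered unlike the rest of the transcript stand out.
  A peptide's value is the minimum over the exons its blocks overlap —
  the conservative choice for junction-spanning peptides, where no single
  exon of origin exists.

## Translation and frame selection

Peptide generation translates the *whole* source transcript first, then
locates the fragment within it:

1. **Reference-guided.** When the assembler linked the transcript to an
   annotated gene with a protein, the spliced cDNA is translated in all
   three frames and each frame scored by the length of its longest exact
   amino-acid match with the reference protein (longest common substring —
   the only parameter-free reading of "longest overlap"). The best frame
   wins; ties break to the lowest frame index, then the 5'-most match.
   The ORF is the stop-free segment containing the match — the matched
   frame trimmed at its first stop codon.
2. **Annotation-free.** Without a reference protein, the ORF starts at the
   5'-most ATG in Kozak context, falling back to the 5'-most ATG. The
   Kozak context is the minimal canonical core: purine at −3 and G at +4
   relative to the A of the ATG. A transcript without any ATG is
   untranslatable and is flagged, not errored.

The fragment's spliced nucleotide sequence is then translated in three
frames and matched against the transcript protein; the longest match of at
least 8 amino acids selects the fragment's frame. Stop codons bound the
match, so only the stop-free portion is used. The matched window is
extended by L−1 residues on each side (L = peptide length, clipped to the
protein) — the minimal width guaranteeing that every L-mer overlapping
the fragment, including junction-spanning ones, can be generated. A
sliding window (step 1) then emits all L-mers, each carrying its genomic
blocks (split at exon junctions) and underlying nucleotide sequence
recovered through the cDNA-to-genome positional map.

One consequence of the extension is worth stating precisely: a peptide
spanning the boundary of a retained intron necessarily covers a few bases
of the flanking annotated exon, which *is* control-covered. The package's
tumor-specificity guarantee is therefore: captured novel **fragments**
never contain a control-covered base (checked per-base in the acceptance
suite), and every reported novel **peptide** covers at least one
zero-coverage base; peptides of purely intergenic transcripts satisfy the
strict zero-overlap form. Differential peptides live in annotated regions
by definition.

## Read support, SNP consensus, and peptide filters

Each candidate is checked against the read alignments: only high-quality
reads count (primary, non-duplicate, mapping quality ≥ 20 — "high
quality" has no single field-wide definition, so this conventional
minimal QC is configurable), and a read supports a peptide only if its
aligned
segments cover *every* base of every peptide block; spliced peptides thus
require compatibly spliced reads. Peptides with fewer than 2 supporting
reads are dropped; the reported `BAM_reads` is capped at 100. The cap
applies to the reported count only — the majority vote below uses all
spanning high-quality reads.

At every peptide base, the nucleotide supported by a strict majority
(> 50%) of the spanning reads replaces the reference base; ties keep the
reference, since no majority exists. The corrected sequence is
re-translated in the peptide's frame, so sample-specific SNPs appear at
the amino-acid level; an edit that introduces a stop codon invalidates the
window.

Novel candidates whose (corrected) sequence occurs among all L-mers of the
reference proteome are removed as self-peptides. Differential candidates
are exempt — they derive from annotated transcripts, and their
tumor-specificity argument is expression, not sequence novelty.

Binding labels follow the standard percentile-rank convention: strong
binder below 0.5, weak binder below 2; candidates binding no allele are
removed. ERV overlap (≥ 1 base against an ERV BED) is an annotation only
and never changes a candidate's category. Two prioritization presets are
provided verbatim from the validation studies: `organoid`
(novel candidates, `TPM_iso_perc` ≥ 50, TPM > 3, `BAM_reads` > 5,
`Exon_cov_ratio` ≥ 0.8, one peptide per transcript by best rank) and
`glioblastoma` (strong binders with `TPM_iso_perc` = 100,
`Exon_cov_ratio` ≥ 0.8, TPM ≥ 1, `BAM_reads` ≥ 5).

## Cassette-exon inclusion

`inclusion_fraction()` quantifies a cassette event from isoform expression
alone. Transcripts *including* the exon show pre-exon, target and
post-exon as consecutive exons; *excluding* transcripts splice the
pre-exon directly to the post-exon. Matching is junction-exact at the
boundaries shared with the event, while outer transcript ends may differ:
assembly trims ends, but junctions are read-supported. All remaining
isoforms overlapping the pre-to-post span count as "others" — the span
rule is our bounding choice where none is stated. Class TPM sums are
converted to percentages of the three-class total (a PSI surrogate);
replicate percentages are averaged, and condition deltas are first minus
second, in concordance with delta-PSI conventions.

## The synthetic study conditions

`generate_fixture()` builds, deterministically from a seed, a 10-kb
single-chromosome genome with one planted feature per antigen class: a
retained intron inside an annotated two-exon gene (reference-guided
translation), a Kozak-initiated two-exon intergenic transcript
(junction-spanning peptides), a minus-strand differential transcript over
a control region expressed at 0.3–0.6 TPM and coverage 2 (below the
sparsity cuts) while the tumor expresses it at 50 TPM / coverage 20, an
ERV-overlapping intergenic transcript, a transcript whose reads carry an
alternative base at 70% frequency at one CDS position, and a three-exon
cassette gene with inclusion/exclusion isoforms at a 60% inclusion
fraction. Coding sequences are built by back-translating designed amino
acid sequences, which guarantees stop-free ORFs and controlled Kozak
contexts; twenty full-length spliced reads per transcript (mapping quality
60) are emitted both as a placement table and as SAM. The truth manifest
is derived from the construction itself — designed proteins, window
arithmetic, the self-peptide library and the deterministic rank stub —
not by running the pipeline, so end-to-end recovery is a genuine test.

What the generator does *not* emulate: sequencing errors, coverage
non-uniformity, multi-chromosome genomes, soft-clipped or indel-bearing
alignments, incomplete or fragmented assemblies, and realistic transcript
or proteome scale. Passing the planted-recovery test therefore
demonstrates the correctness of the algorithmic chain under clean
conditions, not robustness to assembly noise on real data.

For saturation studies the generator can add decoy tumor transcripts,
each covered by three controls of a six-control pool. Control subsets are
sampled *nested* within a replicate (prefixes of one seeded permutation),
so novel predictions are non-increasing along every replicate chain by
construction, and replicate agreement (the Jaccard ratio of the
intersection to the union of predicted sets across replicates) reaches 1
at the full pool.

Test and acceptance problem sizes — 10-kb chromosomes, ≤ 7 transcripts,
20 reads per transcript, 50 simulated cassette events with 10%
multiplicative log-normal TPM noise and 3 replicates, 20 fixture seeds for
the per-base overlap oracle — were chosen as the smallest sizes at which
every code path (both strands, junctions, all categories, SNP consensus,
saturation) is exercised.

## Numerical and convention choices

* Coordinates are 1-based inclusive `GRanges` internally; BED I/O
  converts at the boundary. One internal convention removes a whole class
  of off-by-one errors, and 1-based closed is the native convention of
  the R/Bioconductor container this package is built on.
* The capture BED score column carries the control maximum TPM, which can
  be fractional — hence the permissive BED6 reader/writer.
* All tie-breaks are deterministic and documented: lowest frame index,
  5'-most match, reference base on SNP ties. Output rows are stably
  sorted by (chromosome, first block start, peptide, allele), so reruns
  on identical inputs are byte-identical.
* Degenerate inputs are flagged, not guessed at: a zero-TPM locus reports
  `TPM_iso_perc` 0 with a flag, an uncovered exon reports an infinite
  coverage ratio, an ATG-less transcript is untranslatable, and an event
  with no expressed isoform reports `NA`.
* `removed_self_peptide_pct()` and `coefficient_of_variation()` implement
  the saturation summary statistics exactly as defined (the CV uses the
  sample standard deviation).

## Limitations

The package predicts from transcriptomic evidence only: peptides from
tumor-specific translational events (cryptic ORFs without transcript
support), gene fusions, indels and minor-allele SNPs are out of scope.
Class II support is limited to peptide length (15) and allele naming.
Binding ranks are taken from the provider as given; the stub provider is
a test instrument, not a predictor. Real-data performance depends on the
upstream assembler and on the size and tissue match of the control panel
— the saturation utilities exist precisely to let users measure that
dependence on their own data.
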