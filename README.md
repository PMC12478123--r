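# tsacapture

Capture-based prediction of non-canonical tumor-specific antigens
(ncTSAs) from assembled tumor transcriptomes.

Tumors present HLA-bound peptides that do not come from coding mutations:
retained introns, intergenic transcription, endogenous retroviral (ERV)
expression, and isoforms expressed far above their healthy-tissue level.
`tsacapture` predicts such peptides from reference-guided transcript
assemblies (StringTie-dialect GTF with `TPM`/`cov` attributes) of a tumor
sample against a panel of healthy controls. It is aimed at
immuno-oncology bioinformaticians who already run alignment, assembly,
HLA typing and a peptide–MHC predictor, and need the tumor-specificity
filtering, translation and annotation machinery in between.

## Method

The healthy controls define a **capture database**: their merged exon
regions carry the maximum control TPM and coverage, and the capture
regions are

- **novel** — the genomic complement of control coverage (zero control
  coverage), split at gene boundaries into `novel_intronic` /
  `novel_intergenic`; and
- **differential** — control regions with max TPM < 1 and max coverage
  < 4 (sparse in health).

Tumor exon chains intersected with these regions give fragments, kept when
longer than 23 nt and expressed (novel: TPM ≥ 1, coverage ≥ 4;
differential: TPM ≥ 10, coverage ≥ 16). Each source transcript is
translated — by three-frame comparison against its reference protein
(frame with the longest exact match, trimmed at the first stop) when
annotation links one, otherwise from the 5'-most Kozak-context ATG or the
closest Met. The fragment is located in the protein (≥ 8 aa exact
overlap), extended by L−1 residues per side for junction-spanning
peptides, and chopped into L-mers with genomic block tracking. Candidates
then pass read support (≥ 2 high-quality fully spanning reads, reported
count capped at 100), strict-majority SNP correction, a self-peptide
filter against the reference proteome L-mers (novel categories only),
HLA-binder labelling (%rank < 0.5 strong, < 2 weak; non-binders removed),
and ERV overlap annotation. A separate module quantifies cassette-exon
inclusion as isoform TPM fractions (`TPM_iso_perc`, a PSI surrogate) and
between-condition deltas.

See the methods vignette (`vignettes/tsacapture-methods.Rmd`) for the full
model, parameter table and design rationale.

## Worked example

The package ships a deterministic fixture generator that plants one
antigen of every class on a 10-kb toy genome (intron retention,
intergenic, differential, ERV-overlapping, and a 70/30 SNP):

```r
library(tsacapture)

fx <- generate_fixture(fixture_spec(seed = 42), dir = "fx")
capture <- run_build_ref(fx$paths$controls, fx$paths$reference_gtf,
                         genome_sizes(fx$genome))
#> capture BED: 8 regions (7 novel, 1 differential)
write_capture_bed(capture, "fx/capture.bed")

res <- run_predict(fx$paths$tumor_gtf, fx$paths$genome, "fx/capture.bed",
                   proteome = fx$paths$proteome, erv_bed = fx$paths$erv_bed,
                   alignments = fx$paths$reads_tsv,
                   alleles = fx$paths$alleles, sample_id = "tumor")
#> [transcripts] 7
#> [fragments_captured] 5
#> [fragments_kept] 5
#> [peptide_windows] 85
#> [read_supported] 85
#> [non_self] 85
#> [binders] 65
#> [output_rows] 70

dplyr::count(res$table, category, erv)
#>   category         erv       n
#> 1 differential     FALSE    14
#> 2 novel_intergenic FALSE    32
#> 3 novel_intergenic TRUE      7
#> 4 novel_intronic   FALSE    17
```

The stage log shows the funnel: 7 assembled transcripts yield 5 captured
fragments, 85 nine-mer windows, all read-supported, none self, 65 unique
binders, 70 output rows (one per peptide–allele pair). Each row carries
the peptide, its exact genomic blocks, expression (`TPM`,
`TPM_iso_perc`), coverage metadata (`Exon_cov_ratio`, `BAM_reads`), the
reference and SNP-corrected nucleotide sequences (`REF_NT`,
`corrected_NT`), and the binding label:

```
peptide   category       chrom blocks      TPM BAM_reads allele      rank_pct binder_label
HAPCGLPFE novel_intronic chr1  1037-1063     5        20 HLA-B*07:02    0.653 WB
APCGLPFEQ novel_intronic chr1  1040-1066     5        20 HLA-A*02:01    1.76  WB
APCGLPFEQ novel_intronic chr1  1040-1066     5        20 HLA-B*07:02    0.126 SB
```

Every reported peptide matches the generator's truth manifest — category,
SNP-corrected sequence and ERV flag — with no extras. The packaged
23-row worked example of published ncTSA calls runs through the same
confirmation cascade:

```r
sum(table2_cascade(read_table2())$confirmed)
#> [1] 4
```

A command-line wrapper over the same functions is at
`inst/cli/tsacapture.R` (`build-ref`, `predict`, `exon-inclusion`,
`saturate`, `simulate` subcommands).

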