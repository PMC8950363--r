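# igloci

Annotation and characterization of immunoglobulin (IG) germline loci in R.

Antibody heavy (IGH) and light chain (IGK, IGL) loci hold hundreds of
variable (V), diversity (D), joining (J) and constant (C) genes — many of
them pseudogenes, duplicated, or inverted within the locus. Curating such a
locus means classifying V genes into subgroups, naming genes and alleles,
deciding the functionality of every allele, and describing the non-coding
machinery around the genes: the V(D)J recombination signals (RS) and the
promoter elements of the 5' UTR. `igloci` implements this curation pipeline
for people who build or audit germline gene repertoires: immunogenetics
curators, AIRR-seq reference builders, and comparative immunologists.

## What it computes

* **Locus model** — strand-aware coordinate arithmetic (1-based, GenBank
  convention), assembly-gap (N-run) detection, FASTA and GFF3 round-trips
  with the standard sub-region labels (L-PART1, V-INTRON, V-REGION, …).
* **Subgroups** — V genes sharing > 75% core nucleotide identity form a
  subgroup; the relation is closed by single linkage, with identity from a
  global affine-gap alignment (match 1 / mismatch 0, gap open 10 / extend
  0.5; terminal gap columns excluded). Pseudogene-only families are clans.
* **Nomenclature** — V genes numbered 3'→5', D/J/C genes 5'→3'; adjacent
  100%-identical copies get the terminal-`D` duplicate suffix; unlocalized
  genes get provisional `S` names; alleles `gene*NN` with the 100%-identity
  matching rule against a reference directory.
* **Functionality** — F / ORF / P calls: pseudogene on stop codons,
  frameshifts, missing initiation codon or truncation; ORF on non-canonical
  RS, splice defects, missing promoter elements, or non-conserved pivotal
  residues (C23, W41, hydrophobic 89, C104); functional otherwise. Mixed
  allele sets yield FO / FP / OP gene labels.
* **IMGT unique numbering** — template-based placement on the V-domain grid
  (FR1 1–26 … CDR3 105–117) with per-locus framework gap sets, middle-out
  CDR gapping, lettered insertions, CDR length triplets `[c1.c2.c3]`,
  conserved-residue reports and fixed-width protein displays.
* **Recombination signals** — heptamer/spacer/nonamer extraction under the
  12/23 spacer rule, position frequency matrices, plurality consensus with
  reported ties, and the canonical-RS rule (shared by >1 functional gene, or
  within one heptamer / two nonamer mutations of the locus consensus).
* **Promoters** — 500-bp 5' UTR extraction; octamer `ATGCAAAT` (heavy) and
  its inverted-complementary decamer `nnATTTGCAT` (light), TATA box (A/T
  run), CCCT element, pentadecamer with inner E-box, pyrimidine-rich region;
  ordered 3'→5' architecture assignment and per-subgroup summaries.
* **Synthetic loci** — a generator that plants all of the above with known
  ground truth (seeded, deterministic), used by the test suite for full
  round-trip verification.
* **Reporting** — gene tables, repertoire totals, CDR length distributions,
  and a consistency audit of the shipped published rhesus monkey (Mmul_10)
  repertoire tables.

## Worked example

Generate a small kappa-style locus with known truth, then run the full
annotation pipeline on it:

```r
library(igloci)
library(dplyr)

spec <- locus_spec(
  locus_id = "IGK",
  v_plan = tibble::tibble(
    subgroup = c("SG1", "SG2", "CLAN1"), clan = c(FALSE, FALSE, TRUE),
    n_f = c(5L, 3L, 0L), n_orf = c(3L, 0L, 0L), n_p = c(3L, 1L, 3L)
  ),
  n_j = 3L, n_c = 1L, n_unlocalized = 1L, duplications = 2L, seed = 42
)
synth <- generate_locus(spec)
synth$locus
#> <ig_locus> IGK | chrUn:1-28,575 (FWD) | 28575 bp | 2 gap(s) | span 29 kb

genes <- synth$genes[, c("gene_key", "gene_type", "start", "end", "strand",
                         "localized", "atg_position", "core")]
directory <- rename(synth$alleles, gene_name = gene_key)
ann <- annotate_locus(synth$locus, genes, synth$labels,
                      template = imgt_template("igkv"), directory = directory)
ann
#> <ig_annotation> IGK: 24 genes (F=14, ORF=3, P=7)

ann$consensus
#> # A tibble: 4 × 4
#>   side  element  consensus     n
#>   <chr> <chr>    <chr>     <int>
#> 1 J-RS  heptamer cactgtg       3
#> 2 J-RS  nonamer  ggtttttgt     3
#> 3 V-RS  heptamer cacagtg      12
#> 4 V-RS  nonamer  acaaaaacc    12

ann$annotations |> filter(gene_type == "V") |> gene_table() |> format()
#> # A tibble: 3 × 4
#>   group   functionality                       total_genes total_alleles
#>   <chr>   <chr>                                     <int>         <int>
#> 1 IGKV(I) 3 P (4)                                       3             4
#> 2 IGKV1   5 F (5), 2 FP (4), 3 O (3), 3 P (4)          13            16
#> 3 IGKV2   2 F (2), 1 FO (2), 1 P (2)                    4             6
```

The generator planted 8 functional, 3 ORF and 7 pseudogene alleles across
two subgroups and one clan (plus a duplicated gene, an unlocalized gene,
and mixed-functionality second alleles); the pipeline recovers every
functionality call, the subgroup partition, the duplicate's terminal-`D`
name, and the planted recombination-signal consensus (`cacagtg` /
`acaaaaacc` for the V side). Promoter architecture per gene reads, 3' to 5':

```r
utr <- extract_5utr(synth$locus, synth$genes$atg_position[2], synth$genes$strand[2])
architecture_key(annotate_promoter(utr, promoter_elements("IGK")))
#> [1] "TATA_BOX-CCCT_3-DECAMER-CCCT_5-PENTADECAMER"
```

Published worked-example arithmetic is available directly, e.g. the heavy
locus span from its chromosome coordinates:

```r
locus_span_kb(167900000, 169868564)
#> [1] 1969
```

## Scope

Gene *discovery* (locating genes on an unannotated assembly by homology
search), borne identification, phylogenetic subgroup confirmation, cDNA
rearrangement-evidence mining and database integration are out of scope:
the pipeline starts from a locus sequence plus gene coordinates (or from
its own synthetic loci) and performs the classification, numbering, signal
and promoter analysis downstream of that point.
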