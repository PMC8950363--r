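---
title: "Annotating immunoglobulin germline loci with igloci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating immunoglobulin germline loci with igloci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igloci)
library(dplyr)
```

## The problem

The antibody heavy (IGH) and light chain (IGK, IGL) loci are among the most
repetitive regions of a vertebrate genome: hundreds of variable (V) genes,
plus diversity (D, heavy chain only), joining (J) and constant (C) genes,
many of them pseudogenes, many duplicated, some inverted within the locus.
Curating such a locus means placing every gene, classifying V genes into
subgroups, naming genes and alleles consistently, deciding whether each
allele is functional, and describing the non-coding signals that make the
locus work: the V(D)J recombination signals (RS) and the promoter elements
upstream of each V gene. `igloci` implements this curation pipeline as
composable, tested R functions, together with a synthetic-locus generator
that provides fully known ground truth, and machine-readable copies of the
published rhesus monkey (Mmul_10) repertoire tables for cross-checking the
arithmetic of the reporting layer.

## Conventions and coordinate model

All coordinates are 1-based inclusive, the GenBank convention under which the
published locus positions are printed. A locus is always stored in its
5'→3' *locus* orientation; a locus on the reverse chromosome strand
(`orientation = "REV"`) stores the reverse complement of the chromosome
slice, and `chrom_to_locus_position()` / `locus_to_chrom_position()` are the
mutually inverse maps between the two systems. Genes inverted *within* the
locus are represented by a strand flag; their sub-region sequences are
reverse-complemented on demand by `extract_label_sequence()`, never at parse
time. Locus spans in kb round half up: that choice reproduces all three
published rhesus spans (1969, 1301, 1357 kb) from their printed coordinates.
Runs of `N` of any length count as assembly gaps, since no minimum is
established in the source material.

## Subgroups: the >75% rule

Two V genes belong to the same subgroup when their core (V-REGION)
nucleotide identity exceeds 75%. Three details are under-determined by that
sentence and are fixed here as follows:

* **Identity definition.** Global (Needleman–Wunsch) alignment with affine
  gaps (match 1, mismatch 0, gap opening 10, gap extension 0.5); identity is
  matches divided by alignment columns, *excluding terminal gap columns* so
  that a length difference at the ends is not punished twice. Gapped global
  identity is the conservative reading of "percentage of identity" for
  full-length germline cores.
* **Strictness.** "Greater than 75%" is taken literally: a pair at exactly
  0.750 is *not* grouped. Exact duplicates (identity 1) always stay
  together, at any threshold.
* **Non-transitivity.** The relation is closed by single linkage (connected
  components): a chain A–B (0.80), B–C (0.80) places A and C in one subgroup
  even at A–C = 0.70. This reproduces "assigned to the same subgroup" as an
  equivalence relation without arbitrary exclusions, and the per-pair
  evidence is retained for audit in the `evidence` attribute.

For all-against-all matrices, `identity_matrix()` optionally screens pairs
by shared 6-mer containment before aligning (the seed-and-filter idea behind
BLAST and CD-HIT); a pair sharing almost no 6-mers cannot approach the
subgroup threshold. The pipeline uses a cutoff of 0.12; passing
`prefilter = NULL` aligns every pair exactly.

Clusters that contain no functional gene are reported as *clans*
(pseudogene-only families) with parenthesized roman-numeral labels; clusters
containing at least one functional member become numbered subgroups, ordered
by size. Matching these synthetic-label partitions against a reference
nomenclature (human orthology) is out of scope; the partition itself is what
the round-trip tests score, via the adjusted Rand index.

## Nomenclature

V genes are numbered by locus position from 3' to 5' — the V gene closest to
the D/J cluster takes position 1 — while D, J and C genes number 5' to 3'.
An adjacent gene with a 100%-identical core is treated as a duplication and
receives its twin's name with a terminal `D`. Unlocalized genes get
provisional `S` names in input order. Alleles are `gene*NN`, two digits from
01; `match_allele()` assigns an existing name only on 100% core identity
(then the new sequence is a "sequence from the literature"), otherwise the
next free number, the new sequence becoming the reference.

## Functionality calling

`classify_functionality()` applies a strict hierarchy. Pseudogene (P):
in-frame stop codon, frameshift (coding length not a multiple of 3), missing
initiation codon (V genes), or truncated core. ORF: intact reading frame but
a non-canonical recombination signal, a defective splice site, a missing key
promoter element, or a non-conserved pivotal residue (C23, W41, hydrophobic
89, C104). Otherwise functional (F). Every triggered defect is reported, and
the call is monotone: adding a P-level defect can never improve a call. Genes
whose alleles disagree carry the mixed labels FO, FP, or (by symmetry, a case
the source tables never show) OP.

Functionality and RS canonicality are mutually dependent — the canonical-RS
rule compares against the consensus *of functional genes* — so the pipeline
makes two passes: a structural pass (stops, frameshifts, initiation codon,
splice sites) fixes a provisional functional set, which anchors the RS
consensus and the promoter checks, which then refine provisional-F alleles
into F or ORF. This mirrors manual curation practice, where coding-region
defects are decided before signal quality.

## IMGT unique numbering by template

The V-domain grid is FR1 1–26, CDR1 27–38, FR2 39–55, CDR2 56–65, FR3
66–104, CDR3 105–117, with conserved C23, W41, hydrophobic 89 and C104. The
full profile-based numbering algorithm is not re-implemented; instead,
numbering is template-driven: a template carries the framework gap set
characteristic of a locus (kappa-style: 26 FR1 residues, FR3 gaps at
73/81/82; lambda-style: 25 FR1 residues with a gap at position 10), and CDR
residues pack middle-out into their windows (extra residue on the 5' side,
gaps in the middle), with lettered insertions at each window's anchor
(15 for FR1, window midpoints for CDRs) when capacity is exceeded.

When CDR lengths are not supplied they are inferred by **anchor scoring**:
every partition of the sequence into FR1/CDR1/FR2/CDR2/FR3/CDR3 consistent
with the template is scored by how many conserved anchors it places
correctly (C23 and C104 and W41 weigh 2, hydrophobic-89 weighs 1), and the
best layout wins, smallest first on ties. Within-capacity layouts
(CDRs ≤ 12/10/13) are preferred; insertion layouts are considered only when
nothing fits. A domain that has *lost* an anchor (say W41 replaced, the very
situation that makes it ORF) can be genuinely ambiguous to anchor scoring,
so the pipeline adds a subgroup-profile pass: members of a cluster are
snapped to the cluster's modal CDR triplet whenever that layout is exactly
length-compatible and scores at least as well on the anchors. Genuine length
variants (an allele with a one-residue CDR deletion) are length-incompatible
with the modal triplet and keep their own inference. Domains with several
destroyed anchors and no informative subgroup may still number ambiguously;
that limitation is inherent to anchor-based placement without profile HMMs.

CDR length tables follow the reported conventions: only first alleles
(`*01`), out-of-frame pseudogenes excluded (they have no defined triplet),
in-frame pseudogenes shown separately.

## Recombination signals

The heptamer always abuts the core: 3' of a V-REGION, 5' of a J-REGION, and
on both flanks of a D-REGION with the heptamers facing the D. Spacer classes
follow the standard 12/23 rule (heavy V: 23, heavy D: 12 both sides, heavy
J: 23; kappa V: 12 / J: 23; lambda V: 23 / J: 12) and are configuration, not
hard-coded. Consensus is per-column plurality over functional sources;
ties resolve to the lexicographically smallest base *and are reported* —
deterministic and auditable, which matters because real loci do print two
co-dominant joining-heptamer variants rather than forcing one. The
canonical-RS rule is: canonical outright if the exact motif occurs in more
than one functional gene; otherwise a heptamer tolerates one mutation and a
nonamer two, measured against the locus consensus — against the *minimum*
over variants when the consensus itself is ambiguous, since the tolerance
clause does not say which variant anchors it. Signals beyond tolerance are
flagged as possible rearrangement-evidence exceptions rather than silently
dropped.

## Promoter architecture

`extract_5utr()` trims up to 500 bp immediately upstream of the initiation
codon, strand-corrected; offsets count nucleotides upstream of the A of ATG,
with the element's 3'-most base as its primary offset, so sorted offsets
read 3'→5'. Element definitions are data (`promoter_elements()`):

* Heavy chain, 3'→5': TATA box, octamer `ATGCAAAT`, heptanucleotide,
  pyrimidine-rich region, with E-boxes (`CAnnTG`) auxiliary.
* Light chains: TATA box, CCCT element, decamer `nnATTTGCAT` — the octamer
  in inverted complementary form with two extra 5' bases, an identity the
  test suite asserts as a motif-table self-check — a second CCCT, and the
  pentadecamer `TGCAnCTGTGnCCAG` with its inner E-box. `TCCT` is accepted as
  a configurable CCCT variant (one kappa subgroup uses it).

The TATA box has no single consensus and is operationalized as a run of
five or more consecutive A/T within its window. The pyrimidine-rich region
is described but never quantified in the source; the default rule — maximal
regions assembled from ≥10-nt windows with ≥80% C/T — is configurable. The
heptanucleotide has no published consensus at all; it is an empty slot that
skips silently unless the user supplies a pattern. Annotation walks the
canonical order 3'→5' greedily: each element is searched within its offset
window, strictly 5' of the previously assigned element; the match closest to
the window center wins, ties going 3'-ward. Missing elements are data, not
errors. `subgroup_architecture()` then summarizes presence fractions, offset
means and ranges, and per-column consensus of the matched sequences per
subgroup.

## The synthetic-locus generator

`locus_spec()` + `generate_locus()` build loci with fully known truth. Gene
anatomy: a 500-nt UTR carrying the planted promoter architecture; a leader
split L-PART1 (46 nt, starting ATG) / V-INTRON (GT…AG) / L-PART2 (11 nt), so
leader length is a codon multiple and the V-REGION translates in frame 0; the
V-REGION built from a subgroup founder with planted CDR lengths and
conserved anchors; then heptamer–spacer–nonamer. Defects are planted so the
planned functionality is guaranteed under the calling rules: an in-frame TAA
(P), a single-base deletion (P), ATG→ATA (P), donor GT→AT (ORF), a heptamer
with three substitutions (ORF), W41→R (ORF), or a deleted octamer/decamer
(ORF). Subgroup members diverge from their founder at 5% per base with
repairs that revert any mutation creating a stop or touching an anchor, so
within-subgroup identity stays near 90% and cross-subgroup identity (between
independent random founders) far below the 75% threshold.

Two generator subtleties deserve a note. First, UTR backgrounds are
*sanitized*: accidental matches of any scanned element pattern, stray A/T
runs, and (heavy chain) stray pyrimidine-rich windows are deterministically
redrawn so the planted elements are the only signals in their windows —
otherwise exact offset recovery would be impossible to assert. The
pyrimidine-rich element's truth is recorded as its own windowed rule's
maximal region, since the rule, not the planted string, defines that
element. Second, a duplicated gene gets an identical core but freshly built
flanks: a duplicated *broken* heptamer would otherwise occur in two
provisional-functional genes and become canonical under the occurrence
clause, silently converting the planned ORF into F — the rule working
exactly as specified, on an input the plan did not intend.

Defaults are the study conditions: the heavy-locus subgroup structure (228 V
genes across 8 subgroups and 3 clans with the published functionality mix,
45 D in 7 sets, 7 J, 8 C), published consensus RS motifs, intergenic spacing
of 100–300 nt — about one tenth of physical scale, which preserves every
structural relationship the pipeline tests while keeping a full round trip
near three minutes. Unit tests run reduced loci (about 20 genes, seconds
each); the acceptance script runs the full default scale.

## Reporting and the consistency audit

`gene_table()` aggregates per-gene labels into the standard gene-table shape
(genes per group and functionality, allele counts in parentheses semantics);
mixed-label genes count once under their mixed label, matching the published
presentation. `repertoire_summary()` sums to per-locus and overall totals
and is associative. `consistency_check()` re-adds every shipped printed
total from its printed addends and lists disagreements without correcting
them. On the shipped rhesus tables exactly one disagreement appears: the
kappa locus allele total is printed as 214 while its per-type addends sum to
213. The package surfaces this discrepancy; it does not resolve it.

## What the tests do and do not show

The synthetic round trip proves internal consistency: every rule the
generator encodes is recovered by the analysis side exactly (functionality,
subgroup partition at adjusted Rand index 1, RS strings, promoter offsets,
CDR triplets), at substitution rate 0 and with unambiguous planted defects.
Real genomic data differ in ways the generator deliberately does not
emulate: indel processes and phylogenetic correlation between subgroup
members, promoter elements at subgroup-specific rather than shared offsets,
RS spacer-length polymorphism, truncated genes at contig edges, and
borderline identity pairs near the 75% threshold. Passing tests therefore
validate the rules' implementation, not their adequacy for any particular
genome; the worked-example checks against the published rhesus tables tie
the arithmetic, consensus and tolerance rules to real printed values.

## Reduced problem sizes

Unit tests use loci of roughly 15–25 genes per locus type; the full
acceptance round trip uses the default 291-gene heavy locus. These sizes
were chosen so the complete suite runs in well under fifteen minutes on a
single CPU with the synthetic full-pipeline round trip well under its
two-minute target at test scale.
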