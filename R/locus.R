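# Locus sequences, coordinate arithmetic and the standard file formats.
#
# All coordinates are 1-based inclusive (GenBank convention). A locus sequence
# is always stored in its 5'->3' *locus* orientation; for loci that lie on the
# reverse strand of a chromosome (orientation "REV") the stored sequence is the
# reverse complement of the chromosome slice.

VALID_NT <- c("A", "C", "G", "T", "N")

#' Construct an immunoglobulin locus sequence
#'
#' Bundles a locus identifier, its chromosomal placement and the nucleotide
#' sequence in 5'->3' locus orientation. Assembly gaps (runs of `N`) are
#' detected on construction.
#'
#' @param locus_id Locus identifier, one of `"IGH"`, `"IGK"`, `"IGL"` (other
#'   identifiers are allowed for synthetic loci).
#' @param sequence Nucleotide sequence (single string over `A,C,G,T,N`,
#'   case-insensitive) in 5'->3' locus orientation.
#' @param chromosome Chromosome name.
#' @param chrom_start,chrom_end 1-based inclusive chromosome coordinates of the
#'   locus. Defaults place the locus at the start of an anonymous chromosome.
#' @param orientation `"FWD"` if the locus runs 5'->3' along the chromosome,
#'   `"REV"` otherwise.
#'
#' @return An object of class `ig_locus`: a list with fields `locus_id`,
#'   `chromosome`, `chrom_start`, `chrom_end`, `orientation`, `sequence` and
#'   `gaps` (a tibble of N-run intervals in locus coordinates).
#' @export
#' @examples
#' loc <- ig_locus("IGH", "ACGTNNNNACGT")
#' loc$gaps
ig_locus <- function(locus_id, sequence, chromosome = "chrUn",
                     chrom_start = 1L, chrom_end = chrom_start + nchar(sequence) - 1L,
                     orientation = c("FWD", "REV")) {
  orientation <- match.arg(orientation)
  sequence <- check_nucleotides(sequence)
  if (chrom_end < chrom_start) {
    abort("`chrom_end` must be >= `chrom_start`.")
  }
  if (chrom_end - chrom_start + 1L != nchar(sequence)) {
    abort(sprintf(
      "sequence length (%d) does not match the chromosome interval (%d bp)",
      nchar(sequence), chrom_end - chrom_start + 1L
    ))
  }
  structure(
    list(
      locus_id = locus_id, chromosome = chromosome,
      chrom_start = as.integer(chrom_start), chrom_end = as.integer(chrom_end),
      orientation = orientation, sequence = sequence,
      gaps = detect_gaps(sequence)
    ),
    class = "ig_locus"
  )
}

#' @export
print.ig_locus <- function(x, ...) {
  cat(sprintf(
    "<ig_locus> %s | %s:%s-%s (%s) | %d bp | %d gap(s) | span %d kb\n",
    x$locus_id, x$chromosome,
    format(x$chrom_start, big.mark = ","), format(x$chrom_end, big.mark = ","),
    x$orientation, nchar(x$sequence), nrow(x$gaps),
    locus_span_kb(x$chrom_start, x$chrom_end)
  ))
  invisible(x)
}

#' @export
glance.ig_locus <- function(x, ...) {
  tibble(
    locus_id = x$locus_id, chromosome = x$chromosome,
    chrom_start = x$chrom_start, chrom_end = x$chrom_end,
    orientation = x$orientation, length_bp = nchar(x$sequence),
    span_kb = locus_span_kb(x$chrom_start, x$chrom_end),
    n_gaps = nrow(x$gaps)
  )
}

check_nucleotides <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence)) {
    abort("`sequence` must be a single character string.")
  }
  sequence <- toupper(sequence)
  bad <- which(!strsplit(sequence, "", fixed = TRUE)[[1]] %in% VALID_NT)
  if (length(bad) > 0) {
    abort(sprintf(
      "non-nucleotide character %s at position %d",
      substr(sequence, bad[1], bad[1]), bad[1]
    ))
  }
  sequence
}

#' Place a chromosome-strand sequence in 5'->3' locus orientation
#'
#' For a forward-orientation locus the input is returned unchanged; for a
#' reverse-orientation locus the reverse complement is returned (`N`
#' complements to `N`). The operation is an involution for `"REV"`.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param orientation `"FWD"` or `"REV"`.
#' @return The sequence in locus orientation (uppercase).
#' @export
#' @examples
#' flip_to_locus_orientation("AACG", "REV") # "CGTT"
flip_to_locus_orientation <- function(sequence, orientation = c("FWD", "REV")) {
  orientation <- match.arg(orientation)
  sequence <- check_nucleotides(sequence)
  if (orientation == "FWD") {
    return(sequence)
  }
  revcomp(sequence)
}

#' Reverse complement of a nucleotide string
#' @param sequence Nucleotide string (IUPAC codes accepted).
#' @return The reverse complement, preserving case pattern as uppercase.
#' @export
revcomp <- function(sequence) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(sequence)))
}

#' Map between chromosome and locus coordinates
#'
#' A locus stored in 5'->3' locus orientation indexes its sequence 1..L. For a
#' forward locus, locus position 1 is `chrom_start`; for a reverse locus it is
#' `chrom_end`. The two mappings are mutually inverse bijections on the locus
#' interval.
#'
#' @param p Position(s) to convert (integer vector).
#' @param locus An [ig_locus()].
#' @return Integer vector of converted positions.
#' @export
chrom_to_locus_position <- function(p, locus) {
  p <- as.integer(p)
  if (any(p < locus$chrom_start | p > locus$chrom_end)) {
    abort("position outside the locus chromosome interval")
  }
  if (locus$orientation == "FWD") p - locus$chrom_start + 1L else locus$chrom_end - p + 1L
}

#' @rdname chrom_to_locus_position
#' @export
locus_to_chrom_position <- function(p, locus) {
  p <- as.integer(p)
  len <- locus$chrom_end - locus$chrom_start + 1L
  if (any(p < 1L | p > len)) {
    abort("position outside the locus")
  }
  if (locus$orientation == "FWD") p + locus$chrom_start - 1L else locus$chrom_end - p + 1L
}

#' Locus span in kilobases
#'
#' Span of a chromosome interval rounded half-up to the nearest kilobase, the
#' convention under which the three rhesus IG locus coordinates reproduce their
#' published sizes (1969, 1301 and 1357 kb).
#'
#' @param chrom_start,chrom_end 1-based inclusive coordinates.
#' @return Integer span in kb.
#' @export
#' @examples
#' locus_span_kb(167900000, 169868564) # 1969
locus_span_kb <- function(chrom_start, chrom_end) {
  if (any(chrom_end < chrom_start)) {
    abort("`chrom_end` must be >= `chrom_start`.")
  }
  bp <- as.numeric(chrom_end) - as.numeric(chrom_start) + 1
  as.integer(floor(bp / 1000 + 0.5)) # round half up
}

#' Detect assembly gaps (runs of N)
#'
#' @param sequence Nucleotide string.
#' @return A tibble with columns `start`, `end`, `width`: the maximal runs of
#'   `N` (1-based inclusive, sorted, non-overlapping). Runs of any length >= 1
#'   count.
#' @export
#' @examples
#' detect_gaps("ACGTNNNNAC")
detect_gaps <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  is_n <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]] == "N"
  if (!any(is_n)) {
    return(tibble(start = integer(), end = integer(), width = integer()))
  }
  r <- rle(is_n)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep], width = r$lengths[keep])
}

#' Extract the sequence of a labeled interval
#'
#' Returns the locus subsequence `start..end`; if `strand` is `"-"` (the gene
#' is inverted within the locus) the reverse complement is returned, so the
#' result always reads 5'->3' on the gene's own strand.
#'
#' @param locus An [ig_locus()] or a plain nucleotide string.
#' @param start,end 1-based inclusive locus coordinates.
#' @param strand `"+"` (gene on the locus strand) or `"-"` (inverted).
#' @return Nucleotide string.
#' @export
extract_label_sequence <- function(locus, start, end, strand = "+") {
  seqstr <- if (inherits(locus, "ig_locus")) locus$sequence else locus
  if (start < 1 || end > nchar(seqstr) || end < start) {
    abort("interval outside the locus sequence")
  }
  s <- substr(seqstr, start, end)
  if (strand == "-") revcomp(s) else s
}

# ---- gene models as tidy tables ---------------------------------------------

CORE_LABEL <- c(V = "V-REGION", D = "D-REGION", J = "J-REGION", C = "C-REGION")

#' Core label for a gene type
#' @param gene_type `"V"`, `"D"`, `"J"` or `"C"`.
#' @return The IMGT core label, e.g. `"V-REGION"`.
#' @export
core_label <- function(gene_type) {
  unname(CORE_LABEL[match.arg(gene_type, names(CORE_LABEL), several.ok = TRUE)])
}

#' Validate a gene-model label table
#'
#' A gene model is described by one row per gene in `genes` (columns
#' `gene_name`, `gene_type`, `start`, `end`, `strand`, `localized`) plus one
#' row per labeled sub-region in `labels` (columns `gene_name`, `label`,
#' `start`, `end`). This checks the structural invariants: exactly one core
#' label per gene matching its type, and every label nested inside its gene's
#' interval.
#'
#' @param genes,labels Tibbles as described above.
#' @return `invisible(TRUE)`; aborts with an informative message otherwise.
#' @export
validate_gene_models <- function(genes, labels) {
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lab <- labels[labels$gene_name == g$gene_name, ]
    core <- lab[lab$label == CORE_LABEL[[g$gene_type]], ]
    if (nrow(core) != 1L) {
      abort(sprintf(
        "gene %s must carry exactly one %s label (found %d)",
        g$gene_name, CORE_LABEL[[g$gene_type]], nrow(core)
      ))
    }
    if (nrow(lab) && any(lab$start < g$start | lab$end > g$end)) {
      abort(sprintf("labels of gene %s extend outside its interval", g$gene_name))
    }
  }
  invisible(TRUE)
}

# ---- FASTA / GFF3 -----------------------------------------------------------

#' Read and write locus FASTA
#'
#' Thin wrappers over Biostrings for the package's FASTA conventions.
#' Reference-directory FASTA headers are structured as
#' `<gene>*<allele>|<functionality>|<locus>`.
#'
#' @param path File path.
#' @return `read_locus_fasta()` returns a named character vector of sequences.
#' @export
read_locus_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_locus_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_locus_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sequences), path, width = 70L
  )
  invisible(path)
}

#' Parse reference-directory FASTA headers
#'
#' @param headers Character vector like `"IGKV1-5*01|F|IGK"`.
#' @return Tibble with columns `allele_ref`, `gene_name`, `allele_number`,
#'   `functionality`, `locus_id`.
#' @export
parse_directory_headers <- function(headers) {
  parts <- stringr::str_split_fixed(headers, stringr::fixed("|"), 3)
  allele <- parts[, 1]
  gene <- stringr::str_remove(allele, "\\*\\d+$")
  num <- suppressWarnings(as.integer(stringr::str_extract(allele, "(?<=\\*)\\d+$")))
  tibble(
    allele_ref = allele, gene_name = gene, allele_number = num,
    functionality = parts[, 2], locus_id = parts[, 3]
  )
}

#' Write / read gene models as GFF3
#'
#' One feature per gene (`type` = gene) and one per labeled sub-region, using
#' the IMGT label vocabulary in `Name=`. Round-trips bit-exactly through
#' [read_gene_models_gff3()].
#'
#' @param genes,labels Gene-model tables (see [validate_gene_models()]).
#' @param locus An [ig_locus()] (provides the sequence name).
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(genes, labels, locus, path) {
  seqnm <- locus$locus_id
  gene_gr <- GenomicRanges::GRanges(
    seqnames = seqnm,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand
  )
  S4Vectors::mcols(gene_gr) <- S4Vectors::DataFrame(
    source = "igloci", type = "gene",
    ID = genes$gene_name, Name = genes$gene_name,
    gene_type = genes$gene_type,
    localized = ifelse(genes$localized, "true", "false")
  )
  lab <- dplyr::left_join(labels, genes[, c("gene_name", "strand")], by = "gene_name")
  lab_gr <- GenomicRanges::GRanges(
    seqnames = seqnm,
    ranges = IRanges::IRanges(lab$start, lab$end),
    strand = lab$strand
  )
  S4Vectors::mcols(lab_gr) <- S4Vectors::DataFrame(
    source = "igloci", type = "region",
    ID = paste0(lab$gene_name, ":", lab$label),
    Name = lab$label, Parent = lab$gene_name,
    gene_type = NA_character_, localized = NA_character_
  )
  rtracklayer::export(c(gene_gr, lab_gr), path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @return `read_gene_models_gff3()` returns `list(genes = , labels = )`.
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as_tibble(as.data.frame(gr))
  genes <- df |>
    filter(.data$type == "gene") |>
    mutate(
      gene_name = as.character(.data$Name),
      strand = as.character(.data$strand),
      localized = .data$localized == "true"
    ) |>
    select("gene_name", gene_type = "gene_type", "start", "end", "strand", "localized") |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  labels <- df |>
    filter(.data$type == "region") |>
    mutate(
      gene_name = purrr::map_chr(.data$Parent, 1),
      label = as.character(.data$Name)
    ) |>
    select("gene_name", "label", "start", "end") |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  list(genes = genes, labels = labels)
}
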