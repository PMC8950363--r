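# Subgroup clustering, nomenclature, allele matching and functionality calls.

#' Pairwise nucleotide identity from a global alignment
#'
#' Aligns two sequences globally (Needleman-Wunsch with affine gaps; match 1,
#' mismatch 0, gap opening 10, gap extension 0.5) and returns the fraction of
#' identical columns among alignment columns, terminal gap columns excluded.
#' This is the identity used for the ">75%" subgroup rule.
#'
#' @param a,b Non-empty nucleotide strings.
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @export
#' @examples
#' percent_identity("AAAA", "AAAT") # 0.75
percent_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) {
    abort("sequences must be non-empty")
  }
  unname(percent_identity_to(toupper(b), toupper(a)))
}

# identity of each sequence in `patterns` against one `subject` (vectorized).
# Gapless alignments (the overwhelming majority under a gap opening cost of
# 10) take a counting fast path; alignments with indels fall back to explicit
# column-wise comparison with terminal gap columns excluded.
percent_identity_to <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global", substitutionMatrix = identity_submat(),
    gapOpening = 10, gapExtension = 0.5
  )
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::indel(aln)
  n_ind <- lengths(Biostrings::insertion(ind)) + lengths(Biostrings::deletion(ind))
  gapless <- n_ind == 0L & nchar(patterns) == nchar(subject)
  out <- ifelse(gapless, nm / (nm + nmm), NA_real_)
  for (k in which(!gapless)) {
    out[k] <- aligned_identity(
      as.character(Biostrings::alignedPattern(aln[k])),
      as.character(Biostrings::alignedSubject(aln[k]))
    )
  }
  out
}

# fraction of each sequence's 6-mers found in the other (containment of the
# smaller repertoire); a cheap upper-bound screen for high identity
kmer_containment <- function(sequences, width = 6L) {
  prof <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(sequences),
    width = width
  ) > 0
  shared <- tcrossprod(prof * 1L)
  n_kmers <- rowSums(prof)
  denom <- outer(n_kmers, n_kmers, pmin)
  shared / pmax(denom, 1L)
}

identity_submat <- function() {
  nt <- c("A", "C", "G", "T", "N")
  m <- matrix(0, 5, 5, dimnames = list(nt, nt))
  diag(m) <- 1
  m["N", "N"] <- 0 # N never counts as a match
  m
}

aligned_identity <- function(p, s) {
  pc <- strsplit(p, "", fixed = TRUE)[[1]]
  sc <- strsplit(s, "", fixed = TRUE)[[1]]
  gap <- pc == "-" | sc == "-"
  # drop terminal gap columns on either end
  keep <- rep(TRUE, length(pc))
  i <- 1L
  while (i <= length(gap) && gap[i]) {
    keep[i] <- FALSE
    i <- i + 1L
  }
  i <- length(gap)
  while (i >= 1L && gap[i]) {
    keep[i] <- FALSE
    i <- i - 1L
  }
  pc <- pc[keep]
  sc <- sc[keep]
  if (length(pc) == 0L) {
    return(0)
  }
  sum(pc == sc & pc != "-" & pc != "N") / length(pc)
}

#' All-against-all identity matrix
#'
#' @param sequences Named character vector of nucleotide sequences.
#' @param prefilter Optional shared-6-mer containment cutoff: pairs below it
#'   are not aligned and get identity 0. At any plausible subgroup threshold a
#'   pair with almost no shared 6-mers cannot be highly identical, so this
#'   skips the quadratic bulk of far pairs (the seed-and-filter idea behind
#'   BLAST and CD-HIT). `NULL` (default) aligns every pair exactly.
#' @return A symmetric numeric matrix of pairwise identities (diagonal 1).
#' @export
identity_matrix <- function(sequences, prefilter = NULL) {
  n <- length(sequences)
  nms <- names(sequences) %||% as.character(seq_len(n))
  m <- diag(1, n)
  dimnames(m) <- list(nms, nms)
  if (n < 2L) {
    return(m)
  }
  keep <- if (is.null(prefilter)) {
    matrix(TRUE, n, n)
  } else {
    kmer_containment(toupper(sequences)) >= prefilter
  }
  for (i in seq_len(n - 1L)) {
    j <- which(keep[i, ] & seq_len(n) > i)
    if (length(j) == 0L) next
    ids <- percent_identity_to(sequences[j], sequences[i])
    m[i, j] <- ids
    m[j, i] <- ids
  }
  m
}

#' Cluster V genes into subgroups by the >75% identity rule
#'
#' Two genes belong to the same subgroup when their core sequences share a
#' nucleotide identity strictly greater than `threshold`; the partition is the
#' single-linkage closure (connected components) of that relation, so a chain
#' A-B, B-C places A and C together even if their direct identity falls below
#' the threshold. The result does not depend on input order: clusters are
#' numbered by their alphabetically smallest member.
#'
#' @param sequences Named character vector (names are gene identifiers) of core
#'   nucleotide sequences.
#' @param threshold Identity threshold; membership requires identity strictly
#'   greater than this value (default 0.75).
#' @param identities Optional precomputed [identity_matrix()].
#' @param prefilter Passed to [identity_matrix()] when `identities` is not
#'   supplied.
#' @return A tibble with columns `gene_name`, `cluster` (integer id) and an
#'   `evidence` attribute: a tibble of all above-threshold pairs with their
#'   identities.
#' @export
cluster_subgroups <- function(sequences, threshold = 0.75, identities = NULL,
                              prefilter = NULL) {
  if (length(sequences) < 1L) {
    abort("need at least one sequence")
  }
  nms <- names(sequences) %||% as.character(seq_along(sequences))
  m <- identities %||% identity_matrix(setNames(sequences, nms), prefilter = prefilter)
  adj <- m > threshold | m == 1 # exact duplicates stay together at any threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel components by alphabetically smallest member for order invariance
  first <- vapply(split(nms, comp), function(x) min(x), character(1))
  relabel <- match(names(sort(rank(first))), names(first))
  out <- tibble(
    gene_name = nms,
    cluster = match(comp, relabel)
  ) |> arrange(match(.data$gene_name, nms))
  ev_idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  attr(out, "evidence") <- tibble(
    gene_a = nms[ev_idx[, 1]], gene_b = nms[ev_idx[, 2]],
    identity = m[ev_idx]
  )
  out
}

#' Assign IMGT-style gene names
#'
#' V genes are numbered by locus position from 3' to 5' (the most 3' V gene
#' gets position 1); D, J and C genes are numbered 5' to 3'. Names take the
#' form `<subgroup>-<position>` (the subgroup label itself carries locus and
#' type, e.g. `IGHV3`). A gene whose core is 100% identical to an
#' already-numbered gene is treated as a duplicate and receives that gene's
#' name with a terminal `D`. Unlocalized genes receive provisional
#' `<subgroup>S<n>` names in input order. C genes are named by their isotype
#' label, with an ordinal appended when an isotype occurs more than once.
#'
#' @param genes A tibble with columns `gene_key` (input identifier),
#'   `gene_type`, `subgroup` (subgroup/clan/set label, or isotype for C genes),
#'   `start`, `end` (locus coordinates; `NA` for unlocalized genes),
#'   `localized` (logical) and `core` (core nucleotide sequence, used for
#'   duplicate detection).
#' @return The input tibble with a `gene_name` column appended.
#' @export
assign_gene_names <- function(genes) {
  stopifnot(all(c("gene_key", "gene_type", "subgroup", "start", "localized", "core") %in% names(genes)))
  out <- genes
  out$gene_name <- NA_character_
  for (tp in unique(genes$gene_type)) {
    idx <- which(genes$gene_type == tp & genes$localized)
    if (length(idx)) {
      ord <- if (tp == "V") idx[order(-genes$start[idx])] else idx[order(genes$start[idx])]
      if (tp == "C") {
        iso <- genes$subgroup[ord]
        nm <- iso
        dupiso <- iso[duplicated(iso)] # isotypes occurring more than once get ordinals
        for (d in unique(dupiso)) {
          k <- which(iso == d)
          nm[k] <- paste0(d, seq_along(k))
        }
        out$gene_name[ord] <- nm
      } else {
        pos <- 0L
        prev_core <- NA_character_
        prev_name <- NA_character_
        single_member <- length(ord) == 1L ||
          !anyDuplicated(genes$subgroup[ord]) # one gene per set: no hyphen number
        for (i in ord) {
          if (!is.na(prev_core) && toupper(genes$core[i]) == prev_core) {
            # adjacent identical copy: same position, terminal D
            out$gene_name[i] <- paste0(prev_name, "D")
          } else {
            pos <- pos + 1L
            out$gene_name[i] <- if (tp == "J" && single_member) {
              genes$subgroup[i]
            } else {
              paste0(genes$subgroup[i], "-", pos)
            }
            prev_core <- toupper(genes$core[i])
            prev_name <- out$gene_name[i]
          }
        }
      }
    }
    uidx <- which(genes$gene_type == tp & !genes$localized)
    if (length(uidx)) {
      for (sg in unique(genes$subgroup[uidx])) {
        k <- uidx[genes$subgroup[uidx] == sg]
        out$gene_name[k] <- paste0(sg, "S", seq_along(k))
      }
    }
  }
  if (anyDuplicated(out$gene_name)) {
    abort(sprintf(
      "gene name collision after suffixing: %s",
      paste(unique(out$gene_name[duplicated(out$gene_name)]), collapse = ", ")
    ))
  }
  out
}

#' Match a core sequence against a reference directory
#'
#' Allele identity requires 100% nucleotide identity of the core sequence. An
#' exact match returns the stored allele name with provenance
#' `"literature"`; otherwise the next free allele number for the gene is
#' assigned (a gene absent from the directory starts at `*01`) and the new
#' sequence becomes the reference, provenance `"reference"`.
#'
#' @param core_sequence Core nucleotide sequence to match.
#' @param directory A tibble with columns `gene_name`, `allele_number`, `core`.
#' @param gene_name Gene the sequence maps to.
#' @return A one-row tibble: `allele_name`, `gene_name`, `allele_number`,
#'   `provenance`, `is_new`.
#' @export
match_allele <- function(core_sequence, directory, gene_name) {
  core_sequence <- toupper(core_sequence)
  hits <- directory[toupper(directory$core) == core_sequence, , drop = FALSE]
  if (nrow(hits) > 0 && length(unique(hits$gene_name)) > 1L &&
    !gene_name %in% hits$gene_name) {
    abort(sprintf(
      "core matches alleles of multiple genes (%s); cannot resolve",
      paste(unique(hits$gene_name), collapse = ", ")
    ))
  }
  mine <- directory[directory$gene_name == gene_name, , drop = FALSE]
  exact <- mine[toupper(mine$core) == core_sequence, , drop = FALSE]
  if (nrow(exact) > 0) {
    num <- min(exact$allele_number)
    return(tibble(
      allele_name = allele_label(gene_name, num), gene_name = gene_name,
      allele_number = as.integer(num), provenance = "literature", is_new = FALSE
    ))
  }
  num <- if (nrow(mine) == 0) 1L else max(mine$allele_number) + 1L
  tibble(
    allele_name = allele_label(gene_name, num), gene_name = gene_name,
    allele_number = as.integer(num), provenance = "reference", is_new = TRUE
  )
}

#' IMGT allele label
#' @param gene_name Gene name.
#' @param allele_number Integer >= 1; rendered with two digits (`*01`).
#' @return e.g. `"IGKV1-5*01"`.
#' @export
allele_label <- function(gene_name, allele_number) {
  sprintf("%s*%02d", gene_name, as.integer(allele_number))
}

P_DEFECTS <- c("STOP_CODON", "FRAMESHIFT", "NO_INIT_CODON", "TRUNCATED")
ORF_DEFECTS <- c("SPLICE_DEFECT", "RS_DEFECT", "NONCONSERVED_AA", "REGULATORY_DEFECT")

#' Call the functionality of an allele
#'
#' Applies the F / ORF / P rules: a pseudogene (P) has an in-frame stop codon,
#' a frameshift, a missing initiation codon (V genes) or a truncated core; an
#' ORF has an intact reading frame but a non-canonical recombination signal, a
#' splice-site defect, a defective promoter, or a non-conserved pivotal amino
#' acid (C23, W41, hydrophobic 89, C104); an allele with none of these defects
#' is functional (F). Every triggered defect is reported.
#'
#' @param gene_type `"V"`, `"D"`, `"J"` or `"C"`.
#' @param translation Result of [translate_v_region()] on the coding region
#'   (for C genes, per exon), or `NULL` when no reading-frame check applies.
#' @param has_init_codon Does the gene model carry an `INIT-CODON` starting
#'   with ATG? Only required for V genes.
#' @param splice_ok,rs_canonical,promoter_ok Logical checks fed from the other
#'   modules (`NA` = not assessed, treated as passing).
#' @param conserved Optional [conserved_residues()] report for V domains.
#' @param truncated Is the core region truncated?
#' @return A list with `call` (`"F"`, `"ORF"` or `"P"`) and `defects`, a tibble
#'   of `code` + `detail` for every triggered defect.
#' @export
classify_functionality <- function(gene_type, translation = NULL,
                                   has_init_codon = TRUE, splice_ok = TRUE,
                                   rs_canonical = TRUE, promoter_ok = TRUE,
                                   conserved = NULL, truncated = FALSE) {
  gene_type <- match.arg(gene_type, c("V", "D", "J", "C"))
  defects <- tibble(code = character(), detail = character())
  add <- function(code, detail) {
    defects <<- bind_rows(defects, tibble(code = code, detail = detail))
  }
  if (!is.null(translation)) {
    if (is.null(translation$aa)) {
      abort("unresolvable reading frame: translation carries no amino-acid sequence")
    }
    if (length(translation$stop_codons) > 0) {
      add("STOP_CODON", paste0("in-frame stop at codon ", paste(translation$stop_codons, collapse = ",")))
    }
    if (isTRUE(translation$frameshift)) {
      add("FRAMESHIFT", "coding length not a multiple of 3")
    }
  }
  if (gene_type == "V" && !isTRUE(has_init_codon)) {
    add("NO_INIT_CODON", "initiation codon absent or not ATG")
  }
  if (isTRUE(truncated)) {
    add("TRUNCATED", "core region truncated")
  }
  if (identical(splice_ok, FALSE)) {
    add("SPLICE_DEFECT", "non-canonical splice site")
  }
  if (identical(rs_canonical, FALSE)) {
    add("RS_DEFECT", "non-canonical recombination signal")
  }
  if (identical(promoter_ok, FALSE)) {
    add("REGULATORY_DEFECT", "defective promoter element")
  }
  if (!is.null(conserved)) {
    fails <- conserved[!conserved$pass, , drop = FALSE]
    for (i in seq_len(nrow(fails))) {
      add("NONCONSERVED_AA", sprintf(
        "position %s is %s (expected %s)",
        fails$position[i], fails$residue[i], fails$expected[i]
      ))
    }
  }
  call <- if (any(defects$code %in% P_DEFECTS)) {
    "P"
  } else if (any(defects$code %in% ORF_DEFECTS)) {
    "ORF"
  } else {
    "F"
  }
  list(call = call, defects = defects)
}

#' Gene-level functionality label from allele calls
#'
#' A gene whose alleles agree carries the shared label; mixed allele sets are
#' labeled `FO` (functional or ORF), `FP` (functional or pseudogene) or `OP`
#' (ORF or pseudogene).
#'
#' @param calls Character vector of per-allele calls (`"F"`, `"ORF"`, `"P"`).
#' @return A single label.
#' @export
gene_functionality_label <- function(calls) {
  if (length(calls) < 1L) {
    abort("need at least one allele call")
  }
  u <- sort(unique(calls))
  if (length(u) == 1L) {
    return(u)
  }
  key <- paste(u, collapse = "+")
  switch(key,
    "F+ORF" = "FO",
    "F+P" = "FP",
    "ORF+P" = "OP",
    "F+ORF+P" = "FOP",
    abort(sprintf("unknown functionality mixture: %s", key))
  )
}
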