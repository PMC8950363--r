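# Synthetic IG loci with fully known ground truth.
#
# The generator builds an ordered locus of V / D / J / C gene units with the
# anatomy the annotation modules expect: a 500-nt 5' UTR carrying planted
# promoter elements, a leader split as L-PART1 (starting with the ATG
# initiation codon) / V-INTRON (canonical GT..AG) / L-PART2, a V-REGION built
# on a numbering template with planted CDR lengths and conserved anchors, and
# flanking recombination signals. Defects (stop codons, frameshifts, ATG loss,
# splice or RS damage, non-conserved residues, missing regulatory elements)
# are planted so that the planned functionality is guaranteed under the
# calling rules. Everything is deterministic for a fixed seed.

AA_CODONS <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})
AA_PLAIN <- setdiff(names(AA_CODONS), c("*", "C", "W")) # background residues

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit(
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rev_translate <- function(aa) {
  ch <- strsplit(aa, "", fixed = TRUE)[[1]]
  paste(vapply(ch, function(a) sample(AA_CODONS[[a]], 1L), character(1)),
    collapse = ""
  )
}

DEFAULT_RS_MOTIFS <- list(
  IGH = list(
    "V-RS" = c(heptamer = "cacagtg", nonamer = "acacaaacc"),
    "5'D-RS" = c(heptamer = "cactgtg", nonamer = "ggtttttgt"),
    "3'D-RS" = c(heptamer = "cacagtg", nonamer = "tcaaaaacc"),
    "J-RS" = c(heptamer = "cactgtg", nonamer = "ggtttttgt")
  ),
  IGK = list(
    "V-RS" = c(heptamer = "cacagtg", nonamer = "acaaaaacc"),
    "J-RS" = c(heptamer = "cactgtg", nonamer = "ggtttttgt")
  ),
  IGL = list(
    "V-RS" = c(heptamer = "cacagtg", nonamer = "acaaaaacc"),
    "J-RS" = c(heptamer = "cacagtg", nonamer = "ggtttttgt")
  )
)

default_promoter_plan <- function(locus_id) {
  if (locus_id == "IGH") {
    tibble(
      name = c("TATA_BOX", "OCTAMER", "PYRIMIDINE_RICH"),
      sequence = c("TATATAA", "ATGCAAAT", "TCCTCCTTCCTCCT"),
      offset = c(30L, 70L, 130L), jitter = c(3L, 5L, 5L)
    )
  } else {
    tibble(
      name = c("TATA_BOX", "CCCT_3", "DECAMER", "CCCT_5", "PENTADECAMER"),
      sequence = c("TATATAA", "CCCT", "AGATTTGCAT", "CCCT", "TGCAACTGTGACCAG"),
      offset = c(53L, 78L, 100L, 125L, 155L), jitter = c(3L, 3L, 5L, 3L, 8L)
    )
  }
}

default_v_plan <- function(locus_id) {
  # Heavy-chain study conditions: eight subgroups and three clans with the
  # per-subgroup functionality mix of the rhesus IGH repertoire.
  if (locus_id == "IGH") {
    tibble(
      subgroup = c(paste0("SG", 1:8), paste0("CLAN", 1:3)),
      clan = c(rep(FALSE, 8), rep(TRUE, 3)),
      n_f = c(11L, 5L, 39L, 19L, 2L, 1L, 2L, 0L, 0L, 0L, 0L),
      n_orf = c(0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
      n_p = c(14L, 1L, 38L, 6L, 1L, 0L, 12L, 2L, 6L, 35L, 32L)
    )
  } else {
    tibble(
      subgroup = c("SG1", "SG2", "SG3", "CLAN1"),
      clan = c(FALSE, FALSE, FALSE, TRUE),
      n_f = c(6L, 4L, 2L, 0L),
      n_orf = c(1L, 0L, 0L, 0L),
      n_p = c(2L, 2L, 1L, 3L)
    )
  }
}

#' Specification of a synthetic locus
#'
#' The defaults describe a heavy-chain-like locus: the per-subgroup V gene
#' functionality mix of the rhesus IGH repertoire (228 V genes in 8 subgroups
#' and 3 pseudogene-only clans), 45 D genes in 7 sets, 7 J and 8 C genes, with
#' published consensus RS motifs, subgroup-specific promoter architectures,
#' two assembly gaps and one gene duplication, at roughly 1/10 of the physical
#' scale (intergenic spacing 100-300 nt).
#'
#' @param locus_id Locus identifier; picks motif and promoter defaults.
#' @param v_plan Tibble (`subgroup`, `clan`, `n_f`, `n_orf`, `n_p`) giving the
#'   number of V genes per subgroup and planned functionality. Clan rows must
#'   be pseudogene-only.
#' @param n_d,n_d_sets,n_j,n_c Counts of D genes / D sets / J genes / C genes.
#' @param n_d_orf Number of D genes planted as ORF (RS defect).
#' @param p_defects Cycle of P-level defect codes used for planted pseudogenes.
#' @param orf_defects Cycle of ORF-level defect codes for planted ORF genes.
#' @param template [imgt_template()] used to build V regions.
#' @param cdr_menu List of CDR length triplets sampled per subgroup.
#' @param divergence Per-base substitution rate of subgroup members from their
#'   founder (0.05 keeps within-subgroup identity near 90%).
#' @param allele_sub_rate Per-base substitution rate of extra alleles relative
#'   to the first allele (0 makes every re-annotated allele match `*01`).
#' @param n_extra_alleles How many genes receive a second (same-functionality)
#'   allele.
#' @param n_fp,n_fo How many functional V genes receive a second allele with a
#'   pseudogene-level (stop) / ORF-level (non-conserved W41) defect, giving
#'   mixed FP / FO genes.
#' @param rs_motifs Per-side heptamer/nonamer motifs (defaults: published
#'   locus consensus strings).
#' @param promoter_plan Tibble (`name`, `sequence`, `offset`, `jitter`) of
#'   elements planted in every V 5' UTR; offsets are of the element's 3' edge,
#'   jittered uniformly per gene.
#' @param intergenic Range (min, max) of intergenic spacer lengths, nt.
#' @param inverted_fraction Fraction of V genes inverted within the locus.
#' @param gap_lengths Lengths of planted N-run assembly gaps.
#' @param duplications Indices (in generation order) of V genes to duplicate;
#'   see [plant_duplication()].
#' @param n_unlocalized Number of unlocalized V genes (cores without locus
#'   coordinates, provisional names).
#' @param utr_length Length of the sanitized promoter-bearing UTR segment.
#' @param seed Mandatory integer seed.
#' @return A list of class `locus_spec`.
#' @export
locus_spec <- function(locus_id = "IGH",
                       v_plan = default_v_plan(locus_id),
                       n_d = if (locus_id == "IGH") 45L else 0L,
                       n_d_sets = if (locus_id == "IGH") 7L else 0L,
                       n_d_orf = if (locus_id == "IGH") 1L else 0L,
                       n_j = if (locus_id == "IGH") 7L else 5L,
                       n_c = if (locus_id == "IGH") 8L else 1L,
                       p_defects = c("STOP_CODON", "FRAMESHIFT", "NO_INIT_CODON"),
                       orf_defects = c("RS_DEFECT", "NONCONSERVED_AA", "REGULATORY_DEFECT"),
                       template = imgt_template(switch(locus_id,
                         IGK = "igkv", IGL = "iglv", "ighv"
                       )),
                       cdr_menu = list(c(8L, 8L, 2L), c(8L, 10L, 2L), c(6L, 3L, 7L), c(9L, 8L, 2L)),
                       divergence = 0.05,
                       allele_sub_rate = 0,
                       n_extra_alleles = 3L,
                       n_fp = 2L, n_fo = 1L,
                       rs_motifs = DEFAULT_RS_MOTIFS[[locus_id]] %||% DEFAULT_RS_MOTIFS$IGH,
                       promoter_plan = default_promoter_plan(locus_id),
                       intergenic = c(100L, 300L),
                       inverted_fraction = 0.1,
                       gap_lengths = c(100L, 5120L),
                       duplications = 1L,
                       n_unlocalized = 2L,
                       utr_length = 500L,
                       seed) {
  if (missing(seed)) {
    abort("`seed` is mandatory")
  }
  stopifnot(divergence >= 0, divergence <= 1, allele_sub_rate >= 0, allele_sub_rate <= 1)
  if (any(v_plan$clan & (v_plan$n_f + v_plan$n_orf) > 0)) {
    abort("clan members must all be pseudogenes")
  }
  structure(
    list(
      locus_id = locus_id, v_plan = v_plan, n_d = n_d, n_d_sets = n_d_sets,
      n_d_orf = n_d_orf, n_j = n_j, n_c = n_c,
      p_defects = p_defects, orf_defects = orf_defects,
      template = template, cdr_menu = cdr_menu, divergence = divergence,
      allele_sub_rate = allele_sub_rate, n_extra_alleles = n_extra_alleles,
      n_fp = n_fp, n_fo = n_fo,
      rs_motifs = rs_motifs, promoter_plan = promoter_plan,
      intergenic = intergenic, inverted_fraction = inverted_fraction,
      gap_lengths = gap_lengths, duplications = as.integer(duplications),
      n_unlocalized = n_unlocalized, utr_length = utr_length, seed = seed
    ),
    class = "locus_spec"
  )
}

#' Add a gene duplication to a locus specification
#'
#' The generator inserts an exact copy immediately 5' of the target V gene;
#' the naming stage must then emit the terminal-`D` suffix for the copy.
#'
#' @param spec A [locus_spec()].
#' @param gene_index Index of the V gene (in generation order) to duplicate.
#' @return The modified spec.
#' @export
plant_duplication <- function(spec, gene_index) {
  spec$duplications <- sort(unique(c(spec$duplications, as.integer(gene_index))))
  spec
}

# ---- building blocks --------------------------------------------------------

make_founder_aa <- function(template, cdr) {
  frl <- template_fr_len(template)
  fr1 <- sample(AA_PLAIN, frl[["FR1"]], replace = TRUE)
  fr1[sum(setdiff(1:26, template$fr1_gaps) <= 23L)] <- "C"
  fr2 <- sample(AA_PLAIN, 17L, replace = TRUE)
  fr2[3L] <- "W"
  fr3 <- sample(AA_PLAIN, frl[["FR3"]], replace = TRUE)
  fr3_res <- setdiff(66:104, template$fr3_gaps)
  fr3[sum(fr3_res <= 89L)] <- "L"
  fr3[length(fr3)] <- "C"
  paste(c(
    fr1, sample(AA_PLAIN, cdr[1], replace = TRUE), fr2,
    sample(AA_PLAIN, cdr[2], replace = TRUE), fr3,
    sample(AA_PLAIN, cdr[3], replace = TRUE)
  ), collapse = "")
}

# substitute bases at `rate`, then revert any codon that gained a stop or
# broke a conserved anchor, so planted functionality is preserved
mutate_core <- function(nt, rate, template, cdr) {
  if (rate <= 0) {
    return(nt)
  }
  ch <- strsplit(nt, "", fixed = TRUE)[[1]]
  hit <- which(runif(length(ch)) < rate)
  if (length(hit) == 0) {
    return(nt)
  }
  orig <- ch
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  lay <- grid_layout(template, 0L, cdr[1], cdr[2], cdr[3])
  ai <- anchor_indices(template, lay)
  gc <- Biostrings::GENETIC_CODE
  for (cd in unique((hit - 1L) %/% 3L + 1L)) {
    idx <- (3L * cd - 2L):(3L * cd)
    new_aa <- gc[[paste(ch[idx], collapse = "")]]
    old_aa <- gc[[paste(orig[idx], collapse = "")]]
    anchor_broken <- (cd %in% ai) && new_aa != old_aa
    if (new_aa == "*" || anchor_broken) {
      ch[idx] <- orig[idx]
    }
  }
  paste(ch, collapse = "")
}

apply_core_defect <- function(core, defect, template, cdr) {
  lay <- grid_layout(template, 0L, cdr[1], cdr[2], cdr[3])
  ai <- anchor_indices(template, lay)
  n_codon <- nchar(core) %/% 3L
  mid <- setdiff(seq(10L, n_codon - 5L), ai)[1]
  switch(defect,
    STOP_CODON = paste0(
      substr(core, 1L, 3L * mid - 3L), "TAA",
      substr(core, 3L * mid + 1L, nchar(core))
    ),
    FRAMESHIFT = paste0(
      substr(core, 1L, 3L * mid), substr(core, 3L * mid + 2L, nchar(core))
    ),
    NONCONSERVED_AA = {
      i41 <- ai[["i41"]]
      paste0(
        substr(core, 1L, 3L * i41 - 3L), "CGG", # W41 -> R
        substr(core, 3L * i41 + 1L, nchar(core))
      )
    },
    core
  )
}

break_motif <- function(motif, n_mut = 3L) {
  ch <- strsplit(tolower(motif), "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(ch), n_mut)
  for (i in pos) {
    ch[i] <- sample(setdiff(c("a", "c", "g", "t"), ch[i]), 1L)
  }
  paste(ch, collapse = "")
}

# background sequence free of accidental promoter signals: the planted
# elements must be the only matches inside the scanned windows
sanitize_utr <- function(utr, planted, locus_id, max_iter = 100L) {
  elements <- promoter_elements(locus_id)
  pat <- elements[!is.na(elements$pattern) & elements$name != "E_BOX", , drop = FALSE]
  protected <- rep(FALSE, nchar(utr))
  for (i in seq_len(nrow(planted))) {
    protected[planted$start[i]:planted$end[i]] <- TRUE
  }
  for (iter in seq_len(max_iter)) {
    dirty <- integer(0)
    for (i in seq_len(nrow(pat))) {
      hits <- scan_pattern(utr, pat$pattern[i], pat$max_mismatches[i])
      for (k in seq_len(nrow(hits))) {
        planted_hit <- any(planted$start == hits$start[k] & planted$end == hits$end[k])
        if (planted_hit) next
        # a shifted hit overlapping a planted element is broken via its
        # unprotected flank positions
        span <- hits$start[k]:hits$end[k]
        dirty <- c(dirty, span[!protected[span]])
      }
    }
    # stray A/T runs would masquerade as TATA boxes (including runs that
    # extend a planted element across its boundary); stray pyrimidine-rich
    # windows matter only where that element is scanned (heavy chain)
    runs <- scan_at_run(utr)
    for (k in seq_len(nrow(runs))) {
      span <- runs$start[k]:runs$end[k]
      unprot <- span[!protected[span]]
      if (length(unprot) > 0) dirty <- c(dirty, unprot[1L])
    }
    if (locus_id == "IGH") {
      # a qualifying 10-window with >= 8 planted pyrimidines reaches at most 2
      # bases past the planted region, so the detected maximal region carries
      # a +-2 margin by construction; only growth beyond that margin (caused
      # by pyrimidine background) is redrawn
      margin <- protected
      prot_idx <- which(protected)
      for (d in 1:2) {
        margin[pmax(1L, prot_idx - d)] <- TRUE
        margin[pmin(length(margin), prot_idx + d)] <- TRUE
      }
      # margin bases must be purines or the qualifying windows keep creeping
      ch0 <- strsplit(utr, "", fixed = TRUE)[[1]]
      dirty <- c(dirty, which(margin & !protected & ch0 %in% c("C", "T")))
      pyr <- scan_pyrimidine_rich(utr)
      for (k in seq_len(nrow(pyr))) {
        span <- pyr$start[k]:pyr$end[k]
        unprot <- span[!margin[span]]
        dirty <- c(dirty, unprot[seq_len(min(3L, length(unprot)))])
      }
    }
    dirty <- setdiff(unique(dirty), which(protected))
    if (length(dirty) == 0) {
      return(utr)
    }
    ch <- strsplit(utr, "", fixed = TRUE)[[1]]
    ch[dirty] <- "G" # breaks A/T runs, pyrimidine windows and every pattern
    utr <- paste(ch, collapse = "")
  }
  abort("could not sanitize a synthetic UTR (raise max_iter)")
}

build_utr <- function(spec, drop_element = NULL) {
  L <- spec$utr_length
  utr <- rand_nt(L)
  plan <- spec$promoter_plan
  if (!is.null(drop_element)) {
    plan <- plan[plan$name != drop_element, , drop = FALSE]
  }
  placed <- list()
  for (i in seq_len(nrow(plan))) {
    e <- plan[i, ]
    off <- e$offset + sample(seq(-e$jitter, e$jitter), 1L)
    w <- nchar(e$sequence)
    end <- L - off + 1L
    start <- end - w + 1L
    utr <- paste0(substr(utr, 1L, start - 1L), e$sequence, substr(utr, end + 1L, L))
    placed[[i]] <- tibble(
      name = e$name, start = start, end = end,
      offset_start = off, sequence = e$sequence
    )
  }
  planted <- bind_rows(placed)
  utr <- sanitize_utr(utr, planted, spec$locus_id)
  # the pyrimidine-rich element is defined by its windowed rule, so its truth
  # is the rule's own maximal region on the final sequence
  pk <- which(planted$name == "PYRIMIDINE_RICH")
  if (length(pk) == 1L) {
    det <- scan_pyrimidine_rich(utr)
    hit <- det[det$start <= planted$end[pk] & det$end >= planted$start[pk], ]
    if (nrow(hit) == 1L) {
      planted$start[pk] <- hit$start
      planted$end[pk] <- hit$end
      planted$offset_start[pk] <- L - hit$end + 1L
      planted$sequence[pk] <- hit$sequence
    }
  }
  list(utr = utr, planted = planted)
}

# one V gene unit on its own + strand; relative coordinates
build_v_unit <- function(spec, core, defect) {
  utr_parts <- build_utr(
    spec,
    drop_element = if (identical(defect, "REGULATORY_DEFECT")) {
      if (spec$locus_id == "IGH") "OCTAMER" else "DECAMER"
    } else {
      NULL
    }
  )
  init <- if (identical(defect, "NO_INIT_CODON")) "ATA" else "ATG"
  lpart1 <- paste0(init, rand_nt(43L))
  donor <- if (identical(defect, "SPLICE_DEFECT")) "AT" else "GT"
  intron <- paste0(donor, rand_nt(80L), "AG")
  lpart2 <- rand_nt(11L)
  rs <- spec$rs_motifs[["V-RS"]]
  hept <- if (identical(defect, "RS_DEFECT")) break_motif(rs[["heptamer"]]) else rs[["heptamer"]]
  spacer <- tolower(rand_nt(rs_spacer_length(spec$locus_id, "V-RS")))
  seqs <- c(
    utr_parts$utr, lpart1, intron, lpart2, core,
    toupper(hept), toupper(spacer), toupper(rs[["nonamer"]])
  )
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs) + 1L
  labels <- tibble(
    label = c("L-PART1", "INIT-CODON", "V-INTRON", "L-PART2", "V-REGION", "V-RS"),
    start = c(starts[2], starts[2], starts[3], starts[4], starts[5], starts[6]),
    end = c(ends[2], starts[2] + 2L, ends[3], ends[4], ends[5], ends[8])
  )
  list(
    seq = paste(seqs, collapse = ""),
    labels = labels,
    atg_rel = starts[2],
    rs = tibble(
      side = "V-RS", heptamer = tolower(hept), spacer = spacer,
      nonamer = rs[["nonamer"]]
    ),
    promoters = utr_parts$planted |>
      mutate(offset_start = .data$offset_start) |>
      select("name", "offset_start", "sequence")
  )
}

build_d_unit <- function(spec, core, defect) {
  rs5 <- spec$rs_motifs[["5'D-RS"]]
  rs3 <- spec$rs_motifs[["3'D-RS"]]
  h5 <- if (identical(defect, "RS_DEFECT")) break_motif(rs5[["heptamer"]]) else rs5[["heptamer"]]
  sp5 <- tolower(rand_nt(rs_spacer_length(spec$locus_id, "5'D-RS")))
  sp3 <- tolower(rand_nt(rs_spacer_length(spec$locus_id, "3'D-RS")))
  seqs <- c(
    toupper(rs5[["nonamer"]]), toupper(sp5), toupper(h5), core,
    toupper(rs3[["heptamer"]]), toupper(sp3), toupper(rs3[["nonamer"]])
  )
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs) + 1L
  list(
    seq = paste(seqs, collapse = ""),
    labels = tibble(
      label = c("5'D-RS", "D-REGION", "3'D-RS"),
      start = c(starts[1], starts[4], starts[5]),
      end = c(ends[3], ends[4], ends[7])
    ),
    atg_rel = NA_integer_,
    rs = tibble(
      side = c("5'D-RS", "3'D-RS"),
      heptamer = c(tolower(h5), rs3[["heptamer"]]),
      spacer = c(sp5, sp3),
      nonamer = c(rs5[["nonamer"]], rs3[["nonamer"]])
    ),
    promoters = tibble(name = character(), offset_start = integer(), sequence = character())
  )
}

build_j_unit <- function(spec, core) {
  rs <- spec$rs_motifs[["J-RS"]]
  sp <- tolower(rand_nt(rs_spacer_length(spec$locus_id, "J-RS")))
  seqs <- c(toupper(rs[["nonamer"]]), toupper(sp), toupper(rs[["heptamer"]]), core)
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs) + 1L
  list(
    seq = paste(seqs, collapse = ""),
    labels = tibble(
      label = c("J-RS", "J-REGION"),
      start = c(starts[1], starts[4]), end = c(ends[3], ends[4])
    ),
    atg_rel = NA_integer_,
    rs = tibble(
      side = "J-RS", heptamer = rs[["heptamer"]], spacer = sp,
      nonamer = rs[["nonamer"]]
    ),
    promoters = tibble(name = character(), offset_start = integer(), sequence = character())
  )
}

build_c_unit <- function(core) {
  list(
    seq = core,
    labels = tibble(label = "C-REGION", start = 1L, end = nchar(core)),
    atg_rel = NA_integer_,
    rs = tibble(
      side = character(), heptamer = character(), spacer = character(),
      nonamer = character()
    ),
    promoters = tibble(name = character(), offset_start = integer(), sequence = character())
  )
}

# ---- the generator ----------------------------------------------------------

#' Generate a synthetic locus with known truth
#'
#' @param spec A [locus_spec()].
#' @return A list of class `ig_synthetic_locus`:
#'   * `locus`: the [ig_locus()] (sequence with planted gaps);
#'   * `genes`: truth table (gene_key, gene_type, subgroup, clan, start, end,
#'     strand, localized, functionality label, defect, core, atg_position,
#'     duplicate_of, cdr1/2/3);
#'   * `labels`: sub-region label table in locus coordinates;
#'   * `alleles`: the reference directory (gene_key, allele_number, core,
#'     functionality, defect);
#'   * `rs`: planted signal truth; `promoters`: planted element offsets;
#'   * `spec`: the input spec.
#' @export
generate_locus <- function(spec) {
  stopifnot(inherits(spec, "locus_spec"))
  with_seed(spec$seed, generate_locus_impl(spec))
}

generate_locus_impl <- function(spec) {
  tmpl <- spec$template
  # --- plan per-gene rows -----------------------------------------------
  vp <- spec$v_plan
  plan <- list()
  for (i in seq_len(nrow(vp))) {
    func <- c(
      rep("F", vp$n_f[i]), rep("ORF", vp$n_orf[i]), rep("P", vp$n_p[i])
    )
    if (length(func) == 0) next
    plan[[length(plan) + 1L]] <- tibble(
      subgroup = vp$subgroup[i], clan = vp$clan[i], functionality = func
    )
  }
  vplan <- bind_rows(plan)
  n_v <- nrow(vplan)
  vplan <- vplan[sample.int(n_v), ] # interleave subgroups along the locus
  vplan$defect <- NA_character_
  vplan$defect[vplan$functionality == "P"] <-
    rep_len(spec$p_defects, sum(vplan$functionality == "P"))
  vplan$defect[vplan$functionality == "ORF"] <-
    rep_len(spec$orf_defects, sum(vplan$functionality == "ORF"))

  # --- subgroup founders -------------------------------------------------
  sgs <- unique(vplan$subgroup)
  founders <- list()
  sg_cdr <- list()
  for (sg in sgs) {
    cdr <- spec$cdr_menu[[1L + (match(sg, sgs) - 1L) %% length(spec$cdr_menu)]]
    sg_cdr[[sg]] <- cdr
    founders[[sg]] <- rev_translate(make_founder_aa(tmpl, cdr))
  }

  # --- V gene units -------------------------------------------------------
  units <- list()
  vrows <- list()
  for (i in seq_len(n_v)) {
    sg <- vplan$subgroup[i]
    cdr <- sg_cdr[[sg]]
    core <- mutate_core(founders[[sg]], spec$divergence, tmpl, cdr)
    defect <- vplan$defect[i]
    core <- if (!is.na(defect)) apply_core_defect(core, defect, tmpl, cdr) else core
    u <- build_v_unit(spec, core, defect)
    units[[length(units) + 1L]] <- u
    vrows[[i]] <- tibble(
      gene_key = sprintf("V%03d", i), gene_type = "V",
      subgroup = sg, clan = vplan$clan[i],
      functionality = vplan$functionality[i], defect = defect,
      core = core, cdr1 = cdr[1], cdr2 = cdr[2], cdr3 = cdr[3],
      duplicate_of = NA_character_
    )
  }
  genes <- bind_rows(vrows)

  # duplications: a copy with an identical core inserted 5'-adjacent (just
  # before the target). Flanks (UTR, intron, RS) are rebuilt: a duplicated
  # RS-defect heptamer shared by two genes would otherwise become canonical
  # under the occurrence clause and break the planned ORF call.
  for (di in rev(sort(spec$duplications))) {
    if (di < 1 || di > length(units) || genes$gene_type[di] != "V") next
    g <- genes[di, ]
    g$gene_key <- paste0(g$gene_key, "dup")
    g$duplicate_of <- genes$gene_key[di]
    dup_unit <- build_v_unit(spec, g$core, g$defect)
    units <- append(units, list(dup_unit), after = di - 1L)
    genes <- bind_rows(genes[seq_len(di - 1L), ], g, genes[di:nrow(genes), ])
  }

  # --- D / J / C units ----------------------------------------------------
  if (spec$n_d > 0) {
    d_founders <- replicate(spec$n_d_sets, rand_nt(sample(14:22, 1L)))
    d_set <- rep_len(seq_len(spec$n_d_sets), spec$n_d)
    d_orf_idx <- if (spec$n_d_orf > 0) sample.int(spec$n_d, spec$n_d_orf) else integer(0)
    for (i in seq_len(spec$n_d)) {
      core <- d_founders[[d_set[i]]]
      defect <- if (i %in% d_orf_idx) "RS_DEFECT" else NA_character_
      units[[length(units) + 1L]] <- build_d_unit(spec, core, defect)
      genes <- bind_rows(genes, tibble(
        gene_key = sprintf("D%03d", i), gene_type = "D",
        subgroup = paste0("DSET", d_set[i]), clan = FALSE,
        functionality = if (is.na(defect)) "F" else "ORF", defect = defect,
        core = core, cdr1 = NA_integer_, cdr2 = NA_integer_, cdr3 = NA_integer_,
        duplicate_of = NA_character_
      ))
    }
  }
  for (i in seq_len(spec$n_j)) {
    core <- rev_translate(paste(sample(AA_PLAIN, 16L, replace = TRUE), collapse = ""))
    units[[length(units) + 1L]] <- build_j_unit(spec, core)
    genes <- bind_rows(genes, tibble(
      gene_key = sprintf("J%03d", i), gene_type = "J",
      subgroup = paste0("JSET", i), clan = FALSE,
      functionality = "F", defect = NA_character_,
      core = core, cdr1 = NA_integer_, cdr2 = NA_integer_, cdr3 = NA_integer_,
      duplicate_of = NA_character_
    ))
  }
  for (i in seq_len(spec$n_c)) {
    core <- rev_translate(paste(sample(AA_PLAIN, 100L, replace = TRUE), collapse = ""))
    units[[length(units) + 1L]] <- build_c_unit(core)
    genes <- bind_rows(genes, tibble(
      gene_key = sprintf("C%03d", i), gene_type = "C",
      subgroup = paste0("ISO", i), clan = FALSE,
      functionality = "F", defect = NA_character_,
      core = core, cdr1 = NA_integer_, cdr2 = NA_integer_, cdr3 = NA_integer_,
      duplicate_of = NA_character_
    ))
  }

  # --- assembly -----------------------------------------------------------
  n_units <- length(units)
  inverted <- rep(FALSE, n_units)
  v_idx <- which(genes$gene_type == "V")
  inverted[sample(v_idx, round(spec$inverted_fraction * length(v_idx)))] <- TRUE

  gap_after <- if (length(spec$gap_lengths)) {
    pmax(1L, floor(seq_along(spec$gap_lengths) * length(v_idx) /
      (length(spec$gap_lengths) + 1L)))
  } else {
    integer(0)
  }

  pieces <- character(0)
  pos <- 0L
  all_labels <- list()
  all_rs <- list()
  all_prom <- list()
  genes$start <- NA_integer_
  genes$end <- NA_integer_
  genes$strand <- "+"
  genes$atg_position <- NA_integer_
  for (i in seq_len(n_units)) {
    ig <- rand_nt(sample(spec$intergenic[1]:spec$intergenic[2], 1L))
    pieces <- c(pieces, ig)
    pos <- pos + nchar(ig)
    u <- units[[i]]
    ulen <- nchar(u$seq)
    if (inverted[i]) {
      useq <- revcomp(u$seq)
      lab <- u$labels |>
        mutate(
          new_start = ulen - .data$end + 1L,
          new_end = ulen - .data$start + 1L
        ) |>
        mutate(start = .data$new_start, end = .data$new_end) |>
        select("label", "start", "end")
      atg <- if (!is.na(u$atg_rel)) ulen - u$atg_rel + 1L else NA_integer_
      strand <- "-"
    } else {
      useq <- u$seq
      lab <- u$labels
      atg <- u$atg_rel
      strand <- "+"
    }
    pieces <- c(pieces, useq)
    genes$start[i] <- pos + 1L
    genes$end[i] <- pos + ulen
    genes$strand[i] <- strand
    genes$atg_position[i] <- if (!is.na(atg)) pos + atg else NA_integer_
    all_labels[[i]] <- lab |>
      mutate(gene_name = genes$gene_key[i], start = .data$start + pos, end = .data$end + pos) |>
      select("gene_name", "label", "start", "end")
    if (nrow(u$rs)) {
      all_rs[[length(all_rs) + 1L]] <- mutate(u$rs, gene_key = genes$gene_key[i])
    }
    if (nrow(u$promoters)) {
      all_prom[[length(all_prom) + 1L]] <- mutate(u$promoters, gene_key = genes$gene_key[i])
    }
    pos <- pos + ulen
    gi <- match(i, v_idx)
    if (!is.na(gi) && gi %in% gap_after) {
      for (k in which(gap_after == gi)) {
        gap <- strrep("N", spec$gap_lengths[k])
        pieces <- c(pieces, gap)
        pos <- pos + nchar(gap)
      }
    }
  }
  tail_seq <- rand_nt(sample(spec$intergenic[1]:spec$intergenic[2], 1L))
  pieces <- c(pieces, tail_seq)
  locus_seq <- paste(pieces, collapse = "")
  genes$localized <- TRUE

  # --- unlocalized genes ----------------------------------------------------
  if (spec$n_unlocalized > 0) {
    real_sgs <- sgs[!vp$clan[match(sgs, vp$subgroup)]]
    for (i in seq_len(spec$n_unlocalized)) {
      sg <- real_sgs[1L + (i - 1L) %% length(real_sgs)]
      core <- mutate_core(founders[[sg]], spec$divergence, tmpl, sg_cdr[[sg]])
      genes <- bind_rows(genes, tibble(
        gene_key = sprintf("U%03d", i), gene_type = "V",
        subgroup = sg, clan = FALSE, functionality = "F",
        defect = NA_character_, core = core,
        cdr1 = sg_cdr[[sg]][1], cdr2 = sg_cdr[[sg]][2], cdr3 = sg_cdr[[sg]][3],
        duplicate_of = NA_character_, start = NA_integer_, end = NA_integer_,
        strand = "+", atg_position = NA_integer_, localized = FALSE
      ))
    }
  }

  # --- alleles --------------------------------------------------------------
  alleles <- genes |>
    select("gene_key", "core", "functionality", "defect") |>
    mutate(allele_number = 1L, .before = "core")
  loc_v <- which(genes$gene_type == "V" & genes$localized & is.na(genes$duplicate_of))
  f_v <- loc_v[genes$functionality[loc_v] == "F"]
  extra <- list()
  pick <- function(pool, n) if (n > 0 && length(pool) > 0) sample(pool, min(n, length(pool))) else integer(0)
  fp_idx <- pick(f_v, spec$n_fp)
  fo_idx <- pick(setdiff(f_v, fp_idx), spec$n_fo)
  plain_idx <- pick(setdiff(loc_v, c(fp_idx, fo_idx)), spec$n_extra_alleles)
  for (i in c(fp_idx, fo_idx, plain_idx)) {
    g <- genes[i, ]
    cdr <- c(g$cdr1, g$cdr2, g$cdr3)
    core2 <- mutate_core(g$core, max(spec$allele_sub_rate, 0.005), tmpl, cdr)
    if (i %in% fp_idx) {
      core2 <- apply_core_defect(core2, "STOP_CODON", tmpl, cdr)
      fun2 <- "P"
      def2 <- "STOP_CODON"
    } else if (i %in% fo_idx) {
      core2 <- apply_core_defect(core2, "NONCONSERVED_AA", tmpl, cdr)
      fun2 <- "ORF"
      def2 <- "NONCONSERVED_AA"
    } else {
      fun2 <- g$functionality
      def2 <- g$defect
    }
    extra[[length(extra) + 1L]] <- tibble(
      gene_key = g$gene_key, allele_number = 2L, core = core2,
      functionality = fun2, defect = def2
    )
  }
  alleles <- bind_rows(alleles, bind_rows(extra))

  # gene-level functionality label from the allele set
  gene_label <- alleles |>
    group_by(.data$gene_key) |>
    summarise(label = gene_functionality_label(.data$functionality), .groups = "drop")
  # a duplicated copy is its own gene with its own (single-allele) set
  genes <- left_join(genes, gene_label, by = "gene_key")

  locus <- ig_locus(spec$locus_id, locus_seq)
  out <- list(
    locus = locus,
    genes = genes,
    labels = bind_rows(all_labels),
    alleles = alleles,
    rs = bind_rows(all_rs),
    promoters = bind_rows(all_prom),
    spec = spec
  )
  class(out) <- "ig_synthetic_locus"
  out
}

#' @export
print.ig_synthetic_locus <- function(x, ...) {
  cat(sprintf(
    "<ig_synthetic_locus> %s: %d genes (%s) on %d bp, seed %d\n",
    x$spec$locus_id, nrow(x$genes),
    paste(sprintf("%d %s", table(x$genes$gene_type)[c("V", "D", "J", "C")],
      c("V", "D", "J", "C")
    )[!is.na(table(x$genes$gene_type)[c("V", "D", "J", "C")])], collapse = ", "),
    nchar(x$locus$sequence), x$spec$seed
  ))
  invisible(x)
}

#' Write a synthetic locus to FASTA + GFF3 + truth TSV
#'
#' @param x An [generate_locus()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_synthetic_locus <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(x$spec$locus_id, ".fasta"))
  gff <- file.path(dir, paste0(x$spec$locus_id, ".gff3"))
  tsv <- file.path(dir, paste0(x$spec$locus_id, "_truth.tsv"))
  write_locus_fasta(setNames(x$locus$sequence, x$spec$locus_id), fa)
  loc_genes <- x$genes |>
    filter(.data$localized) |>
    select(gene_name = "gene_key", "gene_type", "start", "end", "strand", "localized")
  write_gene_models_gff3(loc_genes, x$labels, x$locus, gff)
  readr::write_tsv(x$genes, tsv)
  invisible(c(fa, gff, tsv))
}
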