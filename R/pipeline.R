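# The end-to-end annotation pipeline: classify -> number -> RS -> promoters.
#
# Functionality calling and RS canonicality are mutually dependent (the
# canonical rule needs the consensus over functional genes), so the pipeline
# runs two passes: a structural pass (stop codons, frameshifts, initiation
# codon, splice sites) defines the provisional functional set; the RS
# consensus, canonicality, promoter and conserved-residue checks then refine
# provisional-F alleles into F or ORF.

#' Annotate a locus from gene coordinates
#'
#' Runs the whole curation pipeline on a locus sequence with known gene
#' intervals (gene discovery is out of scope): core extraction, subgroup
#' clustering by the >75% rule, IMGT-style naming (with duplicate `D`
#' suffixes), structural and refined functionality calls, RS extraction with
#' consensus and canonicality, promoter architecture, V-domain numbering with
#' CDR lengths, and allele matching against an optional reference directory.
#'
#' @param locus An [ig_locus()].
#' @param genes Tibble with one row per gene: `gene_key`, `gene_type`,
#'   `start`, `end`, `strand`, `localized`; optional `atg_position` (locus
#'   coordinate of the A of the initiation codon on the gene strand) and
#'   `core` (required for unlocalized genes).
#' @param labels Sub-region label table (`gene_name` = `gene_key`, `label`,
#'   `start`, `end`); must carry the core label of every localized gene, and
#'   `INIT-CODON` / `V-INTRON` where those checks apply.
#' @param template [imgt_template()] for V-domain numbering.
#' @param directory Optional reference directory: `gene_name` (matching
#'   `gene_key`), `allele_number`, `core`, and optionally `functionality`
#'   (used for gene-level mixed labels).
#' @param elements Promoter element set; default [promoter_elements()] for the
#'   locus.
#' @param spacer_config Optional RS spacer table ([rs_spacer_length()]).
#' @param threshold Subgroup identity threshold (strictly greater than).
#' @param prefilter Shared-6-mer screen passed to [identity_matrix()]; the
#'   default 0.12 skips alignment of pairs that cannot approach the subgroup
#'   threshold. Set `NULL` to align every pair.
#' @return A list of class `ig_annotation`: `annotations` (per-gene tibble),
#'   `rs` (signals with canonicality), `consensus` (per side and element),
#'   `promoters` (per-gene element rows), `domains` (named list of numbered V
#'   domains), `subgroups` (cluster evidence).
#' @export
annotate_locus <- function(locus, genes, labels, template = imgt_template("ighv"),
                           directory = NULL,
                           elements = NULL, spacer_config = NULL,
                           threshold = 0.75, prefilter = 0.12) {
  locus_id <- locus$locus_id
  elements <- elements %||% promoter_elements(
    if (locus_id %in% c("IGH", "IGK", "IGL")) locus_id else "IGH"
  )
  genes <- as_tibble(genes)
  n <- nrow(genes)

  # ---- cores and structural checks --------------------------------------
  get_label <- function(key, lab) {
    hit <- labels[labels$gene_name == key & labels$label == lab, ]
    if (nrow(hit) == 1L) hit else NULL
  }
  core <- character(n)
  has_init <- rep(NA, n)
  splice_ok <- rep(NA, n)
  atg <- genes$atg_position %||% rep(NA_integer_, n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    if (isTRUE(g$localized)) {
      cl <- get_label(g$gene_key, CORE_LABEL[[g$gene_type]])
      if (is.null(cl)) {
        abort(sprintf("gene %s lacks its core label", g$gene_key))
      }
      core[i] <- extract_label_sequence(locus, cl$start, cl$end, g$strand)
      if (g$gene_type == "V") {
        ic <- get_label(g$gene_key, "INIT-CODON")
        if (!is.null(ic)) {
          codon <- extract_label_sequence(locus, ic$start, ic$end, g$strand)
          has_init[i] <- toupper(codon) == "ATG"
          if (is.na(atg[i])) {
            atg[i] <- if (g$strand == "+") ic$start else ic$end
          }
        } else {
          has_init[i] <- FALSE
        }
        vi <- get_label(g$gene_key, "V-INTRON")
        if (!is.null(vi)) {
          intron <- extract_label_sequence(locus, vi$start, vi$end, g$strand)
          splice_ok[i] <- startsWith(intron, "GT") && endsWith(intron, "AG")
        }
      }
    } else {
      if (is.null(genes$core) || is.na(genes$core[i])) {
        abort(sprintf("unlocalized gene %s needs a `core` column", g$gene_key))
      }
      core[i] <- toupper(genes$core[i])
      has_init[i] <- if (g$gene_type == "V") TRUE else NA
    }
  }

  translations <- vector("list", n)
  provisional <- character(n)
  for (i in seq_len(n)) {
    tp <- genes$gene_type[i]
    if (tp %in% c("V", "J", "C")) {
      translations[[i]] <- translate_v_region(core[i])
    }
    prov <- classify_functionality(
      tp,
      translation = translations[[i]],
      has_init_codon = if (tp == "V") isTRUE(has_init[i]) || is.na(has_init[i]) else TRUE,
      splice_ok = if (is.na(splice_ok[i])) TRUE else splice_ok[i]
    )
    provisional[i] <- prov$call
  }

  # ---- subgroup clustering ----------------------------------------------
  subgroup <- rep(NA_character_, n)
  clusters <- NULL
  v_idx <- which(genes$gene_type == "V")
  if (length(v_idx) > 0) {
    clusters <- cluster_subgroups(setNames(core[v_idx], genes$gene_key[v_idx]),
      threshold = threshold, prefilter = prefilter
    )
    memb <- split(seq_along(v_idx), clusters$cluster)
    is_sub <- vapply(memb, function(m) any(provisional[v_idx[m]] == "F"), logical(1))
    size <- vapply(memb, length, integer(1))
    three_prime <- vapply(memb, function(m) {
      s <- genes$start[v_idx[m]]
      if (all(is.na(s))) -Inf else max(s, na.rm = TRUE)
    }, numeric(1))
    ord_sub <- order(-size, -three_prime)
    sub_ids <- ord_sub[is_sub[ord_sub]]
    clan_ids <- ord_sub[!is_sub[ord_sub]]
    lab_map <- character(length(memb))
    lab_map[sub_ids] <- paste0(locus_id, "V", seq_along(sub_ids))
    lab_map[clan_ids] <- paste0(locus_id, "V(", as.character(utils::as.roman(seq_along(clan_ids))), ")")
    subgroup[v_idx] <- lab_map[clusters$cluster]
  }
  # D and J set labels by clustering, numbered by first 5'->3' occurrence
  for (tp in c("D", "J")) {
    idx <- which(genes$gene_type == tp)
    if (length(idx) == 0) next
    cl <- cluster_subgroups(setNames(core[idx], genes$gene_key[idx]),
      threshold = threshold, prefilter = prefilter
    )
    firsts <- vapply(split(seq_along(idx), cl$cluster), function(m) {
      min(genes$start[idx[m]], na.rm = TRUE)
    }, numeric(1))
    set_no <- match(cl$cluster, order(firsts))
    subgroup[idx] <- paste0(locus_id, tp, set_no)
  }
  c_idx <- which(genes$gene_type == "C")
  if (length(c_idx) > 0) {
    subgroup[c_idx] <- if (length(c_idx) == 1L) {
      paste0(locus_id, "C")
    } else {
      paste0(locus_id, "C", rank(genes$start[c_idx]))
    }
  }

  # ---- recombination signals --------------------------------------------
  loc_genes <- genes |>
    mutate(gene_name = .data$gene_key) |>
    filter(.data$localized)
  rs <- extract_rs(loc_genes, labels, locus, spacer_config)
  rs$provisional <- provisional[match(rs$gene_name, genes$gene_key)]
  consensus <- rs |>
    tidyr::pivot_longer(c("heptamer", "nonamer"),
      names_to = "element", values_to = "motif"
    ) |>
    filter(.data$provisional == "F") |>
    group_by(.data$side, .data$element) |>
    summarise(
      consensus = as.character(consensus_string(.data$motif)),
      n = dplyr::n(), .groups = "drop"
    )
  rs_ok <- rep(NA, n)
  if (nrow(rs) > 0) {
    f_motifs <- rs[rs$provisional == "F", ]
    rs$heptamer_canonical <- NA
    rs$nonamer_canonical <- NA
    for (k in seq_len(nrow(rs))) {
      for (el in c("heptamer", "nonamer")) {
        cons <- consensus$consensus[consensus$side == rs$side[k] &
          consensus$element == el]
        if (length(cons) == 0) next
        occ <- sum(f_motifs[[el]][f_motifs$side == rs$side[k]] == rs[[el]][k])
        v <- is_canonical_rs(rs[[el]][k], cons,
          element = el,
          functional_occurrence_count = occ
        )
        rs[[paste0(el, "_canonical")]][k] <- v$canonical
      }
    }
    by_gene <- rs |>
      group_by(.data$gene_name) |>
      summarise(
        ok = all(c(.data$heptamer_canonical, .data$nonamer_canonical), na.rm = TRUE),
        .groups = "drop"
      )
    rs_ok[match(by_gene$gene_name, genes$gene_key)] <- by_gene$ok
  }

  # ---- promoters ---------------------------------------------------------
  prom_rows <- list()
  promoter_ok <- rep(NA, n)
  key_element <- if (locus_id == "IGH") "OCTAMER" else "DECAMER"
  for (i in v_idx) {
    if (!isTRUE(genes$localized[i]) || is.na(atg[i])) next
    utr <- extract_5utr(locus, atg[i], genes$strand[i], check = FALSE)
    ann <- annotate_promoter(utr, elements)
    promoter_ok[i] <- any(ann$name == key_element & ann$found)
    prom_rows[[length(prom_rows) + 1L]] <- mutate(
      as_tibble(ann),
      gene_key = genes$gene_key[i], .before = 1
    )
  }
  promoters <- if (length(prom_rows)) bind_rows(prom_rows) else tibble()

  # ---- numbering ---------------------------------------------------------
  domains <- list()
  cdr <- matrix(NA_integer_, n, 3)
  conserved_reports <- vector("list", n)
  for (i in v_idx) {
    tr <- translations[[i]]
    if (isTRUE(tr$frameshift)) next # out-of-frame: no numbering
    dom <- tryCatch(number_v_domain(tr$aa, template), error = function(e) NULL)
    if (is.null(dom)) next
    domains[[genes$gene_key[i]]] <- dom
    cdr[i, ] <- cdr_lengths(dom)
  }
  # subgroup-profile pass: anchor-based inference is ambiguous when a
  # conserved residue is substituted (or duplicated by chance), so members
  # are snapped to their subgroup's modal CDR triplet whenever that layout is
  # length-compatible and scores at least as well on the anchors
  if (!is.null(clusters)) {
    for (cl_id in unique(clusters$cluster)) {
      mem <- v_idx[clusters$cluster == cl_id]
      mem <- mem[!is.na(cdr[mem, 1])]
      if (length(mem) < 2L) next
      trip <- apply(cdr[mem, , drop = FALSE], 1, paste, collapse = ".")
      modal <- as.integer(strsplit(names(which.max(table(trip))), ".", fixed = TRUE)[[1]])
      for (i in mem) {
        if (all(cdr[i, ] == modal)) next
        aa <- translations[[i]]$aa
        if (layout_score(aa, template, modal) >= layout_score(aa, template, cdr[i, ])) {
          dom <- tryCatch(number_v_domain(aa, template, cdr = modal),
            error = function(e) NULL
          )
          if (!is.null(dom)) {
            domains[[genes$gene_key[i]]] <- dom
            cdr[i, ] <- modal
          }
        }
      }
    }
  }
  for (i in v_idx) {
    dom <- domains[[genes$gene_key[i]]]
    if (!is.null(dom)) conserved_reports[[i]] <- conserved_residues(dom)
  }

  # ---- final functionality ----------------------------------------------
  calls <- character(n)
  defects <- vector("list", n)
  for (i in seq_len(n)) {
    tp <- genes$gene_type[i]
    res <- classify_functionality(
      tp,
      translation = translations[[i]],
      has_init_codon = if (tp == "V") isTRUE(has_init[i]) || is.na(has_init[i]) else TRUE,
      splice_ok = if (is.na(splice_ok[i])) TRUE else splice_ok[i],
      rs_canonical = if (is.na(rs_ok[i])) TRUE else rs_ok[i],
      promoter_ok = if (is.na(promoter_ok[i])) TRUE else promoter_ok[i],
      conserved = if (provisional[i] == "F") conserved_reports[[i]] else NULL
    )
    calls[i] <- res$call
    defects[[i]] <- res$defects
  }

  # ---- naming ------------------------------------------------------------
  named <- assign_gene_names(tibble(
    gene_key = genes$gene_key, gene_type = genes$gene_type,
    subgroup = subgroup, start = genes$start, end = genes$end,
    localized = genes$localized, core = core
  ))

  # ---- allele matching / gene-level labels -------------------------------
  allele_name <- rep(NA_character_, n)
  provenance <- rep(NA_character_, n)
  is_new <- rep(NA, n)
  n_alleles <- rep(1L, n)
  label <- calls
  if (!is.null(directory)) {
    for (i in seq_len(n)) {
      m <- match_allele(core[i], directory, genes$gene_key[i])
      allele_name[i] <- m$allele_name
      provenance[i] <- m$provenance
      is_new[i] <- m$is_new
      dirg <- directory[directory$gene_name == genes$gene_key[i], ]
      n_alleles[i] <- nrow(dirg) + as.integer(m$is_new)
      if ("functionality" %in% names(directory)) {
        other <- dirg$functionality[dirg$allele_number != m$allele_number | m$is_new]
        label[i] <- gene_functionality_label(c(calls[i], other))
      }
    }
  }

  annotations <- tibble(
    gene_key = genes$gene_key,
    gene_name = named$gene_name,
    gene_type = genes$gene_type,
    locus_id = locus_id,
    subgroup = subgroup,
    start = genes$start, end = genes$end, strand = genes$strand,
    localized = genes$localized,
    core = core,
    functionality = calls,
    label = label,
    defects = defects,
    rs_canonical = rs_ok,
    promoter_ok = promoter_ok,
    cdr1 = cdr[, 1], cdr2 = cdr[, 2], cdr3 = cdr[, 3],
    allele_name = allele_name, provenance = provenance, is_new = is_new,
    n_alleles = n_alleles
  )
  structure(
    list(
      annotations = annotations, rs = rs, consensus = consensus,
      promoters = promoters, domains = domains, subgroups = clusters
    ),
    class = "ig_annotation"
  )
}

#' @export
print.ig_annotation <- function(x, ...) {
  a <- x$annotations
  cat(sprintf(
    "<ig_annotation> %s: %d genes (%s)\n", a$locus_id[1], nrow(a),
    paste(names(table(a$functionality)), table(a$functionality),
      sep = "=", collapse = ", "
    )
  ))
  invisible(x)
}

#' @export
tidy.ig_annotation <- function(x, ...) {
  x$annotations |>
    mutate(defects = purrr::map_chr(
      .data$defects,
      ~ paste(.x$code, collapse = ";")
    ))
}

#' @export
glance.ig_annotation <- function(x, ...) {
  a <- x$annotations
  tibble(
    locus_id = a$locus_id[1],
    n_genes = nrow(a),
    n_v = sum(a$gene_type == "V"),
    n_d = sum(a$gene_type == "D"),
    n_j = sum(a$gene_type == "J"),
    n_c = sum(a$gene_type == "C"),
    n_f = sum(a$functionality == "F"),
    n_orf = sum(a$functionality == "ORF"),
    n_p = sum(a$functionality == "P"),
    n_subgroups = length(unique(a$subgroup[a$gene_type == "V" & !grepl("\\(", a$subgroup)])),
    n_clans = length(unique(a$subgroup[a$gene_type == "V" & grepl("\\(", a$subgroup)]))
  )
}
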