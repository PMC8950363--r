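# Repertoire summary tables: gene tables, totals, CDR-length distributions,
# and the arithmetic consistency audit of the shipped reference tables.

#' Gene table: counts of genes per group and functionality label
#'
#' Aggregates per-gene annotations into the standard gene-table shape: one row
#' per (group, functionality label) with the gene count and, in parentheses
#' semantics, the allele count. Mixed-functionality genes (FO/FP/OP) are
#' counted once, under the mixed label.
#'
#' @param annotations Tibble with one row per gene carrying the grouping
#'   column, a `label` column (F/ORF/P/FO/FP/OP) and `n_alleles`.
#' @param group Name of the grouping column (e.g. `"subgroup"`).
#' @return A tibble of class `gene_table` (`group`, `label`, `genes`,
#'   `alleles`) with attribute `totals` (per-label and grand totals).
#' @export
gene_table <- function(annotations, group = "subgroup") {
  if (nrow(annotations) == 0) {
    out <- tibble(
      group = character(), label = character(),
      genes = integer(), alleles = integer()
    )
  } else {
    out <- annotations |>
      mutate(.group = .data[[group]]) |>
      group_by(.data$.group, .data$label) |>
      summarise(genes = dplyr::n(), alleles = sum(.data$n_alleles), .groups = "drop") |>
      rename(group = ".group")
  }
  totals <- out |>
    group_by(.data$label) |>
    summarise(genes = sum(.data$genes), alleles = sum(.data$alleles), .groups = "drop")
  structure(
    out,
    class = c("gene_table", class(out)),
    totals = totals,
    grand = c(genes = sum(out$genes), alleles = sum(out$alleles))
  )
}

#' Format a gene table the way repertoire pages print it
#' @param x A [gene_table()].
#' @param ... Unused.
#' @return A tibble with one row per group and a formatted `functionality`
#'   string like `"39 F (62), 1 O (2)"`.
#' @export
format.gene_table <- function(x, ...) {
  short <- c(F = "F", ORF = "O", P = "P", FO = "FO", FP = "FP", OP = "OP")
  x |>
    group_by(.data$group) |>
    summarise(
      functionality = paste(
        sprintf("%d %s (%d)", .data$genes, short[.data$label], .data$alleles),
        collapse = ", "
      ),
      total_genes = sum(.data$genes), total_alleles = sum(.data$alleles),
      .groups = "drop"
    )
}

#' Sum gene tables into a potential germline repertoire
#'
#' @param counts A tibble of gene-table rows across loci and gene types, with
#'   columns `locus_id`, `gene_type`, `genes`, `alleles` (additional columns
#'   ignored).
#' @return Per-locus totals plus a final `all` row; summing summaries of
#'   partitions equals summarizing the concatenation.
#' @export
repertoire_summary <- function(counts) {
  per_locus <- counts |>
    group_by(.data$locus_id) |>
    summarise(genes = sum(.data$genes), alleles = sum(.data$alleles), .groups = "drop")
  bind_rows(
    per_locus,
    tibble(
      locus_id = "all",
      genes = sum(per_locus$genes), alleles = sum(per_locus$alleles)
    )
  )
}

#' CDR-length distribution per subgroup
#'
#' Counts first alleles (`*01`) per (subgroup, CDR length triplet), split into
#' F / ORF / in-frame P; out-of-frame pseudogenes (no defined triplet) are
#' excluded, so a subgroup whose genes are all out of frame disappears from
#' the table.
#'
#' @param domains Tibble with one row per gene/first allele: `subgroup`,
#'   `functionality`, `cdr1`, `cdr2`, `cdr3` (`NA` = out of frame),
#'   optionally `allele_number` (filtered to 1 when `first_allele_only`).
#' @param first_allele_only Keep only `*01` alleles (the reported convention).
#' @return Tibble: `subgroup`, `lengths` (e.g. `"[6.3.7]"`), `f`, `orf`,
#'   `in_frame_p`.
#' @export
cdr_length_table <- function(domains, first_allele_only = TRUE) {
  d <- domains
  if (first_allele_only && "allele_number" %in% names(d)) {
    d <- filter(d, .data$allele_number == 1L)
  }
  d <- filter(d, !is.na(.data$cdr1) & !is.na(.data$cdr2) & !is.na(.data$cdr3))
  if (nrow(d) == 0) {
    return(tibble(
      subgroup = character(), lengths = character(),
      f = integer(), orf = integer(), in_frame_p = integer()
    ))
  }
  d |>
    mutate(lengths = sprintf("[%d.%d.%d]", .data$cdr1, .data$cdr2, .data$cdr3)) |>
    group_by(.data$subgroup, .data$lengths) |>
    summarise(
      f = sum(.data$functionality == "F"),
      orf = sum(.data$functionality == "ORF"),
      in_frame_p = sum(.data$functionality == "P"),
      .groups = "drop"
    ) |>
    arrange(.data$subgroup, .data$lengths)
}

# ---- shipped reference tables ----------------------------------------------

#' Published rhesus monkey (Mmul_10) IG repertoire tables
#'
#' Loads the machine-readable transcriptions of the published per-locus /
#' per-subgroup gene and allele counts, CDR-length distributions and locus
#' coordinates for the rhesus monkey IG loci, shipped with the package.
#'
#' @return A list of tibbles: `overview` (per-locus coordinates, orientation,
#'   gene counts), `totals` (per locus and gene type: printed gene and allele
#'   totals, plus the printed per-locus integration totals as `gene_type ==
#'   "all"`), `gene_tables` (per subgroup/set/isotype counts), `cdr_lengths`.
#' @export
rhesus_tables <- function() {
  dir <- system.file("extdata", "rhesus_mmul10", package = "igloci", mustWork = TRUE)
  rd <- function(f) {
    readr::read_tsv(file.path(dir, f), show_col_types = FALSE, progress = FALSE) |>
      mutate(across(dplyr::where(is.numeric), as.integer))
  }
  list(
    overview = rd("locus_overview.tsv"),
    totals = rd("locus_totals.tsv"),
    gene_tables = rd("gene_tables.tsv"),
    cdr_lengths = rd("cdr_lengths.tsv")
  )
}

#' Audit the arithmetic of the reference tables
#'
#' Re-adds every printed total from its printed addends: per-type totals from
#' the per-subgroup gene tables, and per-locus integration totals from the
#' per-type totals. Disagreements are listed, never corrected; the shipped
#' rhesus tables contain exactly one (the kappa-locus allele total, printed
#' one higher than the sum of its per-type addends).
#'
#' @param tables A table set as returned by [rhesus_tables()].
#' @return A tibble: `check`, `quantity`, `printed`, `computed`, `agree`.
#' @export
consistency_check <- function(tables = rhesus_tables()) {
  out <- list()
  add <- function(check, quantity, printed, computed) {
    out[[length(out) + 1L]] <<- tibble(
      check = check, quantity = quantity,
      printed = as.integer(printed), computed = as.integer(computed),
      agree = printed == computed
    )
  }
  per_type <- tables$totals |> filter(.data$gene_type != "all")
  per_locus <- tables$totals |> filter(.data$gene_type == "all")
  # per-type totals vs their per-subgroup addends
  sums <- tables$gene_tables |>
    group_by(.data$locus_id, .data$gene_type) |>
    summarise(genes = sum(.data$genes), alleles = sum(.data$alleles), .groups = "drop")
  for (i in seq_len(nrow(per_type))) {
    r <- per_type[i, ]
    s <- sums[sums$locus_id == r$locus_id & sums$gene_type == r$gene_type, ]
    add(
      paste0(r$locus_id, r$gene_type, " subgroup rows"),
      "genes", r$genes, s$genes
    )
    add(
      paste0(r$locus_id, r$gene_type, " subgroup rows"),
      "alleles", r$alleles, s$alleles
    )
  }
  # per-locus integration totals vs per-type addends
  type_sums <- per_type |>
    group_by(.data$locus_id) |>
    summarise(genes = sum(.data$genes), alleles = sum(.data$alleles), .groups = "drop")
  for (i in seq_len(nrow(per_locus))) {
    r <- per_locus[i, ]
    s <- type_sums[type_sums$locus_id == r$locus_id, ]
    add(paste0(r$locus_id, " locus total"), "genes", r$genes, s$genes)
    add(paste0(r$locus_id, " locus total"), "alleles", r$alleles, s$alleles)
  }
  bind_rows(out)
}

#' @export
autoplot.gene_table <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$group, y = .data$genes, fill = .data$label)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "genes", fill = "functionality") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
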