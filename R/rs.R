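# Recombination signal (RS) extraction, consensus and canonicality.
#
# An RS is heptamer + spacer + nonamer. The heptamer always abuts the core
# coding region: 3' of a V-REGION, 5' of a J-REGION, and on both flanks of a
# D-REGION (heptamers facing the D-REGION). Spacer lengths follow the 12/23
# rule and are configurable per locus and gene type.

DEFAULT_SPACERS <- tibble(
  locus_id = c("IGH", "IGH", "IGH", "IGH", "IGK", "IGK", "IGL", "IGL"),
  side = c("V-RS", "5'D-RS", "3'D-RS", "J-RS", "V-RS", "J-RS", "V-RS", "J-RS"),
  spacer = c(23L, 12L, 12L, 23L, 12L, 23L, 23L, 12L)
)

#' Spacer length class for an RS
#'
#' @param locus_id Locus identifier.
#' @param side RS side: `"V-RS"`, `"5'D-RS"`, `"3'D-RS"` or `"J-RS"`.
#' @param config Optional replacement for the built-in 12/23 table (a tibble
#'   with columns `locus_id`, `side`, `spacer`).
#' @return Integer spacer length (12 or 23 by default).
#' @export
rs_spacer_length <- function(locus_id, side, config = NULL) {
  cfg <- config %||% DEFAULT_SPACERS
  hit <- cfg$spacer[cfg$locus_id == locus_id & cfg$side == side]
  if (length(hit) != 1L) {
    abort(sprintf("no spacer class configured for %s %s", locus_id, side))
  }
  hit
}

#' Extract recombination signals from gene models
#'
#' For each V, D and J gene the heptamer, spacer and nonamer are read off the
#' locus sequence, contiguous with the core region on the gene's own strand.
#' D genes yield two signals (5' and 3'), heptamers facing the D-REGION.
#'
#' @param genes,labels Gene-model tables (see [validate_gene_models()]).
#' @param locus An [ig_locus()] (or plain sequence string).
#' @param spacer_config Optional spacer table, see [rs_spacer_length()].
#' @return A tibble with one row per signal: `gene_name`, `side`, `heptamer`,
#'   `spacer`, `nonamer` (heptamer/nonamer lowercase).
#' @export
extract_rs <- function(genes, labels, locus, spacer_config = NULL) {
  locus_id <- if (inherits(locus, "ig_locus")) locus$locus_id else "IGH"
  seq_len_locus <- if (inherits(locus, "ig_locus")) nchar(locus$sequence) else nchar(locus)
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$gene_type %in% c("V", "D", "J") || !isTRUE(g$localized)) next
    core <- labels[labels$gene_name == g$gene_name &
      labels$label == CORE_LABEL[[g$gene_type]], ]
    if (nrow(core) != 1L) {
      abort(sprintf("gene %s lacks a unique core label", g$gene_name))
    }
    sides <- switch(g$gene_type,
      V = "V-RS", J = "J-RS", D = c("5'D-RS", "3'D-RS")
    )
    for (side in sides) {
      sp <- rs_spacer_length(locus_id, side, spacer_config)
      # "downstream" RS (3' of core on gene strand): heptamer-spacer-nonamer
      downstream <- side %in% c("V-RS", "3'D-RS")
      w <- 7L + sp + 9L
      if (g$strand == "+") {
        int <- if (downstream) c(core$end + 1L, core$end + w) else c(core$start - w, core$start - 1L)
      } else {
        int <- if (downstream) c(core$start - w, core$start - 1L) else c(core$end + 1L, core$end + w)
      }
      if (int[1] < 1L || int[2] > seq_len_locus) {
        abort(sprintf("locus too short to host the %s of %s", side, g$gene_name))
      }
      s <- extract_label_sequence(locus, int[1], int[2], g$strand)
      if (!downstream) {
        # upstream of the core the order along the gene strand is
        # nonamer-spacer-heptamer, heptamer abutting the core
        hept <- substr(s, w - 6L, w)
        spacer <- substr(s, 10L, w - 7L)
        nona <- substr(s, 1L, 9L)
      } else {
        hept <- substr(s, 1L, 7L)
        spacer <- substr(s, 8L, 7L + sp)
        nona <- substr(s, 8L + sp, w)
      }
      out[[length(out) + 1L]] <- tibble(
        gene_name = g$gene_name, side = side,
        heptamer = tolower(hept), spacer = tolower(spacer),
        nonamer = tolower(nona), spacer_length = sp
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(
      gene_name = character(), side = character(), heptamer = character(),
      spacer = character(), nonamer = character(), spacer_length = integer()
    ))
  }
  bind_rows(out)
}

#' Column-wise consensus of equal-length sequences
#'
#' Plurality base per column; ties are broken by the lexicographically
#' smallest base and reported.
#'
#' @param seqs Character vector of equal-length sequences.
#' @return The consensus (lowercase) with attribute `ties`: a tibble of
#'   columns where two or more bases tied, with the tied bases.
#' @export
consensus_string <- function(seqs) {
  if (length(seqs) < 1L) {
    abort("no sequences to build a consensus from")
  }
  seqs <- tolower(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    abort("sequences must share one length")
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  ties <- list()
  cons <- vapply(seq_len(w), function(j) {
    tab <- sort(table(mat[, j]), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1L) {
      ties[[length(ties) + 1L]] <<- tibble(
        position = j, bases = paste(sort(top), collapse = "/")
      )
    }
    sort(top)[1]
  }, character(1))
  structure(
    paste(cons, collapse = ""),
    ties = if (length(ties)) bind_rows(ties) else tibble(position = integer(), bases = character())
  )
}

#' Consensus heptamer or nonamer of a set of RS
#'
#' @param signals An [extract_rs()] tibble; a `functionality` column (allele
#'   functionality of the source gene) is required when `functional_only`.
#' @param element `"heptamer"` or `"nonamer"`.
#' @param functional_only Restrict to signals from functional (F) sources.
#' @return Lowercase consensus string (see [consensus_string()] for the tie
#'   attribute).
#' @export
rs_consensus <- function(signals, element = c("heptamer", "nonamer"),
                         functional_only = TRUE) {
  element <- match.arg(element)
  if (functional_only) {
    if (!"functionality" %in% names(signals)) {
      abort("`functional_only` needs a `functionality` column")
    }
    signals <- signals[signals$functionality == "F", , drop = FALSE]
  }
  if (nrow(signals) == 0) {
    abort("no signals left after filtering")
  }
  consensus_string(signals[[element]])
}

#' Hamming distance between equal-length motifs
#'
#' @param seq,consensus Equal-length strings; comparison is case-insensitive.
#' @return Integer mismatch count.
#' @export
#' @examples
#' mismatch_count("ggctgtg", "cactgtg") # 3
mismatch_count <- function(seq, consensus) {
  if (nchar(seq) != nchar(consensus)) {
    abort("sequences must have equal length")
  }
  a <- strsplit(tolower(seq), "", fixed = TRUE)[[1]]
  b <- strsplit(tolower(consensus), "", fixed = TRUE)[[1]]
  sum(a != b)
}

#' Is a heptamer or nonamer canonical?
#'
#' The annotation rule: a motif found in more than one functional gene of the
#' locus is canonical outright; otherwise a heptamer is canonical with at most
#' one mutation from the locus consensus, a nonamer with at most two. When the
#' locus consensus has reported variants, the minimum mismatch count over the
#' variants is used.
#'
#' @param seq The motif.
#' @param consensus Locus consensus (one string, or several variants).
#' @param element `"heptamer"` or `"nonamer"`.
#' @param functional_occurrence_count In how many functional genes of the
#'   locus this exact motif occurs.
#' @return A list: `canonical` (logical), `reason`, `mismatches` (minimum over
#'   consensus variants).
#' @export
is_canonical_rs <- function(seq, consensus, element = c("heptamer", "nonamer"),
                            functional_occurrence_count = 0L) {
  element <- match.arg(element)
  mm <- min(vapply(consensus, mismatch_count, integer(1), seq = seq))
  tol <- if (element == "heptamer") 1L else 2L
  if (functional_occurrence_count > 1L) {
    return(list(
      canonical = TRUE, mismatches = mm,
      reason = sprintf("found in %d functional genes", functional_occurrence_count)
    ))
  }
  if (mm <= tol) {
    list(
      canonical = TRUE, mismatches = mm,
      reason = sprintf("%d mismatch(es) <= %d allowed for a %s", mm, tol, element)
    )
  } else {
    list(
      canonical = FALSE, mismatches = mm,
      reason = sprintf(
        "%d mismatches > %d allowed for a %s; possible rearrangement-evidence exception",
        mm, tol, element
      )
    )
  }
}

#' Position frequency matrix of RS motifs
#'
#' @param seqs Character vector of equal-length motifs (or an [extract_rs()]
#'   tibble plus `element`).
#' @param element Column to use when `seqs` is a tibble.
#' @return A tibble of class `ig_pfm`: `position`, `base`, `count`, `freq`;
#'   attribute `n_sequences`. Every position's counts sum to `n_sequences`.
#' @export
rs_pfm <- function(seqs, element = c("heptamer", "nonamer")) {
  if (is.data.frame(seqs)) {
    element <- match.arg(element)
    seqs <- seqs[[element]]
  }
  seqs <- tolower(seqs)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    abort("sequences must share one length")
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  bases <- c("a", "c", "g", "t", "n")
  out <- tidyr::expand_grid(position = seq_len(w), base = bases) |>
    mutate(count = purrr::map2_int(
      .data$position, .data$base,
      function(p, b) sum(mat[, p] == b)
    )) |>
    mutate(freq = .data$count / length(seqs))
  structure(out, class = c("ig_pfm", class(out)), n_sequences = length(seqs))
}

#' @export
autoplot.ig_pfm <- function(object, ...) {
  ggplot2::ggplot(
    dplyr::filter(object, .data$count > 0),
    ggplot2::aes(x = .data$position, y = .data$freq, fill = .data$base)
  ) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::scale_x_continuous(breaks = unique(object$position)) +
    ggplot2::labs(
      x = "position", y = "relative frequency",
      title = sprintf("Position frequencies (n = %d)", attr(object, "n_sequences"))
    ) +
    ggplot2::theme_minimal()
}
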