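# 5' UTR extraction and promoter-element architecture.
#
# Offsets are counted in nucleotides upstream of the A of the initiation
# codon: the base immediately 5' of the ATG has offset 1. Element offsets are
# reported for both edges; `offset_start` is the element's 3'-most base (the
# edge nearest the ATG), so elements sorted by increasing offset_start read
# 3' -> 5'.

#' Built-in promoter element definitions
#'
#' Heavy-chain (IGH) promoters carry, 3' to 5': TATA box, octamer
#' (`ATGCAAAT`), heptanucleotide and a pyrimidine-rich region. Light-chain
#' (IGK/IGL) promoters carry: TATA box, CCCT element, decamer
#' (`nnATTTGCAT` - the octamer in inverted complementary form with two extra
#' 5' bases), a second CCCT, and a pentadecamer (`TGCAnCTGTGnCCAG`, with an
#' inner E-box). The E-box (`CAnnTG`) is scanned as an auxiliary element
#' everywhere. `n` positions in a pattern match any base at no mismatch cost.
#'
#' The TATA box has no single consensus: it is operationalized as a run of 5
#' or more consecutive A/T. The pyrimidine-rich region is a windowed-fraction
#' rule (length >= `pyr_min_len`, C+T fraction >= `pyr_min_frac`). The
#' heptanucleotide has no published consensus; supply `heptanucleotide` to
#' scan for one, otherwise it is skipped.
#'
#' @param locus_id `"IGH"`, `"IGK"` or `"IGL"`.
#' @param heptanucleotide Optional 7-nt IUPAC pattern for the IGH
#'   heptanucleotide element.
#' @param ccct_variant Accepted CCCT variant (e.g. `"TCCT"` for the IGKV5
#'   subgroup); scanned as an alternative to `CCCT`.
#' @param pyr_min_len,pyr_min_frac Pyrimidine-rich rule parameters.
#' @return A tibble: `name`, `pattern`, `max_mismatches`, `window_min`,
#'   `window_max` (offset window searched), `rank` (3'->5' order in the
#'   canonical architecture; `NA` for auxiliary elements), `rule` (for
#'   non-pattern elements).
#' @export
promoter_elements <- function(locus_id = c("IGH", "IGK", "IGL"),
                              heptanucleotide = NULL, ccct_variant = NULL,
                              pyr_min_len = 10L, pyr_min_frac = 0.8) {
  locus_id <- match.arg(locus_id)
  if (locus_id == "IGH") {
    out <- tibble(
      name = c("TATA_BOX", "OCTAMER", "HEPTANUCLEOTIDE", "PYRIMIDINE_RICH", "E_BOX"),
      pattern = c(NA, "ATGCAAAT", heptanucleotide %||% NA_character_, NA, "CANNTG"),
      max_mismatches = c(NA, 1L, 1L, NA, 0L),
      window_min = c(1L, 20L, 60L, 80L, 1L),
      window_max = c(120L, 250L, 400L, 500L, 500L),
      rank = c(1L, 2L, 3L, 4L, NA),
      rule = c("at_run", NA, NA, "pyrimidine_rich", NA)
    )
  } else {
    out <- tibble(
      name = c("TATA_BOX", "CCCT_3", "DECAMER", "CCCT_5", "PENTADECAMER", "E_BOX"),
      pattern = c(NA, "CCCT", "NNATTTGCAT", "CCCT", "TGCANCTGTGNCCAG", "CANNTG"),
      max_mismatches = c(NA, 0L, 1L, 0L, 2L, 0L),
      window_min = c(1L, 30L, 60L, 95L, 110L, 1L),
      window_max = c(75L, 90L, 160L, 250L, 450L, 500L),
      rank = c(1L, 2L, 3L, 4L, 5L, NA),
      rule = c("at_run", NA, NA, NA, NA, NA)
    )
  }
  attr(out, "locus_id") <- locus_id
  attr(out, "ccct_variant") <- ccct_variant
  attr(out, "pyr") <- c(min_len = pyr_min_len, min_frac = pyr_min_frac)
  out
}

#' Extract the 5' UTR window upstream of an initiation codon
#'
#' @param locus An [ig_locus()] or plain sequence string.
#' @param atg_position Locus coordinate of the A of the ATG **on the gene's
#'   strand** (for an inverted gene this is the largest coordinate of the
#'   codon).
#' @param strand `"+"` or `"-"` (gene inverted in the locus).
#' @param window Window size in nt (default 500).
#' @param check Require an ATG at `atg_position` (disable when annotating a
#'   pseudogene whose initiation codon is mutated but whose position is known).
#' @return The up-to-`window`-nt sequence immediately 5' of the ATG on the
#'   gene strand, with attribute `truncated` set when the locus boundary cut
#'   the window short.
#' @export
extract_5utr <- function(locus, atg_position, strand = "+", window = 500L,
                         check = TRUE) {
  seqstr <- if (inherits(locus, "ig_locus")) locus$sequence else locus
  codon <- if (strand == "+") {
    substr(seqstr, atg_position, atg_position + 2L)
  } else {
    revcomp(substr(seqstr, atg_position - 2L, atg_position))
  }
  if (check && toupper(codon) != "ATG") {
    abort(sprintf("no ATG at position %d (%s strand): found %s", atg_position, strand, codon))
  }
  if (strand == "+") {
    from <- max(1L, atg_position - window)
    utr <- substr(seqstr, from, atg_position - 1L)
  } else {
    to <- min(nchar(seqstr), atg_position + window)
    utr <- revcomp(substr(seqstr, atg_position + 1L, to))
  }
  structure(toupper(utr), truncated = nchar(utr) < window)
}

# brute-force-equivalent IUPAC pattern scan with mismatches at fixed positions
scan_pattern <- function(utr, pattern, max_mismatches = 0L) {
  utr_dna <- Biostrings::DNAString(utr)
  pat <- Biostrings::DNAString(toupper(pattern))
  hits <- Biostrings::matchPattern(pat, utr_dna,
    max.mismatch = max_mismatches, fixed = FALSE
  )
  if (length(hits) == 0) {
    return(tibble(start = integer(), end = integer(), sequence = character(), mismatches = integer()))
  }
  pc <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  fixed_pos <- pc != "N"
  mm <- vapply(as.character(hits), function(s) {
    sc <- strsplit(s, "", fixed = TRUE)[[1]]
    sum(fixed_pos & !iupac_match(pc, sc))
  }, integer(1), USE.NAMES = FALSE)
  tibble(
    start = Biostrings::start(hits), end = Biostrings::end(hits),
    sequence = as.character(hits), mismatches = mm
  )
}

iupac_match <- function(pattern_chars, subject_chars) {
  codes <- Biostrings::IUPAC_CODE_MAP
  mapply(function(p, s) {
    grepl(s, codes[[p]], fixed = TRUE)
  }, pattern_chars, subject_chars, USE.NAMES = FALSE)
}

scan_at_run <- function(utr, min_len = 5L) {
  ch <- strsplit(toupper(utr), "", fixed = TRUE)[[1]]
  r <- rle(ch %in% c("A", "T"))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= min_len)
  if (length(keep) == 0L) {
    return(tibble(start = integer(), end = integer(), sequence = character(), mismatches = integer()))
  }
  tibble(
    start = starts[keep], end = ends[keep],
    sequence = substring(utr, starts[keep], ends[keep]),
    mismatches = 0L
  )
}

scan_pyrimidine_rich <- function(utr, min_len = 10L, min_frac = 0.8) {
  ch <- strsplit(toupper(utr), "", fixed = TRUE)[[1]]
  py <- ch %in% c("C", "T")
  n <- length(ch)
  if (n < min_len) {
    return(tibble(start = integer(), end = integer(), sequence = character(), mismatches = integer()))
  }
  # positions covered by any qualifying window, merged into maximal intervals
  csum <- cumsum(c(0L, py))
  ok_start <- which((csum[(min_len + 1):(n + 1)] - csum[1:(n - min_len + 1)]) / min_len >= min_frac)
  if (length(ok_start) == 0) {
    return(tibble(start = integer(), end = integer(), sequence = character(), mismatches = integer()))
  }
  covered <- rep(FALSE, n)
  for (s in ok_start) covered[s:(s + min_len - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(
    start = starts[keep], end = ends[keep],
    sequence = substring(utr, starts[keep], ends[keep]),
    mismatches = 0L
  )
}

#' Scan a 5' UTR for one promoter element
#'
#' Pattern elements report all positions matching the IUPAC pattern with at
#' most `max_mismatches` mismatches at fixed (non-`n`) positions. The TATA box
#' reports A/T runs of length >= 5; the pyrimidine-rich element reports
#' maximal regions assembled from length->=`min_len` windows with C/T fraction
#' >= `min_frac`.
#'
#' @param utr 5' UTR string (3' end adjacent to the ATG).
#' @param name Element name (used for rule dispatch and labeling).
#' @param pattern IUPAC pattern (ignored for rule elements).
#' @param max_mismatches Allowed mismatches at fixed positions.
#' @param rule `NA`, `"at_run"` or `"pyrimidine_rich"`.
#' @param pyr_min_len,pyr_min_frac Pyrimidine-rich parameters.
#' @return Tibble: `name`, `start`, `end` (UTR coordinates), `offset_start`
#'   (offset of the 3'-most base), `offset_end` (5'-most), `sequence`,
#'   `mismatches`.
#' @export
scan_element <- function(utr, name, pattern = NA, max_mismatches = 0L,
                         rule = NA, pyr_min_len = 10L, pyr_min_frac = 0.8) {
  L <- nchar(utr)
  hits <- if (identical(rule, "at_run")) {
    scan_at_run(utr)
  } else if (identical(rule, "pyrimidine_rich")) {
    scan_pyrimidine_rich(utr, pyr_min_len, pyr_min_frac)
  } else if (is.na(pattern)) {
    tibble(start = integer(), end = integer(), sequence = character(), mismatches = integer())
  } else {
    scan_pattern(utr, pattern, max_mismatches)
  }
  hits |>
    mutate(
      name = name,
      offset_start = L - .data$end + 1L, # 3'-most base
      offset_end = L - .data$start + 1L # 5'-most base
    ) |>
    select("name", "start", "end", "offset_start", "offset_end", "sequence", "mismatches")
}

#' Annotate the promoter architecture of one 5' UTR
#'
#' Walks the locus's canonical element order 3' -> 5', assigning to each core
#' element the match inside its offset window that lies 5' of the previously
#' assigned element; among candidates the one closest to the window center
#' wins, ties going to the 3'-most (closest to the ATG). Missing elements are
#' recorded, not errors. Auxiliary E-box matches are appended unordered.
#'
#' @param utr A 5' UTR (see [extract_5utr()]).
#' @param elements An element table from [promoter_elements()].
#' @return A tibble of class `promoter_annotation`: one row per element with
#'   `name`, `found`, `offset_start`, `offset_end`, `sequence`, `mismatches`;
#'   attribute `architecture_key` is the dash-joined 3'->5' list of found core
#'   elements.
#' @export
annotate_promoter <- function(utr, elements) {
  pyr <- attr(elements, "pyr") %||% c(min_len = 10, min_frac = 0.8)
  ccct_variant <- attr(elements, "ccct_variant")
  core <- elements[!is.na(elements$rank), , drop = FALSE]
  core <- core[order(core$rank), , drop = FALSE]
  rows <- list()
  min_offset <- 0L
  for (i in seq_len(nrow(core))) {
    e <- core[i, ]
    if (is.na(e$pattern) && is.na(e$rule)) { # unconfigured (e.g. heptanucleotide)
      next
    }
    hits <- scan_element(utr, e$name,
      pattern = e$pattern, max_mismatches = e$max_mismatches,
      rule = e$rule, pyr_min_len = pyr[["min_len"]], pyr_min_frac = pyr[["min_frac"]]
    )
    if (!is.null(ccct_variant) && startsWith(e$name, "CCCT")) {
      hits <- bind_rows(hits, scan_element(utr, e$name, pattern = ccct_variant))
    }
    hits <- hits[hits$offset_start > min_offset &
      hits$offset_start >= e$window_min &
      hits$offset_start <= e$window_max, , drop = FALSE]
    if (nrow(hits) == 0) {
      rows[[length(rows) + 1L]] <- tibble(
        name = e$name, found = FALSE, offset_start = NA_integer_,
        offset_end = NA_integer_, sequence = NA_character_, mismatches = NA_integer_
      )
      next
    }
    center <- (e$window_min + e$window_max) / 2
    hits <- hits[order(abs(hits$offset_start - center), hits$offset_start), , drop = FALSE]
    best <- hits[1, ]
    rows[[length(rows) + 1L]] <- tibble(
      name = e$name, found = TRUE, offset_start = best$offset_start,
      offset_end = best$offset_end, sequence = best$sequence,
      mismatches = best$mismatches
    )
    min_offset <- best$offset_end
  }
  out <- bind_rows(rows)
  ebox <- elements[elements$name == "E_BOX", , drop = FALSE]
  if (nrow(ebox) == 1L) {
    eb <- scan_element(utr, "E_BOX", pattern = ebox$pattern, max_mismatches = ebox$max_mismatches)
    if (nrow(eb)) {
      out <- bind_rows(out, eb |>
        mutate(found = TRUE) |>
        select("name", "found", "offset_start", "offset_end", "sequence", "mismatches"))
    }
  }
  key <- paste(out$name[out$found & out$name != "E_BOX"], collapse = "-")
  structure(out, class = c("promoter_annotation", class(out)), architecture_key = key)
}

#' Architecture key of a promoter annotation
#' @param annotation An [annotate_promoter()] result.
#' @return The 3'->5' dash-joined string of found core elements.
#' @export
architecture_key <- function(annotation) {
  attr(annotation, "architecture_key")
}

#' Summarize promoter architecture per subgroup
#'
#' @param annotations A tibble combining [annotate_promoter()] rows across
#'   alleles, with added columns `allele_ref` and `subgroup`.
#' @return Per (subgroup, element): presence fraction, mean/min/max
#'   `offset_start` among found, and the per-column consensus of the matched
#'   sequences (equal-length elements only; `NA` otherwise).
#' @export
subgroup_architecture <- function(annotations) {
  stopifnot(all(c("subgroup", "name", "found") %in% names(annotations)))
  annotations |>
    group_by(.data$subgroup, .data$name) |>
    summarise(
      n = dplyr::n(),
      presence = mean(.data$found),
      offset_mean = mean(.data$offset_start[.data$found]),
      offset_min = suppressWarnings(min(.data$offset_start[.data$found])),
      offset_max = suppressWarnings(max(.data$offset_start[.data$found])),
      consensus = {
        s <- .data$sequence[.data$found & !is.na(.data$sequence)]
        if (length(s) > 0 && length(unique(nchar(s))) == 1L) {
          as.character(consensus_string(s))
        } else {
          NA_character_
        }
      },
      .groups = "drop"
    ) |>
    mutate(across(c("offset_min", "offset_max"), ~ ifelse(is.finite(.x), .x, NA_integer_)))
}

#' @export
autoplot.promoter_annotation <- function(object, ...) {
  d <- dplyr::filter(object, .data$found)
  ggplot2::ggplot(d, ggplot2::aes(
    xmin = -.data$offset_end, xmax = -.data$offset_start,
    ymin = 0, ymax = 1, fill = .data$name
  )) +
    ggplot2::geom_rect(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::annotate("text", x = 0, y = 1.15, label = "ATG") +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(0, 1.3)) +
    ggplot2::labs(x = "position relative to ATG (nt)", fill = "element") +
    ggplot2::theme_minimal()
}
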