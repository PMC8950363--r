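# Template-based placement of V domains on the IMGT unique-numbering grid.
#
# The grid: FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104,
# CDR3 105-117. Templates carry the framework gap positions characteristic of
# a locus (kappa-style V domains have 26 FR1 residues and FR3 gaps at 73, 81
# and 82; lambda-style have 25 FR1 residues with a gap at position 10). CDRs
# shorter than their window are gapped middle-out; residues beyond a window's
# capacity get lettered insertion labels at the window anchor.

REGION_BOUNDS <- tibble(
  region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3"),
  from = c(1L, 27L, 39L, 56L, 66L, 105L),
  to = c(26L, 38L, 55L, 65L, 104L, 117L)
)

HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "C", "Y")

#' Built-in numbering templates
#'
#' @param name `"igkv"` (FR1 = 26 AA, FR3 gaps at 73/81/82), `"iglv"`
#'   (FR1 = 25 AA with a gap at position 10), or `"ighv"` (no framework gaps).
#' @param fr1_gaps,fr3_gaps Integer positions gapped in FR1/FR3 (override the
#'   built-ins to describe other subgroups).
#' @return A list of class `imgt_template` with the gap sets, CDR window
#'   capacities (12/10/13) and insertion anchors (FR1: 15; CDR windows: their
#'   midpoints).
#' @export
imgt_template <- function(name = c("igkv", "iglv", "ighv"),
                          fr1_gaps = NULL, fr3_gaps = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    igkv = list(fr1 = integer(0), fr3 = c(73L, 81L, 82L)),
    iglv = list(fr1 = 10L, fr3 = integer(0)),
    ighv = list(fr1 = integer(0), fr3 = integer(0))
  )
  structure(
    list(
      name = name,
      fr1_gaps = as.integer(fr1_gaps %||% defaults$fr1),
      fr3_gaps = as.integer(fr3_gaps %||% defaults$fr3),
      cdr_capacity = c(CDR1 = 12L, CDR2 = 10L, CDR3 = 13L),
      insertion_anchor = c(FR1 = 15L, CDR1 = 32L, FR2 = 50L, CDR2 = 60L, CDR3 = 111L)
    ),
    class = "imgt_template"
  )
}

template_fr_len <- function(template) {
  c(
    FR1 = 26L - length(template$fr1_gaps),
    FR2 = 17L,
    FR3 = 39L - length(template$fr3_gaps)
  )
}

#' Translate a V-REGION (or other coding stretch)
#'
#' Standard genetic code translation from a given frame anchor. In-frame stop
#' codons are flagged with their codon index rather than truncating; codons
#' containing an ambiguous base translate to `X` and are flagged; a 3' tail
#' shorter than a codon is reported, not an error.
#'
#' @param core Nucleotide string.
#' @param frame Codon phase of the first base: 0 (default), 1 or 2 bases are
#'   skipped before the first full codon.
#' @return A list: `aa` (amino acids, stops as `*`), `stop_codons` (integer
#'   codon indices), `untranslatable` (codon indices containing N),
#'   `frameshift` (`TRUE` when the translated stretch is not a whole number of
#'   codons), `tail` (leftover 3' bases).
#' @export
#' @examples
#' translate_v_region("TGTGCC")$aa # "CA"
translate_v_region <- function(core, frame = 0) {
  core <- toupper(core)
  stopifnot(frame %in% 0:2)
  body <- substr(core, frame + 1L, nchar(core))
  n_codon <- nchar(body) %/% 3L
  tail_len <- nchar(body) %% 3L
  codons <- substring(body, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  untranslatable <- which(is.na(aa))
  aa[is.na(aa)] <- "X"
  list(
    aa = paste(aa, collapse = ""),
    stop_codons = which(aa == "*"),
    untranslatable = untranslatable,
    frameshift = tail_len != 0L,
    tail = if (tail_len) substr(body, nchar(body) - tail_len + 1L, nchar(body)) else ""
  )
}

# middle-out fill of a CDR window: which window slots (1..capacity) hold the
# n residues. IMGT convention: extra residue on the 5' side, gaps in the middle.
cdr_fill_slots <- function(n, capacity) {
  if (n >= capacity) {
    return(seq_len(capacity))
  }
  lead <- ceiling(n / 2)
  c(seq_len(lead), capacity - (n - lead) + seq_len(n - lead))
}

# residue index (1-based within the amino-acid sequence) of a grid position,
# for a candidate layout
grid_layout <- function(template, fr1_ins, c1, c2, c3) {
  frl <- template_fr_len(template)
  list(
    n_fr1 = frl[["FR1"]] + fr1_ins, c1 = c1, c2 = c2, c3 = c3,
    n_fr3 = frl[["FR3"]],
    total = frl[["FR1"]] + fr1_ins + c1 + 17L + c2 + frl[["FR3"]] + c3
  )
}

# residue indices (within the ungapped sequence) of grid anchors 23/41/89/104
anchor_indices <- function(template, lay) {
  fr1_before <- function(p) {
    sum(setdiff(1:26, template$fr1_gaps) <= p) +
      if (template$insertion_anchor[["FR1"]] <= p) {
        lay$n_fr1 - (26L - length(template$fr1_gaps))
      } else {
        0L
      }
  }
  fr3_res <- setdiff(66:104, template$fr3_gaps)
  c(
    i23 = fr1_before(23L),
    i41 = lay$n_fr1 + lay$c1 + 3L, # positions 39,40,41: FR2 has no gaps
    i89 = lay$n_fr1 + lay$c1 + 17L + lay$c2 + sum(fr3_res <= 89L),
    i104 = lay$n_fr1 + lay$c1 + 17L + lay$c2 + lay$n_fr3
  )
}

anchor_score <- function(aa_chars, template, lay) {
  ai <- anchor_indices(template, lay)
  sc <- 0
  at <- function(i) if (i >= 1 && i <= length(aa_chars)) aa_chars[i] else ""
  if (at(ai[["i23"]]) == "C") sc <- sc + 2
  if (at(ai[["i41"]]) == "W") sc <- sc + 2
  if (at(ai[["i89"]]) %in% HYDROPHOBIC_AA) sc <- sc + 1
  if (at(ai[["i104"]]) == "C") sc <- sc + 2
  sc
}

#' Place an amino-acid V region on the IMGT numbering grid
#'
#' Framework columns follow the template's gap set; CDR residues are packed
#' middle-out into their windows. When the CDR lengths are not supplied they
#' are inferred by anchoring on the conserved residues (C23, W41, hydrophobic
#' 89, C104): all candidate partitions of the sequence into
#' FR1/CDR1/FR2/CDR2/FR3/CDR3 consistent with the template are scored by how
#' many anchors they place correctly and the best-scoring (smallest, on ties)
#' layout wins. One or two extra FR1 residues are accommodated as lettered
#' insertions after the FR1 anchor (position 15).
#'
#' @param aa Amino-acid string (stops as `*` allowed).
#' @param template An [imgt_template()].
#' @param cdr Optional known CDR lengths `c(c1, c2, c3)`; skips inference.
#' @param fr1_insertions Extra FR1 residues beyond the template (only used
#'   together with `cdr`).
#' @return A tibble of class `numbered_v_domain`: one row per grid column with
#'   `position` (integer), `ins` (insertion letter or `""`), `label` (e.g.
#'   `"15A"`), `region` and `residue` (`NA` for gap columns). Attributes:
#'   `aa`, `template`, `cdr_lengths`.
#' @export
number_v_domain <- function(aa, template = imgt_template("igkv"), cdr = NULL,
                            fr1_insertions = 0L) {
  aa <- toupper(aa)
  aa_chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  frl <- template_fr_len(template)
  min_len <- sum(frl)
  if (length(aa_chars) < min_len) {
    abort(sprintf(
      "sequence too short for the %s template: %d residues < %d framework residues (anchors C23/W41/C104 cannot all be placed)",
      template$name, length(aa_chars), min_len
    ))
  }
  if (is.null(cdr)) {
    search <- function(c1_max, c2_max, c3_max) {
      best <- NULL
      best_score <- -Inf
      for (ins in 0:2) {
        rem0 <- length(aa_chars) - (frl[["FR1"]] + ins + 17L + frl[["FR3"]])
        if (rem0 < 0) next
        for (c1 in 0:min(c1_max, rem0)) {
          for (c2 in 0:min(c2_max, rem0 - c1)) {
            c3 <- rem0 - c1 - c2
            if (c3 < 0 || c3 > c3_max) next
            lay <- grid_layout(template, ins, c1, c2, c3)
            sc <- anchor_score(aa_chars, template, lay) - 0.01 * ins
            if (sc > best_score) {
              best_score <- sc
              best <- c(ins, c1, c2, c3)
            }
          }
        }
      }
      best
    }
    # germline CDRs normally fit their windows; lettered-insertion layouts are
    # only considered when no within-capacity layout matches the length
    best <- search(12L, 10L, 13L) %||% search(16L, 13L, 17L)
    if (is.null(best)) {
      abort("no grid layout fits this sequence length")
    }
    fr1_insertions <- best[1]
    cdr <- best[2:4]
  }
  lay <- grid_layout(template, fr1_insertions, cdr[1], cdr[2], cdr[3])
  if (lay$total != length(aa_chars)) {
    abort(sprintf(
      "CDR lengths [%s] imply %d residues but sequence has %d",
      paste(cdr, collapse = "."), lay$total, length(aa_chars)
    ))
  }

  rows <- list()
  cursor <- 0L
  take <- function() {
    cursor <<- cursor + 1L
    aa_chars[cursor]
  }
  add_row <- function(position, ins, region, residue) {
    rows[[length(rows) + 1L]] <<- tibble(
      position = as.integer(position), ins = ins,
      label = paste0(position, ins), region = region, residue = residue
    )
  }
  fr_emit <- function(region, from, to, gaps, n_ins = 0L, anchor = NA_integer_) {
    for (p in from:to) {
      if (p %in% gaps) {
        add_row(p, "", region, NA_character_)
      } else {
        add_row(p, "", region, take())
      }
      if (!is.na(anchor) && p == anchor && n_ins > 0L) {
        for (k in seq_len(n_ins)) add_row(p, LETTERS[k], region, take())
      }
    }
  }
  cdr_emit <- function(region, from, to, n) {
    capacity <- to - from + 1L
    slots <- cdr_fill_slots(min(n, capacity), capacity)
    anchor <- template$insertion_anchor[[region]]
    overflow <- max(0L, n - capacity)
    for (s in seq_len(capacity)) {
      p <- from + s - 1L
      if (s %in% slots) add_row(p, "", region, take()) else add_row(p, "", region, NA_character_)
      if (p == anchor && overflow > 0L) {
        for (k in seq_len(overflow)) add_row(p, LETTERS[k], region, take())
      }
    }
  }
  fr_emit("FR1", 1L, 26L, template$fr1_gaps,
    n_ins = fr1_insertions,
    anchor = template$insertion_anchor[["FR1"]]
  )
  cdr_emit("CDR1", 27L, 38L, cdr[1])
  fr_emit("FR2", 39L, 55L, integer(0))
  cdr_emit("CDR2", 56L, 65L, cdr[2])
  fr_emit("FR3", 66L, 104L, template$fr3_gaps)
  cdr_emit("CDR3", 105L, 117L, cdr[3])

  out <- bind_rows(rows)
  structure(
    out,
    class = c("numbered_v_domain", class(out)),
    aa = aa, template = template$name, cdr_lengths = as.integer(cdr)
  )
}

#' @export
tidy.numbered_v_domain <- function(x, ...) {
  as_tibble(unclass(x)[c("position", "ins", "label", "region", "residue")])
}

# anchor score of a hypothetical layout for an ungapped sequence
layout_score <- function(aa, template, cdr, fr1_ins = 0L) {
  aa_chars <- strsplit(toupper(aa), "", fixed = TRUE)[[1]]
  lay <- grid_layout(template, fr1_ins, cdr[1], cdr[2], cdr[3])
  if (lay$total != length(aa_chars)) {
    return(-Inf)
  }
  anchor_score(aa_chars, template, lay)
}

#' CDR length triplet of a numbered domain
#'
#' @param domain A [number_v_domain()] result.
#' @return Integer vector `c(c1, c2, c3)` of non-gap residue counts per CDR
#'   window.
#' @export
cdr_lengths <- function(domain) {
  cnt <- function(region) sum(!is.na(domain$residue[domain$region == region]))
  c(cnt("CDR1"), cnt("CDR2"), cnt("CDR3"))
}

#' Render CDR lengths as the bracketed triplet
#' @param lengths Integer vector of length 3.
#' @return e.g. `"[6.3.7]"`.
#' @export
format_cdr_lengths <- function(lengths) {
  sprintf("[%d.%d.%d]", lengths[1], lengths[2], lengths[3])
}

#' Check the four conserved V-domain residues
#'
#' Positions 23 and 104 must be cysteine, 41 tryptophan, 89 any hydrophobic
#' amino acid. A position absent from a truncated domain is reported as
#' missing and fails.
#'
#' @param domain A [number_v_domain()] result.
#' @return A tibble with columns `position`, `residue`, `expected`, `pass`.
#' @export
conserved_residues <- function(domain) {
  expect <- tibble(
    position = c(23L, 41L, 89L, 104L),
    expected = c("C", "W", "hydrophobic", "C")
  )
  res <- vapply(expect$position, function(p) {
    r <- domain$residue[domain$position == p & domain$ins == ""]
    if (length(r) == 0 || is.na(r[1])) "missing" else r[1]
  }, character(1))
  pass <- ifelse(
    expect$expected == "hydrophobic",
    res %in% HYDROPHOBIC_AA,
    res == expect$expected
  )
  mutate(expect, residue = res, pass = pass) |>
    select("position", "residue", "expected", "pass")
}

#' Aligned protein display of numbered domains
#'
#' Builds the fixed-width IMGT-style protein display: columns are the union of
#' grid labels across domains (numeric-then-letter order), gaps are `.`,
#' in-frame stops are `*`.
#'
#' @param domains A named list of [number_v_domain()] results.
#' @return An object of class `protein_display`: a list with `columns` (label
#'   tibble) and `rows` (named character vector of display strings). Printed
#'   with region ruler lines.
#' @export
protein_display <- function(domains) {
  if (is.null(names(domains))) {
    names(domains) <- paste0("domain", seq_along(domains))
  }
  cols <- bind_rows(lapply(domains, function(d) d[, c("position", "ins", "label", "region")])) |>
    distinct() |>
    arrange(.data$position, .data$ins)
  rows <- vapply(domains, function(d) {
    res <- d$residue[match(cols$label, d$label)]
    res[is.na(res)] <- "."
    paste(res, collapse = "")
  }, character(1))
  structure(list(columns = cols, rows = rows), class = "protein_display")
}

#' @export
print.protein_display <- function(x, ...) {
  nm_w <- max(nchar(names(x$rows)), 6L)
  ruler <- vapply(seq_len(nrow(x$columns)), function(i) {
    substr(x$columns$region[i], 1, 1)
  }, character(1))
  boundary <- c(TRUE, x$columns$region[-1] != x$columns$region[-nrow(x$columns)])
  marks <- ifelse(boundary, "|", ruler)
  cat(format("", width = nm_w), " ", paste(marks, collapse = ""), "\n", sep = "")
  for (i in seq_along(x$rows)) {
    cat(format(names(x$rows)[i], width = nm_w), " ", x$rows[i], "\n", sep = "")
  }
  invisible(x)
}

#' Strip gaps from a numbered domain
#' @param domain A [number_v_domain()] result.
#' @return The amino-acid string of the domain (round-trips the input).
#' @export
domain_sequence <- function(domain) {
  paste(domain$residue[!is.na(domain$residue)], collapse = "")
}
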