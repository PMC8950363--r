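# Independent oracles used across the suite. These are deliberately naive
# re-derivations (full DP, per-position scans) kept separate from the package
# implementations they check.

# Gotoh affine-gap global alignment returning the same identity definition as
# percent_identity: match 1 / mismatch 0, gap open 10 / extend 0.5, identity =
# matches / columns excluding terminal gaps.
oracle_identity <- function(a, b, open = 10, ext = 0.5) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  n <- length(a)
  m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (a aligned to '-')
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -open - ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- as.numeric(a[i - 1] == b[j - 1] & a[i - 1] != "N")
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  # traceback
  al_a <- character(0)
  al_b <- character(0)
  i <- n + 1
  j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1) {
      s <- as.numeric(a[i - 1] == b[j - 1] & a[i - 1] != "N")
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      al_a <- c(a[i - 1], al_a)
      al_b <- c(b[j - 1], al_b)
      i <- i - 1
      j <- j - 1
    } else if (state == 2) {
      from_m <- isTRUE(all.equal(X[i, j], M[i - 1, j] - open - ext))
      al_a <- c(a[i - 1], al_a)
      al_b <- c("-", al_b)
      i <- i - 1
      state <- if (from_m) 1 else 2
    } else {
      from_m <- isTRUE(all.equal(Y[i, j], M[i, j - 1] - open - ext))
      al_a <- c("-", al_a)
      al_b <- c(b[j - 1], al_b)
      j <- j - 1
      state <- if (from_m) 1 else 3
    }
  }
  gap <- al_a == "-" | al_b == "-"
  keep <- rep(TRUE, length(gap))
  k <- 1
  while (k <= length(gap) && gap[k]) {
    keep[k] <- FALSE
    k <- k + 1
  }
  k <- length(gap)
  while (k >= 1 && gap[k]) {
    keep[k] <- FALSE
    k <- k - 1
  }
  sum(al_a[keep] == al_b[keep] & al_a[keep] != "-" & al_a[keep] != "N") / sum(keep)
}

# per-position N scan (oracle for detect_gaps)
oracle_n_positions <- function(sequence) {
  which(strsplit(toupper(sequence), "")[[1]] == "N")
}

# naive codon-table translation
oracle_translate <- function(nt) {
  nt <- toupper(nt)
  tab <- Biostrings::GENETIC_CODE
  n <- nchar(nt) %/% 3
  paste(vapply(seq_len(n), function(i) {
    cd <- substr(nt, 3 * i - 2, 3 * i)
    if (grepl("N", cd)) "X" else unname(tab[cd])
  }, character(1)), collapse = "")
}

# brute-force sliding-window exact IUPAC match (oracle for scan_element at 0
# mismatches)
oracle_scan <- function(utr, pattern) {
  codes <- Biostrings::IUPAC_CODE_MAP
  utr <- toupper(utr)
  pc <- strsplit(toupper(pattern), "")[[1]]
  w <- length(pc)
  hits <- integer(0)
  for (s in seq_len(nchar(utr) - w + 1)) {
    sub <- strsplit(substr(utr, s, s + w - 1), "")[[1]]
    ok <- all(mapply(function(p, x) grepl(x, codes[[p]], fixed = TRUE), pc, sub))
    if (ok) hits <- c(hits, s)
  }
  hits
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a small, quick synthetic locus spec shared by round-trip tests
small_spec <- function(locus_id = "IGK", seed = 42, ...) {
  locus_spec(
    locus_id = locus_id,
    v_plan = tibble::tibble(
      subgroup = c("SG1", "SG2", "CLAN1"),
      clan = c(FALSE, FALSE, TRUE),
      n_f = c(5L, 3L, 0L), n_orf = c(3L, 0L, 0L), n_p = c(3L, 1L, 3L)
    ),
    n_j = 3L, n_c = 1L, n_unlocalized = 1L,
    n_extra_alleles = 1L, n_fp = 1L, n_fo = 1L,
    duplications = 2L, gap_lengths = c(50L, 200L),
    seed = seed, ...
  )
}

annotate_synth <- function(synth, template, with_directory = TRUE) {
  genes_in <- synth$genes[, c(
    "gene_key", "gene_type", "start", "end", "strand",
    "localized", "atg_position", "core"
  )]
  dir <- if (with_directory) dplyr::rename(synth$alleles, gene_name = gene_key) else NULL
  annotate_locus(synth$locus, genes_in, synth$labels,
    template = template, directory = dir
  )
}
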