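test_that("RS extraction recovers planted signals around V, D and J cores", {
  withr::with_seed(4, {
    hept <- "cacagtg"
    nona <- "acaaaaacc"
    sp23 <- tolower(random_dna(23))
    vcore <- random_dna(60)
    seqstr <- paste0(
      random_dna(30), vcore, toupper(hept), toupper(sp23), toupper(nona),
      random_dna(20)
    )
    loc <- ig_locus("IGH", seqstr)
    genes <- tibble::tibble(
      gene_name = "v1", gene_type = "V", start = 31L,
      end = 31L + 60L + 7L + 23L + 9L - 1L, strand = "+", localized = TRUE
    )
    labels <- tibble::tibble(
      gene_name = "v1", label = "V-REGION", start = 31L, end = 90L
    )
    rs <- extract_rs(genes, labels, loc)
    expect_identical(rs$heptamer, hept)
    expect_identical(rs$nonamer, nona)
    expect_identical(rs$spacer, sp23)

    # D gene: signals on both flanks, heptamers facing the D-REGION
    h5 <- "cactgtg"
    n5 <- "ggtttttgt"
    h3 <- "cacagtg"
    n3 <- "tcaaaaacc"
    s5 <- tolower(random_dna(12))
    s3 <- tolower(random_dna(12))
    dcore <- random_dna(16)
    pre <- 25L
    dseq <- paste0(
      random_dna(pre), toupper(n5), toupper(s5), toupper(h5), dcore,
      toupper(h3), toupper(s3), toupper(n3), random_dna(10)
    )
    dloc <- ig_locus("IGH", dseq)
    dstart <- pre + 1L
    dgenes <- tibble::tibble(
      gene_name = "d1", gene_type = "D", start = dstart,
      end = pre + 28L + 16L + 28L, strand = "+", localized = TRUE
    )
    dlabels <- tibble::tibble(
      gene_name = "d1", label = "D-REGION",
      start = pre + 28L + 1L, end = pre + 28L + 16L
    )
    drs <- extract_rs(dgenes, dlabels, dloc)
    expect_identical(nrow(drs), 2L)
    expect_identical(drs$heptamer[drs$side == "5'D-RS"], h5)
    expect_identical(drs$nonamer[drs$side == "5'D-RS"], n5)
    expect_identical(drs$heptamer[drs$side == "3'D-RS"], h3)
    expect_identical(drs$nonamer[drs$side == "3'D-RS"], n3)

    # J gene: nonamer-spacer-heptamer upstream of the J-REGION
    sj <- tolower(random_dna(23))
    jcore <- random_dna(48)
    jseq <- paste0(random_dna(15), toupper(n5), toupper(sj), toupper(h5), jcore, random_dna(10))
    jloc <- ig_locus("IGH", jseq)
    jgenes <- tibble::tibble(
      gene_name = "j1", gene_type = "J", start = 16L,
      end = 15L + 39L + 48L, strand = "+", localized = TRUE
    )
    jlabels <- tibble::tibble(
      gene_name = "j1", label = "J-REGION", start = 15L + 39L + 1L, end = 15L + 39L + 48L
    )
    jrs <- extract_rs(jgenes, jlabels, jloc)
    expect_identical(jrs$heptamer, h5)
    expect_identical(jrs$nonamer, n5)
    expect_identical(jrs$spacer, sj)

    # too short to host the signal
    shortloc <- ig_locus("IGH", paste0(random_dna(5), vcore))
    sgenes <- tibble::tibble(
      gene_name = "v1", gene_type = "V", start = 6L, end = 65L,
      strand = "+", localized = TRUE
    )
    slab <- tibble::tibble(gene_name = "v1", label = "V-REGION", start = 6L, end = 65L)
    expect_error(extract_rs(sgenes, slab, shortloc), "too short")
  })
})

test_that("consensus is the column plurality with reported lexicographic ties", {
  expect_identical(as.character(consensus_string("cacagtg")), "cacagtg")
  s <- c("cacagtg", "cacagtg", "cacagag")
  expect_identical(as.character(consensus_string(s)), "cacagtg")
  tied <- consensus_string(c("cacagtg", "cacagag"))
  expect_identical(as.character(tied), "cacagag") # 'a' < 't' at the tie column
  expect_identical(attr(tied, "ties")$position, 6L)
  # permutation invariance
  withr::with_seed(8, {
    ss <- c("cactgtg", "cactgtg", "caatgtg", "cactgtg", "ggctgtg")
    for (i in 1:5) {
      expect_identical(
        as.character(consensus_string(sample(ss))),
        as.character(consensus_string(ss))
      )
    }
  })
  expect_error(consensus_string(character(0)), "no sequences")
  expect_error(consensus_string(c("aa", "aaa")), "one length")
})

test_that("functional-only consensus reproduces the published light-chain J motifs", {
  # a J set shaped like the kappa joining genes: functional signals dominated
  # by the published consensus, one pseudogene source excluded by the filter
  signals <- tibble::tibble(
    heptamer = c("cactgtg", "cattgtg", "cactgtg", "tactgtg", "cactgtg", "gggggtg"),
    nonamer = c(
      "ggtttttgt", "agtttttgt", "ggtttttgt", "gatttttgt", "ggtttttgt",
      "ccccctttt"
    ),
    functionality = c("F", "F", "F", "F", "F", "P")
  )
  expect_identical(
    as.character(rs_consensus(signals, "heptamer", functional_only = TRUE)),
    "cactgtg"
  )
  expect_identical(
    as.character(rs_consensus(signals, "nonamer", functional_only = TRUE)),
    "ggtttttgt"
  )
  # a subgroup dominated by the cacagag variant yields that consensus
  sub2 <- tibble::tibble(
    heptamer = c("cacagag", "cacagag", "cacagag", "cacagtg"),
    functionality = "F"
  )
  expect_identical(
    as.character(rs_consensus(sub2, "heptamer")),
    "cacagag"
  )
  expect_error(
    rs_consensus(dplyr::filter(signals, functionality == "X"), "heptamer"),
    "no signals"
  )
})

test_that("mismatch counts are case-insensitive Hamming distances", {
  expect_identical(mismatch_count("cacagtg", "cacagtg"), 0L)
  expect_identical(mismatch_count("CACAGTG", "cacagtg"), 0L)
  # the published joining-heptamer variants differ at these counts
  expect_identical(mismatch_count("ggctgtg", "cactgtg"), 2L)
  expect_identical(mismatch_count("caatgtg", "cactgtg"), 1L)
  expect_error(mismatch_count("cacagtg", "cacagtga"), "equal length")
})

test_that("the canonical-RS rule applies occurrence then tolerance clauses", {
  # found in >1 functional gene: canonical regardless of mismatches
  r <- is_canonical_rs("ttttttt", "cacagtg", "heptamer", functional_occurrence_count = 2)
  expect_true(r$canonical)
  expect_match(r$reason, "functional genes")
  # singleton heptamer, 1 mismatch: canonical by tolerance
  r2 <- is_canonical_rs("cacagta", "cacagtg", "heptamer", functional_occurrence_count = 1)
  expect_true(r2$canonical)
  # singleton heptamer beyond tolerance: flagged as a possible
  # rearrangement-evidence exception (the IGHJ2-like case)
  r3 <- is_canonical_rs("ggctgtg", c("cactgtg", "caatgtg"), "heptamer",
    functional_occurrence_count = 1
  )
  expect_false(r3$canonical)
  expect_match(r3$reason, "rearrangement")
  # with consensus variants the minimum mismatch anchors the tolerance clause
  r4 <- is_canonical_rs("caatgtg", c("cactgtg", "caatgtg"), "heptamer", 1)
  expect_true(r4$canonical)
  expect_identical(r4$mismatches, 0L)
  # nonamers tolerate two mutations
  expect_true(is_canonical_rs("ggtttttAA", "ggtttttgt", "nonamer", 1)$canonical)
  expect_false(is_canonical_rs("ggttttAAA", "ggtttttgt", "nonamer", 1)$canonical)
})

test_that("canonicality is monotone in mismatch count", {
  cons <- "cacagtg"
  base <- "cacagtg"
  muts <- c("aacagtg", "atcagtg", "attagtg", "attcgtg")
  canon <- vapply(
    c(base, muts),
    function(s) is_canonical_rs(s, cons, "heptamer", 1)$canonical, logical(1)
  )
  # once canonicality is lost it is never regained at higher mismatch counts
  expect_identical(canon, !cumsum(!canon) > 0)
})

test_that("position frequency matrices conserve counts", {
  p <- rs_pfm(c("cacagtg", "cacagtg", "cacagtg", "cacagtg"))
  expect_identical(attr(p, "n_sequences"), 4L)
  top <- dplyr::filter(p, .data$freq == 1)
  expect_identical(nrow(top), 7L)
  p2 <- rs_pfm(c("cacagtg", "cacagag"))
  col6 <- dplyr::filter(p2, .data$position == 6, .data$count > 0)
  expect_identical(sort(col6$freq), c(0.5, 0.5))
  withr::with_seed(10, {
    seqs <- vapply(1:12, function(i) tolower(random_dna(9)), "")
    p3 <- rs_pfm(seqs)
    sums <- dplyr::summarise(dplyr::group_by(p3, .data$position), s = sum(.data$count))
    expect_true(all(sums$s == 12L))
  })
})

test_that("spacer classes follow the 12/23 rule per locus and side", {
  expect_identical(rs_spacer_length("IGH", "V-RS"), 23L)
  expect_identical(rs_spacer_length("IGH", "5'D-RS"), 12L)
  expect_identical(rs_spacer_length("IGK", "V-RS"), 12L)
  expect_identical(rs_spacer_length("IGK", "J-RS"), 23L)
  expect_identical(rs_spacer_length("IGL", "V-RS"), 23L)
  expect_identical(rs_spacer_length("IGL", "J-RS"), 12L)
  expect_error(rs_spacer_length("IGH", "C-RS"), "no spacer class")
  custom <- tibble::tibble(locus_id = "X", side = "V-RS", spacer = 15L)
  expect_identical(rs_spacer_length("X", "V-RS", custom), 15L)
})

test_that("a planted motif survives consensus at low mutation rates", {
  withr::with_seed(123, {
    motif <- "cacagtg"
    n <- 25
    seqs <- vapply(seq_len(n), function(i) {
      ch <- strsplit(motif, "")[[1]]
      hit <- which(stats::runif(7) < 0.05)
      for (p in hit) ch[p] <- sample(setdiff(c("a", "c", "g", "t"), ch[p]), 1)
      paste(ch, collapse = "")
    }, character(1))
    expect_identical(as.character(consensus_string(seqs)), motif)
  })
})
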