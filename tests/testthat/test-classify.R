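test_that("percent identity matches the definition on simple cases", {
  expect_equal(percent_identity("ACGTACGT", "ACGTACGT"), 1.0)
  expect_equal(percent_identity("AAAA", "AAAT"), 0.75)
  expect_equal(percent_identity("AAAA", "TTTT"), 0)
  expect_equal(
    percent_identity("ACGTAC", "GTAC"),
    percent_identity("GTAC", "ACGTAC")
  )
  expect_error(percent_identity("", "ACGT"), "non-empty")
})

test_that("percent identity equals a full affine-gap DP oracle", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      a <- random_dna(60)
      # plant 10 substitutions and one 3-nt deletion
      ch <- strsplit(a, "")[[1]]
      pos <- sample(60, 10)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      b <- paste(ch[-(25:27)], collapse = "")
      expect_equal(percent_identity(a, b), oracle_identity(a, b), tolerance = 1e-9)
    }
  })
})

test_that("subgroup clustering applies single-linkage closure above 75%", {
  seqs <- setNames(rep(strrep("ACGT", 25), 5), paste0("g", 1:5))
  cl <- cluster_subgroups(seqs)
  expect_identical(length(unique(cl$cluster)), 1L)

  # two families: within-family identity >= 0.9, cross-family <= 0.5
  withr::with_seed(5, {
    f1 <- random_dna(120)
    f2 <- random_dna(120)
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      for (p in sample(length(ch), k)) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }
    seqs <- c(a1 = f1, a2 = mut(f1, 5), a3 = mut(f1, 8), b1 = f2, b2 = mut(f2, 6))
    m <- identity_matrix(seqs)
    expect_true(all(m[1:3, 1:3] >= 0.85))
    expect_true(all(m[1:3, 4:5] <= 0.5))
    cl <- cluster_subgroups(seqs, identities = m)
    expect_identical(length(unique(cl$cluster)), 2L)
    expect_identical(length(unique(cl$cluster[1:3])), 1L)
  })

  # chain closure on a synthetic identity matrix: A-B 0.80, B-C 0.80, A-C 0.70
  m <- matrix(c(1, .8, .7, .8, 1, .8, .7, .8, 1), 3,
    dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  cl <- cluster_subgroups(c(A = "ACGT", B = "ACGT", C = "ACGT"), identities = m)
  expect_identical(length(unique(cl$cluster)), 1L)
  # exactly 75.0% is NOT the same subgroup (strictly greater than)
  m2 <- m
  m2[m2 == .8] <- .75
  cl2 <- cluster_subgroups(c(A = "ACGT", B = "ACGT", C = "ACGT"), identities = m2)
  expect_identical(length(unique(cl2$cluster)), 3L)
})

test_that("clustering is invariant to input order and to threshold extremes", {
  withr::with_seed(9, {
    f1 <- random_dna(90)
    f2 <- random_dna(90)
    seqs <- c(a = f1, b = f1, c = f2, d = f2)
    m <- identity_matrix(seqs)
    cl1 <- cluster_subgroups(seqs, identities = m)
    perm <- c("d", "b", "a", "c")
    cl2 <- cluster_subgroups(seqs[perm], identities = m[perm, perm])
    j <- match(cl1$gene_name, cl2$gene_name)
    # same partition regardless of labels
    expect_identical(
      outer(cl1$cluster, cl1$cluster, "=="),
      outer(cl2$cluster[j], cl2$cluster[j], "==")
    )
    expect_identical(length(unique(cluster_subgroups(seqs, threshold = 0, identities = m)$cluster)), 1L)
    clt <- cluster_subgroups(seqs, threshold = 1, identities = m)
    expect_identical(length(unique(clt$cluster)), 2L) # exact duplicates stay together
  })
})

test_that("gene naming runs 3'->5' for V genes and suffixes duplicates", {
  genes <- tibble::tibble(
    gene_key = c("x", "y", "z"), gene_type = "V", subgroup = "IGKV1",
    start = c(100L, 500L, 900L), end = c(400L, 800L, 1200L),
    localized = TRUE, core = c("AAA", "CCC", "GGG")
  )
  named <- assign_gene_names(genes)
  # the most 3' V gene (largest coordinate) takes number 1
  expect_identical(named$gene_name, c("IGKV1-3", "IGKV1-2", "IGKV1-1"))

  # duplicated gene: adjacent identical core gets the same number plus D
  genes2 <- tibble::tibble(
    gene_key = c("d2", "d1", "w"), gene_type = "V", subgroup = "IGHV3",
    start = c(100L, 500L, 900L), end = c(400L, 800L, 1200L),
    localized = TRUE, core = c("TTTT", "TTTT", "ACGT")
  )
  named2 <- assign_gene_names(genes2)
  expect_identical(named2$gene_name, c("IGHV3-2D", "IGHV3-2", "IGHV3-1"))

  # unlocalized genes get provisional S names in input order
  genes3 <- tibble::tibble(
    gene_key = c("u1", "u2"), gene_type = "V", subgroup = "IGLV5",
    start = NA_integer_, end = NA_integer_, localized = FALSE,
    core = c("AA", "CC")
  )
  expect_identical(assign_gene_names(genes3)$gene_name, c("IGLV5S1", "IGLV5S2"))
})

test_that("allele matching applies the 100% identity rule", {
  dir <- tibble::tibble(
    gene_name = c("IGKV1-5", "IGKV1-5"), allele_number = c(1L, 2L),
    core = c("ACGTACGT", "ACGTACGA")
  )
  m <- match_allele("acgtacgt", dir, "IGKV1-5")
  expect_identical(m$allele_name, "IGKV1-5*01")
  expect_identical(m$provenance, "literature")
  expect_false(m$is_new)
  # one substitution: next free number, becomes the reference
  m2 <- match_allele("ACGTACGC", dir, "IGKV1-5")
  expect_identical(m2$allele_name, "IGKV1-5*03")
  expect_identical(m2$provenance, "reference")
  expect_true(m2$is_new)
  # unseen gene starts at *01
  m3 <- match_allele("TTTT", dir, "IGKV2-1")
  expect_identical(m3$allele_name, "IGKV2-1*01")
  expect_true(m3$is_new)
  # idempotence: re-matching a stored reference returns the same name
  m4 <- match_allele(m$allele_name <- dir$core[1], dir, "IGKV1-5")
  expect_identical(m4$allele_name, "IGKV1-5*01")
  expect_identical(m4$provenance, "literature")
  # exact match to alleles of two different genes is a conflict
  dir2 <- tibble::tibble(
    gene_name = c("A", "B"), allele_number = c(1L, 1L), core = c("ACGT", "ACGT")
  )
  expect_error(match_allele("ACGT", dir2, "C"), "multiple genes")
})

test_that("functionality calls follow the F/ORF/P hierarchy", {
  stop_tr <- translate_v_region("ATGTAACCC") # stop at codon 2
  expect_identical(classify_functionality("V", stop_tr)$call, "P")
  expect_true("STOP_CODON" %in% classify_functionality("V", stop_tr)$defects$code)

  clean <- translate_v_region("ATGGCCGTT")
  expect_identical(classify_functionality("V", clean)$call, "F")
  expect_identical(classify_functionality("V", clean, has_init_codon = FALSE)$call, "P")
  expect_identical(classify_functionality("V", clean, rs_canonical = FALSE)$call, "ORF")
  expect_identical(classify_functionality("V", clean, splice_ok = FALSE)$call, "ORF")
  expect_identical(classify_functionality("V", clean, promoter_ok = FALSE)$call, "ORF")
  bad_w41 <- tibble::tibble(
    position = c(23L, 41L, 89L, 104L), residue = c("C", "R", "L", "C"),
    expected = c("C", "W", "hydrophobic", "C"), pass = c(TRUE, FALSE, TRUE, TRUE)
  )
  r <- classify_functionality("V", clean, conserved = bad_w41)
  expect_identical(r$call, "ORF")
  expect_true("NONCONSERVED_AA" %in% r$defects$code)
  # frameshift
  fs <- translate_v_region("ATGGCCGT")
  expect_identical(classify_functionality("V", fs)$call, "P")
  # D genes have no initiation-codon requirement
  expect_identical(classify_functionality("D", NULL, has_init_codon = FALSE)$call, "F")
})

test_that("functionality is monotone in defect severity", {
  clean <- translate_v_region("ATGGCCGTT")
  stop_tr <- translate_v_region("ATGTAACCC")
  # adding a P-level defect to any configuration yields P
  for (rs in c(TRUE, FALSE)) {
    expect_identical(classify_functionality("V", stop_tr, rs_canonical = rs)$call, "P")
  }
  # adding an ORF-level defect to an F allele yields ORF, never P
  expect_identical(
    classify_functionality("V", clean, rs_canonical = FALSE, splice_ok = FALSE)$call,
    "ORF"
  )
})

test_that("gene-level labels combine allele calls", {
  expect_identical(gene_functionality_label(c("F", "F")), "F")
  expect_identical(gene_functionality_label(c("F", "P")), "FP")
  expect_identical(gene_functionality_label(c("F", "ORF")), "FO")
  expect_identical(gene_functionality_label(c("ORF", "P")), "OP")
  expect_identical(gene_functionality_label("P"), "P")
  expect_error(gene_functionality_label(character(0)), "at least one")
})
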