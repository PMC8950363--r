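test_that("the octamer and decamer are inverted-complementary forms", {
  # motif-table self-check: reverse complement of ATGCAAAT equals the last
  # 8 nt of the decamer consensus, which adds two 5' bases
  expect_identical(revcomp("ATGCAAAT"), "ATTTGCAT")
  igk <- promoter_elements("IGK")
  dec <- igk$pattern[igk$name == "DECAMER"]
  expect_identical(substr(dec, 3, 10), revcomp("ATGCAAAT"))
  igh <- promoter_elements("IGH")
  expect_identical(igh$pattern[igh$name == "OCTAMER"], "ATGCAAAT")
})

test_that("5' UTR extraction is window-limited and strand-corrected", {
  withr::with_seed(14, {
    up <- random_dna(600)
    seqstr <- paste0(up, "ATG", random_dna(50))
    loc <- ig_locus("IGH", seqstr)
    utr <- extract_5utr(loc, 601L, "+", window = 500L)
    expect_identical(nchar(utr), 500L)
    expect_false(attr(utr, "truncated"))
    expect_identical(as.character(utr), substr(seqstr, 101, 600))
    # a 7-nt marker whose 3' end lies 100 nt upstream of the ATG ends at
    # window position 401 of 500 (offset 100 -> locus position 501)
    marked <- paste0(
      substr(seqstr, 1, 494), "GGGCCCG", substr(seqstr, 502, nchar(seqstr))
    )
    mloc <- ig_locus("IGH", marked)
    mutr <- extract_5utr(mloc, 601L, "+", window = 500L)
    expect_identical(substr(as.character(mutr), 395, 401), "GGGCCCG")

    # short upstream flank: truncated window
    loc2 <- ig_locus("IGH", paste0(random_dna(200), "ATG", random_dna(10)))
    utr2 <- extract_5utr(loc2, 201L, "+", window = 500L)
    expect_identical(nchar(utr2), 200L)
    expect_true(attr(utr2, "truncated"))

    # inverted gene: window is the reverse complement of the downstream flank
    fwd_gene <- paste0(up, "ATG", random_dna(50))
    inv <- revcomp(fwd_gene)
    iloc <- ig_locus("IGH", inv)
    atg_locus <- nchar(inv) - 600L # locus coordinate of the A on the - strand
    iutr <- extract_5utr(iloc, atg_locus, "-", window = 500L)
    expect_identical(as.character(iutr), substr(fwd_gene, 101, 600))

    expect_error(extract_5utr(loc, 600L, "+"), "no ATG")
  })
})

test_that("element scanning matches a brute-force sliding-window oracle", {
  withr::with_seed(15, {
    utr <- paste0(random_dna(110), "ATGCAAAT", random_dna(80))
    hits <- scan_element(utr, "OCTAMER", pattern = "ATGCAAAT")
    expect_identical(hits$start, 111L)
    expect_identical(hits$mismatches, 0L)
    # oracle equivalence at zero mismatches, degenerate pattern included
    for (pat in c("ATGCAAAT", "CANNTG", "NNATTTGCAT")) {
      got <- scan_element(utr, "x", pattern = pat)$start
      expect_identical(got, oracle_scan(utr, pat))
    }
  })
  # published decamer consensus matches the degenerate pattern exactly
  d <- scan_element(paste0("GGG", "AGATTTGCAT", "GGG"), "DECAMER",
    pattern = "NNATTTGCAT"
  )
  expect_identical(d$mismatches, 0L)
  expect_identical(d$sequence, "AGATTTGCAT")
  # E-box pattern definition
  expect_identical(nrow(scan_element("GGCAGGTGGG", "E_BOX", pattern = "CANNTG")), 1L)
  expect_identical(nrow(scan_element("GGCAGGTAGG", "E_BOX", pattern = "CANNTG")), 0L)
  # the pentadecamer carries an inner E-box at positions 3-8
  pent <- "TGCAACTGTGTCCAG"
  expect_true(nrow(scan_element(pent, "PENTADECAMER", pattern = "TGCANCTGTGNCCAG")) == 1)
  eb <- scan_element(pent, "E_BOX", pattern = "CANNTG")
  expect_identical(eb$start, 3L)
  # degenerate n positions never count as mismatches
  m <- scan_element("GGACATTTGCATGG", "DECAMER", pattern = "NNATTTGCAT", max_mismatches = 0)
  expect_identical(m$mismatches, 0L)
})

test_that("TATA and pyrimidine-rich rules find runs and windowed regions", {
  t <- scan_element("GGGTATATAAGGG", "TATA_BOX", rule = "at_run")
  expect_identical(t$sequence, "TATATAA")
  expect_identical(nrow(scan_element("GGGTATAGGG", "TATA_BOX", rule = "at_run")), 0L)
  p <- scan_element(paste0("GAGAGAGAGA", "TCCTCCTTCCTCCT", "GAGAGAGAGA"),
    "PYRIMIDINE_RICH",
    rule = "pyrimidine_rich"
  )
  expect_identical(nrow(p), 1L)
  expect_true(p$start <= 11 && p$end >= 24)
  expect_identical(
    nrow(scan_element(strrep("GA", 30), "PYRIMIDINE_RICH", rule = "pyrimidine_rich")),
    0L
  )
})

test_that("promoter annotation walks the canonical order 3' to 5'", {
  withr::with_seed(16, {
    # kappa-style promoter: pentadecamer - CCCT - decamer - CCCT - TATA - ATG
    synth <- generate_locus(small_spec("IGK", seed = 99))
    g <- synth$genes[synth$genes$gene_type == "V" & synth$genes$localized &
      is.na(synth$genes$defect), ][1, ]
    utr <- extract_5utr(synth$locus, g$atg_position, g$strand, check = FALSE)
    ann <- annotate_promoter(utr, promoter_elements("IGK"))
    core <- ann[ann$name != "E_BOX", ]
    expect_true(all(core$found))
    # offsets strictly increase along the ordered element list
    expect_true(all(diff(core$offset_start) > 0))
    expect_identical(
      architecture_key(ann),
      "TATA_BOX-CCCT_3-DECAMER-CCCT_5-PENTADECAMER"
    )
    truth <- synth$promoters[synth$promoters$gene_key == g$gene_key, ]
    j <- dplyr::inner_join(truth, core, by = "name")
    expect_identical(j$offset_start.x, j$offset_start.y)
  })
})

test_that("a heavy-chain-style promoter places the TATA between ATG and octamer", {
  synth <- generate_locus(small_spec("IGH", seed = 101))
  g <- synth$genes[synth$genes$gene_type == "V" & synth$genes$localized &
    is.na(synth$genes$defect), ][1, ]
  utr <- extract_5utr(synth$locus, g$atg_position, g$strand, check = FALSE)
  ann <- annotate_promoter(utr, promoter_elements("IGH"))
  tata <- ann[ann$name == "TATA_BOX", ]
  oct <- ann[ann$name == "OCTAMER", ]
  expect_true(tata$found && oct$found)
  expect_true(tata$offset_start < oct$offset_start)
})

test_that("a missing core element is data, not an error", {
  withr::with_seed(18, {
    utr <- paste0(random_dna(100), "TATATAA", random_dna(40))
    utr <- gsub("CCCT", "GGAT", utr, fixed = TRUE)
    ann <- annotate_promoter(utr, promoter_elements("IGK"))
    expect_false(ann$found[ann$name == "DECAMER"])
    expect_false(grepl("DECAMER", architecture_key(ann)))
  })
})

test_that("subgroup architecture summarizes presence, offsets and consensus", {
  withr::with_seed(19, {
    # 30 genes planting a TATA at mean offset 53 with +-3 jitter
    rows <- purrr::map(1:30, function(i) {
      off <- 53L + sample(-3:3, 1)
      tibble::tibble(
        allele_ref = paste0("g", i), subgroup = "S1", name = "TATA_BOX",
        found = TRUE, offset_start = off, offset_end = off + 6L,
        sequence = "TATATAA", mismatches = 0L
      )
    }) |> dplyr::bind_rows()
    arch <- subgroup_architecture(rows)
    expect_equal(arch$presence, 1)
    expect_lt(abs(arch$offset_mean - 53), 1)
    expect_identical(arch$consensus, "tatataa")
    # mixed presence 7/10
    rows2 <- tibble::tibble(
      allele_ref = paste0("h", 1:10), subgroup = "S2", name = "DECAMER",
      found = rep(c(TRUE, FALSE), c(7, 3)),
      offset_start = c(rep(100L, 7), NA, NA, NA),
      offset_end = c(rep(109L, 7), NA, NA, NA),
      sequence = c(rep("AGATTTGCAT", 7), NA, NA, NA), mismatches = 0L
    )
    arch2 <- subgroup_architecture(rows2)
    expect_equal(arch2$presence, 0.7)
    expect_identical(arch2$offset_min, 100L)
  })
})
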