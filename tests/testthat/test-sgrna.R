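test_that("candidate enumeration matches the brute-force scan on random genomes", {
  for (seed in 1:4) {
    g <- random_genome(c(a = 4000L, b = 3000L), seed = 100 + seed)
    # plant a tandem repeat so real candidates exist
    unit <- "GATTACAGATTACAGATTACAGG"
    substr(g[["a"]], 501, 500 + nchar(unit) * 25) <- strrep(unit, 25)
    got <- enumerate_sgrna_candidates(g, min_copies = 20)
    want <- oracle_kmer_counts(g)
    want_tot <- aggregate(count ~ sequence, want, sum)
    want_max <- aggregate(count ~ sequence, want, max)
    keep <- want_max$sequence[want_max$count >= 20]
    expect_setequal(unique(got$sequence), keep)
    for (sq in keep) {
      for (chrom in names(g)) {
        w <- want$count[want$sequence == sq & want$chrom == chrom]
        expect_equal(got$count[got$sequence == sq & got$chrom == chrom],
                     if (length(w)) w else 0L,
                     info = paste(seed, sq, chrom))
      }
    }
  }
})

test_that("counting is strand-symmetric and respects the copy-number cutoff", {
  g <- random_genome(c(a = 3000L), seed = 7)
  unit <- "TTACGCAAGTCCATAGCTTAAGG"
  substr(g[["a"]], 101, 100 + 23 * 30) <- strrep(unit, 30)
  got <- enumerate_sgrna_candidates(g)
  grc <- c(a = oracle_revcomp(g[["a"]]))
  got_rc <- enumerate_sgrna_candidates(grc)
  expect_equal(
    dplyr::arrange(as.data.frame(got), sequence, chrom),
    dplyr::arrange(as.data.frame(got_rc), sequence, chrom)
  )

  # a 22-mer present exactly 19 times is not returned at min_copies = 20
  g2 <- c(z = paste0(strrep("T", 50),
                     strrep("CTTACGCAAGTCCATAGCTAGG", 19), strrep("T", 50)))
  got2 <- enumerate_sgrna_candidates(g2, min_copies = 20)
  expect_false("CTTACGCAAGTCCATAGCTAGG" %in% got2$sequence)
  got2b <- enumerate_sgrna_candidates(g2, min_copies = 19)
  expect_true("CTTACGCAAGTCCATAGCTAGG" %in% got2b$sequence)

  expect_equal(nrow(enumerate_sgrna_candidates(character())), 0)
  expect_error(enumerate_sgrna_candidates(c(a = "ACGTX")), "non-ACGTN")
})

test_that("specificity follows fc / (1 + sum off) with a strict > 19 retention", {
  stats <- tibble::tibble(
    sequence = rep(c("s1", "s2", "s3"), each = 2),
    chrom = rep(c("cX", "c1"), 3),
    count = c(40L, 1L, 19L, 0L, 0L, 5L),
    total = rep(c(41L, 19L, 5L), each = 2),
    max_count = rep(c(40L, 19L, 5L), each = 2)
  )
  sp <- sgrna_specificity(stats, "cX")
  expect_equal(sp$specificity[sp$sequence == "s1"], 40 / 2)  # retained (20 > 19)
  expect_equal(sp$specificity[sp$sequence == "s2"], 19)      # NOT retained
  expect_equal(sp$specificity[sp$sequence == "s3"], 0)
  retained <- sp$sequence[sp$specificity > 19]
  expect_identical(retained, "s1")
})

test_that("focal regions match the exhaustive window oracle", {
  k <- 23L
  # fc = 45, no off-target copies: bound floor((45-20)/21) = 1, so a window
  # holding 44 of 45 qualifies and one holding 43 does not
  occ1 <- c(seq(0, by = 20000, length.out = 44), 2.5e6)
  r1 <- find_focal_regions(occ1, total_off = 0, k = k)
  o1 <- oracle_focal_regions(occ1, 0, k)
  expect_equal(r1$start, o1$start)
  expect_equal(r1$end, o1$end)
  expect_equal(r1$n_outside, o1$n_outside)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$n_outside, 1)

  occ2 <- c(seq(0, by = 20000, length.out = 43), 2.4e6, 2.5e6)
  expect_equal(nrow(find_focal_regions(occ2, 0, k = k)), 0)

  # fc = 20, sum off = 0: only the region with ALL copies qualifies
  occ3 <- seq(0, by = 40000, length.out = 20)
  r3 <- find_focal_regions(occ3, 0, k = k)
  expect_equal(r3$n_outside, 0)
  expect_equal(r3$in_region, 20)

  # fully clustered: single region, specificity = fc
  occ4 <- seq(0, by = 300, length.out = 30)
  r4 <- find_focal_regions(occ4, 0, k = k)
  expect_equal(nrow(r4), 1)
  expect_equal(r4$specificity_in_region, 30)

  # randomized agreement with the oracle
  for (seed in 1:20) {
    set.seed(200 + seed)
    occ <- sort(sample.int(3e6, sample(20:60, 1)))
    toff <- sample(0:1, 1)
    got <- find_focal_regions(occ, toff, k = k)
    want <- oracle_focal_regions(occ, toff, k)
    expect_equal(got$start, want$start, info = seed)
    expect_equal(got$end, want$end, info = seed)
    expect_equal(got$n_outside, want$n_outside, info = seed)
  }
})

test_that("end-to-end search recovers the planted repeat and rejects decoys", {
  cfg <- sim_config(
    seed = 55,
    chromosomes = tibble::tibble(chrom = c("c1", "c2", "cX"),
                                 length = c(40000L, 40000L, 2500000L)),
    induced_chrom = "cX",
    n_snps_per_kb = 0.2,
    repeat_plants = tibble::tibble(
      chrom = c("cX", "cX", "cX"),
      start = c(100000L, 400000L, 150000L),
      unit = c("ATGCATTGACCTGAGTCAATAGG",   # genuine: 30 tandem copies, 0 off
               "CGTTAGGCAACTTAGCCTGATGG",   # decoy: off-chromosome copies
               "TTACGCAAGTCCATAGCTTAAGG"),  # decoy: split across > 1 Mb
      n_copies = c(30L, 30L, 15L),
      n_off = c(0L, 6L, 0L)
    )
  )
  # second cluster of the split decoy, 1.8 Mb away from the default-centred one
  g <- simulate_genome(cfg)
  unit3 <- "TTACGCAAGTCCATAGCTTAAGG"
  substr(g$hap1[["cX"]], 2200001, 2200000 + 23 * 15) <- strrep(unit3, 15)
  substr(g$hap2[["cX"]], 2200001, 2200000 + 23 * 15) <- strrep(unit3, 15)

  res <- sgrna_find(g$hap1, "cX")
  # the genuine unit is reported with a region at the planted coordinates
  hit <- res$report[res$report$sequence == "ATGCATTGACCTGAGTCAATAGG", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$region_start, 100000)
  expect_equal(hit$region_end, 100000 + 23 * 30)
  expect_gte(hit$specificity_in_region, 20)
  # decoy with off-chromosome copies: specificity 30 / (1 + 6) < 19
  expect_false("CGTTAGGCAACTTAGCCTGATGG" %in% res$report$sequence)
  # split decoy: chromosome-specific (30 copies) but no sub-Mb region
  expect_false(unit3 %in% res$report$sequence)
})

test_that("report_targets writes deterministic BED/TSV and merges duplicates", {
  rep_tbl <- tibble::tibble(
    sequence = c("BBB", "AAA"), chrom = "cX", count = 30L, total_off = 0L,
    specificity = 30, region_start = c(100L, 100L), region_end = c(800L, 800L),
    in_region = 30L, n_outside = 0L, specificity_in_region = 30
  )
  out <- report_targets(rep_tbl, merge = TRUE)
  expect_equal(nrow(out$tsv), 2)
  expect_equal(nrow(out$bed), 1)
  expect_equal(out$bed$name, "AAA,BBB")
  out2 <- report_targets(rep_tbl, merge = FALSE)
  expect_equal(nrow(out2$bed), 2)
  expect_identical(out2$tsv$sequence, c("AAA", "BBB"))  # deterministic order

  empty <- report_targets(rep_tbl[0, ])
  expect_equal(nrow(empty$bed), 0)

  tf <- tempfile(fileext = ".bed"); tf2 <- tempfile(fileext = ".tsv")
  report_targets(rep_tbl, bed_path = tf, tsv_path = tf2)
  expect_true(file.exists(tf) && file.exists(tf2))
})
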