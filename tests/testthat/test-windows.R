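test_that("tiling partitions every chromosome exactly once", {
  tiles <- tile_genome(c(a = 25000, b = 10000), width = 10000)
  expect_equal(tiles$start[tiles$chrom == "a"], c(0, 10000, 20000))
  expect_equal(tiles$end[tiles$chrom == "a"], c(10000, 20000, 25000))
  expect_equal(sum(tiles$chrom == "b"), 1)
  # partition property on random sizes
  for (size in c(9999, 10000, 10001, 123457)) {
    tl <- tile_genome(c(z = size), width = 10000)
    expect_equal(nrow(tl), ceiling(size / 10000))
    expect_equal(tl$start, c(0, head(tl$end, -1)))
    expect_equal(tl$end[nrow(tl)], size)
  }
})

test_that("consensus peaks equal the per-base bitmap AND of merged replicates", {
  r1 <- tibble::tibble(chrom = "c", start = 100L, end = 200L)
  r2 <- tibble::tibble(chrom = "c", start = 150L, end = 250L)
  cons <- consensus_peaks(list(r1, r2))
  expect_equal(cons, tibble::tibble(chrom = "c", start = 150L, end = 200L))

  disj <- consensus_peaks(list(r1, tibble::tibble(chrom = "c", start = 300L,
                                                  end = 400L)))
  expect_equal(nrow(disj), 0)

  expect_warning(
    empty <- consensus_peaks(list(r1, r1[0, ])),
    "empty")
  expect_equal(nrow(empty), 0)
  expect_error(consensus_peaks(list(r1)), ">= 2")

  set.seed(91)
  L <- 5000L
  for (i in 1:30) {
    reps <- lapply(1:3, function(j) {
      n <- sample(3:12, 1)
      s <- sort(sample.int(L - 100L, n))
      tibble::tibble(chrom = "c", start = s,
                     end = pmin(s + sample(20:400, n, replace = TRUE), L))
    })
    got <- consensus_peaks(reps)
    want <- intervals_of(Reduce(`&`, lapply(reps, bitmap_of, L = L)))
    expect_equal(got$start, want$start, info = i)
    expect_equal(got$end, want$end, info = i)
  }
})

test_that("density-intersection threshold sits between well-separated modes", {
  set.seed(92)
  act <- rnorm(200, 0.010, 0.003)
  ina <- rnorm(200, 0.100, 0.020)
  thr <- h3k27me3_threshold(act, ina)
  expect_gt(thr, 0.02); expect_lt(thr, 0.06)

  # fine-grid brute-force crossing of the same two KDEs
  lo <- min(median(act), median(ina)); hi <- max(median(act), median(ina))
  grid <- seq(lo, hi, length.out = 20000)
  da <- density(act, bw = bw.nrd(act), from = lo, to = hi, n = 20000)$y
  di <- density(ina, bw = bw.nrd(ina), from = lo, to = hi, n = 20000)$y
  brute <- grid[which(sign(da - di)[-1] != sign(da - di)[-20000])[1]]
  expect_equal(thr, brute, tolerance = 0.1 * brute)

  expect_error(h3k27me3_threshold(act, act), "crossing|coincide")
  expect_error(h3k27me3_threshold(act[1:5], ina), ">= 30")
  expect_equal(h3k27me3_default_threshold, 0.035)
})

test_that("gene classification matches hand-computed truth for every rule combination", {
  ann <- simulate_annotation(n_genes = 60, seed = 93)
  k9 <- consensus_peaks(ann$peaks$k9ac)
  k4 <- consensus_peaks(ann$peaks$k4me3)
  cls <- classify_genes(ann$transcripts, k9, k4, ann$h3k27me3_t0, ann$tpm)
  merged <- dplyr::inner_join(cls, ann$truth, by = "gene_id")
  expect_equal(merged$category.x, merged$category.y)
  # reasons line up with the design
  expect_true(all(merged$reason[merged$design == "bivalent"] == "bivalent"))
  expect_true(all(merged$reason[merged$design == "single_mark"] == "single_mark"))

  # order independence
  shuf <- ann$transcripts[sample(nrow(ann$transcripts)), ]
  cls2 <- classify_genes(shuf, k9, k4, ann$h3k27me3_t0, ann$tpm)
  expect_equal(cls, cls2)

  # gene without an expression record is excluded with a reason
  cls3 <- classify_genes(ann$transcripts, k9, k4, ann$h3k27me3_t0,
                         ann$tpm[-1, ])
  expect_equal(cls3$reason[cls3$gene_id == ann$tpm$gene_id[1]],
               "no_expression_record")
})

test_that("explicit rule-combination cases classify as specified", {
  tx <- tibble::tibble(gene_id = "g", transcript_id = "g.t1", chrom = "c",
                       strand = "+", start = 1000L, end = 5000L)
  peak_at_tss <- tibble::tibble(chrom = "c", start = 900L, end = 1100L)
  no_peak <- tibble::tibble(chrom = "c", start = 8000L, end = 8100L)
  k27 <- function(v) tibble::tibble(gene_id = "g", signal = v)
  tpm <- function(v) tibble::tibble(gene_id = "g", tpm = v)

  run <- function(k9, k4, sig, expr) {
    classify_genes(tx, k9, k4, k27(sig), tpm(expr))$category
  }
  expect_equal(run(peak_at_tss, peak_at_tss, 0.01, 5), "initially_active")
  expect_equal(run(peak_at_tss, peak_at_tss, 0.05, 5), "excluded")  # bivalent
  expect_equal(run(no_peak, no_peak, 0.01, 0.2), "silent")
  expect_equal(run(no_peak, no_peak, 0.01, 5), "excluded")  # expressed, no marks
  expect_equal(run(peak_at_tss, no_peak, 0.01, 5), "excluded")  # single mark
  expect_equal(run(peak_at_tss, peak_at_tss, 0.01, 0.2), "excluded")  # low TPM

  # TSS rule is the exact base: a peak ending AT the TSS does not overlap it
  peak_left <- tibble::tibble(chrom = "c", start = 900L, end = 1000L)
  expect_equal(run(peak_left, peak_left, 0.01, 5), "excluded")
  # minus-strand TSS is the right end
  tx_m <- dplyr::mutate(tx, strand = "-")
  peak_right <- tibble::tibble(chrom = "c", start = 4900L, end = 5000L)
  expect_equal(
    classify_genes(tx_m, peak_right, peak_right, k27(0.01), tpm(5))$category,
    "initially_active")
})

test_that("intergenic windows agree with the per-base bitmap oracle", {
  tiles <- tile_genome(c(c = 100000), width = 10000)
  genes <- tibble::tibble(chrom = "c", start = c(15000L, 52000L),
                          end = c(18000L, 60000L), strand = c("+", "-"))
  enh <- tibble::tibble(chrom = "c", start = 85000L, end = 85500L)

  ig <- intergenic_windows(tiles, genes, enh)
  # bitmap oracle: gene bodies + strand-aware 2 kb promoters + enhancers
  mask <- dplyr::bind_rows(
    genes[, c("chrom", "start", "end")],
    tibble::tibble(chrom = "c", start = 13000L, end = 15000L),  # + promoter
    tibble::tibble(chrom = "c", start = 60000L, end = 62000L),  # - promoter
    enh
  )
  bm <- bitmap_of(mask, 100000L)
  want <- vapply(seq_len(nrow(tiles)), function(i) {
    !any(bm[(tiles$start[i] + 1):tiles$end[i]])
  }, logical(1))
  expect_equal(ig$window, tiles$window[want])

  # tile 1.5 kb upstream of a + TSS is excluded via the promoter
  tiles2 <- tile_genome(c(c = 30000), width = 10000)
  genes2 <- tibble::tibble(chrom = "c", start = 21500L, end = 25000L,
                           strand = "+")
  ig2 <- intergenic_windows(tiles2, genes2)
  expect_false("c:10000-20000" %in% ig2$window)  # promoter reaches 19500
  expect_true("c:0-10000" %in% ig2$window)

  # random layouts vs oracle
  set.seed(94)
  for (i in 1:15) {
    L <- 80000L
    tl <- tile_genome(c(c = L), width = 5000)
    n <- sample(2:6, 1)
    gs <- sort(sample.int(L - 6000L, n))
    gn <- tibble::tibble(chrom = "c", start = gs,
                         end = gs + sample(1000:5000, n, replace = TRUE),
                         strand = sample(c("+", "-"), n, replace = TRUE))
    got <- intergenic_windows(tl, gn)
    pm <- tibble::tibble(
      chrom = "c",
      start = ifelse(gn$strand == "+", pmax(gn$start - 2000L, 0L), gn$end),
      end = ifelse(gn$strand == "+", gn$start, gn$end + 2000L)
    )
    bm <- bitmap_of(dplyr::bind_rows(gn[, c("chrom", "start", "end")], pm), L)
    want <- tl$window[vapply(seq_len(nrow(tl)), function(j) {
      !any(bm[(tl$start[j] + 1):tl$end[j]])
    }, logical(1))]
    expect_equal(got$window, want, info = i)
  }
})
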