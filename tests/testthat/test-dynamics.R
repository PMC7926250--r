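test_that("noiseless LL.4 curves are recovered to 4 significant digits", {
  tp <- c(0.1, 2, 4, 8, 12, 24)
  # canonical form: c is the lower asymptote, so a decreasing curve given
  # as (b = 1.5, c = 10, d = 2) comes back as the identical (-1.5, 2, 10)
  cases <- list(list(gen = c(-2, 0, 1, 8), want = c(-2, 0, 1, 8)),
                list(gen = c(-4, 50, 150, 6), want = c(-4, 50, 150, 6)),
                list(gen = c(1.5, 10, 2, 12), want = c(-1.5, 2, 10, 12)))
  for (cs in cases) {
    y <- ll4(tp, cs$gen[1], cs$gen[2], cs$gen[3], cs$gen[4])
    f <- fit_ll4(tp, y)
    expect_true(f$converged)
    expect_equal(c(f$b, f$c, f$d, f$e), cs$want, tolerance = 1e-4)
  }
  # t = 0 handled by the limit, increasing curve
  y0 <- ll4(c(0, 4, 8, 12, 24), -4, 5, 20, 8)
  expect_equal(y0[1], 5)
  f0 <- fit_ll4(c(0, 4, 8, 12, 24), y0)
  expect_equal(f0$e, 8, tolerance = 1e-3)
})

test_that("the model identity f(e) = (c+d)/2 holds and flat input is flagged", {
  f <- fit_ll4(c(0, 4, 8, 12, 24), ll4(c(0, 4, 8, 12, 24), -3, 1, 9, 10))
  expect_equal(ll4(f$e, f$b, f$c, f$d, f$e), (f$c + f$d) / 2)
  flat <- fit_ll4(c(0, 4, 8, 12, 24), rep(3, 5))
  expect_false(flat$converged)
  expect_equal(flat$c, flat$d)
  expect_error(fit_ll4(c(1, 2, 3), c(1, 2, 3)), "at least 4")
})

test_that("ED50 recovery on noisy replicated tracks is accurate and unbiased at low noise", {
  set.seed(101)
  sim <- simulate_tracks(300, e_true = rep(c(4, 8, 12), each = 100))
  fits <- fit_accumulation(
    dplyr::rename(sim$tracks, value = "value"))
  fits <- dplyr::inner_join(fits, sim$truth, by = "window")
  err <- abs(fits$e.x - fits$e.y)
  expect_lt(median(err), 1)

  # relative noise -> 0 (Poisson at high depth): error collapses
  set.seed(102)
  sim0 <- simulate_tracks(60, e_true = 8, c = 5e4, d = 1.5e5, dispersion = 0)
  fits0 <- fit_accumulation(sim0$tracks)
  expect_lt(median(abs(fits0$e - 8)), 0.1)
})

test_that("residual filter applies the strict mean + 1.5 SD rule with documented ties", {
  mk <- function(rs) {
    tibble::tibble(window = seq_along(rs), residual_sum = rs,
                   converged = TRUE, e = 8)
  }
  f1 <- filter_fits(mk(c(1, 1, 1, 100)))
  thr <- mean(c(1, 1, 1, 100)) + 1.5 * sd(c(1, 1, 1, 100))
  expect_equal(f1$retained, c(1, 1, 1, 100) < thr)
  expect_false(f1$retained[4])

  # all residuals equal: SD = 0 would reject everything under strict "<";
  # the documented special case retains all
  f2 <- filter_fits(mk(rep(2, 5)))
  expect_true(all(f2$retained))

  # a single 10x outlier among many is excluded
  set.seed(103)
  rs <- c(rgamma(999, 5, 5), 10 * max(rgamma(999, 5, 5)))
  f3 <- filter_fits(mk(rs))
  expect_false(f3$retained[1000])
  expect_gt(mean(f3$retained), 0.95)

  expect_error(filter_fits(mk(1)[FALSE, ]), ">= 2 converged")
})

test_that("ED50 capping maps late/failed windows to exactly 24 and is idempotent", {
  fits <- tibble::tibble(
    window = 1:4,
    e = c(30, 6, NA, 10),
    converged = c(TRUE, TRUE, FALSE, TRUE),
    retained = c(TRUE, TRUE, FALSE, FALSE)
  )
  capped <- cap_ed50(fits)
  expect_equal(capped$ed50_capped, c(24, 6, 24, 24))
  expect_true(all(capped$ed50_capped > 0 & capped$ed50_capped <= 24))
  capped2 <- cap_ed50(capped)
  expect_equal(capped2$ed50_capped, capped$ed50_capped)
})

test_that("paired mark comparison detects a programmed 2-hour shift", {
  set.seed(104)
  a <- runif(100, 4, 20)
  cmp0 <- compare_marks(a, a)
  expect_equal(cmp0$p_value, 1)

  b <- pmin(a + 2, 23.9)
  cmp <- compare_marks(a, b)
  expect_lt(cmp$p_value, 0.05)
  expect_lt(cmp$median_diff, 0)   # mark A earlier

  # windows at or above the cap are excluded; too few pairs error
  expect_error(compare_marks(c(a[1:5], rep(24, 95)), c(b[1:5], rep(24, 95))),
               "need >= 10")
})

test_that("mark ordering is detected end to end from noisy fitted ED50s", {
  set.seed(105)
  e_a <- runif(120, 5, 11)
  sim_a <- simulate_tracks(120, e_true = e_a)
  sim_b <- simulate_tracks(120, e_true = e_a + 2)
  fa <- cap_ed50(filter_fits(fit_accumulation(sim_a$tracks)))
  fb <- cap_ed50(filter_fits(fit_accumulation(sim_b$tracks)))
  cmp <- compare_marks(fa$ed50_capped, fb$ed50_capped)
  expect_lt(cmp$p_value, 0.05)
  expect_lt(cmp$median_diff, 0)
})

test_that("IC35 is below ED50 on increasing curves and classes match generating components", {
  f <- fit_ll4(c(0, 4, 8, 12, 24), ll4(c(0, 4, 8, 12, 24), -4, 0, 10, 10))
  expect_lt(f$ic35, f$ed50)

  set.seed(106)
  truth <- rep(1:3, each = 60)
  vals <- c(rnorm(60, 3, 0.4), rnorm(60, 9, 0.6), rnorm(60, 18, 1))
  cls <- ic35_classes(vals, ids = as.character(seq_along(vals)), seed = 42)
  agreement <- mean(as.integer(cls$class) == truth)
  expect_gte(agreement, 0.95)
  # determinism under the fixed seed
  cls2 <- ic35_classes(vals, ids = as.character(seq_along(vals)), seed = 42)
  expect_identical(cls, cls2)

  expect_error(ic35_classes(rep(5, 10)), "distinct")
})

test_that("per-category correlations behave under identity, independence and structure", {
  set.seed(107)
  x <- rlnorm(200)
  idf <- tibble::tibble(acc_a = x, acc_b = x, category = "g")
  expect_equal(category_correlation(idf)$rho, 1)

  ndf <- tibble::tibble(acc_a = rlnorm(1000), acc_b = rlnorm(1000),
                        category = "g")
  expect_lt(abs(category_correlation(ndf)$rho), 0.1)

  # shared intergenic accumulation vs decoupled gene-body premarking
  n <- 300
  shared <- rlnorm(n, 0, 0.5)
  str_df <- dplyr::bind_rows(
    tibble::tibble(acc_a = shared * rlnorm(n, 0, 0.15),
                   acc_b = shared * rlnorm(n, 0, 0.15),
                   category = "intergenic"),
    tibble::tibble(acc_a = rlnorm(n, 0, 0.5) * rlnorm(n, 0, 0.3),
                   acc_b = rlnorm(n, 0, 0.5) * rlnorm(n, 0, 0.3),
                   category = "active_gene_body")
  )
  cc <- category_correlation(str_df)
  expect_gt(cc$rho[cc$category == "intergenic"],
            cc$rho[cc$category == "active_gene_body"])
  expect_true(all(cc$p_value[cc$category == "intergenic"] < 0.01))

  # non-positive values are dropped and reported
  ddf <- tibble::tibble(acc_a = c(-1, 0, rlnorm(30)),
                        acc_b = c(1, 1, rlnorm(30)), category = "g")
  expect_equal(category_correlation(ddf)$n_dropped, 2)
  expect_error(category_correlation(idf[1:5, ]), "positive pairs")
})

test_that("the spatial ED50 gradient survives the full fragment pipeline", {
  cfg <- sim_config(seed = 108, marks = "H4K20me1",
                    chromosomes = tibble::tibble(chrom = c("c1", "cX"),
                                                 length = c(40000L, 200000L)),
                    induced_chrom = "cX",
                    n_snps_per_kb = 8,  # deep SNP coverage for a clean signal
                    repeat_plants = NULL)
  g <- simulate_genome(cfg)
  sim <- simulate_fragments(cfg, g)
  fr <- assign_alleles(sim$fragments, g$snps)
  counts <- count_windows(fr, sim$windows)
  fac <- tmm_factors(dplyr::select(
    dplyr::filter(counts, chrom == "c1", allele == "B6"),
    peak = window, sample_id, count))
  fac <- dplyr::inner_join(dplyr::select(fac, -library_size),
                           dplyr::summarise(dplyr::group_by(counts, sample_id),
                                            library_size = sum(count),
                                            .groups = "drop"),
                           by = "sample_id")
  tracks <- normalize_tracks(counts, fac, sim$samples, rescale_chrom = "cX",
                             collapse_replicates = FALSE)
  xt <- dplyr::transmute(dplyr::filter(tracks, chrom == "cX"),
                         window, mark, timepoint, value = signal_t0sub)
  fits <- cap_ed50(filter_fits(fit_accumulation(xt)))
  win <- dplyr::distinct(tracks[tracks$chrom == "cX",
                                c("window", "start", "end")])
  fits <- dplyr::inner_join(fits, win, by = "window")
  centre <- 100000
  dist <- abs((fits$start + fits$end) / 2 - centre)
  sm <- loess_ed50(dist, fits$ed50_capped)
  expect_gt(sm$smoothed[nrow(sm)], sm$smoothed[1])
  # proximal windows accumulate earlier on average
  expect_lt(mean(fits$ed50_capped[dist < 50000]),
            mean(fits$ed50_capped[dist > 50000]))
})
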