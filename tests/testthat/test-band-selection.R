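test_that("pearson_with_p matches its definition and handles markers", {
  # perfect linearity
  x <- 1:10
  res <- pearson_with_p(x, 2 * x + 1)
  expect_equal(res$r, 1)
  expect_equal(res$p, 0)
  # undefined markers are dropped pairwise
  res2 <- pearson_with_p(c(1, 2, 3, NA), c(1, 2, 3, 4))
  expect_identical(res2$n_effective, 3L)
  expect_equal(res2$r, 1)
  # degenerate cells are invalid, not zeroed
  expect_false(pearson_with_p(c(1, 1, 1), c(1, 2, 3))$valid)
  expect_false(pearson_with_p(c(1, 2), c(1, 2))$valid)
})

test_that("pearson_with_p agrees with cor.test on random vectors", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(20); y <- 0.4 * x + rnorm(20)
    res <- pearson_with_p(x, y)
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("correlation_scan finds a planted noiseless signal", {
  eff <- effect_spec(
    features = list(N = data.frame(center = 700, width = 10,
                                   weight = 0.01),
                    P = data.frame(center = numeric(0),
                                   width = numeric(0),
                                   weight = numeric(0)),
                    K = data.frame(center = numeric(0),
                                   width = numeric(0),
                                   weight = numeric(0))),
    intensity_albedo = c(light = 0, moderate = 0, severe = 0),
    noise_sd = 0, species_sd = 0)
  d <- trim_spectra(generate_dataset(design_spec(seed = 3), eff))
  m <- correlation_scan(window_spectra(d, 690, 710), "R", "N")
  expect_equal(abs(unname(m$r["700"])), 1, tolerance = 1e-9)
  expect_lt(m$p[["700"]], 1e-12)
})

test_that("scan maps inherit the family's symmetry and match the loop oracle", {
  set.seed(5)
  nutr <- data.frame(sample_id = paste0("S", 1:12),
                     N = rnorm(12, 20, 5), P = rnorm(12, 150, 30),
                     K = rnorm(12, 60, 15))
  s <- window_spectra(trim_spectra(full_range_set(0.2, n = 12)),
                      500, 504)
  s$values <- matrix(runif(60, 0.05, 0.6), 12, 5,
                     dimnames = dimnames(s$values))
  s$nutrients <- nutr
  m <- correlation_scan(s, "D", "N", min_n = 3)
  expect_equal(m$r, -t(m$r), tolerance = 1e-12)
  expect_equal(m$p, t(m$p), tolerance = 1e-12)
  # cell-by-cell agreement with the scalar path
  fd <- first_derivative(s)
  for (fam in c("D", "ND", "ID")) {
    mf <- correlation_scan(s, fam, "N", min_n = 3)
    for (i in wavelengths(s)) for (j in wavelengths(s)) {
      vals <- pair_index(fam, s, i = i, j = j)
      ref <- pearson_with_p(vals, nutr$N)
      cell <- mf$r[as.character(i), as.character(j)]
      if (!ref$valid) expect_true(is.na(cell))
      else {
        expect_equal(cell, ref$r, tolerance = 1e-12)
        expect_equal(mf$p[as.character(i), as.character(j)], ref$p,
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("one-band families produce vector maps, two-band matrices", {
  d <- trim_spectra(generate_dataset(design_spec(n_species = 2,
                                                 n_replicates = 2,
                                                 seed = 1)))
  d <- window_spectra(d, 600, 610)
  expect_false(is.matrix(correlation_scan(d, "R", "N")$r))
  expect_false(is.matrix(correlation_scan(d, "FD", "K")$r))
  expect_true(is.matrix(correlation_scan(d, "ND", "P")$r))
})

test_that("count_significant tallies bands per the definition", {
  bands <- c(500, 600, 700, 800)
  p <- matrix(1, 4, 4); r <- matrix(0, 4, 4)
  # a single significant ordered cell at (500, 600)
  p[1, 2] <- 0.01; r[1, 2] <- 0.9
  cnt <- count_significant(list(manual_map(bands, r, p)), quiet = TRUE)
  expect_equal(cnt$count[cnt$band == 500], 1L)
  expect_equal(cnt$count[cnt$band == 600], 1L)
  expect_equal(sum(cnt$count), 2L)
  expect_equal(cnt$best_abs_r[cnt$band == 500], 0.9)

  # all non-significant: all counts zero, empty selection downstream
  cnt0 <- count_significant(list(manual_map(bands, r * 0, p * 0 + 1)),
                            quiet = TRUE)
  expect_true(all(cnt0$count == 0L))
  expect_warning(sel0 <- select_sensitive_bands(cnt0, 5),
                 "no band")
  expect_identical(nrow(sel0), 0L)
})

test_that("hand-built 4-band maps tally as counted manually", {
  bands <- c(400, 410, 420, 430)
  p1 <- matrix(1, 4, 4); r1 <- matrix(0, 4, 4)
  p1[1, 2] <- 0.01; r1[1, 2] <- 0.5   # 400-410
  p1[2, 1] <- 0.01; r1[2, 1] <- -0.5  # ordered mirror
  p1[3, 4] <- 0.04; r1[3, 4] <- 0.7   # 420-430
  m1 <- manual_map(bands, r1, p1)
  pv <- c(0.2, 0.01, 1, 0.03); rv <- c(0, 0.4, 0, -0.6)
  m2 <- manual_map(bands, rv, pv)     # one-band map: 410, 430 significant
  cnt <- count_significant(list(m1, m2), quiet = TRUE)
  # manual tally: 400 x2, 410 x2+1, 420 x1, 430 x1+1
  expect_equal(cnt$count[match(bands, cnt$band)], c(2L, 3L, 1L, 2L))
  # total = 2 * significant 2-band cells + 1-band cells
  expect_equal(sum(cnt$count), 2L * 3L + 2L)
  expect_equal(cnt$best_abs_r[cnt$band == 430], 0.7)
  # permutation invariance in map order
  cnt_rev <- count_significant(list(m2, m1), quiet = TRUE)
  expect_identical(as.data.frame(cnt), as.data.frame(cnt_rev))
  # mixing nutrients is an error
  m3 <- manual_map(bands, rv, pv, nutrient = "K")
  expect_error(count_significant(list(m1, m3), quiet = TRUE),
               "mix nutrients")
  expect_error(count_significant(list(), quiet = TRUE), "empty")
})

test_that("sensitive-band selection applies the tie-break rule", {
  cnt <- structure(
    data.frame(band = c(500L, 600L, 700L),
               count = c(7L, 3L, 3L),
               best_abs_r = c(0.5, 0.9, 0.6)),
    nutrient = "N", alpha = 0.05, class = c("band_counts", "data.frame"))
  sel <- select_sensitive_bands(cnt, 2)
  expect_identical(sel$band, c(500L, 600L))   # 600 wins on best |r|
  # equal count and |r|: lower wavelength first
  cnt$best_abs_r <- c(0.5, 0.6, 0.6)
  sel2 <- select_sensitive_bands(cnt, 3)
  expect_identical(sel2$band, c(500L, 600L, 700L))
  # k larger than positive-count bands warns and returns all
  cnt$count <- c(2L, 0L, 1L)
  expect_warning(sel3 <- select_sensitive_bands(cnt, 5), "2 band")
  expect_identical(sel3$band, c(500L, 700L))
  expect_error(select_sensitive_bands(cnt, 0), "k must be")
})

test_that("BH adjustment is stricter than raw thresholding", {
  set.seed(21)
  nutr <- data.frame(sample_id = paste0("S", 1:20), N = rnorm(20, 20, 5),
                     P = rnorm(20, 150, 30), K = rnorm(20, 60, 15))
  s <- window_spectra(trim_spectra(full_range_set(0.2, n = 20)), 400, 430)
  s$values <- matrix(runif(20 * 31, 0.05, 0.6), 20, 31,
                     dimnames = dimnames(s$values))
  s$nutrients <- nutr
  maps <- list(correlation_scan(s, "D", "N"),
               correlation_scan(s, "ND", "N"))
  raw <- count_significant(maps, quiet = TRUE)
  bh <- count_significant(maps, adjust = "BH", quiet = TRUE)
  expect_true(sum(bh$count) <= sum(raw$count))
})

test_that("degradation t-test separates shifted groups and degrades gracefully", {
  meta <- data.frame(sample_id = paste0("S", 1:24),
                     species = "sp1",
                     degradation = rep(c("light", "moderate", "severe"),
                                       each = 8),
                     replicate = rep(1:8, 3))
  grid <- 600:604
  # planted separation at stated parameters: means 0.2 vs 0.5, sd 0.01
  set.seed(9)
  vals <- matrix(0.35 + rnorm(24 * 5, 0, 0.01), 24, 5)
  vals[meta$degradation == "light", 3] <- rnorm(8, 0.2, 0.01)
  vals[meta$degradation == "severe", 3] <- rnorm(8, 0.5, 0.01)
  s <- spectra_set(vals, grid, sample_ids = meta$sample_id, meta = meta)
  tt <- degradation_ttest(s, 602)
  ls <- tt[tt$group1 == "light" & tt$group2 == "severe", ]
  expect_lt(ls$p, 0.05)

  # identical constant groups: p = 1 everywhere
  s2 <- spectra_set(matrix(0.3, 24, 5), grid,
                    sample_ids = meta$sample_id, meta = meta)
  tt2 <- degradation_ttest(s2, 600)
  expect_true(all(tt2$p == 1))
  expect_true(all(tt2$t == 0))

  # missing group is an error
  meta3 <- meta[meta$degradation != "severe", ]
  s3 <- spectra_set(vals[1:16, ], grid, sample_ids = meta3$sample_id,
                    meta = meta3)
  expect_error(degradation_ttest(s3, 600), "severe")
})

test_that("scan results are free of hidden state across sample removal", {
  d <- trim_spectra(generate_dataset(design_spec(n_species = 2,
                                                 n_replicates = 3,
                                                 seed = 2)))
  d <- window_spectra(d, 700, 706)
  ids <- sample_ids(d)
  m1 <- correlation_scan(d, "ND", "N")
  m2 <- correlation_scan(subset_samples(d, ids), "ND", "N")
  expect_identical(m1$r, m2$r)
  expect_identical(m1$p, m2$p)
})

test_that("map and count CSV exports round-trip their content", {
  bands <- c(500, 600)
  p <- matrix(c(1, 0.01, 0.01, 1), 2, 2)
  r <- matrix(c(0, -0.8, 0.8, 0), 2, 2)
  m <- manual_map(bands, r, p)
  f <- tempfile(fileext = ".csv")
  write_correlation_map(m, f)
  back <- read.csv(f)
  expect_identical(nrow(back), 2L)
  expect_true(all(back$p < 0.05))
  cnt <- count_significant(list(m), quiet = TRUE)
  f2 <- tempfile(fileext = ".csv")
  write_band_counts(cnt, f2)
  back2 <- read.csv(f2)
  expect_identical(back2$nutrient, c("N", "N"))
})
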