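test_that("mse and psnr match hand-computed values", {
  H <- matrix(c(1, 3, 2, 4), 2, 2)
  S <- matrix(c(1, 3, 2, 5), 2, 2)
  expect_equal(hic_mse(H, S), 0.25)
  expect_equal(hic_psnr(H, S), 10 * log10(16 / 0.25))  # 18.0618 dB
  expect_equal(hic_mse(H, H), 0)
  expect_identical(hic_psnr(H, H), Inf)
  expect_error(hic_psnr(matrix(0, 2, 2), S), "max")
  expect_error(hic_mse(H, matrix(1, 3, 3)), "shape")
})

test_that("global ssim is exactly 1 at identity and penalizes shifts", {
  H <- rand_sym_counts(12, 7, 1)
  expect_identical(hic_ssim(H, H), 1)
  # constant shift: luminance term pushes SSIM below 1
  expect_lt(hic_ssim(H, H + 50), 1)
  # constant inputs need an explicit dynamic range
  expect_error(hic_ssim(matrix(1, 3, 3), matrix(1, 3, 3)), "dynamic_range")
  expect_equal(hic_ssim(matrix(1, 3, 3), matrix(1, 3, 3), dynamic_range = 1),
               1)
})

test_that("ssim matches a term-by-term formula oracle on random pairs", {
  set.seed(7)
  for (i in 1:50) {
    H <- matrix(runif(144, 0, 20), 12, 12)
    S <- if (i %% 2) matrix(runif(144, 0, 20), 12, 12) else
      -H + max(H)  # anti-correlated with matched range
    expect_equal(hic_ssim(H, S), naive_ssim(H, S), tolerance = 1e-12)
  }
})

test_that("windowed ssim variant runs and agrees at identity", {
  H <- rand_sym_counts(15, 6, 2)
  expect_equal(hic_ssim(H, H, window = 7), 1)
  expect_error(hic_ssim(H, H, window = 4), "odd")
})

test_that("distance-stratified correlations have the stated invariances", {
  H <- rand_sym_counts(60, 9, 3)
  tr <- correlation_by_distance(H, H, 10000, 2e6)
  expect_equal(nrow(tr), 60)  # d = 0..59 at 10 kb within 2 Mb cap
  expect_true(all(abs(tr$pearson - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(tr$spearman - 1) < 1e-12, na.rm = TRUE))
  expect_equal(tr$n, 60:1)

  # positive affine map: both coefficients still 1
  tr2 <- correlation_by_distance(H, 2 * H + 3, 10000, 2e6)
  expect_true(all(abs(tr2$pearson - 1) < 1e-12, na.rm = TRUE))
  expect_true(all(abs(tr2$spearman - 1) < 1e-12, na.rm = TRUE))

  # strictly monotone transform: spearman invariant
  tr3 <- correlation_by_distance(H, H^3, 10000, 2e6)
  expect_true(all(abs(tr3$spearman - 1) < 1e-12, na.rm = TRUE))
})

test_that("correlation tracks match the naive per-diagonal oracle", {
  set.seed(11)
  H <- matrix(rpois(10000, 6), 100, 100)
  S <- matrix(rpois(10000, 6), 100, 100)
  got <- correlation_by_distance(H, S, 10000, 5e5)
  ref <- naive_cor_by_distance(H, S, 10000, 5e5)
  expect_equal(got$pearson, ref$pearson, tolerance = 1e-12)
  expect_equal(got$spearman, ref$spearman, tolerance = 1e-12)

  # zero-variance diagonal yields NA, not an error
  Hc <- H; Hc[cbind(1:99, 2:100)] <- 5; Hc[cbind(2:100, 1:99)] <- 5
  tr <- correlation_by_distance(Hc, S, 10000, 5e5)
  expect_true(is.na(tr$pearson[2]))
})

test_that("metric report bundles scalars and tracks, and serializes", {
  H <- rand_sym_counts(30, 8, 4)
  S <- rand_sym_counts(30, 8, 5)
  rep <- metric_report(H, S)
  expect_equal(rep$mse, hic_mse(H, S))
  expect_equal(rep$psnr, hic_psnr(H, S))
  expect_equal(rep$ssim, hic_ssim(H, S))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_metric_report(rep, tsv = tsv, json = json)
  tab <- read.delim(tsv)
  expect_setequal(tab$metric, c("mse", "psnr", "ssim"))
  expect_true(jsonlite::validate(paste(readLines(json), collapse = "")))
})

test_that("interaction sets canonicalize and filter by distance band", {
  is <- interaction_set(bin_i = c(5, 10, 1), bin_j = c(2, 40, 2),
                        resolution = 10000)
  expect_true(all(is$bin_i < is$bin_j))
  expect_error(interaction_set(1, 1), "self pairs")

  # distances 10 kb (dropped), 30 kb and 300 kb (kept, inclusive), 310 kb
  # (dropped)
  s <- interaction_set(bin_i = c(0, 0, 0, 0), bin_j = c(1, 3, 30, 31),
                       resolution = 10000)
  f <- band_filter(s)
  expect_equal(f$bin_j, c(3L, 30L))

  # count after filtering a constructed set matches enumeration
  set.seed(3)
  bi <- sample(0:100, 200, replace = TRUE)
  bj <- bi + sample(1:60, 200, replace = TRUE)
  s2 <- interaction_set(bi, bj, resolution = 10000)
  f2 <- band_filter(s2, 30000, 300000)
  d <- (s2$bin_j - s2$bin_i) * 10000
  expect_equal(nrow(f2), sum(d >= 30000 & d <= 300000))
})

test_that("bedpe export writes half-open anchor intervals", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  s <- interaction_set(c(0, 2), c(4, 9), q = c(1e-8, 1e-9),
                       resolution = 10000)
  write_interactions_bedpe(s, f, chrom = "chr20")
  tab <- read.table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$V2, c(0, 20000))
  expect_equal(tab$V3, c(10000, 30000))
  expect_equal(tab$V5, c(40000, 90000))
})

test_that("interaction recovery scoring matches set arithmetic", {
  # truth {A,B,C}, predicted {B,C,D}
  truth <- interaction_set(c(0, 1, 2), c(5, 6, 7))
  pred <- interaction_set(c(1, 2, 3), c(6, 7, 8))
  sc <- score_interaction_recovery(truth, pred)
  expect_equal(sc$tp, 2); expect_equal(sc$fp, 1); expect_equal(sc$fn, 1)
  expect_equal(sc$precision, 2 / 3)
  expect_equal(sc$recall, 2 / 3)
  expect_equal(sc$f1, 2 / 3)
  expect_equal(sc$fp_rate, 1 / 3)

  # perfect prediction
  sc2 <- score_interaction_recovery(truth, truth)
  expect_equal(sc2$f1, 1)
  expect_equal(sc2$fp_rate, 0)

  # empty prediction: precision undefined, F1 = 0
  empty <- interaction_set(integer(0), integer(0))
  sc3 <- score_interaction_recovery(truth, empty)
  expect_true(is.na(sc3$precision))
  expect_equal(sc3$f1, 0)

  # symmetry: swapping roles swaps precision and recall, F1 unchanged
  a <- interaction_set(c(0, 1, 2, 3, 4), c(9, 9, 9, 9, 9))
  b <- interaction_set(c(0, 1, 7), c(9, 9, 9))
  s_ab <- score_interaction_recovery(a, b)
  s_ba <- score_interaction_recovery(b, a)
  expect_equal(s_ab$precision, s_ba$recall)
  expect_equal(s_ab$recall, s_ba$precision)
  expect_equal(s_ab$f1, s_ba$f1)
})

test_that("random swap-out construction scores as hand-counted", {
  set.seed(5)
  bi <- sample(0:500, 100)
  bj <- bi + sample(3:30, 100, replace = TRUE)
  truth <- interaction_set(bi, bj)
  # replace 20 pairs with novel ones far outside the truth support
  keep <- 1:80
  pred <- interaction_set(c(bi[keep], 1000 + 1:20),
                          c(bj[keep], 1040 + 1:20))
  sc <- score_interaction_recovery(truth, pred)
  expect_equal(sc$tp, 80)
  expect_equal(sc$fn, 20)
  expect_equal(sc$fp, 20)
  expect_equal(sc$f1, 2 * 0.8 * 0.8 / (0.8 + 0.8))
})
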