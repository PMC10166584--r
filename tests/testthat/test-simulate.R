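test_that("simulated matrices are symmetric integer counts, deterministic in the seed", {
  cfg <- synthetic_genome_config(n_bins = 120, depth = 2e5, seed = 5)
  sim <- simulate_hic(cfg)
  m <- sim$matrix$counts
  expect_identical(dim(m), c(120L, 120L))
  expect_identical(m, t(m))
  expect_true(all(m >= 0))
  expect_true(all(m == round(m)))
  sim2 <- simulate_hic(cfg)
  expect_identical(sim2$matrix$counts, m)
  # TADs tile the chromosome
  expect_equal(sim$tads$start_bin[1], 0)
  expect_equal(sim$tads$end_bin[nrow(sim$tads)], 120)
  expect_true(all(sim$tads$start_bin[-1] == head(sim$tads$end_bin, -1)))
  # loop anchors respect the 30-300 kb sampling band
  d_bp <- (sim$loops$bin_j - sim$loops$bin_i) * cfg$resolution
  expect_true(all(d_bp >= 30000 & d_bp <= 300000))
})

test_that("expected intensity integrates to depth and decays with distance", {
  cfg <- synthetic_genome_config(n_bins = 100, depth = 5e5, seed = 2)
  sim <- simulate_hic(cfg)
  expect_equal(sum(sim$expected), cfg$depth)
  # with no TAD/loop structure the mean diagonal profile strictly decreases
  cfg0 <- synthetic_genome_config(n_bins = 100, depth = 5e5, tad_boost = 0,
                                  n_loops = 0, seed = 2)
  e <- simulate_hic(cfg0)$expected
  prof <- sapply(0:20, function(d) {
    i <- seq_len(100 - d); mean(e[cbind(i, i + d)])
  })
  expect_true(all(diff(prof) < 0))
})

test_that("short-range counts exceed long-range counts across seeds", {
  diffs <- sapply(1:100, function(s) {
    m <- simulate_hic(synthetic_genome_config(n_bins = 64, depth = 5e4,
                                              tad_max = 30, seed = s))$matrix$counts
    i1 <- seq_len(63); i50 <- seq_len(14)
    mean(m[cbind(i1, i1 + 1)]) - mean(m[cbind(i50, i50 + 50)])
  })
  expect_gt(mean(diffs), 0)
})

test_that("invalid generator configs are rejected", {
  expect_error(synthetic_genome_config(depth = 0), "depth")
  expect_error(synthetic_genome_config(decay_alpha = 0), "decay_alpha")
  expect_error(synthetic_genome_config(tad_min = 0), "tad_min")
  expect_error(synthetic_genome_config(tad_min = 50, tad_max = 20), "tad_min")
  expect_error(synthetic_genome_config(n_bins = 100, tad_max = 200), "tad_min")
  expect_error(synthetic_genome_config(tad_boost = -1), "boosts")
})

test_that("binomial thinning matches binomial mean and variance", {
  # single large entry: Binomial(10000, 1/16)
  m <- matrix(10000, 2, 2)
  thin <- downsample_reads(contact_matrix(m), 1 / 16, seed = 3)
  mu <- 10000 / 16
  sd3 <- 3 * sqrt(10000 * (1 / 16) * (15 / 16))
  expect_true(abs(thin$counts[1, 2] - mu) <= sd3)

  # whole-matrix total within 3 binomial sd of rate * total
  cm <- contact_matrix(rand_sym_counts(80, 12, 4))
  for (rate in c(1 / 8, 1 / 16)) {
    thin <- downsample_reads(cm, rate, seed = 7)
    up <- upper.tri(cm$counts)
    # total = 2 * upper + diagonal, each entry an independent binomial
    var_tot <- 4 * sum(cm$counts[up]) * rate * (1 - rate) +
      sum(diag(cm$counts)) * rate * (1 - rate)
    expect_true(abs(sum(thin$counts) - rate * sum(cm$counts)) <=
                  3 * sqrt(var_tot))
    expect_identical(thin$counts, t(thin$counts))
    expect_true(all(thin$counts == round(thin$counts)))
    expect_true(all(thin$counts <= cm$counts))
  }
})

test_that("thinning edge cases: identity at rate 1, rejections", {
  cm <- contact_matrix(rand_sym_counts(10, 5, 1))
  expect_identical(downsample_reads(cm, 1, seed = 1)$counts, cm$counts)
  expect_error(downsample_reads(cm, 0), "rate")
  expect_error(downsample_reads(cm, 1.2), "rate")
  frac <- contact_matrix(matrix(0.5, 2, 2))
  expect_error(downsample_reads(frac, 0.5), "integer")
})

test_that("two-stage thinning is distributionally one-stage at the product rate", {
  cm <- contact_matrix(rand_sym_counts(60, 20, 8))
  tot <- sum(cm$counts)
  a <- 1 / 4; b <- 1 / 4
  two <- sapply(1:20, function(s)
    sum(downsample_reads(downsample_reads(cm, a, seed = s), b,
                         seed = 1000 + s)$counts))
  # mean of 20 totals vs expectation under rate a*b, at 3 sigma of the mean
  up <- upper.tri(cm$counts)
  var_tot <- (4 * sum(cm$counts[up]) + sum(diag(cm$counts))) *
    (a * b) * (1 - a * b)
  expect_true(abs(mean(two) - a * b * tot) <= 3 * sqrt(var_tot / 20))
})
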