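test_that("sparse triplets read correctly in both dialects", {
  f <- withr::local_tempfile(fileext = ".txt")

  writeLines(c("0 0 5", "0 2 3"), f)
  m <- read_sparse_contacts(f, n_bins = 3)
  expect_equal(m$counts, matrix(c(5, 0, 3, 0, 0, 0, 3, 0, 0), 3, 3))

  # bp dialect auto-detected: coordinates >= resolution
  writeLines("20000 30000 7", f)
  m <- read_sparse_contacts(f, resolution = 10000)
  expect_equal(m$counts[3, 4], 7)
  expect_equal(m$counts[4, 3], 7)
  expect_equal(n_bins(m), 4)

  # empty file with explicit size
  writeLines(character(0), f)
  m <- read_sparse_contacts(f, n_bins = 4)
  expect_equal(m$counts, matrix(0, 4, 4))

  # malformed inputs are rejected
  writeLines("0 1 -2", f)
  expect_error(read_sparse_contacts(f, n_bins = 3), "negative")
  writeLines("15000 20000 3", f)
  expect_error(read_sparse_contacts(f, resolution = 10000), "divisible")
  writeLines("0 5 1", f)
  expect_error(read_sparse_contacts(f, n_bins = 3), "n_bins")
})

test_that("sparse write/read round-trips integer matrices exactly", {
  f <- withr::local_tempfile(fileext = ".txt")
  for (seed in 1:5) {
    m <- contact_matrix(rand_sym_counts(10, 4, seed), "chrR", 10000)
    write_sparse_contacts(m, f)
    back <- read_sparse_contacts(f, "chrR", 10000, n_bins = 10)
    expect_identical(back$counts, m$counts)
  }
  # gzip round trip
  fgz <- withr::local_tempfile(fileext = ".txt.gz")
  m <- contact_matrix(rand_sym_counts(12, 3, 42), "chrR", 10000)
  write_sparse_contacts(m, fgz)
  expect_identical(read_sparse_contacts(fgz, n_bins = 12)$counts, m$counts)
})

test_that("sparse writer emits upper triangle only", {
  f <- withr::local_tempfile(fileext = ".txt")
  write_sparse_contacts(contact_matrix(matrix(0, 4, 4)), f)
  expect_identical(readLines(f), character(0))

  m <- matrix(0, 6, 6); m[2, 6] <- m[6, 2] <- 2
  write_sparse_contacts(contact_matrix(m), f)
  lines <- readLines(f)
  expect_length(lines, 1)
  expect_identical(lines, "1\t5\t2")
})

test_that("dense container round-trips with metadata and validates on read", {
  f <- withr::local_tempfile(fileext = ".rds")
  m <- contact_matrix(rand_sym_counts(50, 6, 9) + 0.25, "chrS1", 10000)
  write_dense(m, f)
  back <- read_dense(f)
  expect_identical(back$counts, m$counts)
  expect_identical(back$chrom, "chrS1")
  expect_identical(back$resolution, 10000)

  bad <- matrix(runif(16), 4, 4)
  saveRDS(list(chrom = "x", resolution = 1, counts = bad), f)
  expect_error(read_dense(f), "asymmetric")
  saveRDS(list(chrom = "x", resolution = 1, counts = matrix(1, 2, 3)), f)
  expect_error(read_dense(f), "square")
})

test_that("matrix market round-trips", {
  f <- withr::local_tempfile(fileext = ".mtx")
  m <- contact_matrix(rand_sym_counts(15, 2, 3), "chrM", 5000)
  write_mtx(m, f)
  back <- read_mtx(f, "chrM", 5000)
  expect_equal(back$counts, m$counts)
})

test_that("constructor rejects invalid matrices", {
  expect_error(contact_matrix(matrix(1, 2, 3)), "square")
  expect_error(contact_matrix(matrix(c(0, 1, 2, 0), 2, 2)), "asymmetric")
  expect_error(contact_matrix(matrix(-1, 2, 2)), "non-negative")
  expect_error(contact_matrix(matrix(NA_real_, 2, 2)), "finite")
})

test_that("fithic export writes midpoints, marginals, and consistent totals", {
  fi <- withr::local_tempfile(fileext = ".txt")
  fr <- withr::local_tempfile(fileext = ".txt")

  m <- matrix(0, 3, 3); m[1, 3] <- m[3, 1] <- 4
  export_fithic(contact_matrix(m, "chr20", 10000), fi, fr)
  ints <- read.table(fi)
  expect_equal(nrow(ints), 1)
  expect_equal(ints$V2, 5000)
  expect_equal(ints$V4, 25000)
  expect_equal(ints$V5, 4)
  frags <- read.table(fr)
  expect_equal(nrow(frags), 3)
  expect_equal(frags$V3, c(5000, 15000, 25000))

  # marginals equal brute-force row sums; their total counts every read
  # twice off-diagonal and once on the diagonal
  cm <- contact_matrix(rand_sym_counts(8, 5, 11), "chr20", 10000)
  export_fithic(cm, fi, fr)
  frags <- read.table(fr)
  oracle_marg <- sapply(1:8, function(b) sum(cm$counts[b, ]))
  expect_equal(frags$V4, oracle_marg)
  off_total <- sum(cm$counts[upper.tri(cm$counts)])
  diag_total <- sum(diag(cm$counts))
  expect_equal(sum(frags$V4), 2 * off_total + diag_total)
})

test_that("fithic significance tables parse to interaction sets", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr20\t5000\tchr20\t45000\t37\t1e-12\t1e-9",
               "chr20\t15000\tchr20\t95000\t22\t1e-8\t1e-5",
               "chr20\t5000\tchr21\t45000\t10\t1e-12\t1e-9"), f)
  is <- read_fithic_interactions(f, resolution = 10000, q_threshold = 1e-6)
  expect_equal(nrow(is), 1)  # q filter and intra-chromosomal filter
  expect_equal(is$bin_i, 0L)
  expect_equal(is$bin_j, 4L)
})
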