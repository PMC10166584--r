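#' Extract paired training patches from a matrix pair
#'
#' Tiles a (high-resolution, low-resolution) chromosome pair into
#' non-overlapping `block x block` patches at block-aligned offsets
#' `(block*a, block*b)`, keeping upper-triangle block pairs (`b >= a`) whose
#' entries all lie within `max_dist_bp` genomic distance. That bound gives
#' `b - a <= band_blocks` with
#' `band_blocks = floor((max_dist_bp/resolution - block) / block)`
#' (4 at the defaults: the farthest entry of an offset-4 block pair is
#' `(4*40 + 39) * 10 kb = 1.99 Mb` apart). Trailing bins that do not fill a
#' block are dropped.
#'
#' @param hr High-resolution (ground-truth) [contact_matrix()].
#' @param lr Low-resolution [contact_matrix()] of the same shape/resolution.
#' @param block Patch side length in bins.
#' @param max_dist_bp Retain only blocks whose entries are closer than this.
#' @return A `patch_set`: list with 3-d arrays `lr` and `hr`
#'   (`block x block x N`), an `index` data frame (`chrom`, `a`, `b`),
#'   `block`, and `resolution`.
#' @export
extract_patches <- function(hr, lr, block = 40, max_dist_bp = 2e6) {
  stopifnot(is_contact_matrix(hr), is_contact_matrix(lr))
  if (!identical(dim(hr$counts), dim(lr$counts)))
    stop("hr and lr shapes differ")
  if (hr$resolution != lr$resolution)
    stop("hr and lr resolutions differ")
  nb <- n_bins(hr)
  n_blocks <- nb %/% block
  band_blocks <- floor((max_dist_bp / hr$resolution - block) / block)
  pairs <- list()
  if (n_blocks >= 1 && band_blocks >= 0) {
    for (a in 0:(n_blocks - 1)) {
      for (b in a:min(n_blocks - 1, a + band_blocks)) {
        pairs[[length(pairs) + 1]] <- c(a, b)
      }
    }
  }
  n <- length(pairs)
  lr_arr <- array(0, dim = c(block, block, max(n, 0)))
  hr_arr <- array(0, dim = c(block, block, max(n, 0)))
  idx <- data.frame(chrom = character(n), a = integer(n), b = integer(n),
                    stringsAsFactors = FALSE)
  for (p in seq_len(n)) {
    a <- pairs[[p]][1]; b <- pairs[[p]][2]
    rows <- (a * block + 1):((a + 1) * block)
    cols <- (b * block + 1):((b + 1) * block)
    lr_arr[, , p] <- lr$counts[rows, cols]
    hr_arr[, , p] <- hr$counts[rows, cols]
    idx$chrom[p] <- hr$chrom; idx$a[p] <- a; idx$b[p] <- b
  }
  if (n == 0) {
    lr_arr <- array(0, dim = c(block, block, 0))
    hr_arr <- array(0, dim = c(block, block, 0))
  }
  structure(list(lr = lr_arr, hr = hr_arr, index = idx, block = block,
                 resolution = hr$resolution),
            class = "patch_set")
}

#' @export
length.patch_set <- function(x) nrow(x$index)

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %dx%d from %s\n", length(x),
              x$block, x$block, paste(unique(x$index$chrom), collapse = ", ")))
  invisible(x)
}

#' Subset or combine patch sets
#'
#' @param x A `patch_set`.
#' @param i Integer or logical index over patches.
#' @param ... For `c()`: further `patch_set`s with matching block/resolution.
#' @return A `patch_set`.
#' @export
subset_patches <- function(x, i) {
  stopifnot(inherits(x, "patch_set"))
  i <- seq_len(length(x))[i]
  structure(list(lr = x$lr[, , i, drop = FALSE],
                 hr = x$hr[, , i, drop = FALSE],
                 index = x$index[i, , drop = FALSE],
                 block = x$block, resolution = x$resolution),
            class = "patch_set")
}

#' @export
c.patch_set <- function(...) {
  sets <- list(...)
  stopifnot(all(vapply(sets, inherits, TRUE, "patch_set")))
  blk <- unique(vapply(sets, `[[`, 0, "block"))
  res <- unique(vapply(sets, `[[`, 0, "resolution"))
  if (length(blk) != 1 || length(res) != 1)
    stop("patch sets have differing block size or resolution")
  structure(list(
    lr = array(unlist(lapply(sets, `[[`, "lr")),
               dim = c(blk, blk, sum(vapply(sets, length, 0L)))),
    hr = array(unlist(lapply(sets, `[[`, "hr")),
               dim = c(blk, blk, sum(vapply(sets, length, 0L)))),
    index = do.call(rbind, lapply(sets, `[[`, "index")),
    block = blk, resolution = res), class = "patch_set")
}

#' Extract one patch pair
#'
#' @param ps A `patch_set`.
#' @param i Patch number.
#' @return List with `chrom`, `a`, `b`, `lr`, `hr`.
#' @export
patch_pair <- function(ps, i) {
  stopifnot(inherits(ps, "patch_set"), i >= 1, i <= length(ps))
  list(chrom = ps$index$chrom[i], a = ps$index$a[i], b = ps$index$b[i],
       lr = ps$lr[, , i], hr = ps$hr[, , i])
}

#' Split patches into training and validation sets
#'
#' Random disjoint, exhaustive partition with
#' `|train| = round(train_fraction * N)`; deterministic under a fixed seed.
#' The default 0.95 is the 9.5:0.5 train:validation ratio.
#'
#' @param ps A `patch_set` with at least 2 patches.
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @param seed RNG seed.
#' @return List with `patch_set`s `train` and `val`.
#' @export
split_train_val <- function(ps, train_fraction = 0.95, seed = 1) {
  stopifnot(inherits(ps, "patch_set"))
  n <- length(ps)
  if (n < 2) stop("need at least 2 patches to split")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  n_train <- round(train_fraction * n)
  n_train <- max(1L, min(n - 1L, n_train))
  with_seed(seed, {
    perm <- sample.int(n)
    list(train = subset_patches(ps, sort(perm[seq_len(n_train)])),
         val = subset_patches(ps, sort(perm[(n_train + 1):n])))
  })
}

#' Reassemble a banded chromosome matrix from patches
#'
#' Inverse of [extract_patches()] on the retained band: places each block at
#' `(block*a, block*b)`, mirrors to the lower triangle, and leaves the rest
#' zero. `assemble_chromosome(extract_patches(hr, lr), ...)` reproduces `hr`
#' (or `lr`) exactly on the banded support.
#'
#' @param ps A `patch_set` (blocks to place; duplicated `(a, b)` positions
#'   are an error).
#' @param n_bins Side length of the output matrix.
#' @param values Which array of `ps` to place: `"hr"` or `"lr"`.
#' @param blocks Optional `block x block x N` array overriding the values
#'   (e.g. enhanced blocks), aligned with `ps$index`.
#' @param chrom Chromosome label for the output.
#' @return A [contact_matrix()].
#' @export
assemble_chromosome <- function(ps, n_bins, values = c("hr", "lr"),
                                blocks = NULL, chrom = NULL) {
  stopifnot(inherits(ps, "patch_set"))
  values <- match.arg(values)
  arr <- if (is.null(blocks)) ps[[values]] else blocks
  if (!all(dim(arr)[1:2] == ps$block) || dim(arr)[3] != length(ps))
    stop("`blocks` must be block x block x n_patches")
  if (anyDuplicated(ps$index[, c("a", "b")]))
    stop("conflicting duplicate blocks at the same (a, b) position")
  block <- ps$block
  m <- matrix(0, n_bins, n_bins)
  for (p in seq_len(length(ps))) {
    a <- ps$index$a[p]; b <- ps$index$b[p]
    rows <- (a * block + 1):((a + 1) * block)
    cols <- (b * block + 1):((b + 1) * block)
    if (max(rows, cols) > n_bins) stop("block exceeds n_bins")
    m[rows, cols] <- arr[, , p]
  }
  # mirror upper triangle into the lower; diagonal blocks may be asymmetric
  # if they came from a network, so average them first
  low <- lower.tri(m)
  mt <- t(m)
  m[low] <- mt[low]
  m <- (m + t(m)) / 2
  if (is.null(chrom)) chrom <- ps$index$chrom[1] %||% "chr1"
  contact_matrix(m, chrom, ps$resolution)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a
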