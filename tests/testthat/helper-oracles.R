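# Independent reference implementations used as oracles. These are written
# naively (explicit loops, textbook formulas) on purpose: they must not share
# code paths with the package.

# random symmetric integer count matrix
rand_sym_counts <- function(n, lambda = 5, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

naive_mse <- function(H, S) {
  acc <- 0
  for (j in seq_len(ncol(H))) for (i in seq_len(nrow(H)))
    acc <- acc + (H[i, j] - S[i, j])^2
  acc / (nrow(H) * ncol(H))
}

naive_psnr <- function(H, S) {
  mx <- -Inf
  for (v in H) if (v > mx) mx <- v
  m <- naive_mse(H, S)
  if (m == 0) return(Inf)
  10 * log10(mx^2 / m)
}

naive_ssim <- function(H, S, c1 = 0.01, c2 = 0.03) {
  n <- length(H)
  mu_h <- sum(H) / n
  mu_s <- sum(S) / n
  var_h <- sum((H - mu_h)^2) / n
  var_s <- sum((S - mu_s)^2) / n
  cov_hs <- sum((H - mu_h) * (S - mu_s)) / n
  R <- max(H) - min(H)
  C1 <- (c1 * R)^2
  C2 <- (c2 * R)^2
  ((2 * mu_h * mu_s + C1) * (2 * cov_hs + C2)) /
    ((mu_h^2 + mu_s^2 + C1) * (var_h + var_s + C2))
}

naive_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) return(NA_real_)
  num / den
}

# mid-rank (average) ranks computed by counting, not via rank()
naive_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (ties + 1) / 2
  }
  r
}

naive_spearman <- function(x, y) naive_pearson(naive_midrank(x),
                                               naive_midrank(y))

# per-genomic-distance correlation tracks, by explicit diagonal walks
naive_cor_by_distance <- function(H, S, resolution, max_dist_bp) {
  n <- nrow(H)
  dmax <- min(n - 1, floor(max_dist_bp / resolution))
  out <- data.frame(distance_bp = (0:dmax) * resolution,
                    pearson = NA_real_, spearman = NA_real_)
  for (d in 0:dmax) {
    h <- numeric(0); s <- numeric(0)
    for (i in seq_len(n - d)) {
      h <- c(h, H[i, i + d]); s <- c(s, S[i, i + d])
    }
    if (length(unique(h)) > 1 && length(unique(s)) > 1) {
      out$pearson[d + 1] <- naive_pearson(h, s)
      out$spearman[d + 1] <- naive_spearman(h, s)
    }
  }
  out
}

# exhaustive patch-tiling oracle: all block-aligned upper-triangle block
# pairs whose entries are all closer than max_dist_bp
enumerate_blocks <- function(n_bins, resolution, block, max_dist_bp) {
  n_blocks <- n_bins %/% block
  keep <- list()
  for (a in 0:(n_blocks - 1)) for (b in a:(n_blocks - 1)) {
    # farthest-apart entry pair of block (a, b)
    max_entry_dist <- (b * block + block - 1) - (a * block)
    if (max_entry_dist * resolution < max_dist_bp)
      keep[[length(keep) + 1]] <- c(a = a, b = b)
  }
  do.call(rbind, keep)
}

# direct-loop dilated convolution, double precision
naive_conv <- function(x, w, b, d) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  k <- dim(w)[1]
  out <- array(0, c(H, W, cout))
  for (co in 1:cout) {
    acc <- matrix(b[co], H, W)
    for (ci in 1:cin) for (kj in 1:k) for (ki in 1:k) {
      di <- (ki - (k + 1) / 2) * d; dj <- (kj - (k + 1) / 2) * d
      for (j in 1:W) for (i in 1:H) {
        si <- i + di; sj <- j + dj
        if (si >= 1 && si <= H && sj >= 1 && sj <= W)
          acc[i, j] <- acc[i, j] + x[si, sj, ci] * w[ki, kj, ci, co]
      }
    }
    out[, , co] <- acc
  }
  out
}

# full network forward in double precision, following the residual topology
naive_forward <- function(L, model) {
  weights <- model$weights; biases <- model$biases
  dil <- model$spec$dilations
  relu <- function(a) { a[a < 0] <- 0; a }
  x <- array(L, c(dim(L), 1))
  a1 <- relu(naive_conv(x, weights[[1]], biases[[1]], dil[1]))
  a2 <- relu(naive_conv(a1, weights[[2]], biases[[2]], dil[2]))
  a3 <- relu(naive_conv(a2, weights[[3]], biases[[3]], dil[3]))
  fe <- a1 + a3
  a4 <- relu(naive_conv(fe, weights[[4]], biases[[4]], dil[4]))
  a5 <- relu(naive_conv(a4, weights[[5]], biases[[5]], dil[5]))
  r1 <- a4 + a5
  a6 <- relu(naive_conv(r1, weights[[6]], biases[[6]], dil[6]))
  a7 <- relu(naive_conv(a6, weights[[7]], biases[[7]], dil[7]))
  r2 <- a6 + a7
  a8 <- relu(naive_conv(r2, weights[[8]], biases[[8]], dil[8]))
  a9 <- relu(naive_conv(a8, weights[[9]], biases[[9]], dil[9]))
  fm <- naive_conv(a9, weights[[10]], biases[[10]], dil[10])
  L + fm[, , 1]
}

# small spec for fast model tests (satisfies all skip-channel constraints)
tiny_spec <- function(dilation_rate = 2)
  model_spec(channels = c(4, 4, 4, 8, 8, 8, 8, 8, 8, 1),
             dilation_rate = dilation_rate)

# tiny patch set built directly (no extraction), for train-loop tests
tiny_patch_set <- function(n_patches = 8, block = 8, seed = 1) {
  set.seed(seed)
  hr <- array(rpois(block * block * n_patches, 20), c(block, block, n_patches))
  lr <- array(rbinom(block * block * n_patches, hr, 0.25),
              c(block, block, n_patches))
  structure(list(lr = lr, hr = hr,
                 index = data.frame(chrom = "chrT", a = seq_len(n_patches) - 1,
                                    b = seq_len(n_patches) - 1),
                 block = block, resolution = 10000),
            class = "patch_set")
}
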