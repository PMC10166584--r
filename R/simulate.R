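#' Configuration for the synthetic Hi-C generator
#'
#' Describes one synthetic chromosome. The generator reproduces the three
#' structural features the enhancement task relies on: power-law decay of
#' contact frequency with genomic distance, block-wise enrichment inside
#' topologically associating domains (TADs), and focal enrichment at loop
#' anchors; counts are Poisson draws around that expectation.
#'
#' Defaults emulate a deeply sequenced 8 Mb chromosome arm at 10 kb
#' resolution: `decay_alpha = 1` (the classic ~ s^-1 contact-probability
#' decay), TAD sizes 100 kb-1 Mb, a 2x within-TAD enrichment, and ~5 loops
#' per Mb at 4x focal enrichment, with `depth = 2e6` expected read pairs for
#' the default 800 bins.
#'
#' @param n_bins Number of bins.
#' @param resolution Bin size in bp.
#' @param depth Expected total read pairs over the whole matrix.
#' @param decay_alpha Power-law exponent (> 0) of distance decay.
#' @param tad_min,tad_max TAD sizes in bins (sampled uniformly).
#' @param tad_boost Multiplicative within-TAD enrichment (>= 0; 1 doubles
#'   within-TAD intensity).
#' @param n_loops Number of loop anchor pairs.
#' @param loop_boost Multiplicative enrichment at loop anchors (>= 0).
#' @param loop_sigma Gaussian radius of each loop bump, in bins.
#' @param nb_dispersion Optional negative-binomial size parameter; `NULL`
#'   (default) draws Poisson counts.
#' @param seed RNG seed used by [simulate_hic()].
#' @return A `synthetic_genome_config` list.
#' @export
synthetic_genome_config <- function(n_bins = 800, resolution = 10000,
                                    depth = 2e6, decay_alpha = 1,
                                    tad_min = 10, tad_max = 100,
                                    tad_boost = 1, n_loops = 40,
                                    loop_boost = 4, loop_sigma = 1,
                                    nb_dispersion = NULL, seed = 1) {
  cfg <- list(n_bins = as.integer(n_bins), resolution = resolution,
              depth = depth, decay_alpha = decay_alpha,
              tad_min = as.integer(tad_min), tad_max = as.integer(tad_max),
              tad_boost = tad_boost, n_loops = as.integer(n_loops),
              loop_boost = loop_boost, loop_sigma = loop_sigma,
              nb_dispersion = nb_dispersion, seed = seed)
  if (cfg$n_bins < 1) stop("n_bins must be positive")
  if (cfg$depth <= 0) stop("depth must be positive")
  if (cfg$decay_alpha <= 0) stop("decay_alpha must be positive")
  if (!(cfg$tad_min >= 1 && cfg$tad_min <= cfg$tad_max &&
        cfg$tad_max <= cfg$n_bins))
    stop("need 1 <= tad_min <= tad_max <= n_bins")
  if (cfg$tad_boost < 0 || cfg$loop_boost < 0)
    stop("boosts must be >= 0")
  if (cfg$n_loops < 0) stop("n_loops must be >= 0")
  class(cfg) <- "synthetic_genome_config"
  cfg
}

# run code under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate a synthetic Hi-C contact matrix
#'
#' Draws one chromosome from a [synthetic_genome_config()]. The expected
#' intensity is
#' `e(i,j) = scale * (1+|i-j|)^(-decay_alpha) * (1 + tad_boost * same_tad(i,j))
#' * (1 + loop_boost * k(i,j))`,
#' where `k` is a Gaussian bump of radius `loop_sigma` at each loop anchor
#' pair and `scale` is set so the expected full-matrix total equals `depth`.
#' Counts are drawn independently on the upper triangle (Poisson, or negative
#' binomial when `nb_dispersion` is set) and mirrored.
#'
#' TADs tile the chromosome with sizes uniform in `[tad_min, tad_max]` (last
#' one truncated). Loop anchors are sampled uniformly among pairs 30-300 kb
#' apart.
#'
#' @param cfg A [synthetic_genome_config()].
#' @param chrom Chromosome label for the output.
#' @return A list of class `hic_simulation`: `matrix` (the [contact_matrix()]),
#'   `tads` (data frame of 0-based half-open `start_bin`, `end_bin`),
#'   `loops` (data frame of anchor bins `bin_i`, `bin_j`), `expected`
#'   (the intensity matrix), and `config`.
#' @examples
#' sim <- simulate_hic(synthetic_genome_config(n_bins = 100, depth = 1e5))
#' sim$matrix
#' @export
simulate_hic <- function(cfg, chrom = "chrS1") {
  stopifnot(inherits(cfg, "synthetic_genome_config"))
  nb <- cfg$n_bins
  with_seed(cfg$seed, {
    # TAD tiling
    starts <- integer(0)
    pos <- 0L
    while (pos < nb) {
      starts <- c(starts, pos)
      pos <- pos + sample.int(cfg$tad_max - cfg$tad_min + 1L, 1L) +
        cfg$tad_min - 1L
    }
    ends <- c(starts[-1], nb)
    tads <- data.frame(start_bin = starts, end_bin = ends)
    tad_id <- rep(seq_along(starts), ends - starts)

    # loop anchors: pairs 30-300 kb apart
    lo_d <- max(1L, ceiling(30000 / cfg$resolution))
    hi_d <- min(nb - 1L, floor(300000 / cfg$resolution))
    loops <- data.frame(bin_i = integer(0), bin_j = integer(0))
    if (cfg$n_loops > 0 && hi_d >= lo_d) {
      d <- sample(lo_d:hi_d, cfg$n_loops, replace = TRUE)
      i <- vapply(d, function(dd) sample.int(nb - dd, 1L) - 1L, integer(1))
      loops <- data.frame(bin_i = i, bin_j = i + d)
    }

    # expected intensity
    dist <- abs(outer(seq_len(nb), seq_len(nb), "-"))
    e <- (1 + dist)^(-cfg$decay_alpha)
    same_tad <- outer(tad_id, tad_id, "==")
    e <- e * (1 + cfg$tad_boost * same_tad)
    if (nrow(loops) > 0 && cfg$loop_boost > 0) {
      k <- matrix(0, nb, nb)
      r <- ceiling(3 * cfg$loop_sigma)
      for (l in seq_len(nrow(loops))) {
        ai <- loops$bin_i[l]; aj <- loops$bin_j[l]
        ii <- max(0, ai - r):min(nb - 1, ai + r)
        jj <- max(0, aj - r):min(nb - 1, aj + r)
        bump <- outer(exp(-(ii - ai)^2 / (2 * cfg$loop_sigma^2)),
                      exp(-(jj - aj)^2 / (2 * cfg$loop_sigma^2)))
        k[ii + 1, jj + 1] <- k[ii + 1, jj + 1] + bump
        k[jj + 1, ii + 1] <- k[jj + 1, ii + 1] + t(bump)
      }
      e <- e * (1 + cfg$loop_boost * k)
    }
    e <- e * (cfg$depth / sum(e))

    # draw upper triangle, mirror
    up <- which(upper.tri(e, diag = TRUE))
    counts <- matrix(0, nb, nb)
    mu <- e[up]
    counts[up] <- if (is.null(cfg$nb_dispersion)) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), size = cfg$nb_dispersion, mu = mu)
    }
    counts <- counts + t(counts) - diag(diag(counts), nb)

    structure(list(matrix = contact_matrix(counts, chrom, cfg$resolution),
                   tads = tads, loops = loops, expected = e, config = cfg),
              class = "hic_simulation")
  })
}

#' Down-sample reads by binomial thinning
#'
#' Emulates shallow sequencing: each read pair is retained independently with
#' probability `rate`, implemented as a `Binomial(c, rate)` draw per
#' upper-triangle entry (identical in distribution to thinning an explicit
#' read list), then mirrored to keep symmetry. The diagonal is thinned like
#' any other entry.
#'
#' @param m A [contact_matrix()] with integer counts.
#' @param rate Retention fraction in (0, 1]; e.g. `1/16` emulates 16-fold
#'   shallower sequencing.
#' @param seed RNG seed.
#' @return A [contact_matrix()] of thinned integer counts.
#' @export
downsample_reads <- function(m, rate, seed = 1) {
  stopifnot(is_contact_matrix(m))
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0 || rate > 1)
    stop("`rate` must be a fraction in (0, 1]")
  if (!is_integer_counts(m$counts))
    stop("down-sampling is defined on integer read counts")
  if (rate == 1) return(m)
  nb <- n_bins(m)
  with_seed(seed, {
    up <- which(upper.tri(m$counts, diag = TRUE))
    thin <- matrix(0, nb, nb)
    thin[up] <- stats::rbinom(length(up), size = round(m$counts[up]),
                              prob = rate)
    thin <- thin + t(thin) - diag(diag(thin), nb)
    contact_matrix(thin, m$chrom, m$resolution)
  })
}
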