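#' Image-quality metrics between matrix pairs
#'
#' `hic_mse()` is the mean squared error `mean((H - S)^2)`; `hic_psnr()` is
#' the peak signal-to-noise ratio `10 * log10(MAX^2 / MSE)` with `MAX` the
#' largest value of the ground truth `H` (`Inf` when `S == H`); `hic_ssim()`
#' is the structural similarity index evaluated as a single global window:
#' \deqn{SSIM = \frac{(2\mu_H\mu_S + (c_1 R)^2)(2\sigma_{HS} + (c_2 R)^2)}
#'  {(\mu_H^2 + \mu_S^2 + (c_1 R)^2)(\sigma_H^2 + \sigma_S^2 + (c_2 R)^2)}}
#' with `c1 = 0.01`, `c2 = 0.03` and `R` the dynamic range (default
#' `max(H) - min(H)`). Means, variances and the covariance are population
#' moments over all entries. A sliding-window mean is available via
#' `window` for cross-tool comparison.
#'
#' @param H Ground-truth matrix.
#' @param S Compared matrix of the same shape.
#' @param dynamic_range Dynamic range `R`; defaults to `max(H) - min(H)`.
#'   Required when both matrices are constant.
#' @param c1,c2 SSIM stabilizing constants.
#' @param window `NULL` for the global formula (default); an odd integer side
#'   length for a uniform sliding-window mean SSIM.
#' @return A scalar.
#' @export
hic_mse <- function(H, S) {
  if (!identical(dim(H), dim(S))) stop("shape mismatch")
  mean((H - S)^2)
}

#' @rdname hic_mse
#' @export
hic_psnr <- function(H, S) {
  if (!identical(dim(H), dim(S))) stop("shape mismatch")
  mx <- max(H)
  if (mx <= 0) stop("PSNR undefined: max(H) must be positive")
  m <- hic_mse(H, S)
  if (m == 0) return(Inf)
  10 * log10(mx^2 / m)
}

#' @rdname hic_mse
#' @export
hic_ssim <- function(H, S, dynamic_range = NULL, c1 = 0.01, c2 = 0.03,
                     window = NULL) {
  if (!identical(dim(H), dim(S))) stop("shape mismatch")
  if (is.null(dynamic_range)) {
    dynamic_range <- max(H) - min(H)
    if (dynamic_range == 0)
      stop("constant H: supply `dynamic_range` explicitly")
  }
  C1 <- (c1 * dynamic_range)^2
  C2 <- (c2 * dynamic_range)^2
  if (is.null(window)) {
    mu_h <- mean(H); mu_s <- mean(S)
    var_h <- mean((H - mu_h)^2)
    var_s <- mean((S - mu_s)^2)
    cov_hs <- mean((H - mu_h) * (S - mu_s))
    return(((2 * mu_h * mu_s + C1) * (2 * cov_hs + C2)) /
             ((mu_h^2 + mu_s^2 + C1) * (var_h + var_s + C2)))
  }
  if (window %% 2 != 1 || window < 3) stop("window must be an odd integer >= 3")
  r <- (window - 1) / 2
  n <- nrow(H)
  if (n < window) stop("matrix smaller than the SSIM window")
  vals <- numeric(0)
  box <- function(M, i, j) M[(i - r):(i + r), (j - r):(j + r)]
  for (i in (1 + r):(n - r)) for (j in (1 + r):(n - r)) {
    h <- box(H, i, j); s <- box(S, i, j)
    mu_h <- mean(h); mu_s <- mean(s)
    vals <- c(vals, ((2 * mu_h * mu_s + C1) *
                       (2 * mean((h - mu_h) * (s - mu_s)) + C2)) /
                ((mu_h^2 + mu_s^2 + C1) *
                   (mean((h - mu_h)^2) + mean((s - mu_s)^2) + C2)))
  }
  mean(vals)
}

#' Distance-stratified correlation tracks
#'
#' Groups upper-triangle entries by genomic distance `d = (j - i) *
#' resolution` and computes Pearson and Spearman (mid-rank ties) correlation
#' between the two matrices within each group, for `d` from 0 up to
#' `max_dist_bp`. Groups where either vector has zero variance (or fewer
#' than 2 entries) yield `NA`.
#'
#' @param H,S Same-shape square matrices.
#' @param resolution Bin size in bp.
#' @param max_dist_bp Largest genomic distance included.
#' @return Data frame with `distance_bp`, `n`, `pearson`, `spearman`.
#' @export
correlation_by_distance <- function(H, S, resolution = 10000,
                                    max_dist_bp = 2e6) {
  if (!identical(dim(H), dim(S))) stop("shape mismatch")
  n <- nrow(H)
  dmax <- min(n - 1, floor(max_dist_bp / resolution))
  res <- data.frame(distance_bp = (0:dmax) * resolution,
                    n = NA_integer_, pearson = NA_real_, spearman = NA_real_)
  for (d in 0:dmax) {
    i <- seq_len(n - d)
    idx <- cbind(i, i + d)
    h <- H[idx]; s <- S[idx]
    res$n[d + 1] <- length(h)
    if (length(h) >= 2 && stats::sd(h) > 0 && stats::sd(s) > 0) {
      res$pearson[d + 1] <- stats::cor(h, s)
      res$spearman[d + 1] <- stats::cor(h, s, method = "spearman")
    }
  }
  res
}

#' Full metric report for a matrix pair
#'
#' Bundles MSE, PSNR, global SSIM and the distance-stratified correlation
#' tracks for one (ground truth, compared) pair.
#'
#' @inheritParams correlation_by_distance
#' @param dynamic_range Passed to [hic_ssim()].
#' @return A `metric_report`: list with `mse`, `psnr`, `ssim`, `by_distance`.
#' @export
metric_report <- function(H, S, resolution = 10000, max_dist_bp = 2e6,
                          dynamic_range = NULL) {
  structure(list(mse = hic_mse(H, S), psnr = hic_psnr(H, S),
                 ssim = hic_ssim(H, S, dynamic_range = dynamic_range),
                 by_distance = correlation_by_distance(H, S, resolution,
                                                       max_dist_bp)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> MSE %.4f  PSNR %.3f dB  SSIM %.4f\n",
              x$mse, x$psnr, x$ssim))
  cat(sprintf("  mean Pearson %.4f, mean Spearman %.4f over %d distances\n",
              mean(x$by_distance$pearson, na.rm = TRUE),
              mean(x$by_distance$spearman, na.rm = TRUE),
              nrow(x$by_distance)))
  invisible(x)
}

#' Write a metric report to TSV / JSON
#'
#' @param x A [metric_report()].
#' @param tsv,json Optional output paths.
#' @return `x`, invisibly.
#' @export
write_metric_report <- function(x, tsv = NULL, json = NULL) {
  stopifnot(inherits(x, "metric_report"))
  if (!is.null(tsv)) {
    scalars <- data.frame(metric = c("mse", "psnr", "ssim"),
                          value = c(x$mse, x$psnr, x$ssim))
    utils::write.table(scalars, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(x$by_distance, sub("(\\.tsv)?$", "_by_distance.tsv",
                                          tsv, perl = TRUE)[1],
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(unclass(x), json, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  invisible(x)
}

#' Significant-interaction set
#'
#' A set of significant bin pairs (i < j, unique) with q-values, as produced
#' by a significance caller such as Fit-Hi-C on a (possibly enhanced)
#' contact matrix.
#'
#' @param bin_i,bin_j 0-based bin indices; pairs are stored with `i < j`.
#' @param q Per-pair q-values (optional, default `NA`).
#' @param resolution Bin size in bp.
#' @param label Provenance label.
#' @return An `interaction_set` (data frame with attributes).
#' @export
interaction_set <- function(bin_i, bin_j, q = NA_real_, resolution = 10000,
                            label = "") {
  if (length(bin_i) != length(bin_j)) stop("bin_i and bin_j lengths differ")
  swap <- bin_i > bin_j
  tmp <- bin_i[swap]; bin_i[swap] <- bin_j[swap]; bin_j[swap] <- tmp
  if (any(bin_i == bin_j)) stop("self pairs (i == j) are not interactions")
  df <- data.frame(bin_i = as.integer(bin_i), bin_j = as.integer(bin_j),
                   q = rep_len(as.numeric(q), length(bin_i)))
  dup <- duplicated(df[, c("bin_i", "bin_j")])
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, resolution = resolution, label = label,
            class = c("interaction_set", "data.frame"))
}

#' Filter interactions to a genomic-distance band
#'
#' Keeps pairs with `lo_bp <= (j - i) * resolution <= hi_bp` (bounds
#' inclusive); the default band is 30-300 kb, where loop calls are reliable.
#'
#' @param x An [interaction_set()].
#' @param lo_bp,hi_bp Band bounds in bp.
#' @return The filtered [interaction_set()].
#' @export
band_filter <- function(x, lo_bp = 30000, hi_bp = 300000) {
  stopifnot(inherits(x, "interaction_set"))
  res <- attr(x, "resolution")
  d <- (x$bin_j - x$bin_i) * res
  keep <- d >= lo_bp & d <= hi_bp
  structure(x[keep, , drop = FALSE], resolution = res,
            label = attr(x, "label"),
            class = c("interaction_set", "data.frame"))
}

#' Export interaction pairs as BEDPE
#'
#' Writes one line per pair with both anchor intervals in 0-based half-open
#' coordinates (`chrom start1 end1 chrom start2 end2 q`).
#'
#' @param x An [interaction_set()].
#' @param path Output path.
#' @param chrom Chromosome label for both anchors.
#' @return `path`, invisibly.
#' @export
write_interactions_bedpe <- function(x, path, chrom = "chr1") {
  stopifnot(inherits(x, "interaction_set"))
  res <- attr(x, "resolution")
  df <- data.frame(chrom, x$bin_i * res, (x$bin_i + 1) * res,
                   chrom, x$bin_j * res, (x$bin_j + 1) * res, x$q)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Score recovery of significant interactions
#'
#' Set arithmetic between a truth set (calls on the real high-resolution
#' matrix) and a predicted set (calls on an enhanced matrix):
#' `TP = |truth ∩ predicted|`, `FN = |truth \\ predicted|`,
#' `FP = |predicted \\ truth|`; precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 their harmonic mean, and false-positive rate `FP / |predicted|`
#' (the proportion of predicted calls that are spurious). An empty predicted
#' set gives `NA` precision and F1 = 0.
#'
#' @param truth,predicted [interaction_set()]s over the same chromosome/band.
#' @return List with `tp`, `fn`, `fp`, `precision`, `recall`, `f1`,
#'   `fp_rate`, `n_truth`, `n_predicted`.
#' @export
score_interaction_recovery <- function(truth, predicted) {
  stopifnot(inherits(truth, "interaction_set"),
            inherits(predicted, "interaction_set"))
  key <- function(x) paste(x$bin_i, x$bin_j, sep = ":")
  kt <- key(truth); kp <- key(predicted)
  tp <- sum(kt %in% kp)
  fn <- length(kt) - tp
  fp <- length(kp) - tp
  precision <- if (length(kp) == 0) NA_real_ else tp / (tp + fp)
  recall <- if (length(kt) == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (length(kp) == 0 || is.na(precision) || is.na(recall) ||
            precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  fp_rate <- if (length(kp) == 0) NA_real_ else fp / length(kp)
  list(tp = tp, fn = fn, fp = fp, precision = precision, recall = recall,
       f1 = f1, fp_rate = fp_rate, n_truth = length(kt),
       n_predicted = length(kp))
}
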