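#' Hi-C contact matrix for one chromosome
#'
#' A `contact_matrix` holds one chromosome's symmetric contact-count matrix at
#' a fixed bin resolution. Bin `b` (0-based) covers the genomic interval
#' `[b * resolution, (b + 1) * resolution)` in 0-based half-open coordinates.
#' Raw counts are integers; enhanced matrices may hold non-negative reals.
#'
#' @param counts Square numeric matrix of non-negative contact counts;
#'   must be symmetric within `tol`.
#' @param chrom Chromosome label.
#' @param resolution Bin size in base pairs.
#' @param tol Maximum tolerated absolute asymmetry `|counts - t(counts)|`.
#'
#' @return An object of class `contact_matrix` with fields `counts`, `chrom`,
#'   `resolution`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 3] <- m[3, 1] <- 4
#' cm <- contact_matrix(m, chrom = "chrS1", resolution = 10000)
#' n_bins(cm)
#' @export
contact_matrix <- function(counts, chrom = "chr1", resolution = 10000,
                           tol = 1e-6) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (nrow(counts) != ncol(counts))
    stop("`counts` must be square, got ", nrow(counts), " x ", ncol(counts))
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("`counts` must be finite and non-missing")
  if (any(counts < 0))
    stop("`counts` must be non-negative")
  asym <- max(abs(counts - t(counts)))
  if (asym > tol)
    stop("`counts` is asymmetric beyond tolerance (max |C - t(C)| = ",
         format(asym), ")")
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0)
    stop("`resolution` must be a positive scalar")
  storage.mode(counts) <- "double"
  structure(
    list(counts = counts, chrom = as.character(chrom),
         resolution = as.numeric(resolution)),
    class = "contact_matrix")
}

#' @rdname contact_matrix
#' @param x A `contact_matrix`.
#' @export
n_bins <- function(x) {
  stopifnot(is_contact_matrix(x))
  nrow(x$counts)
}

#' @rdname contact_matrix
#' @export
is_contact_matrix <- function(x) inherits(x, "contact_matrix")

#' @export
print.contact_matrix <- function(x, ...) {
  nb <- n_bins(x)
  cat(sprintf("<contact_matrix> %s: %d bins @ %s bp (%.1f Mb), total %.4g\n",
              x$chrom, nb, format(x$resolution, big.mark = ","),
              nb * x$resolution / 1e6, sum(x$counts)))
  invisible(x)
}

#' @export
dim.contact_matrix <- function(x) dim(x$counts)

# Force exact symmetry; diagonal taken as-is.
symmetrize <- function(counts) (counts + t(counts)) / 2

# TRUE when every count is a whole number (within double rounding)
is_integer_counts <- function(counts, tol = 1e-8) {
  max(abs(counts - round(counts))) <= tol
}
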