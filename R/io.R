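#' Read a sparse triplet contact file
#'
#' Reads whitespace-separated `i j count` triplets (Juicer-dump style, plain
#' or gzipped) into a [contact_matrix()]. Coordinates are either 0-based bin
#' indices or base-pair positions divisible by the resolution; by default the
#' dialect is auto-detected (any coordinate `>= resolution` means bp).
#' Duplicate entries for the same cell are summed. If only the upper triangle
#' is present it is mirrored; if both triangles are present the matrix must
#' already be symmetric.
#'
#' @param path Path to the triplet text file (may be `.gz`).
#' @param chrom Chromosome label to attach.
#' @param resolution Bin size in bp.
#' @param n_bins Number of bins; inferred as `max index + 1` when `NULL`.
#' @param coords Coordinate dialect: `"auto"`, `"bin"`, or `"bp"`.
#' @return A [contact_matrix()].
#' @seealso [write_sparse_contacts()]
#' @export
read_sparse_contacts <- function(path, chrom = "chr1", resolution = 10000,
                                 n_bins = NULL, coords = c("auto", "bin", "bp")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- read_triplet_table(path)
  if (is.null(dt) || nrow(dt) == 0) {
    if (is.null(n_bins))
      stop("empty file and no `n_bins` given: cannot infer matrix size")
    return(contact_matrix(matrix(0, n_bins, n_bins), chrom, resolution))
  }
  if (ncol(dt) < 3) stop("triplet file must have 3 columns: i j count")
  i <- dt[[1]]; j <- dt[[2]]; cnt <- dt[[3]]
  if (any(cnt < 0)) stop("negative counts in ", path)
  if (any(i < 0) || any(j < 0)) stop("negative coordinates in ", path)
  if (coords == "auto")
    coords <- if (any(i >= resolution) || any(j >= resolution)) "bp" else "bin"
  if (coords == "bp") {
    if (any(i %% resolution != 0) || any(j %% resolution != 0))
      stop("bp coordinates not divisible by resolution ", resolution)
    i <- i / resolution
    j <- j / resolution
  }
  if (is.null(n_bins)) n_bins <- max(i, j) + 1
  if (any(i >= n_bins) || any(j >= n_bins))
    stop("bin index >= n_bins (", n_bins, ")")
  sp <- Matrix::sparseMatrix(i = i + 1, j = j + 1, x = cnt,
                             dims = c(n_bins, n_bins))
  m <- as.matrix(sp)
  if (all(m[lower.tri(m)] == 0)) {
    # upper triangle only: mirror it, diagonal as-is
    m <- m + t(m) - diag(diag(m), n_bins)
  } else if (max(abs(m - t(m))) > 1e-6) {
    stop("file contains both triangles but the matrix is not symmetric")
  }
  contact_matrix(m, chrom, resolution)
}

#' Write a contact matrix as sparse triplets
#'
#' Writes the non-zero upper triangle (`i <= j`) as `i j count` lines in the
#' bin-index dialect. Integer matrices round-trip exactly through
#' [read_sparse_contacts()].
#'
#' @param m A [contact_matrix()].
#' @param path Output path; a `.gz` suffix writes gzipped text.
#' @param coords `"bin"` for 0-based bin indices, `"bp"` for bin-start
#'   positions in base pairs.
#' @return `path`, invisibly.
#' @export
write_sparse_contacts <- function(m, path, coords = c("bin", "bp")) {
  stopifnot(is_contact_matrix(m))
  coords <- match.arg(coords)
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0, arr.ind = TRUE)
  i <- idx[, 1] - 1
  j <- idx[, 2] - 1
  if (coords == "bp") {
    i <- i * m$resolution
    j <- j * m$resolution
  }
  cnt <- m$counts[idx]
  cnt_chr <- ifelse(cnt == round(cnt), format(cnt, scientific = FALSE,
                                              trim = TRUE),
                    sprintf("%.10g", cnt))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (length(i))
    writeLines(paste(i, j, cnt_chr, sep = "\t"), con)
  else
    writeLines(character(0), con)
  invisible(path)
}

# whitespace-separated numeric triplets; NULL for an empty file (connections
# decompress .gz transparently)
read_triplet_table <- function(path) {
  tryCatch(utils::read.table(path, header = FALSE, colClasses = "numeric"),
           error = function(e) {
             if (grepl("no lines available", conditionMessage(e))) NULL
             else stop(e)
           })
}

#' Dense binary container read/write
#'
#' Stores a [contact_matrix()] losslessly (float64 counts plus `chrom` and
#' `resolution` metadata) in a single-object binary file. Symmetry and
#' non-negativity are re-validated on read.
#'
#' @param m A [contact_matrix()].
#' @param path File path.
#' @return `write_dense()` returns `path` invisibly; `read_dense()` returns
#'   the [contact_matrix()].
#' @export
write_dense <- function(m, path) {
  stopifnot(is_contact_matrix(m))
  saveRDS(list(chrom = m$chrom, resolution = m$resolution, counts = m$counts),
          path)
  invisible(path)
}

#' @rdname write_dense
#' @export
read_dense <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !all(c("chrom", "resolution", "counts") %in% names(obj)))
    stop("not a dense contact-matrix container: ", path)
  contact_matrix(obj$counts, obj$chrom, obj$resolution)
}

#' Matrix Market interchange
#'
#' Reads/writes the upper triangle in MatrixMarket coordinate format for
#' interoperability with external tooling. MTX carries no genomic metadata, so
#' `chrom` and `resolution` must be supplied on read.
#'
#' @param m A [contact_matrix()].
#' @param path File path (`.mtx`).
#' @param chrom,resolution Metadata to attach on read.
#' @return `write_mtx()` returns `path` invisibly; `read_mtx()` a
#'   [contact_matrix()].
#' @export
write_mtx <- function(m, path) {
  stopifnot(is_contact_matrix(m))
  sp <- methods::as(Matrix::forceSymmetric(Matrix::Matrix(m$counts,
                                                          sparse = TRUE), "U"),
                    "symmetricMatrix")
  Matrix::writeMM(sp, path)
  invisible(path)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(path, chrom = "chr1", resolution = 10000) {
  sp <- Matrix::readMM(path)
  contact_matrix(as.matrix(sp), chrom, resolution)
}

#' Export a matrix in Fit-Hi-C input format
#'
#' Writes the two gzipped input files Fit-Hi-C expects: an interactions file
#' (one line per non-zero upper-triangle pair: `chrom mid1 chrom mid2 count`)
#' and a fragments file (one line per bin: `chrom 0 mid marginalCount 1`).
#' Midpoints are `bin_start + resolution/2` in 0-based bp; counts are rounded
#' to integers. The marginal of bin `b` is its row sum.
#'
#' @param m A [contact_matrix()].
#' @param interactions_path,fragments_path Output paths (gzip written when the
#'   path ends in `.gz`).
#' @return A list with the two paths, invisibly.
#' @export
export_fithic <- function(m, interactions_path, fragments_path) {
  stopifnot(is_contact_matrix(m))
  res <- m$resolution
  half <- res / 2
  idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
               arr.ind = TRUE)
  mid1 <- (idx[, 1] - 1) * res + half
  mid2 <- (idx[, 2] - 1) * res + half
  cnt <- round(m$counts[idx])
  con <- if (grepl("\\.gz$", interactions_path))
    gzfile(interactions_path, "w") else file(interactions_path, "w")
  writeLines(paste(m$chrom, format(mid1, scientific = FALSE, trim = TRUE),
                   m$chrom, format(mid2, scientific = FALSE, trim = TRUE),
                   cnt, sep = "\t"), con)
  close(con)
  marg <- rowSums(m$counts)
  mids <- (seq_len(n_bins(m)) - 1) * res + half
  con <- if (grepl("\\.gz$", fragments_path))
    gzfile(fragments_path, "w") else file(fragments_path, "w")
  writeLines(paste(m$chrom, 0, format(mids, scientific = FALSE, trim = TRUE),
                   round(marg), 1, sep = "\t"), con)
  close(con)
  invisible(list(interactions = interactions_path, fragments = fragments_path))
}

#' Read significant interactions from Fit-Hi-C output
#'
#' Parses a Fit-Hi-C significance table (columns `chr1 fragmentMid1 chr2
#' fragmentMid2 contactCount p_value q_value`, with or without a header),
#' keeps intra-chromosomal calls with `q_value < q_threshold`, and maps
#' fragment midpoints back to 0-based bins.
#'
#' @param path Fit-Hi-C output file (may be gzipped).
#' @param resolution Bin size in bp used when the file was produced.
#' @param q_threshold Keep calls with q-value strictly below this.
#' @param label Provenance label for the resulting set.
#' @return An [interaction_set()].
#' @export
read_fithic_interactions <- function(path, resolution = 10000,
                                     q_threshold = 1e-6, label = "fithic") {
  # skip a header line when the midpoint column is not numeric
  first <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
  skip <- if (length(first) >= 2 &&
              is.na(suppressWarnings(as.numeric(first[2])))) 1 else 0
  dt <- utils::read.table(path, header = FALSE, skip = skip,
                          stringsAsFactors = FALSE)
  if (ncol(dt) < 7) stop("expected >= 7 Fit-Hi-C columns in ", path)
  keep <- dt[[1]] == dt[[3]] & dt[[7]] < q_threshold
  dt <- dt[keep, , drop = FALSE]
  interaction_set(bin_i = floor(dt[[2]] / resolution),
                  bin_j = floor(dt[[4]] / resolution),
                  q = dt[[7]], resolution = resolution, label = label)
}
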