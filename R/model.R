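#' Network architecture specification
#'
#' The enhancement network is a 10-layer fully convolutional residual net on
#' single-channel matrices. Layer 1 is a 3x3 vanilla convolution (encoding);
#' layers 2-9 are 3x3 dilated convolutions; layer 10 is a 1x1 vanilla
#' convolution producing the residual map, which the merge step adds back to
#' the input. Residual skips connect layer 1 + layer 3 (encoding), layers
#' 4+5 and 6+7 (the two residual components of the mapping module). ReLU
#' follows layers 1-9; the final 1x1 layer is linear so the residual can
#' lower as well as raise counts.
#'
#' All convolutions are zero-padded to "same" size, so the operator applies
#' to inputs of any side length.
#'
#' @param channels Output channels per layer; the residual skips require
#'   `channels[1] == channels[3]`, `channels[4] == channels[5]`,
#'   `channels[6] == channels[7]`, and the last layer must emit 1 channel.
#' @param dilation_rate Dilation applied to layers 2-9 (grid of interest:
#'   2, 5, 7, 9).
#' @param kernels Kernel sizes per layer (only 3 and 1 supported).
#' @return A `hic_model_spec`.
#' @examples
#' spec <- model_spec()
#' model_parameter_count(spec)
#' receptive_field_radius(spec)
#' @export
model_spec <- function(channels = c(32, 32, 32, 64, 64, 128, 128, 256, 256, 1),
                       dilation_rate = 2,
                       kernels = c(rep(3, 9), 1)) {
  if (length(channels) != 10) stop("the network has exactly 10 layers")
  if (length(kernels) != 10 || !all(kernels %in% c(1, 3)))
    stop("kernels must be length 10 with entries 1 or 3")
  if (dilation_rate < 1) stop("dilation_rate must be >= 1")
  if (channels[1] != channels[3])
    stop("encoding skip needs channels[1] == channels[3]")
  if (channels[4] != channels[5] || channels[6] != channels[7])
    stop("residual components need channels[4]==channels[5] and ",
         "channels[6]==channels[7]")
  if (channels[10] != 1) stop("final layer must emit 1 channel")
  dilations <- c(1, rep(dilation_rate, 8), 1)
  structure(list(channels = as.integer(channels),
                 kernels = as.integer(kernels),
                 dilations = as.integer(dilations),
                 dilation_rate = as.integer(dilation_rate)),
            class = "hic_model_spec")
}

#' Replace dilated convolutions with vanilla ones
#'
#' Ablation helper: returns the spec with dilation 1 everywhere, layer count
#' and channels unchanged. Weight shapes (and hence the parameter count) are
#' unaffected; only the receptive field shrinks.
#'
#' @param spec A [model_spec()].
#' @return A [model_spec()] with `dilation_rate = 1`.
#' @export
swap_to_vanilla <- function(spec) {
  stopifnot(inherits(spec, "hic_model_spec"))
  model_spec(channels = spec$channels, dilation_rate = 1,
             kernels = spec$kernels)
}

# input channels per layer, following the residual topology
layer_in_channels <- function(spec) {
  ch <- spec$channels
  c(1, ch[1], ch[2], ch[3], ch[4], ch[5], ch[6], ch[7], ch[8], ch[9])
}

#' Trainable parameter count
#'
#' Sum over layers of `k^2 * c_in * c_out + c_out`.
#'
#' @param spec A [model_spec()].
#' @return Integer parameter count (1,181,185 for the default spec).
#' @export
model_parameter_count <- function(spec) {
  stopifnot(inherits(spec, "hic_model_spec"))
  cin <- layer_in_channels(spec)
  sum(spec$kernels^2 * cin * spec$channels + spec$channels)
}

#' Receptive-field radius
#'
#' Radius (in matrix entries) of the input region influencing one output
#' entry: `sum(dilation * (kernel - 1) / 2)` over layers. 17 for the default
#' dilation-2 spec; 9 after [swap_to_vanilla()].
#'
#' @param spec A [model_spec()].
#' @return Integer radius.
#' @export
receptive_field_radius <- function(spec) {
  stopifnot(inherits(spec, "hic_model_spec"))
  sum(spec$dilations * (spec$kernels - 1) / 2)
}

#' Build an initialized model
#'
#' Allocates per-layer weight tensors (dim `k x k x c_in x c_out`) and zero
#' biases. Weights are He-style fan-in truncated normals
#' (`sd = sqrt(2 / (k^2 c_in))`, truncated at 2 sd), deterministic under
#' `seed`.
#'
#' @param spec A [model_spec()].
#' @param seed RNG seed for the initialization.
#' @return A `hic_model`: list with `spec`, `weights`, `biases`, and `meta`
#'   (training metadata: `epoch`, `val_mae`).
#' @export
build_model <- function(spec = model_spec(), seed = 1) {
  stopifnot(inherits(spec, "hic_model_spec"))
  cin <- layer_in_channels(spec)
  with_seed(seed, {
    weights <- vector("list", 10)
    biases <- vector("list", 10)
    for (l in 1:10) {
      k <- spec$kernels[l]
      n <- k * k * cin[l] * spec$channels[l]
      sd <- sqrt(2 / (k * k * cin[l]))
      weights[[l]] <- array(rtruncnorm(n, sd = sd, trunc = 2 * sd),
                            dim = c(k, k, cin[l], spec$channels[l]))
      biases[[l]] <- numeric(spec$channels[l])
    }
    structure(list(spec = spec, weights = weights, biases = biases,
                   meta = list(epoch = 0L, val_mae = NA_real_)),
              class = "hic_model")
  })
}

# truncated normal by resampling draws outside +/- trunc
rtruncnorm <- function(n, sd, trunc) {
  x <- stats::rnorm(n, sd = sd)
  bad <- which(abs(x) > trunc)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), sd = sd)
    bad <- bad[abs(x[bad]) > trunc]
  }
  x
}

#' Build a model with all parameters zero
#'
#' With zero weights the residual map is zero, so the forward pass is exactly
#' the identity -- useful as a reference point.
#'
#' @param spec A [model_spec()].
#' @return A `hic_model`.
#' @export
build_zero_model <- function(spec = model_spec()) {
  m <- build_model(spec, seed = 1)
  m$weights <- lapply(m$weights, function(w) array(0, dim = dim(w)))
  m
}

#' Forward pass
#'
#' Applies the network to a matrix of any side length (or a `n x n x B`
#' batch): `S = residual_map(L) + L`. The raw output is returned without
#' symmetrization or clamping; see [enhance()] for the contact-matrix
#' boundary.
#'
#' @param model A `hic_model`.
#' @param L Numeric matrix (any size) or 3-d array batch; entries must be
#'   finite.
#' @return Matrix/array of the same shape.
#' @export
forward <- function(model, L) {
  stopifnot(inherits(model, "hic_model"))
  if (is.matrix(L)) {
    dim_in <- dim(L)
  } else if (is.array(L) && length(dim(L)) == 3) {
    dim_in <- dim(L)
  } else stop("L must be a matrix or a 3-d array")
  if (anyNA(L) || any(!is.finite(L))) stop("L must be finite")
  fm <- cpp_dfcn_fm(L, model$weights, model$biases, model$spec$kernels,
                    model$spec$dilations)
  out <- L + fm
  dim(out) <- dim_in
  out
}

#' Layer table of a model spec
#'
#' @param spec A [model_spec()].
#' @return Data frame with one row per layer: kernel, dilation, in/out
#'   channels, parameter count.
#' @export
model_summary <- function(spec = model_spec()) {
  stopifnot(inherits(spec, "hic_model_spec"))
  cin <- layer_in_channels(spec)
  data.frame(layer = 1:10,
             kernel = spec$kernels,
             dilation = spec$dilations,
             c_in = cin,
             c_out = spec$channels,
             params = spec$kernels^2 * cin * spec$channels + spec$channels)
}

#' @export
print.hic_model_spec <- function(x, ...) {
  cat("<hic_model_spec> 10-layer dilated fully convolutional network\n")
  print(model_summary(x))
  cat(sprintf("total params %s; receptive-field radius %d\n",
              format(model_parameter_count(x), big.mark = ","),
              receptive_field_radius(x)))
  invisible(x)
}

#' @export
print.hic_model <- function(x, ...) {
  cat(sprintf("<hic_model> %s params, epoch %d, val MAE %s\n",
              format(model_parameter_count(x$spec), big.mark = ","),
              x$meta$epoch,
              ifelse(is.na(x$meta$val_mae), "-",
                     format(x$meta$val_mae, digits = 6))))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the spec, all weights and biases, and training
#' metadata; reloading reproduces the model bit-exactly.
#'
#' @param model A `hic_model`.
#' @param path Checkpoint file path.
#' @return `save_model()` returns `path` invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "hic_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "hic_model")) stop("not a model checkpoint: ", path)
  m
}
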