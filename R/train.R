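#' Training configuration
#'
#' Defaults follow the published schedule: Adam with learning rate 1e-4,
#' batch size 128, 500 epochs, checkpointing on the best validation MAE.
#' Desk-scale runs lower `epochs` and `batch_size`; everything else is
#' typically left alone. No learning-rate schedule, weight decay, or early
#' stopping is applied.
#'
#' @param batch_size Mini-batch size (>= 1). The final partial batch of an
#'   epoch is kept unless it has fewer than 2 patches.
#' @param epochs Number of epochs.
#' @param learning_rate Adam step size.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabilizer
#'   (conventional defaults).
#' @param seed RNG seed for shuffling.
#' @return A `train_config`.
#' @export
train_config <- function(batch_size = 128, epochs = 500,
                         learning_rate = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8, seed = 1) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be non-negative")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, seed = seed),
            class = "train_config")
}

#' Mean absolute error
#'
#' The training loss: `mean(|H - S|)` pooled over every entry (and over the
#' batch, for 3-d arrays).
#'
#' @param S Prediction matrix/array.
#' @param H Target matrix/array of the same shape.
#' @return Non-negative scalar; 0 iff `S == H`.
#' @export
mae_loss <- function(S, H) {
  if (!identical(dim(S), dim(H))) stop("shape mismatch")
  mean(abs(H - S))
}

#' Train the enhancement network
#'
#' Runs epochs of shuffled mini-batches of (low, high) patch pairs,
#' minimizing the pooled mean absolute error with Adam. After every epoch the
#' MAE on the validation patches is computed and the best-so-far weights are
#' retained; the returned model is the one attaining the minimal validation
#' MAE.
#'
#' @param model A `hic_model` from [build_model()].
#' @param train_patches,val_patches Non-empty `patch_set`s.
#' @param cfg A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpoint; `meta` records its epoch and
#'   validation MAE), `history` (data frame `epoch`, `train_loss`,
#'   `val_mae`), and `best_epoch`.
#' @export
train_model <- function(model, train_patches, val_patches,
                        cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "hic_model"),
            inherits(train_patches, "patch_set"),
            inherits(val_patches, "patch_set"))
  n <- length(train_patches)
  if (n < 1 || length(val_patches) < 1)
    stop("training and validation patch sets must be non-empty")
  spec <- model$spec
  w <- model$weights
  b <- model$biases
  mw <- lapply(w, function(x) array(0, dim(x)))
  vw <- lapply(w, function(x) array(0, dim(x)))
  mb <- lapply(b, function(x) numeric(length(x)))
  vb <- lapply(b, function(x) numeric(length(x)))
  step <- 0L
  lr <- cfg$learning_rate; b1 <- cfg$beta1; b2 <- cfg$beta2; eps <- cfg$epsilon

  history <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                        val_mae = NA_real_)
  best <- list(val = Inf, epoch = NA_integer_, w = w, b = b)

  val_mae_of <- function(w, b) {
    fm <- cpp_dfcn_fm(val_patches$lr, w, b, spec$kernels, spec$dilations)
    mean(abs(val_patches$hr - (val_patches$lr + fm)))
  }

  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      loss_sum <- 0; n_seen <- 0
      for (s in starts) {
        ids <- perm[s:min(s + cfg$batch_size - 1, n)]
        if (length(ids) < 2 && length(starts) > 1) next
        x <- train_patches$lr[, , ids, drop = FALSE]
        h <- train_patches$hr[, , ids, drop = FALSE]
        g <- cpp_dfcn_loss_grad(x, h, w, b, spec$kernels, spec$dilations)
        if (!is.finite(g$loss))
          stop("training diverged: non-finite loss at epoch ", epoch)
        step <- step + 1L
        c1 <- 1 - b1^step; c2 <- 1 - b2^step
        for (l in 1:10) {
          mw[[l]] <- b1 * mw[[l]] + (1 - b1) * g$gw[[l]]
          vw[[l]] <- b2 * vw[[l]] + (1 - b2) * g$gw[[l]]^2
          w[[l]] <- w[[l]] - lr * (mw[[l]] / c1) / (sqrt(vw[[l]] / c2) + eps)
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$gb[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$gb[[l]]^2
          b[[l]] <- b[[l]] - lr * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
        }
        loss_sum <- loss_sum + g$loss * length(ids)
        n_seen <- n_seen + length(ids)
      }
      history$train_loss[epoch] <- loss_sum / n_seen
      vm <- val_mae_of(w, b)
      history$val_mae[epoch] <- vm
      if (vm < best$val) best <- list(val = vm, epoch = epoch, w = w, b = b)
      if (verbose)
        message(sprintf("epoch %3d  train MAE %.5f  val MAE %.5f%s", epoch,
                        history$train_loss[epoch], vm,
                        ifelse(best$epoch == epoch, "  *", "")))
    }
  })

  out <- model
  out$weights <- best$w
  out$biases <- best$b
  out$meta <- list(epoch = best$epoch, val_mae = best$val)
  list(model = out, history = history, best_epoch = best$epoch)
}

#' Enhance a whole chromosome matrix
#'
#' Runs a single forward pass over the full matrix (no tiling -- the network
#' is fully convolutional), then applies the contact-matrix boundary
#' post-processing: symmetrize as `(S + t(S)) / 2` and clamp negatives to 0.
#' Metadata (chromosome, resolution) is preserved.
#'
#' @param model A `hic_model`.
#' @param lr_matrix Low-resolution [contact_matrix()] of any size.
#' @return The enhanced [contact_matrix()].
#' @export
enhance <- function(model, lr_matrix) {
  stopifnot(inherits(model, "hic_model"), is_contact_matrix(lr_matrix))
  S <- forward(model, lr_matrix$counts)
  S <- (S + t(S)) / 2
  S[S < 0] <- 0
  contact_matrix(S, lr_matrix$chrom, lr_matrix$resolution)
}
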