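# Model parameters, training configuration, noise distribution and
# checkpointing for the GRU-cooperation-attention sequence model.

#' Training configuration
#'
#' Defaults follow the published setup: hidden width 256, 2 GRU layers,
#' batch 512, learning rate 0.003 (Adam). The number of negative samples and
#' the noise exponent are unreported there; k = 10 and beta = 1 (probability
#' proportional to raw corpus frequency) are the package defaults, with
#' beta = 0.75 the common alternative.
#'
#' @param hidden embedding/hidden width d.
#' @param layers number of stacked GRU layers L.
#' @param batch_size sequences per optimization step.
#' @param learning_rate Adam step size.
#' @param negatives k, negative samples per position.
#' @param noise_exponent beta; noise probability is frequency^beta.
#' @param epochs training epochs.
#' @param seed integer seed for initialization, shuffling and sampling.
#' @param biased_walk if `FALSE` the pipeline samples walks with `alpha = 0`
#'   (plain single-network random walk); ablation switch.
#' @param cooperation enable the cooperation transform (re-injection of the
#'   current token embedding into the hidden state); ablation switch.
#' @param attention enable attention over the within-walk hidden-state
#'   history; ablation switch.
#' @return object of class `training_config`.
#' @export
training_config <- function(hidden = 256L, layers = 2L, batch_size = 512L,
                            learning_rate = 0.003, negatives = 10L,
                            noise_exponent = 1, epochs = 10L, seed = 1L,
                            biased_walk = TRUE, cooperation = TRUE,
                            attention = TRUE) {
  hidden <- as.integer(hidden); layers <- as.integer(layers)
  batch_size <- as.integer(batch_size); negatives <- as.integer(negatives)
  epochs <- as.integer(epochs)
  if (hidden < 1L || layers < 1L || batch_size < 1L) {
    stopf("hidden, layers and batch_size must be positive")
  }
  if (negatives < 0L) stopf("negatives must be >= 0")
  if (epochs < 0L) stopf("epochs must be >= 0")
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (noise_exponent < 0) stopf("noise_exponent must be >= 0")
  structure(list(hidden = hidden, layers = layers, batch_size = batch_size,
                 learning_rate = learning_rate, negatives = negatives,
                 noise_exponent = noise_exponent, epochs = epochs,
                 seed = as.integer(seed),
                 biased_walk = isTRUE(biased_walk),
                 cooperation = isTRUE(cooperation),
                 attention = isTRUE(attention)),
            class = "training_config")
}

#' Frequency-based noise distribution for negative sampling
#'
#' Sampling probability proportional to `freq^beta`, normalized over the
#' vocabulary and supported only on tokens with nonzero frequency.
#'
#' @param vocab a `gcan_vocabulary` (its `freq` column supplies counts).
#' @param beta noise exponent.
#' @return object of class `noise_distribution` with `prob` (length-V vector
#'   summing to 1).
#' @export
noise_distribution <- function(vocab, beta = 1) {
  f <- vocab$tokens$freq
  if (all(f == 0)) stopf("all vocabulary frequencies are zero")
  p <- ifelse(f > 0, f^beta, 0)
  p <- p / sum(p)
  structure(list(prob = p, beta = beta, size = vocab$size),
            class = "noise_distribution")
}

# One uniform(-0.08, 0.08) array, consuming the current RNG stream.
.init_mat <- function(nr, nc = NULL) {
  if (is.null(nc)) {
    stats::runif(nr, -0.08, 0.08)
  } else {
    matrix(stats::runif(nr * nc, -0.08, 0.08), nr, nc)
  }
}

#' Initialize model parameters
#'
#' All weights are drawn uniform(-0.08, 0.08) under `seed`. Input and output
#' (target/negative) embeddings are tied to the single matrix `E`.
#'
#' @param vocab_size vocabulary size V.
#' @param config a `training_config` (supplies d, L and the seed).
#' @return object of class `gcan_parameters`: list with `E` (V x d), `gru`
#'   (per layer: `Wr,Wz,Wn,Ur,Uz,Un` d x d and `br,bz,bn` length d), `coop`
#'   (`Wh`, `Wx` d x d, `b` length d), `attn` (`Wa` d x d), `out`
#'   (`Wc` d x 2d).
#' @export
init_parameters <- function(vocab_size, config) {
  d <- config$hidden
  with_seed(derive_seed(config$seed, "init"), {
    params <- list(
      E = .init_mat(vocab_size, d),
      gru = lapply(seq_len(config$layers), function(l) {
        list(Wr = .init_mat(d, d), Wz = .init_mat(d, d), Wn = .init_mat(d, d),
             Ur = .init_mat(d, d), Uz = .init_mat(d, d), Un = .init_mat(d, d),
             br = .init_mat(d), bz = .init_mat(d), bn = .init_mat(d))
      }),
      coop = list(Wh = .init_mat(d, d), Wx = .init_mat(d, d), b = .init_mat(d)),
      attn = list(Wa = .init_mat(d, d)),
      out = list(Wc = .init_mat(d, 2L * d))
    )
    class(params) <- "gcan_parameters"
    params
  })
}

# --- nested-parameter functional helpers (shared by Adam and tests) ---

# apply f elementwise across parallel nested parameter structures
pmap_params <- function(f, ...) {
  xs <- list(...)
  x1 <- xs[[1]]
  if (is.numeric(x1)) return(do.call(f, xs))
  out <- x1
  for (i in seq_along(x1)) {
    out[[i]] <- do.call(pmap_params, c(list(f), lapply(xs, `[[`, i)))
  }
  out
}

zeros_like <- function(params) pmap_params(function(x) x * 0, params)

# list of index paths to every numeric leaf
param_paths <- function(p, prefix = list()) {
  if (is.numeric(p)) return(list(prefix))
  out <- list()
  for (i in seq_along(p)) {
    out <- c(out, param_paths(p[[i]], c(prefix, list(i))))
  }
  out
}

param_get <- function(p, path) Reduce(function(acc, i) acc[[i]], path, p)

param_set <- function(p, path, value) {
  if (length(path) == 1) { p[[path[[1]]]] <- value; return(p) }
  p[[path[[1]]]] <- param_set(p[[path[[1]]]], path[-1], value)
  p
}

#' Save a model checkpoint
#'
#' The checkpoint is a versioned single-file archive (RDS) holding the
#' parameters, vocabulary and configuration; `load_checkpoint(save_checkpoint(m))`
#' reproduces every parameter entry exactly.
#'
#' @param model a `gcan_model` from [fit_gcan()].
#' @param path destination file (written atomically).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "gcan_model"))
  obj <- list(format = "gcan-checkpoint", version = 1L,
              params = model$params, vocab = model$vocab,
              config = model$config, loss_history = model$loss_history)
  atomic_write(function(p) saveRDS(obj, p), path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @param vocab optional `gcan_vocabulary` to validate against; a token/index
#'   mismatch is an error.
#' @return a `gcan_model`.
#' @export
load_checkpoint <- function(path, vocab = NULL) {
  obj <- readRDS(path)
  if (!identical(obj$format, "gcan-checkpoint")) {
    stopf("not a gcan checkpoint: %s", path)
  }
  if (!is.null(vocab)) {
    if (!identical(vocab$tokens$token, obj$vocab$tokens$token) ||
        !identical(vocab$tokens$index, obj$vocab$tokens$index)) {
      stopf("checkpoint vocabulary does not match the supplied vocabulary")
    }
  }
  d <- obj$config$hidden
  if (ncol(obj$params$E) != d) {
    stopf("checkpoint parameter width %d does not match config hidden %d",
          ncol(obj$params$E), d)
  }
  if (nrow(obj$params$E) != obj$vocab$size) {
    stopf("checkpoint embedding rows (%d) do not match vocabulary size (%d)",
          nrow(obj$params$E), obj$vocab$size)
  }
  structure(list(params = obj$params, vocab = obj$vocab, config = obj$config,
                 loss_history = obj$loss_history),
            class = "gcan_model")
}

#' @export
print.gcan_model <- function(x, ...) {
  cat(sprintf("<gcan_model> V=%d d=%d L=%d (coop=%s, attn=%s); %d epoch(s) trained\n",
              x$vocab$size, x$config$hidden, x$config$layers,
              x$config$cooperation, x$config$attention,
              length(x$loss_history)))
  invisible(x)
}
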