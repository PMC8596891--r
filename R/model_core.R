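# Single-position building blocks of the sequence model. These are the
# reference forms of the math; the batched trainer in model_train.R computes
# the same quantities over whole batches and is tested against these.

#' Cooperation cell
#'
#' Re-injects the current token embedding into the recurrent state:
#' `h_t = tanh(W_h g_t + W_x x_t + b)`, where `g_t` is the top-layer GRU
#' output at this position. This lets the current node participate directly
#' in prediction instead of only through the gated recurrence.
#'
#' @param x_t token embedding vector (length d).
#' @param g_t top-layer GRU output vector (length d).
#' @param coop list with `Wh`, `Wx` (d x d) and `b` (length d), e.g.
#'   `params$coop`.
#' @return hidden vector `h_t`, elementwise in (-1, 1).
#' @export
cooperation_cell <- function(x_t, g_t, coop) {
  d <- length(x_t)
  if (length(g_t) != d || !all(dim(coop$Wh) == d) || !all(dim(coop$Wx) == d) ||
      length(coop$b) != d) {
    stopf("cooperation_cell: shape mismatch (d = %d)", d)
  }
  as.numeric(tanh(coop$Wh %*% g_t + coop$Wx %*% x_t + coop$b))
}

#' Attention over the within-walk history
#'
#' Scores every earlier hidden vector against the current one with the
#' bilinear form `a_ti = h_t' W_a h_i`, softmax-normalizes the scores, and
#' returns the weighted history sum `c_t = sum_i alpha_ti h_i`. With an empty
#' history (t = 1) the context is the zero vector and the weight vector is
#' empty.
#'
#' @param h_t current hidden vector (length d).
#' @param history matrix with one row per earlier position (`(t-1) x d`), or
#'   `NULL`/0-row for an empty history.
#' @param Wa attention bilinear matrix (d x d).
#' @return list with `weights` (length t-1, nonnegative, sums to 1) and
#'   `context` (length d).
#' @export
attention_context <- function(h_t, history, Wa) {
  d <- length(h_t)
  if (is.null(history) || NROW(history) == 0) {
    return(list(weights = numeric(0), context = numeric(d)))
  }
  history <- matrix(history, ncol = d)
  # scores_i = h_t' Wa h_i = h_i' (Wa' h_t)
  scores <- as.numeric(history %*% crossprod(Wa, h_t))
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  list(weights = w, context = as.numeric(crossprod(history, w)))
}

#' Combine hidden state and attention context into the prediction vector
#'
#' `z_t = W_c [h_t; c_t]`, a linear combiner: the prediction vector feeds a
#' dot-product sampled-softmax objective, and squashing it would bound every
#' score and starve the recurrence of gradient once the output saturates.
#' When the attention mechanism is disabled the layer is bypassed entirely
#' and `z_t = h_t`.
#'
#' @param h_t hidden vector (length d).
#' @param c_t attention context (length d).
#' @param Wc combination matrix (d x 2d).
#' @return prediction vector `z_t` (length d).
#' @export
prediction_vector <- function(h_t, c_t, Wc) {
  d <- length(h_t)
  if (!all(dim(Wc) == c(d, 2L * d))) stopf("prediction_vector: Wc must be d x 2d")
  as.numeric(Wc %*% c(h_t, c_t))
}

#' Negative-sampling loss at one position
#'
#' `loss = -log sigma(z' y) - sum_j log sigma(-z' ybar_j)` with the target
#' vector `y` and the negative vectors `ybar_j` taken as rows of the tied
#' embedding matrix; negatives are drawn from the frequency-based noise
#' distribution. A drawn negative equal to the target is redrawn (its
#' gradient would cancel the positive term, which matters at small
#' vocabulary sizes); negatives passed explicitly are used verbatim, and a
#' degenerate single-token noise support is kept as drawn, with a log
#' message. With `k = 0` the loss reduces to the positive term.
#'
#' @param z prediction vector (length d).
#' @param target_index 0-based vocabulary index of the true next token.
#' @param E embedding matrix (V x d).
#' @param noise a `noise_distribution`.
#' @param k number of negative samples.
#' @param negatives optional 0-based indices of pre-drawn negatives (length
#'   k); if `NULL`, drawn here from the calling RNG state.
#' @return scalar loss (nonnegative, finite) with attribute `"negatives"`
#'   holding the 0-based indices used.
#' @export
negative_sampling_loss <- function(z, target_index, E, noise, k,
                                   negatives = NULL) {
  V <- nrow(E)
  ti <- as.integer(target_index)
  if (ti < 0L || ti >= V) stopf("target index out of vocabulary range")
  if (k > 0 && is.null(negatives)) {
    support <- which(noise$prob > 0)
    if (length(support) == 1L && support == ti + 1L) {
      gcan_log("warn",
               "noise support is the single target token; negatives equal the target")
    }
    negatives <- sample.int(V, k, replace = TRUE, prob = noise$prob) - 1L
    if (length(support) > 1L) {
      # redraw negatives that collide with the target (they cancel the
      # positive term); explicitly supplied negatives are used verbatim
      for (tries in 1:50) {
        bad <- which(negatives == ti)
        if (length(bad) == 0) break
        negatives[bad] <- sample.int(V, length(bad), replace = TRUE,
                                     prob = noise$prob) - 1L
      }
    }
  }
  loss <- -stats::plogis(sum(z * E[ti + 1L, ]), log.p = TRUE)
  if (k > 0) {
    for (j in seq_len(k)) {
      loss <- loss - stats::plogis(-sum(z * E[negatives[j] + 1L, ]), log.p = TRUE)
    }
  }
  structure(loss, negatives = if (k > 0) as.integer(negatives) else integer(0))
}

#' Assemble a padded training batch from walk paths
#'
#' Each walk of n tokens yields n-1 prediction positions: the input at
#' position t is token t and the target is token t+1. Sequences are padded on
#' the right; padded positions are masked out of the loss.
#'
#' @param corpus a `gcan_corpus` (or plain list of token vectors).
#' @param vocab a `gcan_vocabulary`.
#' @return object of class `path_batch`: `inputs` and `targets` (B x S
#'   matrices of 1-based embedding rows, pad = 1), `lengths` (valid input
#'   positions per sequence).
#' @export
path_batch <- function(corpus, vocab) {
  if (length(corpus) == 0) stopf("empty corpus")
  lens <- lengths(corpus)
  if (any(lens < 2L)) stopf("every walk needs at least 2 tokens to form a target")
  B <- length(corpus)
  S <- max(lens) - 1L
  inputs <- matrix(1L, B, S)
  targets <- matrix(1L, B, S)
  for (b in seq_len(B)) {
    idx <- vocab_index(vocab, corpus[[b]]) + 1L
    n <- lens[b] - 1L
    inputs[b, seq_len(n)] <- idx[seq_len(n)]
    targets[b, seq_len(n)] <- idx[1L + seq_len(n)]
  }
  structure(list(inputs = inputs, targets = targets, lengths = lens - 1L),
            class = "path_batch")
}
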