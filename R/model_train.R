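# Batched forward pass, analytic backpropagation and the Adam training loop.
#
# Sequences are processed as B x d matrices per time step. Padding sits at
# the end of each sequence, so padded steps can be computed and simply masked
# out of the loss: they receive zero gradient and propagate zero backwards.
# All math here is checked against the single-position reference functions in
# model_core.R and against central finite differences in the test suite.

.sigmoid <- function(x) stats::plogis(x)

.add_bias <- function(m, b) m + rep(b, each = nrow(m))

# Forward pass over a batch of input positions.
# inputs: B x S matrix of 1-based embedding rows. Returns every intermediate
# needed by the backward pass.
.forward_batch <- function(inputs, params, cooperation = TRUE,
                           attention = TRUE) {
  B <- nrow(inputs); S <- ncol(inputs)
  d <- ncol(params$E); L <- length(params$gru)
  X <- vector("list", S)
  cache <- lapply(seq_len(L), function(l) vector("list", S))
  G <- vector("list", S); Hc <- vector("list", S)
  Alpha <- vector("list", S); Cc <- vector("list", S); Z <- vector("list", S)
  h_prev <- lapply(seq_len(L), function(l) matrix(0, B, d))
  for (t in seq_len(S)) {
    X[[t]] <- params$E[inputs[, t], , drop = FALSE]
    inp <- X[[t]]
    for (l in seq_len(L)) {
      g <- params$gru[[l]]
      hp <- h_prev[[l]]
      r <- .sigmoid(.add_bias(inp %*% g$Wr + hp %*% g$Ur, g$br))
      z <- .sigmoid(.add_bias(inp %*% g$Wz + hp %*% g$Uz, g$bz))
      rh <- r * hp
      n <- tanh(.add_bias(inp %*% g$Wn + rh %*% g$Un, g$bn))
      h <- (1 - z) * n + z * hp
      cache[[l]][[t]] <- list(inp = inp, hp = hp, r = r, z = z, n = n)
      h_prev[[l]] <- h
      inp <- h
    }
    G[[t]] <- inp
    Hc[[t]] <- if (cooperation) {
      tanh(.add_bias(G[[t]] %*% t(params$coop$Wh) + X[[t]] %*% t(params$coop$Wx),
                     params$coop$b))
    } else G[[t]]
    if (attention) {
      if (t == 1L) {
        Cc[[t]] <- matrix(0, B, d)
      } else {
        q <- Hc[[t]] %*% params$attn$Wa             # row i: h_t' Wa
        sc <- matrix(0, B, t - 1L)
        for (i in seq_len(t - 1L)) sc[, i] <- rowSums(q * Hc[[i]])
        sc <- sc - apply(sc, 1L, max)
        a <- exp(sc)
        a <- a / rowSums(a)
        Alpha[[t]] <- a
        ct <- matrix(0, B, d)
        for (i in seq_len(t - 1L)) ct <- ct + a[, i] * Hc[[i]]
        Cc[[t]] <- ct
      }
      Z[[t]] <- cbind(Hc[[t]], Cc[[t]]) %*% t(params$out$Wc)
    } else {
      Z[[t]] <- Hc[[t]]
    }
  }
  list(X = X, cache = cache, G = G, Hc = Hc, Alpha = Alpha, Cc = Cc, Z = Z,
       B = B, S = S, d = d, L = L)
}

#' Run the model forward over a batch of paths
#'
#' Embeds the tokens, runs the stacked GRU, applies the cooperation transform
#' and attention over the within-sequence history (each subject to its flag),
#' and returns the per-position prediction vectors `z_t`. With both flags off
#' the output equals the plain multi-layer GRU hidden states.
#'
#' @param batch a `path_batch`.
#' @param params a `gcan_parameters`.
#' @param cooperation,attention mechanism flags.
#' @return list over positions `t = 1..S` of B x d prediction matrices;
#'   rows beyond a sequence's length are meaningless (masked in training).
#' @export
forward_path <- function(batch, params, cooperation = TRUE, attention = TRUE) {
  fw <- .forward_batch(batch$inputs, params, cooperation, attention)
  fw$Z
}

# Loss and gradients for one batch. negatives: optional list over t of
# B x k matrices of 1-based embedding rows; drawn from `noise` when NULL.
# Returns mean per-position loss, gradients (same structure as params), and
# the negatives used.
.loss_grad_batch <- function(inputs, targets, lens, params, noise, k,
                             cooperation = TRUE, attention = TRUE,
                             negatives = NULL, want_grad = TRUE) {
  fw <- .forward_batch(inputs, params, cooperation, attention)
  B <- fw$B; S <- fw$S; d <- fw$d; L <- fw$L
  valid <- outer(seq_len(B), seq_len(S), function(b, t) t <= lens[b])
  n_pos <- sum(valid)
  if (n_pos == 0) stopf("batch has no valid prediction positions")
  scale <- 1 / n_pos
  draw <- is.null(negatives)
  if (draw && k > 0) {
    V <- nrow(params$E)
    multi_support <- sum(noise$prob > 0) > 1L
    negatives <- lapply(seq_len(S), function(t) {
      m <- matrix(sample.int(V, B * k, replace = TRUE, prob = noise$prob), B, k)
      # a negative equal to its own target cancels the positive signal;
      # redraw collisions (kept as-is if the noise support is one token)
      if (multi_support) {
        for (tries in 1:50) {
          bad <- which(m == targets[, t])
          if (length(bad) == 0) break
          m[bad] <- sample.int(V, length(bad), replace = TRUE, prob = noise$prob)
        }
      }
      m
    })
  }
  loss <- 0
  dZ <- if (want_grad) lapply(seq_len(S), function(t) matrix(0, B, d))
  emb_rows <- list(); emb_grads <- list(); ei <- 0L
  for (t in seq_len(S)) {
    m <- valid[, t]
    if (!any(m)) next
    Y <- params$E[targets[, t], , drop = FALSE]
    s_pos <- rowSums(fw$Z[[t]] * Y)
    loss <- loss - sum(stats::plogis(s_pos[m], log.p = TRUE))
    if (want_grad) {
      co <- -(1 - .sigmoid(s_pos)) * m * scale        # dL/ds_pos, masked
      dZ[[t]] <- dZ[[t]] + co * Y
      ei <- ei + 1L
      emb_rows[[ei]] <- targets[, t]
      emb_grads[[ei]] <- co * fw$Z[[t]]
    }
    if (k > 0) {
      for (j in seq_len(k)) {
        nj <- negatives[[t]][, j]
        Yn <- params$E[nj, , drop = FALSE]
        s_neg <- rowSums(fw$Z[[t]] * Yn)
        loss <- loss - sum(stats::plogis(-s_neg[m], log.p = TRUE))
        if (want_grad) {
          cn <- .sigmoid(s_neg) * m * scale
          dZ[[t]] <- dZ[[t]] + cn * Yn
          ei <- ei + 1L
          emb_rows[[ei]] <- nj
          emb_grads[[ei]] <- cn * fw$Z[[t]]
        }
      }
    }
  }
  loss <- loss * scale
  if (!want_grad) {
    return(list(loss = loss, negatives = negatives))
  }

  grads <- zeros_like(params)
  dHc <- lapply(seq_len(S), function(t) matrix(0, B, d))
  Wa <- params$attn$Wa; Wc <- params$out$Wc
  # --- prediction layer + attention ---
  for (t in seq_len(S)) {
    if (attention) {
      zpre <- dZ[[t]]
      grads$out$Wc <- grads$out$Wc + crossprod(zpre, cbind(fw$Hc[[t]], fw$Cc[[t]]))
      dZC <- zpre %*% Wc
      dHc[[t]] <- dHc[[t]] + dZC[, seq_len(d), drop = FALSE]
      dC <- dZC[, d + seq_len(d), drop = FALSE]
      if (t > 1L) {
        a <- fw$Alpha[[t]]
        da <- matrix(0, B, t - 1L)
        for (i in seq_len(t - 1L)) {
          da[, i] <- rowSums(dC * fw$Hc[[i]])
          dHc[[i]] <- dHc[[i]] + a[, i] * dC
        }
        ds <- a * (da - rowSums(a * da))
        q <- fw$Hc[[t]] %*% Wa
        for (i in seq_len(t - 1L)) {
          dHc[[t]] <- dHc[[t]] + ds[, i] * (fw$Hc[[i]] %*% t(Wa))
          dHc[[i]] <- dHc[[i]] + ds[, i] * q
          grads$attn$Wa <- grads$attn$Wa +
            crossprod(fw$Hc[[t]], ds[, i] * fw$Hc[[i]])
        }
      }
    } else {
      dHc[[t]] <- dHc[[t]] + dZ[[t]]
    }
  }
  # --- cooperation ---
  dG <- vector("list", S)
  dX <- lapply(seq_len(S), function(t) matrix(0, B, d))
  if (cooperation) {
    for (t in seq_len(S)) {
      pre <- dHc[[t]] * (1 - fw$Hc[[t]]^2)
      grads$coop$Wh <- grads$coop$Wh + crossprod(pre, fw$G[[t]])
      grads$coop$Wx <- grads$coop$Wx + crossprod(pre, fw$X[[t]])
      grads$coop$b <- grads$coop$b + colSums(pre)
      dG[[t]] <- pre %*% params$coop$Wh
      dX[[t]] <- dX[[t]] + pre %*% params$coop$Wx
    }
  } else {
    dG <- dHc
  }
  # --- GRU backward through time, top layer down ---
  dTop <- dG
  for (l in rev(seq_len(L))) {
    g <- params$gru[[l]]
    gl <- grads$gru[[l]]
    dInp <- vector("list", S)
    dh_carry <- matrix(0, B, d)
    for (t in rev(seq_len(S))) {
      cc <- fw$cache[[l]][[t]]
      dh <- dTop[[t]] + dh_carry
      dz <- dh * (cc$hp - cc$n)
      dn <- dh * (1 - cc$z)
      dhp <- dh * cc$z
      pn <- dn * (1 - cc$n^2)
      gl$Wn <- gl$Wn + crossprod(cc$inp, pn)
      gl$Un <- gl$Un + crossprod(cc$r * cc$hp, pn)
      gl$bn <- gl$bn + colSums(pn)
      drh <- pn %*% t(g$Un)
      di <- pn %*% t(g$Wn)
      dr <- drh * cc$hp
      dhp <- dhp + drh * cc$r
      pr <- dr * cc$r * (1 - cc$r)
      gl$Wr <- gl$Wr + crossprod(cc$inp, pr)
      gl$Ur <- gl$Ur + crossprod(cc$hp, pr)
      gl$br <- gl$br + colSums(pr)
      di <- di + pr %*% t(g$Wr)
      dhp <- dhp + pr %*% t(g$Ur)
      pz <- dz * cc$z * (1 - cc$z)
      gl$Wz <- gl$Wz + crossprod(cc$inp, pz)
      gl$Uz <- gl$Uz + crossprod(cc$hp, pz)
      gl$bz <- gl$bz + colSums(pz)
      di <- di + pz %*% t(g$Wz)
      dhp <- dhp + pz %*% t(g$Uz)
      dInp[[t]] <- di
      dh_carry <- dhp
    }
    grads$gru[[l]] <- gl
    dTop <- dInp
  }
  for (t in seq_len(S)) dX[[t]] <- dX[[t]] + dTop[[t]]
  # --- embedding gradient: inputs + targets + negatives, aggregated ---
  for (t in seq_len(S)) {
    ei <- ei + 1L
    emb_rows[[ei]] <- inputs[, t]
    emb_grads[[ei]] <- dX[[t]]
  }
  all_rows <- unlist(emb_rows)
  all_grads <- do.call(rbind, emb_grads)
  agg <- rowsum(all_grads, group = all_rows)
  rows <- as.integer(rownames(agg))
  grads$E[rows, ] <- grads$E[rows, , drop = FALSE] + agg
  list(loss = loss, grads = grads, negatives = negatives)
}

#' Fit the sequence model on a walk corpus
#'
#' Trains with the negative-sampling objective and Adam. Deterministic given
#' `config$seed` under single-threaded execution (initialization, shuffling
#' and negative draws all derive from it).
#'
#' @param corpus a `gcan_corpus`.
#' @param network the `bridged_network` the corpus was sampled from (supplies
#'   the vocabulary if `vocab` is `NULL`).
#' @param config a `training_config`.
#' @param vocab optional prebuilt `gcan_vocabulary`; by default built from
#'   the network with corpus frequencies.
#' @return a `gcan_model`: list with `params`, `vocab`, `config`,
#'   `loss_history` (per-epoch mean per-position loss).
#' @export
fit_gcan <- function(corpus, network, config, vocab = NULL) {
  if (length(corpus) == 0) stopf("corpus is empty")
  if (is.null(vocab)) vocab <- build_vocabulary(network, corpus)
  noise <- noise_distribution(vocab, config$noise_exponent)
  params <- init_parameters(vocab$size, config)
  loss_history <- numeric(0)
  if (config$epochs > 0L) {
    full <- path_batch(corpus, vocab)
    B <- nrow(full$inputs)
    adam_m <- zeros_like(params)
    adam_v <- zeros_like(params)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    lr <- config$learning_rate
    with_seed(derive_seed(config$seed, "train"), {
      for (epoch in seq_len(config$epochs)) {
        ord <- sample.int(B)
        starts <- seq(1L, B, by = config$batch_size)
        ep_loss <- 0; ep_pos <- 0L
        for (bi in seq_along(starts)) {
          rows <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, B)]
          lens <- full$lengths[rows]
          S <- max(lens)
          res <- .loss_grad_batch(
            full$inputs[rows, seq_len(S), drop = FALSE],
            full$targets[rows, seq_len(S), drop = FALSE],
            lens, params, noise, config$negatives,
            cooperation = config$cooperation, attention = config$attention)
          if (!is.finite(res$loss)) {
            stopf("non-finite loss at epoch %d, batch %d", epoch, bi)
          }
          npos <- sum(lens)
          ep_loss <- ep_loss + res$loss * npos
          ep_pos <- ep_pos + npos
          step <- step + 1L
          corr <- lr * sqrt(1 - b2^step) / (1 - b1^step)
          adam_m <- pmap_params(function(m, g) b1 * m + (1 - b1) * g,
                                adam_m, res$grads)
          adam_v <- pmap_params(function(v, g) b2 * v + (1 - b2) * g * g,
                                adam_v, res$grads)
          params <- pmap_params(function(p, m, v) p - corr * m / (sqrt(v) + eps),
                                params, adam_m, adam_v)
        }
        loss_history <- c(loss_history, ep_loss / ep_pos)
        gcan_log("debug", "epoch %d/%d mean loss %.5f", epoch, config$epochs,
                 ep_loss / ep_pos)
      }
    })
    class(params) <- "gcan_parameters"
  }
  structure(list(params = params, vocab = vocab, config = config,
                 loss_history = loss_history),
            class = "gcan_model")
}
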