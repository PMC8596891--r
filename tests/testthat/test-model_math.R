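# Oracles for the model math: every mechanism is checked against an
# independently coded reference and, for the full network, against central
# finite differences.

test_that("cooperation cell matches a direct elementwise re-evaluation", {
  d <- 5L
  zero <- list(Wh = matrix(0, d, d), Wx = matrix(0, d, d), b = numeric(d))
  expect_equal(cooperation_cell(runif(d), runif(d), zero), numeric(d))
  ident <- list(Wh = matrix(0, d, d), Wx = diag(d), b = numeric(d))
  expect_equal(cooperation_cell(numeric(d), runif(d), ident), numeric(d))

  set.seed(7)
  for (rep in 1:5) {
    coop <- list(Wh = matrix(rnorm(d * d), d), Wx = matrix(rnorm(d * d), d),
                 b = rnorm(d))
    x <- rnorm(d); g <- rnorm(d)
    # independent oracle: plain elementwise loop
    oracle <- vapply(seq_len(d), function(i) {
      tanh(sum(coop$Wh[i, ] * g) + sum(coop$Wx[i, ] * x) + coop$b[i])
    }, numeric(1))
    got <- cooperation_cell(x, g, coop)
    expect_equal(got, oracle, tolerance = 1e-6)
    expect_true(all(abs(got) < 1))
  }
  expect_error(cooperation_cell(runif(d), runif(d + 1L), zero), "shape")
})

test_that("attention weights and context match a brute-force oracle", {
  d <- 4L
  # singleton history: weight 1 regardless of Wa
  a1 <- attention_context(rnorm(d), matrix(rnorm(d), 1), matrix(rnorm(16), 4))
  expect_equal(a1$weights, 1)
  # zero bilinear matrix: uniform weights
  a2 <- attention_context(rnorm(d), matrix(rnorm(4 * d), 4), matrix(0, d, d))
  expect_equal(a2$weights, rep(0.25, 4))
  # empty history: zero context, empty weights
  a3 <- attention_context(rnorm(d), NULL, matrix(0, d, d))
  expect_equal(a3$context, numeric(d))
  expect_length(a3$weights, 0)

  set.seed(21)
  for (rep in 1:10) {
    Wa <- matrix(rnorm(d * d), d)
    h_t <- rnorm(d)
    hist <- matrix(rnorm(3 * d), 3)
    # brute-force oracle
    sc <- vapply(1:3, function(i) sum(h_t * (Wa %*% hist[i, ])), numeric(1))
    w <- exp(sc) / sum(exp(sc))
    ctx <- colSums(w * hist)
    got <- attention_context(h_t, hist, Wa)
    expect_equal(got$weights, w, tolerance = 1e-6)
    expect_equal(got$context, ctx, tolerance = 1e-6)
    expect_true(all(got$weights >= 0))
    expect_equal(sum(got$weights), 1, tolerance = 1e-9)
  }
})

test_that("prediction vector combines hidden state and context as Wc [h;c]", {
  d <- 4L
  h <- rnorm(d)
  Wc_id <- cbind(diag(d), matrix(0, d, d))
  expect_equal(prediction_vector(h, numeric(d), Wc_id), h)
  set.seed(5)
  for (rep in 1:5) {
    Wc <- matrix(rnorm(d * 2 * d), d)
    cvec <- rnorm(d)
    # independent oracle: explicit sum over the concatenated vector
    oracle <- vapply(seq_len(d), function(i) sum(Wc[i, ] * c(h, cvec)),
                     numeric(1))
    expect_equal(prediction_vector(h, cvec, Wc), oracle, tolerance = 1e-6)
  }
})

test_that("negative-sampling loss has the closed k = 0 form and unrolls exactly", {
  d <- 3L; V <- 6L
  E <- matrix(rnorm(V * d), V)
  vocabish <- list(prob = rep(1 / V, V))
  # orthogonal z: sigma(0) = 1/2 so loss = log 2
  z <- numeric(d)
  l0 <- negative_sampling_loss(z, 2L, E, vocabish, k = 0)
  expect_equal(as.numeric(l0), log(2), tolerance = 1e-8)
  # strongly aligned z: loss -> 0
  zbig <- E[4L + 1L, ] * 100
  expect_lt(as.numeric(negative_sampling_loss(zbig, 4L, E, vocabish, k = 0)),
            1e-8)
  # recorded negatives: hand-unrolled sum
  set.seed(31)
  z <- rnorm(d)
  l2 <- negative_sampling_loss(z, 1L, E, vocabish, k = 2)
  negs <- attr(l2, "negatives")
  expect_length(negs, 2L)
  manual <- -log(plogis(sum(z * E[2, ])))
  for (j in negs) manual <- manual - log(plogis(-sum(z * E[j + 1L, ])))
  expect_equal(as.numeric(l2), manual, tolerance = 1e-6)
  expect_true(is.finite(l2) && l2 >= 0)
})

test_that("batched forward agrees with the single-position reference chain", {
  set.seed(77)
  V <- 9L; d <- 6L
  cfg <- training_config(hidden = d, layers = 2, seed = 8)
  params <- init_parameters(V, cfg)
  toks <- sample.int(V, 5L)
  batch <- structure(list(inputs = matrix(toks[1:4], 1), targets = matrix(toks[2:5], 1),
                          lengths = 4L), class = "path_batch")
  Z <- forward_path(batch, params, cooperation = TRUE, attention = TRUE)
  # reference: run the GRU cell by hand, then the exported single-step ops
  gru_cell <- function(x, hp, g) {
    r <- plogis(as.numeric(t(g$Wr) %*% x + t(g$Ur) %*% hp) + g$br)
    z <- plogis(as.numeric(t(g$Wz) %*% x + t(g$Uz) %*% hp) + g$bz)
    n <- tanh(as.numeric(t(g$Wn) %*% x + t(g$Un) %*% (r * hp)) + g$bn)
    (1 - z) * n + z * hp
  }
  hp <- list(numeric(d), numeric(d))
  Hc <- list()
  for (t in 1:4) {
    x <- params$E[toks[t], ]
    inp <- x
    for (l in 1:2) {
      hp[[l]] <- gru_cell(inp, hp[[l]], params$gru[[l]])
      inp <- hp[[l]]
    }
    Hc[[t]] <- cooperation_cell(x, inp, params$coop)
    hist <- if (t == 1) NULL else do.call(rbind, Hc[seq_len(t - 1)])
    att <- attention_context(Hc[[t]], hist, params$attn$Wa)
    zt <- prediction_vector(Hc[[t]], att$context, params$out$Wc)
    expect_equal(as.numeric(Z[[t]][1, ]), zt, tolerance = 1e-10)
  }
})

test_that("ablation contracts are exact: flags reproduce the simpler model", {
  set.seed(12)
  V <- 8L; d <- 5L
  cfg <- training_config(hidden = d, layers = 2, seed = 4)
  params <- init_parameters(V, cfg)
  inputs <- matrix(sample.int(V, 6L, replace = TRUE), 2L, 3L)
  batch <- structure(list(inputs = inputs, targets = inputs, lengths = c(3L, 3L)),
                     class = "path_batch")
  # attention off: z equals the (cooperation) hidden state exactly
  fw <- gcan:::.forward_batch(inputs, params, cooperation = TRUE, attention = FALSE)
  expect_identical(fw$Z, fw$Hc)
  # both off: z equals the plain top-layer GRU state exactly
  fw0 <- gcan:::.forward_batch(inputs, params, cooperation = FALSE, attention = FALSE)
  expect_identical(fw0$Z, fw0$G)
  # a 3-token path yields 2 prediction positions
  pb <- path_batch(list(c("dA", "r1", "g1")),
                   build_vocabulary(toy_bridged_network()))
  expect_equal(ncol(pb$inputs), 2L)
  expect_equal(pb$lengths, 2L)
})

test_that("analytic gradients match central finite differences (d=4, V=8)", {
  set.seed(42)
  V <- 8L; d <- 4L
  cfg <- training_config(hidden = d, layers = 2, seed = 5)
  params <- init_parameters(V, cfg)
  B <- 3L; S <- 4L
  inputs <- matrix(sample.int(V, B * S, TRUE), B, S)
  targets <- matrix(sample.int(V, B * S, TRUE), B, S)
  lens <- c(4L, 3L, 2L)
  noise <- list(prob = rep(1 / V, V))
  k <- 2L
  negs <- lapply(seq_len(S), function(t) matrix(sample.int(V, B * k, TRUE), B, k))
  for (flags in list(c(TRUE, TRUE), c(TRUE, FALSE), c(FALSE, TRUE))) {
    res <- gcan:::.loss_grad_batch(inputs, targets, lens, params, noise, k,
                                   cooperation = flags[1], attention = flags[2],
                                   negatives = negs)
    lossfun <- function(p) {
      gcan:::.loss_grad_batch(inputs, targets, lens, p, noise, k,
                              cooperation = flags[1], attention = flags[2],
                              negatives = negs, want_grad = FALSE)$loss
    }
    eps <- 1e-5
    worst <- 0
    for (pa in gcan:::param_paths(params)) {
      arr <- gcan:::param_get(params, pa)
      g <- gcan:::param_get(res$grads, pa)
      for (j in seq_along(arr)) {
        a <- arr; a[j] <- a[j] + eps
        lp <- lossfun(gcan:::param_set(params, pa, a))
        a <- arr; a[j] <- a[j] - eps
        lm <- lossfun(gcan:::param_set(params, pa, a))
        gn <- (lp - lm) / (2 * eps)
        # guarded relative error: FD noise dominates entries near zero
        worst <- max(worst, abs(g[j] - gn) / max(1e-6, abs(g[j]) + abs(gn)))
      }
    }
    expect_lt(worst, 1e-4)
  }
})
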