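test_that("candidate sets split into cross (bridge) and within (adjacency)", {
  net <- toy_bridged_network()
  # bridged disease: one father across, two neighbors within
  cs <- candidate_sets(net, "dC", 2)
  expect_equal(cs$cross, "dA")
  expect_equal(sort(cs$within$entity), c("g2", "y1"))
  # a gene is never bridged
  cs2 <- candidate_sets(net, "g1", 1)
  expect_length(cs2$cross, 0)
  expect_equal(sort(cs2$within$entity), c("dA", "dB"))
  expect_error(candidate_sets(net, "nosuch", 1), "nosuch")
})

test_that("step distribution matches exhaustive class-mass enumeration", {
  within2 <- data.frame(relation = c("r", "r"), entity = c("b", "c"),
                        stringsAsFactors = FALSE)
  d1 <- step_distribution(cross = "f", within = within2, alpha = 0.3)
  expect_equal(d1$prob[d1$class == "cross"], 0.3)
  expect_equal(d1$prob[d1$class == "within"], c(0.35, 0.35))

  d2 <- step_distribution("f", data.frame(relation = rep("r", 3),
                                          entity = c("b", "c", "d")), alpha = 0)
  expect_equal(d2$prob[d2$class == "cross"], 0)
  expect_equal(d2$prob[d2$class == "within"], rep(1 / 3, 3))

  d3 <- step_distribution(c("f1", "f2"),
                          data.frame(relation = character(), entity = character()),
                          alpha = 0.5)
  expect_equal(d3$prob, c(0.5, 0.5))

  expect_null(step_distribution(character(),
                                data.frame(relation = character(),
                                           entity = character()), 0.5))

  # brute-force equivalence on the toy graph for several alphas:
  # the per-candidate probability is (class mass) / (class size), with an
  # empty class donating its mass — enumerated here candidate by candidate
  net <- toy_bridged_network()
  for (alpha in c(0, 0.25, 0.5, 1)) {
    for (spec in list(c("dA", 1L), c("dC", 2L), c("g1", 1L), c("x1", 1L))) {
      cs <- candidate_sets(net, spec[1], as.integer(spec[2]))
      dist <- step_distribution(cs$cross, cs$within, alpha)
      n_c <- length(cs$cross); n_w <- nrow(cs$within)
      expected <- numeric(0)
      mass_c <- if (n_c == 0) 0 else if (n_w == 0) 1 else alpha
      for (i in seq_len(n_c)) expected <- c(expected, mass_c / n_c)
      for (i in seq_len(n_w)) expected <- c(expected, (1 - mass_c) / n_w)
      expect_identical(dist$prob, expected)
      expect_equal(sum(dist$prob), 1, tolerance = 1e-12)
      expect_true(all(dist$prob >= 0))
    }
  }
})

test_that("sampled walks alternate tokens, respect depth and bridge semantics", {
  net <- toy_bridged_network()
  cfg <- walk_config(alpha = 0.5, depth_hops = 6, walks_per_entity = 2, seed = 3)
  set.seed(1)
  w <- sample_walk(net, "dA", cfg, 1L)
  expect_true(length(w$tokens) %% 2 == 1)
  expect_lte(length(w$tokens), 2 * cfg$depth_hops + 1)
  # entity positions are entities, relation positions relations or bridge
  v <- build_vocabulary(net)
  kinds <- v$tokens$kind[match(w$tokens, v$tokens$token)]
  expect_true(all(kinds[seq_along(kinds) %% 2 == 1] == "entity"))
  expect_true(all(kinds[seq_along(kinds) %% 2 == 0] != "entity"))
  # consecutive entities are adjacent or bridged
  for (i in seq(1, length(w$tokens) - 2, by = 2)) {
    e1 <- w$tokens[i]; rel <- w$tokens[i + 1]; e2 <- w$tokens[i + 2]
    if (rel == GCAN_BRIDGE_TOKEN) {
      expect_true(e2 %in% c(net$bridge$forward[[e1]], net$bridge$reverse[[e1]]))
    } else {
      nb1 <- net$adjacency[[1]][[e1]]
      nb2 <- net$adjacency[[2]][[e1]]
      expect_true(e2 %in% c(nb1$entity, nb2$entity))
    }
  }

  # alpha = 1 from a bridged disease: first step is always a cross step
  cfg1 <- walk_config(alpha = 1, depth_hops = 3, walks_per_entity = 1, seed = 5)
  for (s in 1:10) {
    set.seed(s)
    w1 <- sample_walk(net, "dA", cfg1, 1L)
    expect_equal(w1$tokens[2], GCAN_BRIDGE_TOKEN)
    expect_equal(w1$tokens[3], "dC")
    expect_equal(w1$networks[2], 2L)
  }

  # depth 1 from a single-neighbor node: exactly 3 tokens
  t1 <- triples("a", "r", "b", 1)
  t2 <- triples("p", "q", "u", 2)
  ty <- entity_types(c(a = "disease", b = "gene", p = "disease", q = "gene",
                       u = "drug"))
  net2 <- build_bridged_network(t1, t2, ty, bridge_map(character(), character()))
  w3 <- sample_walk(net2, "a", walk_config(depth_hops = 1, seed = 1), 1L)
  expect_length(w3$tokens, 3L)

  # determinism: same RNG state, same walk
  set.seed(42); wa <- sample_walk(net, "dC", cfg, 2L)
  set.seed(42); wb <- sample_walk(net, "dC", cfg, 2L)
  expect_identical(wa, wb)
})

test_that("corpus sampling is exhaustive, deterministic and alpha-faithful", {
  net <- fully_bridged_network(4L)
  cfg <- walk_config(alpha = 0.5, depth_hops = 4, walks_per_entity = 3, seed = 9)
  corp <- sample_corpus(net, cfg)
  expect_length(corp, 8L * 3L)   # every entity of both networks
  corp2 <- sample_corpus(net, cfg)
  expect_identical(corp, corp2)

  # alpha = 0: no bridge tokens anywhere
  cfg0 <- walk_config(alpha = 0, depth_hops = 4, walks_per_entity = 3, seed = 9)
  corp0 <- sample_corpus(net, cfg0)
  expect_equal(cross_step_fraction(corp0), 0)

  # alpha = 1 on a graph where every entity is bridged: every step crosses
  cfg1 <- walk_config(alpha = 1, depth_hops = 4, walks_per_entity = 3, seed = 9)
  expect_equal(cross_step_fraction(sample_corpus(net, cfg1)), 1)

  expect_error(cross_step_fraction(structure(list(), class = "gcan_corpus")),
               "empty")
})

test_that("alpha = 0 sampling is distributionally a uniform single-network walk", {
  net <- toy_bridged_network()
  cfg <- walk_config(alpha = 0, depth_hops = 1, walks_per_entity = 1, seed = 1)
  n <- 10000L
  nxt <- character(n)
  set.seed(314)
  for (i in seq_len(n)) nxt[i] <- sample_walk(net, "dA", cfg, 1L)$tokens[3]
  counts <- table(factor(nxt, levels = c("g1", "x1")))
  gof <- stats::chisq.test(counts, p = c(0.5, 0.5))
  expect_gt(gof$p.value, 0.001)
})

test_that("corpus files round-trip through write_corpus/read_corpus", {
  net <- toy_bridged_network()
  corp <- sample_corpus(net, walk_config(depth_hops = 3, walks_per_entity = 2,
                                         seed = 4))
  p <- tempfile()
  write_corpus(corp, p)
  back <- read_corpus(p)
  expect_equal(unclass(back), lapply(unclass(corp), identity))
})
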