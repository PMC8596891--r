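# Shared fixtures: tiny hand-enumerable graphs and writers for TSV inputs.

# Two-network toy graph used for walk-kernel checks.
#   network 1: dA - r1 - g1 - r2 - dB ;  dA - r3 - x1
#   network 2: dC - s1 - g2 ;  dC - s2 - y1
#   bridge: dA <-> dC  (dA is the father of dC)
toy_bridged_network <- function() {
  t1 <- triples(head = c("dA", "g1", "dA"),
                relation = c("r1", "r2", "r3"),
                tail = c("g1", "dB", "x1"), network_id = 1L)
  t2 <- triples(head = c("dC", "dC"),
                relation = c("s1", "s2"),
                tail = c("g2", "y1"), network_id = 2L)
  types <- entity_types(c(dA = "disease", dB = "disease", dC = "disease",
                          g1 = "gene", g2 = "gene", x1 = "drug", y1 = "drug"))
  br <- bridge_map("dA", "dC", t1, t2)
  build_bridged_network(t1, t2, types, br)
}

# A graph where EVERY entity has both candidate classes: two networks with
# mirrored diseases, every node bridged, every node with a within neighbor.
fully_bridged_network <- function(n = 4L) {
  ids1 <- sprintf("u%02d", seq_len(n))
  ids2 <- sprintf("v%02d", seq_len(n))
  ring <- function(ids, rel) {
    triples(head = ids, relation = rel, tail = ids[c(seq_len(n)[-1], 1L)],
            network_id = if (rel == "a") 1L else 2L)
  }
  t1 <- ring(ids1, "a")
  t2 <- ring(ids2, "b")
  types <- entity_types(stats::setNames(rep("disease", 2L * n), c(ids1, ids2)))
  br <- bridge_map(ids1, ids2, t1, t2)
  build_bridged_network(t1, t2, types, br)
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# small trained-model fixture cached across tests (memoized per session)
.fixture_env <- new.env(parent = emptyenv())

fixture_trained_gaucher <- function() {
  if (!is.null(.fixture_env$gaucher)) return(.fixture_env$gaucher)
  bench <- gaucher_fixture()
  net <- benchmark_network(bench)
  wc <- walk_config(alpha = 0.5, depth_hops = 6, walks_per_entity = 8, seed = 401)
  corpus <- sample_corpus(net, wc)
  tc <- training_config(hidden = 32, layers = 2, batch_size = 64,
                        epochs = 120, negatives = 10, seed = 401)
  model <- fit_gcan(corpus, net, tc)
  .fixture_env$gaucher <- list(bench = bench, net = net, corpus = corpus,
                               model = model, walk_cfg = wc, train_cfg = tc)
  .fixture_env$gaucher
}
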